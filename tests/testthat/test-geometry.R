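test_that("read_xyz parses standard files and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0.0 0.0 0.0"), f)
  one <- read_xyz(f)
  expect_identical(one$elements, "C")
  expect_equal(one$coords, matrix(0, 1, 3))

  writeLines(c("x", "", "C 0 0 0"), f)
  expect_error(read_xyz(f), "line 1.*malformed atom count")
  writeLines(c("2", "", "C 0 0 0", "C 1 bad 0"), f)
  expect_error(read_xyz(f), "line 4.*non-numeric")
  writeLines(c("3", "", "C 0 0 0", "C 1 0 0"), f)
  expect_error(read_xyz(f), "3 atoms but only 2")
})

test_that("XYZ round trip preserves elements and coordinates", {
  set.seed(71)
  conf <- conformer(sample(c("C", "N", "O", "H"), 10, replace = TRUE),
                    matrix(rnorm(30, sd = 5), 10, 3))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(conf, f, comment = "random fixture")
  back <- read_xyz(f)
  expect_identical(back$elements, conf$elements)
  expect_lt(max(abs(back$coords - conf$coords)), 1e-6)

  # independent line-by-line parse of the same file
  lines <- readLines(f)
  expect_identical(as.integer(lines[1]), 10L)
  ref <- t(vapply(lines[3:12], function(ln) {
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][2:4])
  }, numeric(3)))
  dimnames(ref) <- NULL
  expect_equal(back$coords, ref)
})

test_that("measure_dihedral honours the planar symmetry cases", {
  cis <- chain4()
  expect_equal(measure_dihedral(cis$conformer, cis$topology, 1), 0)
  trans <- chain4(rbind(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(2, -1, 0)))
  expect_equal(measure_dihedral(trans$conformer, trans$topology, 1), 180)
})

test_that("measure_dihedral agrees with the closed-form torsion oracle", {
  set.seed(12)
  for (i in 1:100) {
    repeat {
      p <- matrix(rnorm(12, sd = 2), 4, 3)
      b2 <- p[3, ] - p[2, ]
      n1 <- rbind(p[2, ] - p[1, ], b2)
      # keep well away from collinearity so both definitions are stable
      ok <- function(a, b) {
        cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1])
        sqrt(sum(cr^2)) > 0.1
      }
      if (ok(p[2, ] - p[1, ], b2) && ok(b2, p[4, ] - p[3, ])) break
    }
    fx <- chain4(p)
    got <- measure_dihedral(fx$conformer, fx$topology, 1)
    want <- reference_torsion(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_lt(min(abs(got - want), 360 - abs(got - want)), 1e-8)
  }
})

test_that("collinear atoms raise an undefined-torsion error", {
  fx <- chain4(rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)))
  expect_error(measure_dihedral(fx$conformer, fx$topology, 1),
               "undefined.*collinear")
})

test_that("set_dihedral hits its target and is an exact rigid-body motion", {
  fx <- chain4()
  # identity: target equals current angle
  cur <- measure_dihedral(fx$conformer, fx$topology, 1)
  same <- set_dihedral(fx$conformer, fx$topology, 1, cur)
  expect_lt(max(abs(same$coords - fx$conformer$coords)), 1e-9)

  set.seed(5)
  for (t in runif(50, -720, 720)) {
    rot <- set_dihedral(fx$conformer, fx$topology, 1, t)
    expect_lt(abs(measure_dihedral(rot, fx$topology, 1) - canonical_angle(t)),
              1e-6)
    # atoms outside the moving set never move
    expect_identical(rot$coords[1:2, ], fx$conformer$coords[1:2, ])
    # rigid fragments keep all internal distances
    for (fr in fx$topology$fragments)
      expect_lt(max(abs(dist(rot$coords[fr, ]) -
                        dist(fx$conformer$coords[fr, ]))), 1e-9)
  }
})

test_that("rotation to 90 degrees matches an explicit axis-angle matrix", {
  # unit geometry: axis along x, atom l at (2, 1, 0)
  fx <- chain4(rbind(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(2, 1, 0)))
  rot <- set_dihedral(fx$conformer, fx$topology, 1, 90)
  theta <- 90 * pi / 180   # the l side turns right-handed about j->k (+x)
  R <- rbind(c(1, 0, 0),
             c(0, cos(theta), -sin(theta)),
             c(0, sin(theta), cos(theta)))
  expect_equal(rot$coords[4, ], drop(R %*% c(2, 1, 0)), tolerance = 1e-9)
})

test_that("set_dihedral is reversible and commutes on tree topologies", {
  fb <- make_fixture_molecule(3, "branched")
  orig <- fb$conformer
  a0 <- measure_configuration(orig, fb$topology)
  there <- set_configuration(orig, fb$topology, c(77, 191, 333))
  back <- set_configuration(there, fb$topology, a0)
  expect_lt(max(abs(back$coords - orig$coords)), 1e-6)

  ab <- set_dihedral(set_dihedral(orig, fb$topology, 1, 40), fb$topology, 2, 250)
  ba <- set_dihedral(set_dihedral(orig, fb$topology, 2, 250), fb$topology, 1, 40)
  expect_lt(max(abs(ab$coords - ba$coords)), 1e-9)
})

test_that("clash detection is strict, brute-force-equivalent and rigid-motion invariant", {
  # two 3-atom fragments; atoms 1 and 6 are >= 4 bonds apart (eligible)
  mk <- function(d16) {
    conf <- conformer(rep("C", 6),
                      rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0),
                            c(4.5, 0, 0), c(6, 0, 0), c(0, d16, 0)))
    top <- dihedral_topology(
      bonds = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6)),
      dihedrals = list(c(2, 3, 4, 5)),
      fragments = list(1:3, 4:6))
    list(conformer = conf, topology = top)
  }
  expect_true(detect_clash(mk(2.0)$conformer, mk(2.0)$topology, 2.1))
  expect_false(detect_clash(mk(2.1)$conformer, mk(2.1)$topology, 2.1))

  fb <- make_fixture_molecule(3, "branched")
  set.seed(31)
  hits <- 0
  for (i in 1:40) {
    conf <- set_configuration(fb$conformer, fb$topology, runif(3, 0, 360))
    got <- detect_clash(conf, fb$topology)
    expect_identical(got, reference_clash(conf, fb$topology))
    hits <- hits + got
    # invariance under a rigid rotation + translation of the whole molecule
    ang <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(ang[1]), -sin(ang[1]), 0),
                c(sin(ang[1]), cos(ang[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[2]), -sin(ang[2])),
                c(0, sin(ang[2]), cos(ang[2])))
    moved <- conf
    moved$coords <- sweep(conf$coords %*% (Rz %*% Rx), 2, rnorm(3, sd = 10), "+")
    expect_identical(detect_clash(moved, fb$topology), got)
  }
  expect_gt(hits, 0)   # the crowded hub fixture does produce clashes
})

test_that("topology construction validates its invariants", {
  bonds <- list(c(1, 2), c(2, 3), c(3, 4))
  expect_error(dihedral_topology(bonds, list(c(1, 2, 4, 3)),
                                 list(c(1, 2), c(3, 4))),
               "not a bond")
  expect_error(dihedral_topology(bonds, list(c(1, 2, 3, 4)),
                                 list(c(1, 2, 3), c(4))),
               "does not connect two rigid fragments")
  expect_error(dihedral_topology(bonds, list(c(1, 2, 3, 4)),
                                 list(c(1, 2), c(3))),
               "do not cover")
  expect_error(dihedral_topology(bonds, list(c(1, 2, 3, 4)),
                                 list(c(1, 2), c(2, 3, 4))),
               "overlap")
})

test_that("topology files round-trip through 0-based YAML", {
  fb <- make_fixture_molecule(4, "branched")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_topology(fb$topology, f)
  back <- read_topology(f)
  expect_identical(back$dihedrals, fb$topology$dihedrals)
  expect_identical(back$moving_sets, fb$topology$moving_sets)
  expect_identical(back$frag_id, fb$topology$frag_id)
  # on-disk indices are 0-based
  y <- yaml::read_yaml(f)
  expect_equal(min(unlist(y$fragments)), 0)
})
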