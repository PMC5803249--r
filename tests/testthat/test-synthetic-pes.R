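test_that("coupling strength zero gives an exactly separable surface", {
  pes <- make_pes(3, coupling_strength = 0, seed = 7)
  set.seed(2)
  a <- matrix(runif(300, 0, 360), ncol = 3)
  one_d <- function(d, ang) {
    cfg <- matrix(0, length(ang), 3)
    cfg[, d] <- ang
    eval_pes(pes, cfg)
  }
  base <- eval_pes(pes, c(0, 0, 0))
  sep <- one_d(1, a[, 1]) + one_d(2, a[, 2]) + one_d(3, a[, 3]) - 2 * base
  expect_equal(eval_pes(pes, a), sep, tolerance = 1e-12)
})

test_that("eval_pes matches an independent term-by-term summation", {
  pes <- make_pes(2, coupling_strength = 1.5, seed = 13)
  set.seed(3)
  a <- matrix(runif(60, 0, 360), ncol = 2)
  manual <- vapply(seq_len(nrow(a)), function(r) {
    e <- -pes$offset
    for (d in 1:2) for (m in seq_len(pes$max_order))
      e <- e + pes$amplitudes[d, m] *
        cos((m * a[r, d] - pes$phases[d, m]) * pi / 180)
    cp <- pes$couplings
    for (q in seq_len(nrow(cp$pairs)))
      e <- e + cp$c[q] *
        cos((cp$m1[q] * a[r, cp$pairs[q, 1]] - cp$p1[q]) * pi / 180) *
        cos((cp$m2[q] * a[r, cp$pairs[q, 2]] - cp$p2[q]) * pi / 180)
    e
  }, numeric(1))
  expect_equal(eval_pes(pes, a), manual, tolerance = 1e-12)
})

test_that("the surface is periodic, reproducible by seed, and zeroable", {
  pes <- make_pes(2, coupling_strength = 1, seed = 5)
  a <- matrix(runif(20, 0, 360), ncol = 2)
  expect_identical(eval_pes(pes, a), eval_pes(pes, a + 360))
  pes_same <- make_pes(2, coupling_strength = 1, seed = 5)
  expect_identical(eval_pes(pes_same, a), eval_pes(pes, a))
  pes_other <- make_pes(2, coupling_strength = 1, seed = 6)
  expect_false(isTRUE(all.equal(pes_other$amplitudes, pes$amplitudes)))

  flat <- pes
  flat$amplitudes[] <- 0
  flat$couplings$c[] <- 0
  flat$offset <- 0
  expect_equal(eval_pes(flat, a), rep(0, nrow(a)))
})

test_that("the energy zero is calibrated: random minima sit in [0 - 1e-6, 0.5]", {
  for (sd in c(1, 2)) {
    pes <- make_pes(3, coupling_strength = 1, seed = sd)
    set.seed(100 + sd)
    m <- min(eval_pes(pes, matrix(runif(1e5 * 3, 0, 360), ncol = 3)))
    expect_gt(m, -1e-6)
    expect_lt(m, 0.5)
  }
})

test_that("amplitude_scale multiplies the whole surface", {
  p1 <- make_pes(3, coupling_strength = 2, seed = 8, amplitude_scale = 1)
  p4 <- make_pes(3, coupling_strength = 2, seed = 8, amplitude_scale = 4)
  a <- matrix(runif(30, 0, 360), ncol = 3)
  expect_equal(eval_pes(p4, a),
               4 * (eval_pes(p1, a) + p1$offset) - p4$offset,
               tolerance = 1e-9)
})

test_that("invalid coupling pairs are rejected", {
  expect_error(make_pes(2, coupling_pairs = rbind(c(1, 3))), "1..n_d")
  expect_error(make_pes(3, coupling_pairs = rbind(c(2, 2))), "distinct")
})

test_that("generated datasets are uniform per angle and exactly sized", {
  pes <- make_pes(3, coupling_strength = 1, seed = 3)
  ds <- generate_dataset(pes, 150000, seed = 12)
  expect_identical(nrow(ds), 150000L)
  expect_identical(names(ds),
                   c(sprintf("dihedral_%d_deg", 1:3), "energy_kcal_mol"))
  expect_equal(ds$energy_kcal_mol,
               eval_pes(pes, as.matrix(ds[1:3])))
  # chi-square uniformity on 36 bins, first 1e5 samples of each angle
  for (d in 1:3) {
    counts <- tabulate(floor(ds[[d]][1:1e5] / 10) + 1, nbins = 36)
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
  # determinism
  ds2 <- generate_dataset(pes, 100, seed = 12)
  expect_identical(ds2, ds[1:100, ])
})

test_that("clash filtering returns only clash-free conformers", {
  fb <- make_fixture_molecule(3, "branched")
  pes <- make_pes(3, coupling_strength = 1, seed = 3)
  ds <- generate_dataset(pes, 60, seed = 4, clash_filtering = TRUE,
                         conformer = fb$conformer, topology = fb$topology)
  expect_identical(nrow(ds), 60L)
  for (r in seq_len(nrow(ds))) {
    conf <- set_configuration(fb$conformer, fb$topology,
                              as.numeric(ds[r, 1:3]))
    expect_false(detect_clash(conf, fb$topology))
  }
  # an unfillable constraint aborts instead of spinning forever
  expect_error(
    generate_dataset(pes, 10, seed = 4, clash_filtering = TRUE,
                     conformer = fb$conformer, topology = fb$topology,
                     clash_threshold = 50),
    "rejection rate")
})

test_that("fixture molecules satisfy the topology invariants", {
  for (spec in list(list(3, "linear"), list(5, "linear"),
                    list(2, "branched"), list(3, "branched"),
                    list(4, "branched"))) {
    fx <- make_fixture_molecule(spec[[1]], spec[[2]])
    top <- fx$topology
    expect_identical(top$n_d, as.integer(spec[[1]]))
    expect_identical(sort(unlist(top$fragments)), seq_len(top$n_atoms))
    for (d in seq_len(top$n_d)) {
      dh <- top$dihedrals[[d]]
      expect_false(top$frag_id[dh[2]] == top$frag_id[dh[3]])
      expect_true(dh[4] %in% top$moving_sets[[d]])
      expect_false(dh[1] %in% top$moving_sets[[d]])
    }
  }
  # the branched fixture has >= 3 dihedrals sharing the hub atom
  fb <- make_fixture_molecule(3, "branched")
  hubs <- vapply(fb$topology$dihedrals, `[[`, 0L, 2)
  expect_identical(hubs, rep(1L, 3))
})

test_that("PES files round-trip", {
  pes <- make_pes(4, coupling_strength = 2, seed = 19, amplitude_scale = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_pes(pes, f)
  back <- read_pes(f)
  a <- matrix(runif(80, 0, 360), ncol = 4)
  expect_equal(eval_pes(back, a), eval_pes(pes, a), tolerance = 1e-12)
})

test_that("the external XYZ-directory oracle matches direct evaluation", {
  fx <- make_fixture_molecule(2, "branched")
  engine <- function(dir) {
    files <- list.files(dir, full.names = TRUE)
    data.frame(file = files,
               energy_kcal_mol = vapply(files, function(p)
                 sum(read_xyz(p)$coords^2), numeric(1)))
  }
  oracle <- external_oracle(fx$conformer, fx$topology, engine)
  cfgs <- matrix(c(10, 200, 90, 340), ncol = 2, byrow = TRUE)
  direct <- vapply(1:2, function(r)
    sum(set_configuration(fx$conformer, fx$topology, cfgs[r, ])$coords^2),
    numeric(1))
  expect_equal(oracle(cfgs), direct, tolerance = 1e-9)
})
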