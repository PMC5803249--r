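#' Synthetic correlated dihedral potential energy surface
#'
#' A ground-truth intramolecular energy over dihedral angles that plays the
#' role of a quantum-chemistry oracle: per-dihedral cosine terms (torsion
#' barriers on the kcal/mol scale) plus pairwise angle-coupling terms
#' `c * cos(m a_i - p) * cos(m' a_j - p')` of tunable strength. Couplings
#' produce exactly the non-additive structure that independent one-angle
#' scans cannot capture; with `coupling_strength = 0` the surface is exactly
#' separable and an uncorrelated force field can represent it.
#'
#' Energies are shifted so that the minimum over `n_calibration` random
#' configurations is zero (the surface's true minimum may lie slightly below
#' zero, within the calibration's sampling tolerance).
#'
#' @param n_d number of dihedral angles (>= 1).
#' @param coupling_pairs two-column matrix (or list of pairs) of dihedral
#'   index pairs to couple; `NULL` picks a branched default: every pair
#'   `(1, d)` (a hub on dihedral 1) plus `(2, 3)` when `n_d >= 3`.
#' @param coupling_strength scale of the coupling amplitudes (kcal/mol),
#'   relative to the per-dihedral barrier scale and before `amplitude_scale`
#'   is applied.
#' @param seed integer seed; the surface is reproducible given the seed.
#' @param n_calibration random samples used to set the zero of energy.
#' @param max_order highest cosine order in both the separable and coupling
#'   terms.
#' @param amplitude_scale global multiplier on all amplitudes (separable and
#'   coupling alike). 1 gives torsion barriers on the 1 kcal/mol scale;
#'   larger values emulate stiffer molecules whose random-conformer energies
#'   span tens of kcal/mol.
#' @return an object of class `synthetic_pes`.
#' @export
make_pes <- function(n_d, coupling_pairs = NULL, coupling_strength = 1,
                     seed = 1L, n_calibration = 10000L, max_order = 3L,
                     amplitude_scale = 1) {
  stopifnot(n_d >= 1, coupling_strength >= 0, max_order >= 1,
            amplitude_scale > 0)
  if (is.null(coupling_pairs)) coupling_pairs <- default_coupling_pairs(n_d)
  if (is.list(coupling_pairs)) coupling_pairs <- do.call(rbind, coupling_pairs)
  if (length(coupling_pairs))
    coupling_pairs <- matrix(as.integer(coupling_pairs), ncol = 2L)
  else coupling_pairs <- matrix(integer(0), ncol = 2L)
  if (nrow(coupling_pairs) &&
      (any(coupling_pairs < 1L) || any(coupling_pairs > n_d) ||
       any(coupling_pairs[, 1] == coupling_pairs[, 2])))
    stop("coupling_pairs must index distinct dihedrals in 1..n_d",
         call. = FALSE)

  pes <- with_seed(seed, {
    amp <- matrix(0, n_d, max_order)
    pha <- matrix(0, n_d, max_order)
    for (m in seq_len(max_order)) {
      amp[, m] <- amplitude_scale * runif(n_d, 0.5, 2) / m
      pha[, m] <- runif(n_d, 0, 360)
    }
    np <- nrow(coupling_pairs)
    couplings <- list(
      pairs = coupling_pairs,
      c = amplitude_scale * coupling_strength * runif(np, 0.75, 1.25) *
        sample(c(-1, 1), np, replace = TRUE),
      m1 = sample.int(max_order, np, replace = TRUE),
      m2 = sample.int(max_order, np, replace = TRUE),
      p1 = runif(np, 0, 360),
      p2 = runif(np, 0, 360))
    structure(list(n_d = as.integer(n_d), amplitudes = amp, phases = pha,
                   couplings = couplings,
                   coupling_strength = coupling_strength,
                   amplitude_scale = amplitude_scale,
                   max_order = as.integer(max_order),
                   offset = 0, seed = as.integer(seed)),
              class = "synthetic_pes")
  })
  # zero of energy: best of a large random sample, polished by local descent
  # from the lowest sampled points (the surface is smooth and periodic, so
  # the sampled basin minima are found essentially exactly)
  calib <- with_seed(seed + 104729L, {
    matrix(runif(n_calibration * n_d, 0, 360), ncol = n_d)
  })
  e <- eval_pes(pes, calib)
  starts <- calib[order(e)[seq_len(min(20L, nrow(calib)))], , drop = FALSE]
  best <- min(e)
  for (r in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[r, ], function(a) eval_pes(pes, a),
                        method = "BFGS", control = list(maxit = 200))
    best <- min(best, opt$value)
  }
  pes$offset <- best
  pes
}

#' @rdname make_pes
#' @export
default_coupling_pairs <- function(n_d) {
  if (n_d < 2L) return(matrix(integer(0), ncol = 2L))
  pairs <- cbind(1L, 2:n_d)
  if (n_d >= 3L) pairs <- rbind(pairs, c(2L, 3L))
  pairs
}

#' Evaluate a synthetic PES
#'
#' Deterministic, finite, and 360-degree periodic in every angle.
#'
#' @param pes a [make_pes()] surface.
#' @param angles a configuration (vector, degrees) or n x n_d matrix.
#' @return energy in kcal/mol (vector for matrix input).
#' @export
eval_pes <- function(pes, angles) {
  a <- .as_config_matrix(angles, pes$n_d, "eval_pes")
  e <- rep(-pes$offset, nrow(a))
  for (d in seq_len(pes$n_d)) {
    for (m in seq_len(pes$max_order)) {
      e <- e + pes$amplitudes[d, m] *
        cos(.deg2rad(m * a[, d] - pes$phases[d, m]))
    }
  }
  cp <- pes$couplings
  for (q in seq_len(nrow(cp$pairs))) {
    e <- e + cp$c[q] *
      cos(.deg2rad(cp$m1[q] * a[, cp$pairs[q, 1]] - cp$p1[q])) *
      cos(.deg2rad(cp$m2[q] * a[, cp$pairs[q, 2]] - cp$p2[q]))
  }
  e
}

#' Wrap a PES as an energy oracle
#'
#' Returns the plain function-of-configurations interface used by
#' [scan_parameterize()] and the Monte Carlo sampler.
#'
#' @param pes a [make_pes()] surface.
#' @return `function(angles) -> energies (kcal/mol)`.
#' @export
pes_oracle <- function(pes) {
  force(pes)
  function(angles) eval_pes(pes, angles)
}

#' @export
print.synthetic_pes <- function(x, ...) {
  cat(sprintf("<synthetic_pes> %d dihedrals, %d coupling pairs (strength %.3g kcal/mol), seed %d\n",
              x$n_d, nrow(x$couplings$pairs), x$coupling_strength, x$seed))
  invisible(x)
}

#' Generate a random-conformer training dataset
#'
#' Draws dihedral configurations i.i.d. uniform on `[0, 360)` per angle and
#' labels them with oracle energies. With `clash_filtering = TRUE` (requires
#' `conformer` and `topology`), configurations that place non-bonded atoms
#' closer than `clash_threshold` are discarded and replaced by fresh random
#' configurations until `n_samples` clash-free rows are collected.
#'
#' @param pes a [make_pes()] surface (or any object accepted by [eval_pes()]).
#' @param n_samples number of rows to generate.
#' @param seed integer seed.
#' @param clash_filtering reject clashing conformers and resample.
#' @param conformer,topology the molecule used for the clash test.
#' @param clash_threshold distance threshold in Angstrom.
#' @return a data frame with columns `dihedral_<i>_deg` and
#'   `energy_kcal_mol`.
#' @export
generate_dataset <- function(pes, n_samples, seed = 1L,
                             clash_filtering = FALSE,
                             conformer = NULL, topology = NULL,
                             clash_threshold = 2.1) {
  stopifnot(n_samples >= 1)
  n_d <- pes$n_d
  angles <- with_seed(seed, {
    if (!clash_filtering) {
      # row-major draw: a shorter run is a prefix of a longer one
      matrix(runif(n_samples * n_d, 0, 360), ncol = n_d, byrow = TRUE)
    } else {
      if (is.null(conformer) || is.null(topology))
        stop("clash filtering requires a conformer and a topology",
             call. = FALSE)
      out <- matrix(NA_real_, n_samples, n_d)
      kept <- 0L; proposed <- 0L; rejected <- 0L
      while (kept < n_samples) {
        cand <- runif(n_d, 0, 360)
        proposed <- proposed + 1L
        conf <- set_configuration(conformer, topology, cand)
        if (detect_clash(conf, topology, clash_threshold)) {
          rejected <- rejected + 1L
          if (proposed >= 1000L && rejected / proposed > 0.999)
            stop("clash rejection rate above 99.9%: topology over-constrained",
                 call. = FALSE)
        } else {
          kept <- kept + 1L
          out[kept, ] <- cand
        }
      }
      out
    }
  })
  energies <- eval_pes(pes, angles)
  df <- as.data.frame(angles)
  names(df) <- sprintf("dihedral_%d_deg", seq_len(n_d))
  df$energy_kcal_mol <- energies
  df
}

#' Read / write a dataset file
#'
#' Comma-separated tables with a header naming each dihedral column
#' (`dihedral_<i>_deg`) and the energy column `energy_kcal_mol`.
#'
#' @param dataset data frame from [generate_dataset()].
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"energy_kcal_mol" %in% names(df))
    stop(sprintf("%s: missing energy_kcal_mol column", path), call. = FALSE)
  df
}

# split a dataset data frame into an angle matrix + energy vector
.dataset_parts <- function(dataset) {
  if (is.list(dataset) && !is.data.frame(dataset) &&
      all(c("angles", "energy") %in% names(dataset)))
    return(list(angles = as.matrix(dataset$angles),
                energy = as.numeric(dataset$energy)))
  stopifnot(is.data.frame(dataset), "energy_kcal_mol" %in% names(dataset))
  acols <- setdiff(names(dataset), "energy_kcal_mol")
  list(angles = as.matrix(dataset[acols]),
       energy = dataset$energy_kcal_mol)
}

#' Serialize / load a synthetic PES
#'
#' @param pes a [make_pes()] surface.
#' @param path file path (JSON).
#' @export
write_pes <- function(pes, path) {
  obj <- unclass(pes)
  obj$couplings$pairs <- apply(pes$couplings$pairs, 1, identity,
                               simplify = FALSE)
  obj$amplitudes <- apply(pes$amplitudes, 1, identity, simplify = FALSE)
  obj$phases <- apply(pes$phases, 1, identity, simplify = FALSE)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pes
#' @export
read_pes <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v, ncol) {
    if (length(v) == 0) matrix(integer(0), ncol = ncol)
    else if (is.matrix(v)) v
    else do.call(rbind, v)
  }
  structure(list(n_d = as.integer(obj$n_d),
                 amplitudes = as_mat(obj$amplitudes, obj$max_order),
                 phases = as_mat(obj$phases, obj$max_order),
                 couplings = list(pairs = as_mat(obj$couplings$pairs, 2L),
                                  c = as.numeric(obj$couplings$c),
                                  m1 = as.integer(obj$couplings$m1),
                                  m2 = as.integer(obj$couplings$m2),
                                  p1 = as.numeric(obj$couplings$p1),
                                  p2 = as.numeric(obj$couplings$p2)),
                 coupling_strength = obj$coupling_strength,
                 amplitude_scale = if (is.null(obj$amplitude_scale)) 1
                                   else obj$amplitude_scale,
                 max_order = as.integer(obj$max_order),
                 offset = obj$offset, seed = as.integer(obj$seed)),
            class = "synthetic_pes")
}

#' Programmatic fixture molecules
#'
#' Builds a conformer plus topology made of small rigid planar fragments
#' (dummy carbon frames) joined by rotatable bonds, either as a linear chain
#' or as a branched hub: one central atom carrying `n_d` blades, the
#' arrangement in which torsion-torsion correlations (and steric clashes
#' between blades) arise. Geometries are invented; they exercise the
#' geometry and clash machinery, not chemistry.
#'
#' @param n_d number of rotatable dihedrals.
#' @param arrangement `"linear"` (chain of fragments) or `"branched"`
#'   (hub atom with `n_d` blades; needs `n_d >= 2`).
#' @return list with elements `conformer` and `topology`.
#' @export
make_fixture_molecule <- function(n_d = 3L,
                                  arrangement = c("linear", "branched")) {
  arrangement <- match.arg(arrangement)
  b <- 1.5   # generic bond length, Angstrom
  if (arrangement == "linear") {
    # fragments of 3 atoms: P (root), Q (links to next fragment), S (side);
    # dihedral m twists about Q_m - P_{m+1}
    nf <- n_d + 1L
    elements <- character(0); coords <- NULL
    bonds <- list(); fragments <- list(); dihedrals <- list()
    for (f in seq_len(nf)) {
      x0 <- (f - 1L) * 2.6
      zig <- if (f %% 2L == 0L) 0.9 else 0
      P <- c(x0, zig, 0)
      Q <- c(x0 + b * cos(pi / 6) * (if (f %% 2L == 0L) 1 else 1),
             zig + b * sin(pi / 6) * (if (f %% 2L == 0L) -1 else 1), 0)
      S <- c(x0 - 0.4, zig + (if (f %% 2L == 0L) -1 else 1) * 1.3, 0)
      base <- length(elements)
      elements <- c(elements, "C", "C", "C")
      coords <- rbind(coords, P, Q, S)
      fragments[[f]] <- base + 1:3
      bonds <- c(bonds, list(c(base + 1L, base + 2L),
                             c(base + 1L, base + 3L)))
      if (f > 1L) {
        prevQ <- base - 1L   # Q of previous fragment
        bonds <- c(bonds, list(c(prevQ, base + 1L)))
        dihedrals[[f - 1L]] <- c(prevQ - 1L, prevQ, base + 1L, base + 2L)
      }
    }
  } else {
    if (n_d < 2L) stop("branched fixtures need n_d >= 2", call. = FALSE)
    # hub atom (own fragment) with n_d planar 3-atom blades; dihedral for
    # blade m uses the root of the previous blade as its first atom (roots
    # sit on rotation axes, so the torsions stay independent)
    elements <- "N"
    coords <- matrix(c(0, 0, 0), 1, 3)
    bonds <- list(); fragments <- list(1L); dihedrals <- list()
    roots <- integer(n_d)
    for (m in seq_len(n_d)) {
      theta <- 2 * pi * (m - 1) / max(n_d, 3L)   # never 180 deg apart
      u <- c(cos(theta), sin(theta), 0)
      # blade plane tilted out of the hub plane so blades are non-coplanar
      w <- c(-sin(theta) * 0.5, cos(theta) * 0.5,
             if (m %% 2L) 0.8660254 else -0.8660254)
      w <- w / sqrt(sum(w^2))
      # deliberately crowded hub (short hub bonds, long arms) so that a
      # sizeable fraction of random rotations produce steric clashes
      root <- 1.05 * u
      a2 <- root + 2.0 * (0.5 * u + 0.8660254 * w)
      a3 <- root + 2.0 * (0.5 * u - 0.8660254 * w)
      a4 <- root + 2.8 * u
      base <- length(elements)
      elements <- c(elements, "C", "C", "C", "C")
      coords <- rbind(coords, root, a2, a3, a4)
      roots[m] <- base + 1L
      fragments[[m + 1L]] <- base + 1:4
      bonds <- c(bonds, list(c(1L, base + 1L), c(base + 1L, base + 2L),
                             c(base + 1L, base + 3L), c(base + 1L, base + 4L)))
    }
    for (m in seq_len(n_d)) {
      prev <- roots[if (m == 1L) n_d else m - 1L]
      dihedrals[[m]] <- c(prev, 1L, roots[m], roots[m] + 1L)
    }
  }
  rownames(coords) <- NULL
  list(conformer = conformer(elements, coords),
       topology = dihedral_topology(bonds, dihedrals, fragments))
}

#' Adapt a directory-of-XYZ energy engine as a configuration oracle
#'
#' The seam where an external quantum-chemistry engine can be plugged in:
#' `engine` receives a directory containing numbered XYZ files
#' (`conf_000001.xyz`, ...) and must return a data frame with columns `file`
#' and `energy_kcal_mol`. The adapter writes each requested configuration as
#' a conformer, invokes the engine once per batch, and returns energies in
#' request order.
#'
#' @param conformer,topology the molecule whose dihedrals are driven.
#' @param engine `function(dir) -> data.frame(file, energy_kcal_mol)`.
#' @param workdir where XYZ batches are written (a fresh subdirectory per
#'   call); defaults to a session temp directory.
#' @return `function(angles) -> energies`, usable with [scan_parameterize()].
#' @export
external_oracle <- function(conformer, topology, engine,
                            workdir = tempfile("oracle_batch_")) {
  force(conformer); force(topology); force(engine); force(workdir)
  batch <- 0L
  function(angles) {
    a <- .as_config_matrix(angles, topology$n_d, "external_oracle")
    batch <<- batch + 1L
    dir <- file.path(workdir, sprintf("batch_%04d", batch))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- sprintf("conf_%06d.xyz", seq_len(nrow(a)))
    for (r in seq_len(nrow(a)))
      write_xyz(set_configuration(conformer, topology, a[r, ]),
                file.path(dir, files[r]))
    res <- engine(dir)
    if (!all(c("file", "energy_kcal_mol") %in% names(res)))
      stop("engine must return columns 'file' and 'energy_kcal_mol'",
           call. = FALSE)
    e <- res$energy_kcal_mol[match(files, basename(res$file))]
    if (any(is.na(e)))
      stop("engine did not return an energy for every conformer",
           call. = FALSE)
    e
  }
}
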