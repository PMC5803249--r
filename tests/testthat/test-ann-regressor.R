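test_that("split sizes follow the 72/13/15 floor rule with remainder to train", {
  s <- split_dataset(150000, seed = 1)
  expect_identical(lengths(s),
                   c(train = 108000L, validation = 19500L, test = 22500L))
  s100 <- split_dataset(100, seed = 1)
  expect_identical(lengths(s100), c(train = 72L, validation = 13L, test = 15L))
  # disjoint and exhaustive
  all_idx <- sort(c(s100$train, s100$validation, s100$test))
  expect_identical(all_idx, 1:100)
})

test_that("splits are deterministic by seed and reshuffled across seeds", {
  a <- split_dataset(500, seed = 42)
  b <- split_dataset(500, seed = 42)
  expect_identical(a, b)
  c <- split_dataset(500, seed = 43)
  expect_false(identical(a$train, c$train))
  expect_identical(sort(c(c$train, c$validation, c$test)), 1:500)
})

test_that("invalid fractions are rejected", {
  expect_error(split_fractions(0.8, 0.3, 0.1), "sum to 1")
  expect_error(split_fractions(-0.1, 0.6, 0.5), "nonnegative")
})

test_that("the ensemble learns a separable surface to high accuracy", {
  pes <- make_pes(3, coupling_strength = 0, seed = 11)
  ds <- generate_dataset(pes, 5000, seed = 2)
  ens <- train_energy_ensemble(ds, control = training_control(max_epochs = 60),
                               seed = 5)
  parts <- torsionPES:::.dataset_parts(ds)
  te <- ens$split$test
  m <- evaluate_predictions(predict_energy(ens, parts$angles[te, ]),
                            parts$energy[te], n_d = 3)
  expect_lt(m$mae_kcal, 0.1)
  # split bookkeeping: disjoint, and recorded metadata is complete
  expect_identical(sort(c(ens$split$train, ens$split$validation,
                          ens$split$test)), seq_len(nrow(ds)))
  expect_identical(nrow(ens$metadata), 5L)
  expect_true(all(ens$metadata$best_epoch <= ens$metadata$stopped_epoch))
})

test_that("on a coupled surface the ensemble beats the scan-fit force field", {
  pes <- make_pes(3, coupling_strength = 1, seed = 11)
  ds <- generate_dataset(pes, 5000, seed = 2)
  ens <- train_energy_ensemble(ds, control = training_control(max_epochs = 60),
                               seed = 5)
  ff <- scan_parameterize(pes_oracle(pes), 3, 72, "tabulated")
  parts <- torsionPES:::.dataset_parts(ds)
  te <- ens$split$test
  mae_ann <- mean(abs(predict_energy(ens, parts$angles[te, ]) -
                      parts$energy[te]))
  mae_ff <- mean(abs(eval_ff(ff, parts$angles[te, ]) - parts$energy[te]))
  expect_lt(mae_ann, mae_ff / 2)
})

test_that("prediction is the arithmetic member mean, de-standardized", {
  pes <- make_pes(2, coupling_strength = 1, seed = 5)
  ds <- generate_dataset(pes, 300, seed = 2)
  ens <- train_energy_ensemble(ds, specs = list(c(8, 4), 6, 5),
                               control = training_control(max_epochs = 8),
                               seed = 3)
  a <- matrix(runif(12, 0, 360), ncol = 2)
  raw <- torsionPES:::.member_outputs(ens, a)
  manual <- rowMeans(raw) * ens$target_scale + ens$target_center
  expect_equal(predict_energy(ens, a), manual, tolerance = 1e-12)
  # a single-member ensemble is exactly that member
  solo <- ens
  solo$members <- ens$members[2]
  expect_equal(predict_energy(solo, a),
               raw[, 2] * ens$target_scale + ens$target_center,
               tolerance = 1e-12)
})

test_that("degenerate and malformed datasets abort", {
  ds <- data.frame(dihedral_1_deg = runif(100, 0, 360),
                   energy_kcal_mol = 5)
  expect_error(train_energy_ensemble(ds), "degenerate target variance")
  ds$energy_kcal_mol <- c(Inf, rep(1, 99))
  expect_error(train_energy_ensemble(ds), "non-finite")
  expect_error(train_energy_ensemble(ds[1:10, ]), "at least 50")
})

test_that("a near-constant target is reproduced within scaler tolerance", {
  set.seed(8)
  ds <- data.frame(dihedral_1_deg = runif(300, 0, 360),
                   energy_kcal_mol = 7 + rnorm(300, sd = 1e-3))
  ens <- train_energy_ensemble(ds, specs = list(5, c(4, 3)),
                               control = training_control(max_epochs = 20),
                               seed = 2)
  pred <- predict_energy(ens, matrix(runif(50, 0, 360), ncol = 1))
  expect_lt(max(abs(pred - 7)), 0.05)
})

test_that("evaluation metrics match hand computation", {
  x <- c(1, 2, 3, 4, 5)
  m <- evaluate_predictions(x, x, n_d = 2)
  expect_identical(m$mae_kcal, 0)
  expect_equal(m$pearson_r, 1)
  m2 <- evaluate_predictions(-(x - 3), x - 3, n_d = 1)
  expect_equal(m2$pearson_r, -1)

  # 5-point spreadsheet check: pred, ref pairs
  pred <- c(1.0, 2.5, 0.5, 4.0, 3.0)
  ref <- c(1.2, 2.0, 1.0, 3.0, 3.5)
  m3 <- evaluate_predictions(pred, ref, n_d = 2, cutoff = 3.2)
  expect_equal(m3$mae_kcal, mean(c(0.2, 0.5, 0.5, 1.0, 0.5)) / 2)
  expect_equal(m3$mae_mev, m3$mae_kcal / 23.0605 * 1000)
  expect_equal(m3$pearson_r,
               sum((pred - mean(pred)) * (ref - mean(ref))) /
                 sqrt(sum((pred - mean(pred))^2) * sum((ref - mean(ref))^2)))
  # cutoff keeps ref < 3.2: rows 1,2,3,4
  expect_identical(m3$n_below_cutoff, 4L)
  expect_equal(m3$mae_kcal_below_cutoff, mean(c(0.2, 0.5, 0.5, 1.0)) / 2)

  expect_true(is.na(evaluate_predictions(rep(1, 5), x, n_d = 1)$pearson_r))
  expect_identical(sum(m3$histogram$reference), 5L)
})

test_that("a persisted ensemble predicts identically after reload", {
  pes <- make_pes(2, coupling_strength = 1, seed = 5)
  ds <- generate_dataset(pes, 300, seed = 2)
  ens <- train_energy_ensemble(ds, specs = list(c(8, 4), 6),
                               control = training_control(max_epochs = 8),
                               seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  a <- matrix(runif(40, 0, 360), ncol = 2)
  expect_equal(predict_energy(back, a), predict_energy(ens, a),
               tolerance = 1e-12)
  expect_s3_class(back, "energy_ensemble")
})
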