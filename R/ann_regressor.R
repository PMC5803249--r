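#' Train / validation / test split fractions
#'
#' Defaults follow the 72/13/15 protocol: 72% of samples train the networks,
#' 13% drive early stopping, and the remaining 15% are held out for testing.
#'
#' @param train,validation,test nonnegative fractions summing to 1.
#' @return an object of class `split_fractions`.
#' @export
split_fractions <- function(train = 0.72, validation = 0.13, test = 0.15) {
  f <- c(train = train, validation = validation, test = test)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("split fractions must be nonnegative and sum to 1", call. = FALSE)
  structure(as.list(f), class = "split_fractions")
}

#' Split sample indices into train / validation / test sets
#'
#' Validation and test sizes are floor-rounded from the fractions; the
#' remainder goes to the training set (150,000 samples split 72/13/15 gives
#' 108,000 / 19,500 / 22,500). The permutation is reproducible by seed.
#'
#' @param n_samples total number of samples (>= 10).
#' @param fractions a [split_fractions()].
#' @param seed integer seed.
#' @return list of disjoint, exhaustive integer index vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(n_samples, fractions = split_fractions(),
                          seed = 1L) {
  stopifnot(n_samples >= 10)
  if (!inherits(fractions, "split_fractions"))
    fractions <- do.call(split_fractions, as.list(fractions))
  n_val <- floor(n_samples * fractions$validation)
  n_test <- floor(n_samples * fractions$test)
  n_train <- n_samples - n_val - n_test
  perm <- with_seed(seed, sample.int(n_samples))
  list(train = perm[seq_len(n_train)],
       validation = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}

#' The five energy-prediction network architectures
#'
#' Hidden-layer sizes of the five model-averaged regression networks:
#' (30,10), (100,10), (110,7), (60,30,10), (50,20,8). All hidden units are
#' logistic; the output unit is linear.
#'
#' @return list of integer vectors, one per ensemble member.
#' @export
network_specs <- function() {
  list(c(30L, 10L), c(100L, 10L), c(110L, 7L),
       c(60L, 30L, 10L), c(50L, 20L, 8L))
}

.check_specs <- function(specs, max_layers, what) {
  for (s in specs)
    if (length(s) < 1L || length(s) > max_layers || any(s < 1L))
      stop(sprintf("%s: hidden layer sizes must be 1-%d positive integers",
                   what, max_layers), call. = FALSE)
  lapply(specs, as.integer)
}

# shared by the regressor and classifier: encode, split, standardize
.prepare_training <- function(dataset, encoding, fractions, seed) {
  parts <- .dataset_parts(dataset)
  n <- nrow(parts$angles)
  if (n < 50L) stop("need at least 50 samples to train", call. = FALSE)
  if (any(!is.finite(parts$energy)))
    stop("non-finite energies in dataset", call. = FALSE)
  split <- split_dataset(n, fractions, seed)
  stopifnot(!anyDuplicated(c(split$train, split$validation, split$test)))
  X <- encode_features(parts$angles, encoding)
  ctr <- colMeans(X[split$train, , drop = FALSE])
  scl <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  list(angles = parts$angles, energy = parts$energy, split = split,
       X = sweep(sweep(X, 2, ctr), 2, scl, "/"),
       feature_center = ctr, feature_scale = scl)
}

#' Train the model-averaged energy network ensemble
#'
#' Trains five logistic-hidden-layer networks (see [network_specs()]) on
#' Fourier-encoded dihedral configurations against reference energies in
#' kcal/mol, with Adam, minibatches of 200, L2 regularization and early
#' stopping on a shared validation split. Features and targets are
#' standardized with training-split statistics; the ensemble prediction is
#' the arithmetic mean of the member outputs, de-standardized back to
#' kcal/mol. Members share the split and differ by architecture and seed
#' (`seed + member index`).
#'
#' @param dataset a data frame from [generate_dataset()] / [read_dataset()],
#'   or `list(angles = matrix, energy = vector)`.
#' @param specs list of hidden-layer size vectors (1-3 layers each).
#' @param encoding a [feature_encoding()].
#' @param fractions a [split_fractions()].
#' @param control a [training_control()].
#' @param seed base integer seed.
#' @return an object of class `energy_ensemble`, carrying the members, the
#'   feature/target scalers, the encoding, the split indices and per-member
#'   training metadata (stopped epoch, best epoch, validation loss).
#' @export
train_energy_ensemble <- function(dataset, specs = network_specs(),
                                  encoding = feature_encoding(),
                                  fractions = split_fractions(),
                                  control = training_control(),
                                  seed = 1L) {
  specs <- .check_specs(specs, 3L, "energy network spec")
  prep <- .prepare_training(dataset, encoding, fractions, seed)
  y_ctr <- mean(prep$energy[prep$split$train])
  y_scl <- stats::sd(prep$energy[prep$split$train])
  if (!is.finite(y_scl) || y_scl == 0)
    stop("degenerate target variance: energies are constant", call. = FALSE)
  ys <- (prep$energy - y_ctr) / y_scl
  Xtr <- prep$X[prep$split$train, , drop = FALSE]
  Xv <- prep$X[prep$split$validation, , drop = FALSE]
  members <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fit <- tryCatch(
      .mlp_train(Xtr, ys[prep$split$train], specs[[i]], "linear",
                 Xv, ys[prep$split$validation], control, seed + i),
      error = function(e)
        stop(sprintf("ensemble member %d (%s): %s", i,
                     paste(specs[[i]], collapse = "x"), conditionMessage(e)),
             call. = FALSE))
    members[[i]] <- fit
  }
  structure(list(members = members, specs = specs, encoding = encoding,
                 feature_center = prep$feature_center,
                 feature_scale = prep$feature_scale,
                 target_center = y_ctr, target_scale = y_scl,
                 n_d = ncol(prep$angles), split = prep$split,
                 control = control, seed = as.integer(seed),
                 metadata = data.frame(
                   member = seq_along(members),
                   spec = vapply(specs, paste, "", collapse = "x"),
                   stopped_epoch = vapply(members, `[[`, 0L, "stopped_epoch"),
                   best_epoch = vapply(members, `[[`, 0L, "best_epoch"),
                   validation_loss = vapply(members, `[[`, 0,
                                            "validation_loss"))),
            class = "energy_ensemble")
}

#' @export
print.energy_ensemble <- function(x, ...) {
  cat(sprintf("<energy_ensemble> %d members over %d dihedrals (%d features)\n",
              length(x$members), x$n_d, length(x$feature_center)))
  print(x$metadata, row.names = FALSE)
  invisible(x)
}

# standardized member outputs for a raw angle matrix
.member_outputs <- function(ensemble, angles, output = "linear") {
  a <- .as_config_matrix(angles, ensemble$n_d, "predict")
  X <- encode_features(a, ensemble$encoding)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- sweep(sweep(X, 2, ensemble$feature_center), 2,
             ensemble$feature_scale, "/")
  vapply(ensemble$members,
         function(m) as.numeric(.mlp_forward(m$net, X, output)),
         numeric(nrow(X)))
}

#' Predict energies with the network ensemble
#'
#' The prediction is the arithmetic mean of the member networks' outputs
#' (model averaging), de-standardized to kcal/mol.
#'
#' @param ensemble an [train_energy_ensemble()] result.
#' @param angles a configuration (vector, degrees) or n x n_d matrix.
#' @return predicted energies in kcal/mol.
#' @export
predict_energy <- function(ensemble, angles) {
  out <- .member_outputs(ensemble, angles, "linear")
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  drop(rowMeans(out)) * ensemble$target_scale + ensemble$target_center
}

#' Accuracy metrics for an energy model
#'
#' The headline unit is the mean absolute error per dihedral angle:
#' `mean(|pred - ref|) / n_d`, reported in kcal/mol and meV (1 eV = 23.0605
#' kcal/mol), alongside the Pearson product-moment correlation and an energy
#' histogram of both series on shared breaks. An optional low-energy cutoff
#' (the customary choice is 11.5 kcal/mol) recomputes the MAE on the
#' reference-energy subset below the cutoff.
#'
#' @param pred,ref predicted and reference energies (kcal/mol).
#' @param n_d number of dihedral angles.
#' @param cutoff optional energy cutoff (kcal/mol) for the filtered MAE.
#' @param bin_width histogram bin width (kcal/mol).
#' @return an object of class `pes_metrics`: `mae_kcal`, `mae_mev` (both per
#'   dihedral), `pearson_r` (`NA` when either series has zero variance),
#'   `n`, `histogram`, and when `cutoff` is given `mae_kcal_below_cutoff` /
#'   `n_below_cutoff`.
#' @export
evaluate_predictions <- function(pred, ref, n_d, cutoff = NULL,
                                 bin_width = 1) {
  stopifnot(length(pred) == length(ref), length(ref) > 0, n_d >= 1)
  kcal_per_ev <- 23.0605
  mae <- mean(abs(pred - ref)) / n_d
  r <- if (stats::sd(pred) == 0 || stats::sd(ref) == 0) NA_real_
       else stats::cor(pred, ref)
  breaks <- seq(floor(min(pred, ref) / bin_width) * bin_width,
                ceiling(max(pred, ref) / bin_width) * bin_width + bin_width,
                by = bin_width)
  out <- list(mae_kcal = mae, mae_mev = mae / kcal_per_ev * 1000,
              pearson_r = r, n = length(ref), n_d = n_d,
              histogram = list(
                breaks = breaks,
                reference = graphics::hist(ref, breaks = breaks,
                                           plot = FALSE)$counts,
                predicted = graphics::hist(pred, breaks = breaks,
                                           plot = FALSE)$counts))
  if (!is.null(cutoff)) {
    keep <- ref < cutoff
    out$cutoff <- cutoff
    out$n_below_cutoff <- sum(keep)
    out$mae_kcal_below_cutoff <-
      if (any(keep)) mean(abs(pred[keep] - ref[keep])) / n_d else NA_real_
  }
  structure(out, class = "pes_metrics")
}

#' @export
print.pes_metrics <- function(x, ...) {
  cat(sprintf("<pes_metrics> n = %d | MAE %.4f kcal/mol (%.2f meV) per dihedral | Pearson r = %s\n",
              x$n, x$mae_kcal, x$mae_mev,
              ifelse(is.na(x$pearson_r), "undefined (zero variance)",
                     sprintf("%.4f", x$pearson_r))))
  if (!is.null(x$cutoff))
    cat(sprintf("  below %.3g kcal/mol (n = %d): MAE %.4f kcal/mol per dihedral\n",
                x$cutoff, x$n_below_cutoff, x$mae_kcal_below_cutoff))
  invisible(x)
}

#' Persist / load a trained ensemble
#'
#' Self-contained JSON archive: member weights and biases, feature and
#' target scalers, the feature encoding, and training metadata, so that a
#' loaded model predicts without access to the training data.
#'
#' @param ensemble an `energy_ensemble` or `classifier_ensemble`.
#' @param path file path.
#' @export
write_ensemble <- function(ensemble, path) {
  ser_net <- function(m)
    list(hidden = m$hidden, output = m$output, seed = m$seed,
         stopped_epoch = m$stopped_epoch, best_epoch = m$best_epoch,
         validation_loss = m$validation_loss,
         layer_sizes = m$net$layer_sizes,
         W = lapply(m$net$W, function(w)
           apply(w, 1, identity, simplify = FALSE)),
         b = m$net$b)
  obj <- list(class = class(ensemble)[1],
              n_d = ensemble$n_d,
              encoding = unclass(ensemble$encoding),
              feature_center = ensemble$feature_center,
              feature_scale = ensemble$feature_scale,
              target_center = ensemble$target_center,
              target_scale = ensemble$target_scale,
              threshold_energy = ensemble$threshold_energy,
              seed = ensemble$seed,
              members = lapply(ensemble$members, ser_net))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  de_net <- function(m) {
    sizes <- as.integer(m$layer_sizes)
    W <- lapply(seq_along(m$W), function(l) {
      w <- do.call(rbind, lapply(m$W[[l]], as.numeric))
      stopifnot(nrow(w) == sizes[l], ncol(w) == sizes[l + 1])
      w
    })
    list(net = list(W = W, b = lapply(m$b, as.numeric),
                    layer_sizes = sizes),
         output = m$output, hidden = as.integer(m$hidden), seed = m$seed,
         stopped_epoch = m$stopped_epoch, best_epoch = m$best_epoch,
         validation_loss = m$validation_loss)
  }
  members <- lapply(obj$members, de_net)
  structure(list(members = members,
                 encoding = do.call(feature_encoding, obj$encoding),
                 feature_center = as.numeric(obj$feature_center),
                 feature_scale = as.numeric(obj$feature_scale),
                 target_center = obj$target_center,
                 target_scale = obj$target_scale,
                 threshold_energy = obj$threshold_energy,
                 n_d = as.integer(obj$n_d), seed = obj$seed),
            class = obj$class)
}
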