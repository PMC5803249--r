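#' The five low/high-energy classification network architectures
#'
#' Hidden-layer sizes of the five classification networks: (30), (40), (50),
#' (5,5), (10,3) — much smaller than the regression networks, so that a
#' classification pass costs a fraction of an energy prediction.
#'
#' @return list of integer vectors, one per ensemble member.
#' @export
classifier_specs <- function() {
  list(30L, 40L, 50L, c(5L, 5L), c(10L, 3L))
}

#' Train the low/high-energy classification ensemble
#'
#' Labels every sample as low-energy (positive class) when its energy is
#' strictly below `threshold_energy` — default 46 kcal/mol (2 eV), the scale
#' above which conformations are irrelevant at typical simulation
#' temperatures — and trains five logistic-output networks on the same
#' feature encoding and split protocol as the energy regressor.
#'
#' @inheritParams train_energy_ensemble
#' @param threshold_energy class boundary in kcal/mol.
#' @param specs list of hidden-layer size vectors (1-2 layers each).
#' @return an object of class `classifier_ensemble`.
#' @export
train_classifier_ensemble <- function(dataset, threshold_energy = 46,
                                      specs = classifier_specs(),
                                      encoding = feature_encoding(),
                                      fractions = split_fractions(),
                                      control = training_control(),
                                      seed = 1L) {
  specs <- .check_specs(specs, 2L, "classifier spec")
  prep <- .prepare_training(dataset, encoding, fractions, seed)
  y <- as.numeric(prep$energy < threshold_energy)
  if (length(unique(y)) < 2L)
    stop(sprintf("single-class dataset at threshold %.3g kcal/mol: %d low, %d high",
                 threshold_energy, sum(y == 1), sum(y == 0)), call. = FALSE)
  Xtr <- prep$X[prep$split$train, , drop = FALSE]
  Xv <- prep$X[prep$split$validation, , drop = FALSE]
  members <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    members[[i]] <- tryCatch(
      .mlp_train(Xtr, y[prep$split$train], specs[[i]], "logistic",
                 Xv, y[prep$split$validation], control, seed + i),
      error = function(e)
        stop(sprintf("classifier member %d (%s): %s", i,
                     paste(specs[[i]], collapse = "x"), conditionMessage(e)),
             call. = FALSE))
  }
  structure(list(members = members, specs = specs, encoding = encoding,
                 feature_center = prep$feature_center,
                 feature_scale = prep$feature_scale,
                 target_center = NULL, target_scale = NULL,
                 threshold_energy = threshold_energy,
                 n_d = ncol(prep$angles), split = prep$split,
                 control = control, seed = as.integer(seed),
                 metadata = data.frame(
                   member = seq_along(members),
                   spec = vapply(specs, paste, "", collapse = "x"),
                   stopped_epoch = vapply(members, `[[`, 0L, "stopped_epoch"),
                   best_epoch = vapply(members, `[[`, 0L, "best_epoch"),
                   validation_loss = vapply(members, `[[`, 0,
                                            "validation_loss"))),
            class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  cat(sprintf("<classifier_ensemble> %d members, low-energy threshold %.3g kcal/mol\n",
              length(x$members), x$threshold_energy))
  print(x$metadata, row.names = FALSE)
  invisible(x)
}

#' Classify configurations as low or high energy
#'
#' Each member casts a binary vote (its logistic output thresholded at 0.5);
#' the reported probability is the mean of the five votes, so it always lies
#' on the lattice 0, 0.2, 0.4, 0.6, 0.8, 1.0, and with five voters a
#' majority is never tied: `is_low = probability > 0.5`.
#'
#' @param ensemble a [train_classifier_ensemble()] result.
#' @param angles a configuration (vector, degrees) or n x n_d matrix.
#' @return for a single configuration, `list(probability, is_low)`; for a
#'   matrix, a data frame with those columns.
#' @export
classify <- function(ensemble, angles) {
  out <- .member_outputs(ensemble, angles, "logistic")
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  votes <- out > 0.5
  probability <- rowMeans(votes)
  is_low <- probability > 0.5
  if (is.null(dim(angles)) && !is.data.frame(angles))
    list(probability = probability[1], is_low = is_low[1])
  else data.frame(probability = probability, is_low = is_low)
}

#' Confusion matrix of a low/high-energy classifier
#'
#' The positive class is "low energy" (the class a Monte Carlo gate must not
#' miss). `P = TP + FN` actual positives, `N = TN + FP` actual negatives.
#'
#' @param predicted_low,actual_low logical vectors, or pass the four counts
#'   directly via `tp`, `fp`, `fn`, `tn`.
#' @param tp,fp,fn,tn explicit counts (used when `predicted_low` is missing).
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted_low, actual_low,
                             tp = NULL, fp = NULL, fn = NULL, tn = NULL) {
  if (missing(predicted_low)) {
    cm <- list(tp = tp, fp = fp, fn = fn, tn = tn)
  } else {
    stopifnot(length(predicted_low) == length(actual_low))
    cm <- list(tp = sum(predicted_low & actual_low),
               fp = sum(predicted_low & !actual_low),
               fn = sum(!predicted_low & actual_low),
               tn = sum(!predicted_low & !actual_low))
  }
  cm <- lapply(cm, as.integer)
  if (any(vapply(cm, length, 1L) != 1L) || any(unlist(cm) < 0))
    stop("confusion matrix needs four nonnegative counts", call. = FALSE)
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d | FP %d | FN %d | TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `f1 = 2TP/(2TP+FP+FN)`.
#' A metric whose denominator is zero is undefined and reported as `NA`.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector (fractions in `[0, 1]`).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fp + cm$fn + cm$tn == 0)
    stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe(cm$tp, cm$tp + cm$fn),
    specificity = safe(cm$tn, cm$tn + cm$fp),
    accuracy = safe(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn),
    f1 = safe(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn))
}
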