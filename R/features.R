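#' Feature encoding for dihedral configurations
#'
#' The network input for a configuration is, per dihedral and in fixed
#' order: the canonical angle itself (degrees), then `sin(k * alpha)` and
#' `cos(k * alpha)` for each periodicity `k`. The default periodicity set is
#' `{0.5, 1, 2, ..., 10}` (11 values, 23 features per dihedral). The
#' half-integer features are not 360-degree periodic; encoding therefore
#' always canonicalizes angles into `[0, 360)` first, which makes them
#' well defined.
#'
#' @param periodicities strictly increasing positive multipliers `k`.
#' @param include_raw_angle include the raw angle (degrees) as a feature.
#' @return an object of class `feature_encoding`.
#' @export
feature_encoding <- function(periodicities = c(0.5, 1:10),
                             include_raw_angle = TRUE) {
  periodicities <- as.numeric(periodicities)
  if (length(periodicities) == 0 || any(periodicities <= 0) ||
      is.unsorted(periodicities, strictly = TRUE))
    stop("periodicities must be strictly increasing and positive",
         call. = FALSE)
  structure(list(periodicities = periodicities,
                 include_raw_angle = isTRUE(include_raw_angle)),
            class = "feature_encoding")
}

#' @export
print.feature_encoding <- function(x, ...) {
  cat(sprintf("<feature_encoding> %d features per dihedral (raw angle: %s; k = %s)\n",
              features_per_dihedral(x),
              if (x$include_raw_angle) "yes" else "no",
              paste(x$periodicities, collapse = ", ")))
  invisible(x)
}

#' @rdname feature_encoding
#' @param enc a `feature_encoding`.
#' @export
features_per_dihedral <- function(enc) {
  as.integer(enc$include_raw_angle) + 2L * length(enc$periodicities)
}

#' Encode dihedral configurations as network features
#'
#' @param angles one configuration (numeric vector, degrees) or a stack of
#'   configurations (n x n_d matrix / data frame).
#' @param enc a [feature_encoding()].
#' @return a numeric feature vector, or an n x feature_dim matrix for matrix
#'   input. Feature order: dihedral 1 block, dihedral 2 block, ...; within a
#'   block the raw angle (if enabled) then `sin(k a), cos(k a)` per `k`.
#' @export
encode_features <- function(angles, enc = feature_encoding()) {
  vec <- is.null(dim(angles)) && !is.data.frame(angles)
  n_d <- if (vec) length(angles) else ncol(angles)
  a <- .as_config_matrix(angles, n_d, "encode_features")
  per <- features_per_dihedral(enc)
  out <- matrix(NA_real_, nrow(a), n_d * per)
  nk <- length(enc$periodicities)
  for (d in seq_len(n_d)) {
    off <- (d - 1L) * per
    col <- a[, d]
    if (enc$include_raw_angle) {
      out[, off + 1L] <- col
      off <- off + 1L
    }
    rad <- .deg2rad(col)
    for (ki in seq_len(nk)) {
      k <- enc$periodicities[ki]
      out[, off + 2L * ki - 1L] <- sin(k * rad)
      out[, off + 2L * ki] <- cos(k * rad)
    }
  }
  if (vec) drop(out) else out
}
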