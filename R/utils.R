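#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Map angles to the canonical dihedral range
#'
#' Dihedral angles are stored as degrees in `[0, 360)`. Canonicalization must
#' happen before feature encoding because the half-integer periodicity
#' features are not 360-degree periodic.
#'
#' @param x numeric vector/matrix of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
#' @examples
#' canonical_angle(c(-30, 360, 725.5))
canonical_angle <- function(x) {
  x %% 360
}

# degrees -> radians
.deg2rad <- function(x) x * pi / 180

# Stable content hash for linking model files to the topology they were fit
# on; md5 of a canonical text rendering (tools::md5sum works on files only).
.text_md5 <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

.stop_dim <- function(what, expected, got) {
  stop(sprintf("%s: expected %d dihedral angles, got %d", what, expected, got),
       call. = FALSE)
}

# Coerce a single configuration or a stack of configurations to a matrix with
# n_d columns, canonicalized.
.as_config_matrix <- function(angles, n_d, what = "configuration") {
  if (is.data.frame(angles)) angles <- as.matrix(angles)
  if (is.null(dim(angles))) {
    if (length(angles) != n_d) .stop_dim(what, n_d, length(angles))
    angles <- matrix(as.numeric(angles), nrow = 1L)
  } else {
    if (ncol(angles) != n_d) .stop_dim(what, n_d, ncol(angles))
    angles <- matrix(as.numeric(angles), ncol = n_d)
  }
  if (any(!is.finite(angles))) stop("non-finite dihedral angle", call. = FALSE)
  canonical_angle(angles)
}
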