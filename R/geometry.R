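#' Molecular conformer
#'
#' A minimal container for one conformation of a molecule: element symbols
#' plus Cartesian coordinates in Angstrom. Conformers differ only by rigid
#' rotations about rotatable bonds; bond lengths and angles inside rigid
#' fragments are never altered by this package.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @return an object of class `conformer`.
#' @export
conformer <- function(elements, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!is.character(elements)) elements <- as.character(elements)
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)", call. = FALSE)
  if (length(elements) != nrow(coords))
    stop(sprintf("%d elements but %d coordinate rows",
                 length(elements), nrow(coords)), call. = FALSE)
  if (any(!is.finite(coords)))
    stop("non-finite coordinates", call. = FALSE)
  dimnames(coords) <- NULL
  structure(list(elements = elements, coords = coords), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms (%s)\n", length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    sort(table(x$elements), decreasing = TRUE),
                    sep = "", collapse = " ")))
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` row per atom (coordinates in Angstrom).
#'
#' @param path path to an XYZ file.
#' @return a [conformer()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1L)
    stop(sprintf("%s: empty file", path), call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L)
    stop(sprintf("%s, line 1: malformed atom count '%s'", path, lines[1L]),
         call. = FALSE)
  if (length(lines) < n + 2L)
    stop(sprintf("%s: header declares %d atoms but only %d atom rows present",
                 path, n, max(0L, length(lines) - 2L)), call. = FALSE)
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop(sprintf("%s, line %d: expected 'element x y z'", path, ln),
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop(sprintf("%s, line %d: non-numeric coordinate", path, ln),
           call. = FALSE)
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  conformer(elements, coords)
}

#' Write an XYZ file
#'
#' @param x a [conformer()].
#' @param path output path.
#' @param comment comment line (second line of the file).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "") {
  stopifnot(inherits(x, "conformer"))
  rows <- sprintf("%-2s %18.10f %18.10f %18.10f",
                  x$elements, x$coords[, 1], x$coords[, 2], x$coords[, 3])
  writeLines(c(as.character(length(x$elements)), comment, rows), path)
  invisible(path)
}

#' Dihedral topology of a molecule
#'
#' Describes which parts of a molecule are rigid and which torsions are
#' rotatable. Each dihedral is a 4-atom tuple `(i, j, k, l)` defining the
#' torsion about the bond `j-k`; rotating it moves every atom on the `l` side
#' of that bond (the moving set, derived from the bond graph) as a rigid
#' body. Atom indices are 1-based in R; topology files on disk use 0-based
#' indices.
#'
#' @param bonds two-column integer matrix (or list of pairs) of bonded atoms.
#' @param dihedrals list of integer 4-vectors `(i, j, k, l)` (or an n x 4
#'   matrix), one per rotatable torsion.
#' @param fragments list of integer vectors partitioning all atoms into rigid
#'   subunits.
#' @return an object of class `dihedral_topology` with elements `bonds`,
#'   `dihedrals`, `fragments`, `moving_sets`, `n_atoms`, `n_d`, and the
#'   clash-eligibility matrix `clash_eligible` (see [detect_clash()]).
#' @export
dihedral_topology <- function(bonds, dihedrals, fragments) {
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (is.matrix(dihedrals))
    dihedrals <- lapply(seq_len(nrow(dihedrals)), function(r) dihedrals[r, ])
  dihedrals <- lapply(dihedrals, as.integer)
  fragments <- lapply(fragments, as.integer)

  n_atoms <- max(c(bonds, unlist(fragments)))
  frag_id <- rep(NA_integer_, n_atoms)
  for (f in seq_along(fragments)) {
    if (any(!is.na(frag_id[fragments[[f]]])))
      stop("rigid fragments overlap", call. = FALSE)
    frag_id[fragments[[f]]] <- f
  }
  if (any(is.na(frag_id)))
    stop("rigid fragments do not cover all atoms", call. = FALSE)

  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_atoms - igraph::vcount(g)))
  bond_key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))

  moving_sets <- vector("list", length(dihedrals))
  for (d in seq_along(dihedrals)) {
    dh <- dihedrals[[d]]
    if (length(dh) != 4L || anyDuplicated(dh))
      stop(sprintf("dihedral %d: need 4 distinct atom indices", d),
           call. = FALSE)
    j <- dh[2L]; k <- dh[3L]
    if (!(paste(min(j, k), max(j, k)) %in% bond_key))
      stop(sprintf("dihedral %d: axis %d-%d is not a bond", d, j, k),
           call. = FALSE)
    if (frag_id[j] == frag_id[k])
      stop(sprintf("dihedral %d: axis %d-%d does not connect two rigid fragments",
                   d, j, k), call. = FALSE)
    gcut <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(j, k)))
    reach <- igraph::subcomponent(gcut, k)
    mv <- sort(as.integer(reach))
    if (dh[1L] %in% mv || !(dh[4L] %in% mv))
      stop(sprintf("dihedral %d: atoms i/l straddle the %d-%d bond incorrectly",
                   d, j, k), call. = FALSE)
    # the moving set must respect rigidity: whole fragments move or stay
    mv_frags <- unique(frag_id[mv])
    if (!setequal(mv, which(frag_id %in% mv_frags)))
      stop(sprintf("dihedral %d: moving set would split a rigid fragment", d),
           call. = FALSE)
    moving_sets[[d]] <- mv
  }

  # clash eligibility: different rigid fragments AND >= 4 bonds apart in the
  # bond graph (1-2/1-3/1-4 neighbours and intra-fragment pairs are excluded;
  # their distances are fixed or controlled by a single torsion)
  bd <- igraph::distances(g)
  eligible <- outer(frag_id, frag_id, "!=") & bd >= 4
  diag(eligible) <- FALSE

  structure(list(bonds = bonds, dihedrals = dihedrals, fragments = fragments,
                 moving_sets = moving_sets, frag_id = frag_id,
                 clash_eligible = eligible, n_atoms = n_atoms,
                 n_d = length(dihedrals)),
            class = "dihedral_topology")
}

#' @export
print.dihedral_topology <- function(x, ...) {
  cat(sprintf("<dihedral_topology> %d atoms, %d bonds, %d rigid fragments, %d rotatable dihedrals\n",
              x$n_atoms, nrow(x$bonds), length(x$fragments), x$n_d))
  invisible(x)
}

#' Read / write a topology file
#'
#' Topology files are YAML with keys `bonds` (list of index pairs),
#' `dihedrals` (list of 4-tuples) and `fragments` (list of index lists),
#' all 0-based; indices are converted to R's 1-based convention on read.
#'
#' @param path file path.
#' @return [read_topology()] returns a [dihedral_topology()];
#'   `write_topology` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  for (key in c("bonds", "dihedrals", "fragments"))
    if (is.null(y[[key]]))
      stop(sprintf("%s: missing key '%s'", path, key), call. = FALSE)
  dihedral_topology(
    bonds = lapply(y$bonds, function(b) as.integer(b) + 1L),
    dihedrals = lapply(y$dihedrals, function(d) as.integer(d) + 1L),
    fragments = lapply(y$fragments, function(f) as.integer(f) + 1L)
  )
}

#' @rdname read_topology
#' @param topology a [dihedral_topology()].
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "dihedral_topology"))
  y <- list(
    bonds = lapply(seq_len(nrow(topology$bonds)),
                   function(r) as.integer(topology$bonds[r, ]) - 1L),
    dihedrals = lapply(topology$dihedrals, function(d) d - 1L),
    fragments = lapply(topology$fragments, function(f) f - 1L)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# canonical text rendering used to tie serialized models to a topology
topology_hash <- function(topology) {
  .text_md5(paste(
    paste(apply(topology$bonds, 1, paste, collapse = "-"), collapse = ","),
    paste(vapply(topology$dihedrals, paste, "", collapse = "-"), collapse = ","),
    paste(vapply(topology$fragments, paste, "", collapse = "-"), collapse = ","),
    sep = ";"
  ))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Measure a dihedral angle
#'
#' Standard torsion convention: looking down the `j -> k` bond, the angle
#' from the projection of `i` to the projection of `l`, counterclockwise
#' positive, reported in degrees in `[0, 360)`. A planar cis arrangement
#' (`i` and `l` on the same side) measures 0, trans measures 180.
#'
#' @param x a [conformer()].
#' @param topology a [dihedral_topology()].
#' @param d_index which dihedral (1-based).
#' @return angle in degrees in `[0, 360)`.
#' @export
measure_dihedral <- function(x, topology, d_index) {
  dh <- topology$dihedrals[[d_index]]
  p <- x$coords[dh, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 * sqrt(sum(b1^2) * sum(b2^2)) ||
      sqrt(sum(n2^2)) < 1e-10 * sqrt(sum(b2^2) * sum(b3^2)))
    stop(sprintf("dihedral %d is undefined: collinear atoms about the %d-%d axis",
                 d_index, dh[2], dh[3]), call. = FALSE)
  ang <- atan2(sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) / pi * 180
  canonical_angle(ang)
}

#' Set a dihedral angle by rigid-body rotation
#'
#' Rotates the dihedral's moving set about the `j-k` axis so that the torsion
#' measures `target` degrees. Bond lengths and angles inside every rigid
#' fragment are untouched; atoms outside the moving set do not move.
#'
#' @inheritParams measure_dihedral
#' @param target target angle in degrees (any real; reduced mod 360).
#' @return the rotated [conformer()].
#' @export
set_dihedral <- function(x, topology, d_index, target) {
  if (!is.finite(target)) stop("target angle must be finite", call. = FALSE)
  current <- measure_dihedral(x, topology, d_index)
  delta <- .deg2rad(canonical_angle(target) - current)
  if (abs(delta) < .Machine$double.eps) return(x)
  dh <- topology$dihedrals[[d_index]]
  origin <- x$coords[dh[2], ]
  axis <- x$coords[dh[3], ] - origin
  axis <- axis / sqrt(sum(axis^2))
  # Rodrigues rotation about the j->k axis; positive torsion change is a
  # counterclockwise rotation of the l side viewed from j towards k
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
  mv <- topology$moving_sets[[d_index]]
  shifted <- sweep(x$coords[mv, , drop = FALSE], 2, origin)
  x$coords[mv, ] <- sweep(shifted %*% t(R), 2, origin, "+")
  x
}

#' Set all dihedrals of a conformer at once
#'
#' @inheritParams measure_dihedral
#' @param angles numeric vector of length `n_d`, degrees.
#' @return the rotated [conformer()].
#' @export
set_configuration <- function(x, topology, angles) {
  angles <- drop(.as_config_matrix(angles, topology$n_d))
  for (d in seq_len(topology$n_d)) x <- set_dihedral(x, topology, d, angles[d])
  x
}

#' Measure all dihedrals of a conformer
#'
#' @inheritParams measure_dihedral
#' @return numeric vector of length `n_d`, degrees in `[0, 360)`.
#' @export
measure_configuration <- function(x, topology) {
  vapply(seq_len(topology$n_d), function(d) measure_dihedral(x, topology, d),
         numeric(1))
}

#' Detect steric clashes
#'
#' A conformer clashes when any eligible atom pair is closer than `threshold`
#' (strictly below; default 2.1 Angstrom). A pair is eligible when the two
#' atoms belong to different rigid fragments and are at least 4 bonds apart
#' in the bond graph — distances within a fragment, or across 1-2/1-3/1-4
#' neighbours, are fixed or governed by a single torsion and are never
#' counted as clashes.
#'
#' @inheritParams measure_dihedral
#' @param threshold distance threshold in Angstrom (> 0).
#' @return `TRUE` if a clash is present.
#' @export
detect_clash <- function(x, topology, threshold = 2.1) {
  stopifnot(threshold > 0)
  el <- which(topology$clash_eligible & upper.tri(topology$clash_eligible),
              arr.ind = TRUE)
  if (nrow(el) == 0L) return(FALSE)
  d2 <- rowSums((x$coords[el[, 1], , drop = FALSE] -
                 x$coords[el[, 2], , drop = FALSE])^2)
  any(d2 < threshold^2)
}
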