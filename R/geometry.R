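#' Minimum-image displacement in a cubic periodic box
#'
#' Displacement from `point_a` to `point_b` taking the nearest periodic
#' image of `point_b`. Each returned component lies in (-L/2, L/2].
#'
#' @param frame A [molecular_frame()] (only its `box_edge` is used), or a
#'   single numeric box edge.
#' @param point_a,point_b Numeric length-3 points, or m x 3 matrices of
#'   points (recycled row-wise against each other).
#' @return A length-3 vector (or m x 3 matrix) of displacements (Angstrom).
#' @export
minimum_image <- function(frame, point_a, point_b) {
  L <- if (inherits(frame, "molecular_frame")) frame$box_edge else frame
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  d <- point_b - point_a
  # component in (-L/2, L/2]: ceiling(x - 0.5) rounds half-integers down
  d - L * ceiling(d / L - 0.5)
}

# unwrap a molecule's atoms about its first atom under minimum image;
# returns coordinates in a contiguous (possibly out-of-cell) layout
.unwrap_about_first <- function(coords, L) {
  ref <- coords[1L, ]
  d <- sweep(coords, 2L, ref)
  d <- d - L * ceiling(d / L - 0.5)
  sweep(d, 2L, ref, "+")
}

#' Geometric centre of a molecule
#'
#' Unweighted mean of the molecule's atom positions after unwrapping the
#' molecule about its first atom under minimum image, so molecules split
#' across the periodic boundary get a physically sensible centre. The
#' result is wrapped into the primary cell [0, L).
#'
#' @param frame A [molecular_frame()].
#' @param molecule_id 1-based molecule index.
#' @param weights Optional per-atom weights (e.g. masses); default
#'   unweighted.
#' @return Length-3 numeric centre (Angstrom).
#' @export
molecule_com <- function(frame, molecule_id, weights = NULL) {
  idx <- molecule_atoms(frame, molecule_id)
  if (!length(idx)) stop("no such molecule: ", molecule_id)
  xyz <- .unwrap_about_first(frame$coords[idx, , drop = FALSE], frame$box_edge)
  com <- if (is.null(weights)) colMeans(xyz)
         else colSums(xyz * weights) / sum(weights)
  com %% frame$box_edge
}

# all molecule centres at once (unweighted); rows indexed by molecule id
.all_coms <- function(frame) {
  n <- n_molecules(frame)
  out <- matrix(NA_real_, n, 3L)
  L <- frame$box_edge
  ord <- order(frame$mol_id)
  ids <- frame$mol_id[ord]
  starts <- c(1L, which(diff(ids) != 0L) + 1L, length(ids) + 1L)
  for (k in seq_len(n)) {
    rows <- ord[starts[k]:(starts[k + 1L] - 1L)]
    xyz <- frame$coords[rows, , drop = FALSE]
    if (nrow(xyz) > 1L) xyz <- .unwrap_about_first(xyz, L)
    out[ids[starts[k]], ] <- colMeans(xyz) %% L
  }
  out
}

#' Least-squares aromatic plane normal of a molecule
#'
#' Unit normal of the least-squares plane through the species'
#' `plane_atoms`, after unwrapping under minimum image. The sign is fixed
#' deterministically (largest-magnitude component positive) unless a
#' `reference` normal is supplied, in which case the sign is chosen to give
#' a positive dot product with it — use this to keep normals continuous
#' across trajectory frames.
#'
#' @param frame A [molecular_frame()].
#' @param molecule_id 1-based molecule index.
#' @param reference Optional length-3 vector fixing the sign by continuity.
#' @return Unit length-3 normal vector.
#' @export
plane_normal <- function(frame, molecule_id, reference = NULL) {
  sp <- frame$species_info[[frame$species[molecule_id]]]
  pa <- sp$plane_atoms
  if (length(pa) < 3L)
    stop("species '", frame$species[molecule_id], "' has no aromatic plane")
  idx <- molecule_atoms(frame, molecule_id)[pa]
  xyz <- .unwrap_about_first(frame$coords[idx, , drop = FALSE], frame$box_edge)
  xc <- sweep(xyz, 2L, colMeans(xyz))
  sv <- svd(xc, nu = 0L)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1)) stop("plane atoms are collinear")
  n <- sv$v[, 3L]
  if (!is.null(reference)) {
    if (sum(n * reference) < 0) n <- -n
  } else {
    j <- which.max(abs(n))
    if (n[j] < 0) n <- -n
  }
  n / sqrt(sum(n^2))
}
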