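#' Periodic molecular configuration
#'
#' A `molecular_frame` holds atom coordinates in a cubic periodic box
#' together with the atom-to-molecule partition and per-species metadata
#' (role, plane atoms). Coordinates may lie outside the primary cell;
#' wrapping is handled by the geometry layer ([minimum_image()]).
#'
#' @param coords Numeric N x 3 matrix of coordinates (Angstrom).
#' @param mol_id Integer vector (length N): 1-based molecule index per atom.
#' @param species Character vector, one species name per molecule.
#' @param species_info Named list: per species a list with elements
#'   `role` (one of xanthine/agent/water/cation), `plane_atoms`
#'   (integer indices within the molecule) and `aromatic` (logical).
#' @param box_edge Cubic box edge length (Angstrom), > 0.
#' @param elements Optional character vector of element labels per atom.
#' @param frame_index Integer frame number (1-based within a trajectory).
#'
#' @return An object of class `molecular_frame`.
#' @export
molecular_frame <- function(coords, mol_id, species, species_info, box_edge,
                            elements = NULL, frame_index = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("'coords' must be N x 3")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  mol_id <- as.integer(mol_id)
  if (length(mol_id) != nrow(coords))
    stop("'mol_id' must assign every atom to a molecule")
  n_mol <- length(species)
  if (any(mol_id < 1L | mol_id > n_mol))
    stop("molecule indices out of range")
  if (!setequal(unique(mol_id), seq_len(n_mol)))
    stop("every molecule must own at least one atom")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || box_edge <= 0)
    stop("'box_edge' must be a single positive length")
  missing_sp <- setdiff(unique(species), names(species_info))
  if (length(missing_sp))
    stop("species without metadata: ", paste(missing_sp, collapse = ", "))
  if (is.null(elements)) elements <- rep("C", nrow(coords))
  structure(list(coords = coords, mol_id = mol_id, species = species,
                 species_info = species_info, box_edge = as.numeric(box_edge),
                 elements = elements, frame_index = as.integer(frame_index)),
            class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat(sprintf("<molecular_frame> %d atoms, %d molecules, box %.2f A\n",
              nrow(x$coords), length(x$species), x$box_edge))
  cat("  roles:", paste(sprintf("%s=%d", names(tab <- table(molecule_roles(x))),
                                tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of molecules in a frame
#' @param frame A [molecular_frame()].
#' @return Integer count.
#' @export
n_molecules <- function(frame) length(frame$species)

#' Per-molecule roles
#' @param frame A [molecular_frame()].
#' @return Character vector of roles, one per molecule.
#' @export
molecule_roles <- function(frame) {
  vapply(frame$species, function(s) frame$species_info[[s]]$role, "")
}

#' Atom indices of one molecule
#' @param frame A [molecular_frame()].
#' @param molecule_id 1-based molecule index.
#' @return Integer vector of atom row indices.
#' @export
molecule_atoms <- function(frame, molecule_id) {
  which(frame$mol_id == molecule_id)
}

#' Multi-frame trajectory
#'
#' An ordered list of [molecular_frame()]s sharing one topology (identical
#' atom count, molecule partition and species map across frames).
#'
#' @param frames List of `molecular_frame` objects.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  ref <- frames[[1L]]
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "molecular_frame")) stop("all elements must be frames")
    if (nrow(f$coords) != nrow(ref$coords) ||
        !identical(f$mol_id, ref$mol_id) ||
        !identical(f$species, ref$species))
      stop("frames share one topology: atom count and species map must match")
    frames[[i]]$frame_index <- i
  }
  structure(frames, class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s) of %d atoms, box %.2f A\n",
              length(x), nrow(x[[1L]]$coords), x[[1L]]$box_edge))
  invisible(x)
}

#' @export
`[.trajectory` <- function(x, i) trajectory(unclass(x)[i])
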