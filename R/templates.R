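#' Species templates
#'
#' A species template is a rigid, coarse molecular geometry used by the
#' synthetic-configuration generator. Templates carry only the heavy-atom
#' footprint needed by the geometric analyses (contact counts, plane
#' normals); they are not force-field geometries.
#'
#' @param name Species identifier (e.g. `"CAF"`).
#' @param role One of `"xanthine"`, `"agent"`, `"water"`, `"cation"`.
#' @param atoms Matrix (n x 3) of heavy-atom coordinates in Angstrom, in a
#'   body frame. Row names (or the `elements` argument) give element labels.
#' @param plane_atoms Integer indices (>= 3, non-collinear) of the atoms
#'   defining the aromatic plane; may be empty for water/cation.
#' @param aromatic Logical; whether the species carries an aromatic plane.
#' @param elements Character vector of element labels, one per atom.
#'
#' @return An object of class `species_template`.
#' @export
species_template <- function(name, role, atoms, plane_atoms = integer(),
                             aromatic = length(plane_atoms) >= 3,
                             elements = NULL) {
  role <- match.arg(role, c("xanthine", "agent", "water", "cation"))
  atoms <- as.matrix(atoms)
  if (ncol(atoms) != 3L || !all(is.finite(atoms)))
    stop("'atoms' must be a finite n x 3 coordinate matrix")
  if (is.null(elements)) {
    elements <- rownames(atoms)
    if (is.null(elements)) elements <- rep("C", nrow(atoms))
  }
  elements <- sub("[0-9]+$", "", elements)
  plane_atoms <- as.integer(plane_atoms)
  if (role %in% c("xanthine", "agent") && aromatic) {
    if (length(plane_atoms) < 3L)
      stop("planar species need >= 3 plane atoms")
    if (.collinear(atoms[plane_atoms, , drop = FALSE]))
      stop("plane atoms are collinear")
  }
  structure(list(name = name, role = role, atoms = unname(atoms),
                 elements = elements, plane_atoms = plane_atoms,
                 aromatic = isTRUE(aromatic)),
            class = "species_template")
}

# TRUE when the points span fewer than 2 independent in-plane directions
.collinear <- function(x, tol = 1e-8) {
  if (nrow(x) < 3L) return(TRUE)
  xc <- sweep(x, 2L, colMeans(x))
  d <- svd(xc, nu = 0L, nv = 0L)$d
  d[2L] < tol * max(d[1L], 1)
}

#' @export
print.species_template <- function(x, ...) {
  cat(sprintf("<species_template> %s (role=%s, %d atoms, aromatic=%s)\n",
              x$name, x$role, nrow(x$atoms), x$aromatic))
  invisible(x)
}

# regular polygon of n atoms with given circumradius, in the xy-plane
.ring <- function(n, radius) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(th), radius * sin(th), 0)
}

#' Built-in coarse templates
#'
#' Flat ring skeletons with a heavy-atom footprint representative of the
#' molecules under study: a fused bicyclic (purine-like) skeleton for
#' methylxanthines, a benzene ring plus carboxylate carbon for aromatic
#' agents, a short aliphatic chain for non-aromatic agents, a single-site
#' (oxygen) bead for water and a single-atom cation.
#'
#' @param name Species identifier used in species maps and PDB residues.
#' @return A [species_template()].
#' @export
xanthine_template <- function(name = "XAN") {
  # pyrimidine six-ring fused to an imidazole five-ring along one edge
  hex <- .ring(6L, 1.39)
  shared <- hex[c(1L, 2L), ]
  mid <- colMeans(shared)
  # direction away from the hexagon centre
  out <- mid / sqrt(sum(mid^2))
  edge <- shared[2L, ] - shared[1L, ]
  edge <- edge / sqrt(sum(edge^2))
  # three extra atoms completing the five-ring on the far side of the edge
  five <- rbind(mid + 1.15 * out + 0.55 * edge,
                mid + 1.75 * out,
                mid + 1.15 * out - 0.55 * edge)
  atoms <- rbind(hex, five)
  # centroid at the body origin, so the generator's placements are exact
  # in centre-of-geometry terms
  atoms <- sweep(atoms, 2L, colMeans(atoms))
  el <- c("N", "C", "N", "C", "C", "C", "N", "C", "N")
  species_template(name, "xanthine", atoms, plane_atoms = 1:9,
                   aromatic = TRUE, elements = el)
}

#' @rdname xanthine_template
#' @export
aromatic_agent_template <- function(name = "AGT") {
  hex <- .ring(6L, 1.39)
  sub <- hex[4L, ] * (1.39 + 1.5) / 1.39   # carboxylate carbon
  atoms <- rbind(hex, sub)
  atoms <- sweep(atoms, 2L, colMeans(atoms))
  species_template(name, "agent", atoms, plane_atoms = 1:6,
                   aromatic = TRUE,
                   elements = c(rep("C", 6L), "C"))
}

#' @rdname xanthine_template
#' @export
aliphatic_agent_template <- function(name = "LEV") {
  # levulinate-like zig-zag carbon chain; no aromatic plane
  z <- cbind(1.3 * (0:4), 0.5 * rep_len(c(0, 1), 5L), 0)
  z <- sweep(z, 2L, colMeans(z))
  species_template(name, "agent", z, plane_atoms = integer(),
                   aromatic = FALSE, elements = rep("C", 5L))
}

#' @rdname xanthine_template
#' @export
water_template <- function(name = "WAT") {
  species_template(name, "water", matrix(0, 1L, 3L), elements = "O")
}

#' @rdname xanthine_template
#' @export
cation_template <- function(name = "SOD") {
  species_template(name, "cation", matrix(0, 1L, 3L), elements = "Na")
}
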