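#' Synthetic-box specification
#'
#' Describes a periodic box of stacked fibrils (ordered sequences of planar
#' molecules along a random axis at a fixed stacking spacing), free planar
#' monomers, water and counter-ions. The generator records exact ground
#' truth (fibril membership, axial occupants, planted per-xanthine agent
#' count k) while building, so downstream classifiers can be validated
#' against a known answer.
#'
#' @param box_edge Cubic box edge (Angstrom).
#' @param fibrils List of character vectors; each vector is an ordered
#'   species sequence (planar roles only), e.g. `c("XAN","AGT","XAN")`.
#' @param n_free_xanthine,n_free_agent,n_water,n_cation Counts of free
#'   (non-fibril) molecules placed uniformly, clash-free.
#' @param free_agent_species Species name used for free agents (allows a
#'   non-aromatic, levulinate-like agent via `"LEV"`).
#' @param stack_spacing Interplane spacing along the fibril axis
#'   (Angstrom); default 3.4, the canonical aromatic stacking distance.
#' @param lateral_jitter_sd In-plane positional noise sd (Angstrom).
#' @param tilt_sd Plane-tilt noise sd (degrees).
#' @param clash_dist Minimum allowed heavy-atom distance between distinct
#'   molecules under minimum image (Angstrom).
#' @param min_planar_separation Minimum centre-to-centre distance between
#'   planar molecules of different placement units (fibrils or free
#'   monomers; Angstrom). Keeping this above the stacking range guarantees
#'   the planted fibril contacts are the only stacking contacts in the
#'   box, so the recorded ground truth is exhaustive.
#' @param max_attempts Rejection-sampling attempts before a packing error.
#' @param templates Named list of [species_template()]s.
#' @param seed Integer seed; identical spec + seed gives identical output.
#'
#' @return An object of class `box_spec`.
#' @export
box_spec <- function(box_edge = 80, fibrils = list(),
                     n_free_xanthine = 0L, n_free_agent = 0L,
                     n_water = 0L, n_cation = 0L,
                     free_agent_species = "AGT",
                     stack_spacing = 3.4, lateral_jitter_sd = 0,
                     tilt_sd = 0, clash_dist = 2.0,
                     min_planar_separation = 6.0, max_attempts = 10000L,
                     templates = default_templates(), seed = 1L) {
  stopifnot(box_edge > 0, stack_spacing > 0, clash_dist > 0,
            n_free_xanthine >= 0, n_free_agent >= 0, n_water >= 0,
            n_cation >= 0, lateral_jitter_sd >= 0, tilt_sd >= 0)
  for (fib in fibrils) {
    if (!is.character(fib) || !length(fib))
      stop("each fibril is a non-empty character species sequence")
    for (s in fib) {
      t <- templates[[s]]
      if (is.null(t)) stop("unknown species in fibril plan: ", s)
      if (!(t$role %in% c("xanthine", "agent")) || length(t$plane_atoms) < 3L)
        stop("fibril sequences may only use planar species; '", s,
             "' is not planar")
    }
  }
  if (is.null(templates[[free_agent_species]]))
    stop("unknown free_agent_species: ", free_agent_species)
  structure(list(box_edge = box_edge, fibrils = fibrils,
                 n_free_xanthine = as.integer(n_free_xanthine),
                 n_free_agent = as.integer(n_free_agent),
                 n_water = as.integer(n_water),
                 n_cation = as.integer(n_cation),
                 free_agent_species = free_agent_species,
                 stack_spacing = stack_spacing,
                 lateral_jitter_sd = lateral_jitter_sd, tilt_sd = tilt_sd,
                 clash_dist = clash_dist,
                 min_planar_separation = min_planar_separation,
                 max_attempts = as.integer(max_attempts),
                 templates = templates, seed = as.integer(seed)),
            class = "box_spec")
}

#' Default species templates used by the generator
#' @return Named list of [species_template()]s.
#' @export
default_templates <- function() {
  list(XAN = xanthine_template("XAN"),
       AGT = aromatic_agent_template("AGT"),
       LEV = aliphatic_agent_template("LEV"),
       WAT = water_template("WAT"),
       SOD = cation_template("SOD"))
}

# --- small rotation helpers ------------------------------------------------

.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# Rodrigues rotation matrix about unit axis by angle (radians)
.rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3L], a[2L], a[3L], 0, -a[1L], -a[2L], a[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation taking the body z-axis onto unit vector u
.rot_z_to <- function(u) {
  z <- c(0, 0, 1)
  c_ <- sum(z * u)
  if (c_ > 1 - 1e-12) return(diag(3L))
  if (c_ < -1 + 1e-12) return(.rot_axis_angle(c(1, 0, 0), pi))
  axis <- c(z[2L] * u[3L] - z[3L] * u[2L],
            z[3L] * u[1L] - z[1L] * u[3L],
            z[1L] * u[2L] - z[2L] * u[1L])
  .rot_axis_angle(axis, acos(c_))
}

# uniform random rotation (quaternion method)
.rand_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# minimum-image clash test of candidate atoms against placed atoms
.clashes <- function(cand, placed, L, clash_dist) {
  if (is.null(placed) || !nrow(placed)) return(FALSE)
  for (i in seq_len(nrow(cand))) {
    d <- sweep(placed, 2L, cand[i, ])
    d <- d - L * ceiling(d / L - 0.5)
    if (min(rowSums(d * d)) < clash_dist^2) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic periodic configuration with known ground truth
#'
#' Builds the box described by a [box_spec()]: each fibril is a rigid stack
#' of planar molecules along a random axis at `stack_spacing`, perturbed by
#' in-plane jitter and plane tilt; free monomers, water and ions are placed
#' uniformly by clash-free rejection sampling under minimum image.
#'
#' @param spec A [box_spec()].
#' @return A list with elements `frame` (a [molecular_frame()]) and `truth`
#'   (class `ground_truth`: a `molecules` data.frame with
#'   `molecule_id, species, role, fibril_id, planted_k` and an `axial`
#'   data.frame recording each planar molecule's up/down stack neighbours).
#' @export
generate_box <- function(spec) {
  stopifnot(inherits(spec, "box_spec"))
  set.seed(spec$seed)
  L <- spec$box_edge
  tilt_sd_rad <- spec$tilt_sd * pi / 180

  coords_list <- list()
  placed <- NULL            # grown matrix of all placed atoms
  planar_coms <- NULL       # centres of placed planar molecules
  species <- character()
  elements <- character()
  fibril_id <- integer()
  axial <- list()           # per planar molecule: up/down neighbour ids

  is_planar <- function(sp) length(spec$templates[[sp]]$plane_atoms) >= 3L

  add_molecule <- function(xyz, sp, fib, com) {
    coords_list[[length(coords_list) + 1L]] <<- xyz
    placed <<- rbind(placed, xyz)
    if (is_planar(sp)) planar_coms <<- rbind(planar_coms, com)
    species <<- c(species, sp)
    elements <<- c(elements, spec$templates[[sp]]$elements)
    fibril_id <<- c(fibril_id, fib)
    length(species)
  }

  # TRUE when any candidate planar centre sits within the planar
  # exclusion distance of a previously placed unit's planar centre
  too_close_planar <- function(coms) {
    if (is.null(planar_coms) || is.null(coms) || !nrow(coms)) return(FALSE)
    .clashes(coms, planar_coms, L, spec$min_planar_separation)
  }

  # --- fibrils: placed as rigid units, retried wholesale on clash ----------
  for (fi in seq_along(spec$fibrils)) {
    seqs <- spec$fibrils[[fi]]
    nseq <- length(seqs)
    ok <- FALSE
    for (attempt in seq_len(spec$max_attempts)) {
      u <- .rand_unit()
      Rz <- .rot_z_to(u)
      # in-plane basis for the lateral jitter
      e1 <- Rz %*% c(1, 0, 0)
      e2 <- Rz %*% c(0, 1, 0)
      centre <- stats::runif(3L, 0, L)
      unit_atoms <- vector("list", nseq)
      unit_pos <- matrix(NA_real_, nseq, 3L)
      for (p in seq_len(nseq)) {
        tmpl <- spec$templates[[seqs[p]]]
        spin <- .rot_axis_angle(u, stats::runif(1L, 0, 2 * pi))
        Rm <- spin %*% Rz
        if (spec$tilt_sd > 0) {
          tilt_axis <- cos(a0 <- stats::runif(1L, 0, 2 * pi)) * e1 +
            sin(a0) * e2
          Rm <- .rot_axis_angle(tilt_axis, stats::rnorm(1L, 0, tilt_sd_rad)) %*%
            Rm
        }
        pos <- centre + (p - (nseq + 1) / 2) * spec$stack_spacing * u
        if (spec$lateral_jitter_sd > 0)
          pos <- pos + stats::rnorm(1L, 0, spec$lateral_jitter_sd) * e1 +
            stats::rnorm(1L, 0, spec$lateral_jitter_sd) * e2
        unit_atoms[[p]] <- tmpl$atoms %*% t(Rm) +
          matrix(pos, nrow(tmpl$atoms), 3L, byrow = TRUE)
        unit_pos[p, ] <- pos
      }
      # clash against previously placed material only (the fibril's own
      # construction guarantees its internal spacing), and keep planar
      # centres outside the stacking range of earlier units
      if (!.clashes(do.call(rbind, unit_atoms), placed, L, spec$clash_dist) &&
          !too_close_planar(unit_pos)) {
        first_id <- length(species) + 1L
        for (p in seq_len(nseq))
          add_molecule(unit_atoms[[p]], seqs[p], fi, unit_pos[p, ])
        for (p in seq_len(nseq)) {
          id <- first_id + p - 1L
          axial[[id]] <- c(up = if (p < nseq) id + 1L else NA_integer_,
                           down = if (p > 1L) id - 1L else NA_integer_)
        }
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "packing failed for fibril %d after %d attempts (%.0f atoms in %.0f A box)",
        fi, spec$max_attempts, NROW(placed), L))
  }

  place_free <- function(sp, n, what) {
    tmpl <- spec$templates[[sp]]
    for (k in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(spec$max_attempts)) {
        Rm <- .rand_rotation()
        pos <- stats::runif(3L, 0, L)
        xyz <- tmpl$atoms %*% t(Rm) +
          matrix(pos, nrow(tmpl$atoms), 3L, byrow = TRUE)
        if (!.clashes(xyz, placed, L, spec$clash_dist) &&
            !(is_planar(sp) && too_close_planar(rbind(pos)))) {
          add_molecule(xyz, sp, NA_integer_, pos)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(
          "packing failed placing %s %d/%d after %d attempts (%.0f atoms in %.0f A box)",
          what, k, n, spec$max_attempts, NROW(placed), L))
    }
  }
  place_free("XAN", spec$n_free_xanthine, "free xanthine")
  place_free(spec$free_agent_species, spec$n_free_agent, "free agent")
  place_free("WAT", spec$n_water, "water")
  place_free("SOD", spec$n_cation, "cation")

  if (!length(species)) stop("empty box: nothing to place")

  n_at <- vapply(coords_list, nrow, 0L)
  frame <- molecular_frame(
    do.call(rbind, coords_list), rep(seq_along(n_at), n_at), species,
    .templates_to_info(spec$templates), L, elements = elements)

  roles <- molecule_roles(frame)
  role_of <- function(id) if (is.na(id)) NA_character_ else roles[id]
  axial_df <- data.frame(
    molecule_id = seq_along(species),
    up_mol = vapply(seq_along(species), function(i)
      if (i <= length(axial) && !is.null(axial[[i]]))
        axial[[i]][["up"]] else NA_integer_, 0L),
    down_mol = vapply(seq_along(species), function(i)
      if (i <= length(axial) && !is.null(axial[[i]]))
        axial[[i]][["down"]] else NA_integer_, 0L))
  axial_df$up_role <- vapply(axial_df$up_mol, role_of, "")
  axial_df$down_role <- vapply(axial_df$down_mol, role_of, "")

  planted_k <- ifelse(
    roles == "xanthine",
    (axial_df$up_role %in% "agent") + (axial_df$down_role %in% "agent"),
    NA_integer_)
  molecules <- data.frame(molecule_id = seq_along(species),
                          species = species, role = roles,
                          fibril_id = fibril_id,
                          planted_k = as.integer(planted_k),
                          stringsAsFactors = FALSE)
  truth <- structure(list(molecules = molecules, axial = axial_df),
                     class = "ground_truth")
  list(frame = frame, truth = truth)
}

.templates_to_info <- function(templates) {
  lapply(templates, function(t)
    list(role = t$role, plane_atoms = t$plane_atoms, aromatic = t$aromatic))
}

#' @export
print.ground_truth <- function(x, ...) {
  m <- x$molecules
  cat(sprintf("<ground_truth> %d molecules, %d in fibrils\n",
              nrow(m), sum(!is.na(m$fibril_id))))
  k <- m$planted_k[m$role == "xanthine"]
  if (length(k))
    cat("  planted k histogram:",
        paste(sprintf("k=%d:%d", as.integer(names(tk <- table(k))), tk),
              collapse = ", "), "\n")
  invisible(x)
}
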