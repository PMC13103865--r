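#' Neighbor-census parameters
#'
#' Cutoff distances defining "surrounding" for the census: a molecule
#' counts as a neighbor of a xanthine when its geometric centre (water:
#' its single site) lies within the cutoff of the xanthine's centre under
#' minimum image. The defaults are calibration choices of this package
#' (7 A is roughly two stacking spacings plus slack), not literature
#' values, and should be varied in sensitivity checks.
#'
#' @param molecule_com_cutoff Xanthine-xanthine and xanthine-agent centre
#'   cutoff (Angstrom).
#' @param water_cutoff Water-site to xanthine-centre cutoff (Angstrom).
#' @return An object of class `census_params`.
#' @export
census_params <- function(molecule_com_cutoff = 7.0, water_cutoff = 5.0) {
  stopifnot(molecule_com_cutoff > 0, water_cutoff > 0)
  structure(list(molecule_com_cutoff = molecule_com_cutoff,
                 water_cutoff = water_cutoff), class = "census_params")
}

# squared minimum-image distance matrix between point sets A (n x 3) and
# B (m x 3) in a cubic box of edge L
.mi_dist2 <- function(A, B, L) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - L * ceiling(dk / L - 0.5)
    d2 <- d2 + dk * dk
  }
  d2
}

# cell-list neighbor candidates: for each query row of 'pts', the indices
# of 'pts' rows within 'cutoff' (excluding self), in a cubic box of edge L.
# Falls back to NULL (meaning "use brute force") when the box is too small
# for a 3+ cell grid.
.cell_list_neighbors <- function(pts, L, cutoff) {
  nc <- floor(L / cutoff)
  if (nc < 3L) return(NULL)
  side <- L / nc
  ijk <- floor((pts %% L) / side)
  ijk[ijk >= nc] <- nc - 1L          # guard against rounding at the edge
  cell_id <- ijk[, 1L] + nc * (ijk[, 2L] + nc * ijk[, 3L])
  by_cell <- split(seq_len(nrow(pts)), cell_id)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(nrow(pts)), function(i) {
    nb_cells <- (rep(ijk[i, 1L], 27L) + offs[, 1L]) %% nc +
      nc * ((ijk[i, 2L] + offs[, 2L]) %% nc +
              nc * ((ijk[i, 3L] + offs[, 3L]) %% nc))
    cand <- unlist(by_cell[as.character(unique(nb_cells))],
                   use.names = FALSE)
    setdiff(cand, i)
  })
}

#' Neighbor census around each xanthine
#'
#' For every xanthine and frame, counts the xanthine, agent and water
#' molecules whose centre lies within the cutoff under minimum image
#' (self excluded); trajectory means average uniformly over frames and
#' xanthines. The default neighbor search uses cell lists with a
#' brute-force distance-matrix fallback; `method = "brute"` forces the
#' O(N^2) path (used as the independent oracle in tests).
#'
#' @param traj A [trajectory()] or single [molecular_frame()].
#' @param params A [census_params()].
#' @param method `"cell"` or `"brute"`.
#' @param stride Use every `stride`-th frame.
#' @return An object of class `neighbor_census`: list with `per_obs`
#'   (data.frame frame, molecule_id, n_xanthine, n_agent, n_water) and
#'   `means` (named numeric).
#' @export
neighbor_census <- function(traj, params = census_params(),
                            method = c("cell", "brute"), stride = 1L) {
  method <- match.arg(method)
  if (inherits(traj, "molecular_frame")) traj <- trajectory(list(traj))
  stopifnot(inherits(params, "census_params"))
  frames <- seq(1L, length(traj), by = stride)
  roles <- molecule_roles(traj[[1L]])
  xan <- which(roles == "xanthine")
  if (!length(xan)) stop("no xanthine molecules in the system")
  rmax <- max(params$molecule_com_cutoff, params$water_cutoff)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- traj[[frames[fi]]]
    coms <- .all_coms(f)
    L <- f$box_edge
    counts <- matrix(0L, length(xan), 3L)
    nb <- if (method == "cell") .cell_list_neighbors(coms, L, rmax) else NULL
    for (q in seq_along(xan)) {
      i <- xan[q]
      cand <- if (is.null(nb)) setdiff(seq_len(nrow(coms)), i) else nb[[i]]
      if (!length(cand)) next
      d2 <- .mi_dist2(coms[i, , drop = FALSE],
                      coms[cand, , drop = FALSE], L)[1L, ]
      r <- roles[cand]
      cc2 <- params$molecule_com_cutoff^2
      counts[q, ] <- c(sum(r == "xanthine" & d2 <= cc2),
                       sum(r == "agent" & d2 <= cc2),
                       sum(r == "water" & d2 <= params$water_cutoff^2))
    }
    out[[fi]] <- data.frame(frame = frames[fi], molecule_id = xan,
                            n_xanthine = counts[, 1L],
                            n_agent = counts[, 2L], n_water = counts[, 3L])
  }
  per_obs <- do.call(rbind, out)
  means <- c(n_xanthine = mean(per_obs$n_xanthine),
             n_agent = mean(per_obs$n_agent),
             n_water = mean(per_obs$n_water))
  structure(list(per_obs = per_obs, means = means, params = params),
            class = "neighbor_census")
}

#' @export
print.neighbor_census <- function(x, ...) {
  cat(sprintf(
    "<neighbor_census> %d observations (%d frame(s))\n",
    nrow(x$per_obs), length(unique(x$per_obs$frame))))
  cat(sprintf(
    "  mean neighbors per xanthine: %.2f xanthine, %.2f agent, %.2f water\n",
    x$means["n_xanthine"], x$means["n_agent"], x$means["n_water"]))
  invisible(x)
}
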