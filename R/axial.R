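#' Axial-stacking classification parameters
#'
#' A neighbor j sits in an axial (stacking) site of planar molecule i when
#' the centre-to-centre displacement, projected on i's plane normal, has
#' magnitude inside `axial_window`, the residual in-plane (lateral) offset
#' is at most `lateral_max`, and the two molecular planes are tilted by at
#' most `max_tilt`. Defaults are this package's calibration around the
#' 3.4 A aromatic stacking distance, not literature values.
#'
#' @param axial_window Length-2 numeric `[d_min, d_max]` (Angstrom),
#'   0 < d_min < d_max.
#' @param lateral_max Maximum lateral offset (Angstrom).
#' @param max_tilt Maximum interplane angle (degrees, in (0, 90]).
#' @return An object of class `axial_params`.
#' @export
axial_params <- function(axial_window = c(2.5, 5.0), lateral_max = 2.5,
                         max_tilt = 40) {
  stopifnot(length(axial_window) == 2L, axial_window[1L] > 0,
            axial_window[1L] < axial_window[2L], lateral_max > 0,
            max_tilt > 0, max_tilt <= 90)
  structure(list(axial_window = as.numeric(axial_window),
                 lateral_max = lateral_max, max_tilt = max_tilt),
            class = "axial_params")
}

# qualifying axial contacts of every 'central' planar molecule in a frame.
# Returns a data.frame: central, neighbor, side (+1 above / -1 below by the
# central normal), axial (|projection|), dist, slot (logical: nearest
# qualifying occupant of its side, ties to the lower molecule id).
.axial_contacts <- function(frame, params, central = NULL) {
  roles <- molecule_roles(frame)
  info <- frame$species_info
  planar <- which(vapply(frame$species, function(s)
    length(info[[s]]$plane_atoms) >= 3L, TRUE))
  if (is.null(central)) central <- planar
  central <- intersect(central, planar)
  if (!length(planar))
    return(data.frame(central = integer(), neighbor = integer(),
                      side = integer(), axial = numeric(),
                      dist = numeric(), slot = logical()))
  coms <- .all_coms(frame)
  L <- frame$box_edge
  normals <- matrix(NA_real_, n_molecules(frame), 3L)
  for (m in planar) normals[m, ] <- plane_normal(frame, m)
  cos_tilt <- cos(params$max_tilt * pi / 180)
  res <- list()
  for (i in central) {
    js <- setdiff(planar, i)
    if (!length(js)) next
    d <- sweep(coms[js, , drop = FALSE], 2L, coms[i, ])
    d <- d - L * ceiling(d / L - 0.5)
    a <- drop(d %*% normals[i, ])
    dist <- sqrt(rowSums(d * d))
    lat2 <- pmax(dist^2 - a^2, 0)
    tilt_ok <- abs(drop(normals[js, , drop = FALSE] %*% normals[i, ])) >=
      cos_tilt - 1e-12
    ok <- abs(a) >= params$axial_window[1L] &
      abs(a) <= params$axial_window[2L] &
      lat2 <= params$lateral_max^2 & tilt_ok
    if (!any(ok)) next
    js <- js[ok]; a <- a[ok]; dist <- dist[ok]
    slot <- logical(length(js))
    for (sgn in c(1, -1)) {
      on_side <- which(sign(a) == sgn)
      if (length(on_side)) {
        o <- on_side[order(dist[on_side], js[on_side])]
        slot[o[1L]] <- TRUE
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      central = i, neighbor = js, side = as.integer(sign(a)),
      axial = abs(a), dist = dist, slot = slot)
  }
  if (!length(res))
    return(data.frame(central = integer(), neighbor = integer(),
                      side = integer(), axial = numeric(),
                      dist = numeric(), slot = logical()))
  do.call(rbind, res)
}

#' Classify axial stacking occupants of each xanthine
#'
#' For every xanthine and frame, finds the planar molecules occupying its
#' two axial sites (one occupant per side: the nearest qualifying
#' neighbor, ties broken by lower molecule id) and counts agent-role
#' occupants. `k_slots` counts agents among the two slot winners (<= 2);
#' `k_all` counts every qualifying agent contact in the axial window, the
#' permissive reading under which three agents can crowd one xanthine.
#'
#' @param traj A [trajectory()] or single [molecular_frame()].
#' @param params An [axial_params()].
#' @param stride Use every `stride`-th frame.
#' @return An object of class `axial_classification`: data.frame with one
#'   row per (frame, xanthine): `frame, molecule_id, up_mol, up_role,
#'   down_mol, down_role, k_slots, k_all`.
#' @export
classify_axial <- function(traj, params = axial_params(), stride = 1L) {
  if (inherits(traj, "molecular_frame")) traj <- trajectory(list(traj))
  stopifnot(inherits(params, "axial_params"))
  roles <- molecule_roles(traj[[1L]])
  xan <- which(roles == "xanthine")
  if (!length(xan)) stop("no xanthine molecules in the system")
  frames <- seq(1L, length(traj), by = stride)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- traj[[frames[fi]]]
    ct <- .axial_contacts(f, params, central = xan)
    rows <- data.frame(frame = frames[fi], molecule_id = xan,
                       up_mol = NA_integer_, up_role = NA_character_,
                       down_mol = NA_integer_, down_role = NA_character_,
                       k_slots = 0L, k_all = 0L, stringsAsFactors = FALSE)
    if (nrow(ct)) {
      for (q in seq_along(xan)) {
        ci <- ct[ct$central == xan[q], , drop = FALSE]
        if (!nrow(ci)) next
        up <- ci[ci$slot & ci$side > 0L, ]
        dn <- ci[ci$slot & ci$side < 0L, ]
        if (nrow(up)) {
          rows$up_mol[q] <- up$neighbor[1L]
          rows$up_role[q] <- roles[up$neighbor[1L]]
        }
        if (nrow(dn)) {
          rows$down_mol[q] <- dn$neighbor[1L]
          rows$down_role[q] <- roles[dn$neighbor[1L]]
        }
        rows$k_slots[q] <- sum(c(rows$up_role[q], rows$down_role[q]) %in%
                                 "agent")
        rows$k_all[q] <- sum(roles[ci$neighbor] == "agent")
      }
    }
    out[[fi]] <- rows
  }
  structure(do.call(rbind, out), params = params,
            class = c("axial_classification", "data.frame"))
}

#' Axial stacking-configuration distribution P(k)
#'
#' Fraction of (xanthine, frame) observations with exactly k agent
#' molecules in axial stacking contact, k = 0..3, pooled over xanthines
#' and frames. Under the default `count = "slots"` k cannot exceed 2 (one
#' occupant per side); `count = "all"` counts every qualifying axial
#' contact and folds occurrences above 3 into k = 3 with a warning.
#'
#' @param axial An [classify_axial()] result.
#' @param count `"slots"` or `"all"`.
#' @return An object of class `config_distribution`: numeric `P(0..3)`
#'   summing to 1, with attribute `n_obs`.
#' @export
config_distribution <- function(axial, count = c("slots", "all")) {
  count <- match.arg(count)
  k <- if (count == "slots") axial$k_slots else axial$k_all
  if (any(k > 3L)) {
    warning(sum(k > 3L), " observation(s) with k > 3 folded into k = 3")
    k[k > 3L] <- 3L
  }
  p <- as.numeric(table(factor(k, levels = 0:3)) / length(k))
  structure(stats::setNames(p, paste0("P", 0:3)), n_obs = length(k),
            count = count, class = "config_distribution")
}

#' @export
print.config_distribution <- function(x, ...) {
  cat("<config_distribution> over", attr(x, "n_obs"), "observations\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Bias-corrected per-agent stacking efficiency
#'
#' The mean agent count per xanthine, `kbar = sum(k * P(k))`, depends on
#' how many xanthines compete for the agents; multiplying by the number of
#' xanthines and dividing by the number of agents gives the average number
#' of xanthines engaged per agent molecule,
#' `E = kbar * n_xanthine / n_agent`, which is comparable across systems
#' with different xanthine concentrations.
#'
#' @param p A [config_distribution()] (or bare numeric P(0..3) summing
#'   to 1).
#' @param n_xanthine,n_agent Molecule counts in the box; `n_agent` > 0.
#' @return An object of class `efficiency_result`: list with `kbar`,
#'   `efficiency`, `n_xanthine`, `n_agent`.
#' @export
agent_efficiency <- function(p, n_xanthine, n_agent) {
  if (n_agent <= 0) stop("n_agent must be positive")
  pv <- as.numeric(p)
  if (length(pv) != 4L || any(pv < 0) || abs(sum(pv) - 1) > 1e-8)
    stop("p must be a probability vector P(0..3)")
  kbar <- sum((0:3) * pv)
  structure(list(kbar = kbar, efficiency = kbar * n_xanthine / n_agent,
                 n_xanthine = n_xanthine, n_agent = n_agent),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf(
    "<efficiency_result> kbar = %.4f; E = %.4f (%d xanthine / %d agent)\n",
    x$kbar, x$efficiency, x$n_xanthine, x$n_agent))
  invisible(x)
}

# minimal union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect stacked aggregates and fibrils in a frame
#'
#' Builds the symmetric stacking-contact graph (i and j are in contact
#' when either occupies an axial slot of the other), takes connected
#' components over the planar molecules, and flags a component as a fibril
#' when its contact graph is a simple path of at least 3 molecules. Agent
#' positions within a fibril distinguish intercalation (degree-2 interior
#' agents) from end-capping (degree-1 terminal agents).
#'
#' @param frame A [molecular_frame()].
#' @param params An [axial_params()].
#' @return An object of class `aggregate_set`: list with `components`
#'   (data.frame: component, size, n_xanthine, n_agent, is_fibril,
#'   interior_agent_fraction), `membership` (component id per molecule, NA
#'   for non-planar) and `edges` (two-column matrix of contacts).
#' @export
detect_aggregates <- function(frame, params = axial_params()) {
  roles <- molecule_roles(frame)
  info <- frame$species_info
  planar <- which(vapply(frame$species, function(s)
    length(info[[s]]$plane_atoms) >= 3L, TRUE))
  ct <- .axial_contacts(frame, params, central = planar)
  sl <- ct[ct$slot, , drop = FALSE]
  edges <- if (nrow(sl))
    unique(cbind(pmin(sl$central, sl$neighbor),
                 pmax(sl$central, sl$neighbor)))
  else matrix(integer(), 0L, 2L)
  n <- n_molecules(frame)
  parent <- seq_len(n)
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ra <- .uf_find(parent, edges[e, 1L])
    rb <- .uf_find(parent, edges[e, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  membership <- rep(NA_integer_, n)
  roots <- vapply(planar, function(i) .uf_find(parent, i), 0L)
  membership[planar] <- match(roots, unique(roots))
  deg <- tabulate(c(edges), nbins = n)
  comps <- lapply(seq_along(unique(roots)), function(ci) {
    mem <- planar[membership[planar] == ci]
    in_comp <- matrix(membership[edges] == ci, ncol = 2L)
    ne <- if (nrow(edges)) sum(in_comp[, 1L]) else 0L
    size <- length(mem)
    is_path <- size >= 3L && ne == size - 1L && all(deg[mem] <= 2L) &&
      sum(deg[mem] == 1L) == 2L
    ag <- mem[roles[mem] == "agent"]
    data.frame(component = ci, size = size,
               n_xanthine = sum(roles[mem] == "xanthine"),
               n_agent = length(ag), is_fibril = is_path,
               interior_agent_fraction =
                 if (length(ag)) mean(deg[ag] == 2L) else NA_real_)
  })
  structure(list(components = do.call(rbind, comps),
                 membership = membership, edges = edges),
            class = "aggregate_set")
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat(sprintf("<aggregate_set> %d component(s), %d fibril(s)\n",
              nrow(x$components), sum(x$components$is_fibril)))
  print(x$components, row.names = FALSE)
  invisible(x)
}
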