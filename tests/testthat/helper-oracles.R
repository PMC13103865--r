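# Independent brute-force oracles used to validate the package's geometry
# and neighbor-search code. These deliberately share no code with the
# implementation: minimum image is taken over all 27 periodic images, and
# molecule centres are recomputed from raw coordinates.

# displacement a -> b choosing the closest of the 27 periodic images of b
# (the raw difference is first folded into the primary cell, so the points
# themselves may lie anywhere)
oracle_min_image <- function(L, a, b) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * L
  cand <- sweep(shifts, 2L, (b - a) %% L, "+")
  unname(cand[which.min(rowSums(cand^2)), ])
}

# vectorised |min-image displacement| for n point pairs (n x 3 matrices)
oracle_min_image_norm <- function(L, A, B) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * L
  best <- rep(Inf, nrow(A))
  D <- (B - A) %% L
  for (s in seq_len(27L)) {
    d2 <- rowSums(sweep(D, 2L, shifts[s, ], "+")^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# geometric centre of a molecule: shift each atom to the image nearest the
# first atom, then average and wrap into [0, L)
oracle_com <- function(frame, mol) {
  idx <- which(frame$mol_id == mol)
  xyz <- frame$coords[idx, , drop = FALSE]
  ref <- xyz[1L, ]
  for (i in seq_len(nrow(xyz)))
    xyz[i, ] <- ref + oracle_min_image(frame$box_edge, ref, xyz[i, ])
  colMeans(xyz) %% frame$box_edge
}

# O(N^2) double-loop neighbor census around every xanthine
oracle_census <- function(frame, params) {
  roles <- molecule_roles(frame)
  n <- n_molecules(frame)
  coms <- t(vapply(seq_len(n), function(m) oracle_com(frame, m), numeric(3)))
  xan <- which(roles == "xanthine")
  out <- data.frame(molecule_id = xan, n_xanthine = 0L, n_agent = 0L,
                    n_water = 0L)
  for (q in seq_along(xan)) {
    i <- xan[q]
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum(oracle_min_image(frame$box_edge, coms[i, ], coms[j, ])^2))
      if (roles[j] == "xanthine" && d <= params$molecule_com_cutoff)
        out$n_xanthine[q] <- out$n_xanthine[q] + 1L
      if (roles[j] == "agent" && d <= params$molecule_com_cutoff)
        out$n_agent[q] <- out$n_agent[q] + 1L
      if (roles[j] == "water" && d <= params$water_cutoff)
        out$n_water[q] <- out$n_water[q] + 1L
    }
  }
  out
}

# smallest inter-molecular heavy-atom distance under minimum image
oracle_min_intermolecular_dist <- function(frame) {
  L <- frame$box_edge
  best <- Inf
  n_at <- nrow(frame$coords)
  for (i in seq_len(n_at - 1L)) {
    js <- which(frame$mol_id[(i + 1L):n_at] != frame$mol_id[i]) + i
    if (!length(js)) next
    d <- oracle_min_image_norm(L,
                               frame$coords[rep(i, length(js)), , drop = FALSE],
                               frame$coords[js, , drop = FALSE])
    best <- min(best, min(d))
  }
  best
}

# ad-hoc frame from a list of per-molecule coordinate matrices
make_frame <- function(mols, roles, box_edge, plane = NULL) {
  species <- paste0("S", seq_along(mols))
  info <- lapply(seq_along(mols), function(i)
    list(role = roles[i],
         plane_atoms = if (is.null(plane)) integer() else plane[[i]],
         aromatic = !is.null(plane) && length(plane[[i]]) >= 3L))
  names(info) <- species
  n_at <- vapply(mols, nrow, 0L)
  molecular_frame(do.call(rbind, mols), rep(seq_along(mols), n_at),
                  species, info, box_edge)
}

# a mixed-composition box spec used across recovery tests (~82 molecules)
recovery_spec <- function(seed, tilt_sd = 0, lateral_jitter_sd = 0) {
  box_spec(box_edge = 45,
           fibrils = list(c("XAN", "AGT", "XAN", "XAN", "AGT", "XAN"),
                          c("AGT", "XAN", "AGT"),
                          c("XAN", "XAN", "XAN", "XAN")),
           n_free_xanthine = 4, n_free_agent = 2, n_water = 60,
           tilt_sd = tilt_sd, lateral_jitter_sd = lateral_jitter_sd,
           seed = seed)
}
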