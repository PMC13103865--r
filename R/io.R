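#' Read and write multi-frame XYZ
#'
#' The XYZ dialect used here: line 1 the atom count, line 2 a comment
#' carrying a `box=<L>` token (Angstrom), then one `element x y z` line per
#' atom; frames are concatenated. XYZ has no topology, so the molecule
#' partition and species metadata come from a species map sidecar
#' ([read_species_map()]).
#'
#' @param path File path.
#' @param species_map Species map as returned by [read_species_map()], or a
#'   path to one.
#' @return [read_xyz()] returns a [trajectory()].
#' @export
read_xyz <- function(path, species_map) {
  if (is.character(species_map)) species_map <- read_species_map(species_map)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed atom-count line at line ", i)
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec("box=([0-9.eE+-]+)", comment))[[1L]]
    if (length(m) < 2L)
      stop("missing 'box=<L>' token on XYZ comment line ", i + 1L)
    L <- as.numeric(m[2L])
    body <- lines[(i + 2L):(i + 1L + nat)]
    if (length(body) != nat || any(is.na(body)) ||
        any(!nzchar(trimws(body))) || (i + 1L + nat) > length(lines))
      stop("atom-count mismatch: header says ", nat, " atoms")
    tok <- strsplit(trimws(body), "[[:space:]]+")
    el <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (any(is.na(xyz))) stop("non-numeric coordinates in XYZ body")
    frames[[length(frames) + 1L]] <-
      .frame_from_map(xyz, el, L, species_map, length(frames) + 1L)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  trajectory(frames)
}

#' @rdname read_xyz
#' @param traj A [trajectory()] or single [molecular_frame()].
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "molecular_frame")) traj <- trajectory(list(traj))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj) {
    writeLines(c(as.character(nrow(f$coords)),
                 sprintf("box=%.6f frame=%d", f$box_edge, f$frame_index)), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", f$elements,
                       f$coords[, 1L], f$coords[, 2L], f$coords[, 3L]), con)
  }
  invisible(path)
}

# build a molecular_frame from flat coordinates + a species map
.frame_from_map <- function(xyz, elements, box_edge, species_map, frame_index) {
  n_per <- species_map$n_atoms
  if (sum(n_per) != nrow(xyz))
    stop("species map covers ", sum(n_per), " atoms but frame has ", nrow(xyz))
  mol_id <- rep(seq_along(n_per), n_per)
  molecular_frame(xyz, mol_id, species_map$species,
                  attr(species_map, "species_info"), box_edge,
                  elements = elements, frame_index = frame_index)
}

#' Species map sidecar CSV
#'
#' One row per molecule: `molecule_id, species, role, n_atoms,
#' plane_atom_indices` (semicolon-separated 1-based indices within the
#' molecule, empty for water/cation). Atoms are assumed ordered by
#' molecule, matching the frame files the generator writes.
#'
#' @param frame A [molecular_frame()] (for writing).
#' @param path File path.
#' @return [read_species_map()] returns a data.frame with a
#'   `species_info` attribute suitable for [read_xyz()] / [read_pdb()].
#' @export
write_species_map <- function(frame, path) {
  info <- frame$species_info
  df <- data.frame(
    molecule_id = seq_along(frame$species),
    species = frame$species,
    role = molecule_roles(frame),
    n_atoms = as.integer(table(factor(frame$mol_id,
                                      seq_along(frame$species)))),
    plane_atom_indices = vapply(frame$species, function(s)
      paste(info[[s]]$plane_atoms, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_species_map
#' @export
read_species_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(plane_atom_indices = "character"))
  need <- c("molecule_id", "species", "role", "n_atoms")
  if (!all(need %in% names(df)))
    stop("species map must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$molecule_id), , drop = FALSE]
  info <- list()
  for (i in seq_len(nrow(df))) {
    s <- df$species[i]
    if (is.null(info[[s]])) {
      pa <- df$plane_atom_indices[i]
      pa <- if (is.na(pa) || !nzchar(pa)) integer() else
        as.integer(strsplit(pa, ";")[[1L]])
      info[[s]] <- list(role = df$role[i], plane_atoms = pa,
                        aromatic = length(pa) >= 3L)
    }
  }
  attr(df, "species_info") <- info
  df
}

#' Read and write multi-frame PDB
#'
#' Cubic boxes only: a `CRYST1` record with a = b = c and all angles 90 is
#' required. Frames are `MODEL`/`ENDMDL` blocks (a single bare frame is
#' also accepted); one residue per molecule, residue name = species.
#' Species roles and plane atoms are not expressible in PDB, so a species
#' map may be supplied; without one, roles default from residue names that
#' match the built-in templates and remain `NA` otherwise.
#'
#' @param path File path.
#' @param species_map Optional species map ([read_species_map()]) or path.
#' @return [read_pdb()] returns a [trajectory()].
#' @export
read_pdb <- function(path, species_map = NULL) {
  hdr <- readLines(path)
  cl <- grep("^CRYST1", hdr, value = TRUE)
  if (!length(cl)) stop("missing CRYST1 record: box size unknown")
  a <- as.numeric(substr(cl[1L], 7, 15))
  b <- as.numeric(substr(cl[1L], 16, 24))
  c3 <- as.numeric(substr(cl[1L], 25, 33))
  ang <- c(as.numeric(substr(cl[1L], 34, 40)),
           as.numeric(substr(cl[1L], 41, 47)),
           as.numeric(substr(cl[1L], 48, 54)))
  if (any(abs(ang - 90) > 1e-3) || abs(a - b) > 1e-3 || abs(a - c3) > 1e-3)
    stop("only cubic cells are supported; got a=", a, " b=", b, " c=", c3,
         " angles=", paste(ang, collapse = "/"))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  mol_id <- match(at$resno, unique(at$resno))
  species <- at$resid[!duplicated(mol_id)]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el))))
    el <- sub("[0-9]+$", "", trimws(at$elety))
  if (is.character(species_map)) species_map <- read_species_map(species_map)
  info <- if (!is.null(species_map)) attr(species_map, "species_info")
          else .guess_species_info(species, mol_id, at)
  nmodel <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nmodel), function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
    molecular_frame(xyz, mol_id, species, info, a, elements = el,
                    frame_index = k)
  })
  trajectory(frames)
}

# fall back to built-in template metadata keyed by residue name
.guess_species_info <- function(species, mol_id, at) {
  builtin <- list(XAN = xanthine_template(), AGT = aromatic_agent_template(),
                  LEV = aliphatic_agent_template(), WAT = water_template(),
                  SOD = cation_template())
  info <- list()
  for (s in unique(species)) {
    t <- builtin[[s]]
    info[[s]] <- if (!is.null(t))
      list(role = t$role, plane_atoms = t$plane_atoms, aromatic = t$aromatic)
    else list(role = NA_character_, plane_atoms = integer(), aromatic = FALSE)
  }
  info
}

#' @rdname read_pdb
#' @param traj A [trajectory()] or single [molecular_frame()].
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "molecular_frame")) traj <- trajectory(list(traj))
  f1 <- traj[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    f1$box_edge, f1$box_edge, f1$box_edge, 90, 90, 90), con)
  # per-molecule atom serial within residue, for unique atom names
  within <- stats::ave(seq_along(f1$mol_id), f1$mol_id, FUN = seq_along)
  anames <- sprintf("%s%d", f1$elements, within)
  resn <- sprintf("%-3s", substr(f1$species, 1L, 3L))
  for (f in traj) {
    writeLines(sprintf("MODEL     %4d", f$frame_index), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%4s  %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_along(f$mol_id) %% 100000L, substr(anames, 1L, 4L),
      resn[f$mol_id], f$mol_id %% 10000L,
      f$coords[, 1L], f$coords[, 2L], f$coords[, 3L],
      substr(f$elements, 1L, 2L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write generator ground truth as a sidecar CSV
#'
#' Columns: `molecule_id, species, role, fibril_id, planted_k` (with empty
#' fields where not applicable).
#'
#' @param gt A `ground_truth` object from [generate_box()].
#' @param path File path.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(gt$molecules, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
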