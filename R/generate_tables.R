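#' Generate a synthetic solubility curve
#'
#' Two generating models span the mechanistic alternatives for small-
#' molecule solubilization: a linear law `s(c) = s0 + slope * c`
#' (complexation-like: stoichiometric association with the agent) and an
#' MHC law that stays flat at `s0` below a minimum hydrotropic
#' concentration and grows exponentially above it,
#' `s(c) = s0 * exp(b * (c - MHC))` for `c >= MHC` (classical hydrotropy).
#' I.i.d. Gaussian noise is added and values are floored at zero.
#'
#' @param model `"linear"` or `"mhc"`.
#' @param params Named numeric: linear needs `s0`, `slope`; mhc needs
#'   `s0`, `mhc`, `b` (growth rate). All must be non-negative.
#' @param noise_sd Gaussian noise sd (mol/kg).
#' @param n_points Number of points (>= 4) on an even grid over
#'   `[0, c_max]`.
#' @param c_max Largest agent molality (mol/kg).
#' @param seed Integer seed.
#' @param xanthine,agent Labels carried on the curve.
#' @return A `solubility_curve`: data.frame with columns `c` (agent
#'   molality) and `s` (xanthine solubility), plus label attributes.
#' @export
generate_solubility_curve <- function(model = c("linear", "mhc"), params,
                                      noise_sd = 0, n_points = 10L,
                                      c_max = 3, seed = 1L,
                                      xanthine = "caffeine",
                                      agent = "agent") {
  model <- match.arg(model)
  if (n_points < 4L) stop("need at least 4 points")
  if (any(unlist(params) < 0)) stop("negative parameters rejected")
  need <- if (model == "linear") c("s0", "slope") else c("s0", "mhc", "b")
  if (!all(need %in% names(params)))
    stop("params for '", model, "' must contain: ",
         paste(need, collapse = ", "))
  set.seed(seed)
  cgrid <- seq(0, c_max, length.out = n_points)
  s <- solubility_law(cgrid, model, params)
  if (noise_sd > 0) s <- s + stats::rnorm(n_points, 0, noise_sd)
  s <- pmax(s, 0)
  solubility_curve(cgrid, s, xanthine = xanthine, agent = agent)
}

#' Evaluate a solubility law
#' @param c_agent Agent molalities (mol/kg).
#' @inheritParams generate_solubility_curve
#' @return Numeric solubilities (mol/kg).
#' @export
solubility_law <- function(c_agent, model = c("linear", "mhc"), params) {
  model <- match.arg(model)
  p <- as.list(params)
  if (model == "linear") p$s0 + p$slope * c_agent
  else ifelse(c_agent < p$mhc, p$s0, p$s0 * exp(p$b * (c_agent - p$mhc)))
}

#' Solubility-curve container
#' @param c_agent Strictly increasing agent molalities >= 0 (mol/kg).
#' @param s Measured xanthine solubilities >= 0 (mol/kg).
#' @param sd Optional per-point standard deviations.
#' @param xanthine,agent Labels.
#' @return A data.frame of class `solubility_curve`.
#' @export
solubility_curve <- function(c_agent, s, sd = NULL, xanthine = "xanthine",
                             agent = "agent") {
  if (any(c_agent < 0) || any(diff(c_agent) <= 0))
    stop("agent molalities must be >= 0 and strictly increasing")
  if (any(s < 0)) stop("solubilities must be >= 0")
  df <- data.frame(c = c_agent, s = s)
  if (!is.null(sd)) df$sd <- sd
  structure(df, xanthine = xanthine, agent = agent,
            class = c("solubility_curve", "data.frame"))
}

# molality of pure water: 1 kg of water contains 1/M_W moles
.M_W <- 0.0180153
.WATER_MOLALITY <- 1 / .M_W

#' Generate a quantitative 1H NMR peak table
#'
#' Produces per-peak integrals proportional to molar amounts in 1 kg of
#' water, under the internal-standard convention used for aqueous qNMR:
#' the water signal (4.80 ppm) carries two protons per molecule at
#' 55.51 mol/kg, and all integrals are normalized so a designated
#' one-proton xanthine peak integrates to exactly 1.
#'
#' @param molalities Named numeric vector of solute molalities (mol/kg),
#'   the first entry being the xanthine whose one-proton peak defines the
#'   normalization.
#' @param protons Named list: per compound, an integer vector of protons
#'   contributing to each of its peaks (>= 1).
#' @param noise_sd Relative Gaussian noise sd applied to each integral.
#' @param seed Integer seed.
#' @return An `nmr_peak_table`: data.frame with columns
#'   `compound, peak, integral, n_protons`, including one `water` row.
#' @export
generate_nmr_table <- function(molalities, protons = NULL, noise_sd = 0,
                               seed = 1L) {
  if (any(molalities < 0)) stop("molalities must be >= 0")
  if (is.null(names(molalities)) || any(!nzchar(names(molalities))))
    stop("molalities must be named by compound")
  if (is.null(protons))
    protons <- stats::setNames(rep(list(1L), length(molalities)),
                               names(molalities))
  if (any(unlist(protons) < 1L)) stop("proton counts must be >= 1")
  set.seed(seed)
  ref_m <- molalities[[1L]]
  # normalization factor: the reference one-proton peak integrates to 1;
  # with nothing dissolved fall back to an arbitrary positive scale
  scale <- if (ref_m > 0) 1 / ref_m else 1
  rows <- list()
  for (cmp in names(molalities)) {
    np <- protons[[cmp]]
    if (is.null(np)) np <- 1L
    for (j in seq_along(np)) {
      a <- molalities[[cmp]] * np[j] * scale
      if (noise_sd > 0) a <- max(0, a * (1 + stats::rnorm(1L, 0, noise_sd)))
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, peak = paste0(cmp, "_", j), integral = a,
        n_protons = np[j], stringsAsFactors = FALSE)
    }
  }
  aw <- .WATER_MOLALITY * 2 * scale
  if (noise_sd > 0) aw <- max(0, aw * (1 + stats::rnorm(1L, 0, noise_sd)))
  rows[[length(rows) + 1L]] <- data.frame(
    compound = "water", peak = "water", integral = aw, n_protons = 2L,
    stringsAsFactors = FALSE)
  structure(do.call(rbind, rows),
            class = c("nmr_peak_table", "data.frame"))
}

#' Generate a synthetic ROESY cross-peak table
#'
#' Emulates the two association regimes seen in xanthine/agent mixtures.
#' Xanthine proton sites are lettered A-D; agent sites are numbered from
#' 2. The intramolecular [A-B] cross-peak is always the largest (it is the
#' normalization reference); [B-C] and [B-D] report xanthine-xanthine
#' (homo) proximity. In the `homo` regime both homo peaks exceed every
#' xanthine-agent cross-peak; in the `hetero` regime the majority of
#' xanthine-agent peaks exceed them.
#'
#' @param regime `"homo"` or `"hetero"`.
#' @param n_hetero_peaks Number of xanthine-agent cross-peaks (>= 1).
#' @param aromatic_sites Agent site numbers flagged aromatic (for
#'   [ring_involvement()]); defaults to the first half.
#' @param aromatic_bias Additive normalized-volume bias planted on peaks
#'   involving aromatic agent sites (hetero regime only).
#' @param m_xanthine,m_agent Concentrations (mol/kg) carried on the table.
#' @param seed Integer seed.
#' @return A `roesy_table` (see [roesy_table()]).
#' @export
generate_roesy_table <- function(regime = c("homo", "hetero"),
                                 n_hetero_peaks = 6L,
                                 aromatic_sites = NULL, aromatic_bias = 0,
                                 m_xanthine = 1, m_agent = 3, seed = 1L) {
  regime <- match.arg(regime)
  if (n_hetero_peaks < 1L) stop("need at least one hetero cross-peak")
  set.seed(seed)
  agent_sites <- as.character(seq(2L, length.out = n_hetero_peaks))
  if (is.null(aromatic_sites))
    aromatic_sites <- agent_sites[seq_len(ceiling(n_hetero_peaks / 2))]
  xs <- rep_len(c("B", "C", "D"), n_hetero_peaks)
  homo <- stats::runif(2L, 0.15, 0.25)                 # [B-C], [B-D]
  hetero <- if (regime == "homo")
    stats::runif(n_hetero_peaks, 0.02, 0.8 * min(homo))
  else stats::runif(n_hetero_peaks, 1.1 * max(homo), 0.8)
  if (regime == "hetero") {
    # a minority of tail sites may fall below the homo level
    n_low <- floor((n_hetero_peaks - 1L) / 3)
    if (n_low > 0L) {
      low_idx <- utils::tail(seq_len(n_hetero_peaks), n_low)
      hetero[low_idx] <- stats::runif(n_low, 0.02, 0.9 * min(homo))
    }
    hetero[agent_sites %in% aromatic_sites] <-
      hetero[agent_sites %in% aromatic_sites] + aromatic_bias
  }
  ab <- max(1, 1.2 * max(hetero))   # [A-B] strictly the maximum
  peaks <- data.frame(
    site_a = c("A", "B", "B", xs),
    site_b = c("B", "C", "D", agent_sites),
    volume = c(ab, homo, hetero), stringsAsFactors = FALSE)
  sites <- data.frame(
    id = c("A", "B", "C", "D", agent_sites),
    molecule = c(rep("xanthine", 4L), rep("agent", n_hetero_peaks)),
    aromatic = c(TRUE, TRUE, FALSE, FALSE,
                 agent_sites %in% aromatic_sites),
    stringsAsFactors = FALSE)
  roesy_table(peaks, sites, m_xanthine = m_xanthine, m_agent = m_agent,
              system = paste0("synthetic-", regime))
}
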