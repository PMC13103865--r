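#' Molality from 1H NMR integrals against the water internal reference
#'
#' Aqueous qNMR with the water signal (4.80 ppm) as internal standard:
#' with `A_c` a compound's peak integral, `N_c` the protons contributing
#' to that peak, and `A_w` the water integral, the molality is
#' `m = (A_c / N_c) / (A_w / 2) / M_W`, with `M_W = 0.0180153` kg/mol the
#' molar mass of water; the division of the water integral by 2 accounts
#' for water's two protons. When a compound shows several well-resolved
#' peaks, their per-proton integrals are averaged first.
#'
#' @param table An `nmr_peak_table` (see [generate_nmr_table()]) or any
#'   data.frame with columns `compound, integral, n_protons` and exactly
#'   one row with `compound == "water"`.
#' @return Named numeric vector of molalities (mol/kg) per compound.
#' @export
molality_from_integrals <- function(table) {
  need <- c("compound", "integral", "n_protons")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  if (any(table$integral < 0)) stop("integrals must be >= 0")
  if (any(table$n_protons < 1)) stop("proton counts must be >= 1")
  w <- table$compound == "water"
  if (sum(w) != 1L) stop("exactly one water row required")
  aw <- table$integral[w]
  if (aw <= 0) stop("water integral must be positive")
  sol <- table[!w, , drop = FALSE]
  per_proton <- tapply(sol$integral / sol$n_protons, sol$compound, mean)
  m <- as.numeric(per_proton) / (aw / 2) / .M_W
  stats::setNames(m, names(per_proton))[unique(sol$compound)]
}

#' Solubility-increase factor
#'
#' Ratio of a xanthine's solubility in the presence of a solubilizing
#' agent to its solubility in pure water: `F_SI = s_sa / s0`.
#'
#' @param s_sa Solubility with the agent (mol/kg), >= 0.
#' @param s0 Solubility in pure water (mol/kg), > 0.
#' @return Numeric factor (dimensionless).
#' @export
fsi <- function(s_sa, s0) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  if (any(s_sa < 0)) stop("s_sa must be >= 0")
  s_sa / s0
}

# corrected Akaike information criterion from a Gaussian RSS
.aicc <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# best MHC-law fit for a fixed breakpoint: optimise (s0, b) by
# Nelder-Mead from a log-linear initialisation
.fit_mhc_at <- function(cc, s, mhc) {
  below <- cc < mhc
  s0_init <- if (any(below)) max(mean(s[below]), 1e-6) else max(s[1L], 1e-6)
  ab <- which(!below & s > 0)
  b_init <- if (length(ab) >= 2L)
    max(stats::coef(stats::lm(log(s[ab]) ~ cc[ab]))[[2L]], 1e-3) else 0.5
  obj <- function(par) {
    s0 <- exp(par[1L]); b <- exp(par[2L])
    sum((s - solubility_law(cc, "mhc", list(s0 = s0, mhc = mhc, b = b)))^2)
  }
  fit <- stats::optim(c(log(s0_init), log(b_init)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  list(s0 = exp(fit$par[1L]), b = exp(fit$par[2L]), rss = fit$value)
}

#' Fit and compare linear versus MHC solubility models
#'
#' Least-squares fits of the two mechanistic alternatives for a solubility
#' curve: a straight line `s = s0 + slope * c` (complexation-like:
#' association complexes form at any agent concentration, so solubility
#' grows linearly and dilution never precipitates) and a minimum-
#' hydrotropic-concentration law, flat at `s0` below the MHC and
#' `s0 * exp(b (c - MHC))` above it (classical hydrotropy). The MHC is
#' profiled over a grid of candidate breakpoints spanning the data; models
#' are compared by small-sample-corrected AIC, and the verdict is
#' `indeterminate` when the criterion difference is below 2.
#'
#' @param curve A [solubility_curve()] (or data.frame with columns
#'   `c`, `s`).
#' @param mhc_grid Candidate breakpoints; default a fine grid over the
#'   interior of the measured span.
#' @return An object of class `solubility_fit` with components `linear`
#'   (s0, slope, rss, aicc), `mhc` (s0, mhc, b, rss, aicc), `verdict`
#'   (`"linear"`, `"mhc"` or `"indeterminate"`), `delta_aicc` and the
#'   data. Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `plot`.
#' @export
fit_solubility_models <- function(curve, mhc_grid = NULL) {
  cc <- curve$c; s <- curve$s
  n <- length(cc)
  if (n < 5L) stop("need at least 5 points")
  if (stats::sd(s) < 1e-12) {
    warning("degenerate (constant) curve; verdict indeterminate")
    lin <- list(s0 = mean(s), slope = 0, rss = 0, aicc = -Inf)
    mh <- list(s0 = mean(s), mhc = mean(cc), b = 0, rss = 0, aicc = -Inf)
    return(structure(list(linear = lin, mhc = mh,
                          verdict = "indeterminate", delta_aicc = 0,
                          curve = curve), class = "solubility_fit"))
  }
  lfit <- stats::lm(s ~ cc)
  lin <- list(s0 = stats::coef(lfit)[[1L]], slope = stats::coef(lfit)[[2L]],
              rss = sum(stats::resid(lfit)^2))
  lin$aicc <- .aicc(lin$rss, n, 3L)   # s0, slope, sigma
  if (is.null(mhc_grid))
    mhc_grid <- seq(cc[2L], cc[n - 1L], length.out = 25L)
  best <- NULL
  for (m0 in mhc_grid) {
    f <- .fit_mhc_at(cc, s, m0)
    if (is.null(best) || f$rss < best$rss) best <- c(f, mhc = m0)
  }
  mh <- list(s0 = best$s0, mhc = best$mhc, b = best$b, rss = best$rss)
  mh$aicc <- .aicc(mh$rss, n, 4L)     # s0, mhc, b, sigma
  delta <- lin$aicc - mh$aicc         # > 0 favours mhc
  verdict <- if (abs(delta) < 2) "indeterminate"
             else if (delta > 0) "mhc" else "linear"
  structure(list(linear = lin, mhc = mh, verdict = verdict,
                 delta_aicc = delta, curve = curve),
            class = "solubility_fit")
}

#' @export
print.solubility_fit <- function(x, ...) {
  cat("<solubility_fit>\n")
  cat(sprintf("  linear: s0 = %.4g, slope = %.4g (RSS %.3g, AICc %.2f)\n",
              x$linear$s0, x$linear$slope, x$linear$rss, x$linear$aicc))
  cat(sprintf("  mhc:    s0 = %.4g, MHC = %.3g, b = %.4g (RSS %.3g, AICc %.2f)\n",
              x$mhc$s0, x$mhc$mhc, x$mhc$b, x$mhc$rss, x$mhc$aicc))
  cat(sprintf("  verdict: %s (|dAICc| = %.2f)\n", x$verdict,
              abs(x$delta_aicc)))
  invisible(x)
}

#' @export
summary.solubility_fit <- function(object, ...) {
  mech <- switch(object$verdict,
                 linear = "complexation-like (linear)",
                 mhc = "hydrotrope-like (MHC)",
                 "indeterminate")
  cat(sprintf("Solubility-curve model comparison (%d points)\n",
              nrow(object$curve)))
  print(object)
  cat("  mechanism reading:", mech, "\n")
  invisible(object)
}

#' @export
coef.solubility_fit <- function(object, model = c("best", "linear", "mhc"),
                                ...) {
  model <- match.arg(model)
  if (model == "best")
    model <- if (object$verdict == "mhc") "mhc" else "linear"
  if (model == "linear")
    c(s0 = object$linear$s0, slope = object$linear$slope)
  else c(s0 = object$mhc$s0, mhc = object$mhc$mhc, b = object$mhc$b)
}

#' @export
predict.solubility_fit <- function(object, newdata = NULL,
                                   model = c("best", "linear", "mhc"), ...) {
  model <- match.arg(model)
  if (model == "best")
    model <- if (object$verdict == "mhc") "mhc" else "linear"
  cc <- if (is.null(newdata)) object$curve$c else
    if (is.data.frame(newdata)) newdata$c else newdata
  if (model == "linear")
    object$linear$s0 + object$linear$slope * cc
  else solubility_law(cc, "mhc", object$mhc[c("s0", "mhc", "b")])
}

#' @export
residuals.solubility_fit <- function(object,
                                     model = c("best", "linear", "mhc"),
                                     ...) {
  object$curve$s - predict(object, model = match.arg(model))
}

#' @export
plot.solubility_fit <- function(x, ...) {
  cc <- x$curve$c
  grid <- seq(min(cc), max(cc), length.out = 200L)
  graphics::plot(cc, x$curve$s, pch = 19,
                 xlab = "agent molality (mol/kg)",
                 ylab = "xanthine solubility (mol/kg)",
                 main = paste("verdict:", x$verdict), ...)
  graphics::lines(grid, x$linear$s0 + x$linear$slope * grid, col = 2)
  graphics::lines(grid, solubility_law(grid, "mhc",
                                       x$mhc[c("s0", "mhc", "b")]),
                  col = 4, lty = 2)
  graphics::legend("topleft", c("linear", "mhc"), col = c(2, 4),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Detect an inflection (breakpoint) or plateau in a solubility curve
#'
#' Best continuous two-segment piecewise-linear fit with the breakpoint
#' profiled over the interior data abscissae; the breakpoint is reported
#' only when it improves the small-sample-corrected AIC over the single
#' straight line by at least 2. A plateau is flagged when the slope after
#' the break is at most a tenth of the slope before it.
#'
#' @param curve A [solubility_curve()] (or data.frame with `c`, `s`).
#' @param min_improvement Required AICc improvement (default 2).
#' @return `NULL` when no breakpoint is supported; otherwise a list with
#'   `c_star`, `slope_before`, `slope_after`, `plateau`, `delta_aicc`.
#' @export
detect_breakpoint <- function(curve, min_improvement = 2) {
  cc <- curve$c; s <- curve$s
  n <- length(cc)
  if (n < 6L) stop("need at least 6 points")
  lfit <- stats::lm(s ~ cc)
  aicc_line <- .aicc(sum(stats::resid(lfit)^2), n, 3L)
  cand <- cc[cc > cc[2L] & cc < cc[n - 1L]]   # >= 2 points on each side
  best <- NULL
  for (cstar in cand) {
    hinge <- pmax(cc - cstar, 0)
    fit <- stats::lm(s ~ cc + hinge)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, c_star = cstar,
                   slope_before = stats::coef(fit)[["cc"]],
                   slope_after = stats::coef(fit)[["cc"]] +
                     stats::coef(fit)[["hinge"]])
  }
  if (is.null(best)) return(NULL)
  aicc_break <- .aicc(best$rss, n, 5L)  # intercept, 2 slopes, c*, sigma
  delta <- aicc_line - aicc_break
  if (delta < min_improvement) return(NULL)
  list(c_star = best$c_star, slope_before = best$slope_before,
       slope_after = best$slope_after,
       plateau = abs(best$slope_after) <= 0.1 * abs(best$slope_before),
       delta_aicc = delta)
}

#' Phase-diagram container and point classification
#'
#' A composition diagram for water + xanthine + agent mixtures, bounded by
#' two binodal polylines in the (agent molality, xanthine molality) plane:
#' the upper binodal holds solutions saturated in xanthine (above it
#' xanthine precipitates), the lower one solutions saturated in agent
#' (below it the agent precipitates). Between the curves the solution is
#' homogeneous — the region where the mutual xanthine/agent solubilization
#' operates, which can extend far beyond the agent's pure-water solubility.
#'
#' @param upper,lower Data.frames with columns `c_agent`, `c_xanthine`
#'   (mol/kg), sorted by `c_agent`.
#' @param agent_water_solubility Agent solubility in pure water (mol/kg),
#'   annotation only.
#' @return An object of class `phase_diagram`.
#' @export
phase_diagram <- function(upper, lower, agent_water_solubility = NA_real_) {
  for (nm in list(upper, lower)) {
    if (!all(c("c_agent", "c_xanthine") %in% names(nm)))
      stop("binodals need columns c_agent, c_xanthine")
    if (is.unsorted(nm$c_agent, strictly = FALSE))
      stop("binodal polylines must be sorted by agent molality")
  }
  structure(list(upper = upper, lower = lower,
                 agent_water_solubility = agent_water_solubility),
            class = "phase_diagram")
}

#' @rdname phase_diagram
#'
#' @details [classify_phase_point()] interpolates both binodals linearly
#' at `c_agent` (no extrapolation: queries outside the common span are an
#' error) and classifies the point as `xanthine_saturated` (above the
#' upper binodal), `agent_saturated` (below the lower one),
#' `homogeneous` (between), or `boundary` (within `eps` of either curve).
#'
#' @param diagram A `phase_diagram`.
#' @param c_agent,c_xanthine Query point (mol/kg).
#' @param eps Boundary tolerance (mol/kg).
#' @return [classify_phase_point()] returns one of `"homogeneous"`,
#'   `"xanthine_saturated"`, `"agent_saturated"`, `"boundary"`.
#' @export
classify_phase_point <- function(diagram, c_agent, c_xanthine, eps = 0.01) {
  stopifnot(inherits(diagram, "phase_diagram"))
  for (bi in list(diagram$upper, diagram$lower))
    if (c_agent < min(bi$c_agent) || c_agent > max(bi$c_agent))
      stop("query at c_agent = ", c_agent,
           " lies outside the measured span; no extrapolation")
  up <- stats::approx(diagram$upper$c_agent, diagram$upper$c_xanthine,
                      xout = c_agent, ties = mean)$y
  lo <- stats::approx(diagram$lower$c_agent, diagram$lower$c_xanthine,
                      xout = c_agent, ties = mean)$y
  if (abs(c_xanthine - up) <= eps || abs(c_xanthine - lo) <= eps)
    return("boundary")
  if (c_xanthine > up) return("xanthine_saturated")
  if (c_xanthine < lo) return("agent_saturated")
  "homogeneous"
}
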