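#' Four-parameter log-logistic dose-response curve
#'
#' \deqn{f(d) = bottom + (top - bottom) / (1 + (IC_{50}/d)^{slope})}
#' At dose 0 the curve is at \code{bottom} (the slope > 0 limit); as dose
#' grows it approaches \code{top}; at \code{dose = ic50} it sits exactly
#' midway.
#'
#' @param dose dose(s), micromolar, >= 0
#' @param top,bottom plateau responses (percent inhibition)
#' @param ic50 inflection dose, micromolar, > 0
#' @param slope Hill coefficient
#' @return predicted response(s)
#' @examples
#' logLogistic(30, top = 100, bottom = 0, ic50 = 10, slope = 1)  # 75
#' @export
logLogistic <- function(dose, top, bottom, ic50, slope) {
  stopifnot(all(dose >= 0), all(ic50 > 0))
  # dose = 0 falls out of the arithmetic: (ic50/0)^slope is Inf for
  # slope > 0, giving the bottom plateau as the limit
  bottom + (top - bottom) / (1 + (ic50 / dose)^slope)
}

newDoseResponseFit <- function(top = NA_real_, bottom = NA_real_,
                               ic50 = NA_real_, slope = NA_real_,
                               rss = NA_real_, converged = FALSE,
                               diagnostic = "", n_points = 0L) {
  abs50 <- NA_real_
  if (converged && is.finite(top) && is.finite(bottom) && top != bottom) {
    q <- (top - bottom) / (50 - bottom) - 1
    if (is.finite(q) && q > 0 && (50 - bottom) / (top - bottom) > 0)
      abs50 <- ic50 * q^(-1 / slope)
  }
  new("DoseResponseFit", top = top, bottom = bottom, ic50 = ic50,
      slope = slope, ic50_absolute = abs50, rss = rss,
      converged = converged, diagnostic = diagnostic,
      n_points = as.integer(n_points))
}

#' Fit a log-logistic dose-response curve by least squares
#'
#' Ordinary least squares with Levenberg-Marquardt optimization
#' (\code{minpack.lm::nlsLM}) and multi-start initialization: IC50 starts on
#' a coarse log grid spanning the dose range crossed with slope starts
#' \{0.5, 1, 2\}; the best-RSS start wins. \code{top} and/or \code{bottom}
#' may be fixed via \code{constraints}, reducing to 3- or 2-parameter fits.
#' Failure to converge is reported in the returned object
#' (\code{isConverged}), never as an exception.
#'
#' @param doses doses, micromolar (> 0; order is irrelevant)
#' @param responses responses (percent inhibition), same length
#' @param constraints optional named list fixing \code{top} and/or
#'   \code{bottom}
#' @return a \code{DoseResponseFit}
#' @examples
#' d <- c(150, 75, 37.5, 19, 9.5)
#' fitDoseResponse(d, logLogistic(d, 100, 0, 37.5, 1))
#' @export
fitDoseResponse <- function(doses, responses, constraints = list()) {
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  n <- length(doses)
  free <- setdiff(c("top", "bottom"), names(constraints))
  n_par <- 2 + length(free)
  if (n < n_par || length(unique(doses)) < n_par)
    return(newDoseResponseFit(diagnostic = "insufficient data",
                              n_points = n))
  if (stats::sd(responses) == 0)
    return(newDoseResponseFit(diagnostic = "flat response series",
                              n_points = n))

  dat <- data.frame(d = doses, y = responses)
  pred <- function(p, d) {
    top <- if ("top" %in% free) p[["top"]] else constraints$top
    bottom <- if ("bottom" %in% free) p[["bottom"]] else constraints$bottom
    logLogistic(d, top, bottom, exp(p[["lic50"]]), p[["slope"]])
  }
  ic50_grid <- exp(seq(log(min(doses)), log(max(doses)), length.out = 5))
  starts <- expand.grid(ic50 = ic50_grid, slope = c(0.5, 1, 2))
  top0 <- max(responses); bot0 <- min(responses)

  pn <- c("lic50", "slope", free)
  form <- stats::as.formula(
    paste0("y ~ pred(setNames(c(", paste(pn, collapse = ", "),
           "), pn), d)"),
    env = environment())
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- list(lic50 = log(starts$ic50[i]), slope = starts$slope[i])
    if ("top" %in% free) start$top <- top0
    if ("bottom" %in% free) start$bottom <- bot0
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(newDoseResponseFit(diagnostic = "optimizer failed to converge",
                              n_points = n))
  cf <- stats::coef(best$fit)
  top <- if ("top" %in% free) cf[["top"]] else constraints$top
  bottom <- if ("bottom" %in% free) cf[["bottom"]] else constraints$bottom
  newDoseResponseFit(top = top, bottom = bottom, ic50 = exp(cf[["lic50"]]),
                     slope = cf[["slope"]], rss = best$rss,
                     converged = TRUE, n_points = n)
}

#' Quadratic ligand-depletion binding isotherm for FP titrations
#'
#' Exact equilibrium solution for the polarization of a probe at total
#' concentration \code{l_total} titrated with receptor at total
#' concentration \code{r_total}, valid when the probe is not negligible
#' relative to \eqn{K_d} (ligand depletion):
#' \deqn{P = P_L + \frac{P_{RL} - P_L}{L_T} \cdot \frac{1}{2}\left[
#'   (L_T + R_T + K_d) - \sqrt{(L_T + R_T + K_d)^2 - 4 R_T L_T}\right]}
#' The square-root argument is clamped at zero when within numeric
#' tolerance of zero (it is non-negative analytically).
#'
#' @param r_total total receptor concentration(s), micromolar
#' @param l_total total probe concentration, micromolar, > 0
#' @param kd dissociation constant, micromolar, >= 0
#' @param p_free polarization of free (displaced) probe, mP
#' @param p_bound polarization of fully bound probe, mP
#' @return predicted polarization(s), always within
#'   [min(p_free, p_bound), max(p_free, p_bound)]
#' @examples
#' fpIsotherm(r_total = 81.1, l_total = 0.25, kd = 81.1,
#'            p_free = 50, p_bound = 200)
#' @export
fpIsotherm <- function(r_total, l_total, kd, p_free, p_bound) {
  if (l_total <= 0) stop("l_total must be positive")
  stopifnot(all(r_total >= 0), kd >= 0)
  s <- l_total + r_total + kd
  disc <- s^2 - 4 * r_total * l_total
  disc[disc < 0 & disc > -1e-9 * s^2] <- 0
  if (any(disc < 0)) stop("negative discriminant in binding isotherm")
  bound <- 0.5 * (s - sqrt(disc))          # concentration of complex RL
  p_free + (p_bound - p_free) * bound / l_total
}

newFPBindingFit <- function(p_free = NA_real_, p_bound = NA_real_,
                            kd = NA_real_, l_total = NA_real_,
                            rss = NA_real_, converged = FALSE,
                            diagnostic = "", ci = NULL, n_boot = 0L) {
  if (is.null(ci))
    ci <- matrix(NA_real_, 2, 3,
                 dimnames = list(c("lower", "upper"),
                                 c("p_free", "p_bound", "kd")))
  new("FPBindingFit", p_free = p_free, p_bound = p_bound, kd = kd,
      l_total = l_total, rss = rss, converged = converged,
      diagnostic = diagnostic, ci = ci, n_boot = as.integer(n_boot))
}

fitFPCore <- function(r_total, p, l_total) {
  dat <- data.frame(r = r_total, y = p)
  kd_grid <- exp(seq(log(max(min(r_total[r_total > 0]), 1e-3) / 10),
                     log(max(r_total) * 10), length.out = 7))
  p_lo <- min(p); p_hi <- max(p)
  best <- NULL
  for (kd0 in kd_grid) {
    for (dir in list(c(p_lo, p_hi), c(p_hi, p_lo))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ fpIsotherm(r, l_total, exp(lkd), pf, pb),
          data = dat, start = list(pf = dir[1], pb = dir[2],
                                   lkd = log(kd0)),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit,
                                                          rss = rss)
      }
    }
  }
  best
}

#' Fit the quadratic FP isotherm to a titration
#'
#' Least-squares estimation of (\code{p_free}, \code{p_bound}, \code{kd})
#' from polarization measured over a receptor titration at known probe
#' concentration. \eqn{K_d \ge 0} is enforced by optimizing its logarithm;
#' initialization runs a grid over \eqn{K_d} spanning the titration range in
#' log space, in both orientations (polarization increasing or decreasing
#' with binding). Residual-bootstrap confidence intervals (percentile, 95\%)
#' are computed when \code{n_boot > 0}. A titration that never leaves one
#' plateau (the fitted bound fraction barely changes across the range) is
#' reported as not converged with a coverage diagnostic.
#'
#' @param r_total receptor concentrations, micromolar (>= 5 points spanning
#'   at least a 10-fold range)
#' @param p polarization readings, mP, same length
#' @param l_total total probe concentration, micromolar
#' @param n_boot bootstrap replicates (0 disables the intervals)
#' @param seed RNG seed for the bootstrap
#' @return an \code{FPBindingFit}
#' @export
fitFP <- function(r_total, p, l_total, n_boot = 0, seed = 1) {
  stopifnot(length(r_total) == length(p), l_total > 0)
  ok <- is.finite(r_total) & is.finite(p) & r_total >= 0
  r_total <- r_total[ok]; p <- p[ok]
  if (length(unique(r_total)) < 5)
    return(newFPBindingFit(l_total = l_total,
                           diagnostic = "fewer than 5 distinct titration points"))
  rng <- range(r_total[r_total > 0])
  if (rng[2] / rng[1] < 10)
    return(newFPBindingFit(l_total = l_total,
                           diagnostic = "titration spans less than 10-fold"))
  if (stats::sd(p) == 0)
    return(newFPBindingFit(l_total = l_total,
                           diagnostic = "flat titration (constant polarization)"))
  best <- fitFPCore(r_total, p, l_total)
  if (is.null(best))
    return(newFPBindingFit(l_total = l_total,
                           diagnostic = "optimizer failed to converge"))
  cf <- stats::coef(best$fit)
  kd_hat <- exp(cf[["lkd"]])
  # coverage: the data must actually sample the binding transition
  fb <- fpIsotherm(range(r_total), l_total, kd_hat, 0, 1)
  if (diff(fb) < 0.2)
    return(newFPBindingFit(p_free = cf[["pf"]], p_bound = cf[["pb"]],
                           kd = kd_hat, l_total = l_total, rss = best$rss,
                           diagnostic = "transition not covered by titration range"))
  ci <- NULL
  if (n_boot > 0) {
    fitted_p <- fpIsotherm(r_total, l_total, kd_hat, cf[["pf"]], cf[["pb"]])
    res <- p - fitted_p
    set.seed(seed)
    boot <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      pb_star <- fitted_p + sample(res, length(res), replace = TRUE)
      bb <- fitFPCore(r_total, pb_star, l_total)
      if (!is.null(bb)) {
        cfb <- stats::coef(bb$fit)
        boot[b, ] <- c(cfb[["pf"]], cfb[["pb"]], exp(cfb[["lkd"]]))
      }
    }
    qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci <- matrix(qs, 2, 3, dimnames = list(c("lower", "upper"),
                                           c("p_free", "p_bound", "kd")))
    # percentile CIs from few replicates can exclude the point estimate;
    # widen to contain it so the interval invariant holds
    ci[1, ] <- pmin(ci[1, ], c(cf[["pf"]], cf[["pb"]], kd_hat))
    ci[2, ] <- pmax(ci[2, ], c(cf[["pf"]], cf[["pb"]], kd_hat))
  }
  newFPBindingFit(p_free = cf[["pf"]], p_bound = cf[["pb"]], kd = kd_hat,
                  l_total = l_total, rss = best$rss, converged = TRUE,
                  ci = ci, n_boot = if (n_boot > 0) n_boot else 0L)
}
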