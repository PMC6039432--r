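# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# two-pass mean/sd by explicit loops
oracleMeanSD <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(mean = m, sd = sqrt(ss / (n - 1)))
}

oracleZprime <- function(mx, mn) {
  a <- oracleMeanSD(mx)
  b <- oracleMeanSD(mn)
  1 - 3 * (a$sd + b$sd) / abs(a$mean - b$mean)
}

oracleInhibition <- function(rc, rmax, rmin) {
  100 - 100 * (rc - rmin) / (rmax - rmin)
}

# coarse-grid RSS minimizer for the log-logistic model: shape on a grid of
# (ic50, slope), plateaus by linear least squares given the shape
oracleGridDR <- function(doses, responses,
                         n_ic50 = 60, slopes = seq(0.3, 3, by = 0.1)) {
  best <- Inf
  ic50s <- exp(seq(log(min(doses) / 3), log(max(doses) * 3),
                   length.out = n_ic50))
  for (ic in ic50s) {
    for (sl in slopes) {
      s <- 1 / (1 + (ic / doses)^sl)
      fit <- stats::lm(responses ~ s)
      rss <- sum(stats::resid(fit)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# exact equilibrium complex concentration by root finding on the
# mass-action equation (L - x)(R - x) = Kd x
oracleEquilibriumBound <- function(r_total, l_total, kd) {
  if (kd == 0) return(min(r_total, l_total))
  f <- function(x) (l_total - x) * (r_total - x) - kd * x
  stats::uniroot(f, c(0, min(r_total, l_total)), tol = 1e-14)$root
}

# coarse-grid RSS minimizer for the quadratic FP isotherm: Kd on a log
# grid, plateaus by linear least squares on the bound fraction
oracleGridFP <- function(r_total, p, l_total, n_kd = 200) {
  kds <- exp(seq(log(1e-3), log(max(r_total) * 100), length.out = n_kd))
  best <- Inf
  for (kd in kds) {
    s <- l_total + r_total + kd
    fb <- 0.5 * (s - sqrt(pmax(s^2 - 4 * r_total * l_total, 0))) / l_total
    fit <- stats::lm(p ~ fb)
    rss <- sum(stats::resid(fit)^2)
    if (rss < best) best <- rss
  }
  best
}

# convenience: small simulated campaign
smallCampaign <- function(n = 120, plates = 1, noise = 0.02, seed = 11,
                          hit_rate = 0.05, interferer_rate = 0.03) {
  simulateCampaign(simulationConfig(
    n_compounds = n, n_plates = plates, noise_cv = noise,
    hit_rate = hit_rate, interferer_rate = interferer_rate, seed = seed))
}
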