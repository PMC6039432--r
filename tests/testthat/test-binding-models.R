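test_that("logLogistic has the expected anchors and hand values", {
  expect_equal(logLogistic(10, 100, 0, 10, 1), 50)    # dose = ic50
  expect_equal(logLogistic(0, 100, 0, 10, 1), 0)      # limit at dose 0
  expect_equal(logLogistic(30, 100, 0, 10, 1), 75)    # 100 * 3/4
  expect_equal(logLogistic(37.5, 80, 20, 37.5, 2), 50)
})

test_that("fitDoseResponse recovers noiseless curves and handles degeneracy", {
  doses <- c(150, 75, 37.5, 19, 9.5)
  y <- logLogistic(doses, 100, 0, 37.5, 1)
  f <- fitDoseResponse(doses, y)
  expect_true(isConverged(f))
  expect_equal(ic50(f), 37.5, tolerance = 1e-3)
  expect_equal(unname(coef(f)[c("top", "bottom")]), c(100, 0),
               tolerance = 0.5)
  # absolute IC50 equals relative IC50 for a full-span curve
  expect_equal(f@ic50_absolute, 37.5, tolerance = 0.01)

  flat <- fitDoseResponse(doses, rep(0, 5))
  expect_false(isConverged(flat))
  expect_match(flat@diagnostic, "flat")

  # permutation invariance
  perm <- sample(length(doses))
  f2 <- fitDoseResponse(doses[perm], y[perm])
  expect_equal(ic50(f2), ic50(f), tolerance = 1e-6)
})

test_that("fixed-plateau constraints reduce the parameter count", {
  doses <- c(300, 150, 75, 37.5, 19, 9.5)
  y <- logLogistic(doses, 100, 0, 50, 1.3)
  f <- fitDoseResponse(doses, y, constraints = list(top = 100, bottom = 0))
  expect_true(isConverged(f))
  expect_equal(ic50(f), 50, tolerance = 1e-3)
  expect_equal(f@top, 100)
  expect_equal(f@bottom, 0)
})

test_that("fpIsotherm matches limits and the mass-action root oracle", {
  expect_equal(fpIsotherm(0, 0.25, 81.1, 50, 200), 50)     # no receptor
  expect_equal(fpIsotherm(5, 0.25, 0, 50, 200), 200)       # saturation
  set.seed(19)
  for (i in 1:40) {
    lt <- runif(1, 0.05, 5)
    rt <- runif(1, 0, 500)
    kd <- runif(1, 0.1, 300)
    pl <- runif(1, 20, 80); pr <- runif(1, 120, 260)
    bound <- oracleEquilibriumBound(rt, lt, kd)
    expect_equal(fpIsotherm(rt, lt, kd, pl, pr),
                 pl + (pr - pl) * bound / lt, tolerance = 1e-8)
  }
  # the worked point: predicted polarization equals the equilibrium root
  b <- oracleEquilibriumBound(81.1, 0.25, 81.1)
  expect_equal(fpIsotherm(81.1, 0.25, 81.1, 50, 200),
               50 + 150 * b / 0.25, tolerance = 1e-8)
  expect_error(fpIsotherm(10, 0, 81.1, 50, 200), "l_total")
})

test_that("fpIsotherm is monotone in receptor and bounded by the plateaus", {
  r <- exp(seq(log(0.01), log(5000), length.out = 200))
  up <- fpIsotherm(r, 0.25, 40, 50, 200)
  expect_true(all(diff(up) >= -1e-10))
  down <- fpIsotherm(r, 0.25, 40, 200, 50)
  expect_true(all(diff(down) <= 1e-10))
  expect_true(all(up >= 50 - 1e-9 & up <= 200 + 1e-9))
})

test_that("fpIsotherm reduces to the hyperbola when depletion is negligible", {
  set.seed(3)
  for (i in 1:200) {
    kd <- 10^runif(1, -1, 3)
    rt <- 10^runif(1, -1, 3)
    lt <- 1e-4 * min(kd, rt)
    p <- fpIsotherm(rt, lt, kd, 50, 200)
    hyp <- 50 + 150 * rt / (rt + kd)
    expect_lt(abs(p - hyp), 0.001 * 150)
  }
})

test_that("fitFP recovers noiseless titrations to high relative accuracy", {
  tit <- simulateFPTitration(kd = 81.1, noise_sd = 0, n_points = 8)
  f <- fitFP(tit$r_total, tit$polarization, 0.25)
  expect_true(isConverged(f))
  expect_equal(kd(f), 81.1, tolerance = 1e-6)
  expect_equal(f@p_free, 50, tolerance = 1e-4)
  expect_equal(f@p_bound, 200, tolerance = 1e-4)
})

test_that("fitFP reports degenerate and non-covering titrations honestly", {
  r <- exp(seq(log(1), log(1000), length.out = 8))
  flat <- fitFP(r, rep(120, 8), 0.25)
  expect_false(isConverged(flat))
  expect_match(flat@diagnostic, "flat")
  # Kd far above the titration range: curve never leaves the free plateau
  tit <- simulateFPTitration(kd = 1e6, r_range = c(1, 1000), noise_sd = 0)
  f <- fitFP(tit$r_total, tit$polarization, 0.25)
  expect_false(isConverged(f))
  expect_error(fitFP(r[1:3], rep(1:3, 1), 0.25), NA)  # returns, no throw
  expect_false(isConverged(fitFP(r[1:4], c(1, 2, 3, 4), 0.25)))
})

test_that("bootstrap intervals contain the point estimate", {
  tit <- simulateFPTitration(kd = 81.1, noise_sd = 3, replicates = 3,
                             seed = 5)
  f <- fitFP(tit$r_total, tit$polarization, 0.25, n_boot = 60, seed = 2)
  expect_true(isConverged(f))
  expect_true(f@ci["lower", "kd"] <= kd(f) && kd(f) <= f@ci["upper", "kd"])
  expect_equal(kd(f), 81.1, tolerance = 0.15)
})

test_that("both fitters match coarse-grid brute-force RSS minimization", {
  set.seed(77)
  doses <- c(150, 75, 37.5, 19, 9.5)
  for (i in 1:10) {
    y <- logLogistic(doses, 100, 0, 10^runif(1, 0.8, 2.2),
                     runif(1, 0.6, 2)) + rnorm(5, 0, 2)
    f <- fitDoseResponse(doses, y)
    grid_rss <- oracleGridDR(doses, y)
    expect_true(isConverged(f))
    expect_lte(f@rss, grid_rss * 1.01 + 1e-9)
  }
  for (i in 1:10) {
    kd0 <- 10^runif(1, 0.5, 2.5)
    tit <- simulateFPTitration(kd = kd0, noise_sd = 2, seed = i)
    f <- fitFP(tit$r_total, tit$polarization, 0.25)
    grid_rss <- oracleGridFP(tit$r_total, tit$polarization, 0.25)
    expect_true(isConverged(f))
    expect_lte(f@rss, grid_rss * 1.01 + 1e-9)
  }
})
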