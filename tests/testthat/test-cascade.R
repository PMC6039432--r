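inhTable <- function(ids, inh) {
  data.frame(compound_id = ids, inhibition = inh,
             n_rep = 1L, flagged = inh < 0 | inh > 100,
             stringsAsFactors = FALSE)
}

test_that("primary screen uses a strict threshold and ranks hits", {
  tab <- inhTable(c("a", "b", "c", "d"), c(15, 15.01, 60, -3))
  hits <- primaryScreen(tab, threshold = 15)
  expect_equal(hits$compound_id, c("c", "b"))  # exactly 15.0 not selected
  expect_equal(nrow(primaryScreen(inhTable(letters[1:5], rep(0, 5)))), 0)
  # ties broken by compound id for determinism
  tie <- primaryScreen(inhTable(c("z", "a"), c(40, 40)))
  expect_equal(tie$compound_id, c("a", "z"))
})

test_that("counter screen classifies the region-A/B quadrants", {
  ppi <- inhTable(c("a", "b", "c", "d"), c(40, 40, 10, 50))
  ctr <- inhTable(c("a", "b", "c"), c(40, 0, 0))
  cls <- counterScreen(ppi, ctr)
  got <- setNames(cls$region, cls$compound_id)
  expect_equal(got[["a"]], "A")             # inhibits both: interferer
  expect_equal(got[["b"]], "B")             # PPI only: candidate
  expect_equal(got[["c"]], "inactive")
  expect_equal(got[["d"]], "unclassified")  # missing counter measurement
  # exactly at the counter bound stays in region B ("more than 15%")
  cls2 <- counterScreen(inhTable("x", 40), inhTable("x", 15))
  expect_equal(cls2$region, "B")
  # partition: regions are disjoint and exhaustive for measured compounds
  expect_true(all(cls$region %in% c("A", "B", "inactive", "unclassified")))
})

test_that("dose-dependence triage separates flat, monotone and curved series", {
  doses <- c(9.5, 19, 37.5, 75, 150)
  flat <- doseDependenceTriage(doses, rep(30, 5))
  expect_false(flat$is_dose_dependent)
  mono <- doseDependenceTriage(doses, c(5, 20, 45, 70, 85))
  expect_true(mono$is_dose_dependent)
  curved <- doseDependenceTriage(doses, logLogistic(doses, 100, 0, 37.5, 1))
  expect_true(curved$is_dose_dependent)
  expect_equal(ic50(curved$fit), 37.5, tolerance = 0.01)
  expect_error(doseDependenceTriage(c(10, 20, 40), c(1, 2, 3)),
               "insufficient")
})

test_that("stage-1 hits equal a brute-force re-derivation from raw wells", {
  sim <- smallCampaign(n = 150, seed = 31, noise = 0.02)
  rep <- runCascade(sim$campaign)
  w <- wells(sim$campaign)
  w <- w[w$assay == "ppi", ]
  # brute force: per-plate control means, per-well inhibition, per-compound
  # mean, strict 15% cut
  exp_hits <- character(0)
  inh_all <- c()
  for (pid in unique(w$plate_id)) {
    p <- w[w$plate_id == pid, ]
    r <- p$i665 / p$i620
    rmax <- mean(r[p$role == "max_control"])
    rmin <- mean(r[p$role == "min_control"])
    cw <- p$role == "compound"
    inh <- 100 - 100 * (r[cw] - rmin) / (rmax - rmin)
    names(inh) <- p$compound_id[cw]
    inh_all <- c(inh_all, inh)
  }
  means <- tapply(inh_all, names(inh_all), mean)
  exp_hits <- names(means)[means > 15]
  expect_setequal(stageHits(rep, 1), exp_hits)
})

test_that("the cascade is empty on inactive campaigns and high thresholds", {
  quiet <- simulateCampaign(simulationConfig(
    n_compounds = 80, n_plates = 1, hit_rate = 0, interferer_rate = 0,
    noise_cv = 0, seed = 2))
  rep <- runCascade(quiet$campaign)
  expect_equal(length(stageHits(rep, 1)), 0)
  expect_equal(length(stageHits(rep, 3)), 0)

  sim <- smallCampaign(n = 150, seed = 13)
  rep100 <- runCascade(sim$campaign,
                       cascadeConfig(threshold_ppi = 100,
                                     threshold_counter = 100))
  expect_equal(length(stageHits(rep100, 1)), 0)
})

test_that("raising thresholds never enlarges downstream hit lists", {
  sim <- smallCampaign(n = 200, seed = 17, hit_rate = 0.1,
                       interferer_rate = 0.05)
  dose <- simulateThirdScreen(sim$truth,
                              sim$truth$compound_id[sim$truth$class !=
                                                    "inactive"],
                              noise_cv = 0.02, seed = 3)
  prev <- NULL
  for (thr in c(10, 15, 30, 60)) {
    rep <- runCascade(sim$campaign,
                      cascadeConfig(threshold_ppi = thr,
                                    threshold_counter = thr),
                      doseData = dose)
    if (!is.null(prev)) {
      for (s in 1:3)
        expect_true(all(stageHits(rep, s) %in% stageHits(prev, s)))
    }
    # nesting within a single run
    expect_true(all(stageHits(rep, 2) %in% stageHits(rep, 1)))
    expect_true(all(stageHits(rep, 3) %in% stageHits(rep, 2)))
    prev <- rep
  }
})

test_that("noiseless region-B selection recovers exactly the true inhibitors", {
  for (seed in c(1, 8, 23)) {
    sim <- simulateCampaign(simulationConfig(
      n_compounds = 400, n_plates = 2, noise_cv = 0, hit_rate = 0.05,
      interferer_rate = 0.03, seed = seed))
    rep <- runCascade(sim$campaign)
    truth <- sim$truth
    expect_setequal(stageHits(rep, 2),
                    truth$compound_id[truth$class == "true_inhibitor"])
    res <- compoundResults(rep)
    interferers <- truth$compound_id[truth$class == "interferer"]
    expect_true(all(res$region[res$compound_id %in% interferers] == "A"))
    # generator/metric consistency: inhibition equals 100 * effect exactly
    m <- merge(res, truth, by = "compound_id")
    expect_equal(m$inhibition_ppi, 100 * m$effect, tolerance = 1e-9)
  }
})

test_that("plates failing QC exclude their compounds with a recorded reason", {
  sim <- smallCampaign(n = 100, seed = 41, noise = 0.02)
  w <- wells(sim$campaign)
  # wreck the ppi plate's min controls so its window collapses
  sel <- w$plate_id == "ppi_01" & w$role == "min_control"
  w$i665[sel] <- w$i620[sel] * 0.95
  broken <- screeningCampaign(w, library = compoundLibrary(sim$campaign))
  rep <- runCascade(broken)
  expect_false(plateQC(rep)$qc_pass[plateQC(rep)$plate_id == "ppi_01"])
  expect_true(any(rep@exclusions$kind == "plate"))
  expect_equal(length(stageHits(rep, 1)), 0)
})
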