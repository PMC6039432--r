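test_that("well addresses parse both padded and unpadded forms", {
  p <- parseWellAddress(c("A1", "A01", "p24", " B07 "))
  expect_equal(p$well, c("A1", "A1", "P24", "B7"))
  expect_equal(p$column, c(1L, 1L, 24L, 7L))
  expect_false(any(isValidWell(c("Q1", "A25", "A0", "1A", ""))))
  expect_equal(formatWellAddress(c(1, 16), c(1, 24)), c("A1", "P24"))
})

writeWellCSV <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("plate_id,well,role,assay,compound_id,conc_um,i665,i620",
               rows), path)
  path
}

test_that("a small well table reads into a campaign with counts conserved", {
  path <- writeWellCSV(c(
    "p1,A1,max_control,ppi,,,900,1000",
    "p1,A2,max_control,ppi,,,910,1000",
    "p1,B1,min_control,ppi,,,100,1000",
    "p1,B2,min_control,ppi,,,105,1000",
    "p1,C1,compound,ppi,C001,50,400,1000",
    "p1,C2,compound,ppi,C002,50,500,1000"))
  camp <- readWellTable(path)
  expect_s4_class(camp, "ScreeningCampaign")
  expect_equal(nrow(wells(camp)), 6)
  expect_equal(length(unique(wells(camp)$plate_id)), 1)
  expect_equal(nrow(rejectedRows(camp)), 0)
})

test_that("row-level violations are rejected with their line numbers", {
  path <- writeWellCSV(c(
    "p1,A1,max_control,ppi,,,900,1000",
    "p1,Q1,compound,ppi,C001,50,400,1000",      # bad row letter
    "p1,C1,compound,ppi,,50,400,1000",          # no compound id
    "p1,C2,compound,ppi,C002,50,oops,1000",     # non-numeric intensity
    "p1,C3,compound,ppi,C003,50,-5,1000",       # negative intensity
    "p1,C4,max_control,ppi,C004,,900,1000"))    # control with compound id
  expect_warning(camp <- readWellTable(path), "rejected")
  rej <- rejectedRows(camp)
  expect_equal(nrow(rej) + nrow(wells(camp)), 6)
  expect_equal(rej$line, c(3L, 4L, 5L, 6L, 7L))
  expect_match(rej$reason[rej$line == 3], "well address")
  expect_match(rej$reason[rej$line == 5], "non-numeric")
})

test_that("structural problems abort the read", {
  dup <- writeWellCSV(c("p1,A1,max_control,ppi,,,900,1000",
                        "p1,A1,min_control,ppi,,,100,1000"))
  expect_error(suppressWarnings(readWellTable(dup)), "duplicate")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,role", "p1,A1,max_control"), path)
  expect_error(readWellTable(path), "mandatory column")
})

test_that("dialect remapping and unit conversion work", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Plate,Well,Type,cmpd,conc,conc_unit,A665,D620",
               "p1,A1,compound,C1,50000,nM,400,1000"), path)
  camp <- readWellTable(path, dialect = c(
    plate_id = "Plate", well = "Well", role = "Type", compound_id = "cmpd",
    conc_um = "conc", i665 = "A665", i620 = "D620"))
  w <- wells(camp)
  expect_equal(w$conc_um, 50)  # nM converted to uM
  expect_equal(w$i665, 400)
})

test_that("write then read round-trips a simulated campaign losslessly", {
  sim <- smallCampaign(n = 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeWellTable(sim$campaign, path)
  back <- readWellTable(path)
  a <- wells(sim$campaign)
  b <- wells(back)
  ord <- function(d) d[order(d$assay, d$plate_id, d$well), ]
  a <- ord(a); b <- ord(b)
  rownames(a) <- rownames(b) <- NULL
  for (col in names(a)) expect_equal(b[[col]], a[[col]], tolerance = 1e-12)
})

test_that("campaign validity rejects malformed well sets", {
  w <- wells(smallCampaign(n = 10, seed = 1)$campaign)
  bad <- w
  bad$compound_id[bad$role == "compound"][1] <- NA
  expect_error(screeningCampaign(bad), "compound_id")
  bad2 <- rbind(w, w[1, ])
  expect_error(screeningCampaign(bad2), "duplicate")
})

test_that("cascade report round-trips through JSON, deterministically", {
  sim <- smallCampaign(n = 120, seed = 5)
  rep1 <- runCascade(sim$campaign,
                     doseData = simulateThirdScreen(
                       sim$truth, stageHits(runCascade(sim$campaign), 2),
                       noise_cv = 0.02, seed = 9),
                     seed = 5L)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeReport(rep1, p1)
  writeReport(rep1, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical repeat

  back <- readReport(p1)
  expect_equal(stageHits(back, 1), stageHits(rep1, 1))
  expect_equal(stageHits(back, 2), stageHits(rep1, 2))
  expect_equal(stageHits(back, 3), stageHits(rep1, 3))
  expect_equal(compoundResults(back)$inhibition_ppi,
               compoundResults(rep1)$inhibition_ppi, tolerance = 1e-12)
  expect_equal(plateQC(back)$zprime, plateQC(rep1)$zprime,
               tolerance = 1e-12)
  expect_equal(names(doseFits(back)), names(doseFits(rep1)))
  if (length(doseFits(rep1)))
    expect_equal(ic50(doseFits(back)[[1]]), ic50(doseFits(rep1)[[1]]),
                 tolerance = 1e-9)
  expect_equal(length(stageHits(back, 1)),
               nrow(jsonlite::fromJSON(p1)$compounds[
                 jsonlite::fromJSON(p1)$compounds$stage_reached >= 1, ]))
})

test_that("an empty report serializes to valid JSON with empty stages", {
  empty <- runCascade(
    screeningCampaign(wells(smallCampaign(n = 0, plates = 1,
                                          seed = 2)$campaign)))
  path <- withr::local_tempfile(fileext = ".json")
  writeReport(empty, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(length(doc$stages$stage1), 0)
  expect_equal(length(doc$stages$stage3), 0)
  expect_equal(doc$provenance$package, "fretscreen")
})
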