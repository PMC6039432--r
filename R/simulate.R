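#' Simulation configuration for synthetic screening campaigns
#'
#' Defines a desk-scale TR-FRET campaign: 384-well plates with on-plate
#' max/min controls, a small fraction of true PPI inhibitors (suppressing
#' only the PPI-assay signal), a fraction of assay interferers (suppressing
#' both the PPI and the monomolecular counter-assay signal, the region-A
#' phenotype), and multiplicative per-well noise on the acceptor channel.
#'
#' Active compounds draw an inhibition effect uniformly from
#' \code{effect_range}; a compound's true IC50 follows from its effect at
#' the 50 micromolar screening concentration under a unit-slope
#' log-logistic curve with full span, so the single-dose campaign and the
#' titration generator describe the same underlying compound.
#'
#' @param n_compounds number of library compounds (0 gives control-only
#'   plates)
#' @param n_plates number of plates per assay
#' @param controls_per_plate c(max = , min = ) control wells per plate
#' @param fold_signal true assay window (ratio max / ratio min)
#' @param ratio_min true background FRET ratio of the min controls
#' @param noise_cv fractional multiplicative per-well noise (log-normal on
#'   the acceptor channel; 0 gives exact signals)
#' @param hit_rate fraction of compounds that are true PPI inhibitors
#' @param interferer_rate fraction suppressing both assay signals
#' @param effect_range uniform range of true inhibition fractions for
#'   actives
#' @param screening_conc single-dose screening concentration, micromolar
#' @param donor_intensity donor-channel intensity, arbitrary units
#' @param assays which assays to simulate
#' @param seed RNG seed
#' @return list of class "simulation_config"
#' @export
simulationConfig <- function(n_compounds = 5000, n_plates = 16,
                             controls_per_plate = c(max = 16, min = 16),
                             fold_signal = 10, ratio_min = 0.1,
                             noise_cv = 0.03, hit_rate = 0.01,
                             interferer_rate = 0.005,
                             effect_range = c(0.2, 0.95),
                             screening_conc = 50,
                             donor_intensity = 1e4,
                             assays = c("ppi", "counter"), seed = 1) {
  stopifnot(hit_rate >= 0, interferer_rate >= 0,
            hit_rate + interferer_rate <= 1, noise_cv >= 0,
            fold_signal > 1, ratio_min > 0,
            all(controls_per_plate >= 4), all(controls_per_plate <= 16),
            sum(controls_per_plate) + ceiling(n_compounds / max(n_plates, 1))
              <= 384,
            all(assays %in% ASSAYS))
  structure(list(n_compounds = n_compounds, n_plates = n_plates,
                 controls_per_plate = controls_per_plate,
                 fold_signal = fold_signal, ratio_min = ratio_min,
                 noise_cv = noise_cv, hit_rate = hit_rate,
                 interferer_rate = interferer_rate,
                 effect_range = effect_range,
                 screening_conc = screening_conc,
                 donor_intensity = donor_intensity,
                 assays = assays, seed = as.integer(seed)),
            class = "simulation_config")
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# multiplicative log-normal factor with unit mean and given CV; exactly 1
# when cv = 0
noiseFactor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# IC50 implied by an inhibition fraction at the screening dose under a
# unit-slope full-span log-logistic curve
ic50FromEffect <- function(effect, screening_conc = 50) {
  screening_conc * (1 - effect) / effect
}

#' Simulate a TR-FRET screening campaign with ground truth
#'
#' Each compound's expected PPI-assay FRET ratio is
#' \code{ratio_min * (fold - (fold - 1) * effect)}, so an effect of 0 sits
#' at the max-control level and an effect of 1 at background; the counter
#' assay uses the compound's counter effect (equal to the PPI effect for
#' interferers, 0 for true inhibitors and inactives). Per-well log-normal
#' multiplicative noise with the configured CV is applied to the acceptor
#' channel; the donor channel is held fixed. Max controls are generated
#' with effect 0 and min controls at the background level, through the same
#' noise model. Deterministic for a given seed.
#'
#' @param config a \code{\link{simulationConfig}}
#' @return list(campaign = ScreeningCampaign, truth = data.frame with
#'   compound_id, class, effect, ic50)
#' @export
simulateCampaign <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulation_config"))
  withSeed(config$seed, {
    n <- config$n_compounds
    ids <- if (n > 0) sprintf("CMP%05d", seq_len(n)) else character(0)
    cls <- rep("inactive", n)
    n_hit <- round(config$hit_rate * n)
    n_int <- round(config$interferer_rate * n)
    pick <- if (n > 0) sample.int(n, n_hit + n_int) else integer(0)
    cls[pick[seq_len(n_hit)]] <- "true_inhibitor"
    if (n_int > 0) cls[pick[n_hit + seq_len(n_int)]] <- "interferer"
    effect <- ifelse(cls == "inactive", 0,
                     stats::runif(n, config$effect_range[1],
                                  config$effect_range[2]))
    truth <- data.frame(compound_id = ids, class = cls, effect = effect,
                        ic50 = ifelse(cls == "inactive", NA_real_,
                                      ic50FromEffect(effect,
                                                     config$screening_conc)),
                        stringsAsFactors = FALSE)

    effect_ppi <- effect
    effect_counter <- ifelse(cls == "interferer", effect, 0)

    n_max <- config$controls_per_plate[["max"]]
    n_min <- config$controls_per_plate[["min"]]
    # controls occupy the last two columns (column-major fill); compound
    # wells fill columns 1..22 row-major
    ctrl_wells_max <- formatWellAddress(((seq_len(n_max) - 1) %% 16) + 1,
                                        23 + (seq_len(n_max) - 1) %/% 16)
    ctrl_wells_min <- formatWellAddress(((seq_len(n_min) - 1) %% 16) + 1,
                                        24 - (seq_len(n_min) - 1) %/% 16)
    cmp_idx <- seq_len(22 * 16)
    cmp_wells <- formatWellAddress(((cmp_idx - 1) %/% 22) + 1,
                                   ((cmp_idx - 1) %% 22) + 1)

    per_plate <- if (n > 0) ceiling(n / config$n_plates) else 0
    plate_of <- if (n > 0) rep(seq_len(config$n_plates),
                               each = per_plate)[seq_len(n)] else integer(0)

    all_wells <- vector("list", length(config$assays) * config$n_plates)
    k <- 0
    for (assay in config$assays) {
      eff <- if (assay == "ppi") effect_ppi else effect_counter
      for (p in seq_len(config$n_plates)) {
        in_plate <- which(plate_of == p)
        n_cmp <- length(in_plate)
        ratio_cmp <- config$ratio_min *
          (config$fold_signal - (config$fold_signal - 1) * eff[in_plate])
        ratio <- c(rep(config$ratio_min * config$fold_signal, n_max),
                   rep(config$ratio_min, n_min), ratio_cmp)
        mult <- noiseFactor(length(ratio), config$noise_cv)
        i620 <- rep(config$donor_intensity, length(ratio))
        i665 <- i620 * ratio * mult
        k <- k + 1
        all_wells[[k]] <- data.frame(
          plate_id = sprintf("%s_%02d", assay, p),
          well = c(ctrl_wells_max, ctrl_wells_min,
                   cmp_wells[seq_len(n_cmp)]),
          role = c(rep("max_control", n_max), rep("min_control", n_min),
                   rep("compound", n_cmp)),
          assay = assay,
          compound_id = c(rep(NA_character_, n_max + n_min),
                          ids[in_plate]),
          conc_um = c(rep(NA_real_, n_max + n_min),
                      rep(config$screening_conc, n_cmp)),
          i665 = i665, i620 = i620,
          stringsAsFactors = FALSE)
      }
    }
    wells <- do.call(rbind, all_wells)
    lib <- data.frame(compound_id = ids,
                      name = ids, stringsAsFactors = FALSE)
    list(campaign = screeningCampaign(wells, library = lib), truth = truth)
  })
}

#' Simulate a third-screen dose series for one compound
#'
#' Responses for active compounds come from the log-logistic curve with the
#' compound's true IC50 (unit slope, full 0-100 span); inactive compounds
#' produce flat series around 0. Noise is additive Gaussian with standard
#' deviation \code{noise_cv * 100} percent points, so \code{noise_cv} keeps
#' the same meaning as in the campaign generator at the inhibition scale.
#'
#' @param truth_entry one row of a truth table (compound_id, class, effect,
#'   ic50)
#' @param doses titration concentrations, micromolar; the default is the
#'   5-point third-screen series
#' @param noise_cv fractional noise (0 gives exact curve values)
#' @param seed RNG seed
#' @return data.frame (compound_id, conc_um, inhibition)
#' @export
simulateDoseSeries <- function(truth_entry,
                               doses = c(150, 75, 37.5, 19, 9.5),
                               noise_cv = 0, seed = 1) {
  stopifnot(all(doses > 0))
  withSeed(seed, {
    mu <- if (truth_entry$class == "inactive" || is.na(truth_entry$ic50))
      rep(0, length(doses))
    else
      logLogistic(doses, top = 100, bottom = 0, ic50 = truth_entry$ic50,
                  slope = 1)
    data.frame(compound_id = truth_entry$compound_id, conc_um = doses,
               inhibition = mu + stats::rnorm(length(doses),
                                              sd = noise_cv * 100),
               stringsAsFactors = FALSE)
  })
}

#' Simulate third-screen dose series for a set of compounds
#'
#' @param truth truth table from \code{\link{simulateCampaign}}
#' @param compound_ids compounds to titrate (e.g. the stage-2 hit list)
#' @inheritParams simulateDoseSeries
#' @return data.frame of stacked dose series
#' @export
simulateThirdScreen <- function(truth, compound_ids,
                                doses = c(150, 75, 37.5, 19, 9.5),
                                noise_cv = 0, seed = 1) {
  rows <- lapply(seq_along(compound_ids), function(i) {
    entry <- truth[truth$compound_id == compound_ids[i], ]
    stopifnot(nrow(entry) == 1)
    simulateDoseSeries(entry, doses, noise_cv, seed = seed + i)
  })
  if (!length(rows))
    return(data.frame(compound_id = character(), conc_um = numeric(),
                      inhibition = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Simulate a fluorescence-polarization titration
#'
#' Polarization values from the quadratic ligand-depletion isotherm plus
#' additive Gaussian noise, at log-spaced receptor concentrations.
#'
#' @param p_free,p_bound polarization of free / fully bound probe, mP
#' @param l_total total probe concentration, micromolar
#' @param kd true dissociation constant, micromolar
#' @param r_range c(min, max) receptor range, micromolar; must span at
#'   least 10-fold
#' @param n_points number of log-spaced titration points
#' @param noise_sd additive Gaussian noise, mP
#' @param replicates technical replicates per point
#' @param seed RNG seed
#' @return data.frame (r_total, replicate, polarization)
#' @export
simulateFPTitration <- function(p_free = 50, p_bound = 200, l_total = 0.25,
                                kd = 81.1, r_range = c(1, 1000),
                                n_points = 8, noise_sd = 0, replicates = 1,
                                seed = 1) {
  if (r_range[2] / r_range[1] < 10)
    stop("r_range must span at least a 10-fold receptor range")
  withSeed(seed, {
    r <- exp(seq(log(r_range[1]), log(r_range[2]),
                 length.out = n_points))
    r <- rep(r, each = replicates)
    mu <- fpIsotherm(r, l_total, kd, p_free, p_bound)
    data.frame(r_total = r,
               replicate = rep(seq_len(replicates), n_points),
               polarization = mu + stats::rnorm(length(r), sd = noise_sd),
               stringsAsFactors = FALSE)
  })
}

#' Evaluate a cascade report against simulation truth
#'
#' Cross-tabulates truth class against the stage each compound reached and
#' reports, per stage, sensitivity (selected true inhibitors over all true
#' inhibitors with effect above the primary threshold), specificity, and
#' the false-discovery rate among selected compounds.
#'
#' @param report a \code{CascadeReport}
#' @param truth truth table from \code{\link{simulateCampaign}}
#' @param effect_threshold effect cut defining detectable true inhibitors
#'   (fraction; default matches the 15 percent primary threshold)
#' @return list(confusion = class-by-outcome table whose cells sum to the
#'   number of simulated compounds, per_stage = data.frame)
#' @export
evaluateAgainstTruth <- function(report, truth, effect_threshold = 0.15) {
  stopifnot(is(report, "CascadeReport"))
  res <- compoundResults(report)
  if (nrow(res) && !all(res$compound_id %in% truth$compound_id))
    stop("report contains compound ids absent from the truth table")
  stage <- res$stage_reached[match(truth$compound_id, res$compound_id)]
  outcome <- ifelse(is.na(stage), "excluded", paste0("stage", stage))
  confusion <- table(class = truth$class,
                     outcome = factor(outcome,
                                      levels = c("excluded", "stage0",
                                                 "stage1", "stage2",
                                                 "stage3")))
  detectable <- truth$compound_id[truth$class == "true_inhibitor" &
                                  truth$effect > effect_threshold]
  not_inhibitor <- truth$compound_id[truth$class != "true_inhibitor"]
  per_stage <- do.call(rbind, lapply(1:3, function(s) {
    sel <- stageHits(report, s)
    tp <- length(intersect(sel, detectable))
    fp <- length(intersect(sel, not_inhibitor))
    data.frame(stage = s, n_selected = length(sel),
               sensitivity = if (length(detectable)) tp /
                 length(detectable) else NA_real_,
               specificity = if (length(not_inhibitor))
                 1 - fp / length(not_inhibitor) else NA_real_,
               fdr = if (length(sel)) fp / length(sel) else 0,
               stringsAsFactors = FALSE)
  }))
  list(confusion = confusion, per_stage = per_stage)
}
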