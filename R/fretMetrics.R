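#' Per-well FRET ratio
#'
#' The TR-FRET readout of a well is the acceptor-channel intensity (665 nm)
#' divided by the donor-channel intensity (620 nm). A non-positive donor
#' reading leaves no valid ratio: with \code{na.degenerate = FALSE} (default)
#' this is an error, with \code{na.degenerate = TRUE} the well gets NA so
#' that plate summaries can exclude and count it.
#'
#' @param acceptor acceptor-channel intensity (arbitrary units), vectorized
#' @param donor donor-channel intensity (arbitrary units), vectorized
#' @param na.degenerate return NA instead of erroring on donor <= 0
#' @return numeric FRET ratio(s)
#' @examples
#' fretRatio(500, 1000)   # 0.5
#' @export
fretRatio <- function(acceptor, donor, na.degenerate = FALSE) {
  bad <- !is.na(donor) & donor <= 0
  if (any(bad) && !na.degenerate)
    stop("degenerate well: donor intensity <= 0")
  r <- acceptor / donor
  r[bad] <- NA_real_
  r
}

#' Assay window in fold units
#'
#' The fold signal is the mean FRET ratio of the max controls (DMSO-treated
#' interacting lysate) divided by that of the min controls (non-transfected
#' lysate background); 1 means no interaction signal.
#'
#' @param ratio_max mean FRET ratio of max controls
#' @param ratio_min mean FRET ratio of min controls
#' @return dimensionless fold signal
#' @export
foldSignal <- function(ratio_max, ratio_min) {
  if (any(!is.na(ratio_min) & ratio_min <= 0))
    stop("degenerate plate: min-control FRET ratio <= 0")
  ratio_max / ratio_min
}

#' Percent inhibition of the FRET signal
#'
#' Normalizes a compound well's FRET ratio to the on-plate control window:
#' \deqn{100 - 100 (R_{cmpd} - R_{min}) / (R_{max} - R_{min})}
#' so the min control maps to 100\% inhibition and the max control to 0\%.
#' Values below 0 (signal enhancers) or above 100 are returned unclamped;
#' callers flag them downstream.
#'
#' @param ratio_compound FRET ratio(s) of the tested compound well(s)
#' @param ratio_max mean max-control FRET ratio (full signal)
#' @param ratio_min mean min-control FRET ratio (background)
#' @return percent inhibition, same length as \code{ratio_compound}
#' @examples
#' percentInhibition(0.55, ratio_max = 1, ratio_min = 0.1)  # 50
#' @export
percentInhibition <- function(ratio_compound, ratio_max, ratio_min) {
  if (any(ratio_max <= ratio_min))
    stop("degenerate plate: no assay window (ratio_max <= ratio_min)")
  100 - 100 * (ratio_compound - ratio_min) / (ratio_max - ratio_min)
}

#' Z'-factor of a screening window
#'
#' The standard screening-window statistic
#' \deqn{Z' = 1 - 3 (\sigma_{max} + \sigma_{min}) / |\mu_{max} - \mu_{min}|}
#' computed from the control FRET ratios of one plate. Z' is at most 1;
#' values above 0.5 are conventionally screenable. A robust variant uses
#' median and scaled MAD in place of mean and SD.
#'
#' @param max_ratios FRET ratios of the max-control wells (>= 4 required)
#' @param min_ratios FRET ratios of the min-control wells (>= 4 required)
#' @param robust use median / MAD (scaled by 1.4826) statistics
#' @return dimensionless Z'-factor
#' @examples
#' zPrime(c(1, 1.02, 0.98, 1), c(0.1, 0.11, 0.09, 0.1))
#' @export
zPrime <- function(max_ratios, min_ratios, robust = FALSE) {
  max_ratios <- max_ratios[is.finite(max_ratios)]
  min_ratios <- min_ratios[is.finite(min_ratios)]
  if (length(max_ratios) < 4 || length(min_ratios) < 4)
    stop("insufficient controls: need >= 4 finite values per group")
  st <- controlStats(max_ratios, robust)
  sb <- controlStats(min_ratios, robust)
  if (st$mean == sb$mean)
    stop("undefined window: control group means are equal")
  1 - 3 * (st$sd + sb$sd) / abs(st$mean - sb$mean)
}

controlStats <- function(x, robust = FALSE) {
  if (robust)
    list(mean = stats::median(x), sd = stats::mad(x, constant = 1.4826))
  else
    list(mean = mean(x), sd = stats::sd(x))
}

emptyPlateQC <- function() {
  data.frame(plate_id = character(), assay = character(),
             mean_max = numeric(), sd_max = numeric(),
             mean_min = numeric(), sd_min = numeric(),
             zprime = numeric(), fold_signal = numeric(),
             qc_pass = logical(), n_excluded_controls = integer(),
             stringsAsFactors = FALSE)
}

#' Summarize one plate's controls and QC verdict
#'
#' Computes FRET ratios for all control wells, excluding wells with missing
#' or degenerate (donor <= 0) readings, then control mean/SD, Z', fold
#' signal, and the QC verdict. A plate passes QC when its Z' reaches
#' \code{qc_threshold} and no more than \code{max_excluded_frac} of its
#' control wells were excluded. Compound wells on failing plates are dropped
#' from downstream cascade stages and reported as exclusions.
#'
#' @param plate data.frame of wells for one plate (long format, see
#'   \code{\link{screeningCampaign}})
#' @param qc_threshold minimum Z' to pass (the first-screen gate is 0.75)
#' @param robust robust control statistics (median/MAD)
#' @param max_excluded_frac maximum tolerated fraction of excluded control
#'   wells
#' @return a \code{PlateSummary}
#' @export
summarizePlate <- function(plate, qc_threshold = 0.75, robust = FALSE,
                           max_excluded_frac = 0.1) {
  stopifnot(is.data.frame(plate), nrow(plate) > 0)
  pid <- unique(plate$plate_id)
  assay <- unique(plate$assay)
  stopifnot(length(pid) == 1, length(assay) == 1)
  ctrl <- plate[plate$role %in% c("max_control", "min_control"), ]
  ratio <- fretRatio(ctrl$i665, ctrl$i620, na.degenerate = TRUE)
  excluded <- !is.finite(ratio)
  n_excluded <- sum(excluded)
  rx <- ratio[ctrl$role == "max_control" & !excluded]
  rn <- ratio[ctrl$role == "min_control" & !excluded]
  if (length(rx) < 4 || length(rn) < 4)
    stop("plate ", pid, ": fewer than 4 usable controls per group")
  st <- controlStats(rx, robust)
  sb <- controlStats(rn, robust)
  zp <- zPrime(rx, rn, robust = robust)
  qc <- zp >= qc_threshold && n_excluded <= max_excluded_frac * nrow(ctrl)
  new("PlateSummary", plate_id = pid, assay = assay,
      mean_max = st$mean, sd_max = st$sd, mean_min = sb$mean, sd_min = sb$sd,
      zprime = zp, fold_signal = foldSignal(st$mean, sb$mean),
      qc_pass = qc, n_excluded_controls = as.integer(n_excluded))
}

plateSummaryRow <- function(s) {
  data.frame(plate_id = s@plate_id, assay = s@assay, mean_max = s@mean_max,
             sd_max = s@sd_max, mean_min = s@mean_min, sd_min = s@sd_min,
             zprime = s@zprime, fold_signal = s@fold_signal,
             qc_pass = s@qc_pass,
             n_excluded_controls = s@n_excluded_controls,
             stringsAsFactors = FALSE)
}

#' Per-plate QC table for a whole campaign
#'
#' Runs \code{\link{summarizePlate}} over every (plate, assay) in the
#' campaign and binds the summaries into one table.
#'
#' @param campaign a \code{ScreeningCampaign}
#' @inheritParams summarizePlate
#' @return data.frame, one row per plate
#' @export
campaignQC <- function(campaign, qc_threshold = 0.75, robust = FALSE,
                       max_excluded_frac = 0.1) {
  stopifnot(is(campaign, "ScreeningCampaign"))
  w <- wells(campaign)
  if (!nrow(w)) return(emptyPlateQC())
  keys <- unique(w[c("plate_id", "assay")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    p <- w[w$plate_id == keys$plate_id[i] & w$assay == keys$assay[i], ]
    plateSummaryRow(summarizePlate(p, qc_threshold, robust,
                                   max_excluded_frac))
  })
  do.call(rbind, rows)
}
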