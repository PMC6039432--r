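#' @import methods
NULL

WELL_ROLES <- c("max_control", "min_control", "compound", "blank")
ASSAYS <- c("ppi", "counter")
PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

# canonical column order of the long-format well table
WELL_COLUMNS <- c("plate_id", "well", "role", "assay", "compound_id",
                  "conc_um", "i665", "i620")

#' ScreeningCampaign: a set of TR-FRET screening plates plus compound library
#'
#' The central container of the package. Wells are held long-format, one row
#' per measured well, across one or both assays (\code{ppi}: the
#' protein-protein-interaction FRET assay; \code{counter}: the monomolecular
#' counter assay used to flag tag/energy-transfer interferers). Rows rejected
#' during import are retained in \code{rejected} with their input line number
#' and reason, so that accepted + rejected always accounts for every input row.
#'
#' @slot wells data.frame with columns \code{plate_id}, \code{well},
#'   \code{role}, \code{assay}, \code{compound_id}, \code{conc_um},
#'   \code{i665} (acceptor channel, 665 nm), \code{i620} (donor channel,
#'   620 nm).
#' @slot library data.frame mapping \code{compound_id} to optional metadata
#'   (\code{name}, \code{smiles}; structures are passed through untouched).
#' @slot rejected data.frame of rejected input rows (\code{line},
#'   \code{reason}).
#'
#' @exportClass ScreeningCampaign
setClass("ScreeningCampaign",
  representation(wells = "data.frame",
                 library = "data.frame",
                 rejected = "data.frame"))

setValidity("ScreeningCampaign", function(object) {
  w <- object@wells
  msgs <- character(0)
  missing_cols <- setdiff(WELL_COLUMNS, names(w))
  if (length(missing_cols))
    return(paste("wells lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(w)) {
    if (!all(w$role %in% WELL_ROLES))
      msgs <- c(msgs, "invalid well role")
    if (!all(w$assay %in% ASSAYS))
      msgs <- c(msgs, "invalid assay label")
    ok_addr <- vapply(w$well, isValidWell, logical(1), USE.NAMES = FALSE)
    if (!all(ok_addr))
      msgs <- c(msgs, "well address outside 384-well A1..P24 geometry")
    dup <- duplicated(w[c("plate_id", "assay", "well")])
    if (any(dup))
      msgs <- c(msgs, "duplicate (plate, well) addresses")
    bad_int <- (!is.na(w$i665) & (w$i665 < 0 | is.infinite(w$i665))) |
               (!is.na(w$i620) & (w$i620 < 0 | is.infinite(w$i620)))
    if (any(bad_int))
      msgs <- c(msgs, "negative or infinite channel intensities")
    cmp <- w$role == "compound"
    if (any(cmp & (is.na(w$compound_id) | w$compound_id == "")))
      msgs <- c(msgs, "compound wells must carry a compound_id")
    ctrl <- w$role %in% c("max_control", "min_control")
    if (any(ctrl & !is.na(w$compound_id) & w$compound_id != ""))
      msgs <- c(msgs, "control wells must not carry a compound_id")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PlateSummary: per-plate control statistics and QC verdict
#'
#' @slot plate_id plate identifier
#' @slot assay assay label ("ppi" or "counter")
#' @slot mean_max,sd_max FRET-ratio statistics of the max controls
#'   (DMSO-treated interacting lysate)
#' @slot mean_min,sd_min FRET-ratio statistics of the min controls
#'   (non-transfected lysate background)
#' @slot zprime Z'-factor of the plate's screening window
#' @slot fold_signal mean_max / mean_min, the assay window in fold units
#' @slot qc_pass whether the plate passes QC (Z' threshold and control
#'   exclusion bound)
#' @slot n_excluded_controls control wells excluded for missing/degenerate
#'   readings
#'
#' @exportClass PlateSummary
setClass("PlateSummary",
  representation(plate_id = "character", assay = "character",
                 mean_max = "numeric", sd_max = "numeric",
                 mean_min = "numeric", sd_min = "numeric",
                 zprime = "numeric", fold_signal = "numeric",
                 qc_pass = "logical", n_excluded_controls = "integer"))

setValidity("PlateSummary", function(object) {
  if (is.finite(object@zprime) && object@zprime > 1)
    return("zprime cannot exceed 1")
  TRUE
})

#' DoseResponseFit: four-parameter log-logistic dose-response fit
#'
#' Parameters of \code{bottom + (top - bottom) / (1 + (ic50/dose)^slope)}.
#' \code{ic50} is the relative IC50 (the curve's inflection dose);
#' \code{ic50_absolute} is the dose at which the fitted curve crosses 50
#' percent inhibition (NA when the curve never crosses it).
#'
#' @slot top,bottom plateau responses, percent inhibition
#' @slot ic50 inflection dose, micromolar
#' @slot slope Hill coefficient (dimensionless)
#' @slot ic50_absolute dose at the 50 percent-inhibition crossing, micromolar
#' @slot rss residual sum of squares
#' @slot converged whether the optimizer converged
#' @slot diagnostic short text on failure mode ("" when clean)
#' @slot n_points number of data points fitted
#'
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(top = "numeric", bottom = "numeric", ic50 = "numeric",
                 slope = "numeric", ic50_absolute = "numeric",
                 rss = "numeric", converged = "logical",
                 diagnostic = "character", n_points = "integer"))

setValidity("DoseResponseFit", function(object) {
  if (object@converged) {
    if (!is.finite(object@rss)) return("converged fit must have finite rss")
    if (!is.na(object@ic50) && object@ic50 <= 0)
      return("ic50 must be positive")
  }
  TRUE
})

#' FPBindingFit: quadratic ligand-depletion isotherm fit
#'
#' Least-squares estimates of the free-ligand polarization \code{P_L}, the
#' fully-bound polarization \code{P_RL}, and the dissociation constant
#' \code{K_d} from a fluorescence-polarization titration at known total probe
#' concentration \code{L_T}. Confidence intervals come from residual-bootstrap
#' resampling.
#'
#' @slot p_free,p_bound polarization of free / fully bound probe (mP)
#' @slot kd dissociation constant, micromolar (constrained non-negative)
#' @slot l_total total probe concentration used in the fit, micromolar
#' @slot rss residual sum of squares
#' @slot converged whether the fit converged and covered the transition
#' @slot diagnostic failure-mode text ("" when clean)
#' @slot ci 2x3 matrix of bootstrap confidence limits (rows lower/upper,
#'   columns p_free, p_bound, kd); all-NA when bootstrap disabled
#' @slot n_boot bootstrap replicates used
#'
#' @exportClass FPBindingFit
setClass("FPBindingFit",
  representation(p_free = "numeric", p_bound = "numeric", kd = "numeric",
                 l_total = "numeric", rss = "numeric", converged = "logical",
                 diagnostic = "character", ci = "matrix", n_boot = "integer"))

setValidity("FPBindingFit", function(object) {
  if (object@converged) {
    if (!is.finite(object@rss)) return("converged fit must have finite rss")
    if (object@kd < 0) return("kd must be non-negative")
    if (all(is.finite(object@ci[, "kd"])) &&
        (object@kd < object@ci[1, "kd"] || object@kd > object@ci[2, "kd"]))
      return("kd interval must contain the point estimate")
  }
  TRUE
})

#' CascadeReport: full record of a screening triage run
#'
#' Holds the plate QC table, per-compound results across both assays with
#' region classification, the nested per-stage hit lists
#' (stage3 is a subset of stage2 is a subset of stage1), dose-response fits
#' for triaged compounds, every exclusion with its reason, and an echo of the
#' configuration so the run is reproducible from the report alone. The
#' \code{external_annotation} field exists for downstream wet-lab confirmation
#' status and is never filled by this package.
#'
#' @slot plate_qc data.frame, one row per plate
#' @slot compounds data.frame, one row per compound with both assay
#'   inhibitions, region, stage reached and flags
#' @slot stage1,stage2,stage3 character vectors of compound ids
#' @slot dose_fits named list of DoseResponseFit for stage-2 compounds with
#'   titration data
#' @slot exclusions data.frame (compound_id/plate_id, reason)
#' @slot config list echo of the thresholds and options used
#' @slot seed integer seed recorded from the simulation, NA for real data
#' @slot external_annotation data.frame placeholder for downstream assay
#'   status (empty by default)
#'
#' @exportClass CascadeReport
setClass("CascadeReport",
  representation(plate_qc = "data.frame", compounds = "data.frame",
                 stage1 = "character", stage2 = "character",
                 stage3 = "character", dose_fits = "list",
                 exclusions = "data.frame", config = "list",
                 seed = "integer", external_annotation = "data.frame"))

setValidity("CascadeReport", function(object) {
  if (!all(object@stage2 %in% object@stage1))
    return("stage2 must be a subset of stage1")
  if (!all(object@stage3 %in% object@stage2))
    return("stage3 must be a subset of stage2")
  TRUE
})

setMethod("show", "ScreeningCampaign", function(object) {
  w <- object@wells
  cat("ScreeningCampaign:", length(unique(w$plate_id)), "plate(s),",
      nrow(w), "well(s)\n")
  for (a in intersect(ASSAYS, unique(w$assay))) {
    wa <- w[w$assay == a, ]
    cat("  ", a, ": ", length(unique(wa$plate_id)), " plate(s), ",
        sum(wa$role == "compound"), " compound well(s), ",
        length(unique(wa$compound_id[wa$role == "compound"])),
        " compound(s)\n", sep = "")
  }
  if (nrow(object@rejected))
    cat("  ", nrow(object@rejected), "rejected input row(s)\n")
})

setMethod("show", "PlateSummary", function(object) {
  cat(sprintf("PlateSummary %s [%s]: Z' = %.3f, fold signal = %.2f, QC %s\n",
              object@plate_id, object@assay, object@zprime,
              object@fold_signal, if (object@qc_pass) "PASS" else "FAIL"))
})

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged) {
    cat(sprintf(paste0("DoseResponseFit: IC50 = %.3g uM (slope %.2f, ",
                       "top %.1f, bottom %.1f), rss = %.3g, n = %d\n"),
                object@ic50, object@slope, object@top, object@bottom,
                object@rss, object@n_points))
  } else {
    cat("DoseResponseFit: not converged (", object@diagnostic, ")\n",
        sep = "")
  }
})

setMethod("show", "FPBindingFit", function(object) {
  if (object@converged) {
    cat(sprintf("FPBindingFit: Kd = %.3g uM (P_L %.1f, P_RL %.1f mP), rss = %.3g\n",
                object@kd, object@p_free, object@p_bound, object@rss))
    if (all(is.finite(object@ci[, "kd"])))
      cat(sprintf("  bootstrap 95%% CI for Kd: [%.3g, %.3g] (%d replicates)\n",
                  object@ci[1, "kd"], object@ci[2, "kd"], object@n_boot))
  } else {
    cat("FPBindingFit: not converged (", object@diagnostic, ")\n", sep = "")
  }
})

setMethod("show", "CascadeReport", function(object) {
  cat("CascadeReport\n")
  cat("  plates:", nrow(object@plate_qc),
      sprintf("(%d passed QC)", sum(object@plate_qc$qc_pass)), "\n")
  cat("  stage 1 (primary > ", object@config$threshold_ppi, "%): ",
      length(object@stage1), " hit(s)\n", sep = "")
  cat("  stage 2 (region B): ", length(object@stage2), " hit(s)\n", sep = "")
  cat("  stage 3 (dose-dependent): ", length(object@stage3), " hit(s)\n",
      sep = "")
  if (nrow(object@exclusions))
    cat("  exclusions:", nrow(object@exclusions), "\n")
})
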