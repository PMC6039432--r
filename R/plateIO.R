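#' Construct a ScreeningCampaign from in-memory tables
#'
#' @param wells data.frame of wells (columns \code{plate_id}, \code{well},
#'   \code{role}, \code{assay}, \code{compound_id}, \code{conc_um},
#'   \code{i665}, \code{i620}); extra columns are dropped
#' @param library optional compound metadata data.frame with at least
#'   \code{compound_id}; compound ids in wells that do not resolve in a
#'   non-empty library are flagged with a warning
#' @param rejected internal: data.frame of rejected rows from a reader
#' @return a validated \code{ScreeningCampaign}
#' @export
screeningCampaign <- function(wells,
                              library = data.frame(compound_id = character(),
                                                   name = character(),
                                                   stringsAsFactors = FALSE),
                              rejected = data.frame(line = integer(),
                                                    reason = character(),
                                                    stringsAsFactors = FALSE)) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  for (col in WELL_COLUMNS)
    if (!col %in% names(wells))
      stop("wells table lacks mandatory column '", col, "'")
  wells <- wells[WELL_COLUMNS]
  wells$well <- parseWellAddress(wells$well)$well  # canonical unpadded form
  wells$conc_um <- as.numeric(wells$conc_um)
  wells$i665 <- as.numeric(wells$i665)
  wells$i620 <- as.numeric(wells$i620)
  wells$compound_id <- as.character(wells$compound_id)
  rownames(wells) <- NULL
  obj <- new("ScreeningCampaign", wells = wells,
             library = as.data.frame(library, stringsAsFactors = FALSE),
             rejected = rejected)
  if (nrow(obj@library)) {
    cmp <- unique(wells$compound_id[wells$role == "compound"])
    unresolved <- setdiff(cmp, obj@library$compound_id)
    if (length(unresolved))
      warning(length(unresolved),
              " compound id(s) not found in the library: ",
              paste(utils::head(unresolved, 5), collapse = ", "),
              if (length(unresolved) > 5) ", ...")
  }
  obj
}

# default mapping from canonical column names to file header names
defaultDialect <- function() {
  c(plate_id = "plate_id", well = "well", role = "role", assay = "assay",
    compound_id = "compound_id", conc_um = "conc_um", i665 = "i665",
    i620 = "i620")
}

#' Read a long-format well table into a ScreeningCampaign
#'
#' Reads a delimited text export (one row per well) and validates each row
#' against the 384-well data model. Rows violating a row-level invariant
#' (bad well address, missing compound id on a compound well, negative or
#' non-numeric intensity) are rejected individually and reported with their
#' file line number via \code{rejectedRows()}; the sum of accepted and
#' rejected rows always equals the number of input rows. Structural problems
#' (missing mandatory columns, duplicate plate/well addresses) abort with an
#' error. If a \code{conc_unit} column is present, concentrations are
#' converted to micromolar (recognized units: nM, uM, mM, M).
#'
#' @param path path to a delimited text file with a header
#' @param dialect named character vector remapping canonical column names
#'   (\code{plate_id}, \code{well}, \code{role}, \code{assay},
#'   \code{compound_id}, \code{conc_um}, \code{i665}, \code{i620}) to the
#'   file's header names; only names to override need be given
#' @param library optional compound library data.frame (see
#'   \code{\link{readCompoundLibrary}})
#' @param sep field separator, default comma
#' @return a \code{ScreeningCampaign}
#' @seealso \code{\link{writeWellTable}} for the inverse; the pair is
#'   lossless on valid campaigns
#' @export
readWellTable <- function(path, dialect = NULL, library = NULL, sep = ",") {
  dia <- defaultDialect()
  if (!is.null(dialect)) {
    stopifnot(!is.null(names(dialect)), all(names(dialect) %in% names(dia)))
    dia[names(dialect)] <- dialect
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  mandatory <- c("plate_id", "well", "role", "i665", "i620")
  missing_cols <- mandatory[!dia[mandatory] %in% names(raw)]
  if (length(missing_cols))
    stop("well table lacks mandatory column(s): ",
         paste(dia[missing_cols], collapse = ", "))

  n <- nrow(raw)
  getcol <- function(canon, default = NA_character_) {
    if (dia[[canon]] %in% names(raw)) raw[[dia[[canon]]]] else
      rep(default, n)
  }
  tab <- data.frame(
    plate_id = getcol("plate_id"),
    well = getcol("well"),
    role = getcol("role"),
    assay = getcol("assay", "ppi"),
    compound_id = getcol("compound_id"),
    conc_um = suppressWarnings(as.numeric(getcol("conc_um"))),
    i665 = suppressWarnings(as.numeric(getcol("i665"))),
    i620 = suppressWarnings(as.numeric(getcol("i620"))),
    stringsAsFactors = FALSE)
  tab$assay[is.na(tab$assay)] <- "ppi"

  if ("conc_unit" %in% names(raw)) {
    fac <- c(nm = 1e-3, um = 1, mm = 1e3, m = 1e6)
    u <- tolower(raw$conc_unit)
    u <- gsub("µ", "u", u)
    mult <- fac[u]
    mult[is.na(mult)] <- 1
    tab$conc_um <- tab$conc_um * unname(mult)
  }

  # row-level validation; file line = data row + header line
  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  flag(is.na(tab$plate_id), "missing plate_id")
  flag(!isValidWell(tab$well), "well address outside A1..P24")
  flag(is.na(tab$role) | !tab$role %in% WELL_ROLES,
       paste("role not one of", paste(WELL_ROLES, collapse = "/")))
  flag(!tab$assay %in% ASSAYS, "assay not one of ppi/counter")
  raw_i665 <- getcol("i665")
  raw_i620 <- getcol("i620")
  flag(is.na(tab$i665) & !is.na(raw_i665), "non-numeric acceptor intensity")
  flag(is.na(tab$i620) & !is.na(raw_i620), "non-numeric donor intensity")
  flag(!is.na(tab$i665) & (tab$i665 < 0 | is.infinite(tab$i665)),
       "negative or infinite acceptor intensity")
  flag(!is.na(tab$i620) & (tab$i620 < 0 | is.infinite(tab$i620)),
       "negative or infinite donor intensity")
  flag(tab$role == "compound" &
         (is.na(tab$compound_id) | tab$compound_id == ""),
       "compound well without compound_id")
  flag(tab$role %in% c("max_control", "min_control") &
         !is.na(tab$compound_id) & tab$compound_id != "",
       "control well with compound_id")

  bad <- !is.na(reasons)
  rejected <- data.frame(line = which(bad) + 1L, reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(nrow(rejected), " row(s) rejected; first: line ",
            rejected$line[1], " (", rejected$reason[1], ")")
  acc <- tab[!bad, , drop = FALSE]
  acc$well <- parseWellAddress(acc$well)$well
  dup <- duplicated(acc[c("plate_id", "assay", "well")])
  if (any(dup))
    stop("duplicate (plate, well) address(es), e.g. plate ",
         acc$plate_id[dup][1], " well ", acc$well[dup][1])

  if (is.null(library))
    library <- data.frame(compound_id = character(), name = character(),
                          stringsAsFactors = FALSE)
  screeningCampaign(acc, library = library, rejected = rejected)
}

#' Write a campaign's well table as CSV
#'
#' Emits the canonical long-format well table (unpadded well addresses,
#' micromolar concentrations). \code{readWellTable} on the output reproduces
#' the campaign's well set field for field.
#'
#' @param campaign a \code{ScreeningCampaign}
#' @param path output file path
#' @export
writeWellTable <- function(campaign, path) {
  stopifnot(is(campaign, "ScreeningCampaign"))
  utils::write.csv(wells(campaign), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a compound library CSV
#'
#' Expects at least a \code{compound_id} column; \code{name} and
#' \code{smiles} are optional and passed through untouched (no
#' chemistry-aware processing is done).
#'
#' @param path CSV path
#' @return data.frame
#' @export
readCompoundLibrary <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"compound_id" %in% names(lib))
    stop("compound library lacks mandatory column 'compound_id'")
  lib
}

fitToList <- function(f) {
  list(top = f@top, bottom = f@bottom, ic50 = f@ic50, slope = f@slope,
       ic50_absolute = f@ic50_absolute, rss = f@rss,
       converged = f@converged, diagnostic = f@diagnostic,
       n_points = f@n_points)
}

fitFromList <- function(l) {
  new("DoseResponseFit",
      top = as.numeric(l$top), bottom = as.numeric(l$bottom),
      ic50 = as.numeric(l$ic50), slope = as.numeric(l$slope),
      ic50_absolute = as.numeric(l$ic50_absolute), rss = as.numeric(l$rss),
      converged = as.logical(l$converged),
      diagnostic = as.character(l$diagnostic),
      n_points = as.integer(l$n_points))
}

#' Write and read a cascade report as JSON
#'
#' The JSON document records per-stage compound lists, the thresholds and
#' options used, the plate QC table, per-compound results, dose-response fit
#' parameters, exclusions, and software provenance (package name and
#' version). Serialization is deterministic: the same report yields
#' byte-identical output, and \code{readReport} reconstructs an equal
#' \code{CascadeReport}.
#'
#' @param report a \code{CascadeReport}
#' @param path output (input) path
#' @return \code{writeReport}: the path, invisibly; \code{readReport}: a
#'   \code{CascadeReport}
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "CascadeReport"))
  doc <- list(
    provenance = list(
      package = "fretscreen",
      version = as.character(utils::packageVersion("fretscreen"))),
    seed = report@seed,
    config = report@config,
    plate_qc = report@plate_qc,
    compounds = report@compounds,
    stages = list(stage1 = as.list(report@stage1),
                  stage2 = as.list(report@stage2),
                  stage3 = as.list(report@stage3)),
    dose_fits = lapply(report@dose_fits, fitToList),
    exclusions = report@exclusions,
    external_annotation = report@external_annotation)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  as_df <- function(x, template) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x))
      return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    for (col in names(template))
      if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
    df[names(template)]
  }
  chr <- function(x) if (is.null(x) || !length(x)) character(0) else
    as.character(unlist(x))
  fits <- doc$dose_fits
  fits <- if (is.null(fits) || !length(fits)) list() else
    lapply(fits, fitFromList)
  new("CascadeReport",
      plate_qc = as_df(doc$plate_qc, emptyPlateQC()),
      compounds = as_df(doc$compounds, emptyCompoundResults()),
      stage1 = chr(doc$stages$stage1),
      stage2 = chr(doc$stages$stage2),
      stage3 = chr(doc$stages$stage3),
      dose_fits = fits,
      exclusions = as_df(doc$exclusions, emptyExclusions()),
      config = doc$config,
      seed = if (is.null(doc$seed) || is.na(doc$seed)) NA_integer_ else
        as.integer(doc$seed),
      external_annotation = as_df(doc$external_annotation,
                                  data.frame(compound_id = character(),
                                             status = character(),
                                             stringsAsFactors = FALSE)))
}

#' Write per-compound cascade results as CSV
#'
#' @param report a \code{CascadeReport}
#' @param path output path
#' @export
writeCompoundResults <- function(report, path) {
  stopifnot(is(report, "CascadeReport"))
  utils::write.csv(compoundResults(report), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
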