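#' Parse and format 384-well addresses
#'
#' Addresses follow 384-well geometry: row letters A-P, columns 1-24. Both
#' zero-padded ("A01") and unpadded ("A1") input forms are accepted, as both
#' occur in plate-reader exports; the canonical emitted form is unpadded.
#'
#' @param x character vector of well addresses
#' @return \code{parseWellAddress}: data.frame with columns \code{row}
#'   (letter), \code{column} (integer) and \code{well} (canonical form);
#'   invalid addresses give NA rows. \code{isValidWell}: logical.
#' @examples
#' parseWellAddress(c("A1", "A01", "P24"))
#' isValidWell("Q1")   # FALSE: row out of range
#' @export
parseWellAddress <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-P])0?([1-9][0-9]?)$", x))
  row <- vapply(m, function(g) if (length(g) == 3) g[2] else NA_character_,
                character(1))
  col <- vapply(m, function(g) if (length(g) == 3) as.integer(g[3]) else
                NA_integer_, integer(1))
  col[!is.na(col) & col > 24] <- NA_integer_
  row[is.na(col)] <- NA_character_
  data.frame(row = row, column = col,
             well = ifelse(is.na(row), NA_character_, paste0(row, col)),
             stringsAsFactors = FALSE)
}

#' @rdname parseWellAddress
#' @export
isValidWell <- function(x) !is.na(parseWellAddress(x)$well)

#' @rdname parseWellAddress
#' @param row row letter (A-P) or index (1-16)
#' @param column column index (1-24)
#' @export
formatWellAddress <- function(row, column) {
  if (is.numeric(row)) {
    stopifnot(all(row >= 1 & row <= 16))
    row <- PLATE_ROWS[row]
  }
  stopifnot(all(row %in% PLATE_ROWS), all(column %in% PLATE_COLS))
  paste0(row, as.integer(column))
}
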