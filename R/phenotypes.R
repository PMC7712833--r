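#' Construct a validated phenotype table
#'
#' One row per farrowing.  Rows violating `0 <= sb <= tnb`, unknown cross
#' codes, or parities outside 1..6 raise an error naming the offending row.
#' Year-season levels are inferred from the data and frozen unless supplied.
#'
#' @param sow_id sow identifiers (coerced to character).
#' @param cross cross codes, subset of [crossCodes()].
#' @param parity integer parity class 1-6 (6 = sixth and beyond).
#' @param year_season year-season labels.
#' @param tnb,sb total number born and number stillborn (integers).
#' @param ysLevels optional frozen level set for year-season.
#' @return a [DiallelData-class].
#' @export
diallelData <- function(sow_id, cross, parity, year_season, tnb, sb,
                        ysLevels = NULL) {
  rec <- data.frame(
    sow_id = as.character(sow_id),
    cross = as.character(cross),
    parity = as.integer(parity),
    year_season = as.character(year_season),
    tnb = as.integer(tnb),
    sb = as.integer(sb),
    stringsAsFactors = FALSE)
  .validate_records(rec)
  if (is.null(ysLevels)) ysLevels <- sort(unique(rec$year_season))
  new("DiallelData", records = rec, ysLevels = as.character(ysLevels))
}

.validate_records <- function(rec) {
  fail <- function(which, what) {
    stop(sprintf("invalid phenotype record at row %d: %s", which[1], what),
         call. = FALSE)
  }
  if (any(is.na(rec$tnb)) || any(is.na(rec$sb)))
    fail(which(is.na(rec$tnb) | is.na(rec$sb)), "non-integer tnb/sb")
  if (any(rec$tnb < 0)) fail(which(rec$tnb < 0), "negative tnb")
  bad <- rec$sb < 0 | rec$sb > rec$tnb
  if (any(bad)) fail(which(bad), "sb outside [0, tnb]")
  badc <- !(rec$cross %in% crossCodes())
  if (any(badc)) fail(which(badc), paste("unknown cross code", rec$cross[which(badc)[1]]))
  badp <- is.na(rec$parity) | rec$parity < 1L | rec$parity > 6L
  if (any(badp)) fail(which(badp), "parity outside 1..6")
  invisible(TRUE)
}

#' Read / write phenotype files
#'
#' Delimited text (comma or tab, autodetected) with header columns `sow_id`,
#' `cross`, `parity`, `year_season`, `tnb`, `sb`.
#'
#' @param path file path.
#' @return `readPhenotypes`: a [DiallelData-class].
#' @export
readPhenotypes <- function(path) {
  tab <- .read_delim(path)
  need <- c("sow_id", "cross", "parity", "year_season", "tnb", "sb")
  if (!all(need %in% names(tab)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "),
         " (got: ", paste(names(tab), collapse = ", "), ")")
  to_int <- function(x, nm) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop(sprintf("non-integer %s at row %d of %s", nm, bad[1], path), call. = FALSE)
    v
  }
  diallelData(tab$sow_id, tab$cross, to_int(tab$parity, "parity"),
              tab$year_season, to_int(tab$tnb, "tnb"), to_int(tab$sb, "sb"))
}

#' @rdname readPhenotypes
#' @param data a [DiallelData-class]
#' @param sep field separator.
#' @export
writePhenotypes <- function(data, path, sep = "\t") {
  stopifnot(is(data, "DiallelData"))
  write.table(records(data), path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
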