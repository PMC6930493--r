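#' Read a peak-list CSV
#'
#' Comma-separated, UTF-8, mandatory header with at least `mz` and `z`
#' columns; an `intensity` column is optional.
#'
#' @param path file path.
#' @return data.frame with columns `mz`, `z`, `intensity`.
#' @export
readPeakList <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "z") %in% names(df)))
    stop("peak list ", sQuote(path), " must have columns mz and z")
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  df$mz <- as.numeric(df$mz)
  df$z <- as.integer(abs(df$z))      # charges may be written as -1, -2, ...
  df[, c("mz", "z", "intensity")]
}

#' Write a peak-list CSV
#'
#' @param peaks data.frame with columns `mz`, `z` (and optionally more).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePeakList <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a digestion product table as CSV
#'
#' @param x a [DigestResult-class].
#' @param path file path.
#' @param includeSurvivors include partial survivors (default TRUE).
#' @return `path`, invisibly.
#' @export
writeProducts <- function(x, path, includeSurvivors = TRUE) {
  utils::write.csv(productTable(x, includeSurvivors = includeSurvivors),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read evidence records from a JSON file
#'
#' The file holds an array of objects with fields `subject`, `treatment`
#' (array), `fate`, and optional `companions` (array) and `trace` (parallel
#' boolean array).
#'
#' @param path file path.
#' @return list of [evidenceRecord()] objects.
#' @export
readEvidence <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    companions <- as.character(unlist(e$companions))
    trace <- if (is.null(e$trace)) rep(FALSE, length(companions))
             else as.logical(unlist(e$trace))
    evidenceRecord(e$subject, as.character(unlist(e$treatment)), e$fate,
                   companions = companions, trace = trace)
  })
}

#' Write evidence records to a JSON file
#'
#' @param evidence list of [evidenceRecord()] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEvidence <- function(evidence, path) {
  if (is(evidence, "evidenceRecord")) evidence <- list(evidence)
  out <- lapply(evidence, function(e)
    list(subject = formatComposition(e$subject), treatment = e$treatment,
         fate = e$fate, companions = e$companions, trace = e$trace))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
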