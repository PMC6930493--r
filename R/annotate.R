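#' Annotate an MS/MS peak list against a candidate sequence
#'
#' Each observed peak is assigned the minimum-absolute-error fragment
#' candidate at its charge state; peaks with no candidate within the
#' tolerance are reported unannotated.
#'
#' @param peaks data.frame with columns `mz`, `z` and optionally
#'   `intensity` (see [readPeakList()]).
#' @param x candidate [GAGSequence-class] or sequence string.
#' @param tol m/z tolerance (default 0.01).
#' @param maxCharge maximum fragment charge considered (default 2).
#' @return data.frame with one row per peak: `mz`, `z`, `intensity`,
#'   `annotated`, `label`, `kind`, `index`, `retained`, `co2`, `h2o`,
#'   `mz_calc`, `error_mDa`.
#' @examples
#' pk <- data.frame(mz = c(175.02, 210.99), z = c(1, 1))
#' annotateMSMS(pk, "I2S–ANS6S")
#' @export
annotateMSMS <- function(peaks, x, tol = 0.01, maxCharge = 2L) {
  stopifnot(is.data.frame(peaks), all(c("mz", "z") %in% names(peaks)))
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  cand <- fragmentCandidates(x, maxCharge = maxCharge)
  out <- peaks[, c("mz", "z", "intensity")]
  out$annotated <- FALSE
  out$label <- NA_character_
  out$kind <- NA_character_
  out$index <- NA_integer_
  out$retained <- NA_integer_
  out$co2 <- NA_integer_
  out$h2o <- NA_integer_
  out$mz_calc <- NA_real_
  out$error_mDa <- NA_real_
  for (p in seq_len(nrow(peaks))) {
    sub <- cand[cand$z == peaks$z[p], , drop = FALSE]
    if (!nrow(sub)) next
    err <- sub$mz - peaks$mz[p]
    best <- which.min(abs(err))
    if (abs(err[best]) > tol) next
    out$annotated[p] <- TRUE
    out$label[p] <- sub$label[best]
    out$kind[p] <- sub$kind[best]
    out$index[p] <- sub$index[best]
    out$retained[p] <- sub$retained[best]
    out$co2[p] <- sub$co2[best]
    out$h2o[p] <- sub$h2o[best]
    out$mz_calc[p] <- round(sub$mz[best], 4)
    out$error_mDa[p] <- round(err[best] * 1000, 2)
  }
  out
}

#' Isomer-discriminating MS/MS comparison
#'
#' Annotates the same peak list against two or more candidate sequences and
#' flags, per peak, which candidates can explain it — the logic used to
#' discriminate positional isomers whose precursor masses coincide.
#'
#' @param peaks data.frame with columns `mz`, `z`.
#' @param candidates named list of sequences (strings or
#'   [GAGSequence-class]).
#' @param tol m/z tolerance (default 0.01).
#' @return data.frame with `mz`, `z`, one logical `matched_<name>` and one
#'   character `label_<name>` column per candidate, and `diagnostic`
#'   (TRUE when the peak is explained by some but not all candidates).
#' @export
compareIsomers <- function(peaks, candidates, tol = 0.01) {
  stopifnot(is.list(candidates), length(candidates) >= 2L,
            !is.null(names(candidates)))
  out <- peaks[, c("mz", "z")]
  matchedCols <- list()
  for (nm in names(candidates)) {
    ann <- annotateMSMS(peaks, candidates[[nm]], tol = tol)
    out[[paste0("matched_", nm)]] <- ann$annotated
    out[[paste0("label_", nm)]] <- ann$label
    matchedCols[[nm]] <- ann$annotated
  }
  m <- do.call(cbind, matchedCols)
  out$diagnostic <- apply(m, 1L, function(v) any(v) && !all(v))
  out
}
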