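#' Enumeration constraints for candidate sequences
#'
#' Controls the substituent rules used by [enumerateSequences()].  The
#' defaults encode heparin biosynthetic regularities: a 2-O-sulfated uronic
#' acid is enumerated as iduronic only; an unsulfated uronic acid may be
#' either epimer; 3-O-sulfation is restricted to N-sulfated glucosamine that
#' either opens the chain or follows an unsulfated glucuronic acid (the
#' antithrombin-binding-region context); free-amine (NH2) glucosamine is off.
#'
#' @param epimer2S `"I"` (default) or `"both"`: epimers allowed for a
#'   2-O-sulfated uronic residue.
#' @param unsulfatedEpimers epimers allowed for an unsulfated uronic residue.
#' @param threeOS 3-O-sulfation context rule: `"afterG"` (default),
#'   `"anyNS"` (any N-sulfated glucosamine) or `"none"`.
#' @param allowNH2 allow unsubstituted (NH2) glucosamine (default FALSE).
#' @param maxResidues hard cap on enumerable chain length (default 10).
#' @return a named list of class `gagConstraints`.
#' @export
gagConstraints <- function(epimer2S = "I",
                           unsulfatedEpimers = c("I", "G"),
                           threeOS = c("afterG", "anyNS", "none"),
                           allowNH2 = FALSE,
                           maxResidues = 10L) {
  structure(list(epimer2S = match.arg(epimer2S, c("I", "both")),
                 unsulfatedEpimers = unsulfatedEpimers,
                 threeOS = match.arg(threeOS),
                 allowNH2 = allowNH2,
                 maxResidues = as.integer(maxResidues)),
            class = "gagConstraints")
}

## residue-class layout implied by a composition code, or NULL if infeasible
.codeLayout <- function(code) {
  n <- code@nRes
  startUronic <- code@nreClass %in% c("dU", "U")
  cls <- rep(c("U", "A"), length.out = n)
  if (!startUronic) cls <- rep(c("A", "U"), length.out = n)
  if (code@nreClass == "dU") cls[1] <- "dU"
  if (code@hasAmol) {
    if (cls[n] != "A") return(NULL)      # RE parity incompatible with aM.ol
    cls[n] <- "aMol"
  }
  cls
}

#' Enumerate all sequences with a given composition
#'
#' Exhaustively generates every [GAGSequence-class] whose composition equals
#' `code` (ignoring the isomer label) under the substituent `constraints`.
#' Ring-contracted residues, when flagged in the code, are placed at each
#' internal amine-type position in turn.
#'
#' @param code a [CompositionCode-class] or composition string.
#' @param constraints a [gagConstraints()] list.
#' @return list of [GAGSequence-class] objects (possibly empty: an
#'   infeasible code yields an empty set, not an error).
#' @examples
#' length(enumerateSequences("ΔU2,3,0"))
#' @export
enumerateSequences <- function(code, constraints = gagConstraints()) {
  if (is.character(code)) code <- parseComposition(code)
  stopifnot(is(code, "CompositionCode"))
  if (code@nRes > constraints$maxResidues)
    stop(sprintf("composition spans %d residues, above the enumeration cap of %d",
                 code@nRes, constraints$maxResidues))
  cls <- .codeLayout(code)
  if (is.null(cls)) return(list())
  n <- code@nRes
  rcChoices <- list(NA_integer_)
  if (code@hasRc) {
    internalA <- which(cls == "A" & seq_len(n) > 1L & seq_len(n) < n)
    if (!length(internalA)) return(list())
    rcChoices <- as.list(internalA)
  } else if (any(cls == "Rc")) return(list())
  out <- list()
  for (rcPos in rcChoices) {
    layout <- cls
    if (!is.na(rcPos)) layout[rcPos] <- "Rc"
    out <- c(out, .enumerateLayout(layout, code@nSulf, code@nAc, constraints))
  }
  out
}

## DFS over per-position substituent options with sulfate/acetyl budget
## pruning; options for an amine position depend on the residue chosen at
## the preceding position (3-O-sulfation context rule).
.enumerateLayout <- function(layout, nSulf, nAc, con) {
  n <- length(layout)
  maxS <- vapply(layout, function(cl)
    switch(cl, dU = 1L, U = 1L, A = 3L, aMol = 1L, Rc = 0L), integer(1))
  maxA <- as.integer(layout == "A")
  cumS <- rev(cumsum(rev(maxS)))
  cumA <- rev(cumsum(rev(maxA)))
  resRow <- function(class, epimer = NA_character_, s2 = FALSE,
                     nsub = NA_character_, s3 = FALSE, s6 = FALSE)
    list(class = class, epimer = epimer, s2 = s2, nsub = nsub,
         s3 = s3, s6 = s6)
  results <- list()
  acc <- vector("list", n)
  recurse <- function(pos, sLeft, aLeft) {
    if (pos > n) {
      if (sLeft == 0L && aLeft == 0L) {
        df <- do.call(rbind, lapply(acc, function(x)
          data.frame(x, stringsAsFactors = FALSE)))
        results[[length(results) + 1L]] <<- .newGAG(df)
      }
      return(invisible())
    }
    if (sLeft > cumS[pos] || aLeft > cumA[pos]) return(invisible())
    prev <- if (pos > 1L) acc[[pos - 1L]] else NULL
    opts <- .positionOptions(layout[pos], prev, con, resRow)
    for (o in opts) {
      ns <- o$s2 + o$s3 + o$s6 +
        (!is.na(o$nsub) && o$nsub == "NS")
      na <- as.integer(!is.na(o$nsub) && o$nsub == "NAc")
      if (ns > sLeft || na > aLeft) next
      acc[[pos]] <<- o
      recurse(pos + 1L, sLeft - as.integer(ns), aLeft - na)
    }
    invisible()
  }
  recurse(1L, as.integer(nSulf), as.integer(nAc))
  results
}

.positionOptions <- function(cl, prev, con, resRow) {
  if (cl == "dU")
    return(list(resRow("dU"), resRow("dU", s2 = TRUE)))
  if (cl == "U") {
    opts <- lapply(con$unsulfatedEpimers, function(e) resRow("U", epimer = e))
    ep2 <- if (con$epimer2S == "both") c("I", "G") else "I"
    opts <- c(opts, lapply(ep2, function(e) resRow("U", epimer = e, s2 = TRUE)))
    return(opts)
  }
  if (cl == "aMol")
    return(list(resRow("aMol"), resRow("aMol", s6 = TRUE)))
  if (cl == "Rc")
    return(list(resRow("Rc")))
  ## glucosamine: N-substituent x 3-O x 6-O, under the 3-O context rule
  s3ok <- switch(con$threeOS,
    none   = FALSE,
    anyNS  = TRUE,
    afterG = is.null(prev) ||
      (prev$class == "U" && !prev$s2 && prev$epimer %in% c("G", "X")))
  nsubs <- c("NS", "NAc", if (con$allowNH2) "NH2")
  opts <- list()
  for (nsub in nsubs) for (s6 in c(FALSE, TRUE)) {
    opts[[length(opts) + 1L]] <- resRow("A", nsub = nsub, s6 = s6)
    if (nsub == "NS" && s3ok)
      opts[[length(opts) + 1L]] <- resRow("A", nsub = nsub, s3 = TRUE, s6 = s6)
  }
  opts
}
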