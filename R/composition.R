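#' Construct a composition code
#'
#' @param nreClass "dU", "U" or "A" (also accepts "ΔU").
#' @param nRes,nSulf,nAc residue, sulfate and N-acetyl counts.
#' @param hasAmol,hasRc end-group flags.
#' @param label opaque isomer label, e.g. "(2)".
#' @return a [CompositionCode-class].
#' @export
compositionCode <- function(nreClass, nRes, nSulf, nAc = 0L,
                            hasAmol = FALSE, hasRc = FALSE, label = "") {
  if (identical(nreClass, "ΔU")) nreClass <- "dU"
  new("CompositionCode", nreClass = nreClass, nRes = as.integer(nRes),
      nSulf = as.integer(nSulf), nAc = as.integer(nAc),
      hasAmol = hasAmol, hasRc = hasRc, label = label)
}

#' Composition code of a sequence
#'
#' Summarises a sequence as its "ΔU/U/A n,s,a" composition: residue count,
#' total sulfate count (2-O + 3-O + 6-O + N-sulfate), N-acetyl count, the
#' NRE residue class and the anhydromannitol / ring-contracted flags.
#'
#' @param x a [GAGSequence-class] or a sequence string.
#' @return a [CompositionCode-class].
#' @examples
#' formatComposition(compositionOf("ΔU–ANAc6S–G–ANS3S"))  # "ΔU4,3,1"
#' @export
setGeneric("compositionOf", function(x) standardGeneric("compositionOf"))

#' @rdname compositionOf
#' @export
setMethod("compositionOf", "GAGSequence", function(x) {
  r <- x@residues
  nre <- switch(r$class[1], dU = "dU", U = "U", "A")
  compositionCode(nre, nrow(r), sum(.residueSulfVec(r)),
                  sum(!is.na(r$nsub) & r$nsub == "NAc"),
                  hasAmol = r$class[nrow(r)] == "aMol",
                  hasRc = any(r$class == "Rc"),
                  label = x@label)
})

#' @rdname compositionOf
#' @export
setMethod("compositionOf", "character",
          function(x) compositionOf(parseGAG(x)))

#' Format a composition code
#'
#' @param code a [CompositionCode-class].
#' @param withLabel append the isomer label, if any (default TRUE).
#' @return character scalar such as `"U8,10,0,Rc–aM.ol"`.
#' @export
formatComposition <- function(code, withLabel = TRUE) {
  stopifnot(is(code, "CompositionCode"))
  sym <- switch(code@nreClass, dU = "ΔU", U = "U", A = "A")
  out <- sprintf("%s%d,%d,%d", sym, code@nRes, code@nSulf, code@nAc)
  if (code@hasRc) out <- paste0(out, ",Rc")
  if (code@hasAmol) out <- paste0(out, "–aM.ol")
  if (withLabel && nzchar(code@label)) out <- paste(out, code@label)
  out
}

#' Parse a composition code string
#'
#' Accepts strings such as `"ΔU4,5,0"`, `"U8,11,0–aM.ol"`,
#' `"U8,10,0,Rc–aM.ol"` and an optional trailing isomer label `"(2)"`,
#' which is preserved as an opaque annotation.  En dash, hyphen and `dU`
#' spellings are tolerated; `formatComposition(parseComposition(s))`
#' reproduces the canonical form.
#'
#' @param text character scalar.
#' @return a [CompositionCode-class].
#' @export
parseComposition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", " ", trimws(text))
  label <- ""
  m <- regexec("^(.*?)\\s*(\\([0-9]+\\))$", s)[[1]]
  if (m[1] != -1) {
    parts <- regmatches(s, list(m))[[1]]
    s <- parts[2]
    label <- parts[3]
  }
  s <- gsub("−", "-", gsub("–", "-", s))
  hasAmol <- grepl("-aM\\.ol$", s)
  s <- sub("-aM\\.ol$", "", s)
  hasRc <- grepl(",Rc$", s)
  s <- sub(",Rc$", "", s)
  m <- regexec("^(ΔU|dU|U|A)([0-9]+),([0-9]+),([0-9]+)$", s)[[1]]
  if (m[1] == -1) stop("malformed composition code: ", sQuote(text))
  parts <- regmatches(s, list(m))[[1]]
  nre <- if (parts[2] %in% c("ΔU", "dU")) "dU" else parts[2]
  compositionCode(nre, as.integer(parts[3]), as.integer(parts[4]),
                  as.integer(parts[5]), hasAmol = hasAmol, hasRc = hasRc,
                  label = label)
}

## equality on composition codes, ignoring the opaque label
.sameComposition <- function(a, b) {
  a@nreClass == b@nreClass && a@nRes == b@nRes && a@nSulf == b@nSulf &&
    a@nAc == b@nAc && a@hasAmol == b@hasAmol && a@hasRc == b@hasRc
}
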