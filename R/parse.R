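#' Parse a GAG sequence string
#'
#' Parses the residue nomenclature used for heparin/LMWH oligosaccharides,
#' e.g. `"G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S"` or `"ΔU2S–ANS6S"`.
#' Residue tokens are separated by an en dash (as printed) or a plain ASCII
#' hyphen.  Recognised tokens:
#'
#' * `ΔU`/`dU` with optional `2S` — 4,5-unsaturated uronic acid;
#' * `I`, `G` or `U` (epimer unknown) with optional `2S` — saturated uronic;
#' * `A` + N-substituent (`NS`, `NAc`, `NH2`) + optional `3S` and/or `6S`;
#' * `aM.ol` with optional `6S` — 2,5-anhydromannitol (reducing end only);
#' * `Rc` — ring-contracted residue.
#'
#' Underscore subscript markup (`A_NS6S_`) and whitespace are tolerated and
#' stripped before tokenisation.
#'
#' @param text character scalar, the sequence written NRE to RE.
#' @param label optional opaque annotation attached to the sequence.
#' @return a [GAGSequence-class].
#' @examples
#' parseGAG("ΔU2S–ANS6S")
#' parseGAG("G-ANS3S6S-I2S-ANS6S-I2S-ANS6S-I2S-aM.ol6S")
#' @export
parseGAG <- function(text, label = "") {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("[_*[:space:]]", "", text)
  clean <- gsub("−", "-", clean)      # minus sign
  if (!nzchar(clean)) stop("empty sequence string")
  tokens <- strsplit(clean, "–|-")[[1]]
  if (!length(tokens) || any(!nzchar(tokens)))
    stop("malformed sequence string: ", sQuote(text))
  rows <- lapply(seq_along(tokens), function(i)
    .parseResidueToken(tokens[i], i))
  res <- do.call(rbind, rows)
  gag <- .newGAG(res, label = label)
  v <- validObject(gag, test = TRUE)
  if (!isTRUE(v))
    stop("invalid sequence ", sQuote(text), ": ", v)
  gag
}

.parseResidueToken <- function(tok, pos) {
  row <- function(class, epimer = NA_character_, s2 = FALSE,
                  nsub = NA_character_, s3 = FALSE, s6 = FALSE)
    data.frame(class = class, epimer = epimer, s2 = s2, nsub = nsub,
               s3 = s3, s6 = s6, stringsAsFactors = FALSE)
  if (grepl("^(ΔU|dU)(2S)?$", tok)) {
    return(row("dU", s2 = grepl("2S$", tok)))
  }
  if (grepl("^(I|G|U)(2S)?$", tok)) {
    ep <- substr(tok, 1, 1)
    if (ep == "U") ep <- "X"
    return(row("U", epimer = ep, s2 = grepl("2S$", tok)))
  }
  m <- regmatches(tok, regexec("^A(NS|NAc|NH2)(3S)?(6S)?$", tok))[[1]]
  if (length(m)) {
    return(row("A", nsub = m[2], s3 = nzchar(m[3]), s6 = nzchar(m[4])))
  }
  if (grepl("^aM\\.ol(6S)?$", tok)) {
    return(row("aMol", s6 = grepl("6S$", tok)))
  }
  if (tok == "Rc") return(row("Rc"))
  stop(sprintf("unknown residue token %s at position %d", sQuote(tok), pos))
}

#' Format a GAG sequence in canonical nomenclature
#'
#' The canonical form joins residue tokens with an en dash and writes the
#' unknown uronic epimer as bare `U`; `parseGAG(formatGAG(x))` reproduces
#' `x` for every valid sequence.
#'
#' @param x a [GAGSequence-class].
#' @return character scalar.
#' @export
formatGAG <- function(x) {
  stopifnot(is(x, "GAGSequence"))
  r <- x@residues
  toks <- vapply(seq_len(nrow(r)), function(i) {
    ri <- r[i, ]
    switch(ri$class,
      dU   = paste0("ΔU", if (ri$s2) "2S"),
      U    = paste0(if (ri$epimer == "X") "U" else ri$epimer,
                    if (ri$s2) "2S"),
      A    = paste0("A", ri$nsub, if (ri$s3) "3S", if (ri$s6) "6S"),
      aMol = paste0("aM.ol", if (ri$s6) "6S"),
      Rc   = "Rc")
  }, character(1))
  paste(toks, collapse = "–")
}

#' Read sequences from a plain-text file
#'
#' One sequence per line; blank lines and `#` comments are skipped.  An
#' optional label may follow the sequence after whitespace.
#'
#' @param path file path.
#' @return list of [GAGSequence-class] objects.
#' @export
readSequenceFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    parts <- strsplit(l, "[[:space:]]+")[[1]]
    parseGAG(parts[1], label = if (length(parts) > 1)
      paste(parts[-1], collapse = " ") else "")
  })
}

#' Write sequences to a plain-text file
#'
#' @param seqs list of [GAGSequence-class] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeSequenceFile <- function(seqs, path) {
  txt <- vapply(seqs, function(s) {
    lab <- s@label
    paste0(formatGAG(s), if (nzchar(lab)) paste0(" ", lab))
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}
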