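## Independent oracles and random generators shared by the property tests.
## These deliberately avoid the package's own mass table and enumeration
## code so that agreement is informative.

## Monoisotopic atom masses (CODATA/AME values, independent of the package
## residue table).
.ATOM <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
           O = 15.9949146196, S = 31.97207100)

## Elemental-formula mass oracle for a sequence string: counts atoms
## residue by residue and from the substituent marks in the tokens.
oracleNeutralMass <- function(text) {
  toks <- strsplit(gsub("−", "-", text), "–|-")[[1]]
  atoms <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (tok in toks) {
    base <- if (grepl("^(ΔU|dU)", tok)) c(C = 6, H = 8, N = 0, O = 6, S = 0)
      else if (grepl("^(I|G|U)", tok))       c(C = 6, H = 10, N = 0, O = 7, S = 0)
      else if (grepl("^aM\\.ol", tok))       c(C = 6, H = 12, N = 0, O = 5, S = 0)
      else if (tok == "Rc")                  c(C = 6, H = 12, N = 0, O = 5, S = 0)
      else if (grepl("^A", tok))             c(C = 6, H = 13, N = 1, O = 5, S = 0)
      else stop("oracle: unknown token ", tok)
    atoms <- atoms + base
    ## each sulfation mark (O-sulfo or N-sulfo) is a net +SO3
    nSulf <- sum(gregexpr("2S|3S|6S|NS", tok)[[1]] > 0)
    if (grepl("NAc", tok)) nSulf <- 0 + sum(gregexpr("3S|6S", tok)[[1]] > 0)
    atoms <- atoms + nSulf * c(C = 0, H = 0, N = 0, O = 3, S = 1)
    if (grepl("NAc", tok)) atoms <- atoms + c(C = 2, H = 2, N = 0, O = 1, S = 0)
  }
  ## one condensation water per glycosidic bond
  atoms <- atoms - (length(toks) - 1L) * c(C = 0, H = 2, N = 0, O = 1, S = 0)
  sum(atoms * .ATOM[names(atoms)])
}

## Random valid sequence text: alternating uronic/glucosamine chain written
## NRE to RE, optionally opened by an unsaturated uronic residue, optionally
## closed by anhydromannitol, optionally carrying one internal
## ring-contracted residue.
randomSequenceText <- function(maxLen = 8, amolProb = 0.3, rcProb = 0.1) {
  n <- sample(2:maxLen, 1L)
  toks <- character(n)
  for (i in seq_len(n)) {
    if (i %% 2L == 1L) {
      if (i == 1L && stats::runif(1) < 0.4) {
        toks[i] <- sample(c("ΔU", "ΔU2S"), 1L)
      } else {
        ep <- sample(c("I", "G", "U"), 1L)
        s2 <- ep != "G" && stats::runif(1) < 0.5
        toks[i] <- paste0(ep, if (s2) "2S")
      }
    } else {
      nsub <- sample(c("NS", "NAc"), 1L, prob = c(0.8, 0.2))
      s3 <- nsub == "NS" && stats::runif(1) < 0.15
      s6 <- stats::runif(1) < 0.6
      toks[i] <- paste0("A", nsub, if (s3) "3S", if (s6) "6S")
    }
  }
  if (n %% 2L == 0L && stats::runif(1) < amolProb) {
    toks[n] <- sample(c("aM.ol", "aM.ol6S"), 1L)
  }
  internalA <- which(seq_len(n) %% 2L == 0L & seq_len(n) > 1L & seq_len(n) < n)
  if (length(internalA) && stats::runif(1) < rcProb) {
    toks[internalA[sample.int(length(internalA), 1L)]] <- "Rc"
  }
  paste(toks, collapse = "–")
}

## Brute-force sequence enumeration oracle for short chains: builds every
## token combination with expand.grid and filters by sulfate/acetyl totals
## and the 3-O-sulfation context rule, completely independently of the
## package's pruned depth-first search.
oracleEnumerationCount <- function(codeText) {
  code <- parseComposition(codeText)
  n <- code@nRes
  nre <- code@nreClass
  startUronic <- nre %in% c("dU", "U")
  cls <- rep(if (startUronic) c("U", "A") else c("A", "U"), length.out = n)
  if (nre == "dU") cls[1] <- "dU"
  if (code@hasAmol) {
    if (cls[n] != "A") return(0L)
    cls[n] <- "aMol"
  }
  optsFor <- function(cl) switch(cl,
    dU   = c("ΔU", "ΔU2S"),
    U    = c("I", "G", "I2S"),
    A    = c("ANS", "ANS6S", "ANS3S", "ANS3S6S", "ANAc", "ANAc6S"),
    aMol = c("aM.ol", "aM.ol6S"))
  grid <- do.call(expand.grid,
                  c(lapply(cls, optsFor), stringsAsFactors = FALSE))
  nSulfTok <- function(tok) {
    s <- sum(gregexpr("2S|3S|6S", tok)[[1]] > 0)
    s + as.integer(grepl("^ANS", tok))
  }
  ok <- apply(grid, 1L, function(row) {
    row <- as.character(row)
    if (sum(vapply(row, nSulfTok, integer(1))) != code@nSulf) return(FALSE)
    if (sum(grepl("NAc", row)) != code@nAc) return(FALSE)
    for (j in which(grepl("^ANS3S", row))) {
      if (j > 1L && row[j - 1L] != "G") return(FALSE)
    }
    TRUE
  })
  sum(ok)
}
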