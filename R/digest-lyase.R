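#' Heparin lyase cleavage patterns
#'
#' The pattern table driving [lyaseSites()].  Each row is one
#' donor/acceptor specificity: heparinase I cleaves N-sulfated glucosamine
#' (any 3-O/6-O sulfation) linked to 2-O-sulfated iduronic acid; heparinase
#' III cleaves N-acetylated glucosamine linked to unsulfated iduronic and
#' N-sulfated glucosamine linked to unsulfated glucuronic; heparinase II is
#' modelled maximally broad (any glucosamine to any uronic).  The table is
#' plain data and can be edited or replaced to tighten specificities.
#'
#' @return data.frame with columns `enzyme`, `donor_nsub` ("NS", "NAc" or
#'   "any"), `acceptor_epimer` ("I", "G" or "any") and `acceptor_s2`
#'   ("yes", "no" or "any").
#' @export
lyaseRules <- function() {
  data.frame(
    enzyme          = c("hepI", "hepIII", "hepIII", "hepII"),
    donor_nsub      = c("NS",   "NAc",    "NS",     "any"),
    acceptor_epimer = c("I",    "I",      "G",      "any"),
    acceptor_s2     = c("yes",  "no",     "no",     "any"),
    stringsAsFactors = FALSE)
}

## does one pattern row match a donor/acceptor residue pair?
## unknown epimer ("X") matches any pattern epimer.
.lyasePatternMatches <- function(pat, donor, acceptor) {
  if (donor$class != "A") return(FALSE)
  if (acceptor$class != "U") return(FALSE)
  if (pat$donor_nsub != "any" && !identical(donor$nsub, pat$donor_nsub))
    return(FALSE)
  if (pat$acceptor_epimer != "any" && acceptor$epimer != "X" &&
      acceptor$epimer != pat$acceptor_epimer) return(FALSE)
  if (pat$acceptor_s2 == "yes" && !acceptor$s2) return(FALSE)
  if (pat$acceptor_s2 == "no" && acceptor$s2) return(FALSE)
  TRUE
}

#' Find heparin lyase cleavage sites
#'
#' Scans every glucosamine-to-uronic bond for a match against the enzyme
#' pattern table, then applies two blocking rules: a bond onto glucuronic
#' acid is protected when the residue two positions downstream is a
#' 3-O-sulfated glucosamine (the antithrombin-binding-region linkage no
#' lyase can cleave), and any bond is protected when that downstream
#' residue is the unnatural anhydromannitol reducing end.
#'
#' @param x a [GAGSequence-class] or sequence string.
#' @param enzymes subset of `c("hepI", "hepII", "hepIII")`.
#' @param rules pattern table, by default [lyaseRules()].
#' @return data.frame with one row per cleavable bond: `bond` (index i of
#'   the bond between residues i and i+1), `enzymes` (comma-collapsed
#'   matching enzymes), `donor`, `acceptor`.
#' @examples
#' lyaseSites("I2S–ANS6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S")
#' @export
lyaseSites <- function(x, enzymes = c("hepI", "hepII", "hepIII"),
                       rules = lyaseRules()) {
  if (is.character(x)) x <- parseGAG(x)
  stopifnot(is(x, "GAGSequence"))
  r <- x@residues
  n <- nrow(r)
  rules <- rules[rules$enzyme %in% enzymes, , drop = FALSE]
  out <- list()
  if (n < 2L) return(.emptySites())
  for (i in seq_len(n - 1L)) {
    donor <- as.list(r[i, ])
    acceptor <- as.list(r[i + 1L, ])
    if (donor$class != "A" || acceptor$class != "U") next
    hit <- vapply(seq_len(nrow(rules)), function(j)
      .lyasePatternMatches(as.list(rules[j, ]), donor, acceptor),
      logical(1))
    if (!any(hit)) next
    ## blocking rules
    nxt <- if (i + 2L <= n) as.list(r[i + 2L, ]) else NULL
    if (!is.null(nxt)) {
      if (nxt$class == "aMol") next                              # unnatural RE
      if (acceptor$epimer %in% c("G", "X") && !acceptor$s2 &&
          nxt$class == "A" && nxt$s3) next                       # ATBR A-G
    }
    out[[length(out) + 1L]] <- data.frame(
      bond = i, enzymes = paste(unique(rules$enzyme[hit]), collapse = ","),
      donor = formatGAG(.newGAG(r[i, , drop = FALSE])),
      acceptor = formatGAG(.newGAG(r[i + 1L, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptySites())
  do.call(rbind, out)
}

.emptySites <- function() {
  data.frame(bond = integer(), enzymes = character(), donor = character(),
             acceptor = character(), stringsAsFactors = FALSE)
}

## eliminative cleavage at bond i: the left product keeps residues 1..i with
## the glucosamine as free reducing end; the right product starts with the
## former acceptor converted into a 4,5-unsaturated uronic acid (loss of
## H2O, 2-O-sulfation retained, epimer information erased).
.cleaveEliminative <- function(seq, i) {
  r <- seq@residues
  left <- .newGAG(r[seq_len(i), , drop = FALSE], label = seq@label)
  right <- r[(i + 1L):nrow(r), , drop = FALSE]
  right$class[1] <- "dU"
  right$epimer[1] <- NA_character_
  list(left = left, right = .newGAG(right, label = seq@label))
}

#' Exhaustive in-silico heparin lyase digestion
#'
#' Iterates eliminative cleavage at every matching, unblocked site to the
#' fixed point.  The chemistry conserves mass exactly: the sum of product
#' neutral masses equals the parent mass (the right-hand product's new
#' unsaturated uronic terminus accounts for the water never released).
#' The fixed point is independent of the order in which sites are cut;
#' `order = "random"` exists to exercise that confluence property.
#'
#' @param pool a [GAGSequence-class], sequence string, or list of either.
#' @param enzymes subset of `c("hepI", "hepII", "hepIII")`.
#' @param rules pattern table, by default [lyaseRules()].
#' @param order `"leftmost"` (default) or `"random"` site selection.
#' @return a [DigestResult-class].
#' @examples
#' res <- digestLyase("G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S")
#' productTable(res)
#' @export
digestLyase <- function(pool, enzymes = c("hepI", "hepII", "hepIII"),
                        rules = lyaseRules(), order = "leftmost") {
  pool <- .asPool(pool)
  prods <- list()
  prov <- list()
  digestOne <- function(seq, parentTxt) {
    sites <- lyaseSites(seq, enzymes = enzymes, rules = rules)
    if (!nrow(sites)) {
      prods[[length(prods) + 1L]] <<- seq
      return(invisible())
    }
    pick <- if (identical(order, "random") && nrow(sites) > 1L)
      sample(seq_len(nrow(sites)), 1L) else 1L
    bond <- sites$bond[pick]
    halves <- .cleaveEliminative(seq, bond)
    seqTxt <- formatGAG(seq)
    for (side in halves) {
      prov[[length(prov) + 1L]] <<- data.frame(
        product = formatGAG(side), parent = seqTxt, bond = bond,
        enzyme = sites$enzymes[pick], rule = "elimination",
        stringsAsFactors = FALSE)
      digestOne(side, seqTxt)
    }
    invisible()
  }
  for (s in pool) digestOne(s, formatGAG(s))
  new("DigestResult", products = prods, partialSurvivors = list(),
      provenance = if (length(prov)) do.call(rbind, prov) else
        new("DigestResult")@provenance)
}

.asPool <- function(pool) {
  if (is(pool, "GAGSequence")) return(list(pool))
  if (is.character(pool)) return(lapply(pool, parseGAG))
  stopifnot(is.list(pool))
  lapply(pool, function(s) if (is.character(s)) parseGAG(s) else s)
}
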