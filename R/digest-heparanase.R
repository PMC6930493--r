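#' Heparanase susceptibility rules
#'
#' Heparanase hydrolyses the bond between an unsulfated glucuronic acid and
#' the following glucosamine, but its action is gated by the sulfation
#' pattern around the cleavage site.  The ordered rule table below is
#' evaluated top to bottom at each candidate site; the first matching row
#' fixes the verdict:
#'
#' * `acceptor_not_glcn` — the downstream residue is anhydromannitol or a
#'   ring-contracted residue: resist (never observed cleaved).
#' * `acceptor_nac` — the downstream glucosamine is N-acetylated: resist
#'   (no such substrate has been observed; flagged unvalidated).
#' * `acceptor_no_6S` — the downstream glucosamine lacks 6-O-sulfation:
#'   resist.
#' * `prev_glcn_no_6S` — the glucosamine preceding the glucuronic acid
#'   lacks 6-O-sulfation: resist.
#' * `context_2S` — the uronic residue two positions upstream is
#'   2-O-sulfated (a highly sulfated environment): partial.
#' * `default` — cleave.
#'
#' The table is plain data; rows can be removed, reordered or edited to
#' explore alternative specificity models.
#'
#' @return data.frame with columns `rule`, `check`, `verdict`, `note`.
#' @export
heparanaseRules <- function() {
  data.frame(
    rule = c("R0a", "R0b", "R1", "R2", "R3", "R4"),
    check = c("acceptor_not_glcn", "acceptor_nac", "acceptor_no_6S",
              "prev_glcn_no_6S", "context_2S", "default"),
    verdict = c("resist", "resist", "resist", "resist", "partial", "cleave"),
    note = c("unnatural residue downstream",
             "N-acetylated acceptor (unvalidated default)",
             "no 6-O-sulfate on the acceptor glucosamine",
             "no 6-O-sulfate on the glucosamine upstream of G",
             "2-O-sulfated uronic two residues upstream",
             ""),
    stringsAsFactors = FALSE)
}

## candidate sites: bonds from an unsulfated glucuronic acid (epimer G, or
## unknown "X", which inference treats as compatible with either epimer)
## onto the following amine-type residue.
.heparanaseSiteIdx <- function(r) {
  n <- nrow(r)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  i[r$class[i] == "U" & !r$s2[i] & r$epimer[i] %in% c("G", "X") &
      .isAmineType(r$class[i + 1L])]
}

.heparanaseCheck <- function(check, r, i) {
  acc <- i + 1L
  switch(check,
    acceptor_not_glcn = r$class[acc] %in% c("aMol", "Rc"),
    acceptor_nac      = identical(r$nsub[acc], "NAc"),
    acceptor_no_6S    = !r$s6[acc],
    prev_glcn_no_6S   = i > 1L && r$class[i - 1L] == "A" && !r$s6[i - 1L],
    context_2S        = i > 2L && .isUronicType(r$class[i - 2L]) &&
                          r$s2[i - 2L],
    default           = TRUE,
    stop("unknown heparanase rule check: ", check))
}

#' Heparanase verdict for one cleavage site
#'
#' @param x a [GAGSequence-class] or sequence string.
#' @param bond index i of the glucuronic-to-glucosamine bond (between
#'   residues i and i+1).
#' @param rules ordered rule table, by default [heparanaseRules()].
#' @return list with elements `verdict` ("cleave", "partial" or "resist")
#'   and `rule` (the id of the rule that fired).
#' @examples
#' heparanaseVerdict("ΔU2S–ANS6S–G–ANS3S6S", 3)$verdict  # "partial"
#' @export
heparanaseVerdict <- function(x, bond, rules = heparanaseRules()) {
  if (is.character(x)) x <- parseGAG(x)
  r <- x@residues
  if (!(bond %in% .heparanaseSiteIdx(r)))
    stop("bond ", bond, " is not a glucuronic-to-glucosamine site")
  for (j in seq_len(nrow(rules))) {
    if (.heparanaseCheck(rules$check[j], r, bond))
      return(list(verdict = rules$verdict[j], rule = rules$rule[j]))
  }
  stop("rule table has no matching row (missing default?)")
}

#' All heparanase sites of a sequence, with verdicts
#'
#' @inheritParams heparanaseVerdict
#' @return data.frame with columns `bond`, `verdict`, `rule`.
#' @export
heparanaseSites <- function(x, rules = heparanaseRules()) {
  if (is.character(x)) x <- parseGAG(x)
  idx <- .heparanaseSiteIdx(x@residues)
  if (!length(idx))
    return(data.frame(bond = integer(), verdict = character(),
                      rule = character(), stringsAsFactors = FALSE))
  v <- lapply(idx, function(i) heparanaseVerdict(x, i, rules))
  data.frame(bond = idx,
             verdict = vapply(v, `[[`, character(1), "verdict"),
             rule = vapply(v, `[[`, character(1), "rule"),
             stringsAsFactors = FALSE)
}

## hydrolytic cleavage: both halves keep their residues unchanged; the left
## product ends in a free glucuronic acid, the right starts with the
## glucosamine.  Each cut adds one water to the summed product mass.
.cleaveHydrolytic <- function(seq, i) {
  r <- seq@residues
  list(left = .newGAG(r[seq_len(i), , drop = FALSE], label = seq@label),
       right = .newGAG(r[(i + 1L):nrow(r), , drop = FALSE],
                       label = seq@label))
}

#' In-silico heparanase digestion
#'
#' Applies the susceptibility rules at every glucuronic-to-glucosamine bond
#' and iterates hydrolysis to the fixed point.  Fully susceptible
#' ("cleave") sites are cut exhaustively; a substrate whose only applicable
#' sites are "partial" contributes both its cleavage products and itself
#' (recorded among the partial survivors); "resist" sites are never cut.
#'
#' @param pool a [GAGSequence-class], sequence string, or list of either.
#' @param rules ordered rule table, by default [heparanaseRules()].
#' @return a [DigestResult-class].
#' @examples
#' productTable(digestHeparanase("G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S"))
#' @export
digestHeparanase <- function(pool, rules = heparanaseRules()) {
  pool <- .asPool(pool)
  prods <- list()
  partial <- list()
  prov <- list()
  record <- function(side, seqTxt, bond, rule) {
    prov[[length(prov) + 1L]] <<- data.frame(
      product = formatGAG(side), parent = seqTxt, bond = bond,
      enzyme = "heparanase", rule = rule, stringsAsFactors = FALSE)
  }
  digestOne <- function(seq) {
    sites <- heparanaseSites(seq, rules)
    cleaves <- sites[sites$verdict == "cleave", , drop = FALSE]
    partials <- sites[sites$verdict == "partial", , drop = FALSE]
    seqTxt <- formatGAG(seq)
    if (nrow(cleaves)) {
      halves <- .cleaveHydrolytic(seq, cleaves$bond[1])
      for (side in halves) {
        record(side, seqTxt, cleaves$bond[1], cleaves$rule[1])
        digestOne(side)
      }
    } else if (nrow(partials)) {
      partial[[length(partial) + 1L]] <<- seq
      for (j in seq_len(nrow(partials))) {
        halves <- .cleaveHydrolytic(seq, partials$bond[j])
        for (side in halves) {
          record(side, seqTxt, partials$bond[j], partials$rule[j])
          digestOne(side)
        }
      }
    } else {
      prods[[length(prods) + 1L]] <<- seq
    }
    invisible()
  }
  for (s in pool) digestOne(s)
  new("DigestResult", products = prods, partialSurvivors = partial,
      provenance = if (length(prov)) do.call(rbind, prov) else
        new("DigestResult")@provenance)
}

#' Sequential lyase-then-heparanase digestion
#'
#' Composes [digestLyase()] and [digestHeparanase()]: the heparanase stage
#' acts on the lyase fixed-point products, mirroring the bench workflow of
#' adding heparanase to an exhaustive heparinase digest.
#'
#' @inheritParams digestLyase
#' @param thenHeparanase run the heparanase stage (default TRUE).
#' @param hepRules heparanase rule table.
#' @return a [DigestResult-class] with chained provenance.
#' @export
digestCombined <- function(pool, enzymes = c("hepI", "hepII", "hepIII"),
                           thenHeparanase = TRUE, rules = lyaseRules(),
                           hepRules = heparanaseRules()) {
  stage1 <- digestLyase(pool, enzymes = enzymes, rules = rules)
  if (!thenHeparanase) return(stage1)
  stage2 <- digestHeparanase(products(stage1), rules = hepRules)
  new("DigestResult", products = products(stage2),
      partialSurvivors = partialSurvivors(stage2),
      provenance = rbind(provenance(stage1), provenance(stage2)))
}

#' Classify the fate of one species under an enzyme treatment
#'
#' Predicts whether a species would resist the treatment, disappear
#' (at least one fully susceptible site) or be partially digested (only
#' partially susceptible sites), without running the full digestion.
#'
#' @param x a [GAGSequence-class] or sequence string.
#' @param enzymes any subset of `c("hepI", "hepII", "hepIII",
#'   "heparanase")`.
#' @param rules lyase pattern table.
#' @param hepRules heparanase rule table.
#' @return one of `"resistant"`, `"disappears"`, `"partial"`.
#' @examples
#' digestFate("ΔU–ANAc6S–G–ANS3S", "heparanase")  # "resistant"
#' @export
digestFate <- function(x, enzymes, rules = lyaseRules(),
                       hepRules = heparanaseRules()) {
  if (is.character(x)) x <- parseGAG(x)
  lyases <- setdiff(enzymes, "heparanase")
  if (length(lyases) && nrow(lyaseSites(x, enzymes = lyases, rules = rules)))
    return("disappears")
  if ("heparanase" %in% enzymes) {
    v <- heparanaseSites(x, hepRules)$verdict
    if (any(v == "cleave")) return("disappears")
    if (any(v == "partial")) return("partial")
  }
  "resistant"
}
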