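#' @import methods
NULL

## Residues are stored as a plain data.frame with one row per monosaccharide,
## nonreducing end (NRE) first:
##   class  : "dU" (4,5-unsaturated uronic), "U" (saturated uronic),
##            "A" (glucosamine), "aMol" (2,5-anhydromannitol), "Rc"
##            (ring-contracted residue)
##   epimer : "I", "G" or "X" (unknown); NA for non-uronic classes and dU
##   s2     : 2-O-sulfate (uronic classes only)
##   nsub   : "NS", "NAc" or "NH2" (glucosamine only), NA otherwise
##   s3     : 3-O-sulfate (glucosamine only)
##   s6     : 6-O-sulfate (glucosamine and aMol)

.residueColumns <- c("class", "epimer", "s2", "nsub", "s3", "s6")

.emptyResidues <- function() {
  data.frame(class = character(), epimer = character(), s2 = logical(),
             nsub = character(), s3 = logical(), s6 = logical(),
             stringsAsFactors = FALSE)
}

.isUronicType <- function(cls) cls %in% c("dU", "U")
.isAmineType  <- function(cls) cls %in% c("A", "aMol", "Rc")

#' GAGSequence: an ordered glycosaminoglycan oligosaccharide
#'
#' An ordered run of monosaccharide residues from the nonreducing end (NRE,
#' position 1) to the reducing end (RE).  Classes strictly alternate between
#' uronic-type (4,5-unsaturated or saturated uronic acid) and amine-type
#' (glucosamine, 2,5-anhydromannitol, ring-contracted residue); an unsaturated
#' uronic acid can only open the chain and anhydromannitol can only close it.
#'
#' @slot residues data.frame with columns `class`, `epimer`, `s2`, `nsub`,
#'   `s3`, `s6`, one row per residue (see [parseGAG()] for the grammar).
#' @slot label optional free-text annotation (e.g. an isomer label) carried
#'   through digestion and inference but never interpreted.
#' @seealso [parseGAG()], [formatGAG()], [compositionOf()], [neutralMass()]
#' @export
setClass("GAGSequence",
         representation(residues = "data.frame", label = "character"),
         prototype(residues = .emptyResidues(), label = ""))

setValidity("GAGSequence", function(object) {
  r <- object@residues
  if (!all(.residueColumns %in% names(r)))
    return("residues must have columns class, epimer, s2, nsub, s3, s6")
  n <- nrow(r)
  if (n < 1L) return("a GAGSequence must contain at least one residue")
  if (!all(r$class %in% c("dU", "U", "A", "aMol", "Rc")))
    return("unknown residue class")
  ## strict alternation of uronic-type and amine-type residues
  types <- ifelse(.isUronicType(r$class), "u", "a")
  if (n > 1L && any(types[-1L] == types[-n]))
    return("uronic- and amine-type residues must alternate")
  if (any(r$class == "dU" & seq_len(n) != 1L))
    return("a 4,5-unsaturated uronic acid may only occupy position 1")
  if (any(r$class == "aMol" & seq_len(n) != n))
    return("anhydromannitol may only occupy the reducing-end position")
  amine <- r$class == "A"
  if (any(!is.na(r$nsub) & !amine))
    return("only glucosamine carries an N-substituent")
  if (any(amine & is.na(r$nsub)))
    return("glucosamine requires an N-substituent (NS, NAc or NH2)")
  if (any(r$s2 & !.isUronicType(r$class)))
    return("2-O-sulfation is restricted to uronic residues")
  if (any(r$s3 & !amine))
    return("3-O-sulfation is restricted to glucosamine")
  if (any(r$s6 & !(amine | r$class == "aMol")))
    return("6-O-sulfation is restricted to glucosamine and anhydromannitol")
  if (any(.isUronicType(r$class) & is.na(r$epimer) & r$class == "U"))
    return("saturated uronic residues need an epimer (I, G or X)")
  TRUE
})

#' CompositionCode: the "dU/U/A n,s,a" species summary
#'
#' The compact nomenclature summarising an oligosaccharide species by its
#' NRE residue class, residue count, sulfate count and N-acetyl count, plus
#' end-group flags for 2,5-anhydromannitol and ring-contracted residues
#' (printed, e.g., "ΔU4,5,0", "U8,11,0–aM.ol").
#'
#' @slot nreClass "dU", "U" or "A".
#' @slot nRes,nSulf,nAc integer counts (residues, sulfates, N-acetyls).
#' @slot hasAmol,hasRc logical end-group/side-product flags.
#' @slot label opaque isomer label such as "(2)" (never interpreted).
#' @seealso [parseComposition()], [formatComposition()], [compositionOf()]
#' @export
setClass("CompositionCode",
         representation(nreClass = "character", nRes = "integer",
                        nSulf = "integer", nAc = "integer",
                        hasAmol = "logical", hasRc = "logical",
                        label = "character"),
         prototype(nreClass = "U", nRes = 1L, nSulf = 0L, nAc = 0L,
                   hasAmol = FALSE, hasRc = FALSE, label = ""))

setValidity("CompositionCode", function(object) {
  if (!object@nreClass %in% c("dU", "U", "A"))
    return("nreClass must be one of dU, U, A")
  if (object@nRes < 1L) return("nRes must be >= 1")
  if (object@nSulf < 0L || object@nAc < 0L)
    return("sulfate and acetyl counts must be non-negative")
  TRUE
})

#' DigestResult: products of an in-silico enzymatic digestion
#'
#' @slot products list of [GAGSequence-class] objects present at the
#'   digestion fixed point (a multiset; duplicates are meaningful).
#' @slot partialSurvivors list of [GAGSequence-class] substrates that carry
#'   only partially susceptible cleavage sites and therefore persist alongside
#'   their cleavage products.
#' @slot provenance data.frame linking each product to its parent, bond and
#'   enzyme/rule (columns `product`, `parent`, `bond`, `enzyme`, `rule`).
#' @seealso [digestLyase()], [digestHeparanase()], [digestCombined()]
#' @export
setClass("DigestResult",
         representation(products = "list", partialSurvivors = "list",
                        provenance = "data.frame"),
         prototype(products = list(), partialSurvivors = list(),
                   provenance = data.frame(product = character(),
                                           parent = character(),
                                           bond = integer(),
                                           enzyme = character(),
                                           rule = character(),
                                           stringsAsFactors = FALSE)))

.newGAG <- function(residues, label = "") {
  rownames(residues) <- NULL
  new("GAGSequence", residues = residues, label = label)
}

#' @describeIn GAGSequence number of residues
#' @param x a `GAGSequence`
#' @export
setMethod("length", "GAGSequence", function(x) nrow(x@residues))

#' Residue table of a GAG sequence
#'
#' @param x a [GAGSequence-class]
#' @return the underlying residue `data.frame` (NRE first).
#' @export
residues <- function(x) {
  stopifnot(is(x, "GAGSequence"))
  x@residues
}

setMethod("show", "GAGSequence", function(object) {
  cat(sprintf("GAGSequence (%d residues): %s\n", length(object),
              formatGAG(object)))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "CompositionCode", function(object) {
  cat("CompositionCode:", formatComposition(object), "\n")
})

setMethod("show", "DigestResult", function(object) {
  cat(sprintf("DigestResult: %d product(s), %d partial survivor(s)\n",
              length(object@products), length(object@partialSurvivors)))
  tab <- productTable(object)
  if (nrow(tab)) print(tab)
})

#' Products of a digestion
#' @param x a [DigestResult-class]
#' @return list of [GAGSequence-class] products at the fixed point.
#' @export
products <- function(x) {
  stopifnot(is(x, "DigestResult"))
  x@products
}

#' Partially resistant substrates surviving a digestion
#' @param x a [DigestResult-class]
#' @return list of [GAGSequence-class] partial survivors.
#' @export
partialSurvivors <- function(x) {
  stopifnot(is(x, "DigestResult"))
  x@partialSurvivors
}

#' Provenance table of a digestion
#' @param x a [DigestResult-class]
#' @return data.frame mapping products to (parent, bond, enzyme, rule).
#' @export
provenance <- function(x) {
  stopifnot(is(x, "DigestResult"))
  x@provenance
}

#' Summarise digestion products by composition
#'
#' @param x a [DigestResult-class]
#' @param includeSurvivors also count partial survivors (default FALSE).
#' @return data.frame with columns `sequence`, `composition`, `count`,
#'   `neutral_mass`, `survivor`.
#' @export
productTable <- function(x, includeSurvivors = FALSE) {
  stopifnot(is(x, "DigestResult"))
  seqs <- x@products
  surv <- rep(FALSE, length(seqs))
  if (includeSurvivors) {
    seqs <- c(seqs, x@partialSurvivors)
    surv <- c(surv, rep(TRUE, length(x@partialSurvivors)))
  }
  if (!length(seqs))
    return(data.frame(sequence = character(), composition = character(),
                      count = integer(), neutral_mass = numeric(),
                      survivor = logical(), stringsAsFactors = FALSE))
  txt <- vapply(seqs, formatGAG, character(1))
  comp <- vapply(seqs, function(s) formatComposition(compositionOf(s)),
                 character(1))
  mass <- vapply(seqs, neutralMass, numeric(1))
  key <- paste(txt, surv)
  idx <- !duplicated(key)
  data.frame(sequence = txt[idx], composition = comp[idx],
             count = as.integer(table(key)[key[idx]]),
             neutral_mass = round(mass[idx], 5), survivor = surv[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}
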