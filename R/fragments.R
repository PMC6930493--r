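## Fragment enumeration for CID MS/MS in negative mode, Domon-Costello
## nomenclature: glycosidic B/C (NRE-retaining) and Y/Z (RE-retaining)
## ions, 0,2 cross-ring cleavage of glucosamine rings, and internal ions
## from one glycosidic plus one cross-ring cut.  Sulfate retention is
## combinatorial (CID readily strips SO3), but capped by the sulfates
## actually present on the atoms a fragment covers.

## does a residue retain a free, never-sulfated ring hydroxyl (O3/O6)?
## Extra water loss beyond the ion-type-defining one is only allowed for
## fragments covering at least one such hydroxyl.
.freeHydroxyl <- function(r) {
  ifelse(r$class == "A", !(r$s3 & r$s6), TRUE)
}

.fragRow <- function(kind, index, neutralFull, sulfMax, hasUronic,
                     hasFreeOH, nacCount = 0L) {
  data.frame(kind = kind, index = index, neutral_full = neutralFull,
             sulf_max = sulfMax, has_uronic = hasUronic,
             has_free_oh = hasFreeOH, stringsAsFactors = FALSE)
}

#' Glycosidic B/C/Y/Z fragment skeletons
#'
#' One row per fragment type and bond, before sulfate-retention and
#' neutral-loss expansion: `neutral_full` is the neutral mass with all
#' covered sulfates retained, `sulf_max` the number of sulfates the covered
#' residues carry.  B and Y are complementary (`B_i + Y_(n-i) = M` exactly);
#' C = B + H2O and Z = Y − H2O.
#'
#' @param x a [GAGSequence-class] or sequence string.
#' @return data.frame of fragment skeletons.
#' @export
glycosidicFragments <- function(x) {
  if (is.character(x)) x <- parseGAG(x)
  r <- x@residues
  n <- nrow(r)
  if (n < 2L) return(NULL)
  M <- neutralMass(x)
  out <- list()
  for (i in seq_len(n - 1L)) {
    suff <- r[(i + 1L):n, , drop = FALSE]
    pref <- r[seq_len(i), , drop = FALSE]
    yNeutral <- sum(.residueMassVec(suff)) - (nrow(suff) - 1L) * .MASS$H2O
    bNeutral <- M - yNeutral
    sSuf <- sum(.residueSulfVec(suff))
    sPre <- sum(.residueSulfVec(pref))
    ohSuf <- any(.freeHydroxyl(suff))
    ohPre <- any(.freeHydroxyl(pref))
    urSuf <- any(.isUronicType(suff$class))
    urPre <- any(.isUronicType(pref$class))
    out[[length(out) + 1L]] <- rbind(
      .fragRow("B", i, bNeutral, sPre, urPre, ohPre),
      .fragRow("C", i, bNeutral + .MASS$H2O, sPre, urPre, ohPre),
      .fragRow("Y", n - i, yNeutral, sSuf, urSuf, ohSuf),
      .fragRow("Z", n - i, yNeutral - .MASS$H2O, sSuf, urSuf, ohSuf))
  }
  do.call(rbind, out)
}

#' Cross-ring 0,2 fragment skeletons
#'
#' A 0,2 cleavage of a glucosamine ring splits it into a C1-C2 unit
#' (anomeric oxygen and the N-substituent; base composition C2H5NO,
#' 59.03711 Da) and a C3-C6 unit (O3, ring oxygen, O6; C4H8O4,
#' 120.04226 Da); the two sum exactly to the free residue mass.  Emitted
#' pieces per glucosamine: the RE-retaining 0,2X (C1-C2 unit plus any
#' downstream residues), the NRE-retaining 0,2A (upstream residues plus the
#' C3-C6 unit), and internal bare units from one additional glycosidic cut.
#' The bare C3-C6 internal ion is only enumerated when that unit carries
#' both a 3-O- and a 6-O-sulfate, reflecting the observed propensity of
#' 0,2A-type ions for more sulfated glucosamines; this is what makes the
#' ion at m/z 198.99 diagnostic between the two trisulfated disaccharide
#' isomers.
#'
#' @param x a [GAGSequence-class] or sequence string.
#' @return data.frame of fragment skeletons (may have zero rows).
#' @export
crossringFragments <- function(x) {
  if (is.character(x)) x <- parseGAG(x)
  r <- x@residues
  n <- nrow(r)
  out <- list()
  for (pos in which(r$class == "A")) {
    nac <- identical(r$nsub[pos], "NAc")
    c12max <- as.integer(identical(r$nsub[pos], "NS"))
    c36max <- as.integer(r$s3[pos]) + as.integer(r$s6[pos])
    c12base <- .XRING$C1C2 + if (nac) .MASS$NAc else 0
    c36base <- .XRING$C3C6
    ## RE-retaining 0,2X: C1-C2 unit (+ downstream residues if internal)
    if (pos == n) {
      out[[length(out) + 1L]] <- .fragRow(
        "02X", pos, c12base + c12max * .MASS$SO3, c12max, FALSE, FALSE)
    } else {
      suff <- r[(pos + 1L):n, , drop = FALSE]
      sNeutral <- sum(.residueMassVec(suff)) - (nrow(suff) - 1L) * .MASS$H2O
      out[[length(out) + 1L]] <- .fragRow(
        "02X", pos,
        c12base + c12max * .MASS$SO3 + sNeutral - .MASS$H2O,
        c12max + sum(.residueSulfVec(suff)),
        any(.isUronicType(suff$class)), any(.freeHydroxyl(suff)))
      ## internal bare C1-C2 unit (extra glycosidic cut at bond pos)
      out[[length(out) + 1L]] <- .fragRow(
        "int02X", pos, c12base + c12max * .MASS$SO3, c12max, FALSE, FALSE)
    }
    ## NRE-retaining 0,2A: upstream residues + C3-C6 unit
    if (pos > 1L) {
      pref <- r[seq_len(pos - 1L), , drop = FALSE]
      pNeutral <- sum(.residueMassVec(pref)) - (nrow(pref) - 1L) * .MASS$H2O
      out[[length(out) + 1L]] <- .fragRow(
        "02A", pos,
        pNeutral + c36base + c36max * .MASS$SO3 - .MASS$H2O,
        c36max + sum(.residueSulfVec(pref)),
        any(.isUronicType(pref$class)), any(.freeHydroxyl(pref)))
    }
    ## internal bare C3-C6 unit, gated by the sulfation-propensity rule
    if (c36max >= 2L) {
      out[[length(out) + 1L]] <- .fragRow(
        "int02A", pos, c36base + c36max * .MASS$SO3, c36max, FALSE, FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Enumerate CID fragment-ion candidates
#'
#' Expands the glycosidic and cross-ring skeletons over all sulfate
#' retention counts (0 up to the sulfates covered), neutral losses (at most
#' one CO2, only for fragments covering a uronic carboxyl; at most one
#' extra H2O, only for fragments retaining a free ring hydroxyl) and charge
#' states 1 to `min(maxCharge, retained + 1)`.
#'
#' @param x a [GAGSequence-class] or sequence string.
#' @param maxCharge maximum fragment charge (default 2).
#' @param tol unused here; see [annotateMSMS()].
#' @return data.frame with columns `kind`, `index`, `retained`, `co2`,
#'   `h2o`, `z`, `neutral`, `mz`, `label`.
#' @examples
#' head(fragmentCandidates("I2S–ANS6S"))
#' @export
fragmentCandidates <- function(x, maxCharge = 2L) {
  if (is.character(x)) x <- parseGAG(x)
  skel <- rbind(glycosidicFragments(x), crossringFragments(x))
  if (is.null(skel) || !nrow(skel)) {
    return(data.frame(kind = character(), index = integer(),
                      retained = integer(), co2 = integer(), h2o = integer(),
                      z = integer(), neutral = numeric(), mz = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (j in seq_len(nrow(skel))) {
    sk <- skel[j, ]
    for (ret in 0:sk$sulf_max) {
      base <- sk$neutral_full - (sk$sulf_max - ret) * .MASS$SO3
      for (co2 in 0:(if (sk$has_uronic) 1L else 0L)) {
        for (h2o in 0:(if (sk$has_free_oh) 1L else 0L)) {
          neutral <- base - co2 * .MASS$CO2 - h2o * .MASS$H2O
          if (neutral <= 0) next
          for (z in seq_len(min(maxCharge, ret + 1L))) {
            rows[[length(rows) + 1L]] <- data.frame(
              kind = sk$kind, index = sk$index, retained = ret,
              co2 = co2, h2o = h2o, z = z, neutral = neutral,
              mz = (neutral - z * .MASS$proton) / z,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  kindLab <- c(B = "B", C = "C", Y = "Y", Z = "Z", `02X` = "0,2X",
               `02A` = "0,2A", int02X = "0,2X*", int02A = "0,2A*")
  stem <- ifelse(out$kind %in% c("B", "C", "Y", "Z"),
                 paste0(kindLab[out$kind], out$index),
                 unname(kindLab[out$kind]))
  out$label <- paste0(stem,
    ifelse(out$retained > 0, sprintf("(+%dSO3)", out$retained), ""),
    ifelse(out$co2 > 0, "-CO2", ""),
    ifelse(out$h2o > 0, "-H2O", ""))
  out
}
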