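#' Neutral monoisotopic mass of a sequence or composition
#'
#' The neutral mass is the sum of free-residue monoisotopic masses minus one
#' water per glycosidic bond, plus 79.95682 Da per sulfate and 42.01057 Da
#' per N-acetyl group.  A composition code determines the mass completely,
#' because the residue-class layout follows from the NRE class, residue
#' count and end-group flags; a sequence and its composition therefore
#' always agree.
#'
#' @param x a [GAGSequence-class], [CompositionCode-class], or a string
#'   parsed as a sequence (containing "–"/"-") or composition code.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' neutralMass("ΔU2S–ANS6S")          # 576.97136
#' neutralMass(parseComposition("U8,11,0–aM.ol"))
#' @export
setGeneric("neutralMass", function(x) standardGeneric("neutralMass"))

#' @rdname neutralMass
#' @export
setMethod("neutralMass", "GAGSequence", function(x) {
  r <- x@residues
  sum(.residueMassVec(r)) - (nrow(r) - 1L) * .MASS$H2O
})

#' @rdname neutralMass
#' @export
setMethod("neutralMass", "CompositionCode", function(x) {
  cls <- .codeLayout(x)
  if (is.null(cls))
    stop("infeasible composition: ", formatComposition(x))
  if (x@hasRc) {
    iA <- which(cls == "A")
    iA <- iA[iA > 1L & iA < length(cls)]
    if (!length(iA)) stop("no internal position for the Rc residue in ",
                          formatComposition(x))
    cls[iA[1]] <- "Rc"
  }
  sum(unlist(.MASS[cls], use.names = FALSE)) -
    (x@nRes - 1L) * .MASS$H2O + x@nSulf * .MASS$SO3 + x@nAc * .MASS$NAc
})

#' @rdname neutralMass
#' @export
setMethod("neutralMass", "character", function(x) {
  if (grepl("–|-|−", x)) {
    ## composition codes may also contain a dash (e.g. "U8,11,0–aM.ol")
    comp <- tryCatch(parseComposition(x), error = function(e) NULL)
    if (!is.null(comp)) return(neutralMass(comp))
    return(neutralMass(parseGAG(x)))
  }
  comp <- tryCatch(parseComposition(x), error = function(e) NULL)
  if (!is.null(comp)) return(neutralMass(comp))
  neutralMass(parseGAG(x))
})

#' Ion form for negative-mode ion-pair electrospray
#'
#' Heparin oligosaccharides are observed as `[M − hH + kDBA]h−` ions:
#' `h` protons removed (the charge) and `k` neutral dibutylamine molecules
#' attached.
#'
#' @param h protons removed (charge), integer >= 1.
#' @param k dibutylamine adducts, integer >= 0.
#' @return a named list with elements `h` and `k`.
#' @export
ionForm <- function(h, k = 0L) {
  h <- as.integer(h); k <- as.integer(k)
  stopifnot(h >= 1L, k >= 0L)
  list(h = h, k = k)
}

#' m/z of a deprotonated, DBA-adducted ion
#'
#' `m/z = (M − h·1.007276 + k·129.15175) / h` for the `[M − hH + kDBA]h−`
#' ion form.
#'
#' @param mass neutral monoisotopic mass (Da), or an object accepted by
#'   [neutralMass()].
#' @param h protons removed (the charge); alternatively pass `ion`.
#' @param k dibutylamine adduct count.
#' @param ion an [ionForm()] list (overrides `h`/`k`).
#' @return m/z value (negative polarity magnitude).
#' @examples
#' ionMz(neutralMass("U8,11,0–aM.ol"), h = 3, k = 4)  # 914.838
#' @export
ionMz <- function(mass, h = 1L, k = 0L, ion = NULL) {
  if (!is.numeric(mass)) mass <- neutralMass(mass)
  if (!is.null(ion)) { h <- ion$h; k <- ion$k }
  h <- as.integer(h); k <- as.integer(k)
  if (any(h < 1L)) stop("charge (protons removed) must be >= 1")
  stopifnot(all(mass > 0), all(k >= 0L))
  (mass - h * .MASS$proton + k * .MASS$DBA) / h
}

#' Match an observed m/z against candidate compositions
#'
#' Scans deprotonation/adduct combinations at the observed charge and
#' returns every candidate composition whose computed m/z lies within the
#' tolerance, sorted by absolute error.
#'
#' @param mzObs observed m/z.
#' @param z observed charge magnitude.
#' @param candidates list (or character vector) of composition codes.
#' @param tol m/z tolerance (default 0.01).
#' @param kRange DBA adduct counts to scan (default `0:(z + 1)`).
#' @return data.frame with columns `composition`, `z`, `dba`, `mz_calc`,
#'   `error_mDa`, sorted by `abs(error)`; zero rows when nothing matches.
#' @examples
#' matchComposition(913.6, 2, list("ΔU6,7,0"), tol = 0.05, kRange = 0:3)
#' @export
matchComposition <- function(mzObs, z, candidates, tol = 0.01,
                             kRange = NULL) {
  if (is.null(kRange)) kRange <- 0:(z + 1L)
  if (is.character(candidates)) candidates <- as.list(candidates)
  candidates <- lapply(candidates, function(cc)
    if (is.character(cc)) parseComposition(cc) else cc)
  rows <- list()
  for (cc in candidates) {
    m <- neutralMass(cc)
    for (k in kRange) {
      mz <- ionMz(m, h = z, k = k)
      err <- mz - mzObs
      if (abs(err) <= tol)
        rows[[length(rows) + 1L]] <- data.frame(
          composition = formatComposition(cc), z = z, dba = k,
          mz_calc = round(mz, 3), error_mDa = round(err * 1000, 2),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(composition = character(), z = integer(),
                      dba = integer(), mz_calc = numeric(),
                      error_mDa = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(abs(out$error_mDa)), , drop = FALSE]
}
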