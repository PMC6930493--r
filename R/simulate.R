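#' Heparin-like chain population model
#'
#' Describes the structural statistics of a synthetic heparin/LMWH
#' oligosaccharide population: background sulfation/acetylation
#' probabilities of the alternating uronic/glucosamine backbone,
#' antithrombin-binding-region (ATBR) insertion, and the reducing-end
#' chemistry (natural free reducing end, or the 2,5-anhydromannitol ends of
#' nitrous-acid-depolymerised LMWHs such as dalteparin).
#'
#' @param lengthRange even chain lengths sampled uniformly (default 4–8).
#' @param p2S probability of 2-O-sulfation on an iduronic residue.
#' @param pG probability that a backbone uronic residue is (unsulfated)
#'   glucuronic rather than iduronic.
#' @param p6S probability of 6-O-sulfation on a glucosamine.
#' @param pNAc probability that a glucosamine is N-acetylated (else
#'   N-sulfated).
#' @param atbrRate per-site probability of overwriting the backbone with
#'   the ATBR pentasaccharide motif `ANX6S–G–ANS3S6S–I2S–ANS6S`.
#' @param atbrNSfrac fraction of ATBR insertions using the N-sulfated
#'   variant (X = SO3) rather than the N-acetylated one (X = Ac); 1 mimics
#'   the variant from which dalteparin's G–A_NS3S6S-initiated oligomers
#'   arise.
#' @param reStyle `"amol"` (deaminative ends: fragments start at a uronic
#'   and end in anhydromannitol) or `"natural"`.
#' @param pRc probability of converting one internal glucosamine to a
#'   ring-contracted residue (default 0.02).
#' @param parentLength length of the parent polymer fragments are cut from.
#' @return named list of class `chainModel`.
#' @export
chainModel <- function(lengthRange = c(4L, 8L), p2S = 0.8, pG = 0.15,
                       p6S = 0.85, pNAc = 0.12, atbrRate = 0.05,
                       atbrNSfrac = 1, reStyle = c("amol", "natural"),
                       pRc = 0.02, parentLength = 40L) {
  stopifnot(all(c(p2S, pG, p6S, pNAc, atbrRate, atbrNSfrac, pRc) >= 0),
            all(c(p2S, pG, p6S, pNAc, atbrRate, atbrNSfrac, pRc) <= 1),
            parentLength >= max(lengthRange) + 2L)
  structure(list(lengthRange = as.integer(lengthRange), p2S = p2S, pG = pG,
                 p6S = p6S, pNAc = pNAc, atbrRate = atbrRate,
                 atbrNSfrac = atbrNSfrac, reStyle = match.arg(reStyle),
                 pRc = pRc, parentLength = as.integer(parentLength)),
            class = "chainModel")
}

#' Peak-list noise model
#'
#' @param mzSd Gaussian m/z jitter (Da, default 0).
#' @param dropout per-peak dropout probability.
#' @param decoyRate decoy peaks added per true peak.
#' @param partialFraction probability that products of a partially
#'   susceptible cleavage appear in the peak list (survivors always do).
#' @return named list of class `noiseModel`.
#' @export
noiseModel <- function(mzSd = 0, dropout = 0, decoyRate = 0,
                       partialFraction = 1) {
  stopifnot(mzSd >= 0, dropout >= 0, dropout <= 1, decoyRate >= 0,
            partialFraction >= 0, partialFraction <= 1)
  structure(list(mzSd = mzSd, dropout = dropout, decoyRate = decoyRate,
                 partialFraction = partialFraction), class = "noiseModel")
}

.atbrMotif <- function(nsVariant) {
  parseGAG(if (nsVariant) "ANS6S–G–ANS3S6S–I2S–ANS6S"
           else "ANAc6S–G–ANS3S6S–I2S–ANS6S")@residues
}

## parent polymer: alternating uronic/glucosamine chain of even length with
## background sulfation statistics, plus optional ATBR overwrites.
.buildParent <- function(model) {
  n <- model$parentLength
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (i %% 2L == 1L) {                      # uronic position
      if (stats::runif(1) < model$pG)
        rows[[i]] <- list(class = "U", epimer = "G", s2 = FALSE,
                          nsub = NA_character_, s3 = FALSE, s6 = FALSE)
      else
        rows[[i]] <- list(class = "U", epimer = "I",
                          s2 = stats::runif(1) < model$p2S,
                          nsub = NA_character_, s3 = FALSE, s6 = FALSE)
    } else {                                  # glucosamine position
      nsub <- if (stats::runif(1) < model$pNAc) "NAc" else "NS"
      rows[[i]] <- list(class = "A", epimer = NA_character_, s2 = FALSE,
                        nsub = nsub, s3 = FALSE,
                        s6 = stats::runif(1) < model$p6S)
    }
  }
  df <- do.call(rbind, lapply(rows, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  ## ATBR insertion: overwrite 5 residues starting at a glucosamine
  starts <- seq(2L, n - 4L, by = 2L)
  occupied <- rep(FALSE, n)
  for (p in starts) {
    if (any(occupied[p:(p + 4L)])) next
    if (stats::runif(1) < model$atbrRate) {
      motif <- .atbrMotif(stats::runif(1) < model$atbrNSfrac)
      df[p:(p + 4L), ] <- motif
      occupied[p:(p + 4L)] <- TRUE
    }
  }
  ## ring-contracted side product on one plain internal glucosamine
  if (stats::runif(1) < model$pRc) {
    cand <- which(df$class == "A" & df$nsub == "NS" & !df$s3 &
                    seq_len(n) > 2L & seq_len(n) < n - 1L & !occupied)
    if (length(cand)) {
      j <- cand[sample.int(length(cand), 1L)]
      df[j, ] <- list("Rc", NA_character_, FALSE, NA_character_, FALSE, FALSE)
    }
  }
  df
}

## nitrous-acid logic: depolymerisation cleaves N-sulfated glucosamine to
## uronic bonds, converting the cut glucosamine to 2,5-anhydromannitol
## (N-sulfate lost, 6-O-sulfate retained).  3-O-sulfated glucosamines are
## not used as cut points here, since the residue model gives
## anhydromannitol no 3-O position.
.cuttable <- function(df, i) {
  df$class[i] == "A" & df$nsub[i] == "NS" & !df$s3[i]
}

#' Generate a synthetic oligosaccharide pool
#'
#' Draws `n` fragments from freshly built parent polymers under the chain
#' model.  Fragments start at a uronic residue whose upstream neighbour (if
#' any) is an eligible deaminative cut point and — for the `"amol"`
#' reducing-end style — end at an N-sulfated glucosamine converted to
#' anhydromannitol.  Reproducible under `seed`.
#'
#' @param model a [chainModel()].
#' @param n number of chains.
#' @param seed optional integer seed.
#' @return list of [GAGSequence-class] objects.
#' @export
generatePool <- function(model, n, seed = NULL) {
  stopifnot(is(model, "chainModel"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(list())
  lens <- model$lengthRange
  lens <- seq(lens[1], lens[2], by = 2L)
  out <- vector("list", n)
  for (ch in seq_len(n)) {
    frag <- NULL
    for (attempt in seq_len(400L)) {
      df <- .buildParent(model)
      L <- lens[sample.int(length(lens), 1L)]
      starts <- which(seq_len(nrow(df)) %% 2L == 1L &
                        seq_len(nrow(df)) + L - 1L <= nrow(df))
      starts <- starts[sample.int(length(starts))]
      for (u in starts) {
        e <- u + L - 1L
        okLeft <- u == 1L || .cuttable(df, u - 1L)
        okRight <- if (model$reStyle == "amol") .cuttable(df, e)
                   else df$class[e] %in% c("A", "Rc")
        if (!(okLeft && okRight)) next
        sub <- df[u:e, , drop = FALSE]
        if (model$reStyle == "amol") {
          sub$class[L] <- "aMol"
          sub$nsub[L] <- NA_character_
          sub$s3[L] <- FALSE
        }
        cand <- .newGAG(sub)
        if (isTRUE(validObject(cand, test = TRUE))) frag <- cand
        break
      }
      if (!is.null(frag)) break
    }
    if (is.null(frag))
      stop("could not draw a fragment satisfying the model after 400 attempts")
    out[[ch]] <- frag
  }
  out
}

#' Summary statistics of a generated pool
#'
#' @param pool list of [GAGSequence-class] objects.
#' @return named list: fraction of 2-O-sulfated iduronic among saturated
#'   iduronic residues, glucuronic fraction among saturated uronic
#'   residues, 6-O-sulfation and N-acetylation fractions among
#'   glucosamines, 3-O-sulfated glucosamines per chain, and the fraction of
#'   chains opening with the G–A_NS3S6S signature.
#' @export
poolStatistics <- function(pool) {
  res <- do.call(rbind, lapply(pool, residues))
  uron <- res[res$class == "U", , drop = FALSE]
  ido <- uron[uron$epimer == "I", , drop = FALSE]
  gl <- res[res$class == "A", , drop = FALSE]
  gSig <- vapply(pool, function(s) {
    r <- residues(s)
    nrow(r) >= 2L && r$class[1] == "U" && identical(r$epimer[1], "G") &&
      !r$s2[1] && r$class[2] == "A" && r$s3[2]
  }, logical(1))
  list(p2S = mean(ido$s2), pG = mean(uron$epimer == "G"),
       p6S = mean(gl$s6), pNAc = mean(gl$nsub == "NAc"),
       s3PerChain = sum(gl$s3) / length(pool),
       gANS3S6SInitiated = mean(gSig))
}

#' Default ion-form policy for converting masses to peaks
#'
#' Mass bands mirror the prevalent observed forms: singly charged with 0–1
#' dibutylamine below 700 Da, doubly charged with 0–3 DBA between 700 and
#' 1600 Da, triply charged with 3–4 DBA above.
#'
#' @return data.frame with columns `min`, `max`, `z`, `kmin`, `kmax`.
#' @export
ionFormPolicy <- function() {
  data.frame(min = c(0, 700, 1600), max = c(700, 1600, Inf),
             z = c(1L, 2L, 3L), kmin = c(0L, 0L, 3L), kmax = c(1L, 3L, 4L))
}

#' Simulate a digestion experiment and its peak list
#'
#' Digests a pool with the chosen enzymes, converts every fixed-point
#' product (and partial survivor) to ions under the ion-form policy,
#' applies the noise model, and returns the peak list together with a
#' ground-truth table linking each true peak to its product sequence.
#'
#' @param pool list of [GAGSequence-class] objects (or strings).
#' @param enzymes subset of `c("hepI", "hepII", "hepIII", "heparanase")`.
#' @param policy ion-form policy table, by default [ionFormPolicy()].
#' @param noise a [noiseModel()].
#' @param seed optional integer seed.
#' @return list with `peaks` (data.frame `mz`, `z`, `intensity`, `id`; `id`
#'   is NA for decoys), `truth` (data.frame `id`, `sequence`,
#'   `composition`, `neutral_mass`, `z`, `dba`, `mz_true`, `observed`) and
#'   the [DigestResult-class] as `digest`.
#' @export
simulateExperiment <- function(pool, enzymes = "heparanase",
                               policy = ionFormPolicy(),
                               noise = noiseModel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- .digestForTreatment(.asPool(pool), enzymes)
  prov <- provenance(res)
  partialProducts <- unique(prov$product[prov$rule == "R3"])
  seqs <- c(products(res), partialSurvivors(res))
  keep <- vapply(seqs, function(s) {
    txt <- formatGAG(s)
    !(txt %in% partialProducts) || stats::runif(1) < noise$partialFraction
  }, logical(1))
  seqs <- seqs[keep]
  truth <- list()
  for (s in seqs) {
    m <- neutralMass(s)
    band <- policy[policy$min <= m & m < policy$max, , drop = FALSE][1, ]
    for (k in band$kmin:band$kmax) {
      truth[[length(truth) + 1L]] <- data.frame(
        sequence = formatGAG(s),
        composition = formatComposition(compositionOf(s), withLabel = FALSE),
        neutral_mass = m, z = band$z, dba = k,
        mz_true = ionMz(m, h = band$z, k = k), stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sequence = character(), composition = character(),
               neutral_mass = numeric(), z = integer(), dba = integer(),
               mz_true = numeric(), stringsAsFactors = FALSE)
  truth$id <- seq_len(nrow(truth))
  truth$observed <- stats::runif(nrow(truth)) >= noise$dropout
  peaks <- data.frame(
    mz = truth$mz_true[truth$observed] +
      stats::rnorm(sum(truth$observed), 0, noise$mzSd),
    z = truth$z[truth$observed],
    intensity = 1, id = truth$id[truth$observed],
    stringsAsFactors = FALSE)
  nDecoy <- round(noise$decoyRate * nrow(peaks))
  if (nDecoy > 0 && nrow(peaks) > 0) {
    peaks <- rbind(peaks, data.frame(
      mz = stats::runif(nDecoy, min(peaks$mz), max(peaks$mz) + 1),
      z = sample(peaks$z, nDecoy, replace = TRUE),
      intensity = 0.1, id = NA_integer_, stringsAsFactors = FALSE))
  }
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, truth = truth, digest = res)
}

#' Closed-loop sequence recovery experiment
#'
#' For each generated chain: simulate a noiseless heparanase digestion,
#' transcribe the chain's fate and product compositions into evidence, run
#' [inferStructures()] on the chain's composition, and test whether the
#' planted sequence is a member of the consistent set.  With noise off this
#' is the completeness property of the inference engine.
#'
#' @param model a [chainModel()].
#' @param n number of chains.
#' @param seed integer seed.
#' @param constraints enumeration constraints (defaults must admit the
#'   generator's output).
#' @return list with `recovered` (fraction), `n`, and a data.frame
#'   `detail` (`sequence`, `composition`, `fate`, `n_consistent`,
#'   `recovered`).
#' @export
recoveryExperiment <- function(model = chainModel(), n = 200L, seed = 1L,
                               constraints = gagConstraints()) {
  pool <- generatePool(model, n, seed = seed)
  memo <- new.env(parent = emptyenv())
  rows <- lapply(pool, function(chain) {
    fate <- digestFate(chain, "heparanase")
    dig <- digestHeparanase(chain)
    comps <- sort(unique(vapply(products(dig), function(p)
      formatComposition(compositionOf(p), withLabel = FALSE), character(1))))
    codeTxt <- formatComposition(compositionOf(chain), withLabel = FALSE)
    key <- paste(codeTxt, fate, paste(comps, collapse = "|"), sep = "#")
    if (is.null(memo[[key]])) {
      ev <- evidenceRecord(codeTxt, "heparanase", fate, companions = comps)
      set <- inferStructures(codeTxt, list(ev), constraints = constraints)
      memo[[key]] <- vapply(set, formatGAG, character(1))
    }
    hits <- memo[[key]]
    data.frame(sequence = formatGAG(chain), composition = codeTxt,
               fate = fate, n_consistent = length(hits),
               recovered = formatGAG(chain) %in% hits,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  list(recovered = mean(detail$recovered), n = n, detail = detail)
}
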