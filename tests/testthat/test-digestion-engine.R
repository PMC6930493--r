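octamers <- dalteparinOctasaccharides()

compositions <- function(seqs) {
  sort(vapply(seqs, function(s)
    formatComposition(compositionOf(s), withLabel = FALSE), character(1)))
}

test_that("lyase site matching follows the enzyme pattern table", {
  ## heparinase I: N-sulfated glucosamine onto 2-O-sulfated iduronic acid
  s <- lyaseSites("I2S–ANS6S–I2S–ANS6S", enzymes = "hepI")
  expect_identical(s$bond, 2L)
  ## heparinase III: N-acetylated glucosamine onto unsulfated iduronic acid,
  ## but not onto a sulfated one
  expect_identical(lyaseSites("I2S–ANAc6S–I–ANS", enzymes = "hepIII")$bond, 2L)
  expect_identical(nrow(lyaseSites("I–ANAc6S–I2S–ANS", enzymes = "hepIII")), 0L)
  ## heparinase II is broad: both bonds of a mixed tetramer
  expect_identical(lyaseSites("I2S–ANS6S–I–ANAc6S–G–ANS",
                              enzymes = "hepII")$bond, c(2L, 4L))
})

test_that("the 3-O-sulfated linkage and the anhydromannitol end block lyases", {
  ## A -> G bond two residues upstream of a 3-O-sulfated glucosamine resists
  ## all three lyases
  expect_identical(nrow(lyaseSites("ΔU–ANS6S–G–ANS3S")), 0L)
  ## the same bond without the 3-O-sulfate is cleavable
  expect_identical(lyaseSites("ΔU–ANS6S–G–ANS")$bond, 2L)
  ## a bond leading onto the anhydromannitol reducing end is protected
  expect_identical(nrow(lyaseSites("ΔU2S–ANS6S–I2S–aM.ol6S")), 0L)
  expect_identical(lyaseSites("ΔU2S–ANS6S–I2S–ANS6S")$bond, 2L)
})

test_that("exhaustive lyase digestion of both octasaccharides yields the
           reference product set and no tetrasulfated disaccharide", {
  res <- digestLyase(list(octamers$major_resistant, octamers$major_susceptible))
  got <- unique(compositions(products(res)))
  expect_setequal(got, c("U2,3,0", "ΔU2,3,0", "ΔU4,5,0–aM.ol"))
  expect_false(any(got %in% c("U2,4,0", "ΔU2,4,0")))
  ## the saturated disaccharide arises as two distinct structures: the
  ## nonreducing-end I2S–ANS6S and G–ANS3S6S openers
  satStruct <- unique(vapply(products(res), formatGAG, character(1)))
  expect_true("I2S–ANS6S" %in% satStruct)
  expect_true("G–ANS3S6S" %in% satStruct)
  ## residue count is conserved
  expect_identical(sum(vapply(products(res), length, integer(1))), 16L)
})

test_that("eliminative cleavage conserves mass exactly", {
  set.seed(11)
  for (i in 1:120) {
    txt <- randomSequenceText()
    res <- digestLyase(txt)
    expect_equal(sum(vapply(products(res), neutralMass, numeric(1))),
                 neutralMass(txt), tolerance = 1e-9)
  }
})

test_that("the lyase fixed point is independent of cleavage order", {
  set.seed(23)
  for (i in 1:40) {
    txt <- randomSequenceText(maxLen = 10)
    ref <- sort(vapply(products(digestLyase(txt)), formatGAG, character(1)))
    for (rep in 1:3) {
      alt <- sort(vapply(products(digestLyase(txt, order = "random")),
                         formatGAG, character(1)))
      expect_identical(alt, ref)
    }
  }
})

test_that("heparanase verdicts follow the ordered rule table", {
  ## fully susceptible: G flanked by 6-O-sulfated glucosamines, no
  ## 2-O-sulfated uronic two residues upstream
  v <- heparanaseVerdict("ΔU–ANS6S–G–ANS6S", 3)
  expect_identical(v$verdict, "cleave")
  ## R1: acceptor glucosamine without 6-O-sulfate resists
  expect_identical(heparanaseVerdict("ΔU–ANS6S–G–ANS3S", 3)$verdict, "resist")
  ## R2: glucosamine upstream of G without 6-O-sulfate resists
  expect_identical(heparanaseVerdict("ΔU2S–ANS–G–ANS3S6S", 3)$verdict,
                   "resist")
  ## R3: 2-O-sulfated uronic two residues upstream -> partial
  p <- heparanaseVerdict("ΔU2S–ANS6S–G–ANS3S6S", 3)
  expect_identical(p$verdict, "partial")
  expect_identical(p$rule, "R3")
  ## R0a: anhydromannitol downstream resists
  expect_identical(heparanaseVerdict("ΔU–ANS6S–G–aM.ol6S", 3)$verdict,
                   "resist")
  ## 2-O-sulfated or iduronic uronic residues are not sites at all
  expect_identical(nrow(heparanaseSites("I2S–ANS6S–I2S–ANS6S")), 0L)
  expect_error(heparanaseVerdict("I2S–ANS6S–I2S–ANS6S", 2))
})

test_that("heparanase removes the terminal glucuronic acid of the susceptible
           octasaccharide and leaves the iduronic isomer intact", {
  resS <- digestHeparanase(octamers$major_susceptible)
  expect_setequal(compositions(products(resS)),
                  c("A7,11,0–aM.ol", "U1,0,0"))
  expect_identical(length(partialSurvivors(resS)), 0L)
  resR <- digestHeparanase(octamers$major_resistant)
  expect_identical(vapply(products(resR), formatGAG, character(1)),
                   formatGAG(octamers$major_resistant))
})

test_that("intrachain glucuronic sites in a sulfated context digest
           partially into the expected halves", {
  res1 <- digestHeparanase(octamers$minor_intrachain_1)
  expect_identical(length(partialSurvivors(res1)), 1L)
  expect_setequal(compositions(products(res1)),
                  c("A5,8,0–aM.ol", "U3,3,0"))
  res2 <- digestHeparanase(octamers$minor_intrachain_2)
  expect_identical(length(partialSurvivors(res2)), 1L)
  expect_setequal(compositions(products(res2)),
                  c("A3,5,0–aM.ol", "U5,6,0"))
})

test_that("hydrolytic cleavage adds exactly one water per cut", {
  set.seed(31)
  checked <- 0L
  while (checked < 80L) {
    txt <- randomSequenceText()
    if (digestFate(txt, "heparanase") == "partial") next
    res <- digestHeparanase(txt)
    nProd <- length(products(res))
    expect_equal(sum(vapply(products(res), neutralMass, numeric(1))),
                 neutralMass(txt) + (nProd - 1L) * 18.01056,
                 tolerance = 1e-6)
    checked <- checked + 1L
  }
})

test_that("fate classification distinguishes resistant, partial and
           disappearing species", {
  expect_identical(digestFate(octamers$major_resistant, "heparanase"),
                   "resistant")
  expect_identical(digestFate(octamers$major_susceptible, "heparanase"),
                   "disappears")
  expect_identical(digestFate(octamers$minor_intrachain_1, "heparanase"),
                   "partial")
  ## under lyases the iduronic-repeat octasaccharide disappears instead
  expect_identical(digestFate(octamers$major_resistant,
                              c("hepI", "hepII", "hepIII")), "disappears")
  expect_identical(digestFate("ΔU–ANAc6S–G–ANS3S",
                              c("hepI", "hepII", "hepIII", "heparanase")),
                   "resistant")
})

test_that("sequential lyase-then-heparanase digestion chains provenance", {
  res <- digestCombined(octamers$major_susceptible)
  prov <- provenance(res)
  expect_true("elimination" %in% prov$rule)
  expect_true("heparanase" %in% prov$enzyme)
  ## the lyase-liberated G–ANS3S6S disaccharide is itself a heparanase
  ## substrate (fully exposed site), so the combined digest splits it again
  expect_setequal(compositions(products(res)),
                  c("A1,3,0", "U1,0,0", "ΔU2,3,0", "ΔU4,5,0–aM.ol"))
  tab <- productTable(res)
  expect_true(all(c("sequence", "composition", "count", "neutral_mass",
                    "survivor") %in% names(tab)))
})
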