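## Reference MS/MS values: the trisulfated disaccharide isomer pair
## G–ANS3S6S (3-O-sulfated, glucuronic) and I2S–ANS6S (2-O-sulfated,
## iduronic) share every glycosidic fragment mass and are told apart only
## by the cross-ring/loss ions at m/z 198.99 versus 210.99/222.01.

iso1 <- parseGAG("G–ANS3S6S")
iso2 <- parseGAG("I2S–ANS6S")
sharedPeaks <- data.frame(mz = c(137.99, 168.49, 175.03), z = c(1, 2, 1))
diagPeaks <- data.frame(mz = c(198.99, 210.99, 222.01), z = c(1, 1, 1))

test_that("B/Y and C/Z glycosidic pairs are exactly complementary", {
  set.seed(101)
  for (i in 1:1000) {
    txt <- randomSequenceText()
    x <- parseGAG(txt)
    M <- neutralMass(x)
    g <- glycosidicFragments(x)
    n <- length(x)
    for (bond in unique(g$index[g$kind == "B"])) {
      b <- g$neutral_full[g$kind == "B" & g$index == bond]
      y <- g$neutral_full[g$kind == "Y" & g$index == n - bond]
      cc <- g$neutral_full[g$kind == "C" & g$index == bond]
      z <- g$neutral_full[g$kind == "Z" & g$index == n - bond]
      expect_equal(b + y, M, tolerance = 1e-9)
      expect_equal(cc, b + 18.01056, tolerance = 1e-9)
      expect_equal(z, y - 18.01056, tolerance = 1e-9)
    }
  }
})

test_that("cross-ring 0,2 units partition the glucosamine residue exactly", {
  ## base units sum to the free residue mass
  m <- residueMasses()
  expect_equal(59.03711 + 120.04226, m[["A"]], tolerance = 1e-4)
  ## for internal glucosamines, 0,2A + 0,2X reassemble the whole molecule
  set.seed(103)
  for (i in 1:200) {
    x <- parseGAG(randomSequenceText())
    cr <- crossringFragments(x)
    if (is.null(cr)) next
    M <- neutralMass(x)
    for (pos in intersect(cr$index[cr$kind == "02A"],
                          cr$index[cr$kind == "02X"])) {
      a <- cr$neutral_full[cr$kind == "02A" & cr$index == pos]
      xr <- cr$neutral_full[cr$kind == "02X" & cr$index == pos]
      expect_equal(a + xr, M, tolerance = 1e-9)
    }
  }
})

test_that("every reference MS/MS ion of the isomer pair finds a candidate
           within 0.01 m/z", {
  for (iso in list(iso1, iso2)) {
    cand <- fragmentCandidates(iso)
    for (j in seq_len(nrow(sharedPeaks))) {
      mzs <- cand$mz[cand$z == sharedPeaks$z[j]]
      expect_true(any(abs(mzs - sharedPeaks$mz[j]) <= 0.01),
                  info = sprintf("%s @ %.2f", formatGAG(iso),
                                 sharedPeaks$mz[j]))
    }
  }
})

test_that("the diagnostic ions separate the trisulfated disaccharide
           isomers", {
  cmp <- compareIsomers(rbind(sharedPeaks, diagPeaks),
                        list(gluc = iso1, ido = iso2))
  shared <- cmp[cmp$mz %in% sharedPeaks$mz, ]
  expect_true(all(shared$matched_gluc & shared$matched_ido))
  expect_false(any(shared$diagnostic))
  ## 198.99 (bare sulfated C3-C6 unit) only from the 3-O/6-O-sulfated ring
  p199 <- cmp[cmp$mz == 198.99, ]
  expect_true(p199$matched_gluc)
  expect_false(p199$matched_ido)
  ## 210.99 (B1 + SO3 - CO2) and 222.01 (Z1 + SO3 - H2O) only from the
  ## 2-O-sulfated isomer, whose reducing ring keeps a free hydroxyl
  p211 <- cmp[cmp$mz == 210.99, ]
  p222 <- cmp[cmp$mz == 222.01, ]
  expect_false(p211$matched_gluc || p222$matched_gluc)
  expect_true(p211$matched_ido && p222$matched_ido)
  expect_true(all(cmp$diagnostic[cmp$mz %in% diagPeaks$mz]))
})

test_that("sulfate retention, losses and charge respect the candidate caps", {
  cand <- fragmentCandidates("G–ANS3S6S–I2S–ANS6S", maxCharge = 2)
  expect_true(all(cand$z <= 2))
  expect_true(all(cand$z <= cand$retained + 1L))
  expect_true(all(cand$co2 <= 1L & cand$h2o <= 1L))
  ## the bare C1-C2 / C3-C6 units carry no carboxyl, hence never lose CO2
  bare <- cand[cand$kind %in% c("int02X", "int02A"), ]
  expect_true(all(bare$co2 == 0L))
  ## retained sulfates never exceed those covered by the fragment
  b1 <- cand[cand$kind == "B" & cand$index == 1, ]
  expect_true(all(b1$retained <= 3L))
})

test_that("peak annotation assigns the closest candidate within tolerance", {
  ann <- annotateMSMS(diagPeaks, iso2, tol = 0.01)
  expect_identical(ann$annotated, c(FALSE, TRUE, TRUE))
  expect_identical(ann$label[2], "B1(+1SO3)-CO2")
  expect_identical(ann$label[3], "Z1(+1SO3)-H2O")
  expect_true(all(abs(ann$error_mDa[ann$annotated]) <= 10))
  ## out-of-tolerance peaks stay unannotated rather than force-fitted
  far <- annotateMSMS(data.frame(mz = 400.123, z = 1), iso2, tol = 0.01)
  expect_false(far$annotated)
})
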