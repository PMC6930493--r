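## The intact-species reference values below are negative-mode ion-pair
## electrospray m/z values of heparin/LMWH oligosaccharides observed as
## [M − hH + kDBA]h− ions; each is checked to the printed decimals.

test_that("neutral masses follow the residue/sulfate/acetyl sum rule", {
  expect_equal(neutralMass("G"), 194.04265, tolerance = 1e-7)
  expect_equal(neutralMass("ΔU2S–ANS6S"), 576.97136, tolerance = 1e-5)
  expect_equal(neutralMass("U8,11,0–aM.ol"), 2230.9281, tolerance = 1e-4)
  ## a sequence and its composition code give the same mass, exactly
  seqs <- c("G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S",
            "ΔU–ANAc6S–G–ANS3S", "I2S–ANS6S")
  for (s in seqs) {
    expect_equal(
      neutralMass(s),
      neutralMass(formatComposition(compositionOf(s), withLabel = FALSE)),
      tolerance = 1e-10)
  }
})

test_that("intact-species m/z values reproduce the reference decimals", {
  mz3 <- function(code, h, k) round(ionMz(neutralMass(code), h = h, k = k), 3)
  ## undecasulfated octasaccharides and their heparanase products
  expect_identical(mz3("U8,11,0–aM.ol", 3, 4), 914.838)
  expect_identical(mz3("U8,11,0–aM.ol", 3, 3), 871.787)
  expect_identical(mz3("A7,11,0–aM.ol", 3, 4), 856.160)
  expect_identical(mz3("A7,11,0–aM.ol", 3, 3), 813.110)
  expect_identical(mz3("A7,10,0–aM.ol", 3, 3), 786.458)
  ## acetylated and decasulfated octasaccharide congeners
  expect_identical(mz3("U8,9,1–aM.ol", 3, 4), 875.537)
  expect_identical(mz3("U8,10,1–aM.ol", 3, 4), 902.189)
  expect_identical(mz3("U8,10,0–aM.ol", 3, 3), 845.135)
  expect_identical(mz3("U8,10,0,Rc–aM.ol", 3, 4), 883.182)
  ## trisulfated disaccharides (lyase digest end points)
  expect_identical(mz3("U2,3,0", 1, 0), 593.975)
  expect_identical(mz3("ΔU2,3,0", 1, 0), 575.964)
  ## unsaturated reducing-end tetrasaccharide
  expect_identical(mz3("ΔU4,5,0–aM.ol", 2, 0), 528.480)
  ## intrachain heparanase products
  expect_identical(mz3("U5,6,0", 2, 1), 737.561)
  expect_identical(mz3("A5,8,0–aM.ol", 2, 3), 931.683)
  expect_identical(mz3("U3,3,0", 2, 0), 384.500)
  expect_identical(mz3("A3,5,0–aM.ol", 2, 0), 449.469)
  ## hexasulfated hexasaccharide at survey-scan precision
  expect_equal(ionMz(neutralMass("ΔU6,7,0"), h = 2, k = 2), 913.6,
               tolerance = 0.05)
})

test_that("ion arithmetic is exact and monotone in the adduct count", {
  m <- neutralMass("U8,11,0–aM.ol")
  for (h in 1:3) {
    for (k in 0:4) {
      expect_equal(ionMz(m, h = h, k = k),
                   (m - h * 1.007276 + k * 129.15175) / h,
                   tolerance = 1e-12)
    }
    ## each added dibutylamine shifts m/z by exactly 129.15175 / h
    expect_equal(ionMz(m, h = h, k = 3) - ionMz(m, h = h, k = 2),
                 129.15175 / h, tolerance = 1e-12)
  }
  expect_error(ionMz(m, h = 0))
  expect_equal(ionMz(m, ion = ionForm(3, 4)), ionMz(m, h = 3, k = 4),
               tolerance = 1e-12)
})

test_that("sequence masses agree with an elemental-formula oracle", {
  set.seed(7)
  for (i in 1:200) {
    txt <- randomSequenceText()
    expect_equal(neutralMass(txt), oracleNeutralMass(txt), tolerance = 1e-4)
  }
})

test_that("an unsaturated chain weighs one water less than its saturated twin", {
  expect_equal(neutralMass("U2,3,0") - neutralMass("ΔU2,3,0"), 18.01056,
               tolerance = 1e-5)
  expect_equal(neutralMass("U4,5,0") - neutralMass("ΔU4,5,0"), 18.01056,
               tolerance = 1e-5)
})

test_that("composition matching recovers the ion form within tolerance", {
  hit <- matchComposition(914.838, 3, "U8,11,0–aM.ol")
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$dba, 4L)
  ## survey-scan value at 0.05 tolerance pins the 2-adduct form
  hit2 <- matchComposition(913.6, 2, list("ΔU6,7,0"), tol = 0.05, kRange = 0:3)
  expect_identical(hit2$dba, 2L)
  hit3 <- matchComposition(528.480, 2, "ΔU4,5,0–aM.ol", kRange = 0:2)
  expect_identical(hit3$dba, 0L)
  ## nothing within a tight window -> empty, not an error
  none <- matchComposition(500.0, 2, "U8,11,0–aM.ol", tol = 0.001)
  expect_identical(nrow(none), 0L)
})

test_that("the residue mass table is internally consistent", {
  m <- residueMasses()
  expect_equal(m[["U"]] - m[["dU"]], 18.01056, tolerance = 1e-5)
  expect_equal(m[["aMol"]], m[["Rc"]], tolerance = 1e-12)
})
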