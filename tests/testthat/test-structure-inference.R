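octamers <- dalteparinOctasaccharides()

test_that("constraint-based enumeration matches a brute-force oracle for
           short chains", {
  codes <- c("ΔU2,2,0", "ΔU2,3,0", "U2,3,0", "ΔU4,4,1", "ΔU4,5,0",
             "ΔU4,6,0", "U4,5,0–aM.ol", "A3,4,0–aM.ol", "U3,3,0")
  for (cc in codes) {
    expect_identical(length(enumerateSequences(cc)),
                     as.integer(oracleEnumerationCount(cc)),
                     info = cc)
  }
  ## infeasible codes give empty sets, not errors
  expect_identical(length(enumerateSequences("U3,3,0–aM.ol")), 0L)
  expect_identical(length(enumerateSequences("ΔU2,9,0")), 0L)
  ## the enumeration cap triggers on absurd sizes
  expect_error(enumerateSequences("U12,10,0"))
})

test_that("every enumerated candidate reproduces the requested composition
           and mass", {
  code <- parseComposition("ΔU4,5,0")
  cands <- enumerateSequences(code)
  expect_true(length(cands) > 1)
  for (cand in cands) {
    expect_identical(formatComposition(compositionOf(cand),
                                       withLabel = FALSE), "ΔU4,5,0")
    expect_equal(neutralMass(cand), neutralMass(code), tolerance = 1e-9)
  }
  ## no duplicated structures
  txt <- vapply(cands, formatGAG, character(1))
  expect_identical(anyDuplicated(txt), 0L)
})

test_that("the 3-O-sulfation context constraint gates the candidate space", {
  loose <- gagConstraints(threeOS = "anyNS")
  none <- gagConstraints(threeOS = "none")
  nDefault <- length(enumerateSequences("ΔU4,5,0"))
  expect_gt(length(enumerateSequences("ΔU4,5,0", loose)), nDefault)
  expect_lt(length(enumerateSequences("ΔU4,5,0", none)), nDefault)
})

test_that("digestion evidence on the octasaccharide composition pins down
           both major structures uniquely", {
  code <- "U8,11,0–aM.ol"
  evResistant <- evidenceRecord(code, "heparanase", "resistant")
  setR <- inferStructures(code, list(evResistant))
  expect_identical(vapply(setR, formatGAG, character(1)),
                   formatGAG(octamers$major_resistant))
  evDisappears <- evidenceRecord(code, "heparanase", "disappears",
                                 companions = c("A7,11,0–aM.ol", "U1,0,0"))
  setD <- inferStructures(code, list(evDisappears))
  expect_identical(vapply(setD, formatGAG, character(1)),
                   formatGAG(octamers$major_susceptible))
})

test_that("partial-fate evidence with product compositions recovers the
           intrachain isomers", {
  code <- "U8,11,0–aM.ol"
  ev1 <- evidenceRecord(code, "heparanase", "partial",
                        companions = c("U3,3,0", "A5,8,0–aM.ol"))
  set1 <- inferStructures(code, list(ev1))
  expect_true(formatGAG(octamers$minor_intrachain_1) %in%
                vapply(set1, formatGAG, character(1)))
  expect_false(formatGAG(octamers$minor_intrachain_2) %in%
                 vapply(set1, formatGAG, character(1)))
})

test_that("infeasible evidence returns an empty set rather than an error", {
  ev <- evidenceRecord("ΔU2,3,0", "heparanase", "disappears")
  expect_identical(length(inferStructures("ΔU2,3,0", list(ev))), 0L)
})

test_that("trace companions are validated as leakage support rather than
           hard constraints", {
  ## the resistant tetrasaccharide still shows a trace 3-O-sulfated
  ## monosaccharide: producible by single hydrolysis at the resistant site
  ev <- list(
    evidenceRecord("ΔU4,3,1", c("hepI", "hepII", "hepIII"), "resistant"),
    evidenceRecord("ΔU4,3,1", "heparanase", "resistant",
                   companions = "A1,2,0", trace = TRUE))
  set <- inferStructures("ΔU4,3,1", ev)
  expect_true(length(set) >= 1)
  support <- attr(set, "traceSupport")
  expect_identical(support$companion, "A1,2,0")
  expect_true(support$producible)
})

test_that("the reference tetrasaccharide report contains every printed
           structure", {
  rep <- tetraReport()
  expect_identical(nrow(rep), 10L)
  expect_true(all(rep$contains_printed))
  expect_true(all(rep$n_consistent >= 1))
  ## fates with stronger evidence give smaller candidate sets
  expect_identical(rep$n_consistent[rep$code == "ΔU4,6,0"], 1L)
})
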