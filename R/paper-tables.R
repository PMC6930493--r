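#' Reported ATBR-derived tetrasaccharides of bovine mucosal heparin
#'
#' The ten lyase-resistant tetrasaccharides arising from the antithrombin
#' binding region of bovine mucosal heparin, with their published
#' structural hypotheses and observed fate under heparanase treatment
#' ("resistant", "disappears" or "partial").  These printed species serve
#' as reference inputs for [tetraReport()] and for validating the
#' susceptibility rules.
#'
#' @return data.frame with columns `code`, `label`, `structure`, `fate`.
#' @export
atbrTetraTable <- function() {
  data.frame(
    code = c("ΔU4,3,1", "ΔU4,4,1", "ΔU4,4,1", "ΔU4,4,0", "ΔU4,4,0",
             "ΔU4,5,0", "ΔU4,5,0", "ΔU4,5,0", "ΔU4,5,1", "ΔU4,6,0"),
    label = c("", "(1)", "(2)", "(1)", "(2)", "(1)", "(2)", "(3)", "", ""),
    structure = c(
      "ΔU–ANAc6S–G–ANS3S",
      "ΔU–ANAc6S–G–ANS3S6S",
      "ΔU2S–ANAc6S–G–ANS3S",
      "ΔU–ANS6S–G–ANS3S",
      "ΔU2S–ANS–G–ANS3S",
      "ΔU–ANS6S–G–ANS3S6S",
      "ΔU2S–ANS–G–ANS3S6S",
      "ΔU2S–ANS6S–G–ANS3S",
      "ΔU2S–ANAc6S–G–ANS3S6S",
      "ΔU2S–ANS6S–G–ANS3S6S"),
    fate = c("resistant", "disappears", "resistant", "resistant",
             "resistant", "disappears", "resistant", "resistant",
             "partial", "partial"),
    stringsAsFactors = FALSE)
}

#' Reported dalteparin octasaccharide sequences
#'
#' The two major undecasulfated octasaccharide isomers (composition
#' U8,11,0–aM.ol) of the dalteparin octasaccharide fraction and the two
#' minor isomers carrying the G–A_NS3S6S motif within the chain.  The major
#' isomers differ at the nonreducing end — the fully 2-O-sulfated iduronic
#' repeat versus the glucuronic/3-O-sulfated glucosamine opening — which is
#' what heparanase digestion discriminates.
#'
#' @return named list of [GAGSequence-class] objects (`major_resistant`,
#'   `major_susceptible`, `minor_intrachain_1`, `minor_intrachain_2`).
#' @export
dalteparinOctasaccharides <- function() {
  list(
    major_resistant =
      parseGAG("I2S–ANS6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S"),
    major_susceptible =
      parseGAG("G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S"),
    minor_intrachain_1 =
      parseGAG("I2S–ANS6S–G–ANS3S6S–I2S–ANS6S–I2S–aM.ol6S"),
    minor_intrachain_2 =
      parseGAG("I2S–ANS6S–I2S–ANS6S–G–ANS3S6S–I2S–aM.ol6S"))
}
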