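# GAGdigest

In-silico enzymatic sequencing of heparin and low-molecular-weight heparin
(LMWH) oligosaccharides.

Heparin is a linear, highly sulfated glycosaminoglycan (GAG) of alternating
uronic acid (iduronic **I** or glucuronic **G**) and glucosamine (**A**)
residues. Mass spectrometry alone determines a species' *composition* — how
many residues, sulfates and N-acetyl groups it carries — but not where those
groups sit, and isomers such as a 2-O-sulfated iduronic unit versus a
glucuronic unit next to a 3-O-sulfated glucosamine have identical masses.
Enzymes break the tie: heparin lyases (heparinases I/II/III) cleave
glucosamine→uronic bonds eliminatively with sulfation-dependent
specificities, and heparanase, a hydrolytic endo-glucuronidase, cleaves only
unsulfated-glucuronic→glucosamine bonds in a sulfation context it tolerates.
Whether a species survives, disappears, or is partially consumed under each
enzyme is structural information. GAGdigest turns that reasoning into code:

* a residue-level grammar and composition-code nomenclature for GAG
  sequences, including the 2,5-anhydromannitol (`aM.ol`) and ring-contracted
  (`Rc`) reducing ends characteristic of nitrous-acid-depolymerised LMWHs
  such as dalteparin;
* exact monoisotopic masses and negative-mode ion-pair m/z arithmetic for
  `[M − hH + kDBA]h−` ions (DBA = dibutylamine);
* rule-driven simulation of heparin lyase and heparanase digestion, with the
  enzyme specificities held in editable data tables;
* Domon–Costello CID fragment enumeration (B/C/Y/Z, 0,2 cross-ring and
  internal ions) and MS/MS peak annotation, including the loss/cross-ring
  ions that discriminate sulfation-pattern isomers;
* constraint-based inference: enumerate every sequence consistent with a
  composition, then keep those whose simulated digestion reproduces the
  observed fates and co-appearing products;
* a synthetic heparin-like chain generator (sulfation statistics,
  antithrombin-binding-region insertion, deaminative reducing-end chemistry)
  for closed-loop validation of the whole pipeline.

## Notation

Sequences are written from the nonreducing end (NRE) to the reducing end
(RE), residues joined by dashes: `G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S`.
`I2S` is 2-O-sulfated iduronic acid; `ANS3S6S` is glucosamine that is
N-, 3-O- and 6-O-sulfated; `ΔU` is the 4,5-unsaturated uronic acid left by
lyase elimination; bare `U` stands for a uronic residue of unknown epimer.
Composition codes read `ΔU/U/A n,s,a` — NRE residue class, residue count,
sulfate count, acetyl count — plus optional `,Rc` and `–aM.ol` end-group
flags, e.g. `U8,11,0–aM.ol`.

## Worked example

The two major undecasulfated octasaccharides of the dalteparin octamer
fraction share the composition `U8,11,0–aM.ol` and are indistinguishable by
mass. Heparanase tells them apart: it removes the terminal glucuronic acid
of the `G–ANS3S6S`-initiated isomer and leaves the iduronic-repeat isomer
untouched.

```r
library(GAGdigest)

x <- parseGAG("G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S")
x
#> GAGSequence (8 residues): G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S

formatComposition(compositionOf(x))
#> [1] "U8,11,0–aM.ol"

ionMz(neutralMass(x), h = 3, k = 4)   # [M − 3H + 4DBA]3−
#> [1] 914.8378

productTable(digestHeparanase(x))
#>                                   sequence   composition count neutral_mass
#> 1                                        G        U1,0,0     1     194.0427
#> 2 ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S A7,11,0–aM.ol     1    2054.8962
#>   survivor
#> 1    FALSE
#> 2    FALSE
```

Running the observation backwards, the evidence "an `U8,11,0–aM.ol` species
disappears under heparanase, and `A7,11,0–aM.ol` plus free glucuronic acid
appear" pins down a single structure out of the enumerable candidates:

```r
ev <- evidenceRecord("U8,11,0–aM.ol", "heparanase", "disappears",
                     companions = c("A7,11,0–aM.ol", "U1,0,0"))
sapply(inferStructures("U8,11,0–aM.ol", list(ev)), formatGAG)
#> [1] "G–ANS3S6S–I2S–ANS6S–I2S–ANS6S–I2S–aM.ol6S"
```

At the disaccharide scale, MS/MS loss and cross-ring ions discriminate the
trisulfated isomers `G–ANS3S6S` and `I2S–ANS6S`, which share all plain
glycosidic fragment masses:

```r
peaks <- data.frame(mz = c(198.99, 210.99, 222.01), z = 1)
compareIsomers(peaks, list(gluc = parseGAG("G–ANS3S6S"),
                           ido  = parseGAG("I2S–ANS6S")))
#>       mz z matched_gluc   label_gluc matched_ido     label_ido diagnostic
#> 1 198.99 1         TRUE 0,2A*(+1SO3)       FALSE          <NA>       TRUE
#> 2 210.99 1        FALSE         <NA>        TRUE B1(+1SO3)-CO2       TRUE
#> 3 222.01 1        FALSE         <NA>        TRUE Z1(+1SO3)-H2O       TRUE
```

A command-line wrapper (`inst/cli/gagpipe.R`, installed under
`system.file("cli", "gagpipe.R", package = "GAGdigest")`) exposes the
`mass`, `digest`, `fragments`, `infer` and `simulate` subcommands; see
`?runCLI`.

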