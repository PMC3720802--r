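# shared small fixtures; everything is generated in code under fixed seeds

smallPropertyFixture <- function(seed = 42L) {
  syntheticPropertyTable(nEntities = 120L, nProperties = 12L, nFactors = 3L,
                         noiseSd = 0.05, seed = seed)
}

tinyScales <- function() {
  # hand-written 3-residue, 2-factor table for exact-lookup checks
  ScaleTable(matrix(c(1, 2,
                      -1, 0.5,
                      0, -2), nrow = 3, byrow = TRUE,
                    dimnames = list(c("A", "G", "101"), c("f1", "f2"))))
}
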