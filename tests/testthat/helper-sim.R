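# place k informative features (default group means) onto the retention-time
# grid of a reduced-size simulated matrix
informativeOnGrid <- function(k, nFeatures) {
  grid <- formatRt(seq(6.1, by = 0.1, length.out = nFeatures))
  inf <- defaultInformativeFeatures()[seq_len(k), ]
  inf$rt <- grid[round(seq(2, nFeatures - 1, length.out = k))]
  inf
}
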