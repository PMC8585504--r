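# half-up rounding for reported integer percentages (round() is banker's)
roundHalfUp <- function(x) floor(x + 0.5)

# derive a bounded sub-seed for per-bundle RNG streams; stays below 2^31
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
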