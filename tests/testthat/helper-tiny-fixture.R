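# a reduced study configuration for fast end-to-end tests; the full-size
# defaults of fixture_config() are exercised by the acceptance suite
tiny_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, genome_length = 96000L, n_planted_increase = 7L,
         n_planted_decrease = 5L, n_neutral_snvs = 16L, n_true_assoc = 4L),
    list(...))
  do.call(fixture_config, args)
}
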