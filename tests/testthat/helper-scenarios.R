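# small scenario used by fast engine tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(strategy = "uninformed", process = "inaccurate",
         years = 50, replicates = 2, summary_every = 10, init_adults = 20),
    list(...))
  do.call(scenario_config, args)
}

# final-year adult allele mean averaged over replicates
final_mean <- function(sim, locus) evolved_trait_mean(sim$snapshot, locus)$mean
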