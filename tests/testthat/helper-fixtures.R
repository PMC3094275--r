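# shared small synthetic dataset, generated once per test run
small_sim_config <- function(...) {
  simulation_config(
    n_chromosomes = 2L, genes_per_chromosome = 4L,
    peptide_plan = c(known = 5L, intronic = 5L, donor = 5L,
                     acceptor = 5L, intergenic = 5L, junction = 3L),
    ...
  )
}

SMALL_SIM <- simulate_dataset(small_sim_config(), seed = 7L)
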