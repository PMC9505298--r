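# Shared fixtures, built lazily once per test session. Everything is
# generated in code; nothing is read from disk except the bundled
# reference tables.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small default-parameter dataset (jitter + decoys on)
small_sim <- function() fixture("small_sim", function()
  simulate_pa_dataset(sim_config(seed = 101L, n_genes = 60L,
                                 n_chromosomes = 2L,
                                 chrom_length = 150000L)))

small_run <- function() fixture("small_run", function()
  run_pa_pipeline(small_sim()))

# noiseless dataset: no jitter, no errors, decoys on (round-trip checks)
noiseless_sim <- function() fixture("noiseless_sim", function()
  simulate_pa_dataset(sim_config(seed = 202L, n_genes = 150L,
                                 n_chromosomes = 3L, chrom_length = 200000L,
                                 cs_jitter_sd = 0, decoy_fraction = 0.08)))

noiseless_run <- function() fixture("noiseless_run", function()
  run_pa_pipeline(noiseless_sim()))

# study-scale dataset for parameter recovery (~20,000 sites)
recovery_sim <- function() fixture("recovery_sim", function()
  simulate_pa_dataset(sim_config(seed = 42L, n_genes = 7700L,
                                 n_chromosomes = 8L,
                                 chrom_length = 3400000L)))

recovery_run <- function() fixture("recovery_run", function()
  run_pa_pipeline(recovery_sim()))

# random genome string at given GC
random_genome <- function(n, gc = 0.364, seed = 1) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# binomial 3-standard-error band check
expect_within_3se <- function(observed, p, n, label = "") {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(observed - p), 3 * se + 1e-12,
            label = sprintf("%s observed=%.4f expected=%.4f 3se=%.4f",
                            label, observed, p, 3 * se))
}
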