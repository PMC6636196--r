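## Shared fixtures: the default simulated scenario and its pipeline run are
## computed once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

scenario_seed <- 101L

default_sim <- function(seed = scenario_seed) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- plant_scaffolds(sim_config(seed = seed))
  .fixture_cache[[key]]
}

default_run <- function(seed = scenario_seed) {
  key <- paste0("run", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- default_sim(seed)
    .fixture_cache[[key]] <- run_pipeline(run_config_from_sim(sim))
  }
  .fixture_cache[[key]]
}

## A small scenario for toggle/determinism tests.
mini_config <- function(seed = 5L) {
  sim_config(seed = seed,
             scaffold_length = c(80000L, 25000L),
             n_scaffolds = 2L,
             n_functional = c(kappa = 2L, beta = 1L, outside = 2L),
             n_pseudogene = c(kappa = 1L),
             n_partial = c(outside = 1L),
             n_recombinants = 0L)
}

## Match recovered models to planted truth loci by interval overlap.
match_truth <- function(models, truth) {
  models$truth_id <- NA_character_
  for (i in seq_len(nrow(models))) {
    cand <- truth[truth$scaffold_id == models$scaffold_id[i] &
                    truth$start < models$g_end[i] &
                    truth$end > models$g_start[i], ]
    if (nrow(cand) == 1L) models$truth_id[i] <- cand$locus_id
  }
  merge(models, truth, by.x = "truth_id", by.y = "locus_id")
}

random_protein <- function(n, seed = 1L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Back-translate a protein with arbitrary (first listed) codons.
backtranslate_simple <- function(prot) {
  tab <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
           E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
           M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
           Y = "TAT", V = "GTT")
  paste(tab[strsplit(prot, "")[[1]]], collapse = "")
}
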