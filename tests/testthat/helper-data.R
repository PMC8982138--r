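# Builders for small deterministic datasets used across the tests.

tiny_counts <- function() {
  count_table(matrix(c(5, 2, 10, 3, 15, 5), 2, 3,
                     dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
}

tiny_conc <- function() {
  concentration_table(matrix(c(10, 2, 20, 3), 2, 2,
                             dimnames = list(c("s1", "s2"), c("A", "B"))))
}

tiny_paired <- function() align_tables(tiny_counts(), tiny_conc())

# Directly assemble a paired dataset, bypassing align_tables; used for the
# degenerate qobs = q case, which the model accepts but the aligner rejects.
manual_paired <- function(W, V) {
  counts <- count_table(W)
  conc <- concentration_table(V)
  structure(list(counts = counts, conc = conc, qobs = ncol(V),
                 taxon_perm = seq_len(ncol(W))),
            class = "paired_abundance")
}

quick_mcmc <- function(seed = 7, chains = 2) {
  mcmc_config(chains = chains, warmup_iters = 300, total_iters = 600,
              seed = seed)
}
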