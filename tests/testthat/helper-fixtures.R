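# Shared in-code fixtures.

# Deterministic toy reads with chosen qualities.
toy_reads <- function() {
  sequence_reads(
    read_id = paste0("r", 1:5),
    seq = c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGT"),
    qual = list(rep(40L, 8), rep(40L, 8), rep(40L, 8), rep(40L, 8),
                rep(10L, 8)))
}

# Small seeded synthetic read set exercising all six frames, with junk
# and sequencing errors; returns reads plus planted clone table.
small_synthetic_reads <- function(n = 400, seed = 11,
                                  per_base_error = 0.002,
                                  fraction_junk_reads = 0.05) {
  sim <- sample_loops(positive_library_spec(n_reads = n, seed = seed))
  reads <- embed_and_sequence(
    sim$clones,
    read_model(per_base_error = per_base_error,
               fraction_junk_reads = fraction_junk_reads),
    seed = seed + 1)
  list(reads = reads, clones = sim$clones, manifest = sim$manifest)
}

default_inhibitor_grid <- c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)
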