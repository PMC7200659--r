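# Shared fixtures: built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 11, ...) {
  synth_config(n_chrom = 1, chrom_len = 200000, n_genes = 40, n_tes = 20,
               n_other = 5, target_gene_count = 15, seed = seed, ...)
}

# A small simulated experiment with effects, reused across test files.
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- small_config()
    genome <- build_toy_genome(cfg)
    sim <- suppressMessages(simulate_counts(genome, cfg))
    .fixture_env$sim <- list(cfg = cfg, genome = genome, sim = sim)
  }
  .fixture_env$sim
}

# The DMP pipeline fitted on the shared simulation.
shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    s <- shared_sim()
    .fixture_env$fit <- suppressMessages(
      dmp_pipeline(s$sim$counts, s$sim$design)
    )
  }
  .fixture_env$fit
}

truth_keys <- function(truth) paste(truth$induced_sites$chrom,
                                    truth$induced_sites$pos)

# Tiny deterministic count table for I/O tests.
tiny_counts <- function() {
  tibble::tibble(
    sample_id = "s1",
    chrom = c("chr1", "chr1", "chr2", "ChrC", "ChrC"),
    pos = c(101L, 205L, 50L, 10L, 20L),
    strand = c("+", "-", "+", "+", "+"),
    context = c("CG", "CHH", "CHG", "CG", "CHH"),
    n_meth = c(8L, 0L, 3L, 1L, 0L),
    n_unmeth = c(2L, 10L, 7L, 99L, 100L)
  )
}

make_annotation <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(2000L, 4500L, 9000L, 500L),
    end = c(4000L, 4800L, 9100L, 900L),
    strand = "+",
    feature_id = c("geneA", "te1", "ncrna1", "geneB"),
    subtype = c("gene", "transposable_element", "ncRNA", "gene"),
    feature_class = c("genic", "TE_related", "other", "genic")
  ) |>
    memsig:::extend_genes(chrom_lengths = c(chr1 = 20000L, chr2 = 20000L))
}
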