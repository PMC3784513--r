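# shared fixtures, built in code

# random uppercase sequence with roughly uniform composition
random_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a 64-row mutated-count tibble from a named vector (zeros elsewhere)
m_table <- function(...) {
  v <- c(...)
  mt <- enumerate_motifs()
  m <- stats::setNames(rep(0L, 64), mt$motif)
  m[names(v)] <- as.integer(v)
  tibble::tibble(motif = mt$motif, m = unname(m))
}

# a 64-row site-count tibble; `default` fills unlisted motifs
t_table <- function(..., default = 0L) {
  v <- c(...)
  mt <- enumerate_motifs()
  t <- stats::setNames(rep(as.integer(default), 64), mt$motif)
  t[names(v)] <- as.integer(v)
  tibble::tibble(motif = mt$motif, t = unname(t))
}

# small end-to-end synthetic dataset: genome + fractions table
synth_fraction_table <- function(seed = 42, genome_length = 30000,
                                 mu = 2e-3, ...) {
  cfg <- synth_config(genome_length = genome_length, mu = mu, seed = seed, ...)
  gen <- make_genome(cfg)
  ds <- deduplicate(simulate_mutations(gen$genome, NULL, NULL, cfg))
  tt <- count_genome_motifs(gen$genome)
  m <- motif_mutation_counts(annotate_contexts(ds, gen$genome))
  motif_fractions(m, tt)
}
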