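toy_multi_sample <- function() {
  mutation_dataset(tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 100L, 200L, 200L, 300L, 400L, 400L, 400L),
    ref = "G", alt = "T",
    sample = c("S1", "S2", "S1", "S1", "S3", "S1", "S2", "S3"),
    tissue = c("lung", "skin", "lung", "lung", "lung", "lung", "skin", "lung")))
}

test_that("recurrence requires hits from distinct samples", {
  ds <- toy_multi_sample()
  rec <- find_recurrent_sites(ds)
  # chr1:100 (S1,S2) and chr1:400 (S1,S2,S3) are recurrent;
  # chr1:200 is S1 twice, chr1:300 once
  expect_setequal(rec$pos, c(100L, 400L))
  expect_equal(rec$n_samples[rec$pos == 400], 3)
  # raising the threshold can only shrink the set
  rec3 <- find_recurrent_sites(ds, min_samples = 3)
  expect_equal(rec3$pos, 400L)
  # all-unique coordinates: nothing recurs
  uni <- mutation_dataset(tibble::tibble(
    chrom = "chr1", pos = 1:5 * 10L, ref = "G", alt = "T",
    sample = paste0("S", 1:5)))
  expect_equal(nrow(find_recurrent_sites(uni)), 0)
  no_lab <- mutation_dataset(tibble::tibble(
    chrom = "chr1", pos = c(1L, 1L), ref = "G", alt = "T"))
  expect_error(find_recurrent_sites(no_lab), "sample labels")
})

test_that("recurrent coordinates count once toward their motif", {
  g <- c(chr1 = paste(rep("TTCGAA", 100), collapse = ""))
  ds <- mutation_dataset(tibble::tibble(
    chrom = "chr1", pos = c(4L, 4L, 4L, 10L, 10L),
    ref = "G", alt = "T",
    sample = c("S1", "S2", "S3", "S1", "S2")))
  rec <- find_recurrent_sites(ds, genome = g)
  d <- recurrence_counts(rec)
  expect_equal(d$d[d$motif == "CGAA"], 2)  # two coordinates, not five hits
  expect_equal(sum(d$d), 2)
})

test_that("enrichment matches hand arithmetic and its invariants", {
  d <- dplyr::rename(m_table(AGAA = 2, AGAC = 2), d = "m")
  t <- t_table(AGAA = 100, AGAC = 300)
  e <- motif_enrichment(d, t)
  expect_equal(e$E[e$motif == "AGAA"], 2.0)
  expect_equal(e$E[e$motif == "AGAC"], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(e$D), 1)
  # d proportional to t: all defined E equal 1
  mt <- enumerate_motifs()
  d2 <- tibble::tibble(motif = mt$motif, d = 3L * seq_len(64))
  t2 <- tibble::tibble(motif = mt$motif, t = 7L * seq_len(64))
  e2 <- motif_enrichment(d2, t2)
  expect_equal(e2$E, rep(1, 64))
  # rescaling denominators leaves E unchanged
  t3 <- tibble::tibble(motif = mt$motif, t = t2$t * 11L)
  expect_equal(motif_enrichment(d2, t3)$E, e2$E)
  zero_d <- tibble::tibble(motif = mt$motif, d = 0L)
  expect_error(motif_enrichment(zero_d, t2), "sum d = 0")
})

test_that("enrichment is near one under context-independent recurrence", {
  cfg <- synth_config(genome_length = 200000, gc = 0.41, seed = 12)
  gen <- make_genome(cfg)
  tt <- count_genome_motifs(gen$genome)
  chars <- strsplit(gen$genome[["chr1"]], "")[[1]]
  eligible <- which(chars %in% c("G", "C"))
  set.seed(12)
  pick <- sample(eligible, 2000)
  ref2 <- rep(chars[pick], each = 2)
  ds <- mutation_dataset(tibble::tibble(
    chrom = "chr1", pos = rep(pick, each = 2), ref = ref2,
    alt = ifelse(ref2 == "G", "T", "A"),
    sample = rep(c("S1", "S2"), times = 2000)))
  rec <- find_recurrent_sites(ds, genome = gen$genome)
  e <- motif_enrichment(recurrence_counts(rec), tt)
  wmean <- sum(e$d * e$E, na.rm = TRUE) / sum(e$d)
  expect_equal(wmean, 1, tolerance = 0.05)
})

test_that("tissue shares normalize by catalog size and sum to one", {
  out <- tissue_share(tibble::tibble(tissue = c("a", "b"), t_n = c(4, 1)),
                      tibble::tibble(tissue = c("a", "b"), c_n = c(100, 100)))
  expect_equal(out$share, c(0.8, 0.2))
  expect_equal(sum(out$share), 1)
  sym <- tissue_share(
    tibble::tibble(tissue = letters[1:8], t_n = 5),
    tibble::tibble(tissue = letters[1:8], c_n = 1000))
  expect_equal(sym$percent, rep(12.5, 8))
  single <- tissue_share(tibble::tibble(tissue = "a", t_n = 3),
                         tibble::tibble(tissue = "a", c_n = 10))
  expect_equal(single$share, 1)
  expect_warning(
    mix <- tissue_share(
      tibble::tibble(tissue = c("a", "b"), t_n = c(4, 1)),
      tibble::tibble(tissue = c("a", "b"), c_n = c(100, 0))),
    "zero total")
  expect_equal(mix$tissue, "a")
})

test_that("pathway ranking scores samples with at least one hit", {
  sg <- tibble::tibble(
    sample = c("P1", "P1", "P2", "P3"),
    tissue = c("lung", "lung", "lung", "skin"),
    gene = c("g1", "g5", "g9", "g1"))
  sets <- list(pwA = c("g1", "g2"), pwB = c("g7", "g8"))
  out <- pathway_hit_ranking(sg, sets)
  lungA <- out[out$pathway == "pwA" & out$tissue == "lung", ]
  expect_equal(lungA$percent, 50)           # P1 hits, P2 does not
  skinA <- out[out$pathway == "pwA" & out$tissue == "skin", ]
  expect_equal(skinA$percent, 100)
  expect_true(all(out$percent[out$pathway == "pwB"] == 0))
  expect_equal(unique(out$combined_score[out$pathway == "pwA"]), 75)
  gh <- attr(out, "gene_hits")
  expect_equal(gh$n_samples_hit[gh$gene == "g1"], 2)
  expect_error(pathway_hit_ranking(sg, list()), "empty")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdesc\tg1\tg2", "pwB\tdesc\tg3"), path)
  sets <- read_gmt(path)
  expect_equal(sets$pwA, c("g1", "g2"))
  expect_equal(sets$pwB, "g3")
})
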