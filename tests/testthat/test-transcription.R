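# one + strand and one - strand gene on a deterministic genome
toy_gene_setup <- function() {
  set.seed(41)
  genome <- c(chr1 = random_seq(3000))
  genes <- gene_models(tibble::tibble(
    gene = c("gp", "gp", "gm", "gm"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    start = c(201L, 501L, 1201L, 1601L),
    end = c(400L, 700L, 1400L, 1800L)))
  list(genome = genome, genes = genes)
}

test_that("gene models validate their exon structure", {
  expect_error(gene_models(tibble::tibble(
    gene = "g", chrom = "chr1", strand = "+",
    start = c(1L, 50L), end = c(100L, 150L))), "overlapping exons")
  expect_error(gene_models(tibble::tibble(gene = "g", chrom = "chr1")),
               "missing column")
})

test_that("junction boundaries follow transcription direction", {
  s <- toy_gene_setup()
  jn <- junctions(s$genes)
  jp <- jn[jn$gene == "gp", ]
  expect_equal(jp$boundary[jp$type == "donor"], 400L)
  expect_equal(jp$boundary[jp$type == "acceptor"], 501L)
  jm <- jn[jn$gene == "gm", ]
  # minus strand: donor at the genomic start of the downstream exon
  expect_equal(jm$boundary[jm$type == "donor"], 1601L)
  expect_equal(jm$boundary[jm$type == "acceptor"], 1400L)
  # single-exon genes contribute nothing
  single <- gene_models(tibble::tibble(
    gene = "s1", chrom = "chr1", strand = "+", start = 1L, end = 100L))
  expect_equal(nrow(junctions(single)), 0)
})

test_that("orientation follows the strand carrying the mutated guanine", {
  s <- toy_gene_setup()
  chars <- strsplit(s$genome[["chr1"]], "")[[1]]
  gpos <- which(chars == "G"); cpos <- which(chars == "C")
  apos <- which(chars == "A")
  in_plus <- function(p) p >= 201 & p <= 700
  pg <- gpos[in_plus(gpos)][1]; pc <- cpos[in_plus(cpos)][1]
  pa <- apos[in_plus(apos)][1]
  ds <- mutation_dataset(tibble::tibble(
    chrom = "chr1", pos = c(pg, pc, pa, 2900L),
    ref = c("G", "C", "A", chars[2900]),
    alt = c("T", "T", "C", setdiff(c("A", "C", "G", "T"), chars[2900])[1])))
  out <- orient_mutations(ds, s$genes)
  expect_equal(out$orientation[1], "NT")  # G on the sense strand of a + gene
  expect_equal(out$orientation[2], "T")   # reverse-strand G: template strand
  expect_equal(out$orientation[3], "unoriented")
  expect_equal(out$orientation[4], "intergenic")
})

test_that("overlapping genes on opposite strands are ambiguous", {
  genome <- c(chr1 = paste(rep("ATGGCC", 100), collapse = ""))
  genes <- gene_models(tibble::tibble(
    gene = c("f", "r"), chrom = "chr1", strand = c("+", "-"),
    start = c(10L, 50L), end = c(200L, 250L)))
  ds <- mutation_dataset(tibble::tibble(
    chrom = "chr1", pos = 99L, ref = "G", alt = "A"))
  expect_equal(orient_mutations(ds, genes)$orientation, "ambiguous")
})

test_that("orientation categories partition the catalog", {
  cfg <- synth_config(genome_length = 40000, n_genes = 8, mu = 3e-3,
                      n_samples = 1, seed = 61)
  gen <- make_genome(cfg)
  gg <- make_genes(gen$genome, cfg)
  ds <- deduplicate(simulate_mutations(gg$genome, gg$genes, NULL, cfg))
  out <- orient_mutations(ds, gg$genes)
  expect_equal(sum(table(out$orientation)), nrow(ds))
  expect_setequal(setdiff(unique(out$orientation), ""),
                  intersect(c("NT", "T", "ambiguous", "intergenic",
                              "unoriented"), unique(out$orientation)))
})

test_that("mirroring gene strands swaps NT and T exactly", {
  cfg <- synth_config(genome_length = 40000, n_genes = 8, mu = 3e-3,
                      n_samples = 1, seed = 62)
  gen <- make_genome(cfg)
  gg <- make_genes(gen$genome, cfg)
  ds <- deduplicate(simulate_mutations(gg$genome, gg$genes, NULL, cfg))
  sr1 <- strand_ratio_per_motif(ds, gg$genome, gg$genes)
  flipped <- gg$genes
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  sr2 <- strand_ratio_per_motif(ds, gg$genome, gene_models(flipped))
  expect_equal(sr1$nt, sr2$t)
  expect_equal(sr1$t, sr2$nt)
  both <- !is.na(sr1$r) & !is.na(sr2$r) & sr1$nt > 0
  expect_equal(sr1$r[both], 1 / sr2$r[both])
})

test_that("splice profile positions follow the declared convention", {
  s <- toy_gene_setup()
  # + strand donor at 400: last exonic base 400 -> -1, first intronic 401 -> +1
  # - strand donor at 1601: first intronic base is 1600 -> +1
  chars <- strsplit(s$genome[["chr1"]], "")[[1]]
  mk <- function(pos) {
    r <- chars[pos]
    tibble::tibble(chrom = "chr1", pos = as.integer(pos), ref = r,
                   alt = ifelse(r == "A", "G", "A"))
  }
  ds <- mutation_dataset(dplyr::bind_rows(mk(401), mk(400), mk(1600), mk(502)))
  prof <- splice_position_profile(ds, s$genes, window = 20)
  donor <- prof[prof$type == "donor", ]
  expect_equal(donor$count[donor$position == 1], 2)   # 401 (+) and 1600 (-)
  expect_equal(donor$count[donor$position == -1], 1)  # 400
  acceptor <- prof[prof$type == "acceptor", ]
  expect_equal(acceptor$count[acceptor$position == 2], 1)  # 502 on + strand
  expect_equal(sum(prof$count), 4)
  # no mutations: all-zero profile of the right shape
  empty <- splice_position_profile(ds[0, ], s$genes, window = 20)
  expect_equal(sum(empty$count), 0)
  expect_equal(nrow(empty), 2 * 40)
})

test_that("profile total never exceeds the catalog size", {
  cfg <- synth_config(genome_length = 30000, n_genes = 6, mu = 4e-3,
                      n_samples = 1, seed = 63)
  gen <- make_genome(cfg)
  gg <- make_genes(gen$genome, cfg)
  ds <- deduplicate(simulate_mutations(gg$genome, gg$genes, NULL, cfg))
  prof <- splice_position_profile(ds, gg$genes, window = 20)
  expect_lte(sum(prof$count), nrow(ds) + attr(prof, "ties"))
})

test_that("junction conservation is exact at engineered canonical sites", {
  cfg <- synth_config(genome_length = 50000, n_genes = 10, seed = 64)
  gen <- make_genome(cfg)
  gg <- make_genes(gen$genome, cfg)
  jc <- junction_conservation(gg$genome, gg$genes, window = 25)
  val <- function(tp, p, b) {
    jc$fraction[jc$type == tp & jc$position == p & jc$base == b]
  }
  expect_equal(val("donor", 1, "G"), 1)
  expect_equal(val("donor", 2, "T"), 1)
  expect_equal(val("acceptor", -2, "A"), 1)
  expect_equal(val("acceptor", -1, "G"), 1)
  # deep intron interior stays near the background composition
  interior <- jc[jc$type == "donor" & jc$position == 20, ]
  expect_true(all(interior$fraction < 0.55))
  expect_equal(sum(interior$fraction), 1, tolerance = 1e-12)
})

test_that("a single junction yields a degenerate 0/1 matrix", {
  genome <- c(chr1 = paste(rep("ACGT", 200), collapse = ""))
  genes <- gene_models(tibble::tibble(
    gene = "g", chrom = "chr1", strand = "+",
    start = c(101L, 301L), end = c(200L, 400L)))
  jc <- junction_conservation(genome, genes, window = 10)
  expect_true(all(jc$fraction %in% c(0, 1)))
  expect_true(all(jc$conservation == 1))
})

test_that("gene model readers agree on the same structure", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstrand\texon_starts\texon_ends",
               "gA\tchr1\t+\t101,301\t200,400"), tsv)
  from_tsv <- read_genes_tsv(tsv)
  expect_equal(nrow(from_tsv), 2)
  expect_equal(from_tsv$start, c(101L, 301L))
  bed <- withr::local_tempfile(fileext = ".bed")
  # BED12: chromStart 0-based; two blocks of 100 starting at 100 and 300
  writeLines(paste(c("chr1", 100L, 400L, "gA", 0L, "+", 100L, 400L, "0",
                     2L, "100,100", "0,200"), collapse = "\t"), bed)
  from_bed <- read_genes_bed12(bed)
  expect_equal(from_bed$start, from_tsv$start)
  expect_equal(from_bed$end, from_tsv$end)
})
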