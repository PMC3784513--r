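#' Construct gene models from an exon table
#'
#' @param df Data frame with columns `gene`, `chrom`, `strand` (+/-),
#'   `start`, `end` (1-based inclusive exon intervals). Exons of a gene must
#'   not overlap; rows are sorted by genomic position within gene.
#' @return `gene_models` tibble.
#' @export
gene_models <- function(df) {
  need <- c("gene", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  out <- tibble::as_tibble(df[, need])
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  stopifnot(all(out$strand %in% c("+", "-")), all(out$start <= out$end))
  out <- dplyr::arrange(out, .data$gene, .data$start)
  bad <- dplyr::summarise(dplyr::group_by(out, .data$gene),
                          ovl = any(.data$start[-1] <= .data$end[-dplyr::n()]),
                          .groups = "drop")
  if (any(bad$ovl, na.rm = TRUE)) {
    stop("overlapping exons in gene(s): ",
         paste(bad$gene[which(bad$ovl)], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("gene_models", class(out))
  out
}

#' Read gene models from BED12
#'
#' @param path BED12 file; block fields give the exon structure.
#' @return `gene_models` tibble.
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(con = path, format = "bed")
  if (is.null(gr$blocks)) stop("not a BED12 file (no block fields)", call. = FALSE)
  rows <- purrr::map_dfr(seq_along(gr), function(i) {
    blocks <- gr$blocks[[i]]
    # blocks are relative to the chromStart of the record
    tibble::tibble(
      gene = gr$name[i],
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      start = GenomicRanges::start(gr)[i] + IRanges::start(blocks) - 1L,
      end = GenomicRanges::start(gr)[i] + IRanges::end(blocks) - 1L
    )
  })
  gene_models(rows)
}

#' Read gene models from a simplified gene TSV
#'
#' Columns: `gene`, `chrom`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated 1-based inclusive coordinates).
#'
#' @param path TSV file.
#' @return `gene_models` tibble.
#' @export
read_genes_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  rows <- purrr::pmap_dfr(raw, function(gene, chrom, strand, exon_starts,
                                        exon_ends, ...) {
    tibble::tibble(gene = gene, chrom = chrom, strand = strand,
                   start = as.integer(strsplit(exon_starts, ",")[[1]]),
                   end = as.integer(strsplit(exon_ends, ",")[[1]]))
  })
  gene_models(rows)
}

#' Splice junctions of a gene model set
#'
#' Every internal exon boundary defines one donor (exon to intron in
#' transcription direction) and one acceptor (intron to exon). Single-exon
#' genes contribute nothing; first and last exons contribute only their
#' internal boundary.
#'
#' @param genes `gene_models` tibble.
#' @return Tibble with columns `gene`, `chrom`, `strand`, `type`
#'   (donor/acceptor) and `boundary`, the genomic coordinate of the exonic
#'   base flanking the junction (last exonic base for donors, first exonic
#'   base for acceptors).
#' @export
junctions <- function(genes) {
  purrr::map_dfr(split(tibble::as_tibble(genes), genes$gene), function(gx) {
    gx <- gx[order(gx$start), ]
    k <- nrow(gx)
    if (k < 2) return(NULL)
    if (gx$strand[1] == "+") {
      don <- gx$end[-k]       # last exonic base before each intron
      acc <- gx$start[-1]     # first exonic base after each intron
    } else {
      don <- gx$start[-1]     # transcription runs right-to-left
      acc <- gx$end[-k]
    }
    tibble::tibble(
      gene = gx$gene[1], chrom = gx$chrom[1], strand = gx$strand[1],
      type = rep(c("donor", "acceptor"), c(k - 1, k - 1)),
      boundary = c(don, acc))
  })
}

# Signed transcription-oriented position of genomic coordinate g relative to
# a junction. Convention: no position 0; for donors the last exonic base is
# -1 and the first intronic base is +1 (canonical G,T at +1,+2); for
# acceptors intronic bases are negative approaching the junction (canonical
# A,G at -2,-1) and exonic bases positive (+1 = first exonic base).
signed_position <- function(g, boundary, strand, type) {
  n <- max(length(g), length(boundary))
  g <- rep_len(g, n); boundary <- rep_len(boundary, n)
  strand <- rep_len(strand, n); type <- rep_len(type, n)
  d <- ifelse(strand == "+", g - boundary, boundary - g)
  ifelse(type == "donor",
         ifelse(d > 0, d, d - 1),    # boundary = last exonic base
         ifelse(d >= 0, d + 1, d))   # boundary = first exonic base
}

# inverse: genomic coordinate of signed position p relative to a junction
position_genomic <- function(p, boundary, strand, type) {
  n <- max(length(p), length(boundary))
  p <- rep_len(p, n); boundary <- rep_len(boundary, n)
  strand <- rep_len(strand, n); type <- rep_len(type, n)
  d <- ifelse(type == "donor",
              ifelse(p > 0, p, p + 1),
              ifelse(p > 0, p - 1, p))
  ifelse(strand == "+", boundary + d, boundary - d)
}

#' Orient mutations relative to transcription
#'
#' Classifies every record by where its mutated guanine lies relative to
#' transcription: `NT` when the canonical motif's G is on the non-transcribed
#' (sense) strand of the single gene containing the record, `T` when it is on
#' the template strand, `ambiguous` when overlapping genes disagree on
#' strand, `intergenic` outside all genes, and `unoriented` for records
#' without a canonical G-strand (reference base A or T).
#'
#' @param ds `mut_ds` tibble.
#' @param genes `gene_models` tibble.
#' @return The input with an `orientation` column.
#' @export
orient_mutations <- function(ds, genes) {
  spans <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(genes), .data$gene, .data$chrom,
                    .data$strand),
    start = min(.data$start), end = max(.data$end), .groups = "drop")
  gr_genes <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start, spans$end))
  gr_mut <- GenomicRanges::GRanges(
    ds$chrom, IRanges::IRanges(ds$pos, ds$pos))
  hits <- GenomicRanges::findOverlaps(gr_mut, gr_genes)
  hit_strand <- split(spans$strand[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
  orientation <- rep("intergenic", nrow(ds))
  for (q in names(hit_strand)) {
    i <- as.integer(q)
    st <- unique(hit_strand[[q]])
    if (length(st) > 1) {
      orientation[i] <- "ambiguous"
    } else if (!ds$ref[i] %in% c("G", "C")) {
      orientation[i] <- "unoriented"
    } else {
      g_strand <- if (ds$ref[i] == "G") "+" else "-"
      orientation[i] <- if (g_strand == st) "NT" else "T"
    }
  }
  out <- ds
  out$orientation <- orientation
  restore_mut_ds(out, ds)
}

#' Per-motif transcription-strand asymmetry ratio r
#'
#' Tallies, per canonical motif, mutations whose P2 guanine lies on the
#' non-transcribed vs the transcribed strand of protein-coding genes, and
#' their ratio r = NT / T (NA-flagged when T = 0).
#'
#' @param ds `mut_ds` tibble (deduplicated).
#' @param genome Genome input.
#' @param genes `gene_models` tibble.
#' @return Tibble with `motif`, `nt`, `t`, `r`, `ln_r`; class
#'   `strand_ratio_tbl`.
#' @export
strand_ratio_per_motif <- function(ds, genome, genes) {
  ann <- annotate_contexts(ds, genome)
  ann <- orient_mutations(ann, genes)
  mt <- enumerate_motifs()
  keep <- ann$status == "ok" & ann$orientation %in% c("NT", "T")
  sub <- ann[keep, ]
  nt <- table(factor(sub$context[sub$orientation == "NT"], levels = mt$motif))
  tt <- table(factor(sub$context[sub$orientation == "T"], levels = mt$motif))
  out <- tibble::tibble(motif = mt$motif,
                        nt = as.integer(nt), t = as.integer(tt))
  out$r <- ifelse(out$t > 0, out$nt / out$t, NA_real_)
  out$ln_r <- log(out$r)
  class(out) <- c("strand_ratio_tbl", class(out))
  out
}

#' Positional profile of mutations around splice junctions
#'
#' Counts mutations at signed transcription-oriented positions within a
#' window of donor and acceptor junctions. A mutation inside the window of
#' two junctions (short exons or introns) is counted at the nearest one;
#' exact ties are counted at both and flagged.
#'
#' @param ds `mut_ds` tibble.
#' @param genes `gene_models` tibble (>= 1 intron).
#' @param window Half-window in nucleotides (default 20).
#' @return Tibble with `type` (donor/acceptor), `position` (-window..window,
#'   no 0), `count`; attribute `ties` = number of tie-counted mutations;
#'   class `splice_profile`.
#' @export
splice_position_profile <- function(ds, genes, window = 20) {
  jn <- junctions(genes)
  if (nrow(jn) == 0) stop("gene models contain no introns", call. = FALSE)
  recs <- tibble::as_tibble(ds)
  recs$.id <- seq_len(nrow(recs))
  assign <- purrr::map_dfr(seq_len(nrow(jn)), function(j) {
    same <- recs[recs$chrom == jn$chrom[j], ]
    if (nrow(same) == 0) return(NULL)
    p <- signed_position(same$pos, jn$boundary[j], jn$strand[j], jn$type[j])
    sel <- abs(p) <= window
    if (!any(sel)) return(NULL)
    tibble::tibble(.id = same$.id[sel], type = jn$type[j],
                   position = p[sel], dist = abs(p[sel]))
  })
  ties <- 0L
  counts <- tibble::tibble(type = character(), position = integer())
  if (nrow(assign) > 0) {
    nearest <- dplyr::filter(dplyr::group_by(assign, .data$.id),
                             .data$dist == min(.data$dist))
    nearest <- dplyr::ungroup(nearest)
    ties <- sum(table(nearest$.id) > 1)
    counts <- nearest[, c("type", "position")]
  }
  grid <- tidyr::expand_grid(
    type = c("donor", "acceptor"),
    position = setdiff(seq(-window, window), 0L))
  tallied <- dplyr::summarise(dplyr::group_by(counts, .data$type,
                                              .data$position),
                              count = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(grid, tallied, by = c("type", "position"))
  out$count[is.na(out$count)] <- 0L
  attr(out, "ties") <- ties
  attr(out, "window") <- window
  class(out) <- c("splice_profile", class(out))
  out
}

#' Base conservation around splice junctions
#'
#' For every signed position within a window of each unique donor and
#' acceptor junction, tabulates the fraction of junctions carrying each base
#' (read in transcription orientation). Position conservation is the maximum
#' base fraction.
#'
#' @param genome Genome input.
#' @param genes `gene_models` tibble.
#' @param window Half-window (default 25).
#' @return Tibble with `type`, `position`, `base`, `fraction`,
#'   `conservation` (per-position max fraction, repeated over bases), and
#'   `n_junctions`; class `junction_conservation`.
#' @export
junction_conservation <- function(genome, genes, window = 25) {
  genome <- as_genome(genome)
  jn <- dplyr::distinct(junctions(genes)[, c("chrom", "strand", "type",
                                             "boundary")])
  if (nrow(jn) == 0) stop("gene models contain no introns", call. = FALSE)
  positions <- setdiff(seq(-window, window), 0L)
  out <- purrr::map_dfr(c("donor", "acceptor"), function(tp) {
    sub <- jn[jn$type == tp, ]
    if (nrow(sub) == 0) return(NULL)
    purrr::map_dfr(positions, function(p) {
      g <- position_genomic(p, sub$boundary, sub$strand, tp)
      len <- nchar(genome[sub$chrom])
      valid <- g >= 1 & g <= len
      base <- rep(NA_character_, nrow(sub))
      base[valid] <- substring(genome[sub$chrom[valid]], g[valid], g[valid])
      flip <- valid & sub$strand == "-"
      base[flip] <- chartr("ACGTN", "TGCAN", base[flip])
      base <- base[!is.na(base) & base != "N"]
      nj <- length(base)
      if (nj == 0) return(NULL)
      tab <- table(factor(base, levels = c("A", "C", "G", "T")))
      tibble::tibble(type = tp, position = p,
                     base = names(tab),
                     fraction = as.numeric(tab) / nj,
                     conservation = max(as.numeric(tab)) / nj,
                     n_junctions = nj)
    })
  })
  class(out) <- c("junction_conservation", class(out))
  out
}
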