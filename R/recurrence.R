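#' Coordinates recurrently mutated across samples
#'
#' A coordinate is recurrent when at least `min_samples` distinct samples
#' carry a substitution there, pooling across datasets; the alternate allele
#' is ignored (coordinate-level counting). A coordinate counts once no matter
#' how many samples beyond the threshold hit it.
#'
#' @param ds `mut_ds` tibble with a `sample` column.
#' @param genome Optional genome; when given, each recurrent coordinate is
#'   annotated with its canonical motif.
#' @param min_samples Minimum number of distinct samples (default 2).
#' @return Tibble with one row per recurrent coordinate: `chrom`, `pos`,
#'   `ref`, `n_samples`, `tissues` (list column of tissue labels), and
#'   `motif` when a genome is supplied.
#' @export
find_recurrent_sites <- function(ds, genome = NULL, min_samples = 2) {
  if (all(is.na(ds$sample))) {
    stop("sample labels are required to detect recurrence", call. = FALSE)
  }
  per_site <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ds), .data$chrom, .data$pos),
    ref = dplyr::first(.data$ref),
    n_samples = dplyr::n_distinct(.data$sample),
    tissues = list(unique(.data$tissue)),
    .groups = "drop")
  out <- per_site[per_site$n_samples >= min_samples, ]
  if (!is.null(genome)) {
    out$motif <- canonical_context(genome, out$chrom, out$pos, out$ref,
                                   on_mismatch = "na")
  }
  out
}

#' Per-motif recurrent-coordinate counts d_i
#'
#' @param sites Output of [find_recurrent_sites()] with a `motif` column.
#' @return 64-row tibble with columns `motif`, `d`. Recurrent coordinates
#'   without a canonical motif (A:T sites, missing context) are excluded and
#'   reported in the `excluded` attribute.
#' @export
recurrence_counts <- function(sites) {
  if (!"motif" %in% names(sites)) {
    stop("sites lack motif annotation; pass a genome to find_recurrent_sites()",
         call. = FALSE)
  }
  mt <- enumerate_motifs()
  tab <- table(factor(sites$motif, levels = mt$motif))
  out <- tibble::tibble(motif = mt$motif, d = as.integer(tab))
  attr(out, "excluded") <- sum(is.na(sites$motif))
  out
}

#' Motif enrichment among recurrent coordinates
#'
#' E_i = D_i / T_i with D_i = d_i / sum(d) the share of recurrent
#' coordinates falling in motif i and T_i = t_i / sum(t) the motif's share
#' of mappable genomic sites. When substitutions are independent of flanking
#' sequence, E_i is expected to approximate 1 for every class.
#'
#' @param d 64-row tibble with columns `motif`, `d`
#'   (see [recurrence_counts()]).
#' @param t 64-row tibble with columns `motif`, `t`
#'   (see [count_genome_motifs()]).
#' @return Tibble with `motif`, `d`, `t`, `D`, `T`, `E` (`E` NA-flagged where
#'   t_i = 0); class `enrichment_tbl`.
#' @export
motif_enrichment <- function(d, t) {
  if (sum(d$d) == 0) stop("no recurrent coordinates (sum d = 0)", call. = FALSE)
  out <- dplyr::left_join(d[, c("motif", "d")], t[, c("motif", "t")],
                          by = "motif")
  out$D <- out$d / sum(out$d)
  out$T <- out$t / sum(out$t)
  out$E <- ifelse(out$t > 0, out$D / out$T, NA_real_)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Tissue share of recurrent hits, normalized for catalog size
#'
#' For each tissue n, s_n = t_n / c_n divides the number of recurrent hits at
#' the selected motif set (t_n) by the tissue's total substitution count
#' (c_n), and the share S = s_n / sum(s_n) rescales to unit total. With
#' identical t_n and c_n everywhere, each of k tissues contributes 1/k.
#'
#' @param hits Tibble with columns `tissue`, `t_n` (recurrent hits).
#' @param totals Tibble with columns `tissue`, `c_n` (total substitutions).
#'   Tissues with c_n = 0 are excluded with a warning.
#' @return Tibble with `tissue`, `t_n`, `c_n`, `s_n`, `share`, `percent`.
#' @export
tissue_share <- function(hits, totals) {
  df <- dplyr::inner_join(hits, totals, by = "tissue")
  zero <- df$c_n == 0
  if (any(zero)) {
    warning("tissue(s) with zero total substitutions excluded: ",
            paste(df$tissue[zero], collapse = ", "), call. = FALSE)
    df <- df[!zero, ]
  }
  if (nrow(df) == 0) stop("no tissues with positive totals", call. = FALSE)
  df$s_n <- df$t_n / df$c_n
  df$share <- df$s_n / sum(df$s_n)
  df$percent <- 100 * df$share
  df
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("read_gmt() needs the fgsea package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' Rank pathways by how often patient samples hit them
#'
#' For every pathway and tissue, the score is the percentage of that tissue's
#' samples with at least one mutated gene in the pathway. Per-tissue scores
#' are combined into an overall ranking by their unweighted mean, and
#' per-pathway gene hit counts are retained for heatmap export.
#'
#' @param sample_genes Tibble with columns `sample`, `tissue`, `gene`: the
#'   mutated-gene list of each sample.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @return Tibble with one row per pathway-tissue pair: `pathway`, `tissue`,
#'   `n_samples`, `n_hit`, `percent`, plus the pathway-level `combined_score`
#'   (mean of per-tissue percentages) repeated across its rows; sorted by
#'   descending combined score. Attribute `gene_hits` holds a tibble
#'   (`pathway`, `gene`, `n_samples_hit`).
#' @export
pathway_hit_ranking <- function(sample_genes, gene_sets) {
  if (length(gene_sets) == 0) stop("empty gene set collection", call. = FALSE)
  stopifnot(all(c("sample", "tissue", "gene") %in% names(sample_genes)))
  samples <- dplyr::distinct(sample_genes[, c("sample", "tissue")])
  per <- purrr::imap_dfr(gene_sets, function(genes, pw) {
    hit_samples <- unique(sample_genes$sample[sample_genes$gene %in% genes])
    dplyr::summarise(
      dplyr::group_by(samples, .data$tissue),
      pathway = pw,
      n_samples = dplyr::n(),
      n_hit = sum(.data$sample %in% hit_samples),
      .groups = "drop")
  })
  per$percent <- 100 * per$n_hit / per$n_samples
  comb <- dplyr::summarise(dplyr::group_by(per, .data$pathway),
                           combined_score = mean(.data$percent),
                           .groups = "drop")
  out <- dplyr::left_join(per, comb, by = "pathway")
  out <- out[order(-out$combined_score, out$pathway, out$tissue),
             c("pathway", "tissue", "n_samples", "n_hit", "percent",
               "combined_score")]
  gh <- dplyr::distinct(sample_genes[, c("sample", "gene")])
  hits <- purrr::imap_dfr(gene_sets, function(genes, pw) {
    sub <- gh[gh$gene %in% genes, ]
    if (nrow(sub) == 0) return(NULL)
    dplyr::summarise(dplyr::group_by(sub, .data$gene),
                     pathway = pw, n_samples_hit = dplyr::n(),
                     .groups = "drop")
  })
  attr(out, "gene_hits") <- hits
  tibble::as_tibble(out)
}
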