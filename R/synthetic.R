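#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator: genome composition, gene structure,
#' mappable fraction, and the context-biased mutation model. Rates act
#' multiplicatively on a per-site baseline: a site's mutation probability is
#' mu times the product of every multiplier whose context applies (CpG motif,
#' 3'-purine motif, P4-adenine in purine-bridged motifs, a log-linear
#' ionization-potential term for DGNN motifs, the non-transcribed-strand
#' factor inside genes, and optional per-position splice targeting weights).
#' The seed is mandatory: every stochastic operation derives its RNG stream
#' from it (genome at `seed`, gene placement at `seed + 1`, mutation
#' sampling at `seed + 2`).
#'
#' @param genome_length Total length in bp (>= 100).
#' @param gc GC content in (0, 1].
#' @param n_chroms Number of sequences the length is split across.
#' @param mappable_fraction Fraction of the genome covered by the mask, via
#'   random 1 kb tiles; 1 means no mask.
#' @param n_genes Number of non-overlapping genes to place.
#' @param n_exons Exons per gene.
#' @param exon_length,intron_length Mean exon/intron lengths (bp); realized
#'   lengths are Poisson draws floored at 10 (exon) / 30 (intron).
#' @param mu Baseline per-site mutation probability.
#' @param kappa_cpg Rate multiplier for CGNN contexts.
#' @param kappa_gpr Rate multiplier for DGRN contexts (3' purine, non-CpG).
#' @param kappa_p4a Rate multiplier for NGRA contexts (purine-bridged
#'   P4-adenine).
#' @param vip_model NULL, or `list(a =, b =)`: DGNN sites get an extra factor
#'   exp(a - b * VIP(trimer)).
#' @param beta_nt Multiplier for sites whose guanine lies on the
#'   non-transcribed strand of a gene.
#' @param splice_weights NULL, or tibble with columns `type`
#'   (donor/acceptor), `position` (signed, no 0), `w`: extra factor at that
#'   junction-relative position.
#' @param n_samples Number of samples drawn independently.
#' @param tissues Tissue labels recycled across samples.
#' @param recurrent_sites NULL, or tibble `chrom`, `pos`, `k`: each
#'   coordinate is forced to be mutated in `k` randomly chosen samples.
#' @param cluster_factor,n_clusters,cluster_width Optional clustered-burst
#'   variant (off by default): `n_clusters` random centers each multiply
#'   rates by `cluster_factor` within `cluster_width` bp.
#' @param dataset Dataset label on the output.
#' @param seed Integer seed (mandatory).
#' @return A `synth_config` list.
#' @export
synth_config <- function(genome_length = 1e5, gc = 0.41, n_chroms = 1,
                         mappable_fraction = 1,
                         n_genes = 0, n_exons = 4,
                         exon_length = 150, intron_length = 300,
                         mu = 1e-3, kappa_cpg = 1, kappa_gpr = 1,
                         kappa_p4a = 1, vip_model = NULL, beta_nt = 1,
                         splice_weights = NULL,
                         n_samples = 1, tissues = "tumor",
                         recurrent_sites = NULL,
                         cluster_factor = 1, n_clusters = 0,
                         cluster_width = 1000,
                         dataset = "synthetic", seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (genome_length < 100) stop("genome_length must be >= 100", call. = FALSE)
  if (gc <= 0 || gc > 1) stop("gc must be in (0, 1]", call. = FALSE)
  mult <- c(kappa_cpg, kappa_gpr, kappa_p4a, beta_nt, cluster_factor,
            if (!is.null(splice_weights)) splice_weights$w)
  if (any(mult <= 0)) stop("all rate multipliers must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic genome and mappability mask
#'
#' Bases are drawn i.i.d. at the configured GC content (G and C each gc/2,
#' A and T each (1-gc)/2). When `mappable_fraction < 1` a mask of randomly
#' retained 1 kb tiles covering approximately that fraction is produced.
#'
#' @param cfg `synth_config`.
#' @return List with `genome` (named character vector) and `mask` (tibble
#'   chrom/start/end or NULL).
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    per <- rep(floor(cfg$genome_length / cfg$n_chroms), cfg$n_chroms)
    per[1] <- per[1] + cfg$genome_length - sum(per)
    probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2,
               G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
    genome <- vapply(per, function(len) {
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(genome) <- paste0("chr", seq_along(genome))
    mask <- NULL
    if (cfg$mappable_fraction < 1) {
      mask <- purrr::map_dfr(seq_along(genome), function(i) {
        len <- per[i]
        starts <- seq(0L, len - 1L, by = 1000L)
        keep <- stats::runif(length(starts)) < cfg$mappable_fraction
        tibble::tibble(chrom = names(genome)[i],
                       start = starts[keep],
                       end = pmin(starts[keep] + 1000L, len))
      })
    }
    list(genome = genome, mask = mask)
  })
}

#' Place synthetic genes and write canonical splice sites into the genome
#'
#' Genes are placed non-overlapping on random strands, each with the
#' configured exon/intron structure. The first two and last two bases of
#' every intron are overwritten so that, in transcription orientation, each
#' intron begins GT (donor) and ends AG (acceptor); on minus-strand genes the
#' forward sequence therefore starts CT and ends AC.
#'
#' @param genome Named character vector from [make_genome()].
#' @param cfg `synth_config`.
#' @return List with the modified `genome` and `genes` (a [gene_models()]
#'   tibble). Requests that do not fit produce fewer genes with a warning.
#' @export
make_genes <- function(genome, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_genes == 0) {
    return(list(genome = genome, genes = gene_models(
      tibble::tibble(gene = character(), chrom = character(),
                     strand = character(), start = integer(),
                     end = integer()))))
  }
  with_seed(cfg$seed + 1L, {
    rows <- list()
    gene_i <- 0
    for (ch in names(genome)) {
      len <- nchar(genome[[ch]])
      cursor <- 1L
      while (gene_i < cfg$n_genes) {
        exon_lens <- pmax(10L, stats::rpois(cfg$n_exons, cfg$exon_length))
        intron_lens <- pmax(30L, stats::rpois(cfg$n_exons - 1,
                                              cfg$intron_length))
        gap <- 100L + stats::rpois(1, 200)
        glen <- sum(exon_lens) + sum(intron_lens)
        start <- cursor + gap
        if (start + glen - 1L > len - 3L) break
        gene_i <- gene_i + 1
        strand <- sample(c("+", "-"), 1)
        ex_start <- integer(cfg$n_exons)
        pos <- start
        for (e in seq_len(cfg$n_exons)) {
          ex_start[e] <- pos
          pos <- pos + exon_lens[e]
          if (e < cfg$n_exons) pos <- pos + intron_lens[e]
        }
        ex_end <- ex_start + exon_lens - 1L
        # force canonical junction dinucleotides into the forward sequence
        for (e in seq_len(cfg$n_exons - 1)) {
          i_start <- ex_end[e] + 1L
          i_end <- ex_start[e + 1] - 1L
          if (strand == "+") {
            substr(genome[[ch]], i_start, i_start + 1L) <- "GT"
            substr(genome[[ch]], i_end - 1L, i_end) <- "AG"
          } else {
            substr(genome[[ch]], i_start, i_start + 1L) <- "CT"
            substr(genome[[ch]], i_end - 1L, i_end) <- "AC"
          }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = sprintf("gene%03d", gene_i), chrom = ch, strand = strand,
          start = ex_start, end = ex_end)
        cursor <- start + glen
      }
    }
    if (gene_i < cfg$n_genes) {
      warning("only ", gene_i, " of ", cfg$n_genes, " genes fitted",
              call. = FALSE)
    }
    list(genome = genome, genes = gene_models(dplyr::bind_rows(rows)))
  })
}

# per-position mutation probability vector for one chromosome
site_rates_chr <- function(seq, ch, genes, mask, cfg) {
  len <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- rep(cfg$mu, len)
  p[chars == "N"] <- 0
  gc_sites <- which(chars == "G" | chars == "C")
  ctx <- rep(NA_character_, len)
  if (length(gc_sites) > 0) {
    ctx[gc_sites] <- canonical_context_chr(seq, gc_sites, chars[gc_sites])
  }
  has_ctx <- !is.na(ctx)
  p1 <- substr(ctx, 1, 1); p3 <- substr(ctx, 3, 3); p4 <- substr(ctx, 4, 4)
  is_cpg <- has_ctx & p1 == "C"
  is_dgrn <- has_ctx & p1 != "C" & p3 %in% c("A", "G")
  is_ngra <- has_ctx & p3 %in% c("A", "G") & p4 == "A"
  p[is_cpg] <- p[is_cpg] * cfg$kappa_cpg
  p[is_dgrn] <- p[is_dgrn] * cfg$kappa_gpr
  p[is_ngra] <- p[is_ngra] * cfg$kappa_p4a
  if (!is.null(cfg$vip_model)) {
    dg <- which(has_ctx & p1 != "C")
    if (length(dg) > 0) {
      vip <- vip_lookup(substr(ctx[dg], 1, 3))
      p[dg] <- p[dg] * exp(cfg$vip_model$a - cfg$vip_model$b * vip)
    }
  }
  if (!is.null(genes) && nrow(genes) > 0 && cfg$beta_nt != 1) {
    spans <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(genes), .data$gene, .data$strand),
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start), end = max(.data$end), .groups = "drop")
    spans <- spans[spans$chrom == ch, ]
    for (i in seq_len(nrow(spans))) {
      idx <- spans$start[i]:spans$end[i]
      idx <- idx[idx >= 1 & idx <= len]
      # guanine on the non-transcribed (sense) strand: G in a + gene,
      # C (reverse-strand G) in a - gene
      g_nt <- if (spans$strand[i] == "+") chars[idx] == "G" else chars[idx] == "C"
      sel <- idx[g_nt & has_ctx[idx]]
      p[sel] <- p[sel] * cfg$beta_nt
    }
  }
  if (!is.null(cfg$splice_weights) && !is.null(genes) && nrow(genes) > 0) {
    jn <- junctions(genes)
    jn <- jn[jn$chrom == ch, ]
    for (i in seq_len(nrow(jn))) {
      sw <- cfg$splice_weights[cfg$splice_weights$type == jn$type[i], ]
      if (nrow(sw) == 0) next
      g <- position_genomic(sw$position, jn$boundary[i], jn$strand[i],
                            jn$type[i])
      ok <- g >= 1 & g <= len
      p[g[ok]] <- p[g[ok]] * sw$w[ok]
    }
  }
  if (cfg$n_clusters > 0 && cfg$cluster_factor != 1) {
    centers <- sample.int(len, cfg$n_clusters)
    for (cc in centers) {
      lo <- max(1L, cc - cfg$cluster_width %/% 2)
      hi <- min(len, cc + cfg$cluster_width %/% 2)
      p[lo:hi] <- p[lo:hi] * cfg$cluster_factor
    }
  }
  if (!is.null(mask)) {
    p[!mask_logical(mask, ch, len)] <- 0
  }
  if (max(p) > 1) {
    stop(sprintf("per-site rate overflow: max rate %.3g > 1; lower mu or the multipliers",
                 max(p)), call. = FALSE)
  }
  p
}

#' Simulate a context-biased substitution catalog
#'
#' Draws, independently for every sample, a per-site Bernoulli mutation at
#' probability mu times the product of the applicable context multipliers
#' (see [synth_config()]); the alternate allele is uniform over the three
#' non-reference bases. Coordinates listed in `recurrent_sites` are forced
#' into `k` randomly chosen samples each. Fully deterministic given the
#' configuration seed.
#'
#' @param genome Named character vector (use the gene-adjusted genome from
#'   [make_genes()] when genes are present).
#' @param genes Optional `gene_models` tibble.
#' @param mask Optional mask tibble.
#' @param cfg `synth_config`.
#' @return `mut_ds` tibble with dataset, sample and tissue labels.
#' @export
simulate_mutations <- function(genome, genes = NULL, mask = NULL, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 2L, {
    tissue_of <- rep_len(cfg$tissues, cfg$n_samples)
    recs <- list()
    for (ch in names(genome)) {
      seq <- genome[[ch]]
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      p <- site_rates_chr(seq, ch, genes, mask, cfg)
      candidate <- which(p > 0)
      pc <- p[candidate]
      for (s in seq_len(cfg$n_samples)) {
        hit <- candidate[stats::runif(length(candidate)) < pc]
        if (length(hit) == 0) next
        ref <- chars[hit]
        bases <- c("A", "C", "G", "T")
        alts <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
        alt <- alts[cbind(match(ref, bases),
                          sample.int(3, length(ref), replace = TRUE))]
        recs[[length(recs) + 1]] <- tibble::tibble(
          chrom = ch, pos = hit, ref = ref, alt = alt,
          sample = sprintf("S%03d", s), tissue = tissue_of[s])
      }
    }
    out <- dplyr::bind_rows(recs)
    if (!is.null(cfg$recurrent_sites) && nrow(cfg$recurrent_sites) > 0) {
      inj <- purrr::pmap_dfr(cfg$recurrent_sites, function(chrom, pos, k) {
        ref <- substring(genome[[chrom]], pos, pos)
        smp <- sample.int(cfg$n_samples, min(k, cfg$n_samples))
        tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                       alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                       sample = sprintf("S%03d", smp),
                       tissue = tissue_of[smp])
      })
      out <- dplyr::bind_rows(out, inj)
      out <- dplyr::distinct(out, .data$chrom, .data$pos, .data$sample,
                             .keep_all = TRUE)
    }
    if (nrow(out) == 0) {
      out <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            sample = character(), tissue = character())
    }
    mutation_dataset(out, dataset = cfg$dataset, scope = "genome")
  })
}
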