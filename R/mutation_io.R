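#' Read a substitution catalog
#'
#' Reads single-base substitution records from a TSV file (header columns
#' `chrom`, `pos`, `ref`, `alt`, optionally `sample` and `tissue`) or from a
#' minimal VCF (CHROM/POS/REF/ALT used; multi-allelic rows are split into one
#' record per alternate allele). Rows that are not single-base substitutions
#' (indels, MNVs, ref == alt, non-ACGT bases) are skipped with a message
#' reporting how many were dropped and the first offending line numbers.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param dataset Dataset label attached to every record.
#' @param scope `"genome"` or `"exome"`; sets the default G:C background for
#'   [gc_fraction()] (0.41 genome-wide, 0.55 exome-wide).
#' @param background_gc Override the scope default.
#' @param normalize_chrom Strip a leading "chr" from chromosome names so that
#'   "chr1" and "1" compare equal. Default FALSE.
#' @return A `mut_ds` tibble with columns `dataset`, `chrom`, `pos`, `ref`,
#'   `alt`, `sample`, `tissue` and attributes `scope`, `background_gc`.
#' @export
read_mutations <- function(path, format = c("tsv", "vcf"), dataset = "ds1",
                           scope = c("genome", "exome"), background_gc = NULL,
                           normalize_chrom = FALSE) {
  format <- match.arg(format)
  scope <- match.arg(scope)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      stop("mutation TSV missing mandatory column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df <- tibble::tibble(
      chrom = raw$chrom,
      pos = suppressWarnings(as.integer(raw$pos)),
      ref = toupper(raw$ref),
      alt = toupper(raw$alt),
      sample = if ("sample" %in% names(raw)) raw$sample else NA_character_,
      tissue = if ("tissue" %in% names(raw)) raw$tissue else NA_character_,
      line = seq_len(nrow(raw)) + 1L
    )
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    df <- tibble::tibble(
      chrom = as.character(fix[, "CHROM"]),
      pos = suppressWarnings(as.integer(fix[, "POS"])),
      ref = toupper(as.character(fix[, "REF"])),
      alt = toupper(as.character(fix[, "ALT"])),
      sample = NA_character_, tissue = NA_character_,
      line = seq_len(nrow(fix))
    )
    # split multi-allelic ALT fields into one record per allele
    df <- tidyr::separate_rows(df, "alt", sep = ",")
  }
  ok <- !is.na(df$pos) & df$pos >= 1 &
    df$ref %in% c("A", "C", "G", "T") &
    df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  if (any(!ok)) {
    bad <- df$line[!ok]
    message(sum(!ok), " non-SNV or malformed row(s) skipped (lines ",
            paste(utils::head(unique(bad), 5), collapse = ", "),
            if (length(unique(bad)) > 5) ", ..." else "", ")")
  }
  df <- df[ok, c("chrom", "pos", "ref", "alt", "sample", "tissue")]
  if (normalize_chrom) df$chrom <- sub("^chr", "", df$chrom)
  mutation_dataset(df, dataset = dataset, scope = scope,
                   background_gc = background_gc)
}

#' Construct a mutation dataset from a data frame
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `sample`, `tissue`, `dataset`.
#' @inheritParams read_mutations
#' @return `mut_ds` tibble.
#' @export
mutation_dataset <- function(df, dataset = "ds1", scope = c("genome", "exome"),
                             background_gc = NULL) {
  scope <- match.arg(scope)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    dataset = if ("dataset" %in% names(df)) as.character(df$dataset) else dataset,
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    ref = toupper(as.character(df$ref)),
    alt = toupper(as.character(df$alt)),
    sample = if ("sample" %in% names(df)) as.character(df$sample) else NA_character_,
    tissue = if ("tissue" %in% names(df)) as.character(df$tissue) else NA_character_
  )
  bad <- which(!(out$ref %in% c("A", "C", "G", "T")) |
                 !(out$alt %in% c("A", "C", "G", "T")) | out$ref == out$alt)
  if (length(bad) > 0) {
    stop("invalid substitution record(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(background_gc)) {
    background_gc <- if (scope == "genome") 0.41 else 0.55
  }
  structure(out, scope = scope, background_gc = background_gc,
            class = c("mut_ds", class(out)))
}

#' Collapse repeated coordinates to one count
#'
#' Within each dataset, multiple records at the same (chrom, pos) coordinate
#' collapse to a single record regardless of alternate allele, sample or
#' zygosity. The per-sample multiplicity is what the recurrence module
#' consumes, so deduplicate the copy used for motif fractions, not the raw
#' catalog.
#'
#' @param ds A `mut_ds` tibble.
#' @param per_sample Deduplicate within (dataset, sample, chrom, pos) instead
#'   of across samples. Default FALSE (across samples within a dataset).
#' @return Deduplicated `mut_ds`; a message reports how many records
#'   collapsed.
#' @export
deduplicate <- function(ds, per_sample = FALSE) {
  keys <- if (per_sample) c("dataset", "sample", "chrom", "pos")
          else c("dataset", "chrom", "pos")
  before <- nrow(ds)
  out <- dplyr::distinct(ds, dplyr::across(dplyr::all_of(keys)),
                         .keep_all = TRUE)
  dropped <- before - nrow(out)
  if (dropped > 0) message(dropped, " duplicate coordinate record(s) collapsed")
  restore_mut_ds(out, ds)
}

restore_mut_ds <- function(out, template) {
  structure(out,
            scope = attr(template, "scope"),
            background_gc = attr(template, "background_gc"),
            class = unique(c("mut_ds", class(out))))
}

#' Fraction of substitutions at G:C pairs, with exact binomial test
#'
#' Computes, per dataset, the fraction of records whose reference base is G or
#' C and a two-sided exact binomial test of that count against the background
#' G:C content (0.41 genome-wide, 0.55 exome-wide, or the value stored on the
#' dataset).
#'
#' @param ds `mut_ds` tibble (>= 1 record).
#' @param background Override the stored background fraction.
#' @return Tibble with one row per dataset: `dataset`, `n`, `n_gc`,
#'   `fraction`, `background`, `p_value`.
#' @export
gc_fraction <- function(ds, background = NULL) {
  if (nrow(ds) == 0) stop("empty mutation dataset", call. = FALSE)
  bg <- background %||% attr(ds, "background_gc") %||% 0.41
  dplyr::group_by(tibble::as_tibble(ds), .data$dataset) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_gc = sum(.data$ref %in% c("G", "C")),
      fraction = .data$n_gc / .data$n,
      background = bg,
      p_value = stats::binom.test(.data$n_gc, .data$n, p = bg,
                                  alternative = "two.sided")$p.value,
      .groups = "drop"
    )
}

#' Annotate records with their canonical motif context
#'
#' Adds a `context` column (canonical NGNN motif, NA where undefined) and a
#' `status` column classifying every record: `"ok"` (counted toward m_i),
#' `"at_site"` (reference base A or T), `"off_mask"` (mutated base outside the
#' mappability mask), `"no_context"` (4-mer overhangs the sequence end or
#' contains N), `"ref_mismatch"` (catalog base disagrees with the genome;
#' excluded rather than fatal, with a summary message).
#'
#' @param ds `mut_ds` tibble (deduplicate first for fraction work).
#' @param genome Genome input (see [as_genome()]).
#' @param mask Optional mappability tibble (chrom/start/end, 0-based
#'   half-open).
#' @return The input tibble with `context` and `status` columns.
#' @export
annotate_contexts <- function(ds, genome, mask = NULL) {
  genome <- as_genome(genome)
  ctx <- canonical_context(genome, ds$chrom, ds$pos, ds$ref, on_mismatch = "na")
  status <- rep("ok", nrow(ds))
  # classify failures in order of precedence
  in_genome <- ds$chrom %in% names(genome)
  glen <- stats::setNames(nchar(genome), names(genome))
  valid_pos <- in_genome & ds$pos >= 1 & ds$pos <= glen[ds$chrom]
  actual <- rep(NA_character_, nrow(ds))
  actual[valid_pos] <- substring(genome[ds$chrom[valid_pos]],
                                 ds$pos[valid_pos], ds$pos[valid_pos])
  mism <- !valid_pos | (actual != ds$ref)
  status[mism] <- "ref_mismatch"
  status[!mism & ds$ref %in% c("A", "T")] <- "at_site"
  if (!is.null(mask)) {
    mappable <- rep(FALSE, nrow(ds))
    for (ch in unique(ds$chrom[valid_pos])) {
      idx <- which(ds$chrom == ch & valid_pos)
      keep <- mask_logical(mask, ch, glen[[ch]])
      mappable[idx] <- keep[ds$pos[idx]]
    }
    off <- status == "ok" & !mappable
    status[off] <- "off_mask"
    ctx[status != "ok"] <- NA_character_
  }
  status[status == "ok" & is.na(ctx)] <- "no_context"
  n_mism <- sum(status == "ref_mismatch")
  if (n_mism > 0) {
    message(n_mism, " record(s) excluded for reference/genome mismatch")
  }
  out <- ds
  out$context <- ifelse(status == "ok", ctx, NA_character_)
  out$status <- status
  restore_mut_ds(out, ds)
}

#' Per-motif mutated-site counts m_i
#'
#' Tallies annotated records into the 64 canonical classes. Records whose
#' status is not `"ok"` are excluded from m_i and reported in the `excluded`
#' attribute (a named count by status).
#'
#' @param annotated Output of [annotate_contexts()].
#' @return 64-row tibble with columns `motif`, `m`; attribute `excluded`.
#' @export
motif_mutation_counts <- function(annotated) {
  if (!"context" %in% names(annotated)) {
    stop("run annotate_contexts() first", call. = FALSE)
  }
  mt <- enumerate_motifs()
  ok <- annotated$status == "ok"
  tab <- table(factor(annotated$context[ok], levels = mt$motif))
  out <- tibble::tibble(motif = mt$motif, m = as.integer(tab))
  excl <- table(annotated$status[!ok])
  attr(out, "excluded") <- stats::setNames(as.integer(excl), names(excl))
  out
}
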