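#' Canonical 5'-NGNN-3' motif classes
#'
#' A mutated G:C base pair is described by the double-stranded tetranucleotide
#' surrounding it, written 5'->3' on the strand that carries the mutated
#' guanine at the second position (P2). Substitutions observed at a cytosine
#' are folded onto the opposite strand by reverse complementation, so all 64
#' classes are G-centred. Four classes (AGCT, CGCG, GGCC, TGCA) equal their
#' own reverse complement and contain two mutable guanines per duplex
#' occurrence.
#'
#' @return A 64-row tibble in lexicographic order with columns `motif`, the
#'   position bases `p1`, `p3`, `p4`, logical subset flags `cgnn` (P1 = C),
#'   `dgnn` (P1 in A/G/T), `dgrn` (DGNN with purine P3), `dgyn` (DGNN with
#'   pyrimidine P3), `dgan` (DGNN with P3 = A), `dgbn` (DGNN with P3 in
#'   C/G/T), and `self_complementary`.
#' @examples
#' enumerate_motifs()
#' @export
enumerate_motifs <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(p1 = bases, p3 = bases, p4 = bases,
                      stringsAsFactors = FALSE)
  motif <- paste0(grid$p1, "G", grid$p3, grid$p4)
  out <- tibble::tibble(
    motif = motif,
    p1 = grid$p1,
    p3 = grid$p3,
    p4 = grid$p4
  )
  out <- out[order(out$motif), ]
  out$cgnn <- out$p1 == "C"
  out$dgnn <- !out$cgnn
  out$dgrn <- out$dgnn & out$p3 %in% c("A", "G")
  out$dgyn <- out$dgnn & out$p3 %in% c("C", "T")
  out$dgan <- out$dgnn & out$p3 == "A"
  out$dgbn <- out$dgnn & out$p3 != "A"
  out$self_complementary <- out$motif == reverse_complement(out$motif)
  out
}

#' Motif subset membership
#'
#' @param subset One of "ALL", "CGNN", "DGNN", "DGRN", "DGYN", "DGAN", "DGBN",
#'   or a character vector of explicit motifs (validated against the 64
#'   canonical classes).
#' @return Character vector of motifs in the subset.
#' @export
motif_subset <- function(subset) {
  mt <- enumerate_motifs()
  if (length(subset) == 1L &&
      toupper(subset) %in% c("ALL", "CGNN", "DGNN", "DGRN", "DGYN", "DGAN", "DGBN")) {
    key <- toupper(subset)
    if (key == "ALL") return(mt$motif)
    return(mt$motif[mt[[tolower(key)]]])
  }
  bad <- setdiff(subset, mt$motif)
  if (length(bad) > 0) {
    stop("not canonical NGNN motifs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  subset
}

#' Reverse complement of a nucleotide string
#'
#' Vectorised over input strings; `N` is its own complement.
#'
#' @param seq Character vector over the alphabet A, C, G, T, N.
#' @return Character vector of Watson-Crick reverse complements.
#' @examples
#' reverse_complement("AGTC")  # "GACT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- stringr::str_locate(seq, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop(sprintf("non-nucleotide character '%s' at position %d of '%s'",
                 substr(seq[i], bad[i], bad[i]), bad[i], seq[i]),
         call. = FALSE)
  }
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' Coerce to an internal genome representation
#'
#' Accepts a path to a (multi-)FASTA file, a `Biostrings::DNAStringSet`, or a
#' named character vector of sequences. Sequences are uppercased; lowercase
#' (soft-masked) bases are treated as their uppercase equivalents unless
#' `drop_soft_masked = TRUE`, in which case they become `N` and are excluded
#' from all counts.
#'
#' @param x Genome input.
#' @param drop_soft_masked Replace soft-masked (lowercase) bases by N.
#' @return Named character vector of uppercase sequences.
#' @export
as_genome <- function(x, drop_soft_masked = FALSE) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             is.null(names(x))) {
    seqs <- as.character(Biostrings::readDNAStringSet(x))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(x)) {
    if (length(x) > 0 && is.null(names(x))) {
      names(x) <- paste0("chr", seq_along(x))
    }
    seqs <- x
  } else {
    stop("cannot interpret genome input of class ", class(x)[1], call. = FALSE)
  }
  if (drop_soft_masked) {
    seqs <- chartr("acgtn", "NNNNN", seqs)
  }
  toupper(seqs)
}

# Per-chromosome logical mappability vector from a BED-style interval tibble
# (0-based half-open). NULL mask => everything mappable.
mask_logical <- function(mask, chrom, len) {
  if (is.null(mask)) return(rep(TRUE, len))
  keep <- rep(FALSE, len)
  mk <- mask[mask$chrom == chrom, , drop = FALSE]
  if (nrow(mk) > 0) {
    for (i in seq_len(nrow(mk))) {
      lo <- max(1L, mk$start[i] + 1L)   # BED start is 0-based
      hi <- min(len, mk$end[i])
      if (lo <= hi) keep[lo:hi] <- TRUE
    }
  }
  keep
}

# Vectorised canonical tetramer for (sequence, positions, ref bases) within one
# chromosome string. Returns NA where no canonical context exists.
canonical_context_chr <- function(seq, pos, ref) {
  len <- nchar(seq)
  out <- rep(NA_character_, length(pos))
  is_g <- ref == "G"
  is_c <- ref == "C"
  okg <- is_g & pos - 1L >= 1L & pos + 2L <= len
  okc <- is_c & pos - 2L >= 1L & pos + 1L <= len
  if (any(okg)) {
    out[okg] <- substring(seq, pos[okg] - 1L, pos[okg] + 2L)
  }
  if (any(okc)) {
    out[okc] <- stringi::stri_reverse(
      chartr("ACGTN", "TGCAN", substring(seq, pos[okc] - 2L, pos[okc] + 1L)))
  }
  out[!is.na(out) & stringr::str_detect(out, "N")] <- NA_character_
  out
}

#' Canonical context of a mutated site
#'
#' Returns the G-centred tetramer covering a mutated G:C site. For a reference
#' guanine the forward 4-mer over positions `pos - 1 .. pos + 2` is returned;
#' for a reference cytosine the reverse complement of the forward 4-mer over
#' `pos - 2 .. pos + 1`, so that the mutated base always sits at P2 as G.
#' Sites at A or T, 4-mers overhanging the sequence end, and 4-mers containing
#' N have no canonical context (NA).
#'
#' @param genome Genome input (see [as_genome()]).
#' @param chrom,pos,ref Parallel vectors: sequence name, 1-based position,
#'   reference base.
#' @param on_mismatch What to do when `ref` disagrees with the genome base:
#'   `"error"` (default) or `"na"`.
#' @return Character vector of canonical motifs (NA where undefined).
#' @examples
#' g <- c(chr1 = "TTCGAA")
#' canonical_context(g, "chr1", 4, "G")  # "CGAA"
#' canonical_context(g, "chr1", 3, "C")  # "CGAA"
#' @export
canonical_context <- function(genome, chrom, pos, ref,
                              on_mismatch = c("error", "na")) {
  on_mismatch <- match.arg(on_mismatch)
  genome <- as_genome(genome)
  pos <- as.integer(pos)
  ref <- toupper(ref)
  n <- max(length(chrom), length(pos), length(ref))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); ref <- rep_len(ref, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome)) {
      if (on_mismatch == "error")
        stop("sequence '", ch, "' not in genome", call. = FALSE)
      next
    }
    seq <- genome[[ch]]
    p <- pos[idx]
    valid <- p >= 1L & p <= nchar(seq)
    actual <- rep(NA_character_, length(p))
    actual[valid] <- substring(seq, p[valid], p[valid])
    mism <- valid & actual != ref[idx]
    if (any(mism)) {
      if (on_mismatch == "error") {
        i <- which(mism)[1]
        stop(sprintf("reference mismatch at %s:%d: catalog says %s, genome has %s",
                     ch, p[i], ref[idx][i], actual[i]), call. = FALSE)
      }
      valid[mism] <- FALSE
    }
    take <- valid & ref[idx] %in% c("G", "C")
    if (any(take)) {
      out[idx[take]] <- canonical_context_chr(seq, p[take], ref[idx][take])
    }
  }
  out
}

new_motif_count_table <- function(counts, mask_label) {
  mt <- enumerate_motifs()
  t <- counts[mt$motif]
  t[is.na(t)] <- 0
  out <- tibble::tibble(motif = mt$motif, t = as.integer(unname(t)))
  attr(out, "mask_label") <- mask_label
  out
}

#' Count mappable canonical motif sites in a genome (per-site scan)
#'
#' Walks every G and every C on the forward strand (a C marks a guanine on the
#' reverse strand); each site whose canonical 4-mer lies fully inside the
#' sequence, contains no N, and whose mutated-base position falls inside the
#' mappability mask increments its canonical motif class. Because each duplex
#' occurrence of a self-complementary tetramer contains both a G-site and a
#' C-site, those classes are counted twice per occurrence, reproducing the
#' doubling rule used for tetramer-occurrence counting.
#'
#' @param genome Genome input (see [as_genome()]).
#' @param mask Optional mappability tibble with columns `chrom`, `start`,
#'   `end` (0-based half-open, BED convention), or NULL for all positions.
#' @param mask_label Label recorded on the result.
#' @param drop_soft_masked See [as_genome()].
#' @return 64-row tibble with columns `motif` and `t` (site counts) and
#'   attribute `mask_label`.
#' @examples
#' count_genome_motifs(c(chr1 = "ACGCGT"))  # CGCG = 2
#' @export
count_genome_motifs <- function(genome, mask = NULL,
                                mask_label = if (is.null(mask)) "none" else "mask",
                                drop_soft_masked = FALSE) {
  genome <- as_genome(genome, drop_soft_masked = drop_soft_masked)
  if (length(genome) == 0 || all(nchar(genome) == 0)) {
    warning("empty genome: all motif counts are zero")
    return(new_motif_count_table(integer(0), mask_label))
  }
  tot <- integer(0)
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    len <- nchar(seq)
    if (len < 4L) next
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    keep <- mask_logical(mask, ch, len)
    sites <- which((chars == "G" | chars == "C") & keep)
    if (length(sites) == 0) next
    ctx <- canonical_context_chr(seq, sites, chars[sites])
    ctx <- ctx[!is.na(ctx)]
    if (length(ctx) > 0) {
      tab <- table(ctx)
      add <- as.integer(tab)
      names(add) <- names(tab)
      for (m in names(add)) tot[m] <- sum(tot[m], add[m], na.rm = TRUE)
    }
  }
  new_motif_count_table(tot, mask_label)
}

#' Count motif sites by sliding-tetramer scan (independent oracle)
#'
#' Alternative counting route used to cross-check [count_genome_motifs()]:
#' slides a 4-mer window along the forward strand and credits motif X once for
#' each occurrence of X and once for each occurrence of its reverse
#' complement. Self-complementary motifs thereby receive two credits per
#' occurrence. Windows containing N are skipped. Equal to the per-site scan on
#' unmasked input by construction.
#'
#' @inheritParams count_genome_motifs
#' @return 64-row tibble with columns `motif`, `t`.
#' @export
count_motifs_tetramerwise <- function(genome, mask = NULL,
                                      mask_label = if (is.null(mask)) "none" else "mask",
                                      drop_soft_masked = FALSE) {
  if (!is.null(mask)) {
    stop("the tetramer-scan oracle supports unmasked input only; ",
         "use count_genome_motifs() with a mask", call. = FALSE)
  }
  genome <- as_genome(genome, drop_soft_masked = drop_soft_masked)
  if (length(genome) == 0 || all(nchar(genome) == 0)) {
    warning("empty genome: all motif counts are zero")
    return(new_motif_count_table(integer(0), mask_label))
  }
  mt <- enumerate_motifs()
  freq <- rep(0L, 256)
  names(freq) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
  for (ch in names(genome)) {
    if (nchar(genome[[ch]]) < 4L) next
    f <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(genome[[ch]]), width = 4)
    freq[names(f)] <- freq[names(f)] + as.integer(f)
  }
  counts <- freq[mt$motif] + freq[reverse_complement(mt$motif)]
  names(counts) <- mt$motif
  new_motif_count_table(counts, mask_label)
}

#' Read a BED3 mappability mask
#'
#' @param path BED file (at least chrom/start/end columns, 0-based half-open).
#' @return Tibble with columns `chrom`, `start`, `end`, intervals merged and
#'   sorted per chromosome.
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(con = path, format = "bed")
  gr <- GenomicRanges::reduce(gr)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}
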