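#' Mappability-normalized mutated-motif fractions f_i
#'
#' Joins mutated-site counts m_i to genome-wide mappable site counts t_i and
#' forms f_i = m_i / t_i per canonical motif. A motif with t_i = 0 and
#' m_i > 0 is an impossible observation and raises an error; t_i = 0 with
#' m_i = 0 yields an undefined (NA, flagged) fraction.
#'
#' @param m 64-row tibble with columns `motif`, `m`
#'   (see [motif_mutation_counts()]).
#' @param t 64-row tibble with columns `motif`, `t`
#'   (see [count_genome_motifs()]).
#' @return Fraction table: tibble with `motif`, subset flags, `m`, `t`, `f`,
#'   `defined`; class `fraction_tbl`.
#' @export
motif_fractions <- function(m, t) {
  mt <- enumerate_motifs()
  stopifnot(all(mt$motif %in% m$motif), all(mt$motif %in% t$motif))
  out <- dplyr::left_join(mt, m[, c("motif", "m")], by = "motif")
  out <- dplyr::left_join(out, t[, c("motif", "t")], by = "motif")
  bad <- out$t == 0 & out$m > 0
  if (any(bad)) {
    stop("mutations observed at motif(s) with zero mappable sites: ",
         paste(out$motif[bad], collapse = ", "), call. = FALSE)
  }
  out$defined <- out$t > 0
  out$f <- ifelse(out$defined, out$m / out$t, NA_real_)
  class(out) <- c("fraction_tbl", class(out))
  out
}

#' Subset-normalized fractions F_i
#'
#' F_i = f_i / sum of f_i over the normalization subset, so that the F_i over
#' the subset sum to 1. Motifs outside the subset get NA.
#'
#' @param ft Fraction table from [motif_fractions()].
#' @param subset Subset name ("DGNN" by default) or explicit motif vector; see
#'   [motif_subset()].
#' @return `ft` with an `F` column and attribute `normalized_over`.
#' @export
normalize_fractions <- function(ft, subset = "DGNN") {
  motifs <- motif_subset(subset)
  in_sub <- ft$motif %in% motifs
  fs <- ft$f[in_sub]
  if (!any(!is.na(fs)) || sum(fs, na.rm = TRUE) <= 0) {
    stop("all fractions over the normalization subset are zero or undefined",
         call. = FALSE)
  }
  total <- sum(fs, na.rm = TRUE)
  ft$F <- ifelse(in_sub, ft$f / total, NA_real_)
  attr(ft, "normalized_over") <- if (is.character(subset) && length(subset) == 1)
    subset else "custom"
  ft
}

#' Contrast mutated-motif fractions between two motif groups
#'
#' Compares mean f_i between two disjoint motif subsets, either by a
#' two-tailed Welch (unequal-variance) t-test across motif-level fractions or
#' by a two-tailed pooled two-proportion z-test (all m and t pooled within
#' each group). `test = "auto"` uses Welch unless some group member has
#' m_i = 0, in which case the z-test is selected — the fallback used for
#' sparse catalogs where not every motif is observed.
#'
#' @param ft Fraction table from [motif_fractions()].
#' @param a,b Subset names or motif vectors (must be disjoint).
#' @param test `"auto"`, `"welch_t"` or `"two_proportion_z"`.
#' @return One-row tibble: group sizes, means and SDs of f_i, `statistic`,
#'   `df` (NA for z), `p_value`, `minus_log10_p` (base 10, capped at 308) and
#'   `underflow` flag.
#' @export
compare_groups <- function(ft, a = "CGNN", b = "DGNN",
                           test = c("auto", "welch_t", "two_proportion_z")) {
  test <- match.arg(test)
  ma <- motif_subset(a); mb <- motif_subset(b)
  if (length(intersect(ma, mb)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  ga <- ft[ft$motif %in% ma & ft$defined, ]
  gb <- ft[ft$motif %in% mb & ft$defined, ]
  if (test == "auto") {
    test <- if (any(ga$m == 0) || any(gb$m == 0)) "two_proportion_z" else "welch_t"
  }
  lab_a <- if (is.character(a) && length(a) == 1) a else "A"
  lab_b <- if (is.character(b) && length(b) == 1) b else "B"
  if (test == "welch_t") {
    if (nrow(ga) < 2 || nrow(gb) < 2) {
      stop("Welch t-test needs >= 2 defined fractions per group; ",
           "use test = \"two_proportion_z\"", call. = FALSE)
    }
    ht <- tryCatch(
      stats::t.test(ga$f, gb$f, var.equal = FALSE, alternative = "two.sided"),
      error = function(e) {
        if (!grepl("essentially constant", conditionMessage(e))) stop(e)
        # zero variance in both groups: identical means are a null result,
        # different means an (unreachable in practice) infinite statistic
        delta <- mean(ga$f) - mean(gb$f)
        list(statistic = c(t = if (delta == 0) 0 else sign(delta) * Inf),
             parameter = c(df = NA_real_),
             p.value = if (delta == 0) 1 else 0)
      })
    statistic <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value
  } else {
    m1 <- sum(ga$m); t1 <- sum(ga$t); m2 <- sum(gb$m); t2 <- sum(gb$t)
    if (t1 == 0 || t2 == 0) stop("empty group for z-test", call. = FALSE)
    p1 <- m1 / t1; p2 <- m2 / t2
    pp <- (m1 + m2) / (t1 + t2)
    se <- sqrt(pp * (1 - pp) * (1 / t1 + 1 / t2))
    statistic <- (p1 - p2) / se
    df <- NA_real_
    p <- 2 * stats::pnorm(-abs(statistic))
  }
  lp <- minus_log10(p)
  tibble::tibble(
    group_a = lab_a, group_b = lab_b, test = test,
    n_a = nrow(ga), n_b = nrow(gb),
    mean_a = mean(ga$f), sd_a = stats::sd(ga$f),
    mean_b = mean(gb$f), sd_b = stats::sd(gb$f),
    statistic = statistic, df = df, p_value = p,
    minus_log10_p = lp$value, underflow = lp$underflow
  )
}

#' P4-adenine enhancement ratio for purine-bridged motifs
#'
#' For each of the eight (P1, P3) stems with a purine at P3 (4 choices of P1
#' times P3 in A/G), divides the fraction of mutations with adenine at P4 by
#' the mean fraction over the other three P4 bases:
#' f(P1 G P3 A) / mean(f(P1 G P3 C), f(P1 G P3 G), f(P1 G P3 T)).
#' Stems with any undefined member fraction are skipped with a warning.
#'
#' @param ft Fraction table from [motif_fractions()].
#' @return Tibble with columns `p1`, `p3`, `f_p4a`, `f_p4_other`, `ratio`; up
#'   to 8 rows. Summarise with `mean(ratio)` and `sd(ratio)`.
#' @export
p4_adenine_ratio <- function(ft) {
  stems <- expand.grid(p1 = c("A", "C", "G", "T"), p3 = c("A", "G"),
                       stringsAsFactors = FALSE)
  rows <- purrr::pmap_dfr(stems, function(p1, p3) {
    f4 <- stats::setNames(
      ft$f[match(paste0(p1, "G", p3, c("A", "C", "G", "T")), ft$motif)],
      c("A", "C", "G", "T"))
    if (any(is.na(f4))) {
      warning("stem ", p1, "G", p3, "N skipped: undefined member fraction(s)",
              call. = FALSE)
      return(NULL)
    }
    other <- mean(f4[c("C", "G", "T")])
    if (other <= 0) {
      warning("stem ", p1, "G", p3, "N skipped: zero comparison fractions",
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(p1 = p1, p3 = p3, f_p4a = f4[["A"]], f_p4_other = other,
                   ratio = f4[["A"]] / other)
  })
  rows
}
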