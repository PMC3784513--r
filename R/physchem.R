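#' Vertical ionization potentials of G-centred DGN trimers
#'
#' Embedded quantum-chemical estimates (eV) of the energy required to
#' abstract one electron, without nuclear relaxation, from the central
#' guanine of the 12 double-stranded D-G-N trimers (D = A/G/T on the 5' side,
#' any base on the 3' side). The table reproduces three physical regularities
#' that the correlation analyses rely on: GGG is the global minimum, every
#' trimer containing a GG doublet lies below every single-G trimer, and a 3'
#' purine always lowers the potential relative to a 3' pyrimidine with the
#' same 5' base. The free-guanine reference is 8.02 eV (8.26 eV measured).
#'
#' @return 12-row tibble with columns `trimer`, `vip_ev`.
#' @examples
#' vip_table()
#' @export
vip_table <- function() {
  tibble::tribble(
    ~trimer, ~vip_ev,
    "GGG", 5.39,
    "GGA", 5.50,
    "GGT", 5.54,
    "GGC", 5.63,
    "AGG", 5.57,
    "TGG", 5.59,
    "TGA", 5.64,
    "AGA", 5.66,
    "AGT", 5.81,
    "TGT", 5.90,
    "AGC", 5.95,
    "TGC", 5.97
  )
}

#' Free (unstacked) guanine ionization potential, eV
#'
#' @param experimental Return the measured band maximum (8.26 eV) instead of
#'   the computed value (8.02 eV).
#' @return Scalar energy in eV.
#' @export
vip_free_guanine <- function(experimental = FALSE) {
  if (experimental) 8.26 else 8.02
}

#' Look up the ionization potential of a trimer
#'
#' @param trimer Character vector of D-G-N trimers (5' base in A/G/T, centre
#'   G), or `"G"` for the free-guanine reference.
#' @return Numeric vector of energies (eV). Trimers with a 5' cytosine (CGN)
#'   or any other string outside the 12 computed forms raise an error.
#' @examples
#' vip_lookup("GGG")  # 5.39
#' @export
vip_lookup <- function(trimer) {
  tab <- vip_table()
  out <- numeric(length(trimer))
  for (i in seq_along(trimer)) {
    tr <- toupper(trimer[i])
    if (tr == "G") {
      out[i] <- vip_free_guanine()
    } else {
      j <- match(tr, tab$trimer)
      if (is.na(j)) {
        stop("no ionization potential for '", tr,
             "': only the 12 DGN trimers (5' base A/G/T) were computed",
             call. = FALSE)
      }
      out[i] <- tab$vip_ev[j]
    }
  }
  out
}

#' Read a dinucleotide-step stacking free-energy table
#'
#' A stacking table maps each of the 16 ordered dinucleotide steps to an
#' absolute coaxial base-stacking free energy. The file is TSV with columns
#' `step` and `dg`; a `# source: <label>` comment line, if present, is kept
#' as the table's source label.
#'
#' @param path TSV file.
#' @return 16-row tibble with columns `step`, `dg` and attribute `source`.
#' @export
read_stacking_table <- function(path) {
  first <- readLines(path, n = 1L)
  src <- if (startsWith(first, "# source:"))
    trimws(sub("^# source:", "", first)) else "user"
  tab <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(step = "c", dg = "d"),
                         progress = FALSE)
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  if (!setequal(tab$step, steps) || nrow(tab) != 16) {
    stop("stacking table must contain exactly the 16 dinucleotide steps",
         call. = FALSE)
  }
  if (any(!is.finite(tab$dg))) stop("non-finite stacking energies", call. = FALSE)
  attr(tab, "source") <- src
  tab
}

#' Built-in synthetic stacking-step table
#'
#' The published stacking free energies are not embedded in this package;
#' this synthetic placeholder only honors the qualitative ordering of
#' absolute stacking free energies (purine-purine >> purine-pyrimidine >
#' pyrimidine-purine > pyrimidine-pyrimidine), with small deterministic
#' within-class offsets so values are distinct. It is suitable for plumbing
#' and recovery tests; to reproduce published correlation axes, supply the
#' published values via [read_stacking_table()].
#'
#' @return 16-row tibble with columns `step`, `dg`; attribute `source` set to
#'   `"synthetic-placeholder"`.
#' @export
default_stacking_table <- function() {
  path <- system.file("extdata", "stacking_steps_synthetic.tsv",
                      package = "mutmotif", mustWork = TRUE)
  read_stacking_table(path)
}

#' Mean stacking free energy of a motif
#'
#' The motif-level descriptor is the arithmetic mean of the step energies of
#' the three ordered dinucleotide steps it contains: P1P2, P2P3, P3P4 (the
#' 5'-neighbour-to-G step, the G-to-3'-neighbour step, and the next step).
#' By the convention of the correlation analysis only DGNN motifs (5' base
#' not C) carry the descriptor; set `allow_all = TRUE` to compute it for all
#' 64 classes.
#'
#' @param motif Character vector of canonical motifs.
#' @param steps Stacking table (default [default_stacking_table()]).
#' @param allow_all Allow CGNN motifs too.
#' @return Numeric vector of mean step energies.
#' @export
mean_stacking_energy <- function(motif, steps = default_stacking_table(),
                                 allow_all = FALSE) {
  motif <- toupper(motif)
  ok <- motif %in% motif_subset("ALL")
  if (any(!ok)) {
    stop("not canonical motifs: ", paste(motif[!ok], collapse = ", "),
         call. = FALSE)
  }
  if (!allow_all && any(startsWith(motif, "C"))) {
    stop("stacking descriptor is defined over DGNN motifs; ",
         "set allow_all = TRUE to include CGNN", call. = FALSE)
  }
  lut <- stats::setNames(steps$dg, steps$step)
  s1 <- substr(motif, 1, 2); s2 <- substr(motif, 2, 3); s3 <- substr(motif, 3, 4)
  miss <- setdiff(unique(c(s1, s2, s3)), names(lut))
  if (length(miss) > 0) {
    stop("stacking table is missing step(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  (lut[s1] + lut[s2] + lut[s3]) / 3
}

#' Aggregate tetramer fractions to G-centred trimers
#'
#' Sums mutated and mappable-site counts over the P4 base within each
#' (P1, G, P3) stem and recomputes the fraction: f(NGN) =
#' sum(m) / sum(t) over the four P4 variants.
#'
#' @param ft Fraction table from [motif_fractions()].
#' @return Tibble with columns `trimer`, `m`, `t`, `f`, `defined`.
#' @export
aggregate_to_trimers <- function(ft) {
  df <- tibble::as_tibble(ft)
  df$trimer <- substr(df$motif, 1, 3)
  out <- dplyr::summarise(dplyr::group_by(df, .data$trimer),
                          m = sum(.data$m), t = sum(.data$t),
                          .groups = "drop")
  out$defined <- out$t > 0
  out$f <- ifelse(out$defined, out$m / out$t, NA_real_)
  out
}

#' Log-linear fit of mutation fractions on a physicochemical descriptor
#'
#' Fits ordinary least squares of ln(y) on x, after dropping zero or
#' undefined y with a warning, and estimates the persistence of significance
#' P(alpha) by nonparametric bootstrap: the fraction of B resamples of the
#' points (with replacement, seeded) whose refitted slope has p < alpha.
#'
#' @param data Data frame holding the variables.
#' @param y,x Column names (strings) or bare names via `{{ }}`-free strings:
#'   give the response (a fraction, log-transformed internally) and the
#'   descriptor.
#' @param bootstrap_B Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (required when `bootstrap_B > 0`).
#' @param alpha Significance level tracked by the bootstrap (default 0.05).
#' @return Object of class `loglin_fit`: list with the `lm` fit, `slope`,
#'   `intercept`, `r2`, `p_value` (two-tailed, slope), `p_alpha`, `n_used`,
#'   `n_dropped` and the fitting data. Methods: [tidy()], [glance()],
#'   `autoplot()`.
#' @export
fit_log_linear <- function(data, y, x, bootstrap_B = 1000, seed = 1,
                           alpha = 0.05) {
  yv <- data[[y]]; xv <- data[[x]]
  if (is.null(yv) || is.null(xv)) stop("columns not found", call. = FALSE)
  usable <- !is.na(yv) & !is.na(xv) & yv > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    warning(n_dropped, " point(s) with zero/undefined response dropped ",
            "before log transform", call. = FALSE)
  }
  df <- tibble::tibble(x = xv[usable], lny = log(yv[usable]))
  if (nrow(df) < 3) stop("fewer than 3 usable points", call. = FALSE)
  if (stats::sd(df$x) == 0) stop("descriptor is constant", call. = FALSE)
  fit <- stats::lm(lny ~ x, data = df)
  sm <- summary(fit)
  slope_p <- sm$coefficients["x", "Pr(>|t|)"]
  p_alpha <- NA_real_
  if (bootstrap_B > 0) {
    p_alpha <- with_seed(seed, {
      hits <- 0L
      n <- nrow(df)
      for (b in seq_len(bootstrap_B)) {
        idx <- sample.int(n, n, replace = TRUE)
        db <- df[idx, ]
        if (stats::sd(db$x) == 0) next
        fb <- summary(stats::lm(lny ~ x, data = db))
        pb <- tryCatch(fb$coefficients["x", "Pr(>|t|)"], error = function(e) NA)
        if (!is.na(pb) && pb < alpha) hits <- hits + 1L
      }
      hits / bootstrap_B
    })
  }
  structure(list(
    fit = fit,
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = sm$r.squared,
    p_value = slope_p,
    p_alpha = p_alpha,
    alpha = alpha,
    bootstrap_B = bootstrap_B,
    n_used = nrow(df),
    n_dropped = n_dropped,
    data = df,
    y = y, x = x
  ), class = "loglin_fit")
}

#' @method tidy loglin_fit
#' @export
tidy.loglin_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @method glance loglin_fit
#' @export
glance.loglin_fit <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, p_value = x$p_value, p_alpha = x$p_alpha,
    alpha = x$alpha, bootstrap_B = x$bootstrap_B,
    n_used = x$n_used, n_dropped = x$n_dropped
  )
}

#' @export
print.loglin_fit <- function(x, ...) {
  cat(sprintf(
    "log-linear fit: ln(%s) ~ %s\n  slope %.4g  intercept %.4g\n  r2 %.3f  p %.3g  P(alpha)_%.2f %s  (n = %d, dropped %d)\n",
    x$y, x$x, x$slope, x$intercept, x$r2, x$p_value, x$alpha,
    ifelse(is.na(x$p_alpha), "NA", sprintf("%.3f", x$p_alpha)),
    x$n_used, x$n_dropped))
  invisible(x)
}
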