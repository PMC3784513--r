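#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot normalized motif fractions
#'
#' Bar chart of F_i (or f_i when not normalized) over the canonical classes,
#' colored by P1 group.
#'
#' @param object Fraction table (see [motif_fractions()]).
#' @param ... Unused.
#' @method autoplot fraction_tbl
#' @export
autoplot.fraction_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$value <- if ("F" %in% names(df)) df$F else df$f
  lab <- if ("F" %in% names(df)) "normalized fraction F" else "fraction f"
  df <- df[!is.na(df$value), ]
  df$group <- ifelse(df$cgnn, "CGNN", ifelse(df$dgrn, "DGRN", "DGYN"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "canonical NGNN motif", y = lab, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a log-linear descriptor fit
#'
#' Scatter of ln(fraction) against the descriptor with the fitted line.
#'
#' @param object `loglin_fit` object.
#' @param ... Unused.
#' @method autoplot loglin_fit
#' @export
autoplot.loglin_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$lny)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2) +
    ggplot2::labs(
      x = object$x, y = paste0("ln(", object$y, ")"),
      subtitle = sprintf("r2 = %.2f, p = %.3g", object$r2, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot motif enrichment among recurrent coordinates
#'
#' @param object Enrichment table (see [motif_enrichment()]).
#' @param ... Unused.
#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::left_join(df, enumerate_motifs()[, c("motif", "cgnn")],
                         by = "motif")
  df$group <- ifelse(df$cgnn, "CGNN", "DGNN")
  ggplot2::ggplot(df[!is.na(df$E), ],
                  ggplot2::aes(x = .data$motif, y = .data$E,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "canonical NGNN motif",
                  y = "relative enrichment E", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a splice-junction mutation profile
#'
#' @param object `splice_profile` tibble.
#' @param ... Unused.
#' @method autoplot splice_profile
#' @export
autoplot.splice_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~type, ncol = 1) +
    ggplot2::labs(x = "position relative to junction (exonic < 0 for donors)",
                  y = "substitutions") +
    ggplot2::theme_minimal()
}

#' Plot base conservation around splice junctions
#'
#' @param object `junction_conservation` tibble.
#' @param ... Unused.
#' @method autoplot junction_conservation
#' @export
autoplot.junction_conservation <- function(object, ...) {
  df <- dplyr::distinct(tibble::as_tibble(object)[, c("type", "position",
                                                      "conservation")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$conservation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~type, ncol = 1) +
    ggplot2::labs(x = "position relative to junction",
                  y = "fractional conservation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-motif transcription-strand ratios
#'
#' @param object `strand_ratio_tbl` tibble.
#' @param ... Unused.
#' @method autoplot strand_ratio_tbl
#' @export
autoplot.strand_ratio_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$r)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "canonical NGNN motif",
                  y = "non-transcribed / transcribed ratio r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
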