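#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# -log10 p, capped; returns list(value, underflow)
minus_log10 <- function(p) {
  cap <- 308
  v <- -log10(p)
  underflow <- !is.finite(v) | v > cap
  v[underflow] <- cap
  list(value = v, underflow = underflow)
}

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for stochastic operations",
                          call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
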