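test_that("embedded ionization potentials look up correctly", {
  expect_equal(vip_lookup("GGG"), 5.39)
  expect_equal(vip_lookup("TGC"), 5.97)
  expect_equal(vip_lookup("G"), 8.02)
  expect_equal(vip_free_guanine(experimental = TRUE), 8.26)
  expect_error(vip_lookup("CGA"), "only the 12")
  expect_error(vip_lookup("GAT"), "only the 12")
})

test_that("the ionization table satisfies its physical ranking invariants", {
  vt <- vip_table()
  expect_equal(nrow(vt), 12)
  lut <- stats::setNames(vt$vip_ev, vt$trimer)
  # GGG is the global minimum
  expect_equal(names(which.min(lut)), "GGG")
  # every GG-doublet trimer lies below every single-G trimer
  doublet <- lut[c("GGG", "GGA", "GGT", "GGC", "AGG", "TGG")]
  single <- lut[setdiff(names(lut), names(doublet))]
  expect_lt(max(doublet), min(single))
  # 3' purine below 3' pyrimidine at fixed 5' base
  for (d in c("A", "G", "T")) {
    pur <- lut[paste0(d, "G", c("A", "G"))]
    pyr <- lut[paste0(d, "G", c("C", "T"))]
    expect_lt(max(pur, na.rm = TRUE), min(pyr, na.rm = TRUE))
  }
  # stacked guanine is easier to ionize than free guanine
  expect_lt(max(lut), vip_free_guanine())
})

test_that("mean stacking energy averages the three ordered steps", {
  toy <- tibble::tibble(
    step = as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0)),
    dg = 9)
  toy$dg[toy$step == "AG"] <- 1
  toy$dg[toy$step == "GT"] <- 2
  toy$dg[toy$step == "TT"] <- 3
  expect_equal(unname(mean_stacking_energy("AGTT", toy)), 2)
  # uniform table maps every motif to the constant
  uni <- tibble::tibble(step = toy$step, dg = 4.2)
  dg48 <- motif_subset("DGNN")
  expect_true(all(mean_stacking_energy(dg48, uni) == 4.2))
  # motifs sharing a multiset of steps get equal values
  set.seed(13)
  rnd <- tibble::tibble(step = toy$step, dg = stats::runif(16))
  vals <- mean_stacking_energy(dg48, rnd)
  key <- vapply(dg48, function(mo) {
    paste(sort(c(substr(mo, 1, 2), substr(mo, 2, 3), substr(mo, 3, 4))),
          collapse = "|")
  }, character(1))
  for (k in unique(key[duplicated(key)])) {
    expect_lt(diff(range(vals[key == k])), 1e-12)
  }
  expect_error(mean_stacking_energy("CGAA", toy), "DGNN")
  expect_equal(unname(mean_stacking_energy("CGAA", toy, allow_all = TRUE)),
               mean(c(9, 9, 9)))
})

test_that("the shipped placeholder table honors the stacking-class ordering", {
  tab <- default_stacking_table()
  expect_equal(attr(tab, "source"), "synthetic-placeholder")
  cls <- function(s) {
    pur <- c("A", "G")
    paste0(ifelse(substr(s, 1, 1) %in% pur, "R", "Y"),
           ifelse(substr(s, 2, 2) %in% pur, "R", "Y"))
  }
  by_class <- split(tab$dg, cls(tab$step))
  expect_gt(min(by_class$RR), max(by_class$RY))
  expect_gt(min(by_class$RY), max(by_class$YR))
  expect_gt(min(by_class$YR), max(by_class$YY))
  # schema check rejects incomplete tables
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab[-1, c("step", "dg")], bad)
  expect_error(read_stacking_table(bad), "16 dinucleotide steps")
})

test_that("trimer aggregation conserves counts", {
  ft <- motif_fractions(
    m_table(AGTA = 1, AGTC = 1, AGTG = 1, AGTT = 1),
    t_table(default = 100))
  tr <- aggregate_to_trimers(ft)
  expect_equal(tr$f[tr$trimer == "AGT"], 4 / 400)
  expect_equal(nrow(tr), 16)
  ft2 <- synth_fraction_table(seed = 31)
  tr2 <- aggregate_to_trimers(ft2)
  dgn <- substr(motif_subset("DGNN"), 1, 3)
  expect_equal(sum(tr2$m[tr2$trimer %in% dgn]),
               sum(ft2$m[ft2$motif %in% motif_subset("DGNN")]))
  expect_equal(sum(tr2$m), sum(ft2$m))
})

test_that("log-linear fits recover exact and null relationships", {
  d <- tibble::tibble(x = 1:5, y = exp(2 * (1:5)))
  f <- suppressWarnings(fit_log_linear(d, "y", "x", bootstrap_B = 200,
                                       seed = 4))
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(f$p_alpha, 1)
  # unrelated response: significance rarely persists, averaged over draws
  set.seed(99)
  stats0 <- purrr::map_dfr(1:10, function(i) {
    d0 <- tibble::tibble(x = stats::runif(48), y = exp(stats::rnorm(48)))
    f0 <- fit_log_linear(d0, "y", "x", bootstrap_B = 100, seed = i)
    tibble::tibble(r2 = f0$r2, p_alpha = f0$p_alpha)
  })
  expect_lt(mean(stats0$r2), 0.15)
  expect_lt(mean(stats0$p_alpha), 0.4)
  expect_error(fit_log_linear(tibble::tibble(x = c(1, 1, 1), y = c(1, 2, 3)),
                              "y", "x", bootstrap_B = 0), "constant")
  expect_error(fit_log_linear(tibble::tibble(x = 1:2, y = c(1, 2)),
                              "y", "x", bootstrap_B = 0), "3 usable")
})

test_that("log-linear fits are scale invariant in the response", {
  set.seed(17)
  d <- tibble::tibble(x = stats::runif(20), y = exp(-1.5 * stats::runif(20)))
  f1 <- fit_log_linear(d, "y", "x", bootstrap_B = 100, seed = 2)
  d10 <- dplyr::mutate(d, y = 10 * y)
  f2 <- fit_log_linear(d10, "y", "x", bootstrap_B = 100, seed = 2)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$r2, f2$r2)
  expect_equal(f1$p_value, f2$p_value)
  expect_equal(f2$intercept - f1$intercept, log(10))
  expect_identical(f1$p_alpha, f2$p_alpha)
})

test_that("bootstrap significance persistence is seed-reproducible", {
  set.seed(8)
  d <- tibble::tibble(x = stats::runif(30), y = exp(0.5 * stats::runif(30)))
  f1 <- fit_log_linear(d, "y", "x", bootstrap_B = 300, seed = 77)
  f2 <- fit_log_linear(d, "y", "x", bootstrap_B = 300, seed = 77)
  expect_identical(f1$p_alpha, f2$p_alpha)
  g <- glance(f1)
  expect_named(g, c("r2", "p_value", "p_alpha", "alpha", "bootstrap_B",
                    "n_used", "n_dropped"))
  td <- tidy(f1)
  expect_equal(td$term, c("intercept", "slope"))
})
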