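#' Spectrum matrix of context frequencies across datasets
#'
#' Builds the rows-by-motifs matrix used for dataset comparison: each row is
#' one dataset's mutated-context fractions scaled to unit sum. At trimer
#' level the tetramer fractions are first aggregated over the P4 base (see
#' [aggregate_to_trimers()]).
#'
#' @param fraction_tables Named list of fraction tables (one per dataset,
#'   from [motif_fractions()]).
#' @param level `"tetramer"` (64 columns) or `"trimer"` (16 columns).
#' @return Numeric matrix with one unit-sum row per dataset. All-zero rows
#'   are dropped with a warning.
#' @export
spectrum_matrix <- function(fraction_tables, level = c("tetramer", "trimer")) {
  level <- match.arg(level)
  if (length(fraction_tables) < 2) stop(">= 2 datasets required", call. = FALSE)
  if (is.null(names(fraction_tables))) {
    names(fraction_tables) <- paste0("dataset", seq_along(fraction_tables))
  }
  rows <- purrr::map(fraction_tables, function(ft) {
    if (level == "trimer") {
      tr <- aggregate_to_trimers(ft)
      stats::setNames(ifelse(is.na(tr$f), 0, tr$f), tr$trimer)
    } else {
      stats::setNames(ifelse(is.na(ft$f), 0, ft$f), ft$motif)
    }
  })
  m <- do.call(rbind, rows)
  sums <- rowSums(m)
  zero <- sums == 0
  if (any(zero)) {
    warning("all-zero spectrum row(s) excluded: ",
            paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
    m <- m[!zero, , drop = FALSE]
    sums <- sums[!zero]
  }
  sweep(m, 1, sums, "/")
}

#' Manhattan distance matrix between spectra
#'
#' d(a, b) = sum over columns of |a_j - b_j|.
#'
#' @param sm Spectrum matrix (rows = datasets).
#' @return Symmetric matrix with zero diagonal.
#' @export
manhattan_matrix <- function(sm) {
  if (nrow(sm) < 2) stop(">= 2 rows required", call. = FALSE)
  as.matrix(stats::dist(sm, method = "manhattan"))
}

#' Agglomerative clustering of context spectra with bootstrap support
#'
#' Clusters datasets by the Manhattan distance between their unit-sum
#' spectra, using average linkage by default, and attaches bootstrap cluster
#' support: columns of the spectrum matrix are resampled with replacement B
#' times, the tree is rebuilt, and each original cluster's support is the
#' fraction of replicates in which the identical leaf set reappears.
#' Clusters with support >= `conf` are flagged.
#'
#' @param sm Spectrum matrix (>= 3 rows for meaningful clusters), or any
#'   numeric matrix of per-dataset features (e.g. a 2-column matrix of
#'   regression slope and intercept).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param bootstrap_B Bootstrap replicates (default 1000; < 100 warns).
#' @param seed Seed for the resampling.
#' @param conf Support threshold to flag (default 0.90).
#' @return Object of class `spectrum_clust`: list with `hclust`, `support`
#'   tibble (`node`, `members`, `support`, `supported`), `B`, `seed`.
#'   Methods: [tidy()], `plot()`, [write_newick()].
#' @export
cluster_spectra <- function(sm, linkage = c("average", "single", "complete"),
                            bootstrap_B = 1000, seed = 1, conf = 0.90) {
  linkage <- match.arg(linkage)
  if (nrow(sm) < 3) stop(">= 3 rows required for clustering", call. = FALSE)
  if (bootstrap_B < 100) warning("fewer than 100 bootstrap replicates",
                                 call. = FALSE)
  build <- function(m) stats::hclust(stats::dist(m, method = "manhattan"),
                                     method = linkage)
  hc <- build(sm)
  clades <- tree_clades(hc)
  keys <- purrr::map_chr(clades, paste, collapse = "\r")
  hits <- stats::setNames(rep(0L, length(keys)), keys)
  with_seed(seed, {
    for (b in seq_len(bootstrap_B)) {
      cols <- sample.int(ncol(sm), ncol(sm), replace = TRUE)
      kb <- purrr::map_chr(tree_clades(build(sm[, cols, drop = FALSE])),
                           paste, collapse = "\r")
      found <- keys %in% kb
      hits[found] <- hits[found] + 1L
    }
  })
  support <- tibble::tibble(
    node = seq_along(clades),
    members = purrr::map(clades, identity),
    n_members = lengths(clades),
    support = as.numeric(hits) / bootstrap_B)
  support$supported <- support$support >= conf
  structure(list(hclust = hc, support = support, B = bootstrap_B,
                 seed = seed, conf = conf),
            class = "spectrum_clust")
}

# leaf-label sets of every internal node of an hclust tree, sorted
tree_clades <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) labs[-j] else sets[[j]]
    }))
    sets[[i]] <- sort(members)
  }
  sets
}

#' @method tidy spectrum_clust
#' @export
tidy.spectrum_clust <- function(x, ...) {
  out <- x$support
  out$members <- purrr::map_chr(out$members, paste, collapse = ",")
  out
}

#' @export
print.spectrum_clust <- function(x, ...) {
  cat(sprintf("spectrum clustering: %d leaves, %s linkage, B = %d\n",
              length(x$hclust$labels), x$hclust$method, x$B))
  n_sup <- sum(x$support$supported)
  cat(sprintf("  %d/%d clusters supported at >= %.0f%% bootstrap confidence\n",
              n_sup, nrow(x$support), 100 * x$conf))
  invisible(x)
}

#' @export
plot.spectrum_clust <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Export a clustering as Newick with support labels
#'
#' @param x `spectrum_clust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  phy <- ape::as.phylo(x$hclust)
  parts <- ape::prop.part(phy)
  labs <- phy$tip.label
  part_keys <- purrr::map_chr(parts, function(idx) {
    paste(sort(labs[idx]), collapse = "\r")
  })
  clade_keys <- purrr::map_chr(x$support$members, paste, collapse = "\r")
  node_support <- x$support$support[match(part_keys, clade_keys)]
  phy$node.label <- ifelse(is.na(node_support), "",
                           sprintf("%.3f", node_support))
  ape::write.tree(phy, file = path)
  invisible(path)
}
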