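#' Zero out insignificant scores
#'
#' Replaces entries that fail the one-tailed significance rule (standard
#' normal P above `alpha_significant`) with zero, focusing downstream
#' correlation and clustering on the most significant chemical-genetic
#' interactions. Significant entries are unchanged and missing entries stay
#' missing. Idempotent.
#'
#' @param x A `screen_matrix` of kind `"fd"` or `"z"` in sensitivity-positive
#'   orientation.
#' @param config An [analysis_config()].
#' @return A `screen_matrix` of the same kind.
#' @export
zero_insignificant <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "screen_matrix"))
  if (!value_kind(x) %in% c("fd", "z")) {
    abort("`x` must hold FD or z scores.")
  }
  if (orientation(x) != "sensitivity_positive") {
    abort("Harmonize `x` to sensitivity_positive before zeroing.")
  }
  vals <- as_plain_matrix(x)
  keep <- !is.na(vals) & vals >= z_threshold(config$alpha_significant)
  vals[!keep & !is.na(vals)] <- 0
  restamp(vals, x)
}

similarity_matrix <- function(values, n_shared, axis) {
  structure(list(values = values, n_shared = n_shared, axis = axis),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d %s, %d missing pair(s)\n",
              nrow(x$values), x$axis,
              sum(is.na(x$values[upper.tri(x$values)]))))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.similarity_matrix <- function(x, ...) {
  v <- x$values
  ut <- upper.tri(v)
  tibble(id_a = rownames(v)[row(v)[ut]], id_b = colnames(v)[col(v)[ut]],
         r = v[ut], n_shared = x$n_shared[ut])
}

#' @exportS3Method generics::tidy
tidy.similarity_matrix <- function(x, ...) as_tibble.similarity_matrix(x)

#' @exportS3Method generics::glance
glance.similarity_matrix <- function(x, ...) {
  ut <- upper.tri(x$values)
  tibble(axis = x$axis, n = nrow(x$values),
         mean_r = mean(x$values[ut], na.rm = TRUE),
         n_missing_pairs = sum(is.na(x$values[ut])))
}

pairwise_pearson <- function(m, ids, axis, min_shared_obs) {
  # pairwise-complete Pearson; constant vectors give NA, never NaN
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs",
                            method = "pearson"))
  obs <- !is.na(m)
  n_shared <- crossprod(obs)
  r[n_shared < min_shared_obs] <- NA_real_
  r[is.nan(r)] <- NA_real_
  diag(r)[colSums(obs) >= 1L] <- 1
  dimnames(r) <- list(ids, ids)
  dimnames(n_shared) <- list(ids, ids)
  similarity_matrix(r, n_shared, axis)
}

#' Coinhibition: screen-by-screen profile similarity
#'
#' The Pearson correlation between two screens' FD profiles across strains.
#' High coinhibition between two compounds implies a shared mechanism of
#' action. Correlations use pairwise-complete strains; pairs sharing fewer
#' than `min_shared_obs` strains are missing, as are pairs involving a
#' zero-variance profile.
#'
#' @param x A `screen_matrix`; apply [zero_insignificant()] first for the
#'   clustering convention (`zero = TRUE` does it for you), or pass full
#'   profiles with `zero = FALSE` for pairwise profile comparisons.
#' @param config An [analysis_config()].
#' @param zero Zero insignificant entries first? Default `TRUE` (the
#'   clustering convention).
#' @return A `similarity_matrix` with `axis = "screens"`.
#' @export
coinhibition <- function(x, config = analysis_config(), zero = TRUE) {
  stopifnot(inherits(x, "screen_matrix"))
  if (zero) x <- zero_insignificant(x, config)
  pairwise_pearson(as_plain_matrix(x), colnames(x), "screens",
                   config$min_shared_obs)
}

#' Cofitness: gene-by-gene fitness-profile similarity
#'
#' The Pearson correlation between two genes' FD scores across screens. High
#' cofitness implies shared gene function.
#'
#' @inheritParams coinhibition
#' @return A `similarity_matrix` with `axis = "genes"`.
#' @export
cofitness <- function(x, config = analysis_config(), zero = FALSE) {
  stopifnot(inherits(x, "screen_matrix"))
  if (zero) x <- zero_insignificant(x, config)
  pairwise_pearson(t(as_plain_matrix(x)), rownames(x), "genes",
                   config$min_shared_obs)
}

#' Most variable genes
#'
#' Ranks genes by the standard deviation of their scores across screens
#' (pairwise-complete) and returns the top fraction — the genes whose
#' deletion strains are actually perturbed by compounds, used to focus
#' cross-dataset gene comparisons.
#'
#' @param x A `screen_matrix` with at least 2 screens.
#' @param fraction Fraction of genes to keep (default
#'   `top_variable_fraction` from [analysis_config()], 0.05).
#' @return Character vector of gene ids, most variable first.
#' @export
top_variable_genes <- function(x, fraction = 0.05) {
  stopifnot(inherits(x, "screen_matrix"), ncol(x) >= 2L)
  sds <- apply(as_plain_matrix(x), 1L, sd, na.rm = TRUE)
  sds[!is.finite(sds)] <- -Inf
  n <- ceiling(fraction * nrow(x))
  names(sort(sds, decreasing = TRUE))[seq_len(n)]
}

#' Per-gene correlation between two datasets
#'
#' For every gene present in both matrices, the Pearson correlation between
#' its FD vectors across paired compounds — the "same gene across sites"
#' comparison. Restricting to the most variable genes raises the typical
#' correlation substantially, since unperturbed genes contribute only noise.
#'
#' @param a,b `screen_matrix` objects harmonized to sensitivity-positive.
#' @param pairs Tibble pairing screens: columns `screen_a`, `screen_b`.
#' @param config An [analysis_config()].
#' @return Tibble: `strain_id`, `r`, `n`; attribute `"summary"` holds the
#'   median r overall and over the top-variable genes, plus skipped-gene
#'   counts.
#' @export
cross_dataset_gene_correlation <- function(a, b, pairs,
                                           config = analysis_config()) {
  stopifnot(inherits(a, "screen_matrix"), inherits(b, "screen_matrix"))
  if (orientation(a) != "sensitivity_positive" ||
      orientation(b) != "sensitivity_positive") {
    abort("Harmonize both matrices to sensitivity_positive first.")
  }
  pairs <- pairs[pairs$screen_a %in% colnames(a) &
                   pairs$screen_b %in% colnames(b), ]
  if (nrow(pairs) < 3L) abort("Need at least 3 paired screens.")
  shared <- intersect(rownames(a), rownames(b))
  skipped <- length(union(rownames(a), rownames(b))) - length(shared)
  ma <- as_plain_matrix(a)[shared, pairs$screen_a, drop = FALSE]
  mb <- as_plain_matrix(b)[shared, pairs$screen_b, drop = FALSE]
  r <- vapply(seq_along(shared), function(i) {
    ok <- is.finite(ma[i, ]) & is.finite(mb[i, ])
    if (sum(ok) < 3L || sd(ma[i, ok]) == 0 || sd(mb[i, ok]) == 0) {
      return(NA_real_)
    }
    cor(ma[i, ok], mb[i, ok])
  }, numeric(1))
  n <- rowSums(is.finite(ma) & is.finite(mb))
  out <- tibble(strain_id = shared, r = r, n = as.integer(n))
  top <- intersect(top_variable_genes(a, config$top_variable_fraction), shared)
  attr(out, "summary") <- tibble(
    median_r = median(r, na.rm = TRUE),
    median_r_top_variable = median(r[shared %in% top], na.rm = TRUE),
    n_genes = length(shared),
    n_skipped = skipped
  )
  out
}
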