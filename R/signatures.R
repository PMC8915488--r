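#' Ward dendrogram on (1 - coinhibition)
#'
#' Hierarchically clusters screens using `1 - coinhibition` as the distance
#' and the Ward agglomeration method (Lance-Williams "ward.D" update on the
#' precomputed dissimilarity, the convention for correlation-derived
#' distances). Pairs whose correlation is missing (too few shared strains)
#' are placed at distance 1 — zero similarity, a conservative neutral
#' placement.
#'
#' @param sim A `similarity_matrix` with `axis = "screens"` (see
#'   [coinhibition()]).
#' @param missing_distance Distance substituted for missing pairs (default 1).
#' @return An [stats::hclust] tree.
#' @export
ward_dendrogram <- function(sim, missing_distance = 1) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (sim$axis != "screens") abort("`sim` must be a screen similarity.")
  r <- sim$values
  if (nrow(r) < 2L) abort("Need at least 2 screens to cluster.")
  d <- 1 - r
  d[is.na(d)] <- missing_distance
  diag(d) <- 0
  hclust(as.dist(d), method = "ward.D")
}

#' Export a dendrogram as Newick
#'
#' @param hc An [stats::hclust] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

# decreasing gap threshold: higher deep_split splits on smaller height drops
deep_split_gap <- function(deep_split) {
  c(0.25, 0.18, 0.12, 0.06, 0.02)[deep_split + 1L]
}

#' Dynamic branch cutting
#'
#' Adaptive extraction of discrete clusters from a dendrogram, replacing the
#' single fixed cut of `cutree`. Branches merging above `cut_height`
#' (default: the 99th percentile of merge heights) are never joined; below
#' it, each candidate branch is examined for internal height gaps: where the
#' jump between consecutive merge heights inside the branch exceeds
#' `min_gap` times the whole tree's height range, the branch is severed in
#' that gap (at the highest such gap first) and the resulting sub-branches
#' are re-examined recursively. A cut is only taken when at least one
#' resulting piece keeps `min_cluster_size` members, so clusters are never
#' dissolved entirely into fragments. `deep_split` (0-4) lowers the default
#' gap threshold, making splitting more aggressive. Branches smaller than
#' `min_cluster_size` are unassigned (cluster 0). Deterministic given the
#' tree; labels are ordered by decreasing cluster size.
#'
#' @param hc An [stats::hclust] tree.
#' @param params A [cluster_params()].
#' @return Named integer vector: leaf label -> cluster id (0 = unassigned).
#' @export
#' @examples
#' d <- dist(c(a1 = 0, a2 = 0.1, b1 = 5, b2 = 5.1, b3 = 4.9, a3 = 0.2))
#' hc <- hclust(d, method = "ward.D")
#' dynamic_cut(hc, cluster_params(min_cluster_size = 3))
dynamic_cut <- function(hc, params = cluster_params()) {
  stopifnot(inherits(hc, "hclust"), inherits(params, "cluster_params"))
  n <- length(hc$labels)
  h <- hc$height
  cut_h <- params$cut_height %||% quantile(h, 0.99, type = 7, names = FALSE)
  gap_frac <- params$min_gap %||% deep_split_gap(params$deep_split)
  gap_abs <- gap_frac * (max(h) - min(h))

  # per-node leaf sets and merge-height sets (node k = row k of hc$merge)
  leaves <- vector("list", nrow(hc$merge))
  merges <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    ch <- hc$merge[k, ]
    leaves[[k]] <- unlist(lapply(ch, function(x) {
      if (x < 0L) -x else leaves[[x]]
    }))
    merges[[k]] <- c(k, unlist(lapply(ch[ch > 0L], function(x) merges[[x]])))
  }

  # sub-branches left after removing every merge above `level` in branch k
  sever <- function(k, level) {
    if (k < 0L || h[k] <= level) return(list(k))
    c(sever(hc$merge[k, 1L], level), sever(hc$merge[k, 2L], level))
  }
  branch_size <- function(k) if (k < 0L) 1L else length(leaves[[k]])

  clusters <- list()
  descend <- function(k) {
    if (k < 0L) {
      clusters[[length(clusters) + 1L]] <<- -k
      return(invisible())
    }
    level <- NULL
    if (h[k] > cut_h) {
      level <- cut_h  # absolute ceiling: no size guard
    } else {
      hs <- sort(h[merges[[k]]])
      gaps <- diff(hs)
      for (q in rev(which(gaps > gap_abs))) {
        cand <- (hs[q] + hs[q + 1L]) / 2
        pieces <- sever(k, cand)
        if (any(vapply(pieces, branch_size, integer(1)) >=
                  params$min_cluster_size)) {
          level <- cand
          break
        }
      }
    }
    if (is.null(level)) {
      clusters[[length(clusters) + 1L]] <<- leaves[[k]]
    } else {
      for (p in sever(k, level)) descend(p)
    }
  }
  descend(nrow(hc$merge))

  sizes <- lengths(clusters)
  keep <- which(sizes >= params$min_cluster_size)
  first_leaf <- vapply(clusters, min, integer(1))
  keep <- keep[order(-sizes[keep], first_leaf[keep])]
  assignment <- stats::setNames(integer(n), hc$labels)
  for (i in seq_along(keep)) {
    assignment[clusters[[keep[i]]]] <- i
  }
  assignment
}

#' Median FD profile of a cluster
#'
#' Per gene, the median score over the cluster's member screens
#' (pairwise-complete); genes missing in every member stay missing.
#'
#' @param members Character vector of member screen ids.
#' @param x A `screen_matrix` of FD scores.
#' @return Named numeric vector over the genes of `x`.
#' @export
median_profile <- function(members, x) {
  stopifnot(inherits(x, "screen_matrix"))
  members <- intersect(members, colnames(x))
  if (length(members) == 0L) abort("Cluster has no member screens in `x`.")
  apply(as_plain_matrix(x)[, members, drop = FALSE], 1L, median, na.rm = TRUE)
}

#' Characteristic signature genes of a median profile
#'
#' Genes whose median FD is significantly positive: median FD >=
#' qnorm(1 - alpha). The single-dataset convention uses alpha = 0.001; the
#' combined two-dataset analysis relaxes to 0.05.
#'
#' @param profile Named numeric vector of per-gene medians
#'   (sensitivity-positive).
#' @param alpha One-tailed significance level.
#' @return Character vector of gene ids.
#' @export
signature_genes <- function(profile, alpha = 0.001) {
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  names(profile)[!is.na(profile) & profile >= z_threshold(alpha)]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene set of
#' interest and each annotation set, within the analyzed universe, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param gene_set Character vector (e.g. signature genes); intersected with
#'   the universe.
#' @param universe Character vector of all genes in the analyzed matrix.
#' @param gmt_sets Named list of gene sets (see [read_gmt()]); each set is
#'   intersected with the universe.
#' @return Tibble: `set`, `set_size`, `overlap`, `p`, `p_adj`,
#'   `overlap_genes` (list column), sorted by p.
#' @export
enrich <- function(gene_set, universe, gmt_sets) {
  if (length(universe) == 0L) abort("`universe` is empty.")
  gene_set <- intersect(gene_set, universe)
  rows <- purrr::map_dfr(names(gmt_sets), function(nm) {
    members <- intersect(gmt_sets[[nm]], universe)
    ov <- intersect(gene_set, members)
    p <- stats::phyper(length(ov) - 1L, length(members),
                       length(universe) - length(members), length(gene_set),
                       lower.tail = FALSE)
    tibble(set = nm, set_size = length(members), overlap = length(ov), p = p,
           overlap_genes = list(ov))
  })
  rows$p_adj <- p.adjust(rows$p, method = "BH")
  dplyr::arrange(rows[, c("set", "set_size", "overlap", "p", "p_adj",
                          "overlap_genes")], .data$p)
}

#' Extract response signatures from a clustering
#'
#' For every nonzero cluster: the median FD profile over member screens, its
#' characteristic signature genes, and (when a gene-set collection is given)
#' hypergeometric GO-style enrichment against the matrix's gene universe.
#' The published retention rule is applied by [filter_signatures()]:
#' signatures with fewer than two genes and no enriched set are flagged for
#' omission.
#'
#' @param x A `screen_matrix` of FD scores (sensitivity-positive).
#' @param clusters Named integer vector from [dynamic_cut()].
#' @param gmt_sets Optional named list of gene sets for enrichment.
#' @param alpha Significance level for signature genes (0.001 single-dataset
#'   convention; use 0.05 for a combined matrix).
#' @param config An [analysis_config()].
#' @return A tibble of class `response_signatures`: `cluster`, `n_screens`,
#'   `members` (list), `median_profile` (list), `n_genes`,
#'   `signature_genes` (list), `enrichment` (list of tibbles), `retained`.
#' @export
response_signatures <- function(x, clusters, gmt_sets = NULL, alpha = 0.001,
                                config = analysis_config()) {
  stopifnot(inherits(x, "screen_matrix"))
  clusters <- clusters[names(clusters) %in% colnames(x)]
  ids <- sort(unique(clusters[clusters > 0L]))
  universe <- rownames(x)
  rows <- purrr::map_dfr(ids, function(k) {
    members <- names(clusters)[clusters == k]
    prof <- median_profile(members, x)
    genes <- signature_genes(prof, alpha)
    enr <- if (!is.null(gmt_sets)) enrich(genes, universe, gmt_sets) else NULL
    tibble(cluster = k, n_screens = length(members), members = list(members),
           median_profile = list(prof), n_genes = length(genes),
           signature_genes = list(genes),
           enrichment = list(enr))
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(cluster = integer(0), n_screens = integer(0),
                   members = list(), median_profile = list(),
                   n_genes = integer(0), signature_genes = list(),
                   enrichment = list())
  }
  rows$retained <- purrr::map2_lgl(rows$n_genes, rows$enrichment,
                                   signature_retained)
  class(rows) <- c("response_signatures", class(rows))
  rows
}

signature_retained <- function(n_genes, enrichment, p_cut = 0.05) {
  if (n_genes >= 2L) return(TRUE)
  !is.null(enrichment) && nrow(enrichment) > 0L &&
    any(enrichment$p_adj <= p_cut, na.rm = TRUE)
}

#' Retain response signatures worth reporting
#'
#' Drops signatures with fewer than two characteristic genes that are also
#' not enriched for any biological process (BH-adjusted p <= 0.05).
#'
#' @param signatures A `response_signatures` tibble.
#' @return The retained subset, same class.
#' @export
filter_signatures <- function(signatures) {
  stopifnot(inherits(signatures, "response_signatures"))
  signatures[signatures$retained, ]
}

#' @exportS3Method generics::glance
glance.response_signatures <- function(x, ...) {
  tibble(n_clusters = nrow(x), n_retained = sum(x$retained),
         n_screens_clustered = sum(x$n_screens),
         median_signature_size = median(x$n_genes[x$retained]))
}

#' @exportS3Method generics::tidy
tidy.response_signatures <- function(x, ...) {
  tidyr::unnest(
    tibble(cluster = x$cluster, strain_id = x$signature_genes),
    "strain_id"
  )
}
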