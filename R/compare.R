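#' Merge two sites' score matrices
#'
#' Column-binds two harmonized matrices (screen ids must be disjoint —
#' prefix them by site). `policy = "union"` keeps the union of strains with
#' missing values where a strain is absent from one site (the convention
#' behind merging a 3356-screen and a 2725-screen matrix into one
#' 6081-screen matrix); `policy = "intersect"` keeps only shared strains.
#'
#' @param a,b `screen_matrix` objects in sensitivity-positive orientation.
#' @param policy `"union"` (default) or `"intersect"`.
#' @return A merged `screen_matrix`.
#' @export
merge_datasets <- function(a, b, policy = c("union", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(inherits(a, "screen_matrix"), inherits(b, "screen_matrix"))
  if (orientation(a) != "sensitivity_positive" ||
      orientation(b) != "sensitivity_positive") {
    abort("Harmonize both matrices to sensitivity_positive before merging.")
  }
  overlap <- intersect(colnames(a), colnames(b))
  if (length(overlap)) {
    abort(sprintf(
      "Screen id(s) present in both matrices (%s ...): prefix them by site.",
      overlap[1L]))
  }
  strains <- if (policy == "union") {
    union(rownames(a), rownames(b))
  } else {
    intersect(rownames(a), rownames(b))
  }
  strains <- sort(strains)
  out <- matrix(NA_real_, length(strains), ncol(a) + ncol(b),
                dimnames = list(strains, c(colnames(a), colnames(b))))
  ra <- intersect(strains, rownames(a))
  rb <- intersect(strains, rownames(b))
  out[ra, colnames(a)] <- as_plain_matrix(a)[ra, , drop = FALSE]
  out[rb, colnames(b)] <- as_plain_matrix(b)[rb, , drop = FALSE]
  screen_matrix(out, value_kind = value_kind(a),
                orientation = "sensitivity_positive")
}

#' Overlap coefficient between two gene sets
#'
#' The Szymkiewicz-Simpson coefficient `|A intersect B| / min(|A|, |B|)`:
#' 1 when one (nonempty) set contains the other, 0 when disjoint or when
#' either set is empty.
#'
#' @param a,b Character vectors.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' overlap_coefficient(c("a", "b", "c"), c("b", "c", "d"))  # 2/3
overlap_coefficient <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Match response signatures across datasets
#'
#' For every signature of dataset A, finds its best-overlapping partner in
#' dataset B by overlap coefficient of the signature gene sets; a signature
#' counts as detected in the other dataset when its best overlap reaches
#' `overlap_match_threshold` (default 0.5). Matching is best-partner
#' (argmax), not one-to-one. The full overlap matrix is always returned so
#' any threshold can be applied post hoc.
#'
#' @param sigs_a,sigs_b `response_signatures` tibbles (typically after
#'   [filter_signatures()]).
#' @param config An [analysis_config()].
#' @param names_a,names_b Labels for the two datasets in the report.
#' @return A `signature_match` object: list with `pairs` (tibble:
#'   `direction`, `from`, `to`, `overlap_coefficient`, `shared_genes`,
#'   `detected`), `overlap` (full matrix A x B), `report` (tibble per
#'   direction: `n`, `n_matched`, `matched_fraction`), and `exclusive`
#'   (per-dataset unmatched signature ids).
#' @export
match_signatures <- function(sigs_a, sigs_b, config = analysis_config(),
                             names_a = "A", names_b = "B") {
  stopifnot(inherits(sigs_a, "response_signatures"),
            inherits(sigs_b, "response_signatures"))
  if (nrow(sigs_a) == 0L || nrow(sigs_b) == 0L) {
    abort("Both signature lists must be nonempty.")
  }
  ga <- stats::setNames(sigs_a$signature_genes, sigs_a$cluster)
  gb <- stats::setNames(sigs_b$signature_genes, sigs_b$cluster)
  ov <- outer(seq_along(ga), seq_along(gb),
              Vectorize(function(i, j) overlap_coefficient(ga[[i]], gb[[j]])))
  dimnames(ov) <- list(names(ga), names(gb))
  thr <- config$overlap_match_threshold

  best_pairs <- function(ovm, gfrom, gto, direction) {
    purrr::map_dfr(seq_len(nrow(ovm)), function(i) {
      j <- which.max(ovm[i, ])
      tibble(direction = direction,
             from = rownames(ovm)[i], to = colnames(ovm)[j],
             overlap_coefficient = ovm[i, j],
             shared_genes = list(intersect(gfrom[[i]], gto[[j]])),
             detected = ovm[i, j] >= thr)
    })
  }
  pairs <- dplyr::bind_rows(
    best_pairs(ov, ga, gb, paste0(names_a, "->", names_b)),
    best_pairs(t(ov), gb, ga, paste0(names_b, "->", names_a))
  )
  report <- dplyr::summarise(
    dplyr::group_by(pairs, .data$direction),
    n = dplyr::n(), n_matched = sum(.data$detected),
    matched_fraction = mean(.data$detected), .groups = "drop")
  exclusive <- list(
    pairs$from[pairs$direction == paste0(names_a, "->", names_b) &
                 !pairs$detected],
    pairs$from[pairs$direction == paste0(names_b, "->", names_a) &
                 !pairs$detected]
  )
  names(exclusive) <- c(names_a, names_b)
  structure(list(pairs = pairs, overlap = ov, report = report,
                 exclusive = exclusive, threshold = thr),
            class = "signature_match")
}

#' @export
print.signature_match <- function(x, ...) {
  cat("<signature_match>\n")
  print(x$report)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.signature_match <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.signature_match <- function(x, ...) {
  tidyr::pivot_wider(x$report[, c("direction", "matched_fraction")],
                     names_from = "direction",
                     values_from = "matched_fraction")
}

#' Run the full comparative pipeline
#'
#' Orchestrates the per-site analysis end to end: harmonize orientations,
#' zero insignificant scores, compute coinhibition, cluster (Ward + dynamic
#' branch cut), extract and filter response signatures, call HIP hits and
#' tabulate target frequencies, then match signatures across the two sites
#' and merge the matrices. Deterministic given the same inputs and
#' configuration.
#'
#' @param a,b `screen_matrix` FD/z matrices for the two sites (any
#'   orientation; harmonized internally).
#' @param meta Screen metadata tibble (`screen_id`, `site`, ...) covering
#'   both matrices.
#' @param gmt_sets Optional gene-set collection for enrichment.
#' @param config An [analysis_config()].
#' @param params A [cluster_params()] used for both sites.
#' @param alpha Signature-gene significance level (default
#'   `config$alpha_significant`).
#' @param names_a,names_b Site labels.
#' @param merge_policy Strain policy for the merged matrix.
#' @return A `hiphop_comparison` object: list with `signatures` (per site),
#'   `match`, `hits` (per site), `target_freq`, `merged`, `clusters`
#'   (per-site assignments), `dendrograms`, and `manifest`.
#' @export
run_pipeline <- function(a, b, meta, gmt_sets = NULL,
                         config = analysis_config(),
                         params = cluster_params(),
                         alpha = config$alpha_significant,
                         names_a = "HIPLAB", names_b = "NIBR",
                         merge_policy = "union") {
  inputs <- list(a = harmonize_orientation(a), b = harmonize_orientation(b))
  names(inputs) <- c(names_a, names_b)

  analyze_site <- function(m) {
    sim <- coinhibition(m, config, zero = TRUE)
    hc <- ward_dendrogram(sim)
    cl <- dynamic_cut(hc, params)
    sigs <- response_signatures(m, cl, gmt_sets = gmt_sets, alpha = alpha,
                                config = config)
    list(similarity = sim, dendrogram = hc, clusters = cl,
         signatures = sigs, hits = hip_hits(m, config))
  }
  per_site <- lapply(inputs, analyze_site)

  retained <- lapply(per_site, function(s) filter_signatures(s$signatures))
  match <- match_signatures(retained[[1L]], retained[[2L]], config,
                            names_a = names_a, names_b = names_b)
  all_hits <- dplyr::bind_rows(lapply(per_site, `[[`, "hits"))
  merged <- merge_datasets(inputs[[1L]], inputs[[2L]], policy = merge_policy)

  structure(
    list(
      signatures = lapply(per_site, `[[`, "signatures"),
      match = match,
      hits = lapply(per_site, `[[`, "hits"),
      target_freq = target_frequency(all_hits, meta),
      clusters = lapply(per_site, `[[`, "clusters"),
      dendrograms = lapply(per_site, `[[`, "dendrogram"),
      similarity = lapply(per_site, `[[`, "similarity"),
      merged = merged,
      manifest = list(
        package_version = as.character(utils::packageVersion("hiphopr")),
        config = unclass(config),
        params = unclass(params),
        alpha = alpha,
        sites = stats::setNames(
          lapply(inputs, function(m) list(n_strains = nrow(m),
                                          n_screens = ncol(m))),
          names(inputs)),
        merge_policy = merge_policy,
        merged_dim = dim(merged)
      )
    ),
    class = "hiphop_comparison"
  )
}

#' @export
print.hiphop_comparison <- function(x, ...) {
  cat("<hiphop_comparison>\n")
  ms <- x$manifest$sites
  for (nm in names(ms)) {
    cat(sprintf("  %s: %d strains x %d screens, %d retained signature(s)\n",
                nm, ms[[nm]]$n_strains, ms[[nm]]$n_screens,
                sum(x$signatures[[nm]]$retained)))
  }
  print(x$match$report)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.hiphop_comparison <- function(x, ...) {
  gl <- glance(x$match)
  dplyr::bind_cols(
    tibble(n_strains_merged = nrow(x$merged),
           n_screens_merged = ncol(x$merged),
           n_hits = sum(vapply(x$hits, nrow, integer(1)))),
    gl
  )
}

#' Write pipeline artifacts to a directory
#'
#' Emits the structured results of [run_pipeline()]: the manifest and
#' signature matches as JSON, hit and target-frequency tables as TSV,
#' cluster assignments as TSV, dendrograms as Newick, and the merged matrix
#' in the delimited format of [write_matrix()].
#'
#' @param x A `hiphop_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(x, dir) {
  stopifnot(inherits(x, "hiphop_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(report = x$match$report, pairs = x$match$pairs[, 1:4],
         exclusive = x$match$exclusive),
    file.path(dir, "signature_matches.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(dplyr::bind_rows(x$hits, .id = "site"),
                     file.path(dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$target_freq, file.path(dir, "target_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(x$clusters)) {
    utils::write.table(
      tibble(screen_id = names(x$clusters[[nm]]),
             cluster = unname(x$clusters[[nm]])),
      file.path(dir, sprintf("clusters_%s.tsv", nm)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    export_dendrogram(x$dendrograms[[nm]],
                      file.path(dir, sprintf("dendrogram_%s.nwk", nm)))
  }
  write_matrix(x$merged, file.path(dir, "merged_matrix.tsv"))
  invisible(dir)
}
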