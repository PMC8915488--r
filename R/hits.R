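#' Clearance specificity scores for one screen
#'
#' Clearance measures how far a putative drug target's fitness defect stands
#' clear of the rest of the profile. Strains are ordered by FD descending
#' (ties broken lexicographically by strain id) and the gap after position i
#' is `FD_(i) - FD_(i+1)`, computed among strains with FD > 0 (the default;
#' set `clearance_positive_only = FALSE` in the config to use all strains).
#' `clearance_max` is the largest such gap (at the highest-FD position when
#' tied) and `fd_max` the FD of the strain sitting on it. Every strain with
#' FD >= `fd_max` is assigned `clearance_max` as its clearance; every other
#' strain keeps its own gap. With fewer than two qualifying strains,
#' `clearance_max` is 0 and nothing can be a hit.
#'
#' @param profile Named numeric vector of FD scores (sensitivity-positive)
#'   for one screen; at least two finite values.
#' @param config An [analysis_config()].
#' @return A `clearance_result`: list with `screen` (tibble: `strain_id`,
#'   `fd`, `rank`, `gap_after`, `clearance`), `clearance_max`, `fd_max`.
#' @export
#' @examples
#' clearance_scores(c(A = 12, B = 4, C = 3.5, D = 1))$clearance_max
clearance_scores <- function(profile, config = analysis_config()) {
  profile <- profile[is.finite(profile)]
  if (length(profile) < 2L) {
    abort("Need at least two strains with finite FD.")
  }
  ord <- order(-profile, names(profile), method = "radix")
  fd <- profile[ord]
  n <- length(fd)
  gap <- c(fd[-n] - fd[-1L], NA_real_)
  eligible <- if (config$clearance_positive_only) fd > 0 else rep(TRUE, n)
  eligible[n] <- FALSE  # the last strain has no successor gap
  if (sum(fd > 0) >= 2L && any(eligible)) {
    idx <- which(eligible)
    best <- idx[which.max(gap[idx])]  # ties: highest-FD position wins
    clearance_max <- gap[best]
    fd_max <- fd[best]
  } else {
    clearance_max <- 0
    fd_max <- Inf
    eligible[] <- FALSE
  }
  gap[!eligible] <- NA_real_  # no gap defined outside the eligible prefix
  clearance <- ifelse(fd >= fd_max, clearance_max, gap)
  structure(
    list(
      screen = tibble(strain_id = names(fd), fd = unname(fd),
                      rank = seq_len(n), gap_after = unname(gap),
                      clearance = unname(clearance)),
      clearance_max = unname(clearance_max),
      fd_max = unname(if (is.finite(fd_max)) fd_max else NA_real_)
    ),
    class = "clearance_result"
  )
}

#' @export
print.clearance_result <- function(x, ...) {
  cat(sprintf("<clearance_result> %d strains, clearance_max = %.3g (FD %.3g)\n",
              nrow(x$screen), x$clearance_max, x$fd_max))
  print(utils::head(x$screen, 5L))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clearance_result <- function(x, ...) x$screen

#' @exportS3Method generics::glance
glance.clearance_result <- function(x, ...) {
  tibble(n_strains = nrow(x$screen), clearance_max = x$clearance_max,
         fd_max = x$fd_max)
}

#' Designate HIP hits
#'
#' A strain is a HIP hit when its FD is significant (one-tailed standard
#' normal P below `alpha_significant`) and its assigned clearance is at least
#' `clearance_threshold` (default 5.75). When `clearance_max` falls below the
#' threshold the screen has no hits.
#'
#' @param result A `clearance_result` from [clearance_scores()].
#' @param significant Optional named logical vector (or one-column slice of a
#'   [significance_mask()]) marking significant strains; by default the
#'   HIPLAB FD rule is applied to the profile itself.
#' @param config An [analysis_config()].
#' @return Tibble of hits: `strain_id`, `fd`, `clearance`.
#' @export
call_hip_hits <- function(result, significant = NULL,
                          config = analysis_config()) {
  stopifnot(inherits(result, "clearance_result"))
  scr <- result$screen
  if (is.null(significant)) {
    sig <- scr$fd >= z_threshold(config$alpha_significant)
  } else {
    sig <- as.logical(significant[scr$strain_id])
    sig[is.na(sig)] <- FALSE
  }
  hit <- sig & !is.na(scr$clearance) &
    scr$clearance >= config$clearance_threshold
  scr[hit, c("strain_id", "fd", "clearance")]
}

#' Call HIP hits across a whole matrix
#'
#' Applies [clearance_scores()] and [call_hip_hits()] to every screen of an
#' FD matrix (harmonizing orientation first if needed).
#'
#' @param x A `screen_matrix` of FD scores.
#' @param config An [analysis_config()].
#' @return Tibble: `screen_id`, `strain_id`, `fd`, `clearance`,
#'   `clearance_max`.
#' @export
hip_hits <- function(x, config = analysis_config()) {
  x <- harmonize_orientation(x)
  vals <- as_plain_matrix(x)
  purrr::map_dfr(colnames(vals), function(sc) {
    profile <- vals[, sc]
    profile <- profile[is.finite(profile)]
    if (length(profile) < 2L) return(tibble())
    res <- clearance_scores(profile, config)
    hits <- call_hip_hits(res, config = config)
    if (nrow(hits) == 0L) return(tibble())
    dplyr::mutate(hits, screen_id = sc, clearance_max = res$clearance_max,
                  .before = 1L)
  })
}

#' Tabulate target frequency across screens
#'
#' Counts, for every gene, the screens in which it was called a HIP hit,
#' split by research site and overall, plus the site-exclusive gene lists —
#' the comparison behind "most frequently targeted genes".
#'
#' @param hits Tibble of hits with `screen_id` and `strain_id` (e.g. from
#'   [hip_hits()]).
#' @param meta Screen metadata tibble with `screen_id` and `site`.
#' @return Tibble sorted by descending total count: `strain_id`, one count
#'   column per site, `total`, `exclusive_to` (site name or `NA`).
#' @export
target_frequency <- function(hits, meta) {
  if (nrow(hits) == 0L) {
    return(tibble(strain_id = character(0), total = integer(0),
                  exclusive_to = character(0)))
  }
  joined <- dplyr::left_join(hits, meta[, c("screen_id", "site")],
                             by = "screen_id")
  joined$site[is.na(joined$site)] <- "unknown"
  counts <- dplyr::count(joined, .data$strain_id, .data$site)
  wide <- tidyr::pivot_wider(counts, names_from = "site",
                             values_from = "n", values_fill = 0L)
  site_cols <- setdiff(names(wide), "strain_id")
  wide$total <- rowSums(wide[site_cols])
  wide$exclusive_to <- apply(wide[site_cols], 1L, function(r) {
    nz <- site_cols[r > 0]
    if (length(nz) == 1L) nz else NA_character_
  })
  dplyr::arrange(wide, dplyr::desc(.data$total), .data$strain_id)
}
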