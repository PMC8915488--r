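#' Median-polish normalization with batch correction
#'
#' Normalizes raw tag intensities across arrays by iterative median sweeps on
#' the log2 scale, decomposing each (strain, tag) x array cell into
#' overall + array effect + batch effect + residual. Array and batch effects
#' are removed; the returned signal is `2^(overall + residual)`, so
#' strain-level structure (which lives in the rows) is untouched. Each tag
#' kind (uptag/downtag) is polished separately, matching the convention of
#' normalizing the tag sets independently. Sweeps stop when the largest
#' absolute effect update falls below 1e-6 or after 20 iterations.
#'
#' @param intensities Tag-intensity tibble with columns `strain_id`, `tag`,
#'   `array_id`, `signal` (> 0), `role`, `batch`, `study_id`, `used`.
#'   Unused (background) features are passed through unchanged.
#' @return The input tibble with normalized `signal`; the estimated effects
#'   are attached as attribute `"effects"` (tibble: tag, array_id, batch,
#'   array_effect, batch_effect, overall).
#' @export
median_polish_normalize <- function(intensities) {
  check_intensity_table(intensities)
  used <- intensities[intensities$used, , drop = FALSE]
  rest <- intensities[!intensities$used, , drop = FALSE]
  if (length(unique(used$array_id)) < 2L) {
    warn("Fewer than 2 arrays; median polish skipped.")
    return(intensities)
  }
  effects <- list()
  out <- lapply(split(used, used$tag), function(tab) {
    strains <- unique(tab$strain_id)
    arr_ids <- unique(tab$array_id)
    m <- matrix(NA_real_, length(strains), length(arr_ids),
                dimnames = list(strains, arr_ids))
    m[cbind(match(tab$strain_id, strains),
            match(tab$array_id, arr_ids))] <- log2(tab$signal)
    batch_of <- tab$batch[match(arr_ids, tab$array_id)]
    overall <- 0
    arr_eff <- stats::setNames(numeric(length(arr_ids)), arr_ids)
    batch_eff <- stats::setNames(numeric(length(unique(batch_of))),
                                 unique(batch_of))
    for (it in seq_len(20L)) {
      fit <- overall + rep(arr_eff, each = nrow(m)) +
        rep(batch_eff[batch_of], each = nrow(m))
      resid <- m - fit
      d0 <- median(resid, na.rm = TRUE)
      overall <- overall + d0
      da <- apply(resid - d0, 2L, median, na.rm = TRUE)
      arr_eff <- arr_eff + da
      db <- tapply(arr_eff, batch_of, median)
      batch_eff <- batch_eff + as.numeric(db[names(batch_eff)])
      arr_eff <- arr_eff - as.numeric(db[batch_of])
      if (max(abs(c(d0, da, db))) < 1e-6) break
    }
    effects[[tab$tag[1L]]] <<- tibble(
      tag = tab$tag[1L], array_id = arr_ids, batch = batch_of,
      array_effect = unname(arr_eff),
      batch_effect = unname(batch_eff[batch_of]), overall = overall)
    adj <- arr_eff[tab$array_id] + batch_eff[tab$batch]
    tab$signal <- 2^(log2(tab$signal) - adj)
    tab
  })
  res <- dplyr::bind_rows(c(out, list(rest)))
  attr(res, "effects") <- dplyr::bind_rows(effects)
  res
}

#' Quantile-normalize arrays within each study
#'
#' Within every `study_id`, array log2-signal distributions of the used
#' features are quantile-normalized to the study's mean empirical
#' distribution (via [limma::normalizeQuantiles()]). No cross-study
#' adjustment is made. Studies with a single array are returned unchanged.
#'
#' @inheritParams median_polish_normalize
#' @return The input tibble with normalized `signal` for used features.
#' @export
normalize_by_study <- function(intensities) {
  check_intensity_table(intensities)
  used <- intensities[intensities$used, , drop = FALSE]
  rest <- intensities[!intensities$used, , drop = FALSE]
  out <- lapply(split(used, used$study_id), function(tab) {
    arr_ids <- unique(tab$array_id)
    if (length(arr_ids) < 2L) return(tab)
    key <- paste(tab$strain_id, tab$tag, sep = "\r")
    keys <- unique(key)
    m <- matrix(NA_real_, length(keys), length(arr_ids),
                dimnames = list(keys, arr_ids))
    m[cbind(match(key, keys), match(tab$array_id, arr_ids))] <-
      log2(tab$signal)
    norm <- limma::normalizeQuantiles(m)
    tab$signal <- 2^norm[cbind(match(key, keys),
                               match(tab$array_id, arr_ids))]
    tab
  })
  dplyr::bind_rows(c(out, list(rest)))
}

#' Flag tags above the array background
#'
#' Per array, the detection threshold is `median + 5 * MAD` of the raw
#' signals of the unused (background) features on that array; a tag passes on
#' an array iff its signal exceeds the threshold. A tag's overall
#' `passes_background` is true iff it passes on every control array.
#'
#' @inheritParams median_polish_normalize
#' @return Tibble with columns `strain_id`, `tag`, `passes_background`.
#' @export
background_filter <- function(intensities) {
  check_intensity_table(intensities)
  bg <- intensities[!intensities$used, , drop = FALSE]
  tags <- intensities[intensities$used, , drop = FALSE]
  if (nrow(bg) == 0L) {
    warn("No unused background features; all tags pass the background filter.")
    return(dplyr::distinct(tags[, c("strain_id", "tag")],
                           .data$strain_id, .data$tag) |>
             dplyr::mutate(passes_background = TRUE))
  }
  thr <- vapply(split(bg$signal, bg$array_id),
                function(s) median(s) + 5 * mad_raw(s), numeric(1))
  ctrl <- tags[tags$role == "control", , drop = FALSE]
  ctrl$pass <- ctrl$signal > thr[ctrl$array_id]
  dplyr::summarise(dplyr::group_by(ctrl, .data$strain_id, .data$tag),
                   passes_background = all(.data$pass), .groups = "drop")
}

#' Choose each strain's best tag
#'
#' Among a strain's tags that pass [background_filter()], select the one with
#' the lowest robust coefficient of variation (raw MAD / median) of its
#' control-array signals; ties go to the uptag. Strains with no passing tag
#' are absent from the result and listed in the `"unusable"` attribute.
#'
#' @inheritParams median_polish_normalize
#' @return Tibble with columns `strain_id`, `tag`, `robust_cv`.
#' @export
select_best_tag <- function(intensities) {
  qual <- background_filter(intensities)
  ctrl <- intensities[intensities$used & intensities$role == "control", ]
  cv <- dplyr::summarise(dplyr::group_by(ctrl, .data$strain_id, .data$tag),
                         robust_cv = mad_raw(.data$signal) /
                           median(.data$signal),
                         .groups = "drop")
  cv <- dplyr::inner_join(cv, qual, by = c("strain_id", "tag"))
  passing <- cv[cv$passes_background, , drop = FALSE]
  passing <- passing[order(passing$strain_id, passing$robust_cv,
                           match(passing$tag, c("up", "down"))), ]
  best <- passing[!duplicated(passing$strain_id),
                  c("strain_id", "tag", "robust_cv")]
  unusable <- setdiff(unique(ctrl$strain_id), best$strain_id)
  attr(best, "unusable") <- unusable
  best
}

#' Average a strain's passing tags per array
#'
#' The NIBR-style strain intensity: the arithmetic mean of the (at most two)
#' tags passing [background_filter()], per strain and array.
#'
#' @inheritParams median_polish_normalize
#' @return Tibble with columns `strain_id`, `array_id`, `role`, `signal`.
#' @export
average_tags <- function(intensities) {
  qual <- background_filter(intensities)
  tags <- dplyr::inner_join(intensities[intensities$used, ],
                            qual[qual$passes_background, c("strain_id", "tag")],
                            by = c("strain_id", "tag"))
  dplyr::summarise(dplyr::group_by(tags, .data$strain_id, .data$array_id,
                                   .data$role),
                   signal = mean(.data$signal), .groups = "drop")
}

#' Per-strain log2 ratios, HIPLAB convention
#'
#' `log2(median control signal / treatment signal)`: larger values mean a
#' greater fitness defect (sensitivity-positive orientation).
#'
#' @param controls Numeric matrix of control signals, strains x control
#'   arrays, with strain row names.
#' @param treatment Named numeric vector of treatment signals.
#' @return Named numeric vector of log2 ratios; strains with non-positive
#'   signal are `NA` (with a warning).
#' @export
log2_ratio_hiplab <- function(controls, treatment) {
  controls <- as.matrix(controls)
  strains <- intersect(rownames(controls), names(treatment))
  ctrl_med <- apply(controls[strains, , drop = FALSE], 1L, median)
  trt <- treatment[strains]
  bad <- !is.finite(ctrl_med) | !is.finite(trt) | ctrl_med <= 0 | trt <= 0
  if (any(bad)) {
    warn(sprintf("%d strain(s) with non-positive signal set to NA.",
                 sum(bad)))
  }
  out <- log2(ctrl_med / trt)
  out[bad] <- NA_real_
  out
}

#' Per-strain log2 ratios, NIBR convention
#'
#' `log2(mean treatment replicate signal / mean control signal)`: more
#' sensitive strains score more negative (sensitivity-negative orientation).
#'
#' @param treatments Numeric matrix of treatment-replicate signals, strains x
#'   replicates (a named vector is treated as one replicate).
#' @param controls Numeric matrix of control signals, strains x arrays.
#' @return Named numeric vector of log2 ratios.
#' @export
log2_ratio_nibr <- function(treatments, controls) {
  if (is.null(dim(treatments))) treatments <- cbind(treatments)
  controls <- as.matrix(controls)
  strains <- intersect(rownames(controls), rownames(treatments))
  trt <- rowMeans(treatments[strains, , drop = FALSE])
  ctrl <- rowMeans(controls[strains, , drop = FALSE])
  bad <- !is.finite(trt) | !is.finite(ctrl) | trt <= 0 | ctrl <= 0
  if (any(bad)) {
    warn(sprintf("%d strain(s) with non-positive signal set to NA.",
                 sum(bad)))
  }
  out <- log2(trt / ctrl)
  out[bad] <- NA_real_
  out
}

#' Robust z-score standardization per screen
#'
#' The fitness-defect (FD / MADL) transform: per screen (column), subtract
#' the column median and divide by the column MAD of the log2 ratios. By
#' default the MAD is the raw median absolute deviation (no 1.4826
#' consistency factor); set `mad_scaled` in the config to use the scaled
#' version. Screens with MAD 0 or fewer than 3 finite values are degenerate:
#' they are dropped from the output and reported in the `"degenerate"`
#' attribute.
#'
#' @param x A `screen_matrix` of log2 ratios (any kind is accepted; columns
#'   are standardized as-is).
#' @param config An [analysis_config()].
#' @return A `screen_matrix` of FD scores (value kind `"fd"` in
#'   sensitivity-positive orientation, `"madl"` otherwise); attribute
#'   `"degenerate"` is a tibble of excluded screens and reasons.
#' @export
robust_z <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "screen_matrix"))
  constant <- if (config$mad_scaled) 1.4826 else 1
  vals <- as_plain_matrix(x)
  med <- apply(vals, 2L, median, na.rm = TRUE)
  madv <- apply(vals, 2L, function(col) {
    stats::mad(col, constant = constant, na.rm = TRUE)
  })
  n_ok <- colSums(is.finite(vals))
  degenerate <- tibble(
    screen_id = colnames(vals),
    reason = dplyr::case_when(n_ok < 3L ~ "fewer than 3 finite values",
                              madv == 0 | !is.finite(madv) ~ "zero MAD",
                              TRUE ~ NA_character_)
  )
  degenerate <- degenerate[!is.na(degenerate$reason), ]
  keep <- setdiff(colnames(vals), degenerate$screen_id)
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2L, med[keep]), 2L,
             madv[keep], `/`)
  kind <- if (orientation(x) == "sensitivity_positive") "fd" else "madl"
  out <- restamp(z, x, value_kind = kind)
  attr(out, "degenerate") <- degenerate
  out
}

#' Replicate-variability p-values for the a_MADL adjustment
#'
#' For every strain and screen, a two-sided Welch two-sample t-test between
#' the strain's log2 signals on the screen's treatment replicate arrays and
#' on the control arrays. Screens with a single replicate yield `NA`
#' (which [adjust_madl()] treats as factor 1).
#'
#' @param signals Tibble with columns `strain_id`, `array_id`, `signal`,
#'   `role` (e.g. the output of [average_tags()]).
#' @param screens Tibble mapping treatment arrays to screens: columns
#'   `array_id`, `screen_id`.
#' @return Numeric matrix of p-values, strains x screens.
#' @export
replicate_pvalues <- function(signals, screens) {
  ctrl <- signals[signals$role == "control", ]
  trt <- dplyr::inner_join(signals, screens, by = "array_id")
  strains <- sort(unique(signals$strain_id))
  screen_ids <- unique(screens$screen_id)
  ctrl_split <- split(log2(ctrl$signal), ctrl$strain_id)
  p <- matrix(NA_real_, length(strains), length(screen_ids),
              dimnames = list(strains, screen_ids))
  for (sc in screen_ids) {
    tsub <- trt[trt$screen_id == sc, ]
    tsplit <- split(log2(tsub$signal), tsub$strain_id)
    for (g in names(tsplit)) {
      a <- tsplit[[g]]
      b <- ctrl_split[[g]]
      if (length(a) >= 2L && length(b) >= 2L) {
        p[g, sc] <- tryCatch(stats::t.test(a, b)$p.value,
                             error = function(e) NA_real_)
      }
    }
  }
  p
}

#' Adjust MADL scores for replicate variability
#'
#' The a_MADL transform: each score is multiplied by `min(0.05 / p, 1)`,
#' where p is the replicate-vs-control t-test p-value for that strain and
#' screen. Scores with reproducible measurements (p <= 0.05) are unchanged;
#' noisy ones are shrunk toward 0 — the factor never increases a magnitude.
#' Missing p-values give factor 1. `method = "p_multiply"` instead multiplies
#' by p itself (an alternative reading of the published description).
#'
#' @param x A `screen_matrix` of MADL scores.
#' @param pvalues Numeric matrix of p-values in (0, 1], conformable with `x`
#'   by dimnames.
#' @param method `"table1"` (default, `min(0.05/p, 1)` factor) or
#'   `"p_multiply"`.
#' @return A `screen_matrix` with value kind `"a_madl"`.
#' @export
adjust_madl <- function(x, pvalues, method = c("table1", "p_multiply")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "screen_matrix"))
  vals <- as_plain_matrix(x)
  p <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  common_r <- intersect(rownames(vals), rownames(pvalues))
  common_c <- intersect(colnames(vals), colnames(pvalues))
  p[common_r, common_c] <- pvalues[common_r, common_c]
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  factor <- if (method == "table1") pmin(0.05 / p, 1) else p
  factor[is.na(factor)] <- 1
  restamp(vals * factor, x, value_kind = "a_madl")
}

#' Gene-wise z-scores, NIBR convention
#'
#' Standardizes each strain's a_MADL scores by its own scale sigma, estimated
#' as the SD of the strain's scores lying within the central
#' `quantile_window` of its empirical distribution (default the 15th-85th
#' percentiles, linear interpolation). Strains whose central scores are
#' constant (sigma = 0) are flagged invariant and their z-scores set missing.
#'
#' @param x A `screen_matrix` of a_MADL (or MADL) scores; at least 10 screens.
#' @param config An [analysis_config()].
#' @return A list with `z` (a `screen_matrix`, value kind `"z"`, orientation
#'   preserved) and `scale` (tibble: `strain_id`, `sigma`, `n_used`,
#'   `flagged`).
#' @export
genewise_z_nibr <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "screen_matrix"))
  if (ncol(x) < 10L) {
    warn("Fewer than 10 screens; gene-wise scale estimates are unstable.")
  }
  vals <- as_plain_matrix(x)
  lo <- (1 - config$quantile_window) / 2
  est <- apply(vals, 1L, function(row) {
    row <- row[is.finite(row)]
    if (length(row) < 3L) return(c(NA_real_, length(row)))
    qs <- quantile(row, c(lo, 1 - lo), type = 7, names = FALSE)
    central <- row[row >= qs[1L] & row <= qs[2L]]
    c(sd(central), length(central))
  })
  sigma <- est[1L, ]
  flagged <- !is.finite(sigma) | sigma == 0
  z <- vals / ifelse(flagged, NA_real_, sigma)
  list(
    z = restamp(z, x, value_kind = "z"),
    scale = tibble(strain_id = rownames(vals), sigma = unname(sigma),
                   n_used = as.integer(est[2L, ]), flagged = unname(flagged))
  )
}

#' Gene-wise robust z-scores, HIPLAB convention
#'
#' Standardizes each strain's FD scores across screens by the strain's own
#' median and raw MAD, exposing outlier screens for that gene. Strains with
#' zero MAD are flagged and set missing.
#'
#' @param x A `screen_matrix` of FD scores with at least 10 screens.
#' @return A `screen_matrix` of gene-wise z-scores (value kind `"z"`); the
#'   `"flagged"` attribute lists invariant strains.
#' @export
genewise_z_hiplab <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  vals <- as_plain_matrix(x)
  med <- apply(vals, 1L, median, na.rm = TRUE)
  madv <- apply(vals, 1L, mad_raw, na.rm = TRUE)
  flagged <- rownames(vals)[!is.finite(madv) | madv == 0]
  madv[!is.finite(madv) | madv == 0] <- NA_real_
  z <- (vals - med) / madv
  out <- restamp(z, x, value_kind = "z")
  attr(out, "flagged") <- flagged
  out
}

#' Significant chemical-genetic interactions
#'
#' HIPLAB rule: a score is significant when its one-tailed upper-tail
#' standard-normal P is at most `alpha_significant`, i.e. FD >=
#' qnorm(1 - alpha) (3.0902 at the default 0.001), in sensitivity-positive
#' orientation. NIBR rule: gene-wise z strictly below `nibr_z_cutoff`
#' (default -5) in the native sensitivity-negative orientation. Both rules
#' respect the matrix orientation flag, flipping the comparison when the
#' matrix has been harmonized. Missing values stay missing.
#'
#' @param x A `screen_matrix` of kind `"fd"` or `"z"`.
#' @param config An [analysis_config()].
#' @param rule `"auto"` (HIPLAB rule for FD matrices, NIBR rule for gene-wise
#'   z), `"hiplab"`, or `"nibr"`.
#' @return A logical matrix of the same shape as `x`.
#' @export
significance_mask <- function(x, config = analysis_config(),
                              rule = c("auto", "hiplab", "nibr")) {
  stopifnot(inherits(x, "screen_matrix"))
  rule <- match.arg(rule)
  kind <- value_kind(x)
  if (!kind %in% c("fd", "z")) {
    abort(sprintf("No significance rule for value kind '%s'.", kind))
  }
  if (rule == "auto") {
    rule <- if (kind == "fd") "hiplab" else "nibr"
  }
  vals <- as_plain_matrix(x)
  positive <- orientation(x) == "sensitivity_positive"
  if (rule == "hiplab") {
    thr <- z_threshold(config$alpha_significant)
    if (positive) vals >= thr else vals <= -thr
  } else {
    if (positive) vals > -config$nibr_z_cutoff else vals < config$nibr_z_cutoff
  }
}

#' Score a tag-intensity table into fitness defects
#'
#' Drives a full site pipeline from raw tag intensities to an FD matrix.
#' The `"hiplab"` variant: median-polish normalization, best-tag selection
#' after background filtering, log2(median control / treatment) ratios, and
#' per-screen robust z. The `"nibr"` variant: study-wise quantile
#' normalization, background filtering and tag averaging,
#' log2(treatment / mean control) ratios, per-screen robust z (MADL), the
#' a_MADL replicate adjustment, and sign stored in the sensitivity-negative
#' convention.
#'
#' @param intensities Tag-intensity tibble (see
#'   [median_polish_normalize()] for the required columns).
#' @param site `"hiplab"` or `"nibr"`.
#' @param screens Optional tibble mapping treatment `array_id` to
#'   `screen_id`; defaults to one screen per treatment array.
#' @param config An [analysis_config()].
#' @return A list with `fd` (a `screen_matrix`) and `qc` (list: `best_tags`
#'   or `tag_quality`, `unusable_strains`, `degenerate_screens`).
#' @export
score_intensities <- function(intensities,
                              site = c("hiplab", "nibr"),
                              screens = NULL,
                              config = analysis_config()) {
  site <- match.arg(site)
  check_intensity_table(intensities)
  trt_arrays <- unique(intensities$array_id[intensities$role == "treatment"])
  if (is.null(screens)) {
    screens <- tibble(array_id = trt_arrays, screen_id = trt_arrays)
  }
  if (site == "hiplab") {
    norm <- median_polish_normalize(intensities)
    best <- select_best_tag(norm)
    sig <- dplyr::inner_join(norm[norm$used, ], best[, c("strain_id", "tag")],
                             by = c("strain_id", "tag"))
    sig <- sig[, c("strain_id", "array_id", "signal", "role")]
    qc_tags <- best
  } else {
    norm <- normalize_by_study(intensities)
    sig <- average_tags(norm)
    qc_tags <- background_filter(intensities)
  }
  ctrl_ids <- unique(sig$array_id[sig$role == "control"])
  strains <- sort(unique(sig$strain_id))
  smat <- matrix(NA_real_, length(strains), length(unique(sig$array_id)),
                 dimnames = list(strains, unique(sig$array_id)))
  smat[cbind(match(sig$strain_id, strains),
             match(sig$array_id, colnames(smat)))] <- sig$signal
  controls <- smat[, ctrl_ids, drop = FALSE]
  screen_ids <- unique(screens$screen_id)
  ratios <- matrix(NA_real_, length(strains), length(screen_ids),
                   dimnames = list(strains, screen_ids))
  for (sc in screen_ids) {
    reps <- screens$array_id[screens$screen_id == sc]
    reps <- intersect(reps, colnames(smat))
    if (length(reps) == 0L) next
    if (site == "hiplab") {
      trt <- smat[, reps[1L]]
      r <- log2_ratio_hiplab(controls, trt)
    } else {
      r <- log2_ratio_nibr(smat[, reps, drop = FALSE], controls)
    }
    ratios[names(r), sc] <- r
  }
  raw <- screen_matrix(ratios, value_kind = "raw_log2ratio",
                       orientation = if (site == "hiplab")
                         "sensitivity_positive" else "sensitivity_negative")
  fd <- robust_z(raw, config)
  if (site == "nibr") {
    p <- replicate_pvalues(sig, screens)
    fd <- adjust_madl(restamp(as_plain_matrix(fd), fd), p)
  }
  list(
    fd = fd,
    qc = list(
      tag_quality = qc_tags,
      unusable_strains = attr(qc_tags, "unusable") %||% character(0),
      degenerate_screens = attr(fd, "degenerate") %||%
        tibble(screen_id = character(0), reason = character(0))
    )
  )
}

check_intensity_table <- function(x) {
  required <- c("strain_id", "tag", "array_id", "signal", "role", "batch",
                "study_id", "used")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("Intensity table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(x$signal[x$used] <= 0, na.rm = TRUE)) {
    abort("Used features must have positive signal.")
  }
  if (anyDuplicated(x[, c("strain_id", "tag", "array_id")])) {
    abort("Duplicate (strain, tag, array) triples in intensity table.")
  }
  invisible(x)
}
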