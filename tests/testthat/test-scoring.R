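make_intensity_table <- function(m, batch = NULL, study = NULL,
                                 role = NULL, tag = "up") {
  # m: strains x arrays matrix of signals
  arrays <- colnames(m)
  if (is.null(batch)) batch <- rep("b1", length(arrays))
  if (is.null(study)) study <- rep("st1", length(arrays))
  if (is.null(role)) role <- rep("control", length(arrays))
  tibble::tibble(
    strain_id = rownames(m)[row(m)],
    tag = tag,
    array_id = arrays[col(m)],
    signal = as.numeric(m),
    role = role[col(m)],
    batch = batch[col(m)],
    study_id = study[col(m)],
    used = TRUE
  )
}

test_that("median polish removes array shifts and recovers batch effects", {
  set.seed(21)
  strain_level <- rnorm(20, 10, 1)
  # identical arrays (pure strain effects): output equals input up to a
  # constant offset from the overall term
  same <- 2^outer(strain_level, rep(0, 3), `+`)
  dimnames(same) <- list(sprintf("g%02d", 1:20), sprintf("a%d", 1:3))
  out <- median_polish_normalize(make_intensity_table(same))
  delta <- log2(out$signal) - log2(same[cbind(
    match(out$strain_id, rownames(same)), match(out$array_id, colnames(same)))])
  expect_lt(diff(range(delta)), 1e-8)

  # one array shifted by +1 log2 unit: shift removed to 1e-6
  base <- 2^outer(strain_level, rep(0, 6), `+`)
  dimnames(base) <- list(sprintf("g%02d", 1:20), sprintf("a%d", 1:6))
  shifted <- base
  shifted[, 3] <- shifted[, 3] * 2
  out2 <- median_polish_normalize(make_intensity_table(shifted))
  o2 <- matrix(log2(out2$signal), 20, 6)
  resid <- o2 - log2(base)
  expect_lt(diff(range(resid)), 1e-6)

  # planted batch offsets {+0.5, -0.5} recovered within 0.05 of a converged
  # two-way median polish oracle on the same noisy table
  batches <- rep(c("b1", "b2"), each = 3)
  offs <- c(b1 = 0.5, b2 = -0.5)
  noisy <- base * 2^(rep(offs[batches], each = 20) +
                       rnorm(length(base), 0, 0.2))
  tab <- make_intensity_table(noisy, batch = batches)
  out3 <- median_polish_normalize(tab)
  eff <- attr(out3, "effects")
  oracle_col <- stats::medpolish(log2(noisy), eps = 1e-10, maxiter = 100,
                                 trace.iter = FALSE)$col
  oracle_batch <- tapply(oracle_col, batches, median)
  est <- tapply(eff$batch_effect, eff$batch, unique)
  expect_equal(unname(est["b1"] - est["b2"]),
               unname(oracle_batch["b1"] - oracle_batch["b2"]),
               tolerance = 0.05)
  expect_equal(unname(est["b1"] - est["b2"]), 1, tolerance = 0.2)

  # a single array passes through unchanged, with a warning
  single <- make_intensity_table(base[, 1, drop = FALSE])
  expect_warning(out4 <- median_polish_normalize(single), "polish")
  expect_identical(out4$signal, single$signal)
})

test_that("study-wise quantile normalization equalizes distributions", {
  set.seed(8)
  base <- matrix(2^rnorm(50 * 2, 10, 1), 50, 2,
                 dimnames = list(sprintf("g%02d", 1:50), c("a1", "a2")))
  # monotone transform of one array: distributions identical afterwards
  m <- base
  m[, 2] <- sort(m[, 1])[rank(m[, 2])]^1.1
  out <- normalize_by_study(make_intensity_table(m))
  o <- matrix(out$signal, 50, 2)
  expect_equal(sort(o[, 1]), sort(o[, 2]), tolerance = 1e-10)

  # identical arrays: unchanged
  same <- base[, c(1, 1)]
  colnames(same) <- c("a1", "a2")
  out2 <- normalize_by_study(make_intensity_table(same))
  expect_equal(out2$signal, as.numeric(same), tolerance = 1e-10)

  # planted 2x scale factor removed
  scaled <- base
  scaled[, 2] <- base[, 1] * 2
  out3 <- normalize_by_study(make_intensity_table(scaled))
  o3 <- matrix(out3$signal, 50, 2)
  expect_equal(median(o3[, 2] / o3[, 1]), 1, tolerance = 0.05)
})

test_that("background filter thresholds at median + 5 MAD of unused features", {
  strains <- c("g1", "g2", "g3")
  sig <- c(g1 = 100, g2 = 10000, g3 = 5000)
  tab <- tibble::tibble(
    strain_id = rep(strains, 2), tag = "up",
    array_id = rep(c("c1", "c2"), each = 3),
    signal = rep(unname(sig), 2), role = "control", batch = "b1",
    study_id = "st1", used = TRUE
  )
  bg <- tibble::tibble(
    strain_id = rep(sprintf("bg%02d", 1:10), 2), tag = "up",
    array_id = rep(c("c1", "c2"), each = 10),
    signal = 100, role = "control", batch = "b1", study_id = "st1",
    used = FALSE
  )
  q <- background_filter(dplyr::bind_rows(tab, bg))
  # MAD = 0 so threshold = 100: signal exactly at background fails
  expect_false(q$passes_background[q$strain_id == "g1"])
  expect_true(q$passes_background[q$strain_id == "g2"])
  expect_warning(background_filter(tab), "background")
})

test_that("planted dead tags are exactly the background failures", {
  ti <- simulate_tag_intensities(sim_config(seed = 13))
  q <- background_filter(ti$intensities)
  failed <- q[!q$passes_background, c("strain_id", "tag")]
  dead <- ti$truth$dead_tags
  expect_setequal(paste(failed$strain_id, failed$tag),
                  paste(dead$strain_id, dead$tag))
})

test_that("best-tag selection minimizes robust CV and prefers the uptag", {
  strains <- "g1"
  arr <- sprintf("c%d", 1:4)
  up <- tibble::tibble(strain_id = "g1", tag = "up", array_id = arr,
                       signal = 1000, role = "control", batch = "b1",
                       study_id = "st1", used = TRUE)
  down <- up
  down$tag <- "down"
  down$signal <- c(800, 1200, 900, 1500)
  bg <- tibble::tibble(strain_id = sprintf("bg%02d", rep(1:10, 4)), tag = "up",
                       array_id = rep(arr, each = 10), signal = 10,
                       role = "control", batch = "b1", study_id = "st1",
                       used = FALSE)
  best <- select_best_tag(dplyr::bind_rows(up, down, bg))
  expect_identical(best$tag, "up")
  expect_identical(best$robust_cv, 0)

  # identical series: documented tie-break to the uptag
  down2 <- down
  down2$signal <- 1000
  best2 <- select_best_tag(dplyr::bind_rows(up, down2, bg))
  expect_identical(best2$tag, "up")

  # on simulated data, the low-variance (non-bad) tag wins almost always
  ti <- simulate_tag_intensities(sim_config(bad_tag_fraction = 0.3, seed = 17))
  best3 <- select_best_tag(ti$intensities)
  bad <- paste(ti$truth$bad_tags$strain_id, ti$truth$bad_tags$tag)
  chosen_bad <- paste(best3$strain_id, best3$tag) %in% bad
  # strains where exactly one tag is bad and none dead: the good tag must win
  n_bad <- table(ti$truth$bad_tags$strain_id)
  one_bad <- best3$strain_id %in% names(n_bad)[n_bad == 1] &
    !best3$strain_id %in% ti$truth$dead_tags$strain_id
  expect_gt(mean(!chosen_bad[one_bad]), 0.95)
})

test_that("average_tags is the mean of passing tag signals", {
  arr <- c("c1", "c2")
  mk <- function(tag, s) {
    tibble::tibble(strain_id = "g1", tag = tag, array_id = arr, signal = s,
                   role = "control", batch = "b1", study_id = "st1",
                   used = TRUE)
  }
  bg <- tibble::tibble(strain_id = sprintf("bg%02d", rep(1:10, 2)), tag = "up",
                       array_id = rep(arr, each = 10), signal = 1,
                       role = "control", batch = "b1", study_id = "st1",
                       used = FALSE)
  out <- average_tags(dplyr::bind_rows(mk("up", c(100, 100)),
                                       mk("down", c(200, 200)), bg))
  expect_equal(out$signal, c(150, 150))
  # one passing tag: that tag's value (down tag dead at background)
  out2 <- average_tags(dplyr::bind_rows(mk("up", c(100, 100)),
                                        mk("down", c(1, 1)), bg))
  expect_equal(out2$signal, c(100, 100))
})

test_that("log2 ratio conventions", {
  ctrl <- matrix(c(90, 100, 110), 1, 3,
                 dimnames = list("g1", c("c1", "c2", "c3")))
  expect_equal(unname(log2_ratio_hiplab(ctrl, c(g1 = 100))), 0)
  expect_equal(unname(log2_ratio_hiplab(ctrl * 2, c(g1 = 50))), 2)
  expect_equal(unname(log2_ratio_hiplab(ctrl, c(g1 = 400))), -2)
  expect_warning(log2_ratio_hiplab(ctrl, c(g1 = 0)), "non-positive")

  trt <- matrix(c(40, 60), 1, 2, dimnames = list("g1", c("t1", "t2")))
  ctl <- matrix(c(150, 250), 1, 2, dimnames = list("g1", c("c1", "c2")))
  expect_equal(unname(log2_ratio_nibr(trt, ctl)), -2)
  expect_equal(unname(log2_ratio_nibr(c(g1 = 100) |> cbind(), ctl * 0 + 100)), 0)
})

test_that("robust_z matches hand values and the brute-force oracle", {
  m <- screen_matrix(matrix(c(1, 2, 3), 3, 1,
                            dimnames = list(c("a", "b", "c"), "s1")),
                     value_kind = "raw_log2ratio")
  z <- robust_z(m)
  expect_equal(unname(unclass(z)[, 1]), c(-1, 0, 1))

  r <- random_screen_matrix(100, 5, seed = 31)
  z2 <- robust_z(r)
  expect_equal(unclass(z2), oracle_robust_z(unclass(r)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # every column has median 0 and MAD 1 (to numerical precision)
  expect_lt(max(abs(apply(unclass(z2), 2, median))), 1e-12)
  expect_lt(max(abs(apply(unclass(z2), 2, mad, constant = 1) - 1)), 1e-12)
  expect_identical(value_kind(z2), "fd")

  # degenerate screen (MAD 0) is excluded and reported
  v <- unclass(r)
  v[, 2] <- 7
  d <- robust_z(screen_matrix(v, value_kind = "raw_log2ratio"))
  expect_false("s02" %in% colnames(d))
  expect_identical(attr(d, "degenerate")$screen_id, "s02")

  # scaled-MAD variant honoured
  z3 <- robust_z(r, analysis_config(mad_scaled = TRUE))
  expect_equal(unclass(z3), oracle_robust_z(unclass(r), constant = 1.4826),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a_MADL factor is min(0.05/p, 1) and never grows a score", {
  m <- screen_matrix(matrix(c(-4, -2, 6), 1, 3,
                            dimnames = list("g1", c("s1", "s2", "s3"))),
                     value_kind = "madl", orientation = "sensitivity_negative")
  p <- matrix(c(0.01, 0.5, 0.05), 1, 3, dimnames = dimnames(m))
  a <- adjust_madl(m, p)
  expect_equal(unname(unclass(a)[1, ]), c(-4, -0.2, 6))
  expect_identical(value_kind(a), "a_madl")
  # missing p: factor 1
  p2 <- p
  p2[1, 1] <- NA
  expect_equal(unclass(adjust_madl(m, p2))[1, 1], -4)
  expect_error(adjust_madl(m, p * 0), "0, 1")
  # property: |a_MADL| <= |MADL| on random inputs
  set.seed(5)
  mm <- random_screen_matrix(30, 8, seed = 5)
  pp <- matrix(runif(240, 1e-4, 1), 30, 8, dimnames = dimnames(mm))
  expect_true(all(abs(unclass(adjust_madl(mm, pp))) <= abs(unclass(mm)) + 1e-12))
  # alternative published reading
  alt <- adjust_madl(m, p, method = "p_multiply")
  expect_equal(unname(unclass(alt)[1, ]), c(-0.04, -1, 0.3))
})

test_that("gene-wise z (NIBR) uses the central-quantile scale", {
  # constant strain is flagged invariant
  v <- matrix(3, 2, 12, dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:12)))
  v[2, ] <- rnorm(12)
  res <- genewise_z_nibr(screen_matrix(v, value_kind = "a_madl",
                                       orientation = "sensitivity_negative"))
  expect_true(res$scale$flagged[res$scale$strain_id == "g1"])
  expect_true(all(is.na(unclass(res$z)["g1", ])))

  # sigma approaches the SD of the central 70% of a standard normal
  set.seed(77)
  n <- 1000
  big <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%04d", 1:n)))
  res2 <- genewise_z_nibr(screen_matrix(big, value_kind = "a_madl",
                                        orientation = "sensitivity_negative"))
  # independent Monte-Carlo oracle for the truncated-normal SD
  set.seed(78)
  oracle <- mean(replicate(200, {
    x <- rnorm(n)
    qs <- quantile(x, c(0.15, 0.85), names = FALSE)
    sd(x[x >= qs[1] & x <= qs[2]])
  }))
  expect_equal(mean(res2$scale$sigma), oracle, tolerance = 0.1)

  # scale invariance: doubling a strain's values leaves its z unchanged
  big2 <- big
  big2[3, ] <- big[3, ] * 2
  res3 <- genewise_z_nibr(screen_matrix(big2, value_kind = "a_madl",
                                        orientation = "sensitivity_negative"))
  expect_equal(unclass(res3$z)[3, ], unclass(res2$z)[3, ], tolerance = 1e-12)
})

test_that("gene-wise z (HIPLAB) matches the row-wise oracle", {
  r <- random_screen_matrix(40, 15, seed = 41)
  z <- genewise_z_hiplab(r)
  expect_equal(unclass(z), oracle_genewise_z(unclass(r)), tolerance = 1e-12,
               ignore_attr = TRUE)
  v <- unclass(r)
  v[4, ] <- 2
  z2 <- genewise_z_hiplab(screen_matrix(v, value_kind = "fd"))
  expect_identical(attr(z2, "flagged"), rownames(v)[4])
  expect_true(all(is.na(unclass(z2)[4, ])))
})

test_that("significance rules respect thresholds, boundaries and orientation", {
  thr <- qnorm(0.999)
  m <- screen_matrix(matrix(c(thr, thr - 1e-9, 0, -4), 4, 1,
                            dimnames = list(letters[1:4], "s1")),
                     value_kind = "fd")
  mask <- significance_mask(m)
  expect_identical(unname(mask[, 1]), c(TRUE, FALSE, FALSE, FALSE))

  nz <- screen_matrix(matrix(c(-4.9, -5, -5.1), 3, 1,
                             dimnames = list(letters[1:3], "s1")),
                      value_kind = "z", orientation = "sensitivity_negative")
  mn <- significance_mask(nz)
  expect_identical(unname(mn[, 1]), c(FALSE, FALSE, TRUE))
  # same scores harmonized: the rule flips with the orientation flag
  mh <- significance_mask(harmonize_orientation(nz))
  expect_identical(unname(mh[, 1]), c(FALSE, FALSE, TRUE))
  expect_error(
    significance_mask(screen_matrix(unclass(m), value_kind = "raw_log2ratio")),
    "rule")
})

test_that("both site pipelines recover the planted sensitive strain", {
  ti <- simulate_tag_intensities(sim_config(seed = 23))
  res <- score_intensities(ti$intensities, site = "hiplab")
  expect_identical(orientation(res$fd), "sensitivity_positive")
  m <- unclass(res$fd)
  tops <- rownames(m)[apply(m, 2, which.max)]
  expect_identical(tops, ti$truth$screens$planted_strain)

  resn <- score_intensities(ti$intensities, site = "nibr")
  expect_identical(orientation(resn$fd), "sensitivity_negative")
  mn <- unclass(resn$fd)
  bots <- rownames(mn)[apply(mn, 2, which.min)]
  expect_identical(bots, ti$truth$screens$planted_strain)
})
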