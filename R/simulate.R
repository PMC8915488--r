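#' Simulation configuration
#'
#' Declares the planted structure of the synthetic two-site chemogenomic
#' experiment: response classes with characteristic gene signatures, replicate
#' screens per compound, unstructured (noise) screens, single-gene HIP targets
#' with large clearance, and the site asymmetries of the real datasets — the
#' NIBR-like site stores scores with the opposite sign and is missing a set
#' of slow-growing deletion strains.
#'
#' Defaults are the study conditions used throughout the package's own
#' validation: 8 response classes of 4 replicate screens each, signature
#' sizes 6-14 genes, signature effect size 8 (z units) over unit-SD Gaussian
#' background, 5% strain dropout at the NIBR-like site, and planted HIP
#' targets at log2 fitness defect 3 on the intensity scale.
#'
#' @param n_strains Number of deletion strains (genes).
#' @param n_classes Number of planted response classes.
#' @param n_shared_classes Classes present at both sites (the remainder are
#'   exclusive to the HIPLAB-like site). Default: all of them.
#' @param replicates_per_class Replicate screens per class and site.
#' @param signature_size Integer range (min, max) of genes per signature.
#' @param effect_size Mean fitness defect of signature genes in their class,
#'   z units.
#' @param background_noise_sd SD of the Gaussian background on the FD scale.
#' @param n_unstructured Unstructured (class 0) screens per site.
#' @param n_target_genes Number of planted single-gene HIP targets.
#' @param screens_per_target HIP screens per planted target and site.
#' @param target_effect FD of a planted target in its screens, z units.
#' @param dropout_count Strains absent from the NIBR-like site.
#' @param bad_tag_fraction Fraction of tags with inflated control variance in
#'   the intensity model.
#' @param dead_tag_fraction Fraction of tags stuck at the array background
#'   level.
#' @param tag_n_strains,n_control_arrays,n_treatment_screens Size of the
#'   tag-intensity experiment.
#' @param control_meanlog2,strain_sdlog2,noise_sdlog2 Log-normal intensity
#'   model: per-strain baseline mean and SD, and residual noise SD, all on
#'   the log2 scale.
#' @param background_level Median raw signal of unused array features.
#' @param n_background_features Unused features per array.
#' @param batch_effect_sd SD of per-batch log2 offsets.
#' @param planted_defect Log2 fitness defect of the planted sensitive strain
#'   in each treatment screen.
#' @param seed Integer seed; every generator is a pure function of its
#'   config.
#' @param preset `"small"` (the defaults) or `"large"` (9 classes, 6
#'   shared across sites, 1000 strains), applied before explicit arguments.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 500,
                       n_classes = 8,
                       n_shared_classes = n_classes,
                       replicates_per_class = 4,
                       signature_size = c(6, 14),
                       effect_size = 8,
                       background_noise_sd = 1,
                       n_unstructured = 8,
                       n_target_genes = 3,
                       screens_per_target = 4,
                       target_effect = 12,
                       dropout_count = 25,
                       bad_tag_fraction = 0.1,
                       dead_tag_fraction = 0.05,
                       tag_n_strains = 150,
                       n_control_arrays = 6,
                       n_treatment_screens = 10,
                       control_meanlog2 = 10,
                       strain_sdlog2 = 1,
                       noise_sdlog2 = 0.25,
                       background_level = 16,
                       n_background_features = 200,
                       batch_effect_sd = 0.2,
                       planted_defect = 3,
                       seed = 1L,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("small", "large"))
    if (preset == "large") {
      mc <- match.call()
      if (!"n_strains" %in% names(mc)) n_strains <- 1000
      if (!"n_classes" %in% names(mc)) n_classes <- 9
      if (!"n_shared_classes" %in% names(mc)) n_shared_classes <- 6
      if (!"dropout_count" %in% names(mc)) dropout_count <- 50
    }
  }
  cfg <- list(
    n_strains = as.integer(n_strains),
    n_classes = as.integer(n_classes),
    n_shared_classes = as.integer(n_shared_classes),
    replicates_per_class = as.integer(replicates_per_class),
    signature_size = as.integer(signature_size),
    effect_size = effect_size,
    background_noise_sd = background_noise_sd,
    n_unstructured = as.integer(n_unstructured),
    n_target_genes = as.integer(n_target_genes),
    screens_per_target = as.integer(screens_per_target),
    target_effect = target_effect,
    dropout_count = as.integer(dropout_count),
    bad_tag_fraction = bad_tag_fraction,
    dead_tag_fraction = dead_tag_fraction,
    tag_n_strains = as.integer(tag_n_strains),
    n_control_arrays = as.integer(n_control_arrays),
    n_treatment_screens = as.integer(n_treatment_screens),
    control_meanlog2 = control_meanlog2,
    strain_sdlog2 = strain_sdlog2,
    noise_sdlog2 = noise_sdlog2,
    background_level = background_level,
    n_background_features = as.integer(n_background_features),
    batch_effect_sd = batch_effect_sd,
    planted_defect = planted_defect,
    seed = as.integer(seed)
  )
  if (cfg$n_shared_classes > cfg$n_classes) {
    abort("`n_shared_classes` cannot exceed `n_classes`.")
  }
  if (cfg$n_classes > 0 &&
      cfg$n_classes * max(1L, cfg$signature_size[1L]) > cfg$n_strains) {
    abort("n_classes x minimum signature size exceeds n_strains.")
  }
  if (cfg$dropout_count >= cfg$n_strains) {
    abort("`dropout_count` must be smaller than `n_strains`.")
  }
  structure(cfg, class = "sim_config")
}

strain_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a two-site fitness-defect dataset with planted truth
#'
#' Builds one genes-by-screens FD matrix per site. Screens of class k carry
#' their signature genes at `effect_size` plus Gaussian noise over a
#' Gaussian background; planted HIP-target screens carry a single gene at
#' `target_effect`. The NIBR-like site is emitted in the
#' sensitivity-negative convention (values sign-flipped) with
#' `dropout_count` strains absent, mirroring the slow-grower loss in
#' overnight-grown pools. Replicate screens share a compound label and
#' differ only in noise (and a dose metadata label), emulating "practical
#' replicates" screened at different concentrations.
#'
#' @param config A [sim_config()].
#' @return A list with elements `hiplab` and `nibr` (both [screen_matrix()]),
#'   `meta` (tibble: screen_id, compound, dose, dose_unit, assay, site,
#'   replicate_group), `truth` (list: `screens` tibble with class/target per
#'   screen, `signature_genes` named list, `dropped_strains`,
#'   `planted_targets`), and `config`.
#' @export
#' @examples
#' sim <- simulate_fd_dataset(sim_config(n_strains = 100, n_classes = 2,
#'                                       n_target_genes = 1, seed = 42))
#' dim(sim$hiplab)
simulate_fd_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- strain_ids(config$n_strains)
    # disjoint signature gene sets, then targets and dropouts outside them
    sizes <- if (config$n_classes > 0) {
      sample(seq(config$signature_size[1L], config$signature_size[2L]),
             config$n_classes, replace = TRUE)
    } else integer(0)
    pool <- sample(genes)
    signature_genes <- list()
    off <- 0L
    for (k in seq_len(config$n_classes)) {
      signature_genes[[paste0("class", k)]] <- sort(pool[off + seq_len(sizes[k])])
      off <- off + sizes[k]
    }
    remaining <- if (off > 0L) pool[-seq_len(off)] else pool
    target_genes <- sort(utils::head(remaining, config$n_target_genes))
    non_target <- setdiff(remaining, target_genes)
    dropped <- sort(sample(non_target, config$dropout_count))

    site_classes <- list(
      HIPLAB = seq_len(config$n_classes),
      NIBR = seq_len(config$n_shared_classes)
    )

    build_site <- function(site) {
      classes <- site_classes[[site]]
      rows <- list()
      for (k in classes) {
        for (r in seq_len(config$replicates_per_class)) {
          rows[[length(rows) + 1L]] <- tibble(
            site = site, class = k, target = NA_character_,
            compound = sprintf("cpd_c%02d", k),
            dose = round(stats::runif(1, 1, 100), 1)
          )
        }
      }
      for (g in target_genes) {
        for (r in seq_len(config$screens_per_target)) {
          rows[[length(rows) + 1L]] <- tibble(
            site = site, class = 0L, target = g,
            compound = sprintf("cpd_t_%s_%d", g, r),
            dose = round(stats::runif(1, 1, 100), 1)
          )
        }
      }
      for (u in seq_len(config$n_unstructured)) {
        rows[[length(rows) + 1L]] <- tibble(
          site = site, class = 0L, target = NA_character_,
          compound = sprintf("cpd_u%02d_%s", u, tolower(site)),
          dose = round(stats::runif(1, 1, 100), 1)
        )
      }
      scr <- dplyr::bind_rows(rows)
      scr$screen_id <- sprintf("%s_s%03d", site, seq_len(nrow(scr)))
      scr$replicate_group <- scr$compound
      scr
    }

    screens <- dplyr::bind_rows(build_site("HIPLAB"), build_site("NIBR"))

    fill_matrix <- function(scr) {
      m <- matrix(stats::rnorm(length(genes) * nrow(scr),
                               sd = config$background_noise_sd),
                  nrow = length(genes),
                  dimnames = list(genes, scr$screen_id))
      for (j in seq_len(nrow(scr))) {
        if (scr$class[j] > 0L) {
          sig <- signature_genes[[paste0("class", scr$class[j])]]
          m[sig, j] <- config$effect_size +
            stats::rnorm(length(sig), sd = config$background_noise_sd)
        }
        if (!is.na(scr$target[j])) {
          m[scr$target[j], j] <- config$target_effect +
            stats::rnorm(1, sd = config$background_noise_sd)
        }
      }
      m
    }

    scr_a <- screens[screens$site == "HIPLAB", ]
    scr_b <- screens[screens$site == "NIBR", ]
    mat_a <- fill_matrix(scr_a)
    mat_b <- fill_matrix(scr_b)
    mat_b <- -mat_b[setdiff(genes, dropped), , drop = FALSE]

    meta <- tibble(
      screen_id = screens$screen_id,
      compound = screens$compound,
      dose = screens$dose,
      dose_unit = "uM",
      assay = ifelse(is.na(screens$target), "HOP", "HIP"),
      site = screens$site,
      replicate_group = screens$replicate_group
    )

    list(
      hiplab = screen_matrix(mat_a, value_kind = "fd",
                             orientation = "sensitivity_positive"),
      nibr = screen_matrix(mat_b, value_kind = "z",
                           orientation = "sensitivity_negative"),
      meta = meta,
      truth = list(
        screens = tibble(screen_id = screens$screen_id,
                         site = screens$site,
                         class = screens$class,
                         target = screens$target,
                         replicate_group = screens$replicate_group),
        signature_genes = signature_genes,
        planted_targets = stats::setNames(screens$target, screens$screen_id),
        dropped_strains = dropped,
        site_classes = site_classes
      ),
      config = config
    )
  })
}

#' Generate a tag-intensity table with planted sensitive strains
#'
#' Emulates the raw barcode-microarray stage: each strain has an uptag and a
#' downtag with a per-tag log-normal baseline shared by all control arrays;
#' each treatment array attenuates the signal of its planted sensitive strain
#' multiplicatively by `2^(-planted_defect)`. A `bad_tag_fraction` of tags
#' get 4x inflated control-array noise (so best-tag selection has something
#' to choose between), a `dead_tag_fraction` are stuck at the array
#' background level, and every array also carries unused background features.
#'
#' @param config A [sim_config()].
#' @return A list with `intensities` (tibble: strain_id, tag, array_id,
#'   signal, role, batch, study_id, used), `truth` (list: `screens` tibble
#'   mapping treatment arrays to their planted strain and defect, `bad_tags`,
#'   `dead_tags` tibbles) and `config`.
#' @export
simulate_tag_intensities <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    strains <- strain_ids(config$tag_n_strains)
    tags <- tidyr::expand_grid(strain_id = strains, tag = c("up", "down"))
    n_tag <- nrow(tags)
    tags$baseline_log2 <- stats::rnorm(n_tag, config$control_meanlog2,
                                       config$strain_sdlog2)
    tags$bad <- stats::runif(n_tag) < config$bad_tag_fraction
    tags$dead <- !tags$bad & stats::runif(n_tag) < config$dead_tag_fraction

    ctrl_ids <- sprintf("ctrl_%02d", seq_len(config$n_control_arrays))
    trt_ids <- sprintf("trt_%02d", seq_len(config$n_treatment_screens))
    arrays <- tibble(
      array_id = c(ctrl_ids, trt_ids),
      role = rep(c("control", "treatment"),
                 c(length(ctrl_ids), length(trt_ids)))
    )
    arrays$batch <- paste0("batch", (seq_len(nrow(arrays)) %% 2L) + 1L)
    arrays$study_id <- "study1"
    batch_off <- stats::setNames(
      stats::rnorm(2, 0, config$batch_effect_sd), c("batch1", "batch2"))
    planted <- sample(strains, config$n_treatment_screens,
                      replace = config$n_treatment_screens > length(strains))

    grid <- tidyr::expand_grid(tags, arrays)
    noise_sd <- ifelse(grid$bad & grid$role == "control",
                       4 * config$noise_sdlog2, config$noise_sdlog2)
    lg <- grid$baseline_log2 + batch_off[grid$batch] +
      stats::rnorm(nrow(grid), 0, noise_sd)
    is_planted <- grid$role == "treatment" &
      grid$strain_id == planted[match(grid$array_id, trt_ids)]
    is_planted[is.na(is_planted)] <- FALSE
    lg[is_planted] <- lg[is_planted] - config$planted_defect
    lg[grid$dead] <- log2(config$background_level) +
      stats::rnorm(sum(grid$dead), 0, 0.1)
    strain_tab <- tibble(
      strain_id = grid$strain_id, tag = grid$tag, array_id = grid$array_id,
      signal = 2^lg, role = grid$role, batch = grid$batch,
      study_id = grid$study_id, used = TRUE
    )

    bg_ids <- sprintf("bg%04d", seq_len(config$n_background_features))
    bg_grid <- tidyr::expand_grid(strain_id = bg_ids, arrays)
    bg_tab <- tibble(
      strain_id = bg_grid$strain_id, tag = "up", array_id = bg_grid$array_id,
      signal = 2^(log2(config$background_level) +
                    stats::rnorm(nrow(bg_grid), 0, 0.1)),
      role = bg_grid$role, batch = bg_grid$batch,
      study_id = bg_grid$study_id, used = FALSE
    )

    list(
      intensities = dplyr::bind_rows(strain_tab, bg_tab),
      truth = list(
        screens = tibble(array_id = trt_ids, planted_strain = planted,
                         planted_defect = config$planted_defect),
        bad_tags = tags[tags$bad, c("strain_id", "tag")],
        dead_tags = tags[tags$dead, c("strain_id", "tag")]
      ),
      config = config
    )
  })
}

#' Build a GMT fixture from planted truth
#'
#' One gene set per planted signature (its exact member genes) plus
#' size-matched decoy sets drawn from non-signature genes, so enrichment of a
#' recovered signature against its own set is maximal by construction and
#' decoys behave as null sets.
#'
#' @param truth The `truth` element of [simulate_fd_dataset()].
#' @param universe Character vector of all genes in the analyzed matrix.
#' @param n_decoys_per_set Decoy sets per true set.
#' @param seed Integer seed for decoy sampling.
#' @return A named list of gene sets (GMT-compatible; see [write_gmt()]).
#' @export
simulate_gmt <- function(truth, universe, n_decoys_per_set = 3, seed = 1L) {
  sig <- truth$signature_genes
  if (length(sig) == 0L) abort("`truth` has no planted signatures.")
  with_seed(seed, {
    non_sig <- setdiff(universe, unlist(sig))
    sets <- sig
    names(sets) <- paste0("sig_", names(sig))
    for (nm in names(sig)) {
      for (d in seq_len(n_decoys_per_set)) {
        sets[[sprintf("decoy_%s_%d", nm, d)]] <-
          sort(sample(non_sig, length(sig[[nm]])))
      }
    }
    sets
  })
}
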