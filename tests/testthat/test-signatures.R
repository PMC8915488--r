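block_similarity <- function(sizes, within = 0.99, between = 0) {
  n <- sum(sizes)
  r <- matrix(between, n, n)
  off <- 0
  for (s in sizes) {
    r[off + seq_len(s), off + seq_len(s)] <- within
    off <- off + s
  }
  diag(r) <- 1
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(r) <- list(ids, ids)
  structure(list(values = r, n_shared = matrix(100, n, n), axis = "screens"),
            class = "similarity_matrix")
}

test_that("ward_dendrogram agrees with an independent Lance-Williams oracle", {
  set.seed(81)
  m <- random_screen_matrix(40, 30, seed = 81)
  sim <- coinhibition(m, zero = FALSE)
  hc <- ward_dendrogram(sim)
  d <- 1 - sim$values
  diag(d) <- 0
  # identical merge structure: full cophenetic equality
  coph <- as.matrix(stats::cophenetic(hc))
  orc <- oracle_ward_cophenetic(d)[rownames(coph), colnames(coph)]
  expect_equal(coph, orc, tolerance = 1e-9)

  # two perfectly separated blocks: the last merge joins the blocks
  bs <- block_similarity(c(4, 4))
  hcb <- ward_dendrogram(bs)
  top <- cutree(hcb, k = 2)
  expect_identical(unname(top), rep(1:2, each = 4))

  # two screens: a single positive-height merge
  two <- block_similarity(c(1, 1), between = 0.5)
  hc2 <- ward_dendrogram(two)
  expect_length(hc2$height, 1)
  expect_gt(hc2$height, 0)
  expect_error(ward_dendrogram(block_similarity(1)), "2 screens")
})

test_that("dendrograms export as readable Newick", {
  hc <- ward_dendrogram(block_similarity(c(3, 3)))
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, hc$labels)
})

test_that("dynamic_cut recovers planted blocks and honours min_cluster_size", {
  for (seed in 1:5) {
    set.seed(seed)
    sizes <- sample(3:6, 4, replace = TRUE)
    bs <- block_similarity(sizes, within = 0.95 + runif(1) / 100)
    cl <- dynamic_cut(ward_dendrogram(bs), cluster_params())
    truth <- rep(seq_along(sizes), sizes)
    expect_identical(length(unique(cl)), length(sizes))
    expect_true(all(cl > 0))
    expect_equal(as.integer(tapply(truth, cl, dplyr::n_distinct)),
                 rep(1L, length(sizes)))
  }
  # min_cluster_size larger than n: everything unassigned
  bs <- block_similarity(c(3, 3))
  cl0 <- dynamic_cut(ward_dendrogram(bs),
                     cluster_params(min_cluster_size = 10))
  expect_true(all(cl0 == 0))
})

test_that("cluster count is nondecreasing in deep_split", {
  for (seed in 1:8) {
    m <- random_screen_matrix(30, 25, seed = 100 + seed)
    hc <- ward_dendrogram(coinhibition(m, zero = FALSE))
    counts <- vapply(0:4, function(ds) {
      cl <- dynamic_cut(hc, cluster_params(deep_split = ds,
                                           min_cluster_size = 2))
      length(unique(cl[cl > 0]))
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("cluster labels are stable under screen permutation", {
  sim <- simulate_fd_dataset(sim_config(n_strains = 200, n_classes = 3,
                                        seed = 53))
  m <- sim$hiplab
  cl <- dynamic_cut(ward_dendrogram(coinhibition(m)), cluster_params())
  set.seed(54)
  perm <- sample(ncol(m))
  mp <- screen_matrix(unclass(m)[, perm], value_kind = "fd")
  clp <- dynamic_cut(ward_dendrogram(coinhibition(mp)), cluster_params())
  clp <- clp[names(cl)]
  # same partition up to relabeling
  expect_equal(mclust::adjustedRandIndex(cl, clp), 1)
})

test_that("median_profile matches the brute-force median", {
  m <- random_screen_matrix(15, 6, seed = 91, missing = 10)
  prof <- median_profile(colnames(m)[c(1, 3, 5)], m)
  manual <- apply(unclass(m)[, c(1, 3, 5)], 1,
                  function(x) median(x, na.rm = TRUE))
  expect_equal(prof, manual)
  # singleton cluster is the screen's own profile
  expect_equal(median_profile(colnames(m)[2], m), unclass(m)[, 2])
  expect_equal(unname(median_profile(c("s01", "s02", "s03"),
    screen_matrix(matrix(c(1, 2, 100), 1, 3,
                         dimnames = list("g", c("s01", "s02", "s03")))))), 2)
})

test_that("signature gene extraction follows the positive-tail rule", {
  prof <- c(gene1 = 3.2, gene2 = 2.0, gene3 = -4.0)
  expect_identical(signature_genes(prof, 0.001), "gene1")
  expect_setequal(signature_genes(prof, 0.05), c("gene1", "gene2"))
  # monotone in alpha on random profiles
  set.seed(95)
  p <- setNames(rnorm(200, 1, 2), sprintf("g%03d", 1:200))
  alphas <- c(1e-4, 1e-3, 1e-2, 0.05, 0.2)
  sets <- lapply(alphas, function(a) signature_genes(p, a))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("hypergeometric enrichment matches closed forms and BH-adjusts", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(hit = universe[1:3], miss = universe[50:60])
  res <- enrich(universe[1:3], universe, sets)
  expect_identical(res$set_size[order(res$set)], c(3L, 11L))
  expect_identical(res$overlap[res$set == "hit"], 3L)
  expect_equal(res$p[res$set == "hit"], 1 / choose(100, 3), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)  # disjoint: P(overlap >= 0) = 1
  expect_equal(res$p_adj, pmin(res$p * 2, 1), tolerance = 1e-12)
  expect_error(enrich("g001", character(0), sets), "universe")
})

test_that("a planted signature enriches most against its own set", {
  sim <- simulate_fd_dataset(sim_config(n_strains = 300, n_classes = 3,
                                        seed = 57))
  sets <- simulate_gmt(sim$truth, rownames(sim$hiplab), seed = 57)
  cl <- dynamic_cut(ward_dendrogram(coinhibition(sim$hiplab)),
                    cluster_params())
  sigs <- response_signatures(sim$hiplab, cl, gmt_sets = sets)
  planted <- sim$truth$signature_genes
  matched <- 0
  for (i in seq_len(nrow(sigs))) {
    enr <- sigs$enrichment[[i]]
    if (enr$set[1] %in% paste0("sig_", names(planted)) &&
        enr$p_adj[1] < 0.05) {
      matched <- matched + 1
    }
  }
  expect_gte(matched, 3)
})

test_that("signature retention follows the published rule", {
  fake <- function(n_genes, p_adj = NULL) {
    enr <- if (is.null(p_adj)) NULL else
      tibble::tibble(set = "S", set_size = 5, overlap = 1, p = p_adj,
                     p_adj = p_adj, overlap_genes = list("g"))
    tibble::tibble(cluster = 1L, n_screens = 3L, members = list("s"),
                   median_profile = list(c(g = 1)), n_genes = n_genes,
                   signature_genes = list(rep("g", n_genes)),
                   enrichment = list(enr),
                   retained = NA)
  }
  mk <- function(...) {
    x <- fake(...)
    x$retained <- mapply(function(n, e) hiphopr:::signature_retained(n, e),
                         x$n_genes, x$enrichment)
    class(x) <- c("response_signatures", class(x))
    x
  }
  expect_false(mk(1)$retained)            # 1 gene, no enrichment: dropped
  expect_true(mk(1, p_adj = 0.01)$retained)  # 1 gene but enriched: kept
  expect_true(mk(5)$retained)             # >= 2 genes: kept
  expect_false(mk(1, p_adj = 0.2)$retained)
  expect_identical(nrow(filter_signatures(mk(1))), 0L)
})

test_that("signature recovery hits planted genes with few false positives", {
  sim <- simulate_fd_dataset(sim_config(seed = 59))
  m <- sim$hiplab
  cl <- dynamic_cut(ward_dendrogram(coinhibition(m)), cluster_params())
  sigs <- filter_signatures(response_signatures(m, cl))
  truth <- sim$truth
  # map each planted class to its best-matching recovered signature
  for (k in seq_along(truth$signature_genes)) {
    planted <- truth$signature_genes[[k]]
    ovs <- vapply(sigs$signature_genes,
                  function(g) length(intersect(g, planted)), integer(1))
    best <- which.max(ovs)
    rec <- sigs$signature_genes[[best]]
    expect_gte(length(intersect(rec, planted)) / length(planted), 0.9)
    expect_lte(length(setdiff(rec, planted)) / max(1, length(rec)), 0.05)
  }
})
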