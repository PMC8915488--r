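# Independent brute-force oracles. These deliberately re-derive each
# statistic with naive loops, staying independent of the package internals.

oracle_robust_z <- function(m, constant = 1) {
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    med <- median(col, na.rm = TRUE)
    madv <- median(abs(col - med), na.rm = TRUE) * constant
    out[, j] <- (col - med) / madv
  }
  out
}

oracle_genewise_z <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    med <- median(row, na.rm = TRUE)
    madv <- median(abs(row - med), na.rm = TRUE)
    out[i, ] <- (row - med) / madv
  }
  out
}

# pairwise-complete Pearson between columns, naive double loop
oracle_pearson <- function(m, min_shared = 1) {
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      if (sum(ok) < max(2, min_shared)) next
      x <- m[ok, i]
      y <- m[ok, j]
      if (sd(x) == 0 || sd(y) == 0) next
      r[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
        ((sum(ok) - 1) * sd(x) * sd(y))
    }
  }
  r
}

# literal transcription of the published clearance algorithm, O(n^2)
oracle_clearance <- function(profile, threshold = 5.75, alpha = 0.001) {
  ord <- order(-profile, names(profile), method = "radix")
  fd <- profile[ord]
  n <- length(fd)
  gap <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    if (fd[i] > 0) gap[i] <- fd[i] - fd[i + 1]
  }
  if (sum(fd > 0) >= 2 && any(!is.na(gap))) {
    clearance_max <- -Inf
    fd_max <- NA_real_
    for (i in seq_len(n)) {
      if (!is.na(gap[i]) && gap[i] > clearance_max) {
        clearance_max <- gap[i]
        fd_max <- fd[i]
      }
    }
  } else {
    clearance_max <- 0
    fd_max <- Inf
    gap[] <- NA_real_
  }
  clearance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    clearance[i] <- if (fd[i] >= fd_max) clearance_max else gap[i]
  }
  sig <- fd >= qnorm(1 - alpha)
  hits <- names(fd)[sig & !is.na(clearance) & clearance >= threshold]
  list(order = names(fd), clearance = setNames(clearance, names(fd)),
       clearance_max = clearance_max,
       fd_max = if (is.finite(fd_max)) fd_max else NA_real_, hits = hits)
}

# naive Lance-Williams ward.D agglomeration returning a cophenetic matrix
oracle_ward_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  dd <- d
  diag(dd) <- Inf
  for (step in seq_len(n - 1)) {
    # find min pair among active
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        i <- active[a]
        j <- active[b]
        if (dd[i, j] < best_d) {
          best_d <- dd[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]
    j <- best[2]
    for (x in members[[i]]) {
      for (y in members[[j]]) {
        coph[x, y] <- coph[y, x] <- best_d
      }
    }
    # ward.D update into slot i
    for (k in active) {
      if (k == i || k == j) next
      dd[i, k] <- dd[k, i] <-
        ((sizes[i] + sizes[k]) * dd[i, k] + (sizes[j] + sizes[k]) * dd[j, k] -
           sizes[k] * best_d) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    dd[j, ] <- Inf
    dd[, j] <- Inf
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# converged two-way median polish via stats::medpolish: residuals plus
# overall plus row (strain) effects, i.e. column (array) effects removed
oracle_medpolish_residuals <- function(m) {
  fit <- stats::medpolish(m, eps = 1e-10, maxiter = 100, trace.iter = FALSE)
  fit$residuals + fit$overall + fit$row
}

random_screen_matrix <- function(n = 20, p = 5, seed = 1, missing = 0,
                                 orientation = "sensitivity_positive") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              sprintf("s%02d", seq_len(p))))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  screen_matrix(m, value_kind = "fd", orientation = orientation)
}
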