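# Loop-based reference implementation of the EDMA bootstrap contrast.
# Deliberately naive: explicit loops everywhere, no shared code with the
# package internals beyond the RNG contract (all control indices drawn in one
# sample.int call, then all patient indices; column b = replicate b).

oracle_centroid_size <- function(xy) {
  ctr <- c(mean(xy[, 1]), mean(xy[, 2]))
  acc <- 0
  for (i in seq_len(nrow(xy)))
    acc <- acc + (xy[i, 1] - ctr[1])^2 + (xy[i, 2] - ctr[2])^2
  sqrt(acc)
}

oracle_form <- function(xy) {
  L <- nrow(xy)
  out <- numeric(0)
  for (i in seq_len(L - 1))
    for (j in (i + 1):L)
      out <- c(out, sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2))
  out
}

oracle_group_forms <- function(subjects) {
  rows <- list()
  for (s in subjects) {
    xy <- s$coords / oracle_centroid_size(s$coords)
    rows[[length(rows) + 1]] <- oracle_form(xy)
  }
  do.call(rbind, rows)
}

oracle_edma_contrast <- function(controls, patients, n_boot, alpha, seed,
                                 statistic = "relative") {
  Xc <- oracle_group_forms(controls)
  Xp <- oracle_group_forms(patients)
  n_c <- nrow(Xc); n_p <- nrow(Xp); K <- ncol(Xc)
  mc <- numeric(K); mp <- numeric(K)
  for (k in seq_len(K)) {
    mc[k] <- sum(Xc[, k]) / n_c
    mp[k] <- sum(Xp[, k]) / n_p
  }
  D <- if (statistic == "relative") (mc - mp) / mc else mc - mp

  set.seed(seed)
  idx_c <- matrix(sample.int(n_c, n_c * n_boot, replace = TRUE), n_c, n_boot)
  idx_p <- matrix(sample.int(n_p, n_p * n_boot, replace = TRUE), n_p, n_boot)
  Db <- matrix(NA_real_, n_boot, K)
  for (b in seq_len(n_boot)) {
    for (k in seq_len(K)) {
      sc <- 0
      for (i in seq_len(n_c)) sc <- sc + Xc[idx_c[i, b], k]
      sp <- 0
      for (i in seq_len(n_p)) sp <- sp + Xp[idx_p[i, b], k]
      bc <- sc / n_c; bp <- sp / n_p
      Db[b, k] <- if (statistic == "relative") (bc - bp) / bc else bc - bp
    }
  }
  k_trim <- floor(alpha / 2 * n_boot)
  ci_low <- numeric(K); ci_high <- numeric(K)
  for (k in seq_len(K)) {
    s <- sort(Db[, k])
    kept <- s[(k_trim + 1):(n_boot - k_trim)]
    ci_low[k] <- min(kept)
    ci_high[k] <- max(kept)
  }
  list(rel_diff = D, mean_control = mc, mean_patient = mp,
       ci_low = ci_low, ci_high = ci_high,
       significant = ci_low > 0 | ci_high < 0)
}
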