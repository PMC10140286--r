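#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances of all landmarks from their centroid. It is
#' translation- and rotation-invariant and scales linearly with the
#' configuration.
#'
#' @param lm a [landmark_set()] or a numeric matrix of coordinates (one row
#'   per landmark).
#' @return A positive scalar in the input's length units.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))  # sqrt(2)
#' @export
centroid_size <- function(lm) {
  xy <- if (inherits(lm, "landmark_set")) lm$coords else as.matrix(lm)
  if (nrow(xy) < 2L) stop("centroid size needs at least 2 landmarks")
  cs <- sqrt(sum(sweep(xy, 2, colMeans(xy))^2))
  if (cs <= 0)
    stop("degenerate configuration: all landmarks coincide")
  cs
}

#' Scale a landmark set to unit centroid size
#'
#' Divides the coordinates by the configuration's centroid size, removing
#' overall scale before shape comparison. The original centroid size is kept
#' in the `centroid_size` field.
#'
#' @param lm a [landmark_set()].
#' @return The input with rescaled (dimensionless) coordinates, classed
#'   additionally as `scaled_landmark_set`.
#' @export
scale_to_unit_centroid_size <- function(lm) {
  if (!inherits(lm, "landmark_set")) stop("lm must be a landmark_set")
  if (inherits(lm, "scaled_landmark_set")) return(lm)
  cs <- centroid_size(lm)
  lm$centroid_size <- cs
  lm$coords <- lm$coords / cs
  class(lm) <- c("scaled_landmark_set", class(lm))
  lm
}

#' Canonical landmark pair order
#'
#' All unordered landmark pairs (i < j) in the row-major order used by form
#' matrices and contrast results: (1,2), (1,3), ..., (1,L), (2,3), ...
#'
#' @param config a [landmark_config()].
#' @return A `L(L-1)/2` x 2 character matrix of landmark id pairs.
#' @export
distance_pairs <- function(config = default_landmark_config()) {
  idx <- utils::combn(length(config$names), 2L)
  cbind(config$names[idx[1, ]], config$names[idx[2, ]])
}

#' Form matrix: all unique interlandmark distances of one subject
#'
#' EDMA represents a shape as the vector of Euclidean distances between all
#' unordered landmark pairs; for the 18-landmark configuration this is 153
#' unique facial measurements. Distances are computed on the coordinates as
#' given — scale first with [scale_to_unit_centroid_size()] for shape
#' analysis.
#'
#' @param lm a [landmark_set()] (scaled or not) or a coordinate matrix.
#' @return Named numeric vector of length `L(L-1)/2` in canonical pair order;
#'   names are `"<id_a>--<id_b>"`.
#' @export
form_matrix <- function(lm) {
  xy <- if (inherits(lm, "landmark_set")) lm$coords else as.matrix(lm)
  d <- as.vector(stats::dist(xy))  # dist() stores exactly the canonical order
  nm <- rownames(xy)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(xy)))
  idx <- utils::combn(nrow(xy), 2L)
  names(d) <- paste0(nm[idx[1, ]], "--", nm[idx[2, ]])
  d
}

#' Mean form of a group
#'
#' Arithmetic mean of each interlandmark distance across subjects.
#'
#' @param forms numeric matrix of form-matrix rows (one subject per row), or a
#'   list of form-matrix vectors of equal length.
#' @return Numeric vector of per-distance means.
#' @export
mean_form <- function(forms) {
  if (is.list(forms)) forms <- do.call(rbind, forms)
  forms <- as.matrix(forms)
  if (nrow(forms) == 0L) stop("mean form of an empty group is undefined")
  colMeans(forms)
}

#' Relative differences between mean forms
#'
#' The per-distance statistic
#' `D = (mean distance in controls - mean distance in patients) / mean
#' distance in controls`. Positive values mean the distance is *shorter* in
#' patients; `D = 0.097` is reported as a 9.7% reduction.
#'
#' @param mean_control,mean_patient numeric vectors of per-distance means.
#' @return Numeric vector of relative differences.
#' @export
relative_differences <- function(mean_control, mean_patient) {
  if (length(mean_control) != length(mean_patient))
    stop("mean form vectors differ in length")
  zero <- which(mean_control <= 0)
  if (length(zero)) {
    nm <- names(mean_control)[zero[1]]
    stop(sprintf("control mean distance is zero for pair %s",
                 if (is.null(nm)) as.character(zero[1]) else nm))
  }
  (mean_control - mean_patient) / mean_control
}

# subjects (list of landmark_set) -> n x K matrix of scaled form matrices
group_form_matrix <- function(subjects) {
  t(vapply(subjects,
           function(s) form_matrix(scale_to_unit_centroid_size(s)),
           form_matrix(scale_to_unit_centroid_size(subjects[[1]]))))
}

# Bootstrap engine on precomputed form-matrix rows. Resampling stream: all
# n_c * n_boot control indices in one sample.int call, then all patient
# indices in a second call, column b of each index matrix forming replicate
# b -- a loop-based reference pre-drawing the same two index matrices
# consumes the identical RNG sequence.
edma_boot_core <- function(Xc, Xp, n_boot, alpha, seed, statistic,
                           significance_only = FALSE) {
  n_c <- nrow(Xc); n_p <- nrow(Xp)
  k_trim <- floor(alpha / 2 * n_boot)
  mc <- colMeans(Xc)
  mp <- colMeans(Xp)
  D <- if (statistic == "relative") relative_differences(mc, mp) else mc - mp

  set.seed(seed)
  idx_c <- sample.int(n_c, n_c * n_boot, replace = TRUE)
  idx_p <- sample.int(n_p, n_p * n_boot, replace = TRUE)
  # per-replicate resampling counts, as one flat tabulate over (replicate,
  # subject) bins
  Wc <- matrix(tabulate(idx_c + rep.int(seq.int(0L, by = n_c,
                                                length.out = n_boot),
                                        rep.int(n_c, n_boot)),
                        n_c * n_boot), n_c, n_boot)
  Wp <- matrix(tabulate(idx_p + rep.int(seq.int(0L, by = n_p,
                                                length.out = n_boot),
                                        rep.int(n_p, n_boot)),
                        n_p * n_boot), n_p, n_boot)
  Bc <- crossprod(Wc, Xc) / n_c   # n_boot x K resampled control means
  Bp <- crossprod(Wp, Xp) / n_p
  if (statistic == "relative") {
    if (any(Bc <= 0))
      stop("degenerate data: a resampled control mean distance is zero")
    Db <- (Bc - Bp) / Bc
  } else {
    Db <- Bc - Bp
  }
  if (significance_only) {
    # 0 below the trimmed interval iff at most k_trim replicates are <= 0;
    # 0 above it iff at most k_trim are >= 0. Equivalent to the sorted-CI
    # rule without the sort.
    sig <- colSums(Db <= 0) <= k_trim | colSums(Db >= 0) <= k_trim
    names(sig) <- names(D)
    return(list(mean_control = mc, mean_patient = mp, rel_diff = D,
                ci_low = NULL, ci_high = NULL, significant = sig))
  }
  # sort all columns at once (radix on column key, then value)
  S <- matrix(Db[order(col(Db), Db)], n_boot, ncol(Db))
  ci_low <- S[k_trim + 1L, ]
  ci_high <- S[n_boot - k_trim, ]
  names(ci_low) <- names(ci_high) <- names(D)
  list(mean_control = mc, mean_patient = mp, rel_diff = D,
       ci_low = ci_low, ci_high = ci_high,
       significant = ci_low > 0 | ci_high < 0)
}

#' EDMA two-sample shape contrast with bootstrap confidence intervals
#'
#' Fits the package's core model: every subject is scaled to unit centroid
#' size, the form matrix of all unique interlandmark distances is computed,
#' and for every distance the relative difference
#' `D = (mean_control - mean_patient) / mean_control` between group mean
#' forms is tested by a two-tailed two-sample nonparametric bootstrap.
#' Each bootstrap replicate resamples subjects with replacement within each
#' group (preserving group sizes) and recomputes `D`; per distance the
#' `n_boot` replicate values are sorted, the lowest and highest
#' `floor(alpha/2 * n_boot)` values are discarded, and the minimum and
#' maximum of the retained values form the confidence limits. A distance is
#' significant when zero lies strictly outside its interval (zero exactly on
#' a bound counts as contained). No multiple-testing correction is applied:
#' each of the `L(L-1)/2` distances is tested marginally at level `alpha`.
#'
#' @param x either a [landmark_cohort()] (then `patient_group` selects the
#'   patient subjects and `control_group` the controls), or a list of
#'   [landmark_set()] objects forming the control group.
#' @param patients list of [landmark_set()] patients (only when `x` is a
#'   list).
#' @param patient_group,control_group group labels used when `x` is a cohort.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param alpha marginal significance level; the default 0.10 yields 90%
#'   confidence intervals. `floor(alpha/2 * n_boot)` must be at least 1.
#' @param seed integer seed making the resampling deterministic.
#' @param statistic bootstrap the relative difference `D` (default) or the
#'   absolute difference `mean_control - mean_patient`.
#' @return An object of class `edma_contrast` with per-distance fields
#'   `mean_control`, `mean_patient`, `rel_diff`, `ci_low`, `ci_high`,
#'   `significant`, the pair table, group sizes, the analysis settings, and
#'   the mean scaled control shape (for wireframe plots). Use [fds()] for the
#'   dysmorphology score, [coef()], [confint()], [summary()], [plot()], and
#'   [as.data.frame()] to inspect it.
#' @examples
#' coh <- generate_cohort(synthetic_spec(n_controls = 10, n_patients = 8,
#'                                       effect = preset_effect("ds_like"),
#'                                       seed = 1))
#' fit <- edma_contrast(coh, patient_group = "patient",
#'                      n_boot = 200, seed = 1)
#' fit
#' @export
edma_contrast <- function(x, patients = NULL, patient_group = NULL,
                          control_group = "control",
                          n_boot = 10000L, alpha = 0.10, seed = 1L,
                          statistic = c("relative", "absolute")) {
  statistic <- match.arg(statistic)
  if (inherits(x, "landmark_cohort")) {
    if (is.null(patient_group))
      stop("patient_group is required when contrasting a cohort")
    controls <- cohort_subset(x, control_group)
    patients <- cohort_subset(x, patient_group)
    config <- x$config
  } else {
    controls <- x
    if (is.null(patients)) stop("patients group is required")
    config <- NULL
  }
  if (length(controls) == 0L || length(patients) == 0L)
    stop("both groups must be nonempty")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be positive")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  k_trim <- floor(alpha / 2 * n_boot)
  if (k_trim < 1L)
    stop("n_boot too small: floor(alpha/2 * n_boot) must be at least 1")

  Xc <- group_form_matrix(controls)
  Xp <- group_form_matrix(patients)
  if (ncol(Xc) != ncol(Xp))
    stop("control and patient groups use different landmark configurations")
  n_c <- nrow(Xc); n_p <- nrow(Xp); K <- ncol(Xc)

  core <- edma_boot_core(Xc, Xp, n_boot, alpha, seed, statistic)

  mean_shape <- Reduce(`+`, lapply(controls, function(s)
    scale_to_unit_centroid_size(s)$coords)) / n_c

  structure(c(list(
    pairs = {
      nm <- rownames(controls[[1]]$coords)
      idx <- utils::combn(length(nm), 2L)
      cbind(nm[idx[1, ]], nm[idx[2, ]])
    }),
    core,
    list(
    n_controls = n_c, n_patients = n_p, n_distances = K,
    n_boot = n_boot, alpha = alpha, seed = seed, statistic = statistic,
    control_group = if (inherits(x, "landmark_cohort")) control_group else "control",
    patient_group = if (inherits(x, "landmark_cohort")) patient_group else "patient",
    mean_shape_control = mean_shape,
    config = config)),
    class = "edma_contrast")
}

#' @export
print.edma_contrast <- function(x, ...) {
  cat(sprintf(
    "EDMA contrast: %s (n = %d) vs %s (n = %d)\n",
    x$control_group, x$n_controls, x$patient_group, x$n_patients))
  cat(sprintf("  %d interlandmark distances, %d bootstrap resamples, alpha = %g\n",
              x$n_distances, x$n_boot, x$alpha))
  cat(sprintf("  statistic: %s difference\n", x$statistic))
  cat(sprintf("  significant distances: %d of %d (FDS = %.1f%%)\n",
              sum(x$significant), x$n_distances,
              100 * sum(x$significant) / x$n_distances))
  invisible(x)
}

#' @export
coef.edma_contrast <- function(object, ...) object$rel_diff

#' @export
confint.edma_contrast <- function(object, parm, level, ...) {
  cbind(ci_low = object$ci_low, ci_high = object$ci_high)
}

#' @export
as.data.frame.edma_contrast <- function(x, ...) {
  data.frame(pair_a = x$pairs[, 1], pair_b = x$pairs[, 2],
             mean_control = unname(x$mean_control),
             mean_patient = unname(x$mean_patient),
             rel_diff = unname(x$rel_diff),
             ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
             significant = unname(x$significant),
             stringsAsFactors = FALSE)
}

#' @export
summary.edma_contrast <- function(object, k = 10L, ...) {
  out <- list(contrast = object, fds = fds(object),
              top = top_differences(object, k = k))
  class(out) <- "summary.edma_contrast"
  out
}

#' @export
print.summary.edma_contrast <- function(x, ...) {
  print(x$contrast)
  print(x$fds)
  print(x$top)
  invisible(x)
}

#' Write a contrast result as TSV
#'
#' One row per distance in canonical pair order, columns
#' `pair_a, pair_b, mean_control, mean_patient, rel_diff, ci_low, ci_high,
#' significant`. A comment header records the settings and the sign
#' convention (`rel_diff > 0` means the distance is reduced in patients).
#'
#' @param contrast an [edma_contrast()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_contrast <- function(contrast, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# EDMA contrast %s vs %s; n_boot=%d alpha=%g seed=%d statistic=%s",
            contrast$control_group, contrast$patient_group,
            contrast$n_boot, contrast$alpha, contrast$seed, contrast$statistic),
    "# sign convention: rel_diff > 0 => distance reduced in patients"), con)
  utils::write.table(as.data.frame(contrast), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
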