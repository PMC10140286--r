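#' Facial Dysmorphology Score
#'
#' The FDS of a contrast is the percentage of interlandmark distances that
#' differ significantly between the patient and control groups.
#'
#' @param contrast an [edma_contrast()] result.
#' @return An object of class `fds_score` with fields `fds` (percentage in
#'   0..100), `n_significant`, `n_distances`, and the contrast.
#' @examples
#' # 89 of 153 significant distances give FDS = 58.2%
#' round(100 * 89 / 153, 1)
#' @export
fds <- function(contrast) {
  if (!inherits(contrast, "edma_contrast"))
    stop("contrast must be an edma_contrast")
  n_sig <- sum(contrast$significant)
  structure(list(fds = 100 * n_sig / contrast$n_distances,
                 n_significant = n_sig,
                 n_distances = contrast$n_distances,
                 contrast = contrast),
            class = "fds_score")
}

#' @export
print.fds_score <- function(x, ...) {
  cat(sprintf("FDS = %.1f%% (%d of %d distances significantly different)\n",
              x$fds, x$n_significant, x$n_distances))
  invisible(x)
}

#' Build one staggered pseudo-subsample
#'
#' Composes a pseudo patient group of fixed size `N` from `M` true patients
#' (sampled without replacement) plus `N - M` controls (sampled without
#' replacement), and a comparison control group of all remaining controls,
#' disjoint from the pseudo group. Draws use the current RNG state; seed the
#' generator beforehand for reproducibility.
#'
#' @param controls,patients lists of [landmark_set()] objects.
#' @param M number of true patients in the pseudo group, `0 <= M <= N`.
#' @param N pseudo group size; defaults to the number of patients.
#' @return A list with `pseudo_patients` (length `N`) and
#'   `comparison_controls`.
#' @export
build_pseudo_groups <- function(controls, patients, M,
                                N = length(patients)) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 0L || M > N) stop("M must lie in 0..N")
  if (N > length(patients)) stop("N cannot exceed the number of patients")
  n_c <- length(controls)
  min_comparison <- 2L
  if (n_c < (N - M) + min_comparison)
    stop(sprintf(
      "need at least %d controls to borrow %d and keep %d for comparison",
      (N - M) + min_comparison, N - M, min_comparison))
  pat_idx <- if (M > 0L) sample.int(length(patients), M) else integer(0)
  ctl_idx <- if (N - M > 0L) sample.int(n_c, N - M) else integer(0)
  list(pseudo_patients = c(patients[pat_idx], controls[ctl_idx]),
       comparison_controls = controls[setdiff(seq_len(n_c), ctl_idx)])
}

# ratio of no-patient simulations whose FDS strictly exceeds the observed one
fds_p_value <- function(null_fds, observed_fds,
                        p_rule = c("strict", "add_one")) {
  p_rule <- match.arg(p_rule)
  k <- sum(null_fds > observed_fds)
  S <- length(null_fds)
  if (p_rule == "strict") k / S else (k + 1) / (S + 1)
}

#' Staggered pseudo-subsample significance simulation for the FDS
#'
#' Assesses whether an observed FDS exceeds what random sampling of controls
#' alone can produce. For each round `M` in `m_values`, `n_sims` simulations
#' each build a pseudo patient group of `M` true patients plus `N - M`
#' controls (see [build_pseudo_groups()]), contrast it against the remaining
#' controls with [edma_contrast()], and record the FDS. The `M = 0` round
#' contains no patients and represents facial differences arising by chance
#' in the general population; the p-value is the fraction of `M = 0`
#' simulations whose FDS strictly exceeds the observed FDS from the full
#' sample (`p_rule = "add_one"` gives the never-zero `(k+1)/(S+1)` variant).
#'
#' @param cohort a [landmark_cohort()].
#' @param patient_group group label of the patients.
#' @param control_group group label of the controls.
#' @param m_values increasing integer vector of patient counts, starting at 0
#'   and ending at `N` (the patient sample size). Default: steps of 3 when
#'   `N > 12`, else 2, closed with `N`.
#' @param n_sims simulations per round (default 150).
#' @param n_boot,alpha bootstrap settings for every EDMA contrast. `n_boot`
#'   defaults to 1000 here: per-distance intervals inside the simulation only
#'   need enough resolution for the significance count, and the full-scale
#'   10000 used for a single reported contrast would be needlessly slow
#'   across hundreds of simulated contrasts (it remains available).
#' @param seed root seed; every (round, simulation) cell derives a private
#'   child stream, so results do not depend on execution order.
#' @param p_rule `"strict"` (default) counts strictly greater null FDS
#'   values; `"add_one"` applies the (k+1)/(S+1) correction.
#' @return An object of class `fds_sim`: observed FDS, per-round FDS draws,
#'   the p-value, and the design settings. See [summarize_rounds()],
#'   [plot.fds_sim()], [write_simulation()].
#' @export
fds_simulation <- function(cohort, patient_group, control_group = "control",
                           m_values = NULL, n_sims = 150L,
                           n_boot = 1000L, alpha = 0.10, seed = 1L,
                           p_rule = c("strict", "add_one")) {
  p_rule <- match.arg(p_rule)
  controls <- cohort_subset(cohort, control_group)
  patients <- cohort_subset(cohort, patient_group)
  N <- length(patients)
  if (is.null(m_values)) {
    step <- if (N > 12L) 3L else 2L
    m_values <- unique(c(seq(0L, N, by = step), N))
  }
  m_values <- as.integer(m_values)
  if (m_values[1] != 0L || m_values[length(m_values)] != N ||
      is.unsorted(m_values, strictly = TRUE))
    stop("m_values must increase from 0 to the number of patients")
  n_sims <- as.integer(n_sims)
  if (n_sims < 1L) stop("n_sims must be at least 1")
  if (length(controls) < N + 2L)
    stop("too few controls for pseudo-subsamples of this size")

  observed_fit <- edma_contrast(controls, patients, n_boot = n_boot,
                                alpha = alpha,
                                seed = mix_seed(seed, 0L, 0L))
  observed <- fds(observed_fit)

  # Scaled form matrices are computed once per subject; each simulation then
  # only indexes rows. The pseudo-group index draws are the same sample.int
  # calls build_pseudo_groups() makes, so results are identical to composing
  # landmark-set lists per simulation.
  Xc <- group_form_matrix(controls)
  Xp <- group_form_matrix(patients)
  n_c <- nrow(Xc)
  K <- ncol(Xc)

  draws <- vector("list", length(m_values))
  names(draws) <- as.character(m_values)
  for (mi in seq_along(m_values)) {
    M <- m_values[mi]
    vals <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      set.seed(mix_seed(seed, 1000L + M, s))
      pat_idx <- if (M > 0L) sample.int(N, M) else integer(0)
      ctl_idx <- if (N - M > 0L) sample.int(n_c, N - M) else integer(0)
      Xpseudo <- rbind(Xp[pat_idx, , drop = FALSE],
                       Xc[ctl_idx, , drop = FALSE])
      Xcomp <- Xc[setdiff(seq_len(n_c), ctl_idx), , drop = FALSE]
      core <- edma_boot_core(Xcomp, Xpseudo, n_boot, alpha,
                             seed = mix_seed(seed, 2000L + M, s),
                             statistic = "relative",
                             significance_only = TRUE)
      vals[s] <- 100 * sum(core$significant) / K
    }
    draws[[mi]] <- vals
  }
  p <- fds_p_value(draws[["0"]], observed$fds, p_rule)

  structure(list(observed = observed, fds_values = draws,
                 m_values = m_values, n_sims = n_sims, n_boot = n_boot,
                 alpha = alpha, seed = seed, p_rule = p_rule, p_value = p,
                 patient_group = patient_group,
                 control_group = control_group,
                 n_controls = length(controls), n_patients = N),
            class = "fds_sim")
}

#' @export
print.fds_sim <- function(x, ...) {
  cat(sprintf("FDS pseudo-subsample simulation: %s (n = %d) vs %s (n = %d)\n",
              x$control_group, x$n_controls, x$patient_group, x$n_patients))
  cat(sprintf("  rounds M = %s; %d simulations/round; n_boot = %d; alpha = %g\n",
              paste(x$m_values, collapse = ", "), x$n_sims, x$n_boot, x$alpha))
  cat(sprintf("  observed FDS = %.1f%%; p = %.4g (%s rule)\n",
              x$observed$fds, x$p_value, x$p_rule))
  invisible(x)
}

#' Per-round summary of an FDS simulation
#'
#' @param sim an [fds_simulation()] result.
#' @param breaks histogram breakpoints on the FDS scale (percent).
#' @return A data frame with one row per round (`M`, `n_sims`, `mean`, `min`,
#'   `max`); the binned counts used for histogram rendering are attached as
#'   attribute `"histogram"` (a list with `breaks` and a per-round count
#'   matrix).
#' @export
summarize_rounds <- function(sim, breaks = seq(0, 100, by = 5)) {
  if (!inherits(sim, "fds_sim")) stop("sim must be an fds_sim")
  tab <- data.frame(
    M = sim$m_values,
    n_sims = sim$n_sims,
    mean = vapply(sim$fds_values, mean, numeric(1)),
    min = vapply(sim$fds_values, min, numeric(1)),
    max = vapply(sim$fds_values, max, numeric(1)),
    row.names = NULL)
  counts <- t(vapply(sim$fds_values, function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE)$counts,
    numeric(length(breaks) - 1L)))
  attr(tab, "histogram") <- list(breaks = breaks, counts = counts)
  tab
}

#' @export
summary.fds_sim <- function(object, ...) summarize_rounds(object)

#' Plot FDS simulation histograms
#'
#' One histogram panel per round `M`, stacked top to bottom, with a dashed
#' red line marking the FDS observed with the complete sample.
#'
#' @param x an [fds_simulation()] result.
#' @param breaks histogram breakpoints (percent FDS).
#' @param ... ignored.
#' @export
plot.fds_sim <- function(x, breaks = seq(0, 100, by = 5), ...) {
  nr <- length(x$m_values)
  op <- graphics::par(mfrow = c(nr, 1),
                      mar = c(2.5, 4, 1.5, 1), oma = c(2, 0, 2, 0))
  on.exit(graphics::par(op))
  for (i in seq_len(nr)) {
    graphics::hist(x$fds_values[[i]], breaks = breaks,
                   col = "grey70", border = "white",
                   main = sprintf("M = %d patients", x$m_values[i]),
                   xlab = "", ylab = "simulations", cex.main = 0.9)
    graphics::abline(v = x$observed$fds, col = "red", lty = 2, lwd = 2)
  }
  graphics::mtext("FDS (%)", side = 1, outer = TRUE, line = 0.5)
  graphics::mtext(sprintf("%s vs %s: observed FDS = %.1f%%, p = %.4g",
                          x$control_group, x$patient_group,
                          x$observed$fds, x$p_value),
                  side = 3, outer = TRUE, line = 0.5)
  invisible(x)
}

#' Write an FDS simulation to disk
#'
#' Writes the raw draws as TSV (`M`, `sim_index`, `fds`; one row per
#' simulation) and a JSON summary (`observed_fds`, `p_value`, design).
#'
#' @param sim an [fds_simulation()] result.
#' @param tsv_path,json_path output files (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(
      M = rep(sim$m_values, each = sim$n_sims),
      sim_index = rep(seq_len(sim$n_sims), times = length(sim$m_values)),
      fds = unlist(sim$fds_values, use.names = FALSE))
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      observed_fds = sim$observed$fds,
      p_value = sim$p_value,
      design = list(m_values = sim$m_values, n_sims = sim$n_sims,
                    n_boot = sim$n_boot, alpha = sim$alpha, seed = sim$seed,
                    p_rule = sim$p_rule,
                    control_group = sim$control_group,
                    patient_group = sim$patient_group,
                    n_controls = sim$n_controls,
                    n_patients = sim$n_patients)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
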