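#' Top significant distance differences of a contrast
#'
#' Splits the significant distances by direction of change and keeps the `k`
#' of largest magnitude on each side, mirroring the convention of plotting
#' the ten longest and shortest significant relative differences.
#' `rel_diff > 0` means the distance is *shorter* in patients (a reduction);
#' `rel_diff < 0` means it is longer (an increase). Ties break by canonical
#' pair order.
#'
#' @param contrast an [edma_contrast()] result.
#' @param k entries kept per direction (default 10).
#' @return An object of class `top_differences`: data frames
#'   `increased_in_patients` and `decreased_in_patients` with columns
#'   `pair_a`, `pair_b`, `rel_diff`, magnitudes nonincreasing.
#' @export
top_differences <- function(contrast, k = 10L) {
  if (!inherits(contrast, "edma_contrast"))
    stop("contrast must be an edma_contrast")
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  df <- as.data.frame(contrast)
  sig <- df[df$significant, , drop = FALSE]
  pick <- function(rows) {
    rows <- rows[order(-abs(rows$rel_diff)), , drop = FALSE]  # stable sort
    utils::head(rows[, c("pair_a", "pair_b", "rel_diff")], k)
  }
  structure(list(
    increased_in_patients = pick(sig[sig$rel_diff < 0, , drop = FALSE]),
    decreased_in_patients = pick(sig[sig$rel_diff > 0, , drop = FALSE]),
    k = k),
    class = "top_differences")
}

#' @export
print.top_differences <- function(x, ...) {
  fmt <- function(df, verb) {
    if (nrow(df) == 0) return(cat("  (none)\n"))
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %s -- %s: %.1f%% %s in patients\n",
                  df$pair_a[i], df$pair_b[i],
                  100 * abs(df$rel_diff[i]), verb))
  }
  cat(sprintf("Top %d distances increased in patients (rel_diff < 0):\n", x$k))
  fmt(x$increased_in_patients, "increase")
  cat(sprintf("Top %d distances decreased in patients (rel_diff > 0):\n", x$k))
  fmt(x$decreased_in_patients, "reduction")
  invisible(x)
}

# segment table for wireframe rendering / serialization
wireframe_segments <- function(contrast, k = 10L) {
  top <- top_differences(contrast, k)
  rbind(
    if (nrow(top$increased_in_patients))
      cbind(top$increased_in_patients, direction = "longer_in_patients"),
    if (nrow(top$decreased_in_patients))
      cbind(top$decreased_in_patients, direction = "shorter_in_patients"))
}

#' Wireframe plot of the largest significant differences
#'
#' Draws the mean control shape with the top `k` significant increased and
#' decreased distances overlaid as line segments: dark lines are distances
#' longer in patients, light lines shorter in patients. [export_wireframe()]
#' writes the figure to PNG/PDF/SVG (by file extension) together with a
#' machine-readable JSON sidecar listing the segments and the template
#' coordinates.
#'
#' @param x an [edma_contrast()] result.
#' @param k segments kept per direction.
#' @param mean_shape optional [landmark_set()] used as the plotted template;
#'   defaults to the contrast's mean scaled control shape.
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.edma_contrast <- function(x, k = 10L, mean_shape = NULL,
                               main = NULL, ...) {
  xy <- if (is.null(mean_shape)) x$mean_shape_control else mean_shape$coords
  seg <- wireframe_segments(x, k)
  if (is.null(main))
    main <- sprintf("%s vs %s: top significant distances",
                    x$control_group, x$patient_group)
  # image convention: y grows downward, so flip the axis for display
  graphics::plot(xy[, 1], -xy[, 2], asp = 1, pch = 19, cex = 0.8,
                 xlab = "x", ylab = "y (up)", main = main, ...)
  if (!is.null(seg) && nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      a <- xy[seg$pair_a[i], ]; b <- xy[seg$pair_b[i], ]
      dark <- seg$direction[i] == "longer_in_patients"
      graphics::segments(a[1], -a[2], b[1], -b[2], lty = 3, lwd = 2,
                         col = if (dark) "grey20" else "grey65")
    }
    graphics::legend("bottomleft", lty = 3, lwd = 2,
                     col = c("grey20", "grey65"), bty = "n", cex = 0.8,
                     legend = c("longer in patients", "shorter in patients"))
  }
  graphics::text(xy[, 1], -xy[, 2], rownames(xy), pos = 3, cex = 0.5,
                 col = "grey40")
  invisible(x)
}

#' @rdname plot.edma_contrast
#' @param contrast an [edma_contrast()] result.
#' @param path figure file; extension selects the device (`.png`, `.pdf`,
#'   `.svg`). The JSON sidecar is written next to it as `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
export_wireframe <- function(contrast, path, k = 10L, mean_shape = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = 900, height = 900, res = 130),
         pdf = grDevices::pdf(path, width = 7, height = 7),
         svg = grDevices::svg(path, width = 7, height = 7),
         stop(sprintf("unsupported figure format '.%s' (png, pdf, svg)", ext)))
  ok <- FALSE
  tryCatch({
    plot.edma_contrast(contrast, k = k, mean_shape = mean_shape)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("wireframe rendering failed")
  seg <- wireframe_segments(contrast, k)
  xy <- if (is.null(mean_shape)) contrast$mean_shape_control
        else mean_shape$coords
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    template = lapply(seq_len(nrow(xy)), function(i)
      list(id = rownames(xy)[i], x = xy[i, 1], y = xy[i, 2])),
    segments = if (is.null(seg) || nrow(seg) == 0) list() else
      lapply(seq_len(nrow(seg)), function(i)
        list(pair = c(seg$pair_a[i], seg$pair_b[i]),
             rel_diff = seg$rel_diff[i],
             direction = seg$direction[i]))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' Write FDS simulation histograms to a figure file
#'
#' Renders [plot.fds_sim()] to `path` (extension selects PNG/PDF/SVG) and
#' writes the underlying draws as a TSV next to it (`<path>.tsv`, one row per
#' simulation: `M`, `sim_index`, `fds`).
#'
#' @param sim an [fds_simulation()] result.
#' @param path figure file.
#' @return Invisibly, the paths written.
#' @export
plot_fds_histograms <- function(sim, path) {
  ext <- tolower(tools::file_ext(path))
  nr <- length(sim$m_values)
  switch(ext,
         png = grDevices::png(path, width = 700,
                              height = max(500, 220 * nr), res = 110),
         pdf = grDevices::pdf(path, width = 6, height = max(4, 1.8 * nr)),
         svg = grDevices::svg(path, width = 6, height = max(4, 1.8 * nr)),
         stop(sprintf("unsupported figure format '.%s' (png, pdf, svg)", ext)))
  tryCatch(plot(sim), finally = grDevices::dev.off())
  tsv <- paste0(path, ".tsv")
  write_simulation(sim, tsv_path = tsv)
  invisible(c(path, tsv))
}

#' Read a contrast TSV written by [write_contrast()]
#'
#' @param path TSV file.
#' @return A data frame with one row per distance.
#' @export
read_contrast <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# Rebuild a minimal edma_contrast from its serialized table, for reporting.
contrast_from_table <- function(df, mean_shape = NULL,
                                control_group = "control",
                                patient_group = "patient") {
  nm <- paste0(df$pair_a, "--", df$pair_b)
  structure(list(
    pairs = cbind(df$pair_a, df$pair_b),
    mean_control = stats::setNames(df$mean_control, nm),
    mean_patient = stats::setNames(df$mean_patient, nm),
    rel_diff = stats::setNames(df$rel_diff, nm),
    ci_low = stats::setNames(df$ci_low, nm),
    ci_high = stats::setNames(df$ci_high, nm),
    significant = stats::setNames(df$significant, nm),
    n_controls = NA_integer_, n_patients = NA_integer_,
    n_distances = nrow(df), n_boot = NA_integer_, alpha = NA_real_,
    seed = NA_integer_, statistic = "relative",
    control_group = control_group, patient_group = patient_group,
    mean_shape_control = if (is.null(mean_shape)) NULL
                         else mean_shape$coords,
    config = NULL),
    class = "edma_contrast")
}
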