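#' 68-point detector output for one subject
#'
#' Container for the standard 68-point facial annotation scheme produced by
#' common face-landmark detectors. Only the detector's output coordinates are
#' handled here; no detection is performed.
#'
#' @param subject_id character scalar.
#' @param coords 68 x 2 numeric matrix of (x, y) positions.
#' @return An object of class `landmark68_set`.
#' @export
landmark68_set <- function(subject_id, coords) {
  coords <- as.matrix(coords)
  if (!identical(dim(coords), c(68L, 2L)))
    stop(sprintf("subject '%s': expected 68 x 2 coordinates", subject_id))
  if (!all(is.finite(coords)))
    stop(sprintf("subject '%s': non-finite coordinates", subject_id))
  dimnames(coords) <- list(paste0("p", 0:67), c("x", "y"))
  structure(list(subject_id = as.character(subject_id), coords = coords),
            class = "landmark68_set")
}

#' Read 68-point landmark CSV
#'
#' Expects header `subject_id,p0_x,p0_y,...,p67_x,p67_y`.
#'
#' @param path input CSV file.
#' @return A list of [landmark68_set()] objects in input order.
#' @export
read_landmarks68 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- c("subject_id",
            as.vector(rbind(paste0("p", 0:67, "_x"), paste0("p", 0:67, "_y"))))
  if (!identical(names(df), want))
    stop(sprintf("%s: header does not match the 68-point CSV dialect", path))
  lapply(seq_len(nrow(df)), function(i) {
    xy <- suppressWarnings(as.numeric(unlist(df[i, -1], use.names = FALSE)))
    if (!all(is.finite(xy)))
      stop(sprintf("%s: non-numeric coordinate at data row %d", path, i))
    landmark68_set(df$subject_id[i],
                   matrix(xy, ncol = 2L, byrow = TRUE))
  })
}

#' Default 68-to-18 landmark mapping
#'
#' Maps the 68-point detector scheme onto the 18-landmark anatomical
#' configuration: 15 landmarks are copied directly from their matched indices
#' and 3 are computed as midpoints — the glabella from the two innermost
#' eyebrow points, and each palpebrale inferius from the two central
#' lower-eyelid points of that eye. Indices are 0-based in the detector's
#' convention (inner brow endpoints 21/22; lower-eyelid centres 40/41 right,
#' 46/47 left). The default ships as an editable YAML file
#' (`system.file("extdata", "map68_default.yaml", package = "facedysm")`) so
#' the anatomy stays auditable and replaceable without code changes; pass a
#' custom table through [read_mapping()] to override it.
#'
#' @return A named list, one entry per target landmark id, each either
#'   `list(source = <0-based index>)` or `list(midpoint_of = c(i, j))`.
#' @export
default_map68 <- function() {
  read_mapping(system.file("extdata", "map68_default.yaml",
                           package = "facedysm"))
}

#' Read a 68-to-18 mapping table from YAML or JSON
#'
#' Entries are either `{target: <id>, source: <index>}` or
#' `{target: <id>, midpoint_of: [<i>, <j>]}` with 0-based 68-scheme indices.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) mapping file.
#' @return A named mapping list as in [default_map68()].
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  out <- list()
  for (e in raw) {
    if (is.null(e$target)) stop("mapping entry without a 'target' field")
    if (!is.null(e$source)) {
      out[[e$target]] <- list(source = as.integer(e$source))
    } else if (!is.null(e$midpoint_of)) {
      idx <- as.integer(unlist(e$midpoint_of))
      if (length(idx) != 2L)
        stop(sprintf("mapping for '%s': midpoint_of needs exactly 2 indices",
                     e$target))
      out[[e$target]] <- list(midpoint_of = idx)
    } else {
      stop(sprintf("mapping for '%s' has neither 'source' nor 'midpoint_of'",
                   e$target))
    }
  }
  bad <- unlist(lapply(out, function(m) c(m$source, m$midpoint_of)))
  if (any(bad < 0L | bad > 67L)) stop("mapping indices must lie in 0..67")
  out
}

#' Map 68-point detector output to the 18-landmark configuration
#'
#' @param lm68 a [landmark68_set()].
#' @param mapping mapping table, as from [default_map68()] or
#'   [read_mapping()]; must cover every landmark of `config`.
#' @param config target [landmark_config()].
#' @param group,sex,age metadata for the resulting [landmark_set()].
#' @return A [landmark_set()] in the target configuration.
#' @export
map68_to_18 <- function(lm68, mapping = default_map68(),
                        config = default_landmark_config(),
                        group = "control", sex = "unknown", age = NA_real_) {
  if (!inherits(lm68, "landmark68_set")) stop("lm68 must be a landmark68_set")
  missing <- setdiff(config$names, names(mapping))
  if (length(missing))
    stop(sprintf("mapping table missing target landmark(s): %s",
                 paste(missing, collapse = ", ")))
  coords <- t(vapply(config$names, function(id) {
    m <- mapping[[id]]
    if (!is.null(m$source)) lm68$coords[m$source + 1L, ]
    else colMeans(lm68$coords[m$midpoint_of + 1L, , drop = FALSE])
  }, numeric(2)))
  landmark_set(lm68$subject_id, coords, group = group, sex = sex, age = age,
               config = config)
}

#' Validate automatic landmarks against manual ones by RMSE
#'
#' For each landmark the root-mean-square Euclidean deviation between the
#' manual and automatic position is pooled over subjects (matched by
#' `subject_id`); the report also carries the mean of the per-landmark RMSE
#' values. Units are those of the input coordinates and are never converted.
#'
#' @param manual,automatic two [landmark_cohort()]s over the same subjects and
#'   configuration, in the same units.
#' @return An object of class `rmse_report` with elements `per_landmark_rmse`
#'   (named vector), `average_rmse`, and `n_subjects`.
#' @export
rmse_validation <- function(manual, automatic) {
  if (!identical(manual$config$names, automatic$config$names))
    stop("cohorts use different landmark configurations")
  ids_m <- vapply(manual$subjects, `[[`, character(1), "subject_id")
  ids_a <- vapply(automatic$subjects, `[[`, character(1), "subject_id")
  if (!setequal(ids_m, ids_a))
    stop("subject ids do not match between manual and automatic cohorts")
  ord <- match(ids_m, ids_a)
  L <- length(manual$config$names)
  sq <- matrix(0, nrow = length(ids_m), ncol = L)
  for (i in seq_along(ids_m)) {
    d <- manual$subjects[[i]]$coords - automatic$subjects[[ord[i]]]$coords
    sq[i, ] <- rowSums(d^2)
  }
  per <- sqrt(colMeans(sq))
  names(per) <- manual$config$names
  structure(list(per_landmark_rmse = per, average_rmse = mean(per),
                 n_subjects = length(ids_m)),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, digits = 3, ...) {
  cat("Landmark placement RMSE over", x$n_subjects, "subjects\n")
  print(round(x$per_landmark_rmse, digits))
  cat("average RMSE:", format(x$average_rmse, digits = digits), "\n")
  invisible(x)
}
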