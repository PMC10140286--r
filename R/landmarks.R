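#' Facial landmark configuration
#'
#' A landmark configuration names the ordered set of anatomical points that
#' every subject in an analysis must carry, and records which of them form
#' bilateral (right/left) pairs and which lie on the facial midline. The
#' default configuration is the 18-point frontal-face scheme used throughout
#' this package: 6 midline points and 6 bilateral pairs.
#'
#' @param names character vector of unique landmark identifiers, in the order
#'   coordinates are stored.
#' @param bilateral_pairs two-column character matrix (right id, left id).
#' @param midline character vector of unpaired, midline landmark ids.
#' @return An object of class `landmark_config`.
#' @examples
#' cfg <- default_landmark_config()
#' length(cfg$names)  # 18
#' @export
landmark_config <- function(names, bilateral_pairs, midline) {
  names <- as.character(names)
  if (anyDuplicated(names))
    stop("landmark names must be unique")
  bilateral_pairs <- matrix(as.character(bilateral_pairs), ncol = 2L)
  paired <- as.vector(t(bilateral_pairs))
  ids <- c(paired, as.character(midline))
  if (length(ids) != length(names) || !setequal(ids, names) || anyDuplicated(ids))
    stop("every landmark must appear in exactly one of bilateral_pairs or midline")
  structure(
    list(names = names, bilateral_pairs = bilateral_pairs,
         midline = as.character(midline)),
    class = "landmark_config")
}

#' @rdname landmark_config
#' @export
default_landmark_config <- function() {
  landmark_config(
    names = c("glabella", "sellion",
              "endocanthion_r", "endocanthion_l",
              "exocanthion_r", "exocanthion_l",
              "palpebrale_inferius_r", "palpebrale_inferius_l",
              "pronasale", "subnasale",
              "subalare_r", "subalare_l",
              "labiale_superius", "labiale_inferius",
              "crista_philtri_r", "crista_philtri_l",
              "chelion_r", "chelion_l"),
    bilateral_pairs = rbind(
      c("endocanthion_r", "endocanthion_l"),
      c("exocanthion_r", "exocanthion_l"),
      c("palpebrale_inferius_r", "palpebrale_inferius_l"),
      c("subalare_r", "subalare_l"),
      c("crista_philtri_r", "crista_philtri_l"),
      c("chelion_r", "chelion_l")),
    midline = c("glabella", "sellion", "pronasale", "subnasale",
                "labiale_superius", "labiale_inferius"))
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration:", length(x$names), "landmarks (",
      nrow(x$bilateral_pairs), "bilateral pairs,",
      length(x$midline), "midline )\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' One subject's landmark coordinates
#'
#' @param subject_id character scalar, unique within a cohort.
#' @param coords numeric matrix, one row per landmark, two columns (x, y), in
#'   a consistent length unit (mm or pixels). Row names, if present, must
#'   match the configuration.
#' @param group group label, e.g. `"control"`, `"DS"`.
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param age age in years, or `NA`.
#' @param config a [landmark_config()]; coordinates are checked and labelled
#'   against it.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, coords, group = "control",
                         sex = "unknown", age = NA_real_,
                         config = default_landmark_config()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must have two columns (x, y)")
  if (nrow(coords) != length(config$names))
    stop(sprintf("subject '%s': expected %d landmarks, got %d",
                 subject_id, length(config$names), nrow(coords)))
  if (!all(is.finite(coords)))
    stop(sprintf("subject '%s': non-finite coordinates are not supported",
                 subject_id))
  if (!is.null(rownames(coords)) && !identical(rownames(coords), config$names))
    stop(sprintf("subject '%s': landmark names do not match the configuration",
                 subject_id))
  dimnames(coords) <- list(config$names, c("x", "y"))
  if (!sex %in% c("M", "F", "unknown"))
    stop("sex must be one of 'M', 'F', 'unknown'")
  age <- as.numeric(age)
  if (!is.na(age) && age < 0) stop("age must be nonnegative")
  structure(
    list(subject_id = as.character(subject_id), group = as.character(group),
         sex = sex, age = age, coords = coords),
    class = "landmark_set")
}

#' A labelled cohort of landmark sets
#'
#' @param subjects list of [landmark_set()] objects sharing one configuration.
#' @param config the shared [landmark_config()].
#' @return An object of class `landmark_cohort`.
#' @export
landmark_cohort <- function(subjects, config = default_landmark_config()) {
  if (length(subjects) == 0L)
    stop("a cohort must contain at least one subject")
  ok <- vapply(subjects, inherits, logical(1), "landmark_set")
  if (!all(ok)) stop("all subjects must be landmark_set objects")
  for (s in subjects)
    if (!identical(rownames(s$coords), config$names))
      stop(sprintf("subject '%s' does not match the cohort configuration",
                   s$subject_id))
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(list(config = config, subjects = subjects),
            class = "landmark_cohort")
}

#' @export
print.landmark_cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat("Landmark cohort:", length(x$subjects), "subjects,",
      length(x$config$names), "landmarks\n")
  tab <- table(g)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"),
      "\n")
  invisible(x)
}

#' @export
length.landmark_cohort <- function(x) length(x$subjects)

#' Group labels and group subsets of a cohort
#'
#' @param cohort a [landmark_cohort()].
#' @param group a group label present in the cohort.
#' @return `cohort_groups()` returns the character vector of group labels, one
#'   per subject; `cohort_subset()` returns the list of `landmark_set` objects
#'   with that label.
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "group")
}

#' @rdname cohort_groups
#' @export
cohort_subset <- function(cohort, group) {
  sel <- cohort$subjects[cohort_groups(cohort) == group]
  if (length(sel) == 0L)
    stop(sprintf("no subjects with group label '%s'", group))
  sel
}

# n x (2L) matrix of flattened coordinates, subjects in rows
cohort_coord_matrix <- function(cohort) {
  t(vapply(cohort$subjects, function(s) as.vector(s$coords),
           numeric(2L * length(cohort$config$names))))
}

csv_header <- function(config) {
  c("subject_id", "group", "sex", "age",
    as.vector(rbind(paste0(config$names, "_x"), paste0(config$names, "_y"))))
}

#' Read a landmark cohort from CSV or TPS
#'
#' The CSV dialect has header
#' `subject_id,group,sex,age,<name>_x,<name>_y,...` with one `_x`/`_y` column
#' pair per landmark in configuration order. The TPS dialect is the standard
#' `LM=<n>` block format with an `ID=<subject_id>` line per specimen;
#' group/sex/age metadata travel in an optional sidecar CSV
#' (`subject_id,group,sex,age`) given as `sidecar`.
#'
#' @param path input file.
#' @param format `"csv"` or `"tps"`.
#' @param config target [landmark_config()].
#' @param sidecar optional metadata CSV for TPS input.
#' @return A [landmark_cohort()], subjects in input order.
#' @export
read_landmarks <- function(path, format = c("csv", "tps"),
                           config = default_landmark_config(),
                           sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") read_landmarks_csv(path, config)
  else read_landmarks_tps(path, config, sidecar)
}

read_landmarks_csv <- function(path, config) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- csv_header(config)
  if (!identical(names(df), want))
    stop(sprintf("%s: header does not match the %d-landmark CSV dialect",
                 path, length(config$names)))
  L <- length(config$names)
  subjects <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    xy <- suppressWarnings(as.numeric(unlist(row[-(1:4)], use.names = FALSE)))
    if (!all(is.finite(xy)))
      stop(sprintf("%s: non-numeric or missing coordinate at data row %d",
                   path, i))
    coords <- matrix(xy, ncol = 2L, byrow = TRUE,
                     dimnames = list(config$names, c("x", "y")))
    landmark_set(row$subject_id, coords, group = row$group, sex = row$sex,
                 age = if (is.na(row$age) || row$age == "") NA_real_
                       else as.numeric(row$age),
                 config = config)
  })
  landmark_cohort(subjects, config)
}

read_landmarks_tps <- function(path, config, sidecar = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  L <- length(config$names)
  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "group", "sex", "age") %in% names(meta)))
      stop(sprintf("%s: sidecar must have subject_id,group,sex,age columns",
                   sidecar))
  }
  subjects <- list()
  i <- 1L
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^LM=([0-9]+)$", lines[i]))[[1]]
    if (length(m) == 0L)
      stop(sprintf("%s: expected 'LM=' at line %d, got '%s'", path, i, lines[i]))
    n <- as.integer(m[2])
    if (n != L)
      stop(sprintf("%s: line %d declares LM=%d, configuration has %d landmarks",
                   path, i, n, L))
    if (i + n + 1L > length(lines))
      stop(sprintf("%s: truncated TPS block starting at line %d", path, i))
    xy <- t(vapply(lines[(i + 1L):(i + n)], function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
      if (length(v) != 2L || !all(is.finite(v)))
        stop(sprintf("%s: malformed coordinate line '%s'", path, ln))
      v
    }, numeric(2), USE.NAMES = FALSE))
    idline <- lines[i + n + 1L]
    mid <- regmatches(idline, regexec("^ID=(.*)$", idline))[[1]]
    if (length(mid) == 0L)
      stop(sprintf("%s: expected 'ID=' at line %d, got '%s'",
                   path, i + n + 1L, idline))
    sid <- mid[2]
    grp <- "control"; sex <- "unknown"; age <- NA_real_
    if (!is.null(meta)) {
      k <- match(sid, meta$subject_id)
      if (!is.na(k)) {
        grp <- meta$group[k]; sex <- meta$sex[k]; age <- as.numeric(meta$age[k])
      }
    }
    rownames(xy) <- config$names
    subjects[[length(subjects) + 1L]] <-
      landmark_set(sid, xy, group = grp, sex = sex, age = age, config = config)
    i <- i + n + 2L
  }
  landmark_cohort(subjects, config)
}

#' Write a landmark cohort to CSV or TPS
#'
#' CSV round-trips coordinates at full double precision together with all
#' metadata; TPS stores coordinates and subject ids only (plus an optional
#' metadata `sidecar` CSV).
#'
#' @inheritParams read_landmarks
#' @param cohort a [landmark_cohort()].
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(cohort, path, format = c("csv", "tps"),
                            sidecar = NULL) {
  format <- match.arg(format)
  if (!inherits(cohort, "landmark_cohort")) stop("not a landmark_cohort")
  if (format == "csv") {
    rows <- vapply(cohort$subjects, function(s) {
      paste(c(s$subject_id, s$group, s$sex,
              if (is.na(s$age)) "" else format(s$age, digits = 17),
              format(as.vector(t(s$coords)), digits = 17, trim = TRUE,
                     scientific = FALSE)),
            collapse = ",")
    }, character(1))
    writeLines(c(paste(csv_header(cohort$config), collapse = ","), rows), path)
  } else {
    blocks <- unlist(lapply(cohort$subjects, function(s) {
      c(sprintf("LM=%d", nrow(s$coords)),
        apply(s$coords, 1, function(p)
          paste(format(p, digits = 17, trim = TRUE, scientific = FALSE),
                collapse = " ")),
        sprintf("ID=%s", s$subject_id))
    }))
    writeLines(blocks, path)
    if (!is.null(sidecar)) {
      meta <- data.frame(
        subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
        group = cohort_groups(cohort),
        sex = vapply(cohort$subjects, `[[`, character(1), "sex"),
        age = vapply(cohort$subjects, `[[`, numeric(1), "age"))
      utils::write.csv(meta, sidecar, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}
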