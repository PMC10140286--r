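# Fixtures are built in code; no data files.

# deterministic random subject on an arbitrary small configuration
rand_coords <- function(L, seed) {
  set.seed(seed)
  matrix(stats::runif(2 * L, 0, 100), ncol = 2)
}

# tiny cohort of random 18-landmark subjects with metadata variety
tiny_cohort <- function(n = 3, seed = 42, group = "control") {
  cfg <- default_landmark_config()
  subjects <- lapply(seq_len(n), function(i) {
    landmark_set(sprintf("s%02d", i), rand_coords(18, seed + i),
                 group = group,
                 sex = c("M", "F", "unknown")[1 + (i %% 3)],
                 age = if (i == 1) NA_real_ else 20 + i,
                 config = cfg)
  })
  landmark_cohort(subjects, cfg)
}

# lists of landmark_set subjects on an L-landmark configuration (generic ids),
# for small-scale contrasts
small_group <- function(n, L, seed, prefix = "s") {
  lapply(seq_len(n), function(i) {
    xy <- rand_coords(L, seed * 1000 + i)
    rownames(xy) <- paste0("lm", seq_len(L))
    structure(list(subject_id = paste0(prefix, i), group = prefix,
                   sex = "unknown", age = NA_real_, coords = xy),
              class = "landmark_set")
  })
}

# apply a similarity transform (rotation in degrees about the origin, uniform
# scale, translation) to every subject of a cohort
transform_cohort <- function(cohort, angle_deg = 0, scale = 1,
                             translate = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  subjects <- lapply(cohort$subjects, function(s) {
    s$coords <- sweep(s$coords %*% t(R) * scale, 2, translate, `+`)
    s
  })
  landmark_cohort(subjects, cohort$config)
}

# minimal contrast-shaped object for pure-reporting tests
mock_contrast <- function(rel_diff, significant,
                          ci_low = rel_diff - 0.01,
                          ci_high = rel_diff + 0.01,
                          pairs = NULL) {
  K <- length(rel_diff)
  if (is.null(pairs))
    pairs <- cbind(sprintf("a%03d", seq_len(K)), sprintf("b%03d", seq_len(K)))
  structure(list(pairs = pairs,
                 mean_control = rep(1, K), mean_patient = 1 - rel_diff,
                 rel_diff = rel_diff, ci_low = ci_low, ci_high = ci_high,
                 significant = significant,
                 n_controls = 10L, n_patients = 5L, n_distances = K,
                 n_boot = 100L, alpha = 0.1, seed = 1L,
                 statistic = "relative",
                 control_group = "control", patient_group = "patient",
                 mean_shape_control = NULL, config = NULL),
            class = "edma_contrast")
}
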