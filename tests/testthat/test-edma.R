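test_that("centroid size matches closed forms and symmetries", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  xy <- rand_coords(18, 4)
  expect_equal(centroid_size(xy * 3.7), 3.7 * centroid_size(xy))
  expect_equal(centroid_size(sweep(xy, 2, c(-50, 12.3), `+`)),
               centroid_size(xy))
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
  expect_error(centroid_size(matrix(1, 1, 2)), "at least 2")
})

test_that("scaling to unit centroid size is a projection onto shape", {
  cfg <- default_landmark_config()
  lm <- landmark_set("s", rand_coords(18, 8), config = cfg)
  s1 <- scale_to_unit_centroid_size(lm)
  expect_equal(centroid_size(s1$coords), 1)
  expect_equal(s1$centroid_size, centroid_size(lm))
  # idempotent
  expect_identical(scale_to_unit_centroid_size(s1), s1)
  # two inputs differing only by global scale coincide after scaling
  lm2 <- landmark_set("s2", lm$coords * 42, config = cfg)
  expect_equal(scale_to_unit_centroid_size(lm2)$coords, s1$coords)
})

test_that("form matrix lists all unique distances in canonical order", {
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  expect_equal(unname(form_matrix(tri)), c(3, 4, 5))  # (1-2), (1-3), (2-3)
  expect_identical(names(form_matrix(tri)), c("1--2", "1--3", "2--3"))
  # 18 landmarks -> 153 unique measurements
  f <- form_matrix(face_template())
  expect_length(f, 153)
  expect_true(all(f >= 0))
  expect_identical(names(f)[1], "glabella--sellion")
  # rotation invariance
  xy <- rand_coords(18, 5)
  rot90 <- xy %*% matrix(c(0, 1, -1, 0), 2, 2)
  expect_equal(unname(form_matrix(rot90)), unname(form_matrix(xy)),
               tolerance = 1e-12)
  # canonical pair table agrees with form-matrix names
  pairs <- distance_pairs()
  expect_identical(paste0(pairs[, 1], "--", pairs[, 2]),
                   names(form_matrix(face_template())))
})

test_that("mean form and relative differences follow their formulas", {
  expect_equal(mean_form(rbind(c(2, 1), c(4, 3))), c(3, 2))
  expect_equal(mean_form(rbind(c(5, 5))), c(5, 5))
  m <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(mean_form(m), mean_form(m[c(3, 1, 2), ]))
  expect_error(mean_form(m[0, ]), "empty")

  expect_equal(relative_differences(10, 9), 0.1)
  expect_equal(relative_differences(c(2, 3), c(2, 3)), c(0, 0))
  # a 9.7% shorter nasal height in patients reads as D = +0.097
  expect_equal(relative_differences(1, 0.903), 0.097)
  expect_error(relative_differences(c(a = 0), c(a = 1)), "a")
  expect_error(relative_differences(1:2, 1:3), "length")
})

test_that("contrast input validation catches unusable settings", {
  g <- small_group(3, 4, 1)
  expect_error(edma_contrast(g, list()), "nonempty")
  expect_error(edma_contrast(g, g, n_boot = 10, alpha = 0.1),
               "n_boot too small")
  expect_error(edma_contrast(g, g, alpha = 1.2), "alpha")
  coh <- tiny_cohort(3)
  expect_error(edma_contrast(coh), "patient_group")
  expect_error(edma_contrast(coh, patient_group = "DS"), "DS")
})

test_that("self-contrast gives zero differences; constant groups give no hits", {
  g <- small_group(4, 5, 3)
  fit <- edma_contrast(g, g, n_boot = 100, alpha = 0.1, seed = 5)
  expect_true(all(fit$rel_diff == 0))
  # groups with no within-group variation: all bootstrap replicates equal,
  # CI collapses to [0, 0], zero is contained -> nothing significant
  const_c <- rep(small_group(1, 5, 7), 3)
  const_p <- rep(small_group(1, 5, 7), 4)
  fit0 <- edma_contrast(const_c, const_p, n_boot = 100, alpha = 0.1, seed = 2)
  expect_true(all(fit0$rel_diff == 0))
  expect_false(any(fit0$significant))
  expect_true(all(fit0$ci_low == 0 & fit0$ci_high == 0))
})

test_that("vectorized contrast matches the loop-based reference exactly", {
  cases <- list(list(nc = 3, np = 4, L = 4, n_boot = 20, alpha = 0.2,
                     seed = 11),
                list(nc = 4, np = 2, L = 5, n_boot = 20, alpha = 0.1,
                     seed = 23),
                list(nc = 2, np = 2, L = 3, n_boot = 15, alpha = 0.2,
                     seed = 31))
  for (cs in cases) {
    controls <- small_group(cs$nc, cs$L, cs$seed, "c")
    patients <- small_group(cs$np, cs$L, cs$seed + 500, "p")
    fit <- edma_contrast(controls, patients, n_boot = cs$n_boot,
                         alpha = cs$alpha, seed = cs$seed)
    ref <- oracle_edma_contrast(controls, patients, n_boot = cs$n_boot,
                                alpha = cs$alpha, seed = cs$seed)
    expect_equal(unname(fit$rel_diff), ref$rel_diff, tolerance = 1e-12)
    expect_equal(unname(fit$mean_control), ref$mean_control,
                 tolerance = 1e-12)
    expect_equal(unname(fit$ci_low), ref$ci_low, tolerance = 1e-12)
    expect_equal(unname(fit$ci_high), ref$ci_high, tolerance = 1e-12)
    expect_identical(unname(fit$significant), ref$significant)
  }
})

test_that("absolute-difference statistic is available and consistent", {
  controls <- small_group(3, 4, 2, "c")
  patients <- small_group(3, 4, 9, "p")
  fit <- edma_contrast(controls, patients, n_boot = 40, alpha = 0.1,
                       seed = 4, statistic = "absolute")
  expect_equal(unname(fit$rel_diff),
               unname(fit$mean_control - fit$mean_patient))
  ref <- oracle_edma_contrast(controls, patients, 40, 0.1, 4, "absolute")
  expect_equal(unname(fit$ci_low), ref$ci_low, tolerance = 1e-12)
})

test_that("contrast results carry coherent intervals and flags", {
  coh <- generate_cohort(synthetic_spec(12, 8, seed = 5,
                                        effect = preset_effect("ds_like")))
  fit <- edma_contrast(coh, patient_group = "patient", n_boot = 400,
                       seed = 6)
  expect_true(all(fit$ci_low <= fit$ci_high))
  expect_identical(unname(fit$significant),
                   unname(fit$ci_low > 0 | fit$ci_high < 0))
  expect_identical(fit$n_distances, 153L)
  df <- as.data.frame(fit)
  expect_identical(nrow(df), 153L)
  expect_identical(df$pair_a, fit$pairs[, 1])
  expect_equal(unname(coef(fit)), df$rel_diff)
  expect_equal(unname(confint(fit)[, "ci_low"]), df$ci_low)
})

test_that("similarity transforms of all subjects leave the contrast invariant", {
  coh <- generate_cohort(synthetic_spec(10, 6, seed = 13,
                                        effect = preset_effect("ns_like")))
  fit <- edma_contrast(coh, patient_group = "patient", n_boot = 300, seed = 3)
  # numeric agreement is at machine precision; the discrete outcomes are
  # exactly invariant
  moved <- transform_cohort(coh, scale = 2, translate = c(37, -11))
  fit_m <- edma_contrast(moved, patient_group = "patient", n_boot = 300,
                         seed = 3)
  expect_equal(fit_m$rel_diff, fit$rel_diff, tolerance = 1e-12)
  expect_equal(fit_m$ci_low, fit$ci_low, tolerance = 1e-12)
  expect_identical(fit_m$significant, fit$significant)
  # rotation perturbs coordinates at machine precision only
  rot <- transform_cohort(coh, angle_deg = 33)
  fit_r <- edma_contrast(rot, patient_group = "patient", n_boot = 300,
                         seed = 3)
  expect_identical(fit_r$significant, fit$significant)
  expect_equal(fit_r$rel_diff, fit$rel_diff, tolerance = 1e-10)
  expect_equal(fit_r$ci_low, fit$ci_low, tolerance = 1e-10)
})

test_that("bootstrap trimming counts follow the floor(alpha/2 * n_boot) rule", {
  g1 <- small_group(3, 4, 6, "c")
  g2 <- small_group(3, 4, 61, "p")
  # alpha = 0.2, n_boot = 20 -> discard 2 from each tail
  fit <- edma_contrast(g1, g2, n_boot = 20, alpha = 0.2, seed = 9)
  ref <- oracle_edma_contrast(g1, g2, 20, 0.2, 9)
  expect_equal(unname(fit$ci_low), ref$ci_low, tolerance = 1e-12)
  expect_equal(unname(fit$ci_high), ref$ci_high, tolerance = 1e-12)
})

test_that("significance counts grow along an effect-magnitude ray", {
  counts <- vapply(c(0.5, 1, 2, 4), function(sc) {
    coh <- generate_cohort(synthetic_spec(
      30, 10, effect = preset_effect("ds_like", scale = sc), seed = 21))
    sum(edma_contrast(coh, patient_group = "patient", n_boot = 500,
                      seed = 22)$significant)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("contrast TSV serialization round-trips", {
  coh <- generate_cohort(synthetic_spec(8, 5, seed = 3,
                                        effect = preset_effect("ms_like")))
  fit <- edma_contrast(coh, patient_group = "patient", n_boot = 200, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast(fit, path)
  back <- read_contrast(path)
  expect_identical(nrow(back), 153L)
  expect_equal(back$rel_diff, unname(fit$rel_diff))
  expect_identical(back$significant, unname(fit$significant))
})
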