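test_that("top differences filter, split, sort and truncate correctly", {
  # nothing significant -> both lists empty
  t0 <- top_differences(mock_contrast(runif(20, -1, 1), rep(FALSE, 20)))
  expect_identical(nrow(t0$increased_in_patients), 0L)
  expect_identical(nrow(t0$decreased_in_patients), 0L)
  # a single significant reduction appears alone on the decreased side
  rd <- rep(0, 10); rd[4] <- 0.097
  sig <- rep(FALSE, 10); sig[4] <- TRUE
  t1 <- top_differences(mock_contrast(rd, sig))
  expect_identical(nrow(t1$increased_in_patients), 0L)
  expect_identical(nrow(t1$decreased_in_patients), 1L)
  expect_equal(t1$decreased_in_patients$rel_diff, 0.097)
  # 25 significant increases, k = 10 -> top 10 by magnitude, nonincreasing
  rd2 <- -seq(0.01, 0.25, by = 0.01)
  t2 <- top_differences(mock_contrast(rd2, rep(TRUE, 25)), k = 10)
  expect_identical(nrow(t2$increased_in_patients), 10L)
  mags <- abs(t2$increased_in_patients$rel_diff)
  expect_true(all(diff(mags) <= 0))
  expect_equal(max(mags), 0.25)
  # ties break by canonical (input) order
  rd3 <- c(-0.2, -0.2, -0.2)
  t3 <- top_differences(mock_contrast(rd3, rep(TRUE, 3)), k = 2)
  expect_identical(t3$increased_in_patients$pair_a, c("a001", "a002"))
  expect_error(top_differences(mock_contrast(0, TRUE), k = 0), "k")
})

test_that("top_differences is a pure function of the contrast", {
  set.seed(99)
  mc <- mock_contrast(runif(10, -1, 1), rep(c(TRUE, FALSE), 5))
  before <- .Random.seed
  top_differences(mc)
  expect_identical(.Random.seed, before)
})

test_that("wireframe export writes a figure and a faithful JSON sidecar", {
  coh <- generate_cohort(synthetic_spec(10, 6, seed = 4,
                                        effect = preset_effect("ds_like",
                                                               scale = 3)))
  fit <- edma_contrast(coh, patient_group = "patient", n_boot = 300, seed = 2)
  fig <- withr::local_tempfile(fileext = ".png")
  paths <- export_wireframe(fit, fig, k = 5)
  expect_true(file.exists(fig))
  side <- jsonlite::read_json(paste0(fig, ".json"), simplifyVector = FALSE)
  seg <- facedysm:::wireframe_segments(fit, 5)
  expect_length(side$segments, nrow(seg))
  for (i in seq_along(side$segments)) {
    expect_identical(unlist(side$segments[[i]]$pair),
                     c(seg$pair_a[i], seg$pair_b[i]))
    expect_equal(side$segments[[i]]$rel_diff, seg$rel_diff[i])
    expect_identical(side$segments[[i]]$direction, seg$direction[i])
    # tone mapping: positive D (shorter in patients) is the light tone
    expect_identical(side$segments[[i]]$direction,
                     if (seg$rel_diff[i] > 0) "shorter_in_patients"
                     else "longer_in_patients")
  }
  expect_length(side$template, 18)
  # a contrast with nothing significant still renders, with no segments
  fit0 <- mock_contrast(rep(0.01, 5), rep(FALSE, 5))
  fit0$mean_shape_control <- face_template()$coords[1:5, ] /
    centroid_size(face_template()$coords[1:5, ])
  fig0 <- withr::local_tempfile(fileext = ".png")
  export_wireframe(fit0, fig0, k = 3)
  side0 <- jsonlite::read_json(paste0(fig0, ".json"))
  expect_length(side0$segments, 0)
  expect_error(export_wireframe(fit, "x.bmp"), "format")
})

test_that("FDS histogram export writes the figure plus one TSV row per draw", {
  coh <- generate_cohort(synthetic_spec(10, 4, seed = 6))
  sim <- fds_simulation(coh, "patient", m_values = c(0, 2, 4), n_sims = 7,
                        n_boot = 100, seed = 3)
  fig <- withr::local_tempfile(fileext = ".png")
  plot_fds_histograms(sim, fig)
  expect_true(file.exists(fig))
  df <- read.delim(paste0(fig, ".tsv"))
  expect_identical(nrow(df), 21L)  # 3 rounds x 7 sims
  expect_setequal(unique(df$M), c(0, 2, 4))
})

test_that("cli drives the full pipeline deterministically", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "spec.yaml")
  writeLines(c("n_controls: 10", "n_patients: 6", "effect: ds_like",
               "effect_scale: 3", "patient_group: DS"), cfg)
  cohort_csv <- file.path(dir, "cohort.csv")
  expect_identical(cli_main(c("generate", "--config", cfg, "--seed", "5",
                              "--out", cohort_csv)), 0L)
  coh <- read_landmarks(cohort_csv)
  expect_length(coh$subjects, 16)

  # split into group files for the edma subcommand
  ctl_csv <- file.path(dir, "controls.csv")
  pat_csv <- file.path(dir, "patients.csv")
  write_landmarks(landmark_cohort(cohort_subset(coh, "control")), ctl_csv)
  write_landmarks(landmark_cohort(cohort_subset(coh, "DS")), pat_csv)
  out1 <- file.path(dir, "contrast1.tsv")
  out2 <- file.path(dir, "contrast2.tsv")
  expect_identical(cli_main(c("edma", "--controls", ctl_csv, "--patients",
                              pat_csv, "--n-boot", "300", "--seed", "7",
                              "--out", out1)), 0L)
  expect_identical(cli_main(c("edma", "--controls", ctl_csv, "--patients",
                              pat_csv, "--n-boot", "300", "--seed", "7",
                              "--out", out2)), 0L)
  expect_identical(readLines(out1), readLines(out2))  # rerun-identical

  expect_output(expect_identical(
    cli_main(c("fds", "--contrast", out1)), 0L), "fds")

  rep_prefix <- file.path(dir, "rep")
  expect_identical(cli_main(c("report", "--contrast", out1, "--shapes",
                              ctl_csv, "--out", rep_prefix, "--k", "5")), 0L)
  expect_true(file.exists(paste0(rep_prefix, "_wireframe.png")))
  expect_true(file.exists(paste0(rep_prefix, "_top.tsv")))

  simdir <- file.path(dir, "sims")
  expect_identical(cli_main(c("simtest", "--cohort", cohort_csv,
                              "--patient-group", "DS", "--step", "6",
                              "--sims", "3", "--n-boot", "100", "--seed",
                              "2", "--out", simdir)), 0L)
  expect_true(file.exists(file.path(simdir, "simulations.tsv")))
  expect_true(file.exists(file.path(simdir, "summary.json")))
  expect_true(file.exists(file.path(simdir, "histograms.png")))
})

test_that("cli maps detector output and validates landmarks", {
  dir <- withr::local_tempdir()
  set.seed(2)
  xy <- matrix(runif(136, 0, 400), ncol = 2)
  p68 <- file.path(dir, "lm68.csv")
  hdr <- c("subject_id",
           as.vector(rbind(paste0("p", 0:67, "_x"), paste0("p", 0:67, "_y"))))
  writeLines(c(paste(hdr, collapse = ","),
               paste(c("s1", format(as.vector(t(xy)), digits = 12)),
                     collapse = ",")), p68)
  mapped_csv <- file.path(dir, "mapped.csv")
  expect_identical(cli_main(c("map68", "--in", p68, "--out", mapped_csv)), 0L)
  mapped <- read_landmarks(mapped_csv)
  expect_equal(unname(mapped$subjects[[1]]$coords["glabella", ]),
               unname((xy[22, ] + xy[23, ]) / 2), tolerance = 1e-9)

  json_out <- file.path(dir, "rmse.json")
  expect_output(expect_identical(
    cli_main(c("rmse", "--manual", mapped_csv, "--automatic", mapped_csv,
               "--out", json_out)), 0L), "RMSE")
  rep <- jsonlite::read_json(json_out, simplifyVector = TRUE)
  expect_equal(rep$average_rmse, 0)
})

test_that("cli reports usage and input errors with conventional exit codes", {
  expect_identical(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(cli_main(c("edma", "--badflag"))), 2L)
  expect_output(expect_identical(cli_main(character(0)), 2L), "Subcommands")
  msg <- capture.output(
    code <- cli_main(c("edma", "--controls", "/nonexistent/c.csv",
                       "--patients", "/nonexistent/p.csv",
                       "--out", "/tmp/x.tsv")),
    type = "message")
  expect_identical(code, 1L)
  expect_true(any(grepl("/nonexistent/c.csv", msg)))
})
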