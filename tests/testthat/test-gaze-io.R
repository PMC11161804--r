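test_that("look rows map directly onto records and sort by trial and onset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,direction,onset_ms,offset_ms",
    "t02,R,600,900",
    "t01,L,0,500",
    "t02,A,0,550",
    "t01,right,700,900",
    "t02,l,1000,1200",
    "t01,AWAY,500,700"
  ), path)
  looks <- read_looks(path)
  expect_equal(nrow(looks), 6)
  expect_equal(looks$trial_id, c("t01", "t01", "t01", "t02", "t02", "t02"))
  expect_equal(looks$onset_ms, c(0, 500, 700, 0, 600, 1000))
  expect_equal(looks$direction[1], "LEFT")
  expect_equal(looks$direction[2], "AWAY")
  expect_equal(looks$direction[4], "AWAY")

  # reader output is invariant to input row order
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,direction,onset_ms,offset_ms",
    "t01,L,0,500",
    "t01,AWAY,500,700",
    "t01,right,700,900",
    "t02,A,0,550",
    "t02,R,600,900",
    "t02,l,1000,1200"
  ), path2)
  expect_equal(read_looks(path2), looks)
})

test_that("malformed and invalid look files fail with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,direction,onset_ms,offset_ms",
    "t01,L,0,500",
    "t01,R,900,600"
  ), path)
  expect_error(read_looks(path), "3", class = "gazelex_validation_error")

  path_overlap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,direction,onset_ms,offset_ms",
    "t01,L,0,500",
    "t01,R,400,600"
  ), path_overlap)
  expect_error(read_looks(path_overlap), "t01",
               class = "gazelex_validation_error")

  expect_error(read_looks(tempfile()), class = "gazelex_format_error")
  expect_error(read_looks(path, dialect = "datavyu-raw"),
               class = "gazelex_format_error")
  expect_error(normalize_direction("UPWARDS"),
               class = "gazelex_format_error")
})

test_that("a registered dialect can adapt a foreign export format", {
  register_look_dialect("semicolon", function(path) {
    d <- utils::read.csv2(path, stringsAsFactors = FALSE)
    names(d) <- c("trial_id", "direction", "onset_ms", "offset_ms")
    d
  })
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial;dir;on;off", "t01;L;0;500"), path)
  looks <- read_looks(path, dialect = "semicolon")
  expect_equal(looks$direction, "LEFT")
  expect_true("semicolon" %in% look_dialects())
})

test_that("manifest readers enforce the counterbalanced design", {
  specs <- manual_manifest("s01")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(specs, path)
  m <- read_trial_manifest(path)
  expect_equal(nrow(m), 32)
  expect_equal(m$trial_id, specs$trial_id)  # file order preserved

  specs2 <- manual_manifest("s01", experiment = "HONORIFICS")
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(specs2, path2)
  expect_equal(nrow(read_trial_manifest(path2)), 8)

  # dropping one target presentation breaks the design, naming the pair
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(specs[-5, ], path3)
  expect_error(read_trial_manifest(path3), "wp2",
               class = "gazelex_design_error")
})

test_that("session assembly enforces cross-references", {
  specs <- manual_manifest("s01")
  meta <- subject_meta("s01", 10.5)
  looks <- clean_look(specs$trial_id[1])
  session <- assemble_session(meta, specs, looks)
  expect_s3_class(session, "gaze_session")
  expect_equal(nrow(session$trials), 32)  # zero-look trials retained

  orphan <- clean_look("sXX_t99")
  expect_error(assemble_session(meta, specs, orphan), "sXX_t99",
               class = "gazelex_validation_error")

  mixed <- rbind(specs, manual_manifest("s02"))
  expect_error(assemble_session(meta, mixed, looks),
               class = "gazelex_validation_error")

  expect_warning(subject_meta("s99", 30), "plausible")
  expect_error(subject_meta("s99", -1), class = "gazelex_validation_error")
})

test_that("a study round-trips through the canonical dialect field-for-field", {
  sim <- simulate_study(sim_config(n_subjects = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_study(sim$study, dir)
  back <- suppressWarnings(read_study(dir))
  expect_equal(back$subjects, sim$study$subjects)
  expect_equal(back$trials, sim$study$trials)
  expect_equal(
    dplyr::arrange(back$looks, subject_id, trial_id, onset_ms),
    dplyr::arrange(sim$study$looks, subject_id, trial_id, onset_ms)
  )
})
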