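test_that("session CSV round-trips values, sentinels and header order", {
  set.seed(42)
  rec <- tiny_recording(10)
  rec$pupil[4, 1] <- NA            # gap sample survives as a NaN sentinel
  rec$gaze_point[, 1] <- rnorm(10, 0, 0.2)
  path <- tempfile(fileext = ".csv")
  write_session(rec, path)
  expect_identical(strsplit(readLines(path, n = 1), ",")[[1]],
                   session_columns())
  back <- read_session(path, subject_id = "T01", group = "HC")
  expect_equal(n_samples(back), 10)
  expect_true(is.na(back$pupil[4, 1]))
  for (ch in c("gaze_point", "pupil", "openness", "fbs"))
    expect_equal(back[[ch]], rec[[ch]], tolerance = 1e-9)

  # three randomized recordings round-trip within 1e-9
  for (i in 1:3) {
    r <- tiny_recording(25)
    r$fbs[] <- matrix(runif(25 * 6), 25)
    r$pupil[] <- matrix(runif(50, 2, 6), 25)
    p2 <- tempfile(fileext = ".csv")
    write_session(r, p2)
    b2 <- read_session(p2)
    expect_equal(b2$fbs, r$fbs, tolerance = 1e-9)
    expect_equal(b2$pupil, r$pupil, tolerance = 1e-9)
  }
})

test_that("schema and validation errors are specific", {
  rec <- tiny_recording(10)
  path <- tempfile(fileext = ".csv")
  write_session(rec, path)
  df <- read.csv(path)
  df$pl <- NULL
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_session(p2), "pl")

  bad <- tiny_recording(10)
  expect_error(
    session_recording("x", "HC", t = rev(bad$t), task = bad$task,
                      trial = bad$trial, eye_origin_left = bad$eye_origin_left,
                      eye_origin_right = bad$eye_origin_right,
                      gaze_point = bad$gaze_point, pupil = bad$pupil,
                      openness = bad$openness, fbs = bad$fbs),
    "timestamps")
  expect_error(tiny_recording(5, openness = 1.5), "openness")
  expect_error(tiny_recording(5, pupil = -1), "pupil")
})

test_that("facial upsampling is nearest-neighbor with ties to earlier", {
  out <- upsample_facial(matrix(c(1, 2, 3)), target_len = 6)
  expect_equal(drop(out), c(1, 1, 2, 2, 3, 3))
  # constant stream stays constant; value set never grows
  expect_equal(drop(upsample_facial(matrix(0.5, 4, 1), 8)), rep(0.5, 8))
  set.seed(1)
  src <- matrix(runif(30), 5)
  up <- upsample_facial(t(src), 10)
  expect_true(all(up %in% src))
  expect_error(upsample_facial(matrix(numeric(0), 0, 6), 4), "empty")
})

test_that("task segmentation partitions labeled samples with nominal phases", {
  co <- small_cohort()
  rec <- co$sessions[[1]]
  segs <- segment_tasks(rec)
  counts <- table(vapply(segs, `[[`, "", "task"))
  expect_equal(counts[["VSST"]], 1)
  expect_equal(counts[["MCT"]], 2)
  expect_equal(counts[["PRT"]], 2)
  expect_equal(counts[["ST"]], 12)
  expect_equal(counts[["FET"]], 2)
  expect_identical(as.integer(counts[names(co$truth[[1]]$task_trials)]),
                   unname(as.integer(co$truth[[1]]$task_trials)))
  # the union of ranges is exactly the labeled samples, with no overlap
  idx <- unlist(lapply(segs, function(s) s$range[1]:s$range[2]))
  expect_false(any(duplicated(idx)))
  expect_setequal(idx, which(rec$task != "NONE"))
  # nominal phase budget: VSST memorize lasts 3 s at 120 Hz
  v <- segs[[which(vapply(segs, `[[`, "", "task") == "VSST")]]
  mem <- v$phases[v$phases$phase == "memorize", ]
  expect_equal(mem$end - mem$start + 1, 360)

  # a recording with only PRT samples yields one task, two trials
  prt <- tiny_recording(1200, task = "PRT",
                        trial = rep(1:2, each = 600))
  segs2 <- segment_tasks(prt)
  expect_length(segs2, 2)
  expect_true(all(vapply(segs2, `[[`, "", "task") == "PRT"))
  # empty label column
  none <- tiny_recording(20, task = "NONE")
  expect_length(segment_tasks(none), 0)
})

test_that("short trials warn and truncate phases", {
  short <- tiny_recording(120, task = "VSST")  # 1 s, far below 11 s nominal
  expect_warning(segs <- segment_tasks(short), "truncated")
  expect_length(segs, 1)
  expect_lte(max(segs[[1]]$phases$end), 120)
})

test_that("zero-filling facial channels is restricted to eye-tracking tasks", {
  rec <- tiny_recording(20, task = "VSST", fbs = 0.4)
  seg <- segment_tasks(rec)[[1]]
  eye_before <- seg$rec$gaze_point
  z <- zero_fill_facial(seg)
  expect_true(all(z$rec$fbs[z$range[1]:z$range[2], ] == 0))
  expect_identical(z$rec$gaze_point, eye_before)
  # idempotent
  z2 <- zero_fill_facial(z)
  expect_identical(z2$rec$fbs, z$rec$fbs)
  fet <- tiny_recording(20, task = "FET", fbs = 0.4)
  expect_error(zero_fill_facial(segment_tasks(fet)[[1]]), "FET")
})

test_that("covariates round-trip and validate", {
  co <- small_cohort()
  path <- tempfile(fileext = ".csv")
  write_covariates(co$covariates, path)
  back <- read_covariates(path)
  expect_equal(back$moca_total, co$covariates$moca_total)
  bad <- co$covariates
  bad$moca_total[1] <- 31
  p2 <- tempfile(fileext = ".csv")
  write_covariates(bad, p2)
  expect_error(read_covariates(p2), "moca_total")
})
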