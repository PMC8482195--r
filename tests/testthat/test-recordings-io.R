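test_that("read_recording parses valid rows and preserves order and values", {
  p <- write_csv_lines(c("t_s,value", "0,70", "1,70", "2,70"))
  rec <- read_recording(p, "monitor", "HR", nominal_interval_s = 1)
  expect_s3_class(rec, "vital_recording")
  expect_equal(nrow(rec), 3)
  expect_equal(diff(range(rec$t_s)), 2)
  expect_equal(rec$value, c(70, 70, 70))
  expect_equal(attr(rec, "n_dropped"), 0L)
})

test_that("non-numeric and non-finite rows are dropped and counted, not fatal", {
  rows <- sprintf("%d,%g", 0:9, 60 + 0:9)
  rows[2] <- "1,NaN"
  p <- write_csv_lines(c("t_s,value", rows))
  expect_message(
    rec <- read_recording(p, "monitor", "HR", nominal_interval_s = 1),
    "dropped 1"
  )
  expect_equal(nrow(rec), 9)
  expect_equal(attr(rec, "n_dropped"), 1L)
})

test_that("a 4-second patch channel yields 10 samples in any 40-s span", {
  p <- write_csv_lines(c("t_s,value", sprintf("%d,72", seq(0, 36, by = 4))))
  rec <- read_recording(p, "patch", "HR", nominal_interval_s = 4)
  expect_equal(median_in_window(rec, 0, 40)$n, 10L)
})

test_that("structural problems are hard errors", {
  p <- write_csv_lines(c("time,val", "0,70"))
  expect_error(read_recording(p, "d", "HR", nominal_interval_s = 1),
               class = "vitalval_format_error")
  p2 <- write_csv_lines(c("t_s,value", "0,70", "2,71", "1,72"))
  expect_error(read_recording(p2, "d", "HR", nominal_interval_s = 1),
               regexp = "row: 3", class = "vitalval_validation_error")
  expect_error(read_recording(tempfile(), "d", "HR", nominal_interval_s = 1),
               class = "vitalval_format_error")
})

test_that("unit must match variable and interval must be positive", {
  expect_error(recording(0:2, 1:3, "d", "HR", unit = "rpm",
                         nominal_interval_s = 1),
               class = "vitalval_validation_error")
  expect_error(recording(0:2, 1:3, "d", "HR", nominal_interval_s = 0),
               class = "vitalval_validation_error")
})

test_that("recording CSV round trip is exact at 3-decimal precision", {
  set.seed(5)
  t <- round(sort(runif(50, 0, 100)) + 0:49, 3)
  v <- round(rnorm(50, 70, 10), 3)
  rec <- recording(t, v, "patch", "HR", nominal_interval_s = 4)
  p <- tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p, "patch", "HR", nominal_interval_s = 4)
  expect_identical(back$t_s, rec$t_s)
  expect_identical(back$value, rec$value)
})

test_that("annotations parse, sort and validate", {
  p <- write_csv_lines(c("stage_id,phase,start_s,end_s",
                         "sts,movement,120,240"))
  ann <- read_annotations(p)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$end_s - ann$start_s, 120)

  stages <- c("at_rest", "sts", "tapping", "rubbing", "drinking",
              "turning_pages", "tablet")
  rows <- sprintf("%s,movement,%d,%d", stages, (0:6) * 100, (1:7) * 100)
  p2 <- write_csv_lines(c("stage_id,phase,start_s,end_s", rows,
                          "hypoxia,hypoxia,700,1400"))
  ann2 <- read_annotations(p2)
  expect_equal(nrow(ann2), 8)
  expect_equal(sum(ann2$phase == "movement"), 7)
})

test_that("overlapping same-phase intervals and unknown stages are rejected", {
  expect_error(
    stage_annotations(c("tapping", "rubbing"), c("movement", "movement"),
                      c(0, 50), c(100, 150)),
    regexp = "overlap", class = "vitalval_validation_error"
  )
  expect_error(
    stage_annotations("jumping", "movement", 0, 100),
    regexp = "unknown stage", class = "vitalval_validation_error"
  )
  expect_error(
    stage_annotations("sts", "hypoxia", 0, 100),
    class = "vitalval_validation_error"
  )
})

test_that("session assembly enforces completeness and span invariants", {
  s <- constant_session()
  expect_s3_class(s, "vital_session")

  ann_hyp <- stage_annotations(c("at_rest", "hypoxia"),
                               c("movement", "hypoxia"), c(0, 60), c(60, 120))
  expect_error(
    assemble_session("p1", s$recordings, ann_hyp),
    regexp = "ref_SPO2", class = "vitalval_completeness_error"
  )

  expect_error(
    assemble_session("p1", s$recordings[c("test_HR", "ref_HR")],
                     s$annotations),
    class = "vitalval_completeness_error"
  )

  ann_long <- stage_annotations("at_rest", "movement", 0, 500)
  expect_error(assemble_session("p1", s$recordings, ann_long),
               class = "vitalval_validation_error")
})

test_that("session manifest round trip reproduces the session", {
  sim <- simulate_session(zero_error_spec(seed = 3))
  dir <- tempfile("sess")
  write_session(sim$session, dir)
  back <- read_session(file.path(dir, "session.yaml"))
  expect_equal(back$participant_id, sim$session$participant_id)
  expect_equal(names(back$recordings), names(sim$session$recordings))
  for (role in names(back$recordings)) {
    expect_equal(round(back$recordings[[role]]$value, 3),
                 round(sim$session$recordings[[role]]$value, 3))
  }
  expect_equal(nrow(back$annotations), nrow(sim$session$annotations))
})
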