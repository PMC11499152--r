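test_that("write/read round-trips a simulated dataset", {
  ds <- simulate_gaze(sim_config(n_participants = 3,
                                 n_items_per_condition = 2, seed = 2))
  dir <- withr::local_tempdir()
  write_gaze_dataset(ds, dir)
  back <- read_gaze_dataset(dir, quiet = TRUE)
  expect_equal(back$trials, ds$trials, ignore_attr = TRUE)
  expect_equal(back$samples, ds$samples, ignore_attr = TRUE)
  expect_equal(back$participants, ds$participants, ignore_attr = TRUE)
})

test_that("a missing required column raises a schema error naming it", {
  ds <- simulate_gaze(sim_config(n_participants = 2,
                                 n_items_per_condition = 2, seed = 2))
  dir <- withr::local_tempdir()
  write_gaze_dataset(ds, dir)
  tr <- read.csv(file.path(dir, "trials.csv"))
  tr$condition <- NULL
  write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(read_gaze_dataset(dir, quiet = TRUE), "column 'condition'")
})

test_that("a hand-written three-trial fixture parses with correct enums", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "participant_id,trial_id,condition,factual_side,audio_duration_ms",
    "P01,1,positive,left,2600",
    "P01,2,nobody,right,2900",
    "P01,3,filler,,2750"),
    file.path(dir, "trials.csv"))
  writeLines(c(
    "participant_id,trial_id,t,x,y",
    "P01,1,0,100,100",
    "P01,1,50,640,360",
    "P01,2,0,900,300"),
    file.path(dir, "samples.csv"))
  d <- read_gaze_dataset(dir, quiet = TRUE)
  expect_equal(nrow(d$trials), 3L)
  expect_equal(d$trials$condition, c("positive", "nobody", "filler"))
  expect_equal(d$trials$factual_side[1:2], c("left", "right"))
  expect_equal(nrow(d$samples), 3L)
})

test_that("unparseable timestamps are reported with file and line", {
  dir <- withr::local_tempdir()
  writeLines(c("participant_id,trial_id,condition,factual_side",
               "P01,1,positive,left"), file.path(dir, "trials.csv"))
  writeLines(c("participant_id,trial_id,t,x,y",
               "P01,1,0,10,10",
               "P01,1,not-a-time,10,10"), file.path(dir, "samples.csv"))
  expect_error(read_gaze_dataset(dir, quiet = TRUE), "line 3")
})

test_that("column mapping ingests externally-named logs", {
  dir <- withr::local_tempdir()
  writeLines(c("subj,trial,cond,side",
               "P01,1,negative,left"), file.path(dir, "trials.csv"))
  writeLines(c("subj,trial,time_ms,gx,gy",
               "P01,1,4000,200,250"), file.path(dir, "samples.csv"))
  d <- read_gaze_dataset(file.path(dir, "trials.csv"),
                         file.path(dir, "samples.csv"),
                         col_map = c(participant_id = "subj",
                                     trial_id = "trial", condition = "cond",
                                     factual_side = "side", t = "time_ms",
                                     x = "gx", y = "gy"),
                         quiet = TRUE)
  expect_equal(d$samples$t, 4000)
  expect_equal(d$trials$condition, "negative")
})

test_that("audio durations outside the recorded range raise a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("participant_id,trial_id,condition,factual_side,audio_duration_ms",
               "P01,1,positive,left,2000"), file.path(dir, "trials.csv"))
  writeLines(c("participant_id,trial_id,t,x,y", "P01,1,0,1,1"),
             file.path(dir, "samples.csv"))
  expect_warning(read_gaze_dataset(dir, quiet = TRUE), "audio_duration_ms")
})

# ---- role assignment --------------------------------------------------

test_that("role assignment maps centres and background correctly", {
  lay <- aoi_layout()
  tr <- data.frame(participant_id = "P01", trial_id = 1,
                   factual_side = "left")
  centre <- function(r) c(r[1] + r[3] / 2, r[2] + r[4] / 2)
  cl <- centre(lay$left_rect); cr <- centre(lay$right_rect)
  sm <- data.frame(participant_id = "P01", trial_id = 1, t = c(0, 50, 100),
                   x = c(cl[1], cr[1], 0), y = c(cl[2], cr[2], 0))
  out <- assign_roles(sm, tr, lay)
  expect_equal(as.character(out$role), c("factual", "illusory", "elsewhere"))
})

test_that("rectangle membership is half-open on all four edges", {
  lay <- aoi_layout()
  r <- lay$left_rect
  tr <- data.frame(participant_id = "P01", trial_id = 1,
                   factual_side = "left")
  # brute-force oracle for [x0, x0+w) x [y0, y0+h)
  oracle <- function(x, y) {
    x >= r[1] && x < r[1] + r[3] && y >= r[2] && y < r[2] + r[4]
  }
  pts <- rbind(c(r[1], r[2]),                     # top-left corner: inside
               c(r[1] + r[3], r[2] + 10),         # right edge: outside
               c(r[1] + 10, r[2] + r[4]),         # bottom edge: outside
               c(r[1] + r[3] - 1e-9, r[2] + 10),  # just inside right edge
               c(r[1] - 1e-9, r[2] + 10))         # just left of left edge
  sm <- data.frame(participant_id = "P01", trial_id = 1,
                   t = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2])
  got <- assign_roles(sm, tr, lay)$role == "factual"
  want <- apply(pts, 1, function(p) oracle(p[1], p[2]))
  expect_equal(unname(got), unname(want))
})

test_that("mirroring the layout and swapping sides swaps role labels", {
  lay <- aoi_layout()
  mirrored <- aoi_layout(left_rect = lay$right_rect,
                         right_rect = lay$left_rect)
  ds <- small_sim(seed = 14)
  sm <- ds$samples[1:2000, c("participant_id", "trial_id", "t", "x", "y")]
  tr_swapped <- ds$trials
  tr_swapped$factual_side <- ifelse(ds$trials$factual_side == "left",
                                    "right", "left")
  a <- assign_roles(sm, ds$trials, lay)
  # swapping which side is factual relabels factual <-> illusory
  b <- assign_roles(sm, tr_swapped, lay)
  swap <- c(factual = "illusory", illusory = "factual",
            elsewhere = "elsewhere")
  expect_equal(as.character(b$role), unname(swap[as.character(a$role)]))
  expect_equal(nrow(a), nrow(sm))  # sample count conserved
  expect_false(anyNA(a$role))
})

test_that("overlapping rectangles are rejected at layout construction", {
  expect_error(aoi_layout(left_rect = c(100, 100, 300, 300),
                          right_rect = c(250, 150, 300, 300)),
               "overlap")
})
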