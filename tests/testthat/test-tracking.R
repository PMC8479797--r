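test_that("render -> track recovers ground-truth centroids to subpixel accuracy", {
  pr <- short_protocol(1, tau = 2, off_period = 2)
  tr <- simulate_condition("dido1_h3k4me3", n_rollers = 2, protocol = pr,
                           seed = 11, tracking_sd = 0, frame_rate = 2)
  st <- render_image_stack(tr, fov = c(320, 140))
  tk <- track_particles(st)
  meta <- roller_metadata(tk)
  expect_equal(nrow(meta), 2)
  truth <- as.data.frame(tr)
  for (id in meta$roller_id) {
    got <- tk[tk$roller_id == id, ]
    ref <- truth[abs(truth$y_um - got$y_um[1]) < 15, ]
    ref <- ref[match(got$frame, ref$frame), ]
    err <- pmax(abs(ref$x_um - got$x_um), abs(ref$y_um - got$y_um))
    expect_lt(max(err), 0.5)  # < 0.5 px at 1 um/px, every frame
  }
  # diameter from component area is close to the 10 um bead
  expect_true(all(abs(meta$est_diameter_um - 10) < 2))
})

test_that("a uniform stack yields an empty track table", {
  st <- structure(list(frames = list(matrix(0.6, 48, 48)), pixel_size = 1,
                       times = 0), class = "image_stack")
  tk <- track_particles(st)
  expect_identical(nrow(tk), 0L)
})

test_that("two well-separated rollers keep their identities across all windows", {
  pr <- short_protocol(2, tau = 2, off_period = 1)
  tr <- simulate_condition("orc1_h4k20me2", n_rollers = 2, protocol = pr,
                           seed = 21, tracking_sd = 0, frame_rate = 2)
  st <- render_image_stack(tr, fov = c(330, 140))
  tk <- track_particles(st)
  expect_equal(nrow(roller_metadata(tk)), 2)
  # each track's y coordinate never strays from its own lane
  for (id in unique(tk$roller_id)) {
    y <- tk$y_um[tk$roller_id == id]
    expect_lt(max(y) - min(y), 5)
    expect_equal(length(y), length(st$frames))
  }
})

test_that("tracking is translation-equivariant", {
  pr <- short_protocol(0)
  shift <- 7
  base <- generate_trajectories(roller_spec(1, true_rp = 0,
                                            start_position = c(40, 30)),
                                pr, noise_model())
  moved <- generate_trajectories(roller_spec(1, true_rp = 0,
                                             start_position = c(40 + shift,
                                                                30 + shift)),
                                 pr, noise_model())
  c1 <- track_particles(render_image_stack(base, fov = c(96, 96)))
  c2 <- track_particles(render_image_stack(moved, fov = c(96, 96)))
  expect_equal(c2$x_um - c1$x_um, shift, tolerance = 1e-6)
  expect_equal(c2$y_um - c1$y_um, shift, tolerance = 1e-6)
})

test_that("track tables round-trip through CSV and reading validates rows", {
  tr <- simulate_condition("dido1_h3k4me1", n_rollers = 3,
                           protocol = short_protocol(1), seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(length(unique(back$roller_id)), 3)

  df <- utils::read.csv(path)
  dup <- rbind(df, df[5, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(read_tracks(path), "duplicate \\(roller_id, frame\\)")

  df2 <- df
  df2$time_s[3] <- df2$time_s[2]   # non-monotone time
  df2$frame[3] <- df2$frame[2] + 1000L
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_tracks(path), "strictly increasing")
})

test_that("segmentation yields 2 x n_cycles windows with exact durations", {
  pr <- actuation_protocol()  # the standard 18-cycle schedule
  tr <- simulate_condition("uhrf1_sra_ubl", n_rollers = 2, protocol = pr,
                           seed = 41)
  seg <- segment_actuations(tr, pr)
  counts <- table(seg$roller_id)
  expect_true(all(counts == 36))
  expect_true(all(abs(seg$t_end - seg$t_start - 5) < 1e-9))
  expect_identical(unname(rle(seg$direction[seg$roller_id == 1])$lengths),
                   rep(1L, 36))

  expect_identical(nrow(segment_actuations(tr, short_protocol(0))), 0L)
})

test_that("insufficient trajectory duration reports how many windows fit", {
  pr <- short_protocol(3)
  tr <- simulate_condition("orc1_h4", n_rollers = 1, protocol = short_protocol(2),
                           seed = 51)
  expect_error(segment_actuations(tr, pr), "4 of 6 actuation windows fit")
})

test_that("segments never mix field-on and field-off time", {
  pr <- short_protocol(2, tau = 5, off_period = 5)
  seg <- segment_actuations(
    simulate_condition("dido1_h3k4me2", n_rollers = 1, protocol = pr,
                       seed = 61), pr)
  step <- 10
  expect_true(all(abs(seg$t_start %% step) < 1e-9))
  expect_true(all(seg$t_end - seg$t_start <= 5 + 1e-9))
})

test_that("QC excludes dimers by apparent diameter and reports reasons", {
  tr <- simulate_condition("dido1_h3k4me3", n_rollers = 9, n_dimers = 1,
                           protocol = short_protocol(2), seed = 71)
  meta <- roller_metadata(tr)
  expect_equal(sum(meta$is_dimer), 1)
  kept <- qc_exclude(tr)
  expect_equal(nrow(roller_metadata(kept)), 9)
  expect_false(any(roller_metadata(kept)$is_dimer))
  log <- attr(kept, "qc_log")
  expect_equal(log$roller_id, meta$roller_id[meta$is_dimer])
  expect_match(log$reason, "diameter")

  # ground-truth flag agrees with the diameter criterion (oracle)
  expect_setdiff <- setdiff(meta$roller_id[!meta$is_dimer],
                            roller_metadata(kept)$roller_id)
  expect_length(expect_setdiff, 0)
})

test_that("QC is the identity on clean sets and errors when nothing survives", {
  tr <- simulate_condition("orc1_h4k20me1", n_rollers = 4,
                           protocol = short_protocol(1), seed = 81)
  kept <- qc_exclude(tr, diameter_limits = c(5, 15))
  expect_equal(as.data.frame(kept), as.data.frame(tr), ignore_attr = TRUE)
  expect_identical(nrow(attr(kept, "qc_log")), 0L)
  expect_error(qc_exclude(tr, diameter_limits = c(11, 12)),
               "all rollers excluded")
})

test_that("surviving rollers all yield the same number of segments", {
  pr <- short_protocol(3)
  tr <- simulate_condition("ube2d1_ubiquitin", n_rollers = 5, n_dimers = 1,
                           protocol = pr, seed = 91)
  seg <- segment_actuations(qc_exclude(tr), pr)
  expect_equal(unname(unique(table(seg$roller_id))), 6L)
  expect_equal(length(unique(seg$roller_id)), 5)
})
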