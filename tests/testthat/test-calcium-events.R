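# Spatiotemporal calcium event detection and metrics.

test_that("planted transients are detected with the >4 s filter applied", {
  p <- short_ca_preset(n_events = 4L)
  g <- gen_ca_movie(p, seed = 2)
  act <- detect_pixel_transients(g$movie)
  # every planted event's central pixel is active for its full support
  for (e in g$ground_truth$events) {
    px <- e$pixels[1, ]
    run <- act[px[1], px[2], e$onset:(e$onset + e$dur - 1)]
    expect_gte(mean(run), 0.9)
  }
  # a 3-second transient is fully erased
  short_mv <- g$movie
  short_mv$frames[10, 10, 50:52] <- short_mv$frames[10, 10, 50:52] + 200
  act2 <- detect_pixel_transients(short_mv)
  expect_false(any(act2[10, 10, 50:52]))
})

test_that("pure-noise movies stay almost silent at 3 sigma", {
  p <- short_ca_preset(n_events = 0L)
  g <- gen_ca_movie(p, seed = 7)
  act <- detect_pixel_transients(g$movie)
  expect_lt(mean(act), 0.005)
})

test_that("too-short movies are rejected", {
  p <- short_ca_preset(n_frames = 50L, n_events = 0L)
  g <- gen_ca_movie(p, seed = 1)
  expect_error(detect_pixel_transients(g$movie, baseline_window = 121),
               "shorter")
})

test_that("labelling follows 26-connectivity in x-y-t", {
  dm <- c(10L, 10L, 40L)
  mask <- array(FALSE, dm)
  mask[3, 3, 5:12] <- TRUE
  mask[8, 8, 25:33] <- TRUE
  mv <- ca_movie(array(0, dm), pixel_size = 1, frame_interval = 1)
  es <- label_events(mask, mv, min_voxels = 2)
  expect_length(es$events, 2L)
  # one shared diagonal voxel merges two blobs into one event
  mask2 <- array(FALSE, dm)
  mask2[3:4, 3:4, 5:10] <- TRUE
  mask2[5, 5, 11] <- TRUE                 # diagonal in space and time
  mask2[5:6, 5:6, 12:18] <- TRUE
  es2 <- label_events(mask2, mv, min_voxels = 2)
  expect_length(es2$events, 1L)
  # empty mask
  expect_length(label_events(array(FALSE, dm), mv)$events, 0L)
})

test_that("event metrics follow the stated arithmetic", {
  dm <- c(12L, 12L, 30L)
  mask <- array(FALSE, dm)
  mask[5, 5, 10:14] <- TRUE                       # 1 px x 5 frames
  mask[8:10, 2:4, 20:29] <- TRUE                  # 3x3 px x 10 frames
  mv <- ca_movie(array(100, dm), pixel_size = 1, frame_interval = 1)
  ev <- event_metrics(label_events(mask, mv, min_voxels = 2))
  ev <- ev[order(ev$onset_frame), ]
  expect_equal(ev$duration, c(5, 10))
  expect_equal(ev$area, c(1, 9))
  expect_equal(ev$volume, c(5, 90))
  expect_equal(ev$init_y[1], 5)
  # set inequality: area*dt <= volume <= area*duration
  expect_true(all(ev$area * 1 <= ev$volume + 1e-9))
  expect_true(all(ev$volume <= ev$area * ev$duration + 1e-9))
})

test_that("frequency density is plain arithmetic and additive", {
  ev <- data.frame(id = 1:600)
  expect_equal(frequency_density(ev, fov_area = 1e4, record_duration = 600),
               1e-4)
  expect_equal(frequency_density(ev[0, ], 1e4, 600), 0)
  a <- frequency_density(data.frame(id = 1:30), 1e4, 600)
  b <- frequency_density(data.frame(id = 1:20), 1e4, 600)
  expect_equal(a + b, frequency_density(data.frame(id = 1:50), 1e4, 600))
})

test_that("initiation statistics conserve the event count", {
  ev <- data.frame(init_y = c(4, 4, 4, 4, 4), init_x = c(6, 6, 6, 6, 6))
  im <- initiation_statistics(ev, bin = 2)
  expect_equal(sum(im$counts), 5)
  expect_equal(as.integer(names(im$histogram)), 5L)
  ev2 <- data.frame(init_y = seq(2, 42, by = 10), init_x = seq(2, 42, by = 10))
  im2 <- initiation_statistics(ev2, bin = 2)
  expect_equal(unname(as.integer(im2$histogram["1"])), 5L)
  expect_equal(sum(im2$counts), nrow(ev2))
})

test_that("spot reuse is recovered from a reuse_prob = 1 movie", {
  p <- short_ca_preset(n_events = 5L, reuse_prob = 1, n_frames = 400L)
  g <- gen_ca_movie(p, seed = 4)
  ev <- detect_ca_events(g$movie, baseline_window = 121)
  im <- initiation_statistics(ev)
  expect_equal(sum(im$counts), nrow(ev))
  # all planted events share one spot; detection may split none or one
  expect_lte(length(im$counts), 2L)
  expect_gte(max(im$counts), nrow(ev) - 1)
})

test_that("detector recall and duration accuracy hold on planted events", {
  total <- hits <- 0; dur_err <- c()
  for (s in 1:3) {
    g <- gen_ca_movie(ca_movie_preset("adult", n_events = 15L), seed = s)
    ev <- detect_ca_events(g$movie)
    gt <- g$ground_truth$events
    total <- total + length(gt)
    for (e in gt) {
      match <- which(abs(ev$onset_frame - e$onset) <= 2 &
                       abs(ev$init_y - e$spot[1]) <= 3 &
                       abs(ev$init_x - e$spot[2]) <= 3)
      if (length(match)) {
        hits <- hits + 1
        dur_err <- c(dur_err, abs(ev$duration[match[1]] - e$duration_s))
      }
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(median(dur_err), 1)
})
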