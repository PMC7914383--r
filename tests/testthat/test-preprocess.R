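test_that("band-pass suppresses out-of-band components and passes the band", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  rec <- recording(rbind(sin(2 * pi * 50 * t),
                         sin(2 * pi * 10 * t),
                         rep(0, length(t))),
                   c("hum", "alpha", "zero"), fs,
                   data.frame(onset_sample = 1L, condition = "hand"))
  out <- bandpass_filter(rec, 0.3, 30)
  interior <- 2000:3000
  # 50 Hz residual under 5% of input amplitude
  expect_lt(max(abs(out$data["hum", interior])), 0.05)
  # 10 Hz passes nearly unchanged
  expect_equal(max(abs(out$data["alpha", interior])), 1, tolerance = 0.01)
  # zero in, zero out
  expect_true(all(out$data["zero", ] == 0))
  # markers and geometry untouched
  expect_identical(out$events, rec$events)
  expect_identical(dim(out$data), dim(rec$data))
})

test_that("zero-phase filtering does not shift in-band peaks", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  # 12.5 Hz puts a peak exactly on a sample every 40 samples
  x <- sin(2 * pi * 12.5 * t)
  rec <- recording(matrix(x, nrow = 1), "a", fs,
                   data.frame(onset_sample = 1L, condition = "hand"))
  y <- bandpass_filter(rec, 0.3, 30)$data[1, ]
  interior <- 2001:2040  # one full cycle, away from the edges
  expect_equal(which.max(y[interior]), which.max(x[interior]))
})

test_that("band edges outside (0, Nyquist) are rejected", {
  rec <- recording(matrix(0, 1, 100), "a", 100,
                   data.frame(onset_sample = 1L, condition = "hand"))
  expect_error(bandpass_filter(rec, 0, 30), "Nyquist")
  expect_error(bandpass_filter(rec, 0.3, 60), "Nyquist")
  expect_error(bandpass_filter(rec, 30, 0.3), "Nyquist")
})

test_that("re-referencing subtracts the reference mean per sample", {
  dat <- rbind(a = c(5, 5), r1 = c(2, 0), r2 = c(4, 0))
  rec <- recording(dat, c("a", "r1", "r2"), 100,
                   data.frame(onset_sample = 1L, condition = "hand"))
  out <- rereference(rec, c("r1", "r2"))
  # 5 - mean(2, 4) = 2 at the first sample; references zero at the second
  expect_equal(out$data["a", ], c(2, 5), ignore_attr = TRUE)
  # zero references leave the recording unchanged
  expect_equal(out$data[, 2], rec$data[, 2])
  # all channels equal to the reference mean -> all-zero output
  same <- recording(matrix(3, 3, 4), c("a", "r1", "r2"), 100,
                    data.frame(onset_sample = 1L, condition = "hand"))
  expect_true(all(rereference(same, c("r1", "r2"))$data == 0))
  expect_error(rereference(rec, c("r1", "missing")), "missing")
})

test_that("re-referencing is idempotent once references are zeroed, and commutes with filtering", {
  gen <- generate_experiment(tiny_config(seed = 2L))
  refs <- c("A1", "A2")
  r1 <- rereference(gen$recording, refs)
  r2 <- rereference(r1, refs)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
  # both operations are linear and act on disjoint axes
  a <- bandpass_filter(rereference(gen$recording, refs), 0.3, 30)
  b <- rereference(bandpass_filter(gen$recording, 0.3, 30), refs)
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("segmentation extracts decimated half-open windows at the event offset", {
  cfg <- tiny_config(seed = 8L)
  gen <- generate_experiment(cfg)
  ep <- segment_epochs(gen$recording, window_ms = c(400, 900), decimate = 2)
  expect_equal(dim(ep$data$hand), c(6, 21, 25))
  expect_equal(ep$sampling_rate, 50)
  # first retained sample sits at onset + round(0.4 s * fs)
  ev <- gen$recording$events
  i <- which(ev$condition == "hand")[1]
  raw_start <- ev$onset_sample[i] + round(0.4 * 100)
  ch <- match("C3", gen$recording$channel_labels)
  expect_equal(ep$data$hand[1, ch, ],
               gen$recording$data[ch, seq(raw_start, by = 2, length.out = 25)])
  # window overrunning the recording is an error naming the event
  short <- gen$recording
  short$data <- short$data[, 1:(max(ev$onset_sample) + 10)]
  expect_error(segment_epochs(short, window_ms = c(400, 900)), "event")
  # a condition without events yields an empty, flagged stack
  no_none <- gen$recording
  no_none$events <- ev[ev$condition != "none", ]
  expect_warning(ep2 <- segment_epochs(no_none, window_ms = c(400, 900)),
                 "none")
  expect_equal(dim(ep2$data$none)[1], 0L)
  expect_equal(ep2$empty_conditions, "none")
})

test_that("artifact rejection drops exactly the epochs beyond the threshold, strictly", {
  cfg <- tiny_config(noise = noise_spec(sd = 0), seed = 3L)
  gen <- generate_experiment(cfg)
  rec <- gen$recording
  ev <- rec$events
  # place a boundary-valued and an above-threshold frontal sample in two epochs
  fp <- match("Fp1", rec$channel_labels)
  w0 <- round(0.4 * 100)
  rec$data[fp, ev$onset_sample[2] + w0 + 4] <- 50    # exactly at threshold
  rec$data[fp, ev$onset_sample[5] + w0 + 4] <- 51    # strictly beyond
  ep <- segment_epochs(rec, window_ms = c(400, 900), decimate = 2)
  before <- ep$data
  rr <- reject_artifacts(ep, c("Fp2", "FpZ", "Fp1"), threshold = 50)
  expect_equal(rr$report$rejected$event_index, 5L)
  expect_equal(sum(rr$report$n_surviving), 17L)
  # pure selection: surviving epochs are bitwise untouched
  cond5 <- ev$condition[5]
  keep <- ep$provenance[[cond5]] != 5L
  expect_identical(rr$epochs$data[[cond5]],
                   before[[cond5]][keep, , , drop = FALSE])
  for (cond in setdiff(names(before), cond5)) {
    expect_identical(rr$epochs$data[[cond]], before[[cond]])
  }
  expect_error(reject_artifacts(ep, c("Fp1"), threshold = -1), "threshold")
  expect_error(reject_artifacts(ep, c("nope"), 50), "nope")
})

test_that("epoch exclusion removes the listed epochs and flags emptied conditions", {
  gen <- generate_experiment(tiny_config(seed = 4L))
  ep <- segment_epochs(gen$recording, window_ms = c(400, 900))
  expect_identical(exclude_epochs(ep, integer(0)), ep)
  hand_idx <- ep$provenance$hand
  ex <- exclude_epochs(ep, hand_idx[c(1, 6)])
  expect_equal(dim(ex$data$hand)[1], 4L)
  expect_equal(dim(ex$data$ball)[1], 6L)
  all_gone <- exclude_epochs(ep, hand_idx)
  expect_equal(dim(all_gone$data$hand)[1], 0L)
  expect_equal(all_gone$empty_conditions, "hand")
  expect_error(exclude_epochs(ep, 999L), "999")
})
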