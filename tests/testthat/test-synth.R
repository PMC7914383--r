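test_that("all-flat templates with zero noise give an identically zero recording", {
  cfg <- tiny_config(
    templates = list(hand = template_spec("flat"),
                     ball = template_spec("flat"),
                     none = template_spec("flat")),
    noise = noise_spec(sd = 0))
  gen <- generate_experiment(cfg)
  expect_true(all(gen$recording$data == 0))
})

test_that("experiment layout matches the design: markers, epoch length, trial spacing", {
  cfg <- sim_config(seed = 3L)  # study-sized defaults: 500 Hz, 60 x 3 trials
  gen <- generate_experiment(cfg)
  ev <- gen$recording$events
  expect_equal(nrow(ev), 180L)
  expect_equal(unname(table(ev$condition)[c("ball", "hand", "none")]),
               rep(60L, 3), ignore_attr = TRUE)
  # 3 s trial + 1 s gap at 500 Hz
  expect_true(all(diff(ev$onset_sample) == 2000L))
  expect_equal(ncol(gen$recording$data), 180L * 2000L)
  # an epoch spans 1500 samples; the analysis window starts 1250 samples in
  expect_equal(round(cfg$epoch_length_ms / 1000 * cfg$sampling_rate), 1500)
  expect_equal(round(cfg$event_time_ms / 1000 * cfg$sampling_rate), 1250)
})

test_that("generation is deterministic given config and seed", {
  g1 <- generate_experiment(tiny_config(seed = 11L))
  g2 <- generate_experiment(tiny_config(seed = 11L))
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$recording$events, g2$recording$events)
  g3 <- generate_experiment(tiny_config(seed = 12L))
  expect_false(identical(g1$recording$data, g3$recording$data))
})

test_that("noiseless averages recover template x gain exactly", {
  cfg <- tiny_config(noise = noise_spec(sd = 0))
  gen <- generate_experiment(cfg)
  ep <- segment_epochs(gen$recording, window_ms = c(400, 900), decimate = 2)
  avg <- average_conditions(ep, cfg$montage$sets$sensorimotor_left$channels,
                            set_name = "sensorimotor_left")
  for (cond in c("hand", "ball", "none")) {
    expected <- decimated_template(cfg$templates[[cond]])
    for (el in cfg$montage$sets$sensorimotor_left$channels) {
      row <- which(avg$meta$electrode == el & avg$meta$condition == cond)
      expect_equal(avg$waveforms[row, ], expected, tolerance = 1e-12)
    }
  }
  # temporal control channels have zero gain: all averages flat
  avg_t <- average_conditions(ep, cfg$montage$sets$temporal_left$channels,
                              set_name = "temporal_left")
  expect_true(all(avg_t$waveforms == 0))
})

test_that("template contrast grows monotonically with amplitude difference", {
  d <- vapply(c(2, 5, 10, 20), function(A) {
    ramp <- eval_template(template_spec("negative_ramp", amplitude = A), 500)
    flat <- eval_template(template_spec("flat"), 500)
    sqrt(sum((ramp - flat)^2))
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("null experiments have no true condition differences", {
  gen <- generate_null_experiment(tiny_config(seed = 5L))
  expect_true(all(!gen$ground_truth$differs$differ))
  # with zero noise, the 12 averaged waveforms are identical and clustering
  # degenerates to a single label
  cfg0 <- tiny_config(noise = noise_spec(sd = 0), seed = 5L)
  gen0 <- generate_null_experiment(cfg0)
  ep <- segment_epochs(gen0$recording, window_ms = c(400, 900))
  avg <- average_conditions(ep, cfg0$montage$sets$sensorimotor_left$channels)
  expect_equal(max(avg$waveforms) - min(avg$waveforms), 0)
  sol <- cluster_waveforms(avg, seed = 1L)
  expect_true(sol$degenerate)
  expect_equal(length(unique(as.character(sol$assignments))), 1L)
  expect_equal(sol$inertia, 0)
})

test_that("ground truth reflects per-set template overrides", {
  cfg <- tiny_config(template_overrides = list(
    sensorimotor_left = list(ball = template_spec("flat"))))
  gt <- generate_experiment(cfg)$ground_truth$differs
  left <- gt[gt$set == "sensorimotor_left", ]
  expect_false(left$differ[left$cond_a == "ball" & left$cond_b == "none"])
  expect_true(left$differ[left$cond_a == "hand" & left$cond_b == "none"])
  right <- gt[gt$set == "sensorimotor_right", ]
  expect_true(all(right$differ))
  expect_true(all(!gt$differ[grepl("temporal", gt$set)]))
})

test_that("artifact injection is seeded, bounded, and detected exactly by rejection", {
  cfg <- tiny_config(seed = 21L)
  gen <- generate_experiment(cfg)
  # rate 0: unchanged
  un <- inject_artifacts(gen$recording, rate = 0, amplitude = 120,
                         channels = "Fp2", seed = 1L)
  expect_identical(un$recording$data, gen$recording$data)
  expect_length(un$injected_epochs, 0L)
  # unknown channel errors
  expect_error(inject_artifacts(gen$recording, 0.5, 120, "nope"), "unknown")
  # seeded injection: rejection recovers exactly the injected set
  inj <- inject_artifacts(gen$recording, rate = 0.3, amplitude = 120,
                          channels = cfg$montage$frontal_channels,
                          seed = 9L,
                          window_offset = round(0.4 * 100),
                          window_length = round(0.5 * 100))
  inj2 <- inject_artifacts(gen$recording, rate = 0.3, amplitude = 120,
                           channels = cfg$montage$frontal_channels,
                           seed = 9L,
                           window_offset = round(0.4 * 100),
                           window_length = round(0.5 * 100))
  expect_identical(inj$injected_epochs, inj2$injected_epochs)
  expect_gt(length(inj$injected_epochs), 0L)
  ep <- segment_epochs(inj$recording, window_ms = c(400, 900))
  rr <- reject_artifacts(ep, cfg$montage$frontal_channels, threshold = 50)
  expect_setequal(rr$report$rejected$event_index, inj$injected_epochs)
  # rate 1 with amplitude above threshold: every epoch rejected
  all_in <- inject_artifacts(gen$recording, rate = 1, amplitude = 100,
                             channels = "FpZ", seed = 2L,
                             window_offset = 40, window_length = 50)
  ep_all <- segment_epochs(all_in$recording, window_ms = c(400, 900))
  rr_all <- reject_artifacts(ep_all, cfg$montage$frontal_channels, 50)
  expect_equal(unname(rr_all$report$n_surviving),
               rep(0L, 3), ignore_attr = TRUE)
})

test_that("noise models honor the requested marginal scale", {
  for (model in c("white", "ar1", "one_over_f")) {
    x <- withr::with_seed(4L, erpsig:::.gen_noise(model, 50000, 10, 0.9))
    expect_equal(stats::sd(x), 10, tolerance = 0.15)
  }
  expect_identical(erpsig:::.gen_noise("ar1", 100, 0, 0.9), numeric(100))
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(noise_spec(sd = -1), "sd")
  expect_error(noise_spec(ar_coefficient = 1.2), "ar_coefficient")
  expect_error(noise_spec(artifact_rate = 2), "artifact_rate")
  expect_error(tiny_config(event_time_ms = 800), "event_time_ms")
  expect_error(sim_config(n_epochs_per_condition = 0),
               "n_epochs_per_condition")
  expect_error(template_spec("negative_ramp", amplitude = -3), "amplitude")
})
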