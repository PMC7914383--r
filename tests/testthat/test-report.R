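test_that("hemisphere mapping follows the anatomy convention and is symmetric", {
  expect_equal(map_hemisphere("left", "right"), "contralateral")
  expect_equal(map_hemisphere("right", "right"), "ipsilateral")
  expect_equal(map_hemisphere("right", "left"), "contralateral")
  expect_equal(map_hemisphere("left", "left"), "ipsilateral")
  # involution: swapping both sides leaves the relation unchanged
  for (h in c("left", "right")) for (v in c("left", "right")) {
    flip <- function(x) ifelse(x == "left", "right", "left")
    expect_equal(map_hemisphere(h, v), map_hemisphere(flip(h), flip(v)))
  }
  expect_error(map_hemisphere("upper", "right"), "left")
})

test_that("a high-contrast subject yields sensorimotor but not temporal rejections", {
  cfg <- tiny_config(noise = noise_spec(sd = 1), seed = 31L)
  gen <- generate_experiment(cfg)
  res <- run_subject(gen$recording, params = tiny_params(), seed = 5L,
                     viewed_hand = "right", handedness = "right")
  cmp <- res$comparisons
  expect_true(all(cmp$rejected[cmp$region == "sensorimotor"]))
  expect_true(all(!cmp$rejected[cmp$region == "temporal"]))
  expect_equal(res$hand_block, "dominant")
  expect_equal(unique(cmp$rel_hemisphere[cmp$hemisphere == "left"]),
               "contralateral")
  # agreement with the generator's ground truth
  gt <- gen$ground_truth$differs
  key <- function(d) paste(d$set,
                           pmin(d$cond_a, d$cond_b),
                           pmax(d$cond_a, d$cond_b))
  m <- match(key(data.frame(set = cmp$set, cond_a = cmp$cond_a,
                            cond_b = cmp$cond_b)), key(gt))
  expect_identical(unname(cmp$rejected), gt$differ[m])
})

test_that("the pipeline is deterministic given seed and config", {
  gen <- generate_experiment(tiny_config(seed = 17L))
  r1 <- run_subject(gen$recording, params = tiny_params(), seed = 4L)
  r2 <- run_subject(gen$recording, params = tiny_params(), seed = 4L)
  expect_identical(r1$comparisons, r2$comparisons)
  expect_identical(lapply(r1$solutions, `[[`, "assignments"),
                   lapply(r2$solutions, `[[`, "assignments"))
})

test_that("a subject losing every epoch of a condition is marked unanalyzable, not fatal", {
  gen <- generate_experiment(tiny_config(seed = 19L))
  hand_events <- which(gen$recording$events$condition == "hand")
  res <- run_subject(gen$recording, params = tiny_params(), seed = 2L,
                     exclude = hand_events)
  expect_true(all(!res$comparisons$analyzable))
  expect_true(all(is.na(res$comparisons$rejected)))
})

test_that("group summaries are exact bookkeeping over subject flags", {
  r1 <- make_subject_result("s1", c(TRUE, TRUE, FALSE))
  r2 <- make_subject_result("s2", c(TRUE, FALSE, FALSE))
  r3 <- make_subject_result("s3", c(FALSE, FALSE, FALSE))
  sm <- summarize_group(list(r1, r2, r3))
  expect_equal(sm$n_subjects, rep(3L, 3))
  got <- sm$n_reject[match(c("hand x ball", "hand x none", "ball x none"),
                           sm$pair)]
  expect_equal(got, c(2L, 1L, 0L))
  # order invariance
  sm_rev <- summarize_group(list(r3, r2, r1))
  expect_equal(sm[order(sm$pair), ]$n_reject,
               sm_rev[order(sm_rev$pair), ]$n_reject)
  # all-reject and none-reject extremes
  all_r <- summarize_group(list(make_subject_result("a", rep(TRUE, 3)),
                                make_subject_result("b", rep(TRUE, 3))))
  expect_true(all(all_r$n_reject == 2L))
  none_r <- summarize_group(list(make_subject_result("a", rep(FALSE, 3))))
  expect_true(all(none_r$n_reject == 0L))
})

test_that("rejection tables pivot pairs against hand block and hemisphere", {
  res <- list(make_subject_result("s1", rep(TRUE, 6),
                                  hemisphere = c("left", "right")),
              make_subject_result("s2", c(TRUE, FALSE, TRUE),
                                  hemisphere = c("left", "right")))
  sm <- summarize_group(res)
  tab <- rejection_table(sm, region = "sensorimotor")
  expect_equal(nrow(tab), 3L)
  expect_true("pair" %in% names(tab))
  expect_error(rejection_table(sm, region = "occipital"), "occipital")
})

test_that("per-subject BH family pools all sets of the subject", {
  gen <- generate_experiment(tiny_config(noise = noise_spec(sd = 1),
                                         seed = 23L))
  per_set <- run_subject(gen$recording, params = tiny_params(), seed = 3L)
  pooled <- run_subject(gen$recording,
                        params = tiny_params(bh_family = "per_subject"),
                        seed = 3L)
  expect_identical(per_set$comparisons$p, pooled$comparisons$p)
  ok <- !is.na(pooled$comparisons$p)
  expect_equal(pooled$comparisons$p_adjusted[ok],
               bh_adjust_oracle(pooled$comparisons$p[ok]), tolerance = 1e-12)
})
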