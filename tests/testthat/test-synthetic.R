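test_that("cohort generation is deterministic in the seed", {
  c1 <- generate_cohort(protocol_config(n_subjects = 2, seed = 11))
  c2 <- generate_cohort(protocol_config(n_subjects = 2, seed = 11))
  c3 <- generate_cohort(protocol_config(n_subjects = 2, seed = 12))
  expect_identical(c1$recordings[[1]]$channels, c2$recordings[[1]]$channels)
  expect_identical(c1$annotations[[2]], c2$annotations[[2]])
  expect_false(identical(c1$recordings[[1]]$channels,
                         c3$recordings[[1]]$channels))
})

test_that("annotations are valid half-open, non-overlapping and in range", {
  coh <- cached_cohort(3, seed = 4)
  for (s in 1:3) {
    ann <- coh$annotations[[s]]
    rec <- coh$recordings[[s]]
    expect_true(all(ann$end > ann$start))
    expect_true(all(ann$start >= 0))
    expect_true(all(ann$end <= rec$n_samples))
    if (nrow(ann) > 1) {
      expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
    }
    expect_true(all(ann$label %in% c(activity_classes(), "DISTRACTOR")))
    acts <- ann$label[ann$label != "DISTRACTOR"]
    expect_equal(sort(unique(acts)), sort(activity_classes()))
    expect_true(all(table(acts) == coh$config$repetitions_per_activity))
  }
})

test_that("default protocol yields 336 activity segments, 56 per class", {
  # structural count only; build annotations without signal synthesis cost
  coh <- cached_cohort(6, seed = 1)
  per_subject <- 2L * 6L
  expect_equal(
    sum(sapply(coh$annotations, function(a) sum(a$label != "DISTRACTOR"))),
    6L * per_subject)
  expect_equal(protocol_config()$n_subjects * per_subject, 336L)
  expect_equal(protocol_config()$n_subjects *
                 protocol_config()$repetitions_per_activity, 56L)
})

test_that("impairment slows and attenuates the simulated movement", {
  set.seed(99)
  healthy <- subject_profile("H", capacity = 0,
                             duration_jitter_sd = 0, amplitude_jitter_sd = 0)
  set.seed(99)
  impaired <- subject_profile("I", capacity = 8,
                              duration_jitter_sd = 0, amplitude_jitter_sd = 0)
  expect_true(all(impaired$duration_multiplier >
                    healthy$duration_multiplier))
  expect_true(all(impaired$amplitude_multiplier <
                    healthy$amplitude_multiplier))
  # and the recordings reflect it: mean annotated duration grows
  cfg <- protocol_config(n_subjects = 1, seed = 1)
  set.seed(5); rh <- generate_recording(healthy, cfg)
  set.seed(5); ri <- generate_recording(impaired, cfg)
  dh <- with(rh$annotation[rh$annotation$label != "DISTRACTOR", ],
             mean(end - start))
  di <- with(ri$annotation[ri$annotation$label != "DISTRACTOR", ],
             mean(end - start))
  expect_gt(di, dh)
})

test_that("bursts sit on posture-consistent gravity baselines", {
  coh <- cached_cohort(2, seed = 21)
  rec <- coh$recordings[[1]]
  ann <- coh$annotations[[1]]
  # static region before the first burst: low variance, norm near 1 g
  pre <- rec$channels[1:min(64, ann$start[1]), , drop = FALSE]
  expect_lt(stats::sd(pre[, 1]), 0.05)
  norms <- sqrt(rowSums(pre^2))
  expect_true(all(abs(norms - 1) < 0.2))
  # dynamic region exceeds both segmentation thresholds on channel 1
  b <- ann[ann$label != "DISTRACTOR", ][1, ]
  burst <- rec$channels[(b$start + 1):b$end, 1]
  expect_gt(stats::sd(burst), 0.05)
  expect_gt(diff(range(burst)), 0.20)
})

test_that("capacity scores follow the configured range and mean", {
  coh <- cached_cohort(60, seed = 31)
  caps <- sapply(coh$profiles, function(p) p$capacity)
  expect_true(all(caps >= 0 & caps <= 8.1))
  expect_lt(abs(mean(caps) - 3.14), 0.8)
  # both assessment classes occur at the BASFI threshold of 3
  expect_true(any(caps >= 3) && any(caps < 3))
})

test_that("protocol_config validates inputs", {
  expect_error(protocol_config(n_subjects = 0), "n_subjects")
  expect_error(protocol_config(sample_rate = -1), "sample_rate")
  expect_error(protocol_config(static_gap_duration = c(5, 3)), "increasing")
  expect_error(protocol_config(activities = c("getup")), "activities")
})
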