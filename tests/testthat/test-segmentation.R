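fs <- 32

test_that("rough segmentation requires both std and range thresholds", {
  cfg <- segmenter_config()
  n <- 10 * fs
  flat <- rep(0.5, n)
  # pure flat signal: neither criterion met
  expect_equal(nrow(rough_segment(flat, cfg, fs)), 0)
  # slow drift: large range per window possible but sub-threshold std/range
  # per 1 s window; choose a burst exceeding range but not std? A square
  # wave of +-0.15 g has std 0.15 and range 0.3: both exceeded. Use a
  # single short spike: range 0.3 g but window std below 0.05.
  # single-sample spike: window range 0.22 g exceeds the 0.20 threshold
  # but the window standard deviation stays below 0.05 g
  spike <- flat
  spike[5 * fs] <- 0.5 + 0.22
  expect_equal(nrow(rough_segment(spike, cfg, fs)), 0)
  # moderate-variance noise above std but below range threshold
  set.seed(1)
  hum <- 0.5 + 0.06 * sin(2 * pi * (1:n) / 8)  # std 0.042, range 0.12
  expect_equal(nrow(rough_segment(hum, cfg, fs)), 0)
  # genuine burst exceeds both
  burst <- flat
  burst[(4 * fs):(6 * fs)] <- 0.5 + 0.4 * sin(2 * pi * (0:(2 * fs)) / fs)
  seg <- rough_segment(burst, cfg, fs)
  expect_equal(nrow(seg), 1)
  expect_lte(seg$start[1], 4 * fs)
  expect_gte(seg$end[1], 6 * fs)
})

# Deterministic fixture: the "static" floor is a tiny square wave (every
# half-second window has the identical variance), the burst is a 0.4 g
# sine over [4 s, 6 s). Variance ratios at every candidate boundary are
# therefore exact, not sampled.
square_floor_burst <- function(n = 12 * fs, from = 4 * fs, to = 6 * fs) {
  x <- 0.9 + 0.01 * rep_len(c(1, -1), n)
  idx <- from:(to - 1)
  x[idx + 1] <- x[idx + 1] + 0.4 * sin(2 * pi * seq_along(idx) / fs)
  x
}

test_that("static region with homogeneous variance keeps its boundaries", {
  cfg <- segmenter_config()
  x <- square_floor_burst()
  # dynamic region already at the true burst edges: the extension window
  # reaches into the burst (variance way above baseline) and the shrink
  # window has exactly the baseline variance, so neither criterion fires
  dyn <- data.frame(start = 4L * fs, end = 6L * fs)
  refined <- refine_static_boundaries(dyn, x, cfg, fs)
  expect_equal(refined$start, dyn$start)
  expect_equal(refined$end, dyn$end)
})

test_that("boundary refinement reclaims quiet samples from a dynamic region", {
  cfg <- segmenter_config()
  x <- square_floor_burst()
  det <- rough_segment(x, cfg, fs)
  expect_equal(nrow(det), 1)
  # rough windows (1 s, 50% overlap) bleed past the true edges
  expect_lt(det$start[1], 4 * fs)
  expect_gt(det$end[1], 6 * fs)
  ref <- refine_static_boundaries(det, x, cfg, fs)
  expect_equal(nrow(ref), 1)
  # refinement walks the boundaries back to the burst edges
  expect_equal(ref$start[1], 4L * fs)
  expect_equal(ref$end[1], 6L * fs)
})

test_that("channel merging joins near gaps with similar means and drops short segments", {
  cfg <- segmenter_config()
  n <- 20 * fs
  ch <- matrix(0.9, n, 2)
  rec <- actcap:::new_recording("T", fs, ch)
  # two dynamic regions 0.25 s apart, similar means -> joined
  a <- data.frame(start = c(2L * fs, as.integer(3.25 * fs)),
                  end = c(3L * fs, as.integer(4.5 * fs)))
  b <- data.frame(start = integer(0), end = integer(0))
  m <- merge_and_filter(a, b, rec, cfg)
  expect_equal(nrow(m), 1)
  expect_equal(m$start[1], 2L * fs)
  expect_equal(m$end[1], as.integer(4.5 * fs))
  # dissimilar means across the gap -> not joined; and the 0.75 s fragment
  # is dropped by the 1 s minimum-length filter
  ch2 <- ch
  ch2[(2 * fs + 1):(3 * fs), 1] <- 0.2   # first region mean far from second
  rec2 <- actcap:::new_recording("T2", fs, ch2)
  a2 <- data.frame(start = c(2L * fs, as.integer(3.25 * fs)),
                   end = c(3L * fs, 4L * fs))
  m2 <- merge_and_filter(a2, b, rec2, cfg)
  expect_equal(nrow(m2), 1)   # only the 1 s first region survives
  expect_equal(m2$start[1], 2L * fs)
  # union across channels
  u <- merge_and_filter(data.frame(start = 2L * fs, end = 4L * fs),
                        data.frame(start = 3L * fs, end = 5L * fs), rec, cfg)
  expect_equal(u, data.frame(start = 2L * fs, end = 5L * fs))
})

test_that("detector recovers the annotated bursts of a synthetic recording", {
  coh <- cached_cohort(3, seed = 4)
  for (s in 1:3) {
    det <- detect_dynamic_regions(coh$recordings[[s]])
    gt <- coh$annotations[[s]]
    gt <- gt[gt$label != "DISTRACTOR", ]
    rep <- detection_report(gt, det)
    expect_gte(rep$dtpr, 0.9)
    expect_gte(rep$sdc_mean, 0.8)
  }
})

test_that("segmentation handles degenerate inputs", {
  cfg <- segmenter_config()
  expect_warning(rough_segment(rep(0.5, 10), cfg, fs), "short")
  rec <- actcap:::new_recording("Z", fs, matrix(0.9, 5 * fs, 2))
  expect_no_warning(det <- detect_dynamic_regions(rec, cfg))
  expect_equal(nrow(det), 0)
})
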