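# minimal hemo_series constructor for epoching tests
make_hemo <- function(n = 400, rate = 10, n_ch = 2, events = NULL, t0 = 0,
                      fill = function(t, j) sin(t) + j) {
  time <- t0 + (seq_len(n) - 1L) / rate
  ids <- paste0("C", seq_len(n_ch))
  hbo <- sapply(seq_len(n_ch), function(j) fill(time, j))
  hbr <- -0.3 * hbo
  colnames(hbo) <- colnames(hbr) <- ids
  montage <- default_montage()
  montage$channels <- data.frame(
    id = ids, source_id = "S1", detector_id = "D1",
    distance_mm = 30, roi = "MFG", kind = "long", stringsAsFactors = FALSE
  )
  montage$sources <- "S1"
  montage$detectors <- "D1"
  structure(
    list(
      time = time, hbo = hbo, hbr = hbr,
      events = events, montage = montage, sampling_rate = rate
    ),
    class = "hemo_series"
  )
}

test_that("epochs are 8 s windows starting 2 s after their marker", {
  ev <- data.frame(onset = c(10, 22), duration = c(8, 8), label = c("relax", "nback"))
  h <- make_hemo(events = ev, fill = function(t, j) t) # trace equals time
  es <- epoch_series(h)
  expect_equal(dim(es$data), c(2L, 80L, 2L, 2L))
  # marker at 10 s -> window [12, 20): first sample value 12, last 19.9
  expect_equal(es$data[1, 1, 1, "hbo"], 12)
  expect_equal(es$data[1, 80, 1, "hbo"], 19.9)
  expect_equal(es$onsets, c(12, 24))
  expect_equal(es$labels, c("relax", "nback"))
})

test_that("markers whose window exceeds the record are dropped, not truncated", {
  ev <- data.frame(
    onset = c(5, 35), duration = c(8, 8),
    label = c("relax", "nback")
  ) # record is 40 s; 35 + 2 + 8 = 45 > 40
  h <- make_hemo(events = ev)
  expect_warning(es <- epoch_series(h), "dropped 1")
  expect_equal(dim(es$data)[1], 1L)
  expect_equal(es$n_dropped, 1L)
  ev_all_out <- data.frame(onset = 39, duration = 8, label = "relax")
  expect_error(epoch_series(make_hemo(events = ev_all_out)), "no usable markers")
  expect_error(epoch_series(make_hemo(events = NULL)), "no event markers")
})

test_that("epoching is translation-equivariant", {
  ev <- data.frame(onset = c(4, 16), duration = c(8, 8), label = c("relax", "nback"))
  f <- function(t, j) sin(0.7 * t) + 0.1 * j
  h <- make_hemo(events = ev, fill = f)
  shift <- 7.3
  ev_s <- transform(ev, onset = onset + shift)
  f_s <- function(t, j) f(t - shift, j) # the shifted copy of the signal
  h_s <- make_hemo(events = ev_s, t0 = shift, fill = f_s)
  e1 <- epoch_series(h)
  e2 <- epoch_series(h_s)
  expect_equal(e2$data, e1$data, tolerance = 1e-12)
})

test_that("low-pass filter keeps DC, passes 0.1 Hz, and crushes 2 Hz", {
  rate <- 10
  t <- (0:2999) / rate
  ev <- data.frame(onset = 10, duration = 8, label = "relax")
  # constant trace is unchanged (DC gain 1)
  h_const <- make_hemo(n = 3000, events = ev, fill = function(t, j) 3.7 + 0 * t)
  expect_equal(lowpass(h_const)$hbo, h_const$hbo, tolerance = 1e-5)

  measure_gain <- function(freq) {
    h <- make_hemo(n = 3000, events = ev, fill = function(t, j) sin(2 * pi * freq * t))
    y <- lowpass(h)$hbo[, 1]
    mid <- t > 50 & t < 250
    fit <- stats::lm(y[mid] ~ sin(2 * pi * freq * t[mid]) + cos(2 * pi * freq * t[mid]) - 1)
    sqrt(sum(stats::coef(fit)^2))
  }
  # 0.1 Hz retained within 1%
  expect_equal(measure_gain(0.1), 1, tolerance = 0.01)
  # 2 Hz attenuated by far more than the factor-100 single-pass guarantee
  expect_lt(measure_gain(2), 1 / 100)
})

test_that("filtering is linear and channel-independent", {
  ev <- data.frame(onset = 10, duration = 8, label = "relax")
  h1 <- make_hemo(events = ev, fill = function(t, j) sin(0.5 * t) * j)
  h2 <- make_hemo(events = ev, fill = function(t, j) cos(1.1 * t) + 0.2 * j)
  a <- 2.5
  b <- -0.8
  hmix <- h1
  hmix$hbo <- a * h1$hbo + b * h2$hbo
  hmix$hbr <- a * h1$hbr + b * h2$hbr
  f1 <- lowpass(h1)
  f2 <- lowpass(h2)
  fmix <- lowpass(hmix)
  expect_equal(fmix$hbo, a * f1$hbo + b * f2$hbo, tolerance = 1e-9)
  # channel independence: filtering one channel's trace alone gives the
  # same result as filtering the full matrix
  solo <- make_hemo(events = ev, n_ch = 1, fill = function(t, j) sin(0.5 * t) * 1)
  expect_equal(unname(lowpass(solo)$hbo[, 1]), unname(f1$hbo[, 1]), tolerance = 1e-12)
})

test_that("empirical transfer function matches the zero-phase Butterworth response", {
  rate <- 10
  t <- (0:2999) / rate
  ev <- data.frame(onset = 10, duration = 8, label = "relax")
  freqs <- c(0.05, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0, 1.5, 2.0)
  for (f in freqs) {
    h <- make_hemo(n = 3000, events = ev, fill = function(t, j) sin(2 * pi * f * t))
    y <- lowpass(h)$hbo[, 1]
    mid <- t > 50 & t < 250
    fit <- stats::lm(y[mid] ~ sin(2 * pi * f * t[mid]) + cos(2 * pi * f * t[mid]) - 1)
    gain <- sqrt(sum(stats::coef(fit)^2))
    # gains lie in [0, 1]; compare on that scale (2% of full range) so the
    # deep-stopband values are not judged on meaningless relative error
    expect_lt(abs(gain - butterworth_gain(f, 6, 0.6, passes = 2)), 0.02)
  }
})

test_that("cutoff at or above Nyquist is rejected; epoch-stage filtering works", {
  ev <- data.frame(onset = c(4, 16), duration = c(8, 8), label = c("relax", "nback"))
  h <- make_hemo(events = ev)
  expect_error(lowpass(h, cutoff = 5), "Nyquist")
  es <- epoch_series(h)
  esf <- lowpass(es)
  expect_equal(dim(esf$data), dim(es$data))
  expect_false(identical(esf$data, es$data))
})

test_that("epoch sets round-trip through the long-format TSV", {
  ev <- data.frame(onset = c(4, 16), duration = c(8, 8), label = c("relax", "nback"))
  es <- epoch_series(make_hemo(events = ev))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_epochs(es, path)
  es2 <- read_epochs(path)
  expect_equal(es2$data, es$data, tolerance = 1e-12)
  expect_equal(es2$labels, es$labels)
  expect_equal(es2$sampling_rate, es$sampling_rate, tolerance = 1e-9)
  # features computed from the round-tripped set are identical
  expect_equal(extract_features(es2)$x, extract_features(es)$x, tolerance = 1e-12)
})
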