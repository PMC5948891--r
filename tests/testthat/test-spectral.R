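fs <- 500
tt <- (0:499) / fs
freqs <- feature_frequencies()

test_that("Burg spectra locate tones where the periodogram does", {
  set.seed(11)
  x <- sin(2 * pi * 10 * tt) + rnorm(500, 0, 0.2)
  pb <- burg_psd(x, ar_order = 16, freqs, fs)
  pp <- periodogram_psd(x, freqs, fs)
  expect_true(all(pb >= 0))
  expect_lte(abs(freqs[which.max(pb)] - freqs[which.max(pp)]), 1)
  expect_equal(freqs[which.max(pb)], 10)

  # two tones: Burg local maxima agree with the periodogram within 1 Hz
  x2 <- sin(2 * pi * 10 * tt) + 0.8 * sin(2 * pi * 22 * tt + 1) +
    rnorm(500, 0, 0.1)
  local_maxima <- function(p) {
    i <- which(diff(sign(diff(p))) == -2) + 1
    freqs[i[order(p[i], decreasing = TRUE)][1:2]]
  }
  pb2 <- burg_psd(x2, ar_order = 16, freqs, fs)
  pp2 <- periodogram_psd(x2, freqs, fs)
  expect_equal(sort(local_maxima(pp2)), c(10, 22))
  expect_true(all(abs(sort(local_maxima(pb2)) - c(10, 22)) <= 1))
})

test_that("Burg spectra of white noise are flat on average", {
  set.seed(21)
  acc <- rep(0, length(freqs))
  n_rep <- 300
  for (i in seq_len(n_rep))
    acc <- acc + burg_psd(rnorm(500), ar_order = 16, freqs, fs)
  acc <- acc / n_rep
  expect_lt(max(acc) / min(acc), 1.2)
})

test_that("degenerate spectral inputs are rejected", {
  expect_error(burg_psd(rep(0, 500)), "degenerate")
  expect_error(burg_psd(rep(3.3, 500)), "degenerate")
  expect_error(burg_psd(rnorm(10), ar_order = 16), "below the number")
  expect_error(burg_psd(rnorm(500), frequencies_hz = 300), "Nyquist")
})

test_that("normalization produces relative powers summing to one, idempotently", {
  vals <- array(0, c(2, 1, 25))
  vals[1, 1, ] <- 1            # uniform slice
  vals[2, 1, 1] <- 2           # single-bin slice
  pt <- make_power_table(vals, labels = c("RELAX", "IMAGINE"))
  nm <- normalize_powers(pt)
  expect_equal(nm$values[1, 1, ], rep(0.04, 25))
  expect_equal(nm$values[2, 1, ], c(1, rep(0, 24)))
  expect_identical(normalize_powers(nm)$values, nm$values)

  set.seed(5)
  rnd <- make_power_table(array(rexp(3 * 2 * 25), c(3, 2, 25)),
                          labels = c("RELAX", "IMAGINE", "RELAX"))
  sums <- apply(normalize_powers(rnd)$values, c(1, 2), sum)
  expect_equal(as.numeric(sums), rep(1, 6), tolerance = 1e-12)

  zero <- make_power_table(array(0, c(1, 1, 25)), labels = "RELAX")
  expect_error(normalize_powers(zero), "degenerate")
})

test_that("optimal-frequency selection finds the injected difference and breaks ties low", {
  set.seed(7)
  n <- 40
  vals <- array(rep(1, n * 2 * 25), c(n, 2, 25))
  labels <- rep(c("RELAX", "IMAGINE"), n / 2)
  # electrode 1: difference injected at 10 Hz; electrode 2: at 25 Hz
  vals[labels == "IMAGINE", 1, match(10, freqs)] <- 0.3
  vals[labels == "IMAGINE", 2, match(25, freqs)] <- 2.5
  pt <- make_power_table(vals, labels, electrodes = c("CZ", "C3"))
  map <- select_optimal_frequencies(pt)
  expect_equal(map$frequency_hz[map$electrode == "CZ"], 10)
  expect_equal(map$frequency_hz[map$electrode == "C3"], 25)
  expect_true(all(map$abs_diff > 0))

  # identical tasks: all differences zero, tie-break at 6 Hz
  flat <- make_power_table(array(1, c(4, 2, 25)),
                           labels = c("RELAX", "IMAGINE", "RELAX", "IMAGINE"),
                           electrodes = c("CZ", "C3"))
  map0 <- select_optimal_frequencies(flat)
  expect_equal(map0$frequency_hz, c(6, 6))
  expect_equal(map0$abs_diff, c(0, 0))

  # selection is invariant to a common positive rescaling of raw powers
  sc <- pt; sc$values <- pt$values * 37.5
  expect_equal(select_optimal_frequencies(sc)$frequency_hz, map$frequency_hz)

  single <- make_power_table(array(1, c(2, 2, 25)), labels = c("RELAX", "RELAX"))
  expect_error(select_optimal_frequencies(single), "both task")
})

test_that("feature extraction reads the mapped frequency per electrode", {
  n <- 6
  vals <- array(stats::runif(n * 3 * 25), c(n, 3, 25))
  labels <- rep(c("RELAX", "IMAGINE"), 3)
  pt <- normalize_powers(make_power_table(vals, labels,
                                          electrodes = c("CZ", "C1", "C2")))
  map <- data.frame(electrode = c("CZ", "C1", "C2"),
                    frequency_hz = c(10, 6, 28), abs_diff = 1,
                    stringsAsFactors = FALSE)
  class(map) <- c("optimal_frequency_map", "data.frame")
  feats <- extract_features(pt, map)
  expect_equal(dim(feats), c(n, 3))
  expect_equal(feats[, "CZ"], pt$values[, 1, match(10, freqs)])
  expect_equal(feats[, "C1"], pt$values[, 2, match(6, freqs)])
  expect_equal(feats[, "C2"], pt$values[, 3, match(28, freqs)])

  # map covering all electrodes at 6 Hz reproduces the 6 Hz column
  map6 <- map; map6$frequency_hz <- 6
  expect_equal(extract_features(pt, map6), pt$values[, , 1],
               ignore_attr = TRUE)

  # uniform slices give the uniform relative power everywhere
  uni <- normalize_powers(make_power_table(array(1, c(2, 3, 25)),
                                           labels = c("RELAX", "IMAGINE"),
                                           electrodes = c("CZ", "C1", "C2")))
  expect_true(all(abs(extract_features(uni, map) - 0.04) < 1e-12))

  bad <- map[map$electrode != "C1", ]
  class(bad) <- c("optimal_frequency_map", "data.frame")
  expect_error(extract_features(pt, bad), "does not cover")
})

test_that("nine features per epoch come out of the default montage pipeline", {
  spec <- small_spec()
  rec <- generate_session(subject_profile(), spec, day = 1, seed = 6)
  ep <- preprocess_session(rec, spec, trials = 1:2)
  pt <- normalize_powers(power_table(ep))
  map <- select_optimal_frequencies(pt)
  expect_equal(nrow(map), 9)
  feats <- extract_features(pt, map)
  expect_equal(ncol(feats), 9)
  expect_equal(nrow(feats), dim(ep$epochs)[3])
})
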