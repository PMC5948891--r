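fs <- 500
tt <- (0:499) / fs

test_that("epoch slicing honors the discard window, labels and counts", {
  spec <- small_spec()
  rec <- generate_session(subject_profile(noise_amplitude = 0.1), spec,
                          day = 1, seed = 2)
  ep <- slice_epochs(rec, spec)
  n_tasks <- 2 * spec$tasks_per_type_per_trial * spec$trials_per_session
  expect_equal(dim(ep$epochs), c(500, 30, n_tasks * 15))
  expect_equal(sum(ep$labels == "RELAX"), sum(ep$labels == "IMAGINE"))
  # epochs start no earlier than 2 s into their task
  ev <- rec$events[rec$events$label %in% c("RELAX", "IMAGINE"), ]
  rel_start <- ep$epoch_start_s -
    ev$onset_s[findInterval(ep$epoch_start_s, ev$onset_s)]
  expect_true(all(rel_start >= spec$discard_initial_s - 1e-9))
  expect_true(all(rel_start + spec$epoch_length_s <= 5.8 + 1e-9))
  # trial restriction
  ep4 <- slice_epochs(rec, spec, trials = 1:4)
  expect_equal(dim(ep4$epochs)[3], 4 * 4 * 15)

  # a recording with one relax cue yields exactly the enumerated windows
  one <- make_recording(matrix(rnorm(30 * 2900), 30,
                               dimnames = list(acquisition_channels(), NULL)),
                        simple_events("RELAX", 0, 5.8))
  eo <- slice_epochs(one, protocol_spec())
  expect_equal(dim(eo$epochs)[3], 15)
  expect_true(all(eo$labels == "RELAX"))
  expect_equal(eo$epoch_start_s, seq(2, 4.8, by = 0.2))
  # single-window protocol
  expect_equal(dim(slice_epochs(one, protocol_spec(discard_initial_s = 4.8))$epochs)[3],
               1)
  # event running past the recording end
  short <- make_recording(matrix(0, 30, 1000,
                                 dimnames = list(acquisition_channels(), NULL)),
                          simple_events("RELAX", 0, 5.8))
  expect_error(slice_epochs(short, protocol_spec()), "past the end")
})

test_that("filter chain removes DC and line noise but preserves the mu band", {
  cfg <- filter_chain_config()
  out_const <- apply_filter_chain(make_epoch_set(rep(5, 500)), cfg)
  expect_lt(max(abs(out_const$epochs)), 0.01)

  for (ph in c(0, 0.8, 1.6, 2.9)) {
    line <- sin(2 * pi * 50 * tt + ph)
    y <- as.numeric(apply_filter_chain(make_epoch_set(line), cfg)$epochs)
    expect_lt(sqrt(mean(y^2)), 0.1)
    # >= 20 dB attenuation of the 50 Hz component itself
    att <- Mod(fft(y)[51]) / Mod(fft(line)[51])
    expect_lt(att, 0.1)
  }

  mu <- sin(2 * pi * 10 * tt + 0.3)
  y10 <- as.numeric(apply_filter_chain(make_epoch_set(mu), cfg)$epochs)
  expect_equal(sqrt(mean(y10^2)) / sqrt(mean(mu^2)), 1, tolerance = 0.05)
})

test_that("filter chain is linear and insensitive to recording DC offsets", {
  cfg <- filter_chain_config()
  set.seed(42)
  a <- rnorm(500); b <- rnorm(500)
  run <- function(x) as.numeric(apply_filter_chain(make_epoch_set(x), cfg)$epochs)
  # the 0.05 Hz high-pass is numerically stiff; tolerances reflect its
  # conditioning, not the filters' algebra
  expect_lt(max(abs(run(2 * a - 3 * b) - (2 * run(a) - 3 * run(b)))), 1e-4)
  expect_lt(max(abs(run(a + 200) - run(a))), 0.01)
})

test_that("filter configuration errors are caught", {
  expect_error(filter_chain_config(hp_cutoff_hz = 0), "hp_cutoff")
  expect_error(filter_chain_config(lp_cutoff_hz = 0.01), "hp_cutoff")
  ep <- make_epoch_set(rnorm(500))
  expect_error(apply_filter_chain(ep, filter_chain_config(lp_cutoff_hz = 300)),
               "Nyquist")
})

test_that("the second-order-section Butterworth matches the reference design", {
  # cross-check the cascaded-biquad design against an independent
  # transfer-function implementation at frequencies where both are
  # well-conditioned
  fs <- 500
  resp_sos <- function(secs, f) {
    z <- exp(-2i * pi * f / fs)
    Mod(prod(vapply(secs, function(s)
      sum(s$b * z^(seq_along(s$b) - 1)) / sum(s$a * z^(seq_along(s$a) - 1)),
      complex(1))))
  }
  resp_tf <- function(ba, f) {
    z <- exp(-2i * pi * f / fs)
    Mod(sum(ba$b * z^(seq_along(ba$b) - 1)) /
          sum(ba$a * z^(seq_along(ba$a) - 1)))
  }
  for (cutoff in c(45, 30)) {
    sos <- pedalbci:::design_butter_sos(4, cutoff / 250, "low")
    tf <- signal::butter(4, cutoff / 250, type = "low")
    for (f in c(5, 15, 30, 45, 80))
      expect_equal(resp_sos(sos, f), resp_tf(tf, f), tolerance = 1e-8)
  }
  sos_hp <- pedalbci:::design_butter_sos(3, 2 / 250, "high")  # odd order too
  tf_hp <- signal::butter(3, 2 / 250, type = "high")
  for (f in c(0.5, 2, 10, 50))
    expect_equal(resp_sos(sos_hp, f), resp_tf(tf_hp, f), tolerance = 1e-8)
})

test_that("causal streaming mode removes DC and passes the mu rhythm", {
  n <- 5000
  x <- matrix(100 + sin(2 * pi * 10 * (0:(n - 1)) / fs), 1,
              dimnames = list("CZ", NULL))
  rec <- make_recording(x, simple_events("RELAX", 0, n / fs), channels = "CZ")
  out <- apply_filter_chain_causal(rec)
  mid <- out$samples[1, 2000:4000]
  expect_lt(abs(mean(mid)), 0.05)
  expect_equal(sqrt(mean(mid^2)), sqrt(0.5), tolerance = 0.05)
})

test_that("Laplacian re-referencing cancels common-mode and isolates local sources", {
  chans <- acquisition_channels()
  nc <- length(chans)
  sig <- sin(2 * pi * 10 * tt)

  # identical signal everywhere -> exactly zero everywhere
  common <- array(rep(sig, nc), c(500, nc, 1))
  ep <- make_epoch_set(common, channels = chans)
  expect_lt(max(abs(laplacian_reference(ep)$epochs)), 1e-10)

  # signal on Cz only: Cz unchanged, channel i receives -w_i * signal
  alone <- array(0, c(500, nc, 1))
  cz <- match("CZ", chans)
  alone[, cz, 1] <- sig
  out <- laplacian_reference(make_epoch_set(alone, channels = chans))$epochs
  expect_equal(out[, cz, 1], sig)
  W <- pedalbci:::laplacian_weights(chans)
  for (i in c(1, 5, 17))  # spot-check a few channels
    expect_equal(out[, i, 1], -W[i, cz] * sig)

  # two channels: output is the antisymmetric difference pair
  two <- array(0, c(500, 2, 1))
  two[, 1, 1] <- sig
  ep2 <- make_epoch_set(two, channels = c("C3", "C4"))
  out2 <- laplacian_reference(ep2)$epochs
  expect_equal(out2[, 1, 1], sig)
  expect_equal(out2[, 2, 1], -sig)

  dup <- data.frame(label = c("C3", "C4"), x = c(0, 0), y = c(0, 0))
  expect_error(laplacian_reference(ep2, coords = dup), "duplicate")
})

test_that("electrode selection subsets channels in the requested order", {
  spec <- small_spec()
  rec <- generate_session(subject_profile(), spec, day = 1, seed = 3)
  ep <- slice_epochs(rec, spec, trials = 1)
  sel <- select_electrodes(ep)
  expect_equal(sel$channel_labels, motor_electrodes())
  expect_equal(dim(sel$epochs)[2], 9)
  expect_equal(sel$epochs[, 1, 1],
               ep$epochs[, match("CZ", ep$channel_labels), 1])
  all30 <- select_electrodes(ep, ep$channel_labels)
  expect_identical(all30$epochs, ep$epochs)
  one <- select_electrodes(ep, "CZ")
  expect_equal(dim(one$epochs)[2], 1)
  expect_error(select_electrodes(ep, "XX1"), "unknown electrode")
})
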