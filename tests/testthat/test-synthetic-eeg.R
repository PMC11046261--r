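test_that("sessions are bit-identical under the same seed", {
  cfg <- sim_config(channel_labels = c("Oz", "TP9", "Fp1"),
                    condition_table = data.frame(condition = 1:2,
                                                 n_trials = 4L),
                    artifacts = artifact_spec(), eye = eye_spec())
  a <- simulate_session(cfg, seed = 14)
  b <- simulate_session(cfg, seed = 14)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
  expect_identical(a$eye$x, b$eye$x)
  expect_identical(a$truth$artifact_trials$trial,
                   b$truth$artifact_trials$trial)
  c_ <- simulate_session(cfg, seed = 15)
  expect_false(identical(a$recording$data, c_$recording$data))
})

test_that("background spectra follow the configured 1/f exponent", {
  slope_of <- function(exponent, seed) {
    cfg <- sim_config(channel_labels = c("Oz", "Cz"),
                      background_exponent = exponent,
                      condition_table = data.frame(condition = 1L,
                                                   n_trials = 10L))
    rec <- simulate_background(cfg, n_samples = 300000, seed = seed)
    rec$events <- data.frame(onset = seq(1000, 297000, by = 2000),
                             condition = 1L)
    ep <- epoch(rec, c(0, 2000))
    est <- multitaper_psd(ep, c(0, 2000))
    mean(vapply(1:2, function(ch) {
      avg <- apply(est$power[, ch, , drop = FALSE], 3, mean)
      fit_spectral_slope(est$freqs, avg, c(56, 86))
    }, 0))
  }
  expect_lt(abs(slope_of(0, seed = 3)), 0.1)          # white noise
  expect_lt(abs(slope_of(2, seed = 3) - 2), 0.15)     # steep 1/f^2
})

test_that("background amplitude is scaled to the configured RMS", {
  cfg <- sim_config(channel_labels = "Oz", background_rms = 15,
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 5L))
  rec <- simulate_background(cfg, n_samples = 100000, seed = 4)
  expect_equal(stats::sd(rec$data[1, ]), 15, tolerance = 0.05)
})

test_that("zero-dB injection returns the recording unchanged", {
  cfg <- sim_config(channel_labels = c("Oz", "O1"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 5L))
  ses <- simulate_session(cfg, seed = 5)
  out <- inject_band_response(ses$recording, band = c(30, 60),
                              electrodes = c("Oz", "O1"), delta_db = 0)
  expect_identical(out$data, ses$recording$data)
})

test_that("injection validates bands and electrodes", {
  cfg <- sim_config(channel_labels = "Oz",
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 3L))
  ses <- simulate_session(cfg, seed = 6)
  expect_error(inject_band_response(ses$recording, band = c(2, 10),
                                    electrodes = "Oz", delta_db = 1),
               "Nyquist|inside")
  expect_error(inject_band_response(ses$recording, band = c(460, 499),
                                    electrodes = "Oz", delta_db = 1),
               "Nyquist|inside")
  expect_error(inject_band_response(ses$recording, band = c(30, 60),
                                    electrodes = "Pz", delta_db = 1),
               "unknown electrode")
})

test_that("injected band changes are recovered by the spectral pipeline", {
  recover <- function(delta_db, band, seed) {
    chans <- c("O1", "Oz", "O2", "POz")
    cfg <- sim_config(channel_labels = chans,
                      condition_table = data.frame(condition = 1L,
                                                   n_trials = 200L),
                      band_effects = list(band_effect(band, chans,
                                                      delta_db)))
    ses <- simulate_session(cfg, seed = seed)
    ep <- epoch(ses$recording, c(-848, 1650))
    st <- multitaper_psd(ep, c(250, 750))
    bl <- multitaper_psd(ep, c(-500, 0))
    delta_power(st, bl, band)$delta_db
  }
  got <- vapply(1:3, function(s) recover(1, c(30, 60), s), 0)
  expect_equal(mean(got), 1, tolerance = 0.1)
  got_neg <- vapply(1:3, function(s) recover(-1, c(8, 12), s), 0)
  expect_equal(mean(got_neg), -1, tolerance = 0.15)
  expect_true(all(got_neg < 0))
})

test_that("null sessions yield band changes near zero", {
  chans <- c("O1", "Oz", "O2", "POz")
  cfg <- sim_config(channel_labels = chans,
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 100L))
  ses <- simulate_session(cfg, seed = 77)
  ep <- epoch(ses$recording, c(-848, 1650))
  st <- multitaper_psd(ep, c(250, 750))
  bl <- multitaper_psd(ep, c(-500, 0))
  for (band in canonical_bands()) {
    ## 3 x Monte-Carlo SE of the dB ratio: each trial-electrode band sum
    ## has ~2 * n_bins chi-square dof, stimulus and baseline independent
    n_bins <- sum(st$freqs >= band[1] & st$freqs <= band[2])
    se_db <- (10 / log(10)) * sqrt(2 / (n_bins * 100 * length(chans)))
    expect_lt(abs(delta_power(st, bl, band)$delta_db), 3 * se_db)
  }
})

test_that("null band changes are centred on zero across replicates", {
  ## 20 seeded null replicates; one-sample t test must not reject at 1%
  vals <- vapply(1:20, function(s) {
    cfg <- sim_config(channel_labels = c("Oz", "POz"),
                      condition_table = data.frame(condition = 1L,
                                                   n_trials = 40L))
    ses <- simulate_session(cfg, seed = 1000 + s)
    ep <- epoch(ses$recording, c(-848, 1650))
    st <- multitaper_psd(ep, c(250, 750))
    bl <- multitaper_psd(ep, c(-500, 0))
    delta_power(st, bl, c(30, 60))$delta_db
  }, 0)
  expect_gt(stats::t.test(vals)$p.value, 0.01)
})

test_that("artifact injection honours rates and trips the printed rules", {
  cfg <- sim_config(channel_labels = c("Oz", "TP9", "Fp1", "Fp2"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 30L))
  ses <- simulate_session(cfg, seed = 8)

  ## rate zero: untouched recording, empty truth
  out0 <- inject_artifacts(ses$recording,
                           artifact_spec(blink_rate = 0, spike_rate = 0,
                                         flat_rate = 0), seed = 1)
  expect_identical(out0$recording$data, ses$recording$data)
  expect_equal(nrow(out0$truth), 0L)

  ## deterministic-by-construction violations, checked with an
  ## independent filter + RMS oracle
  out <- inject_artifacts(ses$recording,
                          artifact_spec(blink_rate = 0, spike_rate = 0.5,
                                        spike_n_channels = 2,
                                        flat_rate = 0.3,
                                        flat_channel = "Oz"), seed = 2)
  tr <- out$truth
  expect_gt(nrow(tr), 0L)
  expect_true(all(tr$trial >= 1 & tr$trial <= 30))
  fs <- 1000
  rms_of <- function(trial, label) {
    on <- ses$events$onset[trial]
    seg <- out$recording$data[label, seq.int(on - 500, on + 1499)]
    sqrt(mean(oracle_highpass(seg, fs)^2))
  }
  for (i in which(tr$type == "spike")) {
    rms_vals <- vapply(tr$electrodes[[i]],
                       function(el) rms_of(tr$trial[i], el), 0)
    expect_true(any(rms_vals > 35))
  }
  for (i in which(tr$type == "flat")) {
    expect_lt(rms_of(tr$trial[i], tr$electrodes[[i]][1]), 1.5)
  }
})

test_that("blink artifacts exceed the RMS bound on the frontal leads", {
  cfg <- sim_config(channel_labels = c("Fp1", "Fp2", "Oz"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 30L))
  ses <- simulate_session(cfg, seed = 9)
  out <- inject_artifacts(ses$recording,
                          artifact_spec(blink_rate = 0.3, spike_rate = 0,
                                        flat_rate = 0), seed = 3)
  tr <- out$truth
  expect_gt(nrow(tr), 2L)
  for (i in seq_len(nrow(tr))) {
    on <- ses$events$onset[tr$trial[i]]
    seg <- out$recording$data["Fp1", seq.int(on - 500, on + 1499)]
    expect_gt(sqrt(mean(oracle_highpass(seg, 1000)^2)), 35)
  }
})

test_that("session event counts match the task structures", {
  vis <- visual_sim_config(channels = c("Oz", "POz"), artifacts = NULL,
                           eye = NULL)
  expect_equal(sum(vis$condition_table$n_trials), 200)
  expect_equal(nrow(vis$condition_table), 8)
  aud <- auditory_sim_config(channels = c("TP9", "TP7"), artifacts = NULL)
  expect_equal(sum(aud$condition_table$n_trials), 480)
  expect_equal(nrow(aud$condition_table), 12)
  ses <- simulate_session(sim_config(
    channel_labels = "Oz",
    condition_table = data.frame(condition = 1:4, n_trials = 3L)), seed = 2)
  expect_equal(nrow(ses$events), 12L)
  expect_equal(as.vector(table(ses$events$condition)), rep(3L, 4))
  expect_true(all(diff(ses$events$onset) == 1600))
})

test_that("ground-truth fixation breaks are the trials the filter flags", {
  cfg <- sim_config(channel_labels = c("Oz", "Fp1"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 40L),
                    eye = eye_spec(break_rate = 0.2))
  ses <- simulate_session(cfg, seed = 21)
  expect_gt(length(ses$truth$fixation_break_trials), 0L)
  flagged <- as.integer(reject_fixation_breaks(ses$eye, ses$events))
  expect_setequal(flagged, ses$truth$fixation_break_trials)
})
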