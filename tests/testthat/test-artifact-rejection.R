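test_that("impedance screen uses a strict 25 kOhm cutoff", {
  rec <- new_recording(matrix(0, 4, 100), 1000,
                       c("Oz", "O1", "O2", "POz"),
                       impedances = c(7, 26, 25, 24.999))
  expect_equal(impedance_reject(rec), "O1")
  rec_all7 <- new_recording(matrix(0, 3, 100), 1000, c("Oz", "O1", "O2"),
                            impedances = c(7, 7, 7))
  expect_length(impedance_reject(rec_all7), 0L)
  rec_na <- new_recording(matrix(0, 2, 100), 1000, c("Oz", "O1"),
                          impedances = c(NA, 30))
  expect_warning(out <- impedance_reject(rec_na), "missing impedance")
  expect_equal(out, "O1")
})

test_that("high-pass screen filter removes drift and preserves the passband", {
  fs <- 1000
  t <- (0:3999) / fs
  slow <- sin(2 * pi * 0.3 * t)
  fast <- sin(2 * pi * 10 * t)
  y <- rippleGamma:::highpass_epochs(cbind(slow, fast), fs, 1.6)
  i <- 1000:3000
  expect_lt(sqrt(mean(y[i, 1]^2)), 0.02)
  expect_equal(sqrt(mean(y[i, 2]^2)), 1 / sqrt(2), tolerance = 0.01)
})

test_that("RMS bounds flag sinusoids and flat trials as printed", {
  make_sine_epochs <- function(amp) {
    t <- (0:2497) / 1000
    x <- amp * sin(2 * pi * 10 * t)
    arr <- array(rep(x, each = 4), dim = c(4, 1, 2498))
    epochs_from_array(arr, c(-848, 1650), labels = "Oz")
  }
  cfg <- rejection_config()
  keep <- rms_reject(make_sine_epochs(10), cfg)        # RMS ~ 7.07 uV
  expect_length(keep$Oz, 0L)
  flag <- rms_reject(make_sine_epochs(50), cfg)        # RMS ~ 35.36 uV
  expect_equal(as.integer(flag$Oz), 1:4)
  expect_true(all(attr(flag$Oz, "reason") == "rms_high"))
  expect_equal(unname(attr(flag, "rms")[1, 1]), 50 / sqrt(2),
               tolerance = 0.01)
  zero <- rms_reject(make_sine_epochs(0), cfg)         # RMS 0 < 1.5
  expect_equal(as.integer(zero$Oz), 1:4)
  expect_true(all(attr(zero$Oz, "reason") == "rms_low"))
})

test_that("PSD outlier screen flags a gross outlier but not identical trials", {
  withr::with_seed(41, {
    base_trial <- rnorm(2000)
    n_tr <- 50
    arr <- array(rep(base_trial, each = n_tr), dim = c(n_tr, 1, 2000))
    ## all identical: nothing flagged
    ep_same <- epochs_from_array(arr, c(-500, 1500), labels = "Oz")
    expect_length(psd_outlier_reject(ep_same)$Oz, 0L)
    ## one trial with a strong added oscillation: flagged
    arr[7, 1, ] <- arr[7, 1, ] + 20 * sin(2 * pi * 25 * (0:1999) / 1000)
    ep_out <- epochs_from_array(arr, c(-500, 1500), labels = "Oz")
    expect_equal(as.integer(psd_outlier_reject(ep_out)$Oz), 7L)
  })
})

test_that("PSD outlier screen needs at least three trials", {
  arr <- array(rnorm(2 * 1 * 2000), dim = c(2, 1, 2000))
  ep <- epochs_from_array(arr, c(-500, 1500), labels = "Oz")
  expect_warning(out <- psd_outlier_reject(ep), "fewer than 3")
  expect_length(out$Oz, 0L)
})

test_that("power-law slope fit recovers exact exponents", {
  f <- seq(2, 200, by = 2)
  expect_equal(fit_spectral_slope(f, f^-2), 2, tolerance = 1e-10)
  expect_equal(fit_spectral_slope(f, rep(3.7, length(f))), 0,
               tolerance = 1e-10)
  expect_equal(fit_spectral_slope(f, f^1), -1, tolerance = 1e-10)
  expect_error(fit_spectral_slope(f, -f), "non-positive")
  expect_error(fit_spectral_slope(c(60, 70), c(1, 1)), "3 frequency bins")
})

test_that("consolidation applies the strict 30%/10% and priority rules", {
  cfg <- rejection_config()
  trials <- 1:100
  labels <- paste0("Ch", 1:60)
  none <- stats::setNames(rep(list(integer(0)), 60), labels)
  out <- consolidate(none, trials, cfg)
  expect_length(out$discarded_electrodes, 0L)
  expect_length(out$common_bad_trials, 0L)

  ## electrode bad fraction: 31% discarded, exactly 30% kept
  bl <- none
  bl$Ch1 <- 1:31
  bl$Ch2 <- 1:30
  out <- consolidate(bl, trials, cfg)
  expect_equal(out$discarded_electrodes, "Ch1")

  ## trial on 7 of 60 electrodes (11.7%) common; on 6 of 60 (10%) not
  bl <- none
  for (ch in labels[1:7]) bl[[ch]] <- c(bl[[ch]], 50L)
  for (ch in labels[1:6]) bl[[ch]] <- c(bl[[ch]], 60L)
  out <- consolidate(bl, trials, cfg)
  expect_equal(out$common_bad_trials, 50L)

  ## any flag on a surviving priority electrode joins the common set
  bl <- stats::setNames(rep(list(integer(0)), 60),
                        c("Oz", "TP9", paste0("Ch", 1:58)))
  bl$Oz <- 3L
  bl$TP9 <- 9L
  bl$Ch1 <- 4L
  out <- consolidate(bl, trials, cfg)
  expect_setequal(out$common_bad_trials, c(3L, 9L))

  ## a priority electrode discarded by fraction no longer forces trials
  bl$Oz <- 1:40
  out <- consolidate(bl, trials, cfg)
  expect_equal(out$discarded_electrodes, "Oz")
  expect_setequal(out$common_bad_trials, 9L)
})

test_that("subject verdict uses a strict 50% survival rule", {
  cfg <- rejection_config()
  all_64 <- acticap64_labels()
  expect_true(all(reject_subject(all_64, cfg)))
  ## 4 of 9 occipital electrodes survive: visual rejected
  surv <- setdiff(all_64, c("PO7", "PO3", "POz", "PO4", "PO8"))
  v <- reject_subject(surv, cfg)
  expect_false(v["visual"])
  expect_true(v["auditory"])
  ## exactly 5 of 10 temporal survive: kept (strict <)
  surv2 <- setdiff(all_64, c("FT9", "FT7", "T7", "TP7", "TP9"))
  expect_true(reject_subject(surv2, cfg)["auditory"])
  ## 4 of 10: rejected
  surv3 <- setdiff(all_64, c("FT9", "FT7", "T7", "TP7", "TP9", "FT10"))
  expect_false(reject_subject(surv3, cfg)["auditory"])
})

test_that("loosening thresholds never increases the flag sets", {
  cfg <- sim_config(channel_labels = c("Oz", "TP9", "Fp1", "Cz"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 25L),
                    artifacts = artifact_spec(blink_rate = 0.15,
                                              spike_rate = 0.15,
                                              spike_n_channels = 2,
                                              flat_rate = 0.1,
                                              flat_channel = "Cz"))
  ses <- simulate_session(cfg, seed = 17)
  ep <- epoch(ses$recording, c(-848, 1650))
  tight <- rejection_config()
  loose <- rejection_config(rms_bounds = c(0.5, 60), psd_sd_mult = 8)
  rms_t <- rms_reject(ep, tight); rms_l <- rms_reject(ep, loose)
  psd_t <- psd_outlier_reject(ep, tight)
  psd_l <- psd_outlier_reject(ep, loose)
  for (ch in ep$channel_labels) {
    expect_true(all(as.integer(rms_l[[ch]]) %in% as.integer(rms_t[[ch]])))
    expect_true(all(psd_l[[ch]] %in% psd_t[[ch]]))
  }
})

test_that("cascade report is internally consistent and stage-tagged", {
  cfg <- sim_config(channel_labels = c("Oz", "O1", "TP9", "Fp1", "Cz"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 20L),
                    impedances = c(7, 30, 7, 7, 7),
                    artifacts = artifact_spec(blink_rate = 0.1,
                                              spike_rate = 0.2,
                                              spike_n_channels = 2,
                                              flat_rate = 0.1,
                                              flat_channel = "Cz"))
  ses <- simulate_session(cfg, seed = 33)
  rep_ <- run_rejection_cascade(ses$recording)
  ## impedance discard recorded and excluded downstream
  expect_equal(unname(rep_$discarded_electrodes["O1"]), "impedance")
  expect_false("O1" %in% names(rep_$bad_trials_by_electrode))
  expect_false("O1" %in% rep_$surviving_electrodes)
  ## common bad trials within range, good trials complementary
  expect_true(all(rep_$common_bad_trials %in% 1:20))
  expect_setequal(c(rep_$good_trials, rep_$common_bad_trials), 1:20)
  ## every flagged trial has a stage tag
  for (ch in names(rep_$bad_trials_by_electrode)) {
    ids <- rep_$bad_trials_by_electrode[[ch]]
    expect_equal(sort(as.integer(names(rep_$flag_stage[[ch]]))), ids)
  }
  ## serialization round-trip
  d <- withr::local_tempdir()
  p <- file.path(d, "report.json")
  write_rejection_report(rep_, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$common_bad_trials, rep_$common_bad_trials)
  expect_equal(back$n_trials, 20)
})

test_that("fixation-break trials are removed before the EEG screens", {
  cfg <- sim_config(channel_labels = c("Oz", "Fp1"),
                    condition_table = data.frame(condition = 1L,
                                                 n_trials = 30L),
                    eye = eye_spec(break_rate = 0.3))
  ses <- simulate_session(cfg, seed = 51)
  rep_ <- run_rejection_cascade(ses$recording, eye = ses$eye)
  expect_setequal(rep_$eye_bad_trials, ses$truth$fixation_break_trials)
  for (ch in names(rep_$bad_trials_by_electrode)) {
    expect_length(intersect(rep_$bad_trials_by_electrode[[ch]],
                            rep_$eye_bad_trials), 0L)
  }
})
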