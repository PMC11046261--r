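test_that("BrainVision INT_16 round-trip stays within the 0.1 uV resolution", {
  d <- withr::local_tempdir()
  withr::with_seed(11, {
    data <- matrix(rnorm(3 * 5000, sd = 12), nrow = 3)
  })
  rec <- new_recording(data, 1000, c("Oz", "TP9", "Fp1"),
                       impedances = c(7, 8.5, 24),
                       events = data.frame(onset = c(1000, 2500, 4000),
                                           condition = c(1L, 2L, 1L)))
  base <- file.path(d, "ses")
  write_brainvision(rec, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$sampling_rate, 1000)
  expect_lte(max(abs(back$data - rec$data)), 0.05 + 1e-9)
  expect_equal(back$events, rec$events)
  expect_equal(unname(back$impedances), c(7, 8.5, 24))
})

test_that("BrainVision float32 round-trip is exact at single precision", {
  d <- withr::local_tempdir()
  data <- matrix(sin(1:2000), nrow = 2)
  rec <- new_recording(data, 500, c("C3", "C4"))
  base <- file.path(d, "f32")
  write_brainvision(rec, base, binary_format = "IEEE_FLOAT_32")
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(back$data, rec$data, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("empty marker files and truncated binaries are handled", {
  d <- withr::local_tempdir()
  rec <- new_recording(matrix(0, 2, 1000), 1000, c("Oz", "Cz"))
  base <- file.path(d, "empty")
  write_brainvision(rec, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(nrow(back$events), 0L)

  ## drop one byte so frames are incomplete
  eeg <- paste0(base, ".eeg")
  raw_bytes <- readBin(eeg, "raw", n = file.info(eeg)$size)
  writeBin(raw_bytes[-length(raw_bytes)], eeg)
  expect_error(read_brainvision(paste0(base, ".vhdr")),
               "truncated binary.*channels")

  expect_error(read_brainvision(file.path(d, "nothere.vhdr")), "not found")
  file.remove(eeg)
  expect_error(read_brainvision(paste0(base, ".vhdr")), "missing triplet")
})

test_that("epoch window convention yields printed sample counts", {
  rec <- sine_recording(10, 5, n_events = 10)
  ep <- epoch(rec, c(-848, 1650))
  expect_equal(dim(ep$data), c(10, 1, 2498))
  expect_equal(ep$trial_ids, 1:10)
  ## half-open: (-500, 0) and (0, 500) share no samples
  expect_equal(dim(epoch(rec, c(-500, 0))$data)[3], 500L)
  expect_equal(dim(epoch(rec, c(250, 750))$data)[3], 500L)
  expect_error(epoch(rec, c(500, -500)), "start < end")
})

test_that("events too close to the edges are dropped with a warning", {
  rec <- new_recording(matrix(rnorm(4000), 1), 1000, "Oz",
                       events = data.frame(onset = c(10, 1500),
                                           condition = c(1L, 1L)))
  expect_warning(ep <- epoch(rec, c(-848, 1650)), "dropped")
  expect_equal(dim(ep$data)[1], 1L)
  expect_equal(ep$trial_ids, 2L)
})

test_that("epoching non-overlapping windows reconstructs the recording", {
  x <- matrix(rnorm(2 * 6000), nrow = 2)
  onsets <- seq(1, 5001, by = 1000)
  rec <- new_recording(x, 1000, c("A", "B"),
                       events = data.frame(onset = onsets, condition = 1L))
  ep <- epoch(rec, c(0, 1000))
  rebuilt <- matrix(NA_real_, 2, 6000)
  for (i in seq_along(onsets)) {
    rebuilt[, onsets[i] + 0:999] <- ep$data[i, , ]
  }
  expect_identical(rebuilt, unname(x))
})

test_that("bipolar referencing is anti-symmetric and validates labels", {
  withr::with_seed(21, {
    arr <- array(rnorm(4 * 3 * 100), dim = c(4, 3, 100))
  })
  ep <- epochs_from_array(arr, c(0, 100), labels = c("TP9", "TP7", "T7"))
  ab <- bipolar_rereference(ep, rbind(c("TP9", "TP7")))
  ba <- bipolar_rereference(ep, rbind(c("TP7", "TP9")))
  expect_equal(ab$data[, 1, ], -ba$data[, 1, ])
  expect_equal(ab$channel_labels, "TP9-TP7")
  same <- bipolar_rereference(ep, rbind(c("T7", "T7")))
  expect_true(all(same$data == 0))
  expect_error(bipolar_rereference(ep, rbind(c("TP9", "Oz"))), "Oz")
})

test_that("task bipolar montages produce the printed derivation counts", {
  labels <- acticap64_labels()
  withr::with_seed(22, {
    arr <- array(rnorm(2 * 64 * 50), dim = c(2, 64, 50))
  })
  ep <- epochs_from_array(arr, c(0, 50), labels = labels)
  aud <- bipolar_rereference(ep, auditory_bipolar_pairs())
  expect_equal(dim(aud$data)[2], 8L)
  vis <- bipolar_rereference(ep, visual_bipolar_pairs())
  expect_equal(dim(vis$data)[2], 9L)
  expect_equal(vis$channel_labels[1], "PO3-P1")
})

test_that("fixation filter applies the square window in the checked interval", {
  n <- 20000
  events <- data.frame(onset = c(5000, 10000, 15000), condition = 1L)
  ## steady fixation: nothing flagged
  eye <- eye_trace(rep(0.1, n), rep(-0.2, n))
  expect_length(reject_fixation_breaks(eye, events), 0L)

  ## 3 degree excursion at +100 ms of trial 2: flagged
  x <- rep(0, n); x[10100:10200] <- 3
  bad <- reject_fixation_breaks(eye_trace(x, rep(0, n)), events)
  expect_equal(as.integer(bad), 2L)
  expect_equal(attr(bad, "reason"), "fixation break")

  ## same excursion at +800 ms only: outside the checked window, kept
  x2 <- rep(0, n); x2[10800:10900] <- 3
  expect_length(reject_fixation_breaks(eye_trace(x2, rep(0, n)), events), 0L)

  ## blink (NA gap) flagged as blink
  x3 <- rep(0, n); x3[5100:5150] <- NA
  bad3 <- reject_fixation_breaks(eye_trace(x3, rep(0, n)), events)
  expect_equal(as.integer(bad3), 1L)
  expect_equal(attr(bad3, "reason"), "blink")

  ## missing coverage flagged with "no data"
  ev_edge <- data.frame(onset = n - 100, condition = 1L)
  bad4 <- reject_fixation_breaks(eye, ev_edge)
  expect_equal(attr(bad4, "reason"), "no data")
})

test_that("fixation filter is translation invariant", {
  n <- 20000
  events <- data.frame(onset = c(5000, 12000), condition = 1L)
  withr::with_seed(31, {
    x <- cumsum(rnorm(n, sd = 0.01))
    y <- cumsum(rnorm(n, sd = 0.01))
  })
  x[12100] <- x[12100] + 4
  base <- reject_fixation_breaks(eye_trace(x, y), events,
                                 fixation_center = c(0, 0))
  shifted <- reject_fixation_breaks(eye_trace(x + 3, y - 2), events,
                                    fixation_center = c(3, -2))
  expect_equal(as.integer(base), as.integer(shifted))
  expect_equal(as.integer(base), 2L)
})

test_that("eye traces round-trip through CSV", {
  d <- withr::local_tempdir()
  eye <- eye_trace(sin(1:500 / 50), cos(1:500 / 50))
  p <- file.path(d, "eye.csv")
  write_eye_trace(eye, p)
  back <- read_eye_trace(p)
  expect_equal(back$x, eye$x, tolerance = 1e-12)
  expect_equal(attr(back, "sampling_rate"), 1000)
})

test_that("simulated sessions survive serialization", {
  d <- withr::local_tempdir()
  cfg <- sim_config(channel_labels = c("Oz", "TP9", "Fp1"),
                    condition_table = data.frame(condition = 1:2,
                                                 n_trials = 3L),
                    artifacts = artifact_spec(), eye = eye_spec())
  ses <- simulate_session(cfg, seed = 9)
  write_session(ses, file.path(d, "ses"))
  back <- read_session(file.path(d, "ses"))
  expect_lte(max(abs(back$recording$data - ses$recording$data)), 0.05 + 1e-9)
  expect_equal(back$recording$events, ses$events)
  expect_equal(back$truth$seed, 9)
})
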