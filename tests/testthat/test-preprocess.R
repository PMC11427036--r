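test_that("Butterworth band-pass has the designed frequency response", {
  fs <- 12500
  flt <- butter_bandpass(3, 300, 3000, fs)
  t <- (0:(2 * fs - 1)) / fs
  gain_at <- function(freq) {
    y <- filtfilt_zero_phase(flt$b, flt$a, sin(2 * pi * freq * t))
    mid <- (fs / 2):(3 * fs / 2)              # discard edge transients
    sd(y[mid]) / sd(sin(2 * pi * freq * t)[mid])
  }
  expect_lt(abs(gain_at(1000) - 1), 0.05)     # in-band amplitude preserved
  expect_lt(gain_at(100), 0.10)               # below band: > 90% attenuated
  expect_lt(gain_at(5000), 0.10)              # above band
  # zero-phase: forward-backward filtered in-band sine stays aligned
  y <- filtfilt_zero_phase(flt$b, flt$a, sin(2 * pi * 1000 * t))
  mid <- (fs / 2):(3 * fs / 2)
  expect_gt(cor(y[mid], sin(2 * pi * 1000 * t)[mid]), 0.999)
  expect_error(butter_bandpass(3, 300, 7000, fs), "band edges")
})

test_that("median referencing removes common-mode signal", {
  fs <- 12500
  zero <- raw_recording(matrix(0, 3, fs), fs)
  expect_true(all(reference_and_filter(zero)$traces == 0))
  common <- matrix(rep(sin(2 * pi * 700 * (0:(fs - 1)) / fs), each = 3),
                   nrow = 3)
  out <- reference_and_filter(raw_recording(common, fs))
  expect_lt(max(abs(out$traces)), 1e-9)
  expect_error(reference_and_filter(raw_recording(matrix(0, 1, fs), fs)),
               "2 channels")
  expect_error(
    reference_and_filter(raw_recording(matrix(0, 2, 2000), 2000)),
    "Nyquist")
})

test_that("adaptive-threshold spike detection recovers planted transients", {
  fs <- 12500
  rec0 <- raw_recording(matrix(0, 2, fs), fs)
  expect_equal(nrow(detect_spikes(rec0)), 0)
  insert_at <- sort(sample(seq(fs %/% 10, fs * 2 - fs %/% 10), 20))
  # enforce >= 2 ms separation so detections are unambiguous
  while (any(diff(insert_at) < 25))
    insert_at <- sort(sample(seq(fs %/% 10, fs * 2 - fs %/% 10), 20))
  rec <- make_transient_trace(2 * fs, fs, insert_at)
  det <- detect_spikes(rec)
  det <- det[det$unit_id == "probe", ]
  expect_equal(nrow(det), 20)
  expect_true(all(abs(det$time_s - (insert_at - 1) / fs) <= 1e-3))
})

test_that("the 1-ms refractory period merges close transients", {
  fs <- 12500
  set.seed(5)
  x <- rnorm(fs)
  x[6000] <- 10
  x[6005] <- 9            # 0.4 ms later: must merge into one detection
  rec <- raw_recording(rbind(x, rnorm(fs)), fs, channel_ids = c("p", "n"))
  det <- detect_spikes(rec)
  det <- det[det$unit_id == "p", ]
  expect_equal(nrow(det), 1)
  expect_equal(det$time_s, 5999 / fs, tolerance = 1e-9)
})

test_that("spike binning follows the half-open convention and conserves counts", {
  # half-open bins [0, 0.1) and [0.1, 0.2): 0.05 falls in bin 0; 0.149 and
  # 0.150 both fall in bin 1 (oracle: tabulate(floor(t / w)))
  tab <- data.frame(unit_id = "u1", time_s = c(0.05, 0.149, 0.150))
  r <- bin_spikes(tab, 0.1, duration_s = 0.2)
  expect_equal(as.numeric(r$counts),
               as.numeric(tabulate(floor(tab$time_s / 0.1) + 1, 2)))
  expect_equal(as.numeric(r$counts), c(1, 2))
  expect_equal(sum(r$counts), nrow(tab))
  # a spike exactly on a bin edge goes to the right-hand bin
  r_edge <- bin_spikes(data.frame(unit_id = "u", time_s = 0.1), 0.1,
                       duration_s = 0.2)
  expect_equal(as.numeric(r_edge$counts), c(0, 1))
  # empty table
  r0 <- bin_spikes(data.frame(unit_id = character(), time_s = numeric()),
                   0.1, duration_s = 0.5)
  expect_true(all(r0$counts == 0))
  expect_error(bin_spikes(tab, -0.1), "positive")
  # multi-unit conservation under random spikes
  set.seed(1)
  tab2 <- data.frame(unit_id = sample(letters[1:5], 200, TRUE),
                     time_s = runif(200, 0, 10))
  r2 <- bin_spikes(tab2, 0.1, duration_s = 10)
  expect_equal(sum(r2$counts), 200)
  expect_equal(nrow(r2$counts), 5)
})

test_that("population vector sums across units and conserves counts", {
  r <- spike_raster(rbind(c(1, 0), c(0, 2)), 0.1)
  pop <- population_vector(r)
  expect_equal(as.numeric(pop$counts), c(1, 2))
  one <- spike_raster(matrix(c(3, 1, 4), 1), 0.1)
  expect_equal(population_vector(one)$counts, one$counts)
  expect_equal(sum(pop$counts), sum(r$counts))
})

test_that("network-event detection matches the direct half-max scan", {
  v <- c(0, 0, 1, 8, 10, 3, rep(0, 24))
  ev <- detect_network_events(v, bin_width_s = 0.1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 0.3)               # first bin above 5 = bin 3
  expect_equal(ev$start_s, 0)                 # clipped at recording start
  expect_equal(ev$end_s, 2.8)
  expect_equal(nrow(detect_network_events(rep(0, 50), bin_width_s = 0.1)), 0)
  # a second suprathreshold run inside the first window is merged
  v2 <- c(10, rep(0, 5), 8, rep(0, 44))       # onsets at 0.0 and 0.6 s
  ev2 <- detect_network_events(v2, bin_width_s = 0.1)
  expect_equal(nrow(ev2), 1)
  # a run after the window's end opens a new event; windows never overlap
  v3 <- c(10, rep(0, 30), 9, rep(0, 30))      # onsets at 0.0 and 3.1 s
  ev3 <- detect_network_events(v3, bin_width_s = 0.1)
  expect_equal(nrow(ev3), 2)
  expect_true(all(diff(as.vector(t(ev3[, c("start_s", "end_s")]))) >= 0))
})

test_that("event extraction returns segments matching window lengths", {
  r <- spike_raster(matrix(rpois(2 * 100, 1), nrow = 2), 0.1)
  expect_length(extract_event_data(r, data.frame(onset_s = numeric(),
                                                 start_s = numeric(),
                                                 end_s = numeric())), 0)
  full <- data.frame(onset_s = 0, start_s = 0, end_s = 10)
  seg <- extract_event_data(r, full)
  expect_identical(seg[[1]]$counts, r$counts)
  w <- data.frame(onset_s = 2, start_s = 1.5, end_s = 4.5)
  seg2 <- extract_event_data(r, w)
  expect_equal(ncol(seg2[[1]]$counts), 30)    # 3 s / 0.1 s
  expect_warning(extract_event_data(
    r, data.frame(onset_s = 9.8, start_s = 9.3, end_s = 12.3)), "clipped")
})
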