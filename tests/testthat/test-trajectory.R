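test_that("the knee-frequency bounds remove extreme outliers", {
  est <- data.frame(tau_ms = c(20, 25, 30),
                    knee_freq_hz = c(0.005, 0.5, 150),
                    timepoint_days = 1)
  out <- filter_outliers(est, dataset_style = "organoid")
  expect_equal(out$kept$knee_freq_hz, 0.5)
  expect_equal(sort(out$removed$knee_freq_hz), c(0.005, 150))
  expect_equal(out$log$n_removed[out$log$stage == "knee_bounds"], 2)
  # empty input passes through
  empty <- filter_outliers(est[0, ], dataset_style = "organoid")
  expect_equal(nrow(empty$kept), 0)
})

test_that("the per-timepoint 4-SD cut removes exactly the displaced value", {
  set.seed(7)
  lt <- rnorm(50, mean = 1.3, sd = 0.05)
  # displace one value far enough that its z score (computed on the full
  # sample, outlier included) exceeds 4
  lt[50] <- 1.3 + 7 * sd(lt[1:49])
  est <- data.frame(tau_ms = 10^lt, knee_freq_hz = 1,
                    timepoint_days = 3)
  # brute-force z-score oracle
  z <- abs((lt - mean(lt)) / sd(lt))
  expect_equal(sum(z > 4), 1)
  out <- filter_outliers(est, dataset_style = "organoid")
  expect_equal(nrow(out$removed), 1)
  expect_equal(out$removed$stage, "sd_limit")
  expect_equal(out$removed$tau_ms, 10^lt[50])
  # ledger conservation at every stage
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(est))
  expect_equal(sum(out$log$n_removed), nrow(out$removed))
  # timepoints with < 3 survivors skip the SD step (and say so)
  sparse <- data.frame(tau_ms = c(1, 1e6), knee_freq_hz = 1,
                       timepoint_days = 9)
  out2 <- filter_outliers(sparse, dataset_style = "organoid")
  expect_equal(nrow(out2$kept), 2)
  expect_match(out2$log$note[out2$log$stage == "sd_limit"], "skipped")
})

test_that("the single-unit style caps timescales and averages within culture", {
  est <- data.frame(tau_ms = c(10, 20, 150, 40),
                    source_id = c("c1", "c1", "c1", "c2"),
                    timepoint_days = c(6, 6, 6, 6))
  out <- filter_outliers(est, dataset_style = "rat")
  expect_equal(out$removed$tau_ms, 150)
  expect_equal(sort(out$kept$tau_ms), c(15, 40))   # c1 mean, c2 mean
  expect_equal(nrow(out$kept), 2)
})

test_that("trajectory aggregation reports mean, SD and n per timepoint", {
  est <- data.frame(timepoint_days = c(1, 1, 1, 5, 9),
                    tau_ms = c(10, 20, 30, 7, 11))
  agg <- aggregate_trajectory(est)
  expect_equal(nrow(agg), 3)
  expect_equal(agg$mean_tau_ms, c(20, 7, 11))
  expect_equal(agg$sd_tau_ms, c(10, 0, 0))
  expect_equal(agg$n, c(3, 1, 1))
  expect_equal(agg$timepoint_days, c(1, 5, 9))
})

test_that("the constant fit is exactly the sample mean", {
  d <- data.frame(timepoint_days = 1:6, tau_ms = c(4, 4, 4, 4, 4, 4))
  fit <- fit_trajectory(d, "constant")
  expect_equal(fit$params$c, 4)
  expect_equal(fit$rss, 0)
  d2 <- data.frame(timepoint_days = 1:5, tau_ms = c(3, 9, 1, 7, 5))
  expect_equal(fit_trajectory(d2, "constant")$params$c, 5)
})

test_that("noiseless generated trajectories are recovered within 1%", {
  t <- seq(0, 300, by = 15)
  gp <- list(a = 28, mu = 240, sigma = 55, c = 9)
  dg <- data.frame(timepoint_days = t,
                   tau_ms = tau_trajectory("gaussian", gp, t))
  fg <- fit_trajectory(dg, "gaussian")
  expect_lt(abs(fg$params$mu - 240) / 240, 0.01)
  expect_lt(abs(fg$params$sigma - 55) / 55, 0.01)
  expect_lt(fg$rss, 1e-4)
  sp <- list(a = 10, b = 25, t0 = 150, s = 30)
  ds <- data.frame(timepoint_days = t,
                   tau_ms = tau_trajectory("sigmoid", sp, t))
  fs <- fit_trajectory(ds, "sigmoid")
  expect_lt(abs(fs$params$t0 - 150) / 150, 0.01)
  expect_lt(fs$rss, 1e-4)
})

test_that("nested and variance-ratio F tests follow their definitions", {
  fr <- fit_stub("constant", rss = 10, n_points = 10, n_params = 1)  # df 9
  ff <- fit_stub("gaussian", rss = 5, n_points = 10, n_params = 4)   # df 6
  cmp <- f_test(fr, ff)
  expect_equal(cmp$f_ratio, 2)                # ((10-5)/3)/(5/6)
  expect_equal(cmp$df_num, 3)
  expect_equal(cmp$df_den, 6)
  expect_equal(cmp$p_value, pf(2, 3, 6, lower.tail = FALSE))
  # identical fits: F = 0, p = 1
  same <- f_test(fit_stub("constant", 5, 10, 1), fit_stub("gaussian", 5, 10, 4))
  expect_equal(same$f_ratio, 0)
  expect_equal(same$p_value, 1)
  # zero-residual full model is flagged, not silently passed
  inf <- f_test(fr, fit_stub("gaussian", 0, 10, 4))
  expect_true(inf$flagged)
  expect_equal(inf$p_value, 0)
  # equal-complexity comparison is a two-sided variance ratio
  eq <- f_test(fit_stub("sigmoid", 6, 10, 4), fit_stub("gaussian", 6, 10, 4))
  expect_equal(eq$type, "variance_ratio")
  expect_equal(eq$f_ratio, 1)
  expect_equal(eq$p_value, 1)
  expect_error(f_test(fr, fit_stub("gaussian", 5, 12, 4)), "identical data")
})

test_that("model selection recovers the generating family on studies", {
  # gaussian truth beats constant; constant truth stays with constant
  p_gauss <- study_f_pvalue("gaussian",
                            list(a = 30, mu = 250, sigma = 60, c = 10),
                            seed = 21, noise_sd_ms = 5)
  expect_lt(p_gauss, 0.05)
  p_sig <- study_f_pvalue("sigmoid", list(a = 10, b = 25, t0 = 220, s = 30),
                          seed = 22, noise_sd_ms = 5,
                          test_family = "sigmoid")
  expect_lt(p_sig, 0.05)
})

test_that("postnatal-equivalence days follow divs - (gestation - extraction)", {
  expect_equal(postnatal_day(6), 1)
  expect_equal(postnatal_day(35), 30)
  expect_equal(postnatal_day(5), 0)
  expect_equal(postnatal_day(c(6, 35)), c(1, 30))
  expect_error(postnatal_day(4), "undefined")
  expect_equal(postnatal_day(10, gestation_days = 21, extraction_day = 18), 7)
})

test_that("endpoint comparison is a pooled-variance two-sample t test", {
  same <- compare_endpoints(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$df, 4)                    # n_a + n_b - 2
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  shifted <- compare_endpoints(a, b)
  expect_lt(shifted$p_value, 0.001)
  # closed-form oracle for the pooled t statistic
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  expect_equal(shifted$t, (mean(a) - mean(b)) / (sp * sqrt(2 / 3)))
  expect_error(compare_endpoints(1, c(1, 2)), "at least 2")
})
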