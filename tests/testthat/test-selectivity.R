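test_that("psth recovers a homogeneous rate and handles edge cases", {
  u <- make_rate_unit(list(left = list(presample = 10, sample = 10,
                                       delay = 10, response = 10),
                           right = list(presample = 10, sample = 10,
                                        delay = 10, response = 10)),
                      n_per_type = 60, seed = 2)
  ps <- psth(u, smooth_s = 0.2)
  # 10 Hz everywhere within 3 s.e. (smoothed 0.2-s window over 60 trials)
  se <- sqrt(10 / (0.2 * 60))
  expect_true(all(abs(ps$rates$left - 10) < 3 * se))

  # zero spikes -> all-zero trace
  u0 <- u; u0$spikes <- u$spikes[0, ]
  expect_true(all(psth(u0)$rates$right == 0))

  # one trial, one spike, 0.1-s bins, no smoothing -> a single 10-Hz bin
  u1 <- u
  u1$trials <- data.frame(trial_id = 1L, type = "left", outcome = "correct")
  u1$spikes <- data.frame(trial_id = 1L, t_s = -0.55)
  ps1 <- psth(u1, types = "left", bin_s = 0.1, smooth_s = 0)
  expect_equal(sum(ps1$rates$left > 0), 1L)
  expect_equal(max(ps1$rates$left), 10)
  expect_error(psth(u1, types = "right"), "no trials")
})

test_that("epoch selectivity recovers a known rate difference", {
  u <- make_rate_unit(list(left = list(presample = 10, sample = 10,
                                       delay = 10, response = 10),
                           right = list(presample = 10, sample = 10,
                                        delay = 20, response = 20)),
                      n_per_type = 30, seed = 3)
  r <- epoch_selectivity(u, epoch = "delay")
  expect_true(r$usable)
  expect_true(r$significant)
  expect_equal(r$preferred, "right")
  # 95% CI of the estimated amplitude covers the true 10 Hz
  n_est <- 15  # 30 - 15 held out per type
  se <- sqrt(20 / 1.3 / n_est + 10 / 1.3 / n_est)
  expect_lt(abs(r$amplitude_hz - 10), 1.96 * se * 1.5)
  # the trace is positive through the delay epoch
  delay_bins <- r$time >= -1.1 & r$time < 0
  expect_true(mean(r$trace[delay_bins]) > 5)
})

test_that("insufficient trials mark the unit unusable, not dropped", {
  u <- make_rate_unit(list(left = list(presample = 10, sample = 10,
                                       delay = 10, response = 10),
                           right = list(presample = 10, sample = 10,
                                        delay = 10, response = 10)),
                      n_per_type = 10, seed = 4)
  r <- epoch_selectivity(u, epoch = "delay", n_pref_trials = 15)
  expect_false(r$usable)
  expect_true(is.na(r$amplitude_hz))
})

test_that("selectivity is antisymmetric under trial-type relabelling", {
  u <- make_rate_unit(list(left = list(presample = 10, sample = 12,
                                       delay = 18, response = 25),
                           right = list(presample = 10, sample = 10,
                                        delay = 10, response = 12)),
                      n_per_type = 25, seed = 5)
  r1 <- epoch_selectivity(u, epoch = "delay")
  u2 <- u
  u2$trials$type <- ifelse(u$trials$type == "left", "right", "left")
  r2 <- epoch_selectivity(u2, epoch = "delay")
  expect_equal(r1$amplitude_hz, r2$amplitude_hz)
  expect_false(r1$preferred == r2$preferred)
  expect_equal(r1$trace, r2$trace)
})

test_that("held-out preference removes the selection bias a naive split keeps", {
  # 200 null units: the split-trial estimator is centred on zero while the
  # naive estimator (preference and estimation from the same trials) is
  # positively biased
  set.seed(10)
  n_units <- 200; n <- 60
  split_amp <- naive_amp <- numeric(n_units)
  for (i in seq_len(n_units)) {
    vals <- rpois(n, 15)
    type <- rep(c("left", "right"), n / 2)
    hs <- held_out_selectivity(vals, type, n_pref_trials = 15)
    split_amp[i] <- hs$amplitude
    mL <- mean(vals[type == "left"]); mR <- mean(vals[type == "right"])
    naive_amp[i] <- abs(mR - mL)  # preference from the same trials
  }
  expect_lt(abs(mean(split_amp)), 2 * sd(split_amp) / sqrt(n_units))
  expect_gt(mean(naive_amp), 4 * sd(naive_amp) / sqrt(n_units))
})

test_that("population selectivity equals the brute-force mean and s.e.m.", {
  mk <- function(tr) structure(list(trace = tr, time = seq_along(tr)),
                               class = "selectivity_result")
  one <- population_selectivity(list(mk(c(1, 2, 3))))
  expect_equal(one$mean, c(1, 2, 3))
  expect_equal(one$sem, c(0, 0, 0))

  two <- population_selectivity(list(mk(c(1, 2, 3)), mk(c(3, 2, 1))))
  expect_equal(two$mean, c(2, 2, 2))
  expect_equal(two$sem, abs(c(1, 2, 3) - c(3, 2, 1)) / 2)

  set.seed(11)
  traces <- lapply(1:50, function(i) mk(rnorm(40)))
  pop <- population_selectivity(traces)
  M <- do.call(rbind, lapply(traces, `[[`, "trace"))
  want_mean <- apply(M, 2, mean)
  want_sem <- apply(M, 2, function(x) sd(x) / sqrt(length(x)))
  expect_equal(pop$mean, want_mean)
  expect_equal(pop$sem, want_sem)
  expect_error(population_selectivity(list()), "no selectivity traces")
})

test_that("ramping classification distinguishes up, down, and flat units", {
  flat <- list(presample = 10, sample = 10, delay = 10, response = 10)
  up <- list(presample = 10, sample = 10, delay = 18, response = 20)
  down <- list(presample = 20, sample = 20, delay = 10, response = 8)
  u_up <- make_rate_unit(list(left = up, right = flat), 25, seed = 6)
  u_dn <- make_rate_unit(list(left = down, right = flat), 25, seed = 7)
  u_fl <- make_rate_unit(list(left = flat, right = flat), 25, seed = 10)
  expect_equal(classify_ramping(u_up)$label, "up")
  expect_equal(classify_ramping(u_dn)$label, "down")
  expect_equal(classify_ramping(u_fl)$label, "excluded")
})

test_that("units are assigned through zones to connectivity regions", {
  cfg <- gen_config(seed = 11)
  an <- gen_anatomy(cfg, n_mice = 4)
  cl <- classify_regions(
    normalized_density(an$inputs, cfg$atlas, hemisphere = "combine"),
    normalized_density(an$outputs, cfg$atlas, hemisphere = "R"))
  z <- cfg$atlas$zones
  mk_unit <- function(zone, ml) {
    zi <- match(zone, z$zone)
    list(x_um = ml, y_um = mean(c(z$ap_min_um[zi], z$ap_max_um[zi])),
         z_um = 100)
  }
  # Crus 1 at 2.0 mm lateral -> medial Crus 1 -> conjunction
  a <- assign_region(mk_unit("med-Crus 1", 2000), cl, cfg$atlas)
  expect_equal(a$zone, "med-Crus 1")
  expect_equal(a$region, "conjunction")
  # COPY -> output-dominant
  b <- assign_region(mk_unit("COPY", 2000), cl, cfg$atlas)
  expect_equal(b$region, "output-dominant")
  # outside the atlas -> unassigned
  d <- assign_region(list(x_um = 9e5, y_um = 9e5, z_um = 9e5), cl, cfg$atlas)
  expect_equal(d$region, "unassigned")
})
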