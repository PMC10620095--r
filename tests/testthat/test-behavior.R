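test_that("performance arithmetic excludes early and ignore trials", {
  tr <- data.frame(
    mouse_id = "m1", session_id = "s1", trial_id = 1:12,
    type = rep(c("left", "right"), 6), condition = "control",
    outcome = c(rep("correct", 8), "error", "error", "early", "ignore"),
    stringsAsFactors = FALSE)
  p <- performance(tr)
  row <- p[p$type == "all", ]
  expect_equal(row$performance, 0.80)
  expect_equal(row$early_frac, 1 / 12)
  expect_equal(row$ignore_frac, 1 / 12)

  tr$outcome <- "correct"
  expect_equal(performance(tr)[1, "performance"], 1.0)

  tr$outcome <- "early"
  p2 <- performance(tr)[1, ]
  expect_true(is.na(p2$performance))
  expect_equal(p2$early_frac, 1.0)
})

test_that("generated perturbation datasets match the configured truth", {
  cfg0 <- gen_config(seed = 51)
  bh0 <- gen_behavior(cfg0, n_mice = 6, sessions_per_mouse = 4,
                      trials_per_session = 300)
  expect_equal(sort(unique(bh0$spot[!is.na(bh0$spot)])),
               sprintf("spot%02d", 1:16))  # 4 x 4 grid of spots
  # null bias: per-spot deltas hover near zero
  deltas <- sapply(sprintf("spot%02d:delay", 1:16),
                   function(cc) delta_performance(bh0, cc))
  # ~75 stim trials per condition -> se(delta) ~ 0.05; max over 16 spots
  expect_lt(max(abs(deltas)), 3.5 * 0.05)
  expect_lt(abs(mean(deltas)), 0.04)

  # configured -0.20 bias on one spot/epoch is recovered within binomial se
  bias <- matrix(0, 16, 3, dimnames = list(sprintf("spot%02d", 1:16),
                                           c("sample", "delay", "response")))
  bias["spot03", "delay"] <- -0.20
  cfg <- gen_config(seed = 52, stim_bias = bias,
                    stim_conditions = "spot03:delay", perf_control = c(left = 0.8, right = 0.8))
  bh <- gen_behavior(cfg, n_mice = 8, sessions_per_mouse = 4,
                     trials_per_session = 200)
  d <- delta_performance(bh, "spot03:delay")
  n_stim <- sum(bh$condition != "control" & bh$outcome %in% c("correct", "error"))
  se <- sqrt(0.6 * 0.4 / n_stim + 0.8 * 0.2 / n_stim)
  expect_lt(abs(d - (-0.20)), 3 * se)
})

test_that("bootstrap p-value is 0.5 for an exactly zero observed change", {
  mk <- function(outs, cond) data.frame(
    mouse_id = rep(c("m1", "m2"), each = length(outs) / 2),
    session_id = rep(c("m1_s1", "m2_s1"), each = length(outs) / 2),
    trial_id = seq_along(outs), type = "left", condition = cond,
    outcome = outs, stringsAsFactors = FALSE)
  outs <- rep(c("correct", "correct", "correct", "error"), 5)
  tr <- rbind(mk(outs, "control"), mk(outs, "spot01:delay"))
  rep <- hierarchical_bootstrap(tr, "spot01:delay", n_reps = 1000, seed = 2)
  expect_equal(rep$observed_delta, 0)
  expect_equal(rep$p_value, 0.5)
  expect_error(hierarchical_bootstrap(tr, "spot09:delay", n_reps = 1000),
               "absent")
})

test_that("bootstrap p is invariant to trial order within sessions", {
  cfg <- gen_config(seed = 53, stim_conditions = "spot01:delay")
  bh <- gen_behavior(cfg, n_mice = 4, sessions_per_mouse = 3,
                     trials_per_session = 80)
  r1 <- hierarchical_bootstrap(bh, "spot01:delay", n_reps = 1000, seed = 7)
  set.seed(99)
  bh2 <- bh[sample(nrow(bh)), ]
  r2 <- hierarchical_bootstrap(bh2, "spot01:delay", n_reps = 1000, seed = 7)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$observed_delta, r2$observed_delta)
})

test_that("stronger configured effects never raise the median bootstrap p", {
  med_p <- sapply(c(0, -0.10, -0.25), function(eff) {
    ps <- sapply(1:5, function(s) {
      bias <- matrix(0, 16, 3,
                     dimnames = list(sprintf("spot%02d", 1:16),
                                     c("sample", "delay", "response")))
      bias["spot01", "delay"] <- eff
      cfg <- gen_config(seed = 600 + s, stim_bias = bias,
                        stim_conditions = "spot01:delay")
      bh <- gen_behavior(cfg, n_mice = 5, sessions_per_mouse = 3,
                         trials_per_session = 120)
      hierarchical_bootstrap(bh, "spot01:delay", n_reps = 1000,
                             seed = s)$p_value
    })
    median(ps)
  })
  expect_true(all(diff(med_p) <= 0))
})

test_that("index resampling respects the mouse-session-trial hierarchy", {
  cfg <- gen_config(seed = 54, stim_conditions = "spot01:delay")
  bh <- gen_behavior(cfg, n_mice = 3, sessions_per_mouse = 2,
                     trials_per_session = 30)
  rep <- hierarchical_bootstrap(bh, "spot01:delay", n_reps = 1000, seed = 3,
                                method = "index", audit = 20)
  sess_mouse <- unique(bh[, c("session_id", "mouse_id")])
  pool <- bh[bh$condition %in% c("control", "spot01:delay") &
               bh$outcome %in% c("correct", "error"), ]
  for (a in rep$audit) {
    # every resampled session belongs to its recorded mouse
    m <- merge(unique(a[, c("session_id", "mouse_id")]), sess_mouse,
               by = "session_id")
    expect_true(all(m$mouse_id.x == m$mouse_id.y))
    # every resampled trial exists in its session's pool, and each sampled
    # session occurrence draws exactly its observed trial count per arm
    for (s in unique(a$session_id)) {
      for (arm in unique(a$arm[a$session_id == s])) {
        drawn <- a$trial_id[a$session_id == s & a$arm == arm]
        avail <- pool$trial_id[pool$session_id == s &
          (pool$condition == "control") == (arm == "ctrl")]
        expect_true(all(drawn %in% avail))
        expect_equal(length(drawn) %% length(avail), 0)
      }
    }
  }
  expect_true(is.finite(rep$p_value))
})

test_that("BH step-up flags match the brute-force rule on fuzzed inputs", {
  set.seed(55)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))
    alpha <- sample(c(0.01, 0.025, 0.05, 0.1), 1)
    expect_identical(bh_correct(p, alpha, m), bh_bruteforce(p, alpha, m))
  }
  # worked example over the 16-spot grid: the step-up rule stops at rank 2
  p <- c(0.0005, 0.002, 0.010, rep(0.5, 13))
  expect_identical(bh_correct(p, 0.025, 16),
                   c(TRUE, TRUE, rep(FALSE, 14)))
  expect_identical(bh_correct(rep(1, 16), 0.025), rep(FALSE, 16))
  expect_identical(bh_correct(rep(0, 16), 0.025), rep(TRUE, 16))
  expect_identical(bh_correct(numeric(0)), logical(0))
})
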