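test_that("delta-rule update moves values toward feedback by the rate", {
  expect_equal(update_q(27.5, 36, rl_parameters(0)), 27.5)
  expect_equal(update_q(27.5, 36, rl_parameters(1)), 36)
  expect_equal(update_q(27.5, 36, rl_parameters(0.2)), 29.2)
  # negative prediction error selects the second rate
  expect_equal(update_q(50, 45, rl_parameters(0.3, 0.1)), 49.5)
  # a zero prediction error is routed to the positive rate (and is a no-op)
  expect_equal(update_q(40, 40, rl_parameters(0.9, 0.1)), 40)
  expect_error(rl_parameters(1.2), "\\[0, 1\\]")
  expect_error(rl_parameters(0.5, theta = -1), "theta")
})

test_that("value trajectories update both presented options under full feedback", {
  d <- default_design()
  tt <- toy_trials(pairs = "AB", feedback_cor = 40, feedback_inc = 36,
                   accuracy = 1)
  tr <- q_trajectory(tt, d, rl_parameters(0.5))
  # values entering the single trial are the initial ones
  expect_equal(tr$q_cor, 27.5)
  expect_equal(tr$q_inc, 27.5)
  expect_equal(tr$n_cor, 1L)
  expect_equal(tr$n_inc, 1L)
  # after the trial the updated values are 0.5-way toward the feedbacks
  tt2 <- toy_trials(pairs = c("AB", "AB"), feedback_cor = c(40, 40),
                    feedback_inc = c(36, 36), accuracy = c(1, 1))
  tr2 <- q_trajectory(tt2, d, rl_parameters(0.5))
  expect_equal(tr2$q_cor[2], 33.75)  # B: 27.5 + .5 (40 - 27.5)
  expect_equal(tr2$q_inc[2], 31.75)  # A: 27.5 + .5 (36 - 27.5)
  # eta = 0 freezes the trajectory
  tr0 <- q_trajectory(tt2, d, rl_parameters(0))
  expect_true(all(tr0$q_cor == 27.5) && all(tr0$q_inc == 27.5))
})

test_that("later blocks start at the grand mean of the previous block", {
  d <- default_design()
  tt <- toy_trials(pairs = c("AB", "CD", "AB"),
                   feedback_cor = c(40, 54, 40),
                   feedback_inc = c(36, 50, 36),
                   accuracy = c(1, 1, 1), block = c(1L, 1L, 2L))
  eta <- 0.5
  # independent oracle: explicit bookkeeping of the four values
  q <- rep(27.5, 4)
  q[2] <- q[2] + eta * (40 - q[2]); q[1] <- q[1] + eta * (36 - q[1])
  q[4] <- q[4] + eta * (54 - q[4]); q[3] <- q[3] + eta * (50 - q[3])
  grand <- mean(q)
  tr <- q_trajectory(tt, d, rl_parameters(eta))
  expect_equal(tr$q_cor[3], grand)
  expect_equal(tr$q_inc[3], grand)
  # per-option carry-over keeps each option's own value
  tr2 <- q_trajectory(tt, d, rl_parameters(eta), init_rule = "per_option")
  expect_equal(tr2$q_cor[3], q[2])
  expect_equal(tr2$q_inc[3], q[1])
  # presentation counts reset with the new block's new stimuli
  expect_equal(tr$n_cor[3], 1L)
})

test_that("power sensitivity follows (n/b)^c with its edge cases", {
  expect_equal(sensitivity_power(7, rl_parameters(0.5, b = 3, c = 0)), 1)
  expect_equal(sensitivity_power(3, rl_parameters(0.5, b = 3, c = 2.7)), 1)
  expect_equal(sensitivity_power(4, rl_parameters(0.5, b = 2, c = 2)), 4)
  expect_error(sensitivity_power(0, rl_parameters(0.5, b = 2, c = 2)),
               "never seen")
})

test_that("soft-max probability is symmetric, bounded and overflow-safe", {
  expect_equal(choice_probability_softmax(40, 40, 2), 0.5)
  expect_equal(choice_probability_softmax(50, 36, 0), 0.5)
  expect_equal(choice_probability_softmax(50, 36, 0.1), 1 / (1 + exp(-1.4)))
  # extreme sensitivity saturates without overflow
  expect_equal(choice_probability_softmax(50, 36, 1e6), 1)
  p <- choice_probability_softmax(36, 50, 10)
  expect_gt(p, 0); expect_lt(p, 1e-10)
})

test_that("RL log-likelihood matches a brute-force trial-by-trial oracle", {
  d <- default_design()
  set.seed(42)
  pairs <- sample(c("AB", "AC", "BD", "CD"), 10, replace = TRUE)
  fb_c <- round(rnorm(10, 50, 5)); fb_i <- round(rnorm(10, 40, 5))
  acc <- rbinom(10, 1, 0.7)
  tt <- toy_trials(pairs, fb_c, fb_i, acc)
  params <- rl_parameters(0.3, 0.2, theta = 0.08, b = 5, c = 0.6)
  opts <- c("A", "B", "C", "D")
  means <- d$option_means
  # independent loop oracle, including the dual-rate and power-theta paths
  oracle <- function(variant, prm = params) {
    q <- stats::setNames(rep(27.5, 4), opts)
    n <- stats::setNames(rep(0, 4), opts)
    ll <- 0
    for (i in seq_len(10)) {
      po <- strsplit(pairs[i], "")[[1]]
      oc <- if (means[po[1]] >= means[po[2]]) po[1] else po[2]
      oi <- setdiff(po, oc)
      n[oc] <- n[oc] + 1; n[oi] <- n[oi] + 1
      th <- if (variant %in% c(1, 3)) prm$theta
            else ((n[oc] + n[oi]) / 2 / prm$b)^prm$c
      pr <- 1 / (1 + exp(-th * (q[oc] - q[oi])))
      ll <- ll + if (acc[i] == 1) log(pr) else log(1 - pr)
      for (o in c(oc, oi)) {
        f <- if (o == oc) fb_c[i] else fb_i[i]
        eta <- if (variant %in% c(1, 2)) prm$eta_plus
               else if (f - q[o] >= 0) prm$eta_plus else prm$eta_minus
        q[o] <- q[o] + eta * (f - q[o])
      }
    }
    unname(ll)
  }
  p_single <- rl_parameters(0.3, 0.3, theta = 0.08, b = 5, c = 0.6)
  expect_equal(rl_log_likelihood(tt, d, p_single, 1), oracle(1, p_single))
  expect_equal(rl_log_likelihood(tt, d, params, 3), oracle(3))
  expect_equal(rl_log_likelihood(tt, d, params, 4), oracle(4))
  # theta = 0 collapses to coin-flip likelihood
  expect_equal(rl_log_likelihood(tt, d, rl_parameters(0.3, theta = 0), 1),
               10 * log(0.5))
  # dual-rate model with equal rates reproduces the single-rate value
  expect_identical(rl_log_likelihood(tt, d, p_single, 1),
                   rl_log_likelihood(tt, d, p_single, 3))
  expect_error(rl_log_likelihood(tt, d, params, 9), "invalid")
})

test_that("likelihood increases with sensitivity when all choices favor the leader", {
  d <- default_design()
  tt <- toy_trials(rep("BD", 8), feedback_cor = rep(54, 8),
                   feedback_inc = rep(40, 8), accuracy = rep(1, 8))
  lls <- sapply(c(0.01, 0.05, 0.1, 0.5),
                function(th) rl_log_likelihood(tt, d,
                  rl_parameters(0.3, theta = th), 1))
  expect_true(all(diff(lls) > 0))
})

test_that("value trajectories respect the convex-combination bound", {
  d <- default_design()
  set.seed(7)
  for (rep_i in 1:5) {
    pairs <- sample(c("AB", "AC", "BD", "CD"), 30, replace = TRUE)
    fb_c <- round(rnorm(30, 50, 5)); fb_i <- round(rnorm(30, 40, 5))
    tt <- toy_trials(pairs, fb_c, fb_i, rbinom(30, 1, 0.5))
    eta <- runif(2)
    tr <- q_trajectory(tt, d, rl_parameters(eta[1], eta[2]))
    lo <- min(27.5, fb_c, fb_i); hi <- max(27.5, fb_c, fb_i)
    expect_true(all(tr$q_cor >= lo & tr$q_cor <= hi))
    expect_true(all(tr$q_inc >= lo & tr$q_inc <= hi))
    # per-option presentation counts never decrease within a block
    for (p in c("AB", "AC", "BD", "CD")) {
      sel <- tt$pair == p
      expect_true(all(diff(tr$n_cor[sel]) >= 0))
      expect_true(all(diff(tr$n_inc[sel]) >= 0))
    }
  }
})
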