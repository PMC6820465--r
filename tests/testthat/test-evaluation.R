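make_small_fit <- function(seed = 2) {
  d <- default_design()
  spec <- model_spec("RLDDM", 1)
  pars <- rlddm1_subject_params(4, seed)
  tt <- simulate_experiment(d, spec, pars, 4, seed = seed + 1)
  fit <- fit_hierarchical(tt, d, spec,
                          control = hb_control(chains = 2, iter = 400,
                                               max_iter = 400,
                                               pointwise_draws = 0),
                          seed = seed)
  list(design = d, spec = spec, trials = tt, fit = fit)
}

test_that("posterior predictive summaries have the binned structure", {
  ctx <- make_small_fit()
  ppc <- posterior_predictive_check(ctx$fit, ctx$trials, n_draws = 30,
                                    seed = 5)
  expect_s3_class(ppc, "ppc_summary")
  # 4 pairs x 8 bins x 2 statistics
  expect_equal(nrow(ppc), 64)
  expect_equal(sort(unique(ppc$bin)), 1:8)
  expect_true(all(ppc$lower <= ppc$upper))
  expect_true(all(ppc$n_draws == 30))
  acc <- ppc[ppc$statistic == "accuracy", ]
  expect_true(all(acc$observed >= 0 & acc$observed <= 1))
  # a well-specified model should cover most observed cells
  covered <- mean(ppc$observed >= ppc$lower & ppc$observed <= ppc$upper)
  expect_gt(covered, 0.6)
})

test_that("regression predictors use the stated coding conventions", {
  d <- default_design()
  tt <- toy_trials(c("AB", "AC", "BD", "CD"), rep(50, 4), rep(40, 4),
                   rep(1, 4))
  X <- rlddm:::regression_predictors(tt, d)
  expect_identical(colnames(X),
                   c("intercept", "magnitude", "difficulty", "interaction"))
  # easy -> +1, difficult -> -1
  expect_equal(unname(X[, "difficulty"]), c(-1, 1, 1, -1))
  # magnitude is standardized and ordered AB < AC < BD < CD
  expect_equal(mean(X[, "magnitude"]), 0, tolerance = 1e-12)
  expect_true(all(diff(X[, "magnitude"]) > 0))
  expect_equal(unname(X[, "interaction"]),
               unname(X[, "magnitude"] * X[, "difficulty"]))
  # invariance to affine recoding of the raw magnitude before scaling
  d2 <- bandit_design(option_means = c(A = 72, B = 80, C = 100, D = 108),
                      option_sd = 10)
  tt2 <- tt
  X2 <- rlddm:::regression_predictors(tt2, d2)
  expect_equal(X2[, "magnitude"], X[, "magnitude"])
})

test_that("injected effects are detected and the package agrees with an
           external sampler on the same regression", {
  d <- default_design()
  spec <- model_spec("RLDDM", 7)
  tt <- simulate_experiment(d, spec,
                            list(eta = 0.15, v_mod = 0.3, v_max = 2.5,
                                 a_fix = 1.5, a_mod = -0.02, t_er = 0.3),
                            12, seed = 44)
  ctl <- hb_control(iter = 800, max_iter = 800, pointwise_draws = 0)
  rt_res <- fit_rt_regression(tt, d, ctl, seed = 2)
  # negative threshold modulation produces a negative magnitude effect on
  # log response times
  mag <- rt_res[rt_res$coefficient == "magnitude", ]
  expect_lt(mag$upper, 0)
  acc_res <- fit_accuracy_regression(tt, d, ctl, seed = 2)
  # learned value differences make easy pairs more accurate
  diffc <- acc_res[acc_res$coefficient == "difficulty", ]
  expect_gt(diffc$lower, 0)

  # independent oracle: the same hierarchical logistic regression fit with
  # JAGS gives matching group coefficients
  library(rjags)
  kept <- tt[!tt$excluded, ]
  X <- rlddm:::regression_predictors(kept, d)
  model_txt <- "model {
    for (i in 1:N) {
      y[i] ~ dbern(ilogit(inprod(X[i,], beta[subj[i],])))
    }
    for (s in 1:S) {
      for (k in 1:4) { beta[s,k] ~ dnorm(mu[k], tau[k]) }
    }
    for (k in 1:4) {
      mu[k] ~ dnorm(0, 0.25)
      tau[k] <- pow(sd[k], -2)
      sd[k] ~ dnorm(0, 1) T(0,)
    }
  }"
  jd <- list(y = kept$accuracy, X = X,
             subj = as.integer(factor(kept$subject)),
             N = nrow(kept), S = length(unique(kept$subject)))
  m <- jags.model(textConnection(model_txt), data = jd, n.chains = 2,
                  quiet = TRUE)
  update(m, 1500, progress.bar = "none")
  s <- coda.samples(m, "mu", 3000, progress.bar = "none")
  jags_mu <- colMeans(as.matrix(s))
  expect_equal(unname(acc_res$mean), unname(jags_mu), tolerance = 0.12)
})

test_that("null data leave all regression effects straddling zero", {
  d <- default_design()
  tt <- simulate_experiment(d, model_spec("RLDDM", 1),
                            list(eta = 0, v_mod = 0.1, a = 2, t_er = 0.3),
                            10, seed = 99)
  ctl <- hb_control(iter = 600, max_iter = 600, pointwise_draws = 0)
  acc_res <- fit_accuracy_regression(tt, d, ctl, seed = 3)
  rt_res <- fit_rt_regression(tt, d, ctl, seed = 3)
  eff <- c("magnitude", "difficulty", "interaction")
  expect_false(any(acc_res$excludes_zero[acc_res$coefficient %in% eff]))
  expect_false(any(rt_res$excludes_zero[rt_res$coefficient %in% eff]))
  expect_error(fit_accuracy_regression(tt[tt$subject == 1, ], d, ctl),
               ">= 2 subjects")
})

test_that("recovery reports flag degenerate generating distributions", {
  d <- default_design()
  spec <- model_spec("RL", 1)
  mu <- c(eta = stats::qlogis(0.2), theta = log(0.1))
  sg0 <- c(eta = 0, theta = 0)  # identical subjects
  rep0 <- parameter_recovery_study(spec, d, mu, sg0, n_subjects = 6,
                                   n_replications = 1, seed = 5,
                                   control = hb_control(chains = 2,
                                                        iter = 300,
                                                        max_iter = 300,
                                                        pointwise_draws = 0))
  expect_s3_class(rep0, "recovery_report")
  expect_equal(nrow(rep0), 2)
  expect_true(all(is.na(rep0$rank_correlation)))
  expect_identical(rep0$generating, unname(mu[rep0$parameter]))
  # reproducible bit-for-bit under a fixed seed
  rep1 <- parameter_recovery_study(spec, d, mu, sg0, n_subjects = 6,
                                   n_replications = 1, seed = 5,
                                   control = hb_control(chains = 2,
                                                        iter = 300,
                                                        max_iter = 300,
                                                        pointwise_draws = 0))
  expect_identical(rep0, rep1)
})
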