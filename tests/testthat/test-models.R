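test_that("only the cataloged model variants are constructible", {
  cat_all <- model_catalog()
  expect_equal(sum(cat_all$model_class == "RL"), 4)
  expect_equal(sum(cat_all$model_class == "DDM"), 3)
  expect_equal(sum(cat_all$model_class == "RLDDM"), 8)
  expect_equal(sum(cat_all$model_class == "PedersenRLDDM"), 4)
  for (i in seq_len(nrow(cat_all))) {
    s <- model_spec(cat_all$model_class[i], cat_all$variant[i])
    expect_s3_class(s, "model_spec")
    expect_true(length(s$param_names) >= 2)
  }
  expect_error(model_spec("RLDDM", 9), "no such model")
  expect_error(model_spec("RL", 0), "no such model")
})

test_that("drift mappings follow their defining forms", {
  expect_equal(drift_linear(40, 40, 0.5), 0)
  expect_equal(drift_linear(50, 36, 0.1), 1.4)
  expect_equal(drift_linear(36, 50, 0.1), -drift_linear(50, 36, 0.1))
  expect_equal(drift_sigmoid(40, 40, 0.5, 3), 0)
  expect_equal(drift_sigmoid(42, 40, 0.5, 3), 6 / (1 + exp(-1)) - 3)
  expect_equal(drift_sigmoid(40, 42, 0.5, 3), -drift_sigmoid(42, 40, 0.5, 3))
  # saturation at +/- v_max
  expect_equal(drift_sigmoid(1e3, 0, 1, 2.5), 2.5, tolerance = 1e-12)
  expect_equal(drift_sigmoid(0, 1e3, 1, 2.5), -2.5, tolerance = 1e-12)
  expect_error(drift_sigmoid(1, 0, 1, -2), "v_max")
})

test_that("threshold rules stay positive and reduce as advertised", {
  expect_equal(threshold_value_modulated(0.5, 0, 50), exp(0.5))
  expect_equal(threshold_value_modulated(0.5, -0.02, 50), exp(-0.5))
  qb <- seq(20, 60, by = 10)
  th <- threshold_value_modulated(0.5, -0.05, qb)
  expect_true(all(diff(th) < 0) && all(th > 0))
  pm <- pedersen_trial_modulators(1:10, 2, 0.5, 0, 0)
  expect_true(all(pm$threshold == 2) && all(pm$drift_scale == 0.5))
  expect_equal(pedersen_trial_modulators(4, 2, 1, 0.5, 0)$threshold, 1)
  pm2 <- pedersen_trial_modulators(1:10, 2, 0.5, 0.3, 0.2)
  expect_true(all(diff(pm2$threshold) <= 0))
  expect_true(all(diff(pm2$drift_scale) >= 0))
  expect_error(pedersen_trial_modulators(0, 2, 1, 0.5, 0), ">= 1")
})

test_that("trialwise parameters implement the nesting identities", {
  d <- default_design()
  set.seed(3)
  pairs <- sample(c("AB", "AC", "BD", "CD"), 20, replace = TRUE)
  tt <- toy_trials(pairs, round(rnorm(20, 50, 5)), round(rnorm(20, 40, 5)),
                   rbinom(20, 1, 0.7), rt = runif(20, 0.5, 2))
  base <- list(eta = 0.2, v_mod = 0.1, a = 1.8, t_er = 0.3)
  tw1 <- build_trialwise_parameters(tt, d, model_spec("RLDDM", 1), base)
  # value-modulated threshold with a_mod = 0 reproduces the fixed threshold
  tw3 <- build_trialwise_parameters(tt, d, model_spec("RLDDM", 3),
                                    list(eta = 0.2, v_mod = 0.1,
                                         a_fix = log(1.8), a_mod = 0,
                                         t_er = 0.3))
  expect_equal(tw3$v, tw1$v)
  expect_equal(tw3$a, tw1$a)
  # dual-rate spec with equal rates is bit-identical to the single rate
  tw2 <- build_trialwise_parameters(tt, d, model_spec("RLDDM", 2),
                                    list(eta_plus = 0.2, eta_minus = 0.2,
                                         v_mod = 0.1, a = 1.8, t_er = 0.3))
  expect_identical(tw2$v, tw1$v)
  # the sigmoid mapping flattens to the linear one as v_max grows: around
  # zero S(z) ~ v_max z / 2, so the matched sigmoid scaling is 2 v_mod/v_max
  v_max <- 1e6
  tw5 <- build_trialwise_parameters(tt, d, model_spec("RLDDM", 5),
                                    list(eta = 0.2,
                                         v_mod = 2 * 0.1 / v_max,
                                         v_max = v_max, a = 1.8, t_er = 0.3))
  expect_true(max(abs(tw5$v - tw1$v)) < 1e-3)
  # zero learning with equal initial values gives flat zero drift
  tw0 <- build_trialwise_parameters(tt, d, model_spec("RLDDM", 1),
                                    list(eta = 0, v_mod = 0.1, a = 1.8,
                                         t_er = 0.3))
  expect_true(all(tw0$v == 0) && all(tw0$a == 1.8))
  expect_error(build_trialwise_parameters(tt, d, model_spec("RLDDM", 5),
                                          base), "v_max")
})

test_that("joint likelihood matches a per-trial loop oracle and nests the static model", {
  d <- default_design()
  set.seed(4)
  pairs <- sample(c("AB", "AC", "BD", "CD"), 10, replace = TRUE)
  tt <- toy_trials(pairs, round(rnorm(10, 50, 5)), round(rnorm(10, 40, 5)),
                   rbinom(10, 1, 0.7), rt = runif(10, 0.6, 2))
  spec <- model_spec("RLDDM", 7)
  params <- list(eta = 0.25, v_mod = 0.3, v_max = 2.5, a_fix = 0.6,
                 a_mod = -0.01, t_er = 0.3)
  tw <- build_trialwise_parameters(tt, d, spec, params)
  oracle <- sum(vapply(seq_len(10), function(i)
    wfpt_log_density(tt$rt[i], tt$accuracy[i],
                     ddm_parameters(tw$v[i], tw$a[i], params$t_er)),
    numeric(1)))
  expect_equal(rlddm_log_likelihood(tt, d, spec, params), oracle)
  # with zero learning the model is a constant-parameter diffusion model
  spec1 <- model_spec("RLDDM", 1)
  p0 <- list(eta = 0, v_mod = 0.1, a = 1.8, t_er = 0.3)
  ll_static <- sum(wfpt_log_density(tt$rt, tt$accuracy,
                                    ddm_parameters(0, 1.8, 0.3)))
  expect_equal(rlddm_log_likelihood(tt, d, spec1, p0), ll_static)
  # t_er at or above the smallest response time yields -Inf, not an error
  expect_identical(rlddm_log_likelihood(tt, d, spec1,
                                        list(eta = 0.2, v_mod = 0.1, a = 1.8,
                                             t_er = min(tt$rt))), -Inf)
})

test_that("all nineteen variants yield finite likelihoods on their own data", {
  d <- default_design()
  cat_all <- model_catalog()
  base_params <- list(
    RL = list(eta = 0.2, eta_plus = 0.25, eta_minus = 0.15, theta = 0.1,
              b = 5, c = 0.5),
    DDM = list(v_easy = 1.2, v_difficult = 0.4, a = 1.8, t_er = 0.3,
               v_AB = 0.4, v_AC = 1.2, v_BD = 1.2, v_CD = 0.4,
               a_AB = 2, a_AC = 1.9, a_BD = 1.8, a_CD = 1.7),
    RLDDM = list(eta = 0.2, eta_plus = 0.25, eta_minus = 0.15, v_mod = 0.1,
                 v_max = 2.5, a = 1.8, a_fix = 0.6, a_mod = -0.005,
                 t_er = 0.3),
    PedersenRLDDM = list(eta = 0.2, eta_plus = 0.25, eta_minus = 0.15,
                         v_mod = 0.1, d_m = 0.2, a_base = 2.2, d_a = 0.15,
                         t_er = 0.3))
  for (i in seq_len(nrow(cat_all))) {
    spec <- model_spec(cat_all$model_class[i], cat_all$variant[i])
    params <- base_params[[spec$model_class]][
      if (spec$model_class == "DDM") {
        cmap <- ddm_condition_map(d, spec$variant)
        c(unique(unname(cmap$v_conditions)),
          unique(unname(cmap$a_conditions)), "t_er")
      } else spec$param_names]
    tt <- simulate_experiment(d, spec, params, n_subjects = 1,
                              seed = 100 + i)
    s1 <- tt[tt$subject == 1, ]
    ll <- if (spec$model_class == "RL") {
      rlp <- if (spec$n_learning_rates == 1)
        rl_parameters(params$eta, theta = params$theta, b = params$b,
                      c = params$c)
      else
        rl_parameters(params$eta_plus, params$eta_minus,
                      theta = params$theta, b = params$b, c = params$c)
      rl_log_likelihood(s1, d, rlp, spec$variant)
    } else if (spec$model_class == "DDM") {
      ddm_log_likelihood(s1, d, params, spec$variant)
    } else {
      rlddm_log_likelihood(s1, d, spec, params)
    }
    expect_true(is.finite(ll), label = paste(spec$label, "finite loglik"))
  }
})

test_that("simulated experiments show learning and magnitude effects", {
  d <- default_design()
  # learning effect: accuracy rises within a block when values are learned
  tt <- simulate_experiment(d, model_spec("RLDDM", 1),
                            list(eta = 0.15, v_mod = 0.1, a = 1.8,
                                 t_er = 0.3), n_subjects = 50, seed = 60)
  kept <- tt[!tt$excluded, ]
  early <- kept$trial <= 20; late <- kept$trial > 60
  expect_gt(mean(kept$accuracy[late]), mean(kept$accuracy[early]))
  expect_lt(mean(kept$rt[late]), mean(kept$rt[early]))
  # magnitude effect: negative threshold modulation speeds up high-value
  # pairs without a matching accuracy gain
  tt2 <- simulate_experiment(d, model_spec("RLDDM", 7),
                             list(eta = 0.15, v_mod = 0.3, v_max = 2.5,
                                  a_fix = 1.5, a_mod = -0.02, t_er = 0.3),
                             n_subjects = 50, seed = 61)
  kept2 <- tt2[!tt2$excluded, ]
  rt_pair <- tapply(kept2$rt, kept2$pair, mean)
  expect_lt(rt_pair[["CD"]], rt_pair[["AB"]])
  # no learning signal: accuracy stays at chance in every bin
  tt0 <- simulate_experiment(d, model_spec("RLDDM", 1),
                             list(eta = 0, v_mod = 0.1, a = 2, t_er = 0.3),
                             n_subjects = 50, seed = 62)
  kept0 <- tt0[!tt0$excluded, ]
  bins <- ceiling(kept0$trial / 10)
  acc_bin <- tapply(kept0$accuracy, bins, mean)
  n_bin <- tapply(kept0$accuracy, bins, length)
  expect_true(all(abs(acc_bin - 0.5) < 3 * sqrt(0.25 / n_bin)))
})

test_that("simulation is reproducible and reuses one payoff multiset", {
  d <- default_design()
  spec <- model_spec("RLDDM", 1)
  pars <- list(eta = 0.1, v_mod = 0.1, a = 1.8, t_er = 0.3)
  t1 <- simulate_experiment(d, spec, pars, 3, seed = 9)
  t2 <- simulate_experiment(d, spec, pars, 3, seed = 9)
  expect_identical(t1, t2)
  # every subject sees the same multiset of feedbacks per block and option
  fb <- function(tab, s, b, o) {
    rows <- tab[tab$subject == s & tab$block == b &
                (tab$option_left == o | tab$option_right == o), ]
    sort(ifelse(rows$chosen_option == o, rows$feedback_chosen,
                rows$feedback_unchosen))
  }
  for (o in c("A", "D"))
    expect_identical(fb(t1, 1, 1, o), fb(t1, 2, 1, o))
})
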