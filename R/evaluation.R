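#' Posterior predictive check of learning curves
#'
#' Samples parameter sets from the joint posterior, simulates one full
#' dataset per set using each subject's own feedback stream and trial order
#' (under full feedback the value trajectory depends only on the design's
#' feedback, not on the simulated choices), and summarizes mean accuracy and
#' mean response time per option pair and per trial bin, alongside the
#' observed means. Trials within each block are cut into `n_bins` equal
#' consecutive bins by within-block trial number (8 bins of 10 trials under
#' the default design), and each pair's trials falling in a bin are
#' aggregated across blocks and subjects.
#'
#' @param fit An `rlddm_fit`.
#' @param trials The observed (validated, filtered) trial table the model
#'   was fit to.
#' @param n_draws Number of posterior parameter sets / predictive datasets
#'   (default 500).
#' @param n_bins Number of within-block trial bins (default 8).
#' @param seed Integer seed for drawing parameter sets and simulating.
#' @param dt,max_time Accumulator simulation settings.
#' @param prob Mass of the predictive credible band (default 0.95).
#' @return A data.frame of class `ppc_summary`: `pair`, `bin`, `statistic`
#'   (`"accuracy"` / `"rt"`), `observed`, `predicted_mean`, `lower`,
#'   `upper`, `n_draws`.
#' @export
posterior_predictive_check <- function(fit, trials, n_draws = 500,
                                       n_bins = 8, seed = 1, dt = 0.001,
                                       max_time = 5, prob = 0.95) {
  spec <- fit$spec
  design <- fit$design
  set.seed(as.integer(seed))
  subjects <- prepare_subjects(trials, design, spec)
  n_keep <- dim(fit$subject)[1]; chains <- dim(fit$subject)[2]
  total <- n_keep * chains
  idx <- if (total >= n_draws) sample.int(total, n_draws)
         else sample.int(total, n_draws, replace = TRUE)
  bin_width <- design$trials_per_block / n_bins
  pair_all <- unlist(lapply(subjects, `[[`, "pair"))
  bin_all <- unlist(lapply(subjects, function(d)
    ceiling(d$t_in_block / bin_width)))
  g <- interaction(pair_all, bin_all, drop = TRUE)
  acc_mat <- matrix(NA_real_, nlevels(g), n_draws)
  rt_mat <- matrix(NA_real_, nlevels(g), n_draws)
  pnames <- dimnames(fit$subject)[[4]]
  for (r in seq_len(n_draws)) {
    it <- (idx[r] - 1) %% n_keep + 1
    ch <- (idx[r] - 1) %/% n_keep + 1
    acc_sim <- rt_sim <- keep_sim <- vector("list", length(subjects))
    for (s in seq_along(subjects)) {
      d <- subjects[[s]]
      th <- stats::setNames(fit$subject[it, ch, s, ], pnames)
      sim <- simulate_responses(d, spec, design, th, dt, max_time,
                                fit$initial_value, fit$init_rule)
      acc_sim[[s]] <- sim$acc; rt_sim[[s]] <- sim$rt; keep_sim[[s]] <- sim$keep
    }
    acc_v <- unlist(acc_sim); rt_v <- unlist(rt_sim); keep <- unlist(keep_sim)
    acc_mat[, r] <- tapply(acc_v[keep], g[keep], mean)[levels(g)]
    if (!all(is.na(rt_v)))
      rt_mat[, r] <- tapply(rt_v[keep], g[keep], mean)[levels(g)]
  }
  obs_keep <- unlist(lapply(subjects, `[[`, "included"))
  obs_acc <- unlist(lapply(subjects, `[[`, "acc"))
  obs_rt <- unlist(lapply(subjects, `[[`, "rt"))
  obs_acc_g <- tapply(obs_acc[obs_keep], g[obs_keep], mean)[levels(g)]
  obs_rt_g <- tapply(obs_rt[obs_keep], g[obs_keep], mean)[levels(g)]
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  lab <- do.call(rbind, strsplit(levels(g), ".", fixed = TRUE))
  mk <- function(statistic, obs, mat) data.frame(
    pair = lab[, 1], bin = as.integer(lab[, 2]), statistic = statistic,
    observed = as.numeric(obs),
    predicted_mean = rowMeans(mat),
    lower = apply(mat, 1, stats::quantile, qs[1], na.rm = TRUE),
    upper = apply(mat, 1, stats::quantile, qs[2], na.rm = TRUE),
    n_draws = n_draws, row.names = NULL)
  out <- rbind(mk("accuracy", obs_acc_g, acc_mat),
               if (spec$model_class != "RL") mk("rt", obs_rt_g, rt_mat))
  out <- out[order(out$statistic, out$pair, out$bin), ]
  rownames(out) <- NULL
  class(out) <- c("ppc_summary", "data.frame")
  out
}

# simulate choices (and RTs for diffusion specs) along an observed trial
# stream; returns accuracy, rt and the retained-trial filter
simulate_responses <- function(d, spec, design, th, dt, max_time,
                               initial_value, init_rule) {
  thl <- as.list(th)
  if (spec$model_class == "RL") {
    rlp <- expand_eta(spec, thl)
    tr <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                     rlp$eta_plus, rlp$eta_minus, initial_value,
                     init_rule == "grand_mean", length(design$option_means))
    theta <- if (spec$sensitivity_rule == "fixed") thl$theta
             else ((tr$n_cor + tr$n_inc) / 2 / thl$b)^thl$c
    p <- stats::plogis(theta * (tr$q_cor - tr$q_inc))
    list(acc = as.integer(stats::runif(length(p)) < p),
         rt = rep(NA_real_, length(p)), keep = rep(TRUE, length(p)))
  } else {
    if (spec$model_class == "DDM") {
      v <- as.numeric(unlist(thl[d$v_par]))
      a <- as.numeric(unlist(thl[d$a_par]))
    } else {
      rlp <- expand_eta(spec, thl)
      tr <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                       rlp$eta_plus, rlp$eta_minus, initial_value,
                       init_rule == "grand_mean", length(design$option_means))
      tw <- trialwise_from_traj(d, tr, spec, thl)
      v <- tw$v; a <- tw$a
    }
    fp <- sim_fp_cpp(v, a, thl$t_er, dt, max_time)
    keep <- !fp$censored & !is.na(fp$rt) &
      fp$rt >= design$rt_floor & fp$rt <= design$rt_ceiling
    list(acc = fp$upper, rt = fp$rt, keep = keep)
  }
}

regression_predictors <- function(trials, design) {
  ps <- pair_statistics(design)
  mag <- stats::setNames(ps$magnitude, ps$pair)[trials$pair]
  diffc <- stats::setNames(ifelse(ps$difficulty == "easy", 1, -1),
                           ps$pair)[trials$pair]
  mag_std <- as.numeric(scale(mag))
  cbind(intercept = 1, magnitude = mag_std, difficulty = diffc,
        interaction = mag_std * diffc)
}

regression_result <- function(sample, coef_names, prob = 0.95) {
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  rows <- lapply(coef_names, function(p) {
    x <- as.vector(sample$group[, , paste0("mu_", p)])
    lo <- stats::quantile(x, qs[1]); hi <- stats::quantile(x, qs[2])
    data.frame(coefficient = p, mean = mean(x), lower = lo, upper = hi,
               excludes_zero = lo > 0 | hi < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Hierarchical logistic regression of accuracy on design predictors
#'
#' Regresses trialwise accuracy (1 = higher-mean option chosen) on
#' standardized pair magnitude, difficulty coded +1 (easy) / -1
#' (difficult), and their interaction, with subject-level intercepts and
#' slopes drawn from group-level normals. Trial number is deliberately not
#' a predictor. Group coefficients are summarized by their posterior mean
#' and central 95% interval; an effect is flagged when the interval
#' excludes 0.
#'
#' @param trials Validated, filtered trial table (>= 2 subjects).
#' @param design The [bandit_design()].
#' @param control An [hb_control()].
#' @param seed Integer seed.
#' @return A `regression_result` data.frame with the fitted `rlddm_fit`-like
#'   sample as attribute `fit`.
#' @export
fit_accuracy_regression <- function(trials, design, control = hb_control(),
                                    seed = 1) {
  kept <- trials[!trials$excluded & !is.na(trials$accuracy), , drop = FALSE]
  ids <- sort(unique(kept$subject))
  if (length(ids) < 2) stop("hierarchical regression needs >= 2 subjects")
  X_all <- regression_predictors(kept, design)
  coef_names <- colnames(X_all)
  subjects <- lapply(ids, function(s) {
    sel <- kept$subject == s
    list(X = X_all[sel, , drop = FALSE], y = kept$accuracy[sel])
  })
  loglik <- function(d, th) {
    p <- stats::plogis(drop(d$X %*% th[coef_names]))
    sum(ifelse(d$y == 1, log(p), log1p(-p)))
  }
  links <- stats::setNames(rep("identity", length(coef_names)), coef_names)
  uppers <- matrix(NA_real_, length(subjects), length(links))
  smp <- hb_sample_converging(subjects, loglik, links, uppers, control, seed)
  out <- regression_result(smp, coef_names)
  attr(out, "fit") <- smp
  out
}

#' Hierarchical linear regression of log response times
#'
#' Same predictors and coding as [fit_accuracy_regression()], applied to
#' log-transformed retained response times with a subject-level residual
#' SD (log link).
#'
#' @inheritParams fit_accuracy_regression
#' @return A `regression_result` data.frame.
#' @export
fit_rt_regression <- function(trials, design, control = hb_control(),
                              seed = 1) {
  kept <- trials[!trials$excluded & !is.na(trials$rt), , drop = FALSE]
  if (any(kept$rt <= 0)) stop("non-positive response times")
  ids <- sort(unique(kept$subject))
  if (length(ids) < 2) stop("hierarchical regression needs >= 2 subjects")
  X_all <- regression_predictors(kept, design)
  coef_names <- colnames(X_all)
  subjects <- lapply(ids, function(s) {
    sel <- kept$subject == s
    list(X = X_all[sel, , drop = FALSE], y = log(kept$rt[sel]))
  })
  loglik <- function(d, th) {
    mu <- drop(d$X %*% th[coef_names])
    sum(stats::dnorm(d$y, mu, th[["resid_sd"]], log = TRUE))
  }
  links <- stats::setNames(c(rep("identity", length(coef_names)), "log"),
                           c(coef_names, "resid_sd"))
  uppers <- matrix(NA_real_, length(subjects), length(links))
  smp <- hb_sample_converging(subjects, loglik, links, uppers, control, seed)
  out <- regression_result(smp, coef_names)
  attr(out, "fit") <- smp
  out
}

# shared convergence-retry loop around the raw sampler
hb_sample_converging <- function(subjects, loglik, links, uppers, control,
                                 seed) {
  n_iter <- control$iter
  repeat {
    res <- hb_sample(subjects, loglik, links, uppers, control, seed, n_iter)
    converged <- all(is.finite(res$rhat)) && all(res$rhat <= control$rhat_tol)
    if (converged || n_iter >= control$max_iter) break
    n_iter <- min(2 * n_iter, control$max_iter)
  }
  res$converged <- converged
  res$n_iter <- n_iter
  res
}

#' Parameter recovery study by simulation and refitting
#'
#' For each replication, subject-level parameters are drawn from generating
#' group distributions on the unconstrained scale, an experiment is
#' simulated with [simulate_experiment()], the model is refit with
#' [fit_hierarchical()], and the report records whether each group-mean 95%
#' interval covers its generating value, together with the Spearman rank
#' correlation between generating and recovered subject-level parameters.
#'
#' @param spec A [model_spec()] with both a simulator and a likelihood.
#' @param design A [bandit_design()].
#' @param group_mu,group_sigma Named vectors of generating group means and
#'   SDs on the unconstrained scale, one entry per parameter of the spec.
#' @param n_subjects Subjects per replication.
#' @param n_replications Number of replications.
#' @param seed Integer seed.
#' @param control An [hb_control()] for the refits.
#' @return A data.frame of class `recovery_report`, one row per
#'   (replication, parameter): generating value, posterior mean and 95%
#'   interval of the group mean, coverage indicator, subject-level rank
#'   correlation (NA when the generating SD is 0), and the fit's
#'   convergence flag.
#' @export
parameter_recovery_study <- function(spec, design, group_mu, group_sigma,
                                     n_subjects, n_replications, seed,
                                     control = hb_control()) {
  priors <- default_priors(spec, design)
  links <- stats::setNames(priors$link, priors$name)
  stopifnot(all(names(links) %in% names(group_mu)),
            all(names(links) %in% names(group_sigma)))
  rows <- list()
  for (rep_i in seq_len(n_replications)) {
    rep_seed <- as.integer(seed) + 1009L * rep_i
    set.seed(rep_seed)
    z <- sapply(names(links), function(p)
      stats::rnorm(n_subjects, group_mu[[p]], group_sigma[[p]]))
    nat <- as.data.frame(sapply(names(links), function(p)
      link_inverse(z[, p], links[p],
                   if (!is.na(priors$upper[priors$name == p]))
                     priors$upper[priors$name == p] else NA_real_)))
    trials <- simulate_experiment(design, spec, nat, n_subjects, rep_seed)
    fit <- tryCatch(
      fit_hierarchical(trials, design, spec, priors, control, rep_seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        replication = rep_i, parameter = names(links),
        generating = unname(group_mu[names(links)]),
        estimate = NA_real_, lower = NA_real_, upper = NA_real_,
        covered = NA, rank_correlation = NA_real_, converged = FALSE,
        error = conditionMessage(fit))
      next
    }
    for (p in names(links)) {
      ci <- bci(fit, paste0("mu_", p))
      est_subj <- apply(fit$subject[, , , p, drop = FALSE], 3, mean)
      rc <- if (group_sigma[[p]] > 0)
        stats::cor(est_subj, nat[[p]], method = "spearman") else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        replication = rep_i, parameter = p,
        generating = unname(group_mu[[p]]),
        estimate = mean(fit$group[, , paste0("mu_", p)]),
        lower = ci[1], upper = ci[2],
        covered = ci[1] <= group_mu[[p]] && group_mu[[p]] <= ci[2],
        rank_correlation = rc, converged = fit$converged,
        error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recovery_report", "data.frame")
  out
}
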