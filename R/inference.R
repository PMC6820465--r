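#' Default link and prior table for a model specification
#'
#' Each parameter samples on an unconstrained scale and maps to its support
#' through a link: logit for learning rates, log for positive-only
#' parameters (sensitivities, thresholds, asymptotic drift, power
#' exponents), identity for unbounded ones (drift scalings, threshold
#' intercept and modulation, condition drifts), and a scaled logit with a
#' fixed upper bound (default 1 s, column `upper`) for the non-decision
#' time; proposals with `t_er` at or above a subject's fastest retained
#' response are rejected through a `-Inf` likelihood. Group means get wide
#' normal priors on the unconstrained scale and group SDs half-normal
#' priors.
#'
#' @param spec A [model_spec()].
#' @param design The [bandit_design()] (determines condition-parameter names
#'   for static DDM variants).
#' @return A data.frame with columns `name` and `link`.
#' @export
default_priors <- function(spec, design = bandit_design()) {
  names <- if (spec$model_class == "DDM") {
    cmap <- ddm_condition_map(design, spec$variant)
    c(unique(unname(cmap$v_conditions)), unique(unname(cmap$a_conditions)),
      "t_er")
  } else {
    spec$param_names
  }
  link <- vapply(names, link_for_param, character(1))
  data.frame(name = names, link = link,
             upper = ifelse(link == "scaledlogit", 1.0, NA_real_),
             row.names = NULL)
}

link_for_param <- function(name) {
  if (name %in% c("eta", "eta_plus", "eta_minus")) return("logit")
  if (name == "t_er") return("scaledlogit")
  if (name %in% c("theta", "b", "c", "v_max", "a", "a_base", "d_a", "d_m") ||
      grepl("^a_[A-Z]{2}$", name)) return("log")
  "identity"  # v_mod, a_fix, a_mod, condition drifts
}

# likelihood closure over prepared per-subject data, dispatched on class
make_subject_loglik <- function(spec, design, initial_value, init_rule,
                                pointwise = FALSE) {
  n_opts <- length(design$option_means)
  grand <- init_rule == "grand_mean"
  agg <- if (pointwise) identity else sum
  if (spec$model_class == "RL") {
    function(d, th) {
      rlp <- expand_eta(spec, as.list(th))
      tr <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                       rlp$eta_plus, rlp$eta_minus, initial_value, grand,
                       n_opts)
      theta <- if (spec$sensitivity_rule == "fixed") th[["theta"]]
               else ((tr$n_cor + tr$n_inc) / 2 / th[["b"]])^th[["c"]]
      p <- stats::plogis(theta * (tr$q_cor - tr$q_inc))[d$included]
      agg(ifelse(d$acc[d$included] == 1, log(p), log1p(-p)))
    }
  } else if (spec$model_class == "DDM") {
    function(d, th) {
      ter <- th[["t_er"]]
      if (ter >= d$min_rt) return(if (pointwise) rep(-Inf, sum(d$included)) else -Inf)
      v <- th[d$v_par][d$included]
      a <- th[d$a_par][d$included]
      agg(wfpt_logdens_cpp(d$rt[d$included], d$acc[d$included], v, a, ter,
                           0.5, 1e-10))
    }
  } else {
    function(d, th) {
      ter <- th[["t_er"]]
      if (ter >= d$min_rt) return(if (pointwise) rep(-Inf, sum(d$included)) else -Inf)
      thl <- as.list(th)
      rlp <- expand_eta(spec, thl)
      tr <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                       rlp$eta_plus, rlp$eta_minus, initial_value, grand,
                       n_opts)
      tw <- trialwise_from_traj(d, tr, spec, thl)
      agg(wfpt_logdens_cpp(d$rt[d$included], d$acc[d$included],
                           tw$v[d$included], tw$a[d$included], ter, 0.5,
                           1e-10))
    }
  }
}

prepare_subjects <- function(trials, design, spec) {
  ids <- sort(unique(trials$subject))
  cmap <- if (spec$model_class == "DDM") ddm_condition_map(design, spec$variant)
  lapply(ids, function(s) {
    ts <- trials[trials$subject == s, , drop = FALSE]
    d <- prepare_model_data(ts, design)
    # choice-only models score every non-excluded trial, with or without RT
    if (spec$model_class == "RL") d$included <- !ts$excluded
    d$min_rt <- if (any(d$included & !is.na(d$rt)))
      min(d$rt[d$included], na.rm = TRUE) else Inf
    if (!is.null(cmap)) {
      d$v_par <- cmap$v_conditions[d$pair]
      d$a_par <- cmap$a_conditions[d$pair]
    }
    d
  })
}

#' Fit a hierarchical Bayesian model to a trial table
#'
#' Subject-level parameters are drawn from group-level normal distributions
#' on an unconstrained scale (see [default_priors()]) and sampled by an
#' adaptive Metropolis-within-Gibbs scheme; four chains are run and the
#' first half of each is discarded as warm-up. If any group-level split
#' R-hat exceeds the tolerance, the iteration count is doubled and sampling
#' restarts, up to `control$max_iter`; a fit that still has not converged is
#' returned with `converged = FALSE` rather than raising an error. Pointwise
#' log predictive densities of retained trials are recorded for WAIC and
#' model comparison.
#'
#' @param trials Validated trial table with at least two subjects.
#' @param design The generating [bandit_design()].
#' @param spec A [model_spec()].
#' @param priors Optional data.frame as returned by [default_priors()].
#' @param control An [hb_control()].
#' @param seed Integer seed.
#' @param initial_value,init_rule Value-initialization rule for learning
#'   models.
#' @return An object of class `rlddm_fit`: group- and subject-level draws,
#'   per-parameter split R-hat and effective sample sizes, the pointwise
#'   log-density matrix, and a convergence flag.
#' @export
fit_hierarchical <- function(trials, design, spec, priors = NULL,
                             control = hb_control(), seed = 1,
                             initial_value = 27.5,
                             init_rule = "grand_mean") {
  if (nrow(trials) == 0) stop("empty data")
  ids <- sort(unique(trials$subject))
  if (length(ids) < 2)
    stop("hierarchical estimation needs at least 2 subjects")
  if (is.null(priors)) priors <- default_priors(spec, design)
  subjects <- prepare_subjects(trials, design, spec)
  links <- stats::setNames(priors$link, priors$name)
  P <- length(links)
  if (is.null(priors$upper))
    priors$upper <- ifelse(priors$link == "scaledlogit", 1.0, NA_real_)
  uppers <- matrix(rep(priors$upper, each = length(subjects)),
                   length(subjects), P, dimnames = list(NULL, priors$name))
  loglik <- make_subject_loglik(spec, design, initial_value, init_rule)
  # start non-decision times near half of each subject's fastest retained
  # response so initial likelihoods are finite
  init_center <- matrix(0, length(subjects), P,
                        dimnames = list(NULL, priors$name))
  if ("t_er" %in% priors$name) {
    up <- uppers[, "t_er"]
    min_rt <- vapply(subjects, function(d) d$min_rt, numeric(1))
    init_center[, "t_er"] <- stats::qlogis(pmin(0.5 * min_rt / up, 0.9))
  }
  n_iter <- control$iter
  repeat {
    res <- hb_sample(subjects, loglik, links, uppers, control, seed, n_iter,
                     init_center)
    converged <- all(is.finite(res$rhat)) && all(res$rhat <= control$rhat_tol)
    if (converged || n_iter >= control$max_iter) break
    n_iter <- min(2 * n_iter, control$max_iter)
  }
  fit <- structure(
    list(spec = spec, design = design, subject_ids = ids,
         group = res$group, subject = res$subject,
         rhat = res$rhat, ess = res$ess,
         accept_rate = res$accept_rate,
         divergence_fraction = res$nonfinite_fraction,
         converged = converged, n_iter = n_iter,
         links = links, uppers = uppers,
         initial_value = initial_value, init_rule = init_rule),
    class = "rlddm_fit")
  if (control$pointwise_draws > 0)
    fit$pointwise <- pointwise_log_density(fit, subjects, spec, design,
                                           control$pointwise_draws)
  fit
}

pointwise_log_density <- function(fit, subjects, spec, design, max_draws) {
  pw_fun <- make_subject_loglik(spec, design, fit$initial_value,
                                fit$init_rule, pointwise = TRUE)
  n_keep <- dim(fit$subject)[1]; chains <- dim(fit$subject)[2]
  total <- n_keep * chains
  idx <- unique(round(seq(1, total, length.out = min(max_draws, total))))
  pts_per_s <- vapply(subjects, function(d) sum(d$included), integer(1))
  out <- matrix(NA_real_, length(idx), sum(pts_per_s))
  for (r in seq_along(idx)) {
    it <- (idx[r] - 1) %% n_keep + 1
    ch <- (idx[r] - 1) %/% n_keep + 1
    col <- 0
    for (s in seq_along(subjects)) {
      th <- fit$subject[it, ch, s, ]
      names(th) <- dimnames(fit$subject)[[4]]
      lp <- pw_fun(subjects[[s]], th)
      out[r, col + seq_along(lp)] <- lp
      col <- col + pts_per_s[s]
    }
  }
  out
}

#' @export
print.rlddm_fit <- function(x, ...) {
  cat("Hierarchical fit:", x$spec$label, "-", length(x$subject_ids),
      "subjects,", x$n_iter, "iterations/chain\n")
  cat("  converged:", x$converged,
      "| max split R-hat:", round(max(x$rhat), 4),
      "| mean acceptance:", round(x$accept_rate, 2), "\n")
  print(summary(x))
  invisible(x)
}

#' Posterior summary of group-level parameters
#'
#' @param object An `rlddm_fit`.
#' @param prob Central credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Data.frame of posterior mean, central interval, split R-hat and
#'   effective sample size per group-level parameter (unconstrained scale).
#' @export
summary.rlddm_fit <- function(object, prob = 0.95, ...) {
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  pars <- dimnames(object$group)[[3]]
  rows <- lapply(pars, function(p) {
    x <- as.vector(object$group[, , p])
    data.frame(parameter = p, mean = mean(x),
               lower = stats::quantile(x, qs[1]),
               upper = stats::quantile(x, qs[2]),
               rhat = object$rhat[[p]], ess = object$ess[[p]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Central credible interval of a group-level parameter
#'
#' @param fit An `rlddm_fit`.
#' @param parameter Group-level parameter name (e.g. `"mu_eta"`).
#' @param prob Interval mass (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
bci <- function(fit, parameter, prob = 0.95) {
  x <- as.vector(fit$group[, , parameter])
  unname(stats::quantile(x, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
}

#' Widely applicable information criterion from pointwise log densities
#'
#' `lppd` is the sum over data points of the log of the mean (over draws) of
#' the predictive density; the complexity penalty `p_waic` is the summed
#' variance of the pointwise log-density over draws;
#' `waic = -2 (lppd - p_waic) = 2 (-lppd + p_waic)`.
#'
#' @param pointwise Matrix of pointwise log predictive densities, draws x
#'   points (or an `rlddm_fit` with a `pointwise` element).
#' @param model Optional model label.
#' @return A one-row data.frame: `model`, `p_waic`, `neg_lppd`, `waic`, and
#'   a `flagged` column marking data points with zero predictive density.
#' @export
compute_waic <- function(pointwise, model = NA_character_) {
  if (inherits(pointwise, "rlddm_fit")) {
    if (is.na(model)) model <- pointwise$spec$label
    pointwise <- pointwise$pointwise
  }
  if (is.null(pointwise) || nrow(pointwise) < 2)
    stop("need at least 2 draws of pointwise log densities")
  mx <- apply(pointwise, 2, max)
  lppd_i <- ifelse(is.finite(mx),
                   mx + log(colMeans(exp(sweep(pointwise, 2, mx)))),
                   -Inf)
  p_i <- apply(pointwise, 2, stats::var)
  flagged <- !is.finite(lppd_i)
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i[is.finite(p_i)])
  data.frame(model = model, p_waic = p_waic, neg_lppd = -lppd,
             waic = 2 * (-lppd + p_waic), flagged = any(flagged))
}

#' Compare the predictive accuracy of two fitted models
#'
#' Computes the difference in expected log pointwise predictive density
#' (elpd, the WAIC-penalized pointwise accuracy) between two fits of the
#' same data points, and its standard error from the spread of the
#' pointwise differences: `se = sqrt(n * var(d_i))`.
#'
#' @param a,b Pointwise log-density matrices (draws x points) or
#'   `rlddm_fit` objects; data points must be in the same order.
#' @return A list with `elpd_diff` (a minus b) and `se_diff`.
#' @export
compare_models <- function(a, b) {
  pa <- if (inherits(a, "rlddm_fit")) a$pointwise else a
  pb <- if (inherits(b, "rlddm_fit")) b$pointwise else b
  if (ncol(pa) != ncol(pb))
    stop("mismatched number of data points: ", ncol(pa), " vs ", ncol(pb))
  elpd <- function(m) {
    mx <- apply(m, 2, max)
    lppd_i <- ifelse(is.finite(mx),
                     mx + log(colMeans(exp(sweep(m, 2, mx)))), -Inf)
    p_i <- apply(m, 2, stats::var)
    lppd_i - p_i
  }
  d <- elpd(pa) - elpd(pb)
  list(elpd_diff = sum(d), se_diff = sqrt(length(d) * stats::var(d)))
}
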