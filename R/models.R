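#' Construct a model specification
#'
#' A model specification names one point in the model space: the class
#' (`"RL"`, `"DDM"`, `"RLDDM"`, or `"PedersenRLDDM"`) and the variant
#' number within the class. Only the named variants are constructible:
#' 4 RL soft-max models, 3 static DDMs, 8 RLDDMs (one/two learning rates
#' x linear/sigmoid drift mapping x fixed/value-modulated threshold), and
#' 4 power-decay ("Pedersen-style") RLDDMs.
#'
#' @param model_class One of `"RL"`, `"DDM"`, `"RLDDM"`, `"PedersenRLDDM"`.
#' @param variant Variant number within the class.
#' @return An object of class `model_spec` with fields `model_class`,
#'   `variant`, `n_learning_rates`, `drift_mapping`, `threshold_rule`,
#'   `sensitivity_rule`, `label`, and `param_names`.
#' @examples
#' model_spec("RLDDM", 8)
#' model_catalog()
#' @export
model_spec <- function(model_class = c("RL", "DDM", "RLDDM", "PedersenRLDDM"),
                       variant) {
  model_class <- match.arg(model_class)
  cat_all <- model_catalog()
  row <- cat_all[cat_all$model_class == model_class & cat_all$variant == variant, ]
  if (nrow(row) != 1)
    stop("no such model variant: ", model_class, " ", variant)
  spec <- structure(
    list(model_class = model_class,
         variant = as.integer(variant),
         n_learning_rates = row$n_learning_rates,
         drift_mapping = row$drift_mapping,
         threshold_rule = row$threshold_rule,
         sensitivity_rule = row$sensitivity_rule,
         label = row$label),
    class = "model_spec")
  spec$param_names <- spec_param_names(spec)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$label, "-", x$model_class, "variant", x$variant, "\n")
  cat("  learning rates:", x$n_learning_rates,
      "| drift:", x$drift_mapping,
      "| threshold:", x$threshold_rule,
      if (x$model_class == "RL") paste("| sensitivity:", x$sensitivity_rule),
      "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' The full catalog of constructible model variants
#'
#' @return A data.frame with one row per model: class, variant, number of
#'   learning rates, drift mapping, threshold rule, sensitivity rule, label.
#' @export
model_catalog <- function() {
  rl <- data.frame(
    model_class = "RL", variant = 1:4,
    n_learning_rates = c(1L, 1L, 2L, 2L),
    drift_mapping = NA_character_,
    threshold_rule = NA_character_,
    sensitivity_rule = c("fixed", "power", "fixed", "power"))
  ddm <- data.frame(
    model_class = "DDM", variant = 1:3,
    n_learning_rates = 0L,
    drift_mapping = c("difficulty", "difficulty", "per-pair"),
    threshold_rule = c("fixed", "per-pair", "per-pair"),
    sensitivity_rule = NA_character_)
  # variant order: linear 1-4 then sigmoid 5-8, within each: fixed threshold
  # (one, two eta) then value-modulated threshold (one, two eta)
  rlddm <- data.frame(
    model_class = "RLDDM", variant = 1:8,
    n_learning_rates = rep(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)),
    drift_mapping = rep(c("linear", "sigmoid"), each = 4),
    threshold_rule = rep(rep(c("fixed", "value-modulated"), each = 2), 2),
    sensitivity_rule = NA_character_)
  ped <- data.frame(
    model_class = "PedersenRLDDM", variant = 1:4,
    n_learning_rates = c(1L, 1L, 2L, 2L),
    drift_mapping = c("power-fixed", "power-increasing",
                      "power-fixed", "power-increasing"),
    threshold_rule = "power-decay",
    sensitivity_rule = NA_character_)
  out <- rbind(rl, ddm, rlddm, ped)
  out$label <- paste0(ifelse(out$model_class == "PedersenRLDDM",
                             "Pedersen RLDDM", out$model_class),
                      " ", out$variant)
  out
}

spec_param_names <- function(spec) {
  eta <- if (spec$n_learning_rates == 2) c("eta_plus", "eta_minus")
         else if (spec$n_learning_rates == 1) "eta" else character(0)
  switch(spec$model_class,
    RL = c(eta, if (spec$sensitivity_rule == "fixed") "theta" else c("b", "c")),
    DDM = {
      cmap <- ddm_condition_map(bandit_design(), spec$variant)
      c(unique(unname(cmap$v_conditions)),
        unique(unname(cmap$a_conditions)), "t_er")
    },
    RLDDM = c(eta, "v_mod",
              if (spec$drift_mapping == "sigmoid") "v_max",
              if (spec$threshold_rule == "fixed") "a" else c("a_fix", "a_mod"),
              "t_er"),
    PedersenRLDDM = c(eta, "v_mod",
                      if (spec$drift_mapping == "power-increasing") "d_m",
                      "a_base", "d_a", "t_er"))
}

#' Linear value-to-drift mapping
#'
#' The drift rate is proportional to the difference of the learned values of
#' the higher- and lower-mean presented options.
#'
#' @param q_cor,q_inc Subjective values entering the trial.
#' @param v_mod Drift scaling per point of value difference.
#' @return Drift rate.
#' @export
drift_linear <- function(q_cor, q_inc, v_mod) v_mod * (q_cor - q_inc)

#' Sigmoidal value-to-drift mapping
#'
#' An S-shaped, odd transform of the scaled value difference, bounded at
#' `+/- v_max`: `S(z) = 2 v_max / (1 + exp(-z)) - v_max` with
#' `z = v_mod (q_cor - q_inc)`. Small `v_mod` makes the mapping nearly
#' linear; large `v_max` recovers the linear mapping in the limit.
#'
#' @inheritParams drift_linear
#' @param v_max Asymptotic absolute drift (> 0).
#' @return Drift rate.
#' @export
drift_sigmoid <- function(q_cor, q_inc, v_mod, v_max) {
  if (any(v_max <= 0)) stop("v_max must be > 0")
  z <- v_mod * (q_cor - q_inc)
  2 * v_max * stats::plogis(z) - v_max
}

#' Value-modulated decision threshold
#'
#' The log-threshold is linear in the mean learned value of the presented
#' options: `a = exp(a_fix + a_mod * q_bar_pres)`. A negative `a_mod` lowers
#' the threshold for more attractive pairs, producing faster but hardly less
#' accurate choices (the magnitude effect). With `a_mod = 0` the threshold
#' is constant `exp(a_fix)`.
#'
#' @param a_fix Log-threshold intercept.
#' @param a_mod Modulation per point of mean value.
#' @param q_bar_pres Mean subjective value of the presented options.
#' @return Threshold (strictly positive).
#' @export
threshold_value_modulated <- function(a_fix, a_mod, q_bar_pres) {
  exp(a_fix + a_mod * q_bar_pres)
}

#' Power-decay threshold and power-increasing drift scaling
#'
#' Within-block time modulators used by the Pedersen-style variants: the
#' threshold decays as a power of the within-block trial number,
#' `a_t = a_base * t^(-d_a)`, and the drift scaling grows as
#' `m_t = m_base * t^(d_m)`; the trial's drift is then
#' `m_t * (q_cor - q_inc)`. Both exponents are >= 0 and the base values
#' apply at `t = 1`.
#'
#' @param t Within-block trial number (>= 1).
#' @param a_base Threshold at `t = 1` (> 0).
#' @param m_base Drift scaling at `t = 1`.
#' @param d_a Threshold decay exponent (>= 0).
#' @param d_m Drift-scaling growth exponent (>= 0).
#' @return A list with `threshold` and `drift_scale`, each aligned with `t`.
#' @export
pedersen_trial_modulators <- function(t, a_base, m_base, d_a, d_m = 0) {
  if (any(t < 1)) stop("within-block trial number must be >= 1")
  if (any(d_a < 0) || any(d_m < 0)) stop("decay/growth exponents must be >= 0")
  list(threshold = a_base * t^(-d_a), drift_scale = m_base * t^(d_m))
}

# Internal: trialwise (v_t, a_t) from prepared arrays + a Q trajectory.
trialwise_from_traj <- function(d, traj, spec, params) {
  q_cor <- traj$q_cor; q_inc <- traj$q_inc
  q_bar <- (q_cor + q_inc) / 2
  if (spec$model_class == "RLDDM") {
    v <- switch(spec$drift_mapping,
      linear = drift_linear(q_cor, q_inc, params$v_mod),
      sigmoid = {
        if (is.null(params$v_max)) stop("configuration error: sigmoid drift mapping needs v_max")
        drift_sigmoid(q_cor, q_inc, params$v_mod, params$v_max)
      })
    a <- switch(spec$threshold_rule,
      fixed = {
        if (is.null(params$a)) stop("configuration error: fixed threshold rule needs a")
        rep(params$a, length(v))
      },
      `value-modulated` = {
        if (is.null(params$a_fix) || is.null(params$a_mod))
          stop("configuration error: value-modulated threshold needs a_fix and a_mod")
        threshold_value_modulated(params$a_fix, params$a_mod, q_bar)
      })
  } else if (spec$model_class == "PedersenRLDDM") {
    d_m <- if (spec$drift_mapping == "power-increasing") params$d_m else 0
    mod <- pedersen_trial_modulators(d$t_in_block, params$a_base,
                                     params$v_mod, params$d_a, d_m)
    v <- mod$drift_scale * (q_cor - q_inc)
    a <- mod$threshold
  } else {
    stop("spec is not a learning diffusion model")
  }
  data.frame(v = v, a = a, q_cor = q_cor, q_inc = q_inc, q_bar_pres = q_bar)
}

#' Trialwise diffusion parameters implied by a learning model
#'
#' Runs the delta-rule trajectory over a subject's trials and maps the
#' learned values to per-trial drift rates and thresholds according to the
#' model specification. Values entering trial `t` are those updated through
#' trial `t - 1`, since feedback arrives after the response.
#'
#' @param trials Single-subject trial table.
#' @param design The generating [bandit_design()].
#' @param spec A [model_spec()] of class `"RLDDM"` or `"PedersenRLDDM"`.
#' @param params Named list of natural-scale parameters (see
#'   `spec$param_names`; single-rate specs take `eta`).
#' @param initial_value,init_rule Passed to the value trajectory.
#' @return A data.frame with one row per trial: `v`, `a`, `q_cor`, `q_inc`,
#'   `q_bar_pres`.
#' @export
build_trialwise_parameters <- function(trials, design, spec, params,
                                       initial_value = 27.5,
                                       init_rule = "grand_mean") {
  if (!spec$model_class %in% c("RLDDM", "PedersenRLDDM"))
    stop("spec must be an RLDDM or Pedersen-style variant")
  rlp <- expand_eta(spec, params)
  d <- prepare_model_data(trials, design)
  traj <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                     rlp$eta_plus, rlp$eta_minus, initial_value,
                     init_rule == "grand_mean", length(design$option_means))
  trialwise_from_traj(d, traj, spec, params)
}

# single-rate specs expose "eta"; dual-rate specs expose eta_plus/eta_minus
expand_eta <- function(spec, params) {
  if (spec$n_learning_rates == 1) {
    if (is.null(params$eta)) stop("configuration error: spec needs eta")
    list(eta_plus = params$eta, eta_minus = params$eta)
  } else {
    if (is.null(params$eta_plus) || is.null(params$eta_minus))
      stop("configuration error: spec needs eta_plus and eta_minus")
    list(eta_plus = params$eta_plus, eta_minus = params$eta_minus)
  }
}

#' Joint choice/response-time log-likelihood of a learning diffusion model
#'
#' Sums, over retained trials, the log first-passage density of the observed
#' boundary (upper = higher-mean option chosen) and response time under the
#' trialwise drift and threshold implied by the learning model. Returns
#' `-Inf` (rather than an error) when `t_er` is at or above the smallest
#' retained response time, so samplers can reject such proposals.
#'
#' @inheritParams build_trialwise_parameters
#' @param tol Density truncation tolerance.
#' @return Summed log-likelihood.
#' @export
rlddm_log_likelihood <- function(trials, design, spec, params,
                                 initial_value = 27.5,
                                 init_rule = "grand_mean", tol = 1e-10) {
  tw <- build_trialwise_parameters(trials, design, spec, params,
                                   initial_value, init_rule)
  keep <- !trials$excluded & !is.na(trials$rt)
  if (!any(keep)) return(-Inf)
  if (params$t_er >= min(trials$rt[keep])) return(-Inf)
  sum(wfpt_logdens_cpp(trials$rt[keep], as.integer(trials$accuracy[keep]),
                       tw$v[keep], tw$a[keep], params$t_er, 0.5, tol))
}
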