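#' Reinforcement-learning parameters
#'
#' Container for the parameters of the soft-max RL models: one or two
#' delta-rule learning rates and either a fixed sensitivity or the scaling
#' and consistency parameters of a power-increasing sensitivity.
#'
#' @param eta_plus Learning rate applied to positive prediction errors, in
#'   \[0, 1\].
#' @param eta_minus Learning rate applied to negative prediction errors, in
#'   \[0, 1\]. Defaults to `eta_plus` (single-rate models).
#' @param theta Fixed soft-max sensitivity, >= 0 (fixed-sensitivity models).
#' @param b Scaling of the power sensitivity, > 0.
#' @param c Consistency exponent of the power sensitivity, >= 0.
#' @return An object of class `rl_parameters`.
#' @export
rl_parameters <- function(eta_plus, eta_minus = eta_plus,
                          theta = NULL, b = NULL, c = NULL) {
  if (eta_plus < 0 || eta_plus > 1 || eta_minus < 0 || eta_minus > 1)
    stop("learning rates must lie in [0, 1]")
  if (!is.null(theta) && theta < 0) stop("theta must be >= 0")
  if (!is.null(b) && b <= 0) stop("b must be > 0")
  if (!is.null(c) && c < 0) stop("c must be >= 0")
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus,
                 theta = theta, b = b, c = c),
            class = "rl_parameters")
}

#' Delta-rule update of a subjective value
#'
#' Moves a value toward the experienced feedback by the fraction given by
#' the learning rate; when two learning rates are supplied, the sign of the
#' reward prediction error `f - q_prev` selects between them (a zero error
#' uses the positive rate).
#'
#' @param q_prev Current subjective value (points).
#' @param f Experienced feedback (points).
#' @param params An [rl_parameters()] object.
#' @return The updated value.
#' @examples
#' update_q(27.5, 36, rl_parameters(eta_plus = 0.2))  # 29.2
#' @export
update_q <- function(q_prev, f, params) {
  pe <- f - q_prev
  eta <- ifelse(pe >= 0, params$eta_plus, params$eta_minus)
  q_prev + eta * pe
}

#' Subjective-value trajectory across a subject's trials
#'
#' Runs the delta rule over an ordered trial table under full feedback: both
#' presented options are updated on every trial with their own feedback.
#' Values carry over within a block. At a block boundary the options are new
#' stimuli, so values restart: under `init_rule = "grand_mean"` (default)
#' every option starts at the mean of all option values at the end of the
#' previous block; under `init_rule = "per_option"` each option label keeps
#' its previous value. Block 1 starts at `initial_value` for every option.
#'
#' @param trials A trial table for a single subject (see [read_trials()]),
#'   ordered by block then trial, with feedback for both presented options.
#' @param design The [bandit_design()] that generated the data (used to
#'   identify which presented option has the higher generating mean).
#' @param params An [rl_parameters()] (or compatible list with `eta_plus`,
#'   `eta_minus`).
#' @param initial_value Starting value for block 1 (default 27.5, the mean
#'   value advertised in the task instructions).
#' @param init_rule `"grand_mean"` or `"per_option"` (see above).
#' @return A data.frame with one row per trial: `q_cor`, `q_inc` (values of
#'   the higher- and lower-mean presented option entering the trial),
#'   `n_cor`, `n_inc` (presentation counts including the current trial).
#' @export
q_trajectory <- function(trials, design, params,
                         initial_value = 27.5,
                         init_rule = c("grand_mean", "per_option")) {
  init_rule <- match.arg(init_rule)
  d <- prepare_model_data(trials, design)
  tr <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                   params$eta_plus, params$eta_minus,
                   initial_value, init_rule == "grand_mean",
                   length(design$option_means))
  data.frame(q_cor = tr$q_cor, q_inc = tr$q_inc,
             n_cor = tr$n_cor, n_inc = tr$n_inc)
}

#' Power-increasing soft-max sensitivity
#'
#' Sensitivity grows with the number of times an option has been
#' encountered: `theta = (n / b)^c`. With `c = 0` the sensitivity is fixed
#' at 1; larger `c` makes choices increasingly deterministic over a block.
#'
#' @param n Presentation count (>= 1).
#' @param params An [rl_parameters()] with `b` and `c` set.
#' @return The sensitivity value.
#' @export
sensitivity_power <- function(n, params) {
  if (any(n < 1)) stop("option never seen: presentation count must be >= 1")
  (n / params$b)^params$c
}

#' Soft-max probability of choosing the higher-mean option
#'
#' @param q_cor,q_inc Subjective values of the options with the higher and
#'   lower generating mean.
#' @param theta Sensitivity (>= 0).
#' @return `exp(theta * q_cor) / (exp(theta * q_cor) + exp(theta * q_inc))`,
#'   computed overflow-safely.
#' @examples
#' choice_probability_softmax(50, 36, 0.1)  # ~0.8022
#' @export
choice_probability_softmax <- function(q_cor, q_inc, theta) {
  if (any(theta < 0)) stop("theta must be >= 0")
  stats::plogis(theta * (q_cor - q_inc))
}

#' Log-likelihood of choices under a soft-max RL model
#'
#' Propagates subjective values with the delta rule and scores every
#' retained trial's observed choice under the soft-max rule. The four model
#' variants combine one vs. two learning rates with a fixed vs.
#' power-increasing sensitivity; in power-sensitivity variants the
#' presentation count entering the sensitivity is the mean of the two
#' presented options' counts.
#'
#' @param trials Single-subject trial table.
#' @param design The generating [bandit_design()].
#' @param params An [rl_parameters()] appropriate for the variant.
#' @param variant Integer 1--4: 1 single rate/fixed theta, 2 single
#'   rate/power theta, 3 dual rate/fixed theta, 4 dual rate/power theta.
#' @param initial_value,init_rule Passed to [q_trajectory()].
#' @return The summed log-likelihood over retained (non-excluded) trials.
#' @export
rl_log_likelihood <- function(trials, design, params, variant,
                              initial_value = 27.5,
                              init_rule = "grand_mean") {
  if (!variant %in% 1:4) stop("invalid RL variant: ", variant)
  if (variant %in% c(1, 2) && params$eta_plus != params$eta_minus)
    stop("variants 1 and 2 use a single learning rate")
  tr <- q_trajectory(trials, design, params, initial_value, init_rule)
  theta <- if (variant %in% c(1, 3)) {
    params$theta
  } else {
    sensitivity_power((tr$n_cor + tr$n_inc) / 2, params)
  }
  p_cor <- choice_probability_softmax(tr$q_cor, tr$q_inc, theta)
  keep <- !trials$excluded
  acc <- trials$accuracy[keep]
  sum(ifelse(acc == 1, log(p_cor[keep]), log1p(-p_cor[keep])))
}
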