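#' Diffusion decision model parameters
#'
#' Core parameters of the simple (unbiased) diffusion decision model with
#' unit diffusion coefficient: drift rate `v` (signed; positive toward the
#' upper boundary, which codes the higher-generating-mean option), boundary
#' separation `a > 0`, and non-decision time `t_er >= 0` seconds. The
#' starting point is fixed at `a / 2`.
#'
#' @param v Drift rate (evidence per second).
#' @param a Threshold separation (> 0).
#' @param t_er Non-decision time in seconds (>= 0).
#' @return An object of class `ddm_parameters`.
#' @export
ddm_parameters <- function(v, a, t_er = 0) {
  if (!all(is.finite(c(v, a, t_er)))) stop("parameters must be finite")
  if (any(a <= 0)) stop("threshold a must be > 0")
  if (any(t_er < 0)) stop("non-decision time must be >= 0")
  structure(list(v = v, a = a, t_er = t_er), class = "ddm_parameters")
}

#' Simulate first-passage samples of the diffusion process
#'
#' Euler-Maruyama simulation of the accumulation process
#' `x[i+1] = x[i] + N(v dt, sqrt(dt))`, starting at `a / 2`, until the
#' evidence reaches `a` (upper boundary, the higher-mean option) or 0
#' (lower boundary). The response time is the passage time plus the
#' non-decision time. Paths that have not terminated by `max_time` are
#' returned with `censored = TRUE` and `rt = NA`.
#'
#' @param params A [ddm_parameters()] object; `v` and `a` may be vectors to
#'   draw one sample per trialwise parameter pair.
#' @param n Number of samples when `v`/`a` are scalars.
#' @param dt Euler time step in seconds (default 0.001).
#' @param max_time Maximum accumulation time in seconds (default 5, the
#'   response window of the task).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `rt` (s), `upper` (1 upper / 0 lower),
#'   `censored`.
#' @export
simulate_first_passage <- function(params, n = 1, dt = 0.001, max_time = 5,
                                   seed = NULL) {
  stopifnot(dt > 0, max_time > max(params$t_er))
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- params$v; a <- params$a
  if (length(v) == 1 && length(a) == 1 && n > 1) {
    v <- rep(v, n); a <- rep(a, n)
  }
  sim_fp_cpp(v, a, params$t_er, dt, max_time)
}

#' Closed-form probability of absorption at the upper boundary
#'
#' For the unbiased process (start `a / 2`, unit diffusion), the probability
#' of hitting the upper boundary is the logistic function `1 / (1 +
#' exp(-v * a))`; it serves as an analytic oracle for the simulator and for
#' the integral of the first-passage density.
#'
#' @param v Drift rate.
#' @param a Threshold separation (> 0).
#' @return Probability of an upper-boundary response.
#' @export
upper_hit_probability <- function(v, a) {
  if (any(a <= 0)) stop("threshold a must be > 0")
  stats::plogis(v * a)
}

#' Closed-form mean decision time of the unbiased process
#'
#' `E[T] = (a / (2 v)) * tanh(v a / 2)` for `v != 0`, and `a^2 / 4` at
#' `v = 0` (the limit).
#'
#' @inheritParams upper_hit_probability
#' @return Mean first-passage (decision) time in seconds.
#' @export
mean_decision_time <- function(v, a) {
  if (any(a <= 0)) stop("threshold a must be > 0")
  ifelse(v == 0, a^2 / 4, (a / (2 * v)) * tanh(v * a / 2))
}

#' Log first-passage-time density of the diffusion process
#'
#' Density of a response at time `rt` at the stated boundary, for drift `v`,
#' separation `a`, unbiased start, and non-decision time `t_er`. The
#' standardized density is evaluated by a small-time or large-time series,
#' whichever needs fewer terms for the requested truncation error; the
#' lower-boundary form is reflected (`v -> -v`) for upper-boundary
#' responses. Responses at or before `t_er` have zero density (`-Inf`).
#'
#' @param rt Response time(s) in seconds.
#' @param boundary `"upper"`/`"lower"`, or a 1/0 vector.
#' @param params A [ddm_parameters()]; `v` and `a` may be trialwise vectors.
#' @param tol Series truncation tolerance (default 1e-10).
#' @return Log-density, one value per `rt`.
#' @export
wfpt_log_density <- function(rt, boundary, params, tol = 1e-10) {
  if (is.character(boundary))
    boundary <- match.arg(boundary, c("upper", "lower")) == "upper"
  upper <- as.integer(boundary)
  if (length(upper) == 1) upper <- rep(upper, length(rt))
  if (tol <= 0) stop("tol must be > 0")
  wfpt_logdens_cpp(rt, upper, params$v, params$a, params$t_er, 0.5, tol)
}

#' Static DDM variants: condition structure
#'
#' The three static diffusion variants differ in how drift and threshold
#' depend on the choice pair: variant 1 has one drift per difficulty class
#' (easy/difficult) and a single threshold; variant 2 keeps difficulty
#' drifts but fits one threshold per pair; variant 3 fits one drift and one
#' threshold per pair. One non-decision time is shared throughout.
#'
#' @param design A [bandit_design()].
#' @param variant Integer 1--3.
#' @return A list with `v_conditions` and `a_conditions`: named assignment
#'   of each pair to a drift / threshold condition label.
#' @export
ddm_condition_map <- function(design, variant) {
  if (!variant %in% 1:3) stop("invalid DDM variant: ", variant)
  ps <- pair_statistics(design)
  by_difficulty <- stats::setNames(paste0("v_", ps$difficulty), ps$pair)
  by_pair_v <- stats::setNames(paste0("v_", ps$pair), ps$pair)
  by_pair_a <- stats::setNames(paste0("a_", ps$pair), ps$pair)
  single_a <- stats::setNames(rep("a", nrow(ps)), ps$pair)
  list(v_conditions = if (variant == 3) by_pair_v else by_difficulty,
       a_conditions = if (variant == 1) single_a else by_pair_a)
}

#' Log-likelihood of a static diffusion decision model
#'
#' Sums the log first-passage density of every retained trial's observed
#' boundary (upper = higher-mean option chosen) and response time, with the
#' trial's drift and threshold looked up through the variant's condition
#' map.
#'
#' @param trials Single-subject trial table.
#' @param design The generating [bandit_design()].
#' @param params Named list/vector of parameters: drift per drift condition
#'   (e.g. `v_easy`, `v_difficult`), threshold per threshold condition
#'   (`a` or `a_AB`, ...), and `t_er`.
#' @param variant Integer 1--3 (see [ddm_condition_map()]).
#' @param tol Density truncation tolerance.
#' @return Summed log-likelihood (can be `-Inf`, e.g. when `t_er` exceeds an
#'   observed RT).
#' @export
ddm_log_likelihood <- function(trials, design, params, variant, tol = 1e-10) {
  cmap <- ddm_condition_map(design, variant)
  unknown <- setdiff(unique(trials$pair), names(cmap$v_conditions))
  if (length(unknown))
    stop("trial with unmapped condition: pair ", paste(unknown, collapse = ", "))
  v_names <- cmap$v_conditions[trials$pair]
  a_names <- cmap$a_conditions[trials$pair]
  missing <- setdiff(unique(c(v_names, a_names, "t_er")), names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  v <- as.numeric(unlist(params[v_names]))
  a <- as.numeric(unlist(params[a_names]))
  keep <- !trials$excluded & !is.na(trials$rt)
  ld <- wfpt_logdens_cpp(trials$rt[keep], as.integer(trials$accuracy[keep]),
                         v[keep], a[keep], params$t_er, 0.5, tol)
  sum(ld)
}
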