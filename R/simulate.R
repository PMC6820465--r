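#' Simulate a full experiment under a generative model
#'
#' Generates synthetic data matching the task's structure: a representative
#' payoff schedule (one multiset per design and seed, observed by every
#' subject in a different order), a constrained pair sequence per subject,
#' and per-trial responses simulated from the specified model. For learning
#' diffusion specs the per-trial drift and threshold follow from the
#' delta-rule value trajectory (values entering a trial are those updated
#' through the previous trial); responses are first-passage samples of the
#' accumulation process. For RL specs, choices are soft-max draws and
#' response times are absent. Simulated response times outside the design's
#' retained window are flagged excluded (`"too_fast"`/`"too_slow"`) but
#' remain in the table, preserving the feedback stream; paths that do not
#' terminate by `max_time` are flagged `"censored"` with `rt = NA`.
#'
#' @param design A [bandit_design()].
#' @param spec A [model_spec()].
#' @param params Named list of natural-scale parameters shared by all
#'   subjects, or a data.frame with one row per subject.
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed governing payoffs, sequences and responses.
#' @param dt Euler step for the accumulator (s).
#' @param max_time Response window (s).
#' @param initial_value,init_rule Value-initialization rule (see
#'   [q_trajectory()]).
#' @return A validated trial table covering all subjects.
#' @export
simulate_experiment <- function(design, spec, params, n_subjects, seed,
                                dt = 0.001, max_time = 5,
                                initial_value = 27.5,
                                init_rule = "grand_mean") {
  validate_design(design)
  payoffs <- generate_payoffs(design, seed)
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == n_subjects)
    plist <- lapply(seq_len(n_subjects), function(s) as.list(params[s, ]))
  } else {
    plist <- rep(list(params), n_subjects)
  }
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    out[[s]] <- simulate_subject(design, spec, plist[[s]], payoffs,
                                 subject_id = s,
                                 seed = as.integer(seed) + s * 101L,
                                 dt = dt, max_time = max_time,
                                 initial_value = initial_value,
                                 init_rule = init_rule)
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  validate_trials(trials, design)
  trials
}

simulate_subject <- function(design, spec, params, payoffs, subject_id, seed,
                             dt, max_time, initial_value, init_rule) {
  seqs <- generate_pair_sequence(design, seed)
  # consume the subject-specific permutation of the shared payoff multiset
  opts <- names(design$option_means)
  fb_left <- fb_right <- numeric(nrow(seqs))
  for (b in seq_len(design$n_blocks)) {
    rows <- which(seqs$block == b)
    used <- stats::setNames(integer(length(opts)), opts)
    shuffled <- lapply(payoffs[[b]], function(x) x[sample.int(length(x))])
    for (i in rows) {
      ol <- seqs$option_left[i]; or_ <- seqs$option_right[i]
      used[ol] <- used[ol] + 1L; used[or_] <- used[or_] + 1L
      fb_left[i] <- shuffled[[ol]][used[ol]]
      fb_right[i] <- shuffled[[or_]][used[or_]]
    }
  }
  m_left <- design$option_means[seqs$option_left]
  m_right <- design$option_means[seqs$option_right]
  cor_left <- m_left >= m_right
  o_cor <- ifelse(cor_left, seqs$option_left, seqs$option_right)
  o_inc <- ifelse(cor_left, seqs$option_right, seqs$option_left)
  f_cor <- ifelse(cor_left, fb_left, fb_right)
  f_inc <- ifelse(cor_left, fb_right, fb_left)
  d <- list(block = seqs$block, t_in_block = seqs$trial, pair = seqs$pair,
            o_cor = match(o_cor, opts), o_inc = match(o_inc, opts),
            f_cor = f_cor, f_inc = f_inc)

  if (spec$model_class == "RL") {
    rlp <- expand_eta(spec, params)
    traj <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                       rlp$eta_plus, rlp$eta_minus, initial_value,
                       init_rule == "grand_mean", length(opts))
    theta <- if (spec$sensitivity_rule == "fixed") params$theta
             else sensitivity_power((traj$n_cor + traj$n_inc) / 2,
                                    list(b = params$b, c = params$c))
    p_cor <- choice_probability_softmax(traj$q_cor, traj$q_inc, theta)
    acc <- as.integer(stats::runif(length(p_cor)) < p_cor)
    rt <- rep(NA_real_, length(p_cor))
    censored <- rep(FALSE, length(p_cor))
  } else if (spec$model_class == "DDM") {
    cmap <- ddm_condition_map(design, spec$variant)
    v <- as.numeric(unlist(params[cmap$v_conditions[seqs$pair]]))
    a <- as.numeric(unlist(params[cmap$a_conditions[seqs$pair]]))
    fp <- sim_fp_cpp(v, a, params$t_er, dt, max_time)
    acc <- fp$upper; rt <- fp$rt; censored <- fp$censored
  } else {
    rlp <- expand_eta(spec, params)
    traj <- q_traj_cpp(d$block, d$o_cor, d$o_inc, d$f_cor, d$f_inc,
                       rlp$eta_plus, rlp$eta_minus, initial_value,
                       init_rule == "grand_mean", length(opts))
    tw <- trialwise_from_traj(d, traj, spec, params)
    fp <- sim_fp_cpp(tw$v, tw$a, params$t_er, dt, max_time)
    acc <- fp$upper; rt <- fp$rt; censored <- fp$censored
  }

  chosen <- ifelse(is.na(acc) | acc == 1, o_cor, o_inc)
  choice_side <- ifelse(chosen == seqs$option_left, "left", "right")
  fb_chosen <- ifelse(chosen == seqs$option_left, fb_left, fb_right)
  fb_unchosen <- ifelse(chosen == seqs$option_left, fb_right, fb_left)
  acc_final <- as.integer(chosen == o_cor)

  tab <- data.frame(subject = subject_id, block = seqs$block,
                    trial = seqs$trial, pair = seqs$pair,
                    option_left = seqs$option_left,
                    option_right = seqs$option_right,
                    choice_side = choice_side, chosen_option = chosen,
                    accuracy = acc_final, rt = rt,
                    feedback_chosen = fb_chosen,
                    feedback_unchosen = fb_unchosen,
                    excluded = FALSE, exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  tab$excluded[censored] <- TRUE
  tab$exclusion_reason[censored] <- "censored"
  if (spec$model_class != "RL") tab <- filter_trials(tab, design)
  tab
}
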