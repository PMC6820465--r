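# fixtures are built in code: designs, toy trial tables and shared
# generating parameters used across test files

default_design <- function() bandit_design()

# a tiny two-block design for hand-checkable trajectories
toy_design <- function() {
  bandit_design(option_means = c(A = 36, B = 40, C = 50, D = 54),
                option_sd = 5, n_blocks = 2, trials_per_block = 4,
                pairs = c("AB", "AC", "BD", "CD"),
                presentations_per_pair_per_block = 1,
                max_run_length = 4)
}

# hand-built single-subject trial table (all retained)
toy_trials <- function(pairs, feedback_cor, feedback_inc, accuracy,
                       rt = NULL, block = NULL, design = default_design()) {
  n <- length(pairs)
  if (is.null(rt)) rt <- rep(1, n)
  if (is.null(block)) block <- rep(1L, n)
  trial <- stats::ave(seq_len(n), block, FUN = seq_along)
  opts <- t(vapply(pairs, function(p) strsplit(p, "")[[1]], character(2)))
  m <- design$option_means
  cor_opt <- ifelse(m[opts[, 1]] >= m[opts[, 2]], opts[, 1], opts[, 2])
  inc_opt <- ifelse(m[opts[, 1]] >= m[opts[, 2]], opts[, 2], opts[, 1])
  chosen <- ifelse(accuracy == 1, cor_opt, inc_opt)
  data.frame(subject = 1L, block = block, trial = trial, pair = pairs,
             option_left = cor_opt, option_right = inc_opt,
             choice_side = ifelse(chosen == cor_opt, "left", "right"),
             chosen_option = chosen, accuracy = accuracy, rt = rt,
             feedback_chosen = ifelse(accuracy == 1, feedback_cor,
                                      feedback_inc),
             feedback_unchosen = ifelse(accuracy == 1, feedback_inc,
                                        feedback_cor),
             excluded = FALSE, exclusion_reason = NA_character_,
             stringsAsFactors = FALSE)
}

# generating group-level parameters for the simplest learning diffusion
# model on the unconstrained scale (logit eta, identity v_mod, log a,
# scaled-logit t_er); chosen to produce accuracies around .75 and response
# times near one second under the default design
rlddm1_group_mu <- function() {
  c(eta = stats::qlogis(0.12), v_mod = 0.08, a = log(1.8),
    t_er = stats::qlogis(0.35))
}
rlddm1_group_sigma <- function() {
  c(eta = 0.4, v_mod = 0.02, a = 0.15, t_er = 0.3)
}

rlddm1_subject_params <- function(n_subjects, seed) {
  mu <- rlddm1_group_mu(); sg <- rlddm1_group_sigma()
  set.seed(seed)
  z <- sapply(names(mu), function(p) stats::rnorm(n_subjects, mu[p], sg[p]))
  data.frame(eta = stats::plogis(z[, "eta"]), v_mod = z[, "v_mod"],
             a = exp(z[, "a"]), t_er = stats::plogis(z[, "t_er"]))
}
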