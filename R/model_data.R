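# Internal: convert a validated trial table (one subject) into the flat
# arrays used by the likelihoods and the compiled trajectory kernel.
# Ordering is by block then trial; "cor"/"inc" denote the presented options
# with the higher and lower generating mean.
prepare_model_data <- function(trials, design) {
  trials <- trials[order(trials$block, trials$trial), , drop = FALSE]
  opts <- names(design$option_means)
  po <- t(vapply(trials$pair, pair_options, character(2)))
  m1 <- design$option_means[po[, 1]]
  m2 <- design$option_means[po[, 2]]
  cor_opt <- ifelse(m1 >= m2, po[, 1], po[, 2])
  inc_opt <- ifelse(m1 >= m2, po[, 2], po[, 1])
  chose_cor <- trials$chosen_option == cor_opt
  f_cor <- ifelse(chose_cor, trials$feedback_chosen, trials$feedback_unchosen)
  f_inc <- ifelse(chose_cor, trials$feedback_unchosen, trials$feedback_chosen)
  if (anyNA(f_cor) || anyNA(f_inc)) {
    bad <- which(is.na(f_cor) | is.na(f_inc))
    stop("missing feedback at trial(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  list(block = as.integer(trials$block),
       t_in_block = as.integer(trials$trial),
       pair = trials$pair,
       o_cor = match(cor_opt, opts),
       o_inc = match(inc_opt, opts),
       f_cor = as.numeric(f_cor),
       f_inc = as.numeric(f_inc),
       rt = as.numeric(trials$rt),
       acc = as.integer(trials$accuracy),
       included = !trials$excluded & !is.na(trials$rt),
       n_trials = nrow(trials))
}
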