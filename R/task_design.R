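#' Define a multi-armed bandit learning design
#'
#' A design describes the generating experiment: reward distributions of the
#' four options, the block and pair-presentation structure, scheduling
#' constraints, the points-to-currency conversion, and the response-time
#' window used to retain trials.
#'
#' The default design has four options A--D with generating means 36, 40, 50
#' and 54 points (SD 5), three blocks of 80 trials in which each of the pairs
#' AB, AC, BD and CD is shown 20 times, no more than three consecutive
#' presentations of the same pair, a bonus of 1 Swiss franc per 1400 points,
#' and a retained response-time window of 0.150 to 3.000 s.
#'
#' @param option_means Named numeric vector of generating means (points), one
#'   per option.
#' @param option_sd Common payoff standard deviation (points), must be > 0.
#' @param n_blocks Number of learning blocks.
#' @param trials_per_block Trials per block; must equal
#'   `presentations_per_pair_per_block * length(pairs)`.
#' @param pairs Character vector of two-letter pair labels (e.g. `"AB"`).
#' @param presentations_per_pair_per_block Times each pair is shown per block.
#' @param max_run_length Maximum number of consecutive trials with the same
#'   pair.
#' @param points_per_franc Divisor converting accumulated points to Swiss
#'   francs.
#' @param rt_floor,rt_ceiling Retained response-time window in seconds.
#' @return An object of class `bandit_design`.
#' @examples
#' d <- bandit_design()
#' pair_statistics(d)
#' @export
bandit_design <- function(option_means = c(A = 36, B = 40, C = 50, D = 54),
                          option_sd = 5,
                          n_blocks = 3,
                          trials_per_block = 80,
                          pairs = c("AB", "AC", "BD", "CD"),
                          presentations_per_pair_per_block = 20,
                          max_run_length = 3,
                          points_per_franc = 1400,
                          rt_floor = 0.150,
                          rt_ceiling = 3.000) {
  if (is.null(names(option_means)))
    names(option_means) <- LETTERS[seq_along(option_means)]
  design <- structure(
    list(option_means = option_means,
         option_sd = option_sd,
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         pairs = pairs,
         presentations_per_pair_per_block = as.integer(presentations_per_pair_per_block),
         max_run_length = as.integer(max_run_length),
         points_per_franc = points_per_franc,
         rt_floor = rt_floor,
         rt_ceiling = rt_ceiling),
    class = "bandit_design")
  validate_design(design)
  design
}

#' @export
print.bandit_design <- function(x, ...) {
  cat("Bandit learning design\n")
  cat("  options:", paste(sprintf("%s (mean %g)", names(x$option_means),
                                  x$option_means), collapse = ", "),
      "- SD", x$option_sd, "\n")
  cat("  blocks:", x$n_blocks, "x", x$trials_per_block, "trials; pairs:",
      paste(x$pairs, collapse = ", "),
      sprintf("(%d presentations each)", x$presentations_per_pair_per_block), "\n")
  cat("  max run", x$max_run_length, "| RT window [",
      x$rt_floor, ",", x$rt_ceiling, "] s |", x$points_per_franc,
      "points per franc\n")
  invisible(x)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "bandit_design"))
  counts <- c(design$n_blocks, design$trials_per_block,
              design$presentations_per_pair_per_block, design$max_run_length)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: all counts must be positive integers")
  if (!is.numeric(design$option_sd) || design$option_sd <= 0)
    stop("invalid design: option_sd must be > 0")
  if (design$trials_per_block !=
      design$presentations_per_pair_per_block * length(design$pairs))
    stop("invalid design: trials_per_block must equal ",
         "presentations_per_pair_per_block * number of pairs")
  opts <- names(design$option_means)
  pair_opts <- unique(unlist(strsplit(design$pairs, "")))
  if (!all(pair_opts %in% opts))
    stop("invalid design: pair refers to unknown option: ",
         paste(setdiff(pair_opts, opts), collapse = ", "))
  if (design$rt_floor < 0 || design$rt_ceiling <= design$rt_floor)
    stop("invalid design: RT window must satisfy 0 <= rt_floor < rt_ceiling")
  invisible(design)
}

#' Split a pair label into its two options
#' @noRd
pair_options <- function(pair) strsplit(pair, "")[[1]]

#' Number of presentations of each option per block
#' @noRd
option_presentations_per_block <- function(design) {
  opts <- names(design$option_means)
  sapply(opts, function(o)
    sum(vapply(design$pairs, function(p) o %in% pair_options(p), logical(1)))) *
    design$presentations_per_pair_per_block
}

#' Generate representative payoff schedules
#'
#' Draws, for every block and option, one payoff per presentation from a
#' normal distribution with the option's generating mean and common SD,
#' rounds to integer points, and then applies minimal +/-1 corrections (to
#' the draws closest to the mean first) so that the sample mean of each
#' option within each block equals its generating mean exactly. The order of
#' payoffs is a seeded permutation; the payoff multiset itself depends only
#' on the design and seed, so different participants can observe the same
#' outcomes in different orders by permuting the returned lists.
#'
#' @param design A [bandit_design()].
#' @param seed Integer seed.
#' @return An object of class `payoff_schedule`: a list with one element per
#'   block, each a named list of integer payoff vectors (one per option, one
#'   entry per presentation).
#' @export
generate_payoffs <- function(design, seed) {
  validate_design(design)
  set.seed(as.integer(seed))
  n_pres <- option_presentations_per_block(design)
  out <- vector("list", design$n_blocks)
  for (b in seq_len(design$n_blocks)) {
    blk <- list()
    for (o in names(design$option_means)) {
      n <- n_pres[[o]]
      mu <- design$option_means[[o]]
      x <- round(stats::rnorm(n, mu, design$option_sd))
      x <- adjust_to_mean(x, mu)
      blk[[o]] <- x[sample.int(n)]
    }
    out[[b]] <- blk
  }
  structure(out, class = "payoff_schedule", design = design)
}

# Distribute the integer residual (target sum - actual sum) over draws by
# +/-1 steps, correcting draws closest to the mean first; preserves the
# approximate normality of the rounded draws. The target sum n * mu must be
# an integer for exactness to be achievable.
adjust_to_mean <- function(x, mu) {
  target <- mu * length(x)
  if (abs(target - round(target)) > 1e-9)
    stop("generating mean times draw count must be an integer for exact ",
         "representative sampling")
  resid <- as.integer(round(target) - sum(x))
  step <- sign(resid)
  while (resid != 0L) {
    ord <- order(abs(x - mu))
    for (i in ord) {
      x[i] <- x[i] + step
      resid <- resid - step
      if (resid == 0L) break
    }
  }
  x
}

#' Generate a constrained pair-presentation sequence
#'
#' Produces, per block, a pseudo-random order of pair presentations in which
#' every pair occurs exactly `presentations_per_pair_per_block` times and no
#' pair occurs more than `max_run_length` times in a row, together with an
#' independent fair-coin left/right side assignment per trial. Orders are
#' drawn by rejection sampling of permutations, which is uniform over the
#' valid sequences.
#'
#' @param design A [bandit_design()].
#' @param seed Integer seed.
#' @param max_tries Bounded number of rejection-sampling attempts per block.
#' @return A data.frame with columns `block`, `trial`, `pair`,
#'   `option_left`, `option_right`, of class `pair_sequence`.
#' @export
generate_pair_sequence <- function(design, seed, max_tries = 10000) {
  validate_design(design)
  set.seed(as.integer(seed))
  res <- vector("list", design$n_blocks)
  base <- rep(design$pairs, each = design$presentations_per_pair_per_block)
  for (b in seq_len(design$n_blocks)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      seq_b <- sample(base)
      if (max_run_length_of(seq_b) <= design$max_run_length) { ok <- TRUE; break }
    }
    if (!ok)
      stop("scheduling error: could not satisfy max_run_length = ",
           design$max_run_length, " within ", max_tries, " attempts")
    opts <- t(vapply(seq_b, pair_options, character(2)))
    flip <- stats::runif(length(seq_b)) < 0.5
    res[[b]] <- data.frame(
      block = b,
      trial = seq_along(seq_b),
      pair = seq_b,
      option_left = ifelse(flip, opts[, 1], opts[, 2]),
      option_right = ifelse(flip, opts[, 2], opts[, 1]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  class(out) <- c("pair_sequence", "data.frame")
  out
}

max_run_length_of <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(x)$lengths)
}

#' Full presentation schedule as a flat table
#'
#' Combines a payoff schedule and a pair sequence generated from the same
#' seed into one delimited-text-ready table: one row per trial with the
#' presented pair, side assignment, and the payoff each side would deliver.
#'
#' @param design A [bandit_design()].
#' @param seed Integer seed (payoffs use `seed`, the sequence `seed + 1`).
#' @return A data.frame with columns `block`, `trial`, `pair`,
#'   `option_left`, `option_right`, `payoff_left`, `payoff_right`.
#' @export
schedule_table <- function(design, seed) {
  payoffs <- generate_payoffs(design, seed)
  seqs <- generate_pair_sequence(design, as.integer(seed) + 1L)
  opts <- names(design$option_means)
  seqs$payoff_left <- NA_real_
  seqs$payoff_right <- NA_real_
  for (b in seq_len(design$n_blocks)) {
    used <- stats::setNames(integer(length(opts)), opts)
    for (i in which(seqs$block == b)) {
      for (side in c("left", "right")) {
        o <- seqs[[paste0("option_", side)]][i]
        used[o] <- used[o] + 1L
        seqs[[paste0("payoff_", side)]][i] <- payoffs[[b]][[o]][used[o]]
      }
    }
  }
  class(seqs) <- "data.frame"
  seqs
}

#' Pair-level design statistics
#'
#' For each presented pair, computes the magnitude (mean of the two
#' generating means), the absolute difference of generating means, and a
#' difficulty class: a pair is `easy` when its mean difference lies above the
#' midpoint between the smallest and largest differences in the design,
#' otherwise `difficult`.
#'
#' @param design A [bandit_design()].
#' @return A data.frame with columns `pair`, `magnitude`, `mean_difference`,
#'   `difficulty`.
#' @examples
#' pair_statistics(bandit_design())
#' @export
pair_statistics <- function(design) {
  validate_design(design)
  opts <- t(vapply(design$pairs, pair_options, character(2)))
  m1 <- design$option_means[opts[, 1]]
  m2 <- design$option_means[opts[, 2]]
  diffs <- abs(m1 - m2)
  midpoint <- (min(diffs) + max(diffs)) / 2
  data.frame(pair = design$pairs,
             magnitude = as.numeric((m1 + m2) / 2),
             mean_difference = as.numeric(diffs),
             difficulty = ifelse(diffs > midpoint, "easy", "difficult"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Minimum above-chance accuracy by an exact binomial test
#'
#' Returns `k*/n_trials`, where `k*` is the smallest number of correct
#' responses whose one-sided exact binomial tail probability
#' `P(X >= k* | n_trials, chance)` falls below `alpha`. Observed accuracies
#' at or below this proportion are consistent with random responding.
#'
#' @param n_trials Number of trials.
#' @param chance Probability of a correct response under random behavior.
#' @param alpha One-sided significance level.
#' @return The threshold proportion, with attribute `k` (the critical count)
#'   and attribute `unattainable = TRUE` when no count reaches significance
#'   (then 1.0 is returned with a warning).
#' @examples
#' min_accuracy_threshold(240, 0.5, 0.05)  # 134/240, i.e. 56% to the percent
#' @export
min_accuracy_threshold <- function(n_trials, chance = 0.5, alpha = 0.05) {
  stopifnot(n_trials >= 1, chance > 0, chance < 1, alpha > 0, alpha < 1)
  tails <- stats::pbinom(seq_len(n_trials) - 1, n_trials, chance,
                         lower.tail = FALSE)
  k <- which(tails < alpha)[1]
  if (is.na(k)) {
    warning("no count reaches significance at alpha = ", alpha)
    return(structure(1.0, k = NA_integer_, unattainable = TRUE))
  }
  structure(k / n_trials, k = as.integer(k), unattainable = FALSE)
}

#' Convert accumulated reward points to Swiss francs
#'
#' @param points Accumulated reward points (non-negative).
#' @param design A [bandit_design()]; the divisor is
#'   `design$points_per_franc`.
#' @return Bonus in Swiss francs.
#' @examples
#' points_to_francs(7000, bandit_design())  # 5
#' @export
points_to_francs <- function(points, design = bandit_design()) {
  if (any(points < 0)) stop("points must be non-negative")
  points / design$points_per_franc
}
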