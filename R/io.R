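#' @useDynLib rlddm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

trial_table_columns <- c("subject", "block", "trial", "pair", "option_left",
                         "option_right", "choice_side", "chosen_option",
                         "accuracy", "rt", "feedback_chosen",
                         "feedback_unchosen", "excluded", "exclusion_reason")

#' Validate a trial table against a design
#'
#' Checks the schema (all columns present), key uniqueness of
#' (subject, block, trial), consistency of the accuracy coding with the
#' design's generating means (accuracy is 1 exactly when the chosen option
#' has the higher generating mean of the presented pair), and positivity of
#' response times. Response times that look like milliseconds (values above
#' 100) raise a unit-suspicion warning.
#'
#' @param trials A data.frame in the trial-table schema.
#' @param design The [bandit_design()] the data come from.
#' @return The validated table (invisibly), ordered by subject, block,
#'   trial.
#' @export
validate_trials <- function(trials, design) {
  missing <- setdiff(trial_table_columns, names(trials))
  if (length(missing))
    stop("validation error: missing columns: ", paste(missing, collapse = ", "))
  key <- paste(trials$subject, trials$block, trials$trial)
  if (anyDuplicated(key))
    stop("validation error: duplicate (subject, block, trial) keys in rows: ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  po <- t(vapply(trials$pair, pair_options, character(2)))
  bad_pair <- !(po[, 1] %in% names(design$option_means)) |
              !(po[, 2] %in% names(design$option_means))
  if (any(bad_pair))
    stop("validation error: unknown option in pair, rows: ",
         paste(utils::head(which(bad_pair), 5), collapse = ", "))
  m_chosen <- design$option_means[trials$chosen_option]
  m_other <- design$option_means[ifelse(trials$chosen_option == po[, 1],
                                        po[, 2], po[, 1])]
  expected_acc <- as.integer(m_chosen > m_other)
  bad_acc <- trials$accuracy != expected_acc
  if (any(bad_acc))
    stop("validation error: accuracy inconsistent with generating means, rows: ",
         paste(utils::head(which(bad_acc), 5), collapse = ", "))
  rt <- trials$rt[!is.na(trials$rt)]
  if (any(rt <= 0))
    stop("validation error: non-positive response times")
  if (length(rt) && stats::median(rt) > 100)
    warning("response times look like milliseconds (median > 100); ",
            "the schema expects seconds")
  invisible(trials[order(trials$subject, trials$block, trials$trial), ,
                   drop = FALSE])
}

#' Read a trial table from delimited text
#'
#' @param path Path to a comma-separated file with a header naming the
#'   schema columns (UTF-8, decimal point).
#' @param design The [bandit_design()] used for validation.
#' @param validate Validate after reading (default TRUE).
#' @return A validated trial-table data.frame.
#' @export
read_trials <- function(path, design, validate = TRUE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"exclusion_reason" %in% names(x)) x$exclusion_reason <- NA_character_
  x$excluded <- as.logical(x$excluded)
  x$exclusion_reason <- as.character(x$exclusion_reason)
  if (validate) validate_trials(x, design) else x
}

#' Write a trial table to delimited text
#'
#' The written file round-trips through [read_trials()] unchanged.
#'
#' @param trials Trial-table data.frame.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, trial_table_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Flag trials outside the retained response-time window
#'
#' Rows faster than `design$rt_floor` are flagged `"too_fast"`, rows slower
#' than `design$rt_ceiling` are flagged `"too_slow"`. Flagged rows are
#' excluded from likelihoods and summaries but stay in the table so the
#' feedback stream is preserved.
#'
#' @param trials Validated trial table.
#' @param design The [bandit_design()].
#' @return The table with updated `excluded` / `exclusion_reason`.
#' @export
filter_trials <- function(trials, design) {
  fast <- !is.na(trials$rt) & trials$rt < design$rt_floor
  slow <- !is.na(trials$rt) & trials$rt > design$rt_ceiling
  trials$excluded <- trials$excluded | fast | slow
  trials$exclusion_reason[fast] <- "too_fast"
  trials$exclusion_reason[slow] <- "too_slow"
  trials
}

#' List subjects whose accuracy is consistent with random responding
#'
#' A subject is listed for exclusion when their overall accuracy over
#' retained trials does not exceed [min_accuracy_threshold()] for that
#' number of trials. Subjects with no retained trials are flagged
#' indeterminate.
#'
#' @param trials Validated trial table (all subjects).
#' @param design The [bandit_design()].
#' @param alpha One-sided binomial significance level (default 0.05).
#' @return A data.frame per subject: retained trial count, accuracy,
#'   threshold, and status (`"retain"`, `"exclude"`, `"indeterminate"`).
#' @export
exclude_subjects <- function(trials, design, alpha = 0.05) {
  kept <- trials[!trials$excluded & !is.na(trials$rt), , drop = FALSE]
  subjects <- sort(unique(trials$subject))
  rows <- lapply(subjects, function(s) {
    d <- kept[kept$subject == s, , drop = FALSE]
    n <- nrow(d)
    if (n == 0)
      return(data.frame(subject = s, n_retained = 0L, accuracy = NA_real_,
                        threshold = NA_real_, status = "indeterminate"))
    thr <- min_accuracy_threshold(n, 0.5, alpha)
    acc <- mean(d$accuracy)
    data.frame(subject = s, n_retained = n, accuracy = acc,
               threshold = as.numeric(thr),
               status = if (acc >= thr) "retain" else "exclude")
  })
  do.call(rbind, rows)
}

#' Read / write a flat key-value configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with `#`
#' are ignored. Values that parse as numbers become numeric.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}
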