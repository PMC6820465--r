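# Generic hierarchical sampler used by every model class and by the
# behavioral regressions: subject-level parameter vectors are sampled on an
# unconstrained scale by adaptive random-walk Metropolis within Gibbs;
# group-level normal means have conjugate updates and group SDs a
# random-walk step on the log scale. Half of each chain is warm-up, during
# which proposal scales adapt toward a target acceptance rate; adaptation is
# frozen afterwards.

#' Sampler control settings
#'
#' @param chains Number of chains (default 4).
#' @param iter Iterations per chain at the first attempt; the first half of
#'   each chain is discarded as warm-up.
#' @param max_iter Iteration cap: when convergence (all split R-hat <=
#'   `rhat_tol` on group-level parameters) is not reached, the iteration
#'   count doubles and sampling restarts until this cap.
#' @param rhat_tol Convergence threshold for split R-hat (default 1.01).
#' @param target_accept Target acceptance rate of the subject-level
#'   random-walk updates during adaptation.
#' @param mu_scale Prior SD of group means on the unconstrained scale.
#' @param sigma_scale Half-normal prior scale of group SDs.
#' @param pointwise_draws Maximum number of retained draws used for the
#'   pointwise log predictive density matrix (thinned evenly); 0 disables
#'   pointwise computation.
#' @return A list of class `hb_control`.
#' @export
hb_control <- function(chains = 4, iter = 1000, max_iter = 16000,
                       rhat_tol = 1.01, target_accept = 0.3,
                       mu_scale = 2, sigma_scale = 1,
                       pointwise_draws = 500) {
  structure(list(chains = chains, iter = iter, max_iter = max_iter,
                 rhat_tol = rhat_tol, target_accept = target_accept,
                 mu_scale = mu_scale, sigma_scale = sigma_scale,
                 pointwise_draws = pointwise_draws),
            class = "hb_control")
}

# links map the unconstrained sampling scale to each parameter's support;
# "scaledlogit" squashes into (0, upper) for parameters with a fixed upper
# bound (the non-decision time).
link_inverse <- function(z, link, upper = NA_real_) {
  switch(link,
         identity = z,
         log = exp(z),
         logit = stats::plogis(z),
         scaledlogit = upper * stats::plogis(z),
         stop("unknown link: ", link))
}

transform_subject <- function(z, links, uppers_s) {
  nat <- numeric(length(z))
  for (p in seq_along(z))
    nat[p] <- link_inverse(z[p], links[p], uppers_s[p])
  names(nat) <- names(links)
  nat
}

run_hb_chain <- function(subjects, loglik, links, uppers, control, n_iter,
                         chain_seed, init_center) {
  set.seed(chain_seed)
  S <- length(subjects)
  P <- length(links)
  pnames <- names(links)
  mu <- stats::rnorm(P, 0, 0.1)
  sigma <- rep(0.5, P)
  z <- matrix(0, S, P)
  ll <- numeric(S)
  for (s in seq_len(S)) {
    # start each subject near its own likelihood mode: best finite candidate
    # out of a random batch around the initialization center
    best <- -Inf; best_z <- NULL
    for (try in 1:150) {
      cand <- init_center[s, ] + stats::rnorm(P, 0, if (try <= 50) 0.4 else 1)
      l <- loglik(subjects[[s]], transform_subject(cand, links, uppers[s, ]))
      if (is.finite(l) && l > best) { best <- l; best_z <- cand }
    }
    if (is.null(best_z))
      stop("could not initialize subject ", s,
           ": likelihood not finite at any tried starting point")
    z[s, ] <- best_z
    ll[s] <- best
  }
  lam <- rep(0.4, S)
  # per-subject proposal shape: Cholesky of the running covariance of z
  chol_s <- rep(list(diag(0.3, P)), S)
  wf_n <- 0
  wf_mean <- matrix(0, S, P)
  wf_cov <- rep(list(matrix(0, P, P)), S)
  sig_step <- rep(0.3, P)
  asis_step <- rep(0.2, P)
  n_keep <- floor(n_iter / 2)
  keep0 <- n_iter - n_keep
  group <- matrix(NA_real_, n_keep, 2 * P,
                  dimnames = list(NULL, c(paste0("mu_", pnames),
                                          paste0("sigma_", pnames))))
  subj <- array(NA_real_, c(n_keep, S, P))
  acc_n <- 0; acc_y <- 0; nonfinite <- 0
  for (it in seq_len(n_iter)) {
    warm <- it <= keep0
    for (s in seq_len(S)) {
      zp <- z[s, ] + lam[s] * drop(chol_s[[s]] %*% stats::rnorm(P))
      lp <- loglik(subjects[[s]], transform_subject(zp, links, uppers[s, ]))
      if (!warm) { acc_n <- acc_n + 1; if (!is.finite(lp)) nonfinite <- nonfinite + 1 }
      la <- lp + sum(stats::dnorm(zp, mu, sigma, log = TRUE)) -
            ll[s] - sum(stats::dnorm(z[s, ], mu, sigma, log = TRUE))
      accept <- is.finite(la) && log(stats::runif(1)) < la
      if (accept) { z[s, ] <- zp; ll[s] <- lp; if (!warm) acc_y <- acc_y + 1 }
      if (warm) {
        lam[s] <- lam[s] * exp(0.05 * ((accept) - control$target_accept))
        lam[s] <- min(max(lam[s], 1e-3), 10)
      }
    }
    if (warm) {  # running covariance of z feeds the proposal shape
      wf_n <- wf_n + 1
      for (s in seq_len(S)) {
        delta <- z[s, ] - wf_mean[s, ]
        wf_mean[s, ] <- wf_mean[s, ] + delta / wf_n
        wf_cov[[s]] <- wf_cov[[s]] + tcrossprod(delta, z[s, ] - wf_mean[s, ])
      }
      if (wf_n > 50 && wf_n %% 25 == 0) {
        for (s in seq_len(S)) {
          cv <- wf_cov[[s]] / (wf_n - 1) + diag(1e-3, P)
          ch <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(ch)) chol_s[[s]] <- t(ch)
        }
      }
    }
    # conjugate update of group means (prior N(0, mu_scale^2))
    prec <- S / sigma^2 + 1 / control$mu_scale^2
    mean_post <- (colSums(z) / sigma^2) / prec
    mu <- stats::rnorm(P, mean_post, 1 / sqrt(prec))
    # log-scale random walk on group SDs (half-normal prior)
    for (p in seq_len(P)) {
      s_prop <- sigma[p] * exp(sig_step[p] * stats::rnorm(1))
      la <- sum(stats::dnorm(z[, p], mu[p], s_prop, log = TRUE)) -
            sum(stats::dnorm(z[, p], mu[p], sigma[p], log = TRUE)) +
            stats::dnorm(s_prop, 0, control$sigma_scale, log = TRUE) -
            stats::dnorm(sigma[p], 0, control$sigma_scale, log = TRUE) +
            log(s_prop) - log(sigma[p])
      acc <- is.finite(la) && log(stats::runif(1)) < la
      if (acc) sigma[p] <- s_prop
      if (warm) sig_step[p] <- min(max(sig_step[p] *
                                       exp(0.05 * (acc - 0.4)), 1e-3), 5)
    }
    # interleaved non-centered move (one parameter per iteration): propose
    # (mu_p, sigma_p) jointly while holding the standardized subject
    # effects fixed, which breaks the group-scale funnel of the centered
    # scheme for weakly identified parameters
    p <- (it - 1) %% P + 1
    eps <- (z[, p] - mu[p]) / sigma[p]
    mu_prop <- mu[p] + asis_step[p] * stats::rnorm(1)
    sig_prop <- sigma[p] * exp(asis_step[p] * stats::rnorm(1))
    znew <- z
    znew[, p] <- mu_prop + sig_prop * eps
    llnew <- vapply(seq_len(S), function(s)
      loglik(subjects[[s]], transform_subject(znew[s, ], links, uppers[s, ])),
      numeric(1))
    la <- sum(llnew) - sum(ll) +
      stats::dnorm(mu_prop, 0, control$mu_scale, log = TRUE) -
      stats::dnorm(mu[p], 0, control$mu_scale, log = TRUE) +
      stats::dnorm(sig_prop, 0, control$sigma_scale, log = TRUE) -
      stats::dnorm(sigma[p], 0, control$sigma_scale, log = TRUE) +
      log(sig_prop) - log(sigma[p])
    acc <- is.finite(la) && log(stats::runif(1)) < la
    if (acc) {
      z <- znew; ll <- llnew; mu[p] <- mu_prop; sigma[p] <- sig_prop
    }
    if (warm) asis_step[p] <- min(max(asis_step[p] *
                                      exp(0.1 * (acc - 0.3)), 1e-3), 5)
    if (!warm) {
      k <- it - keep0
      group[k, ] <- c(mu, sigma)
      for (s in seq_len(S))
        subj[k, s, ] <- transform_subject(z[s, ], links, uppers[s, ])
    }
  }
  list(group = group, subj = subj, z_last = z,
       accept_rate = if (acc_n) acc_y / acc_n else NA_real_,
       nonfinite_fraction = if (acc_n) nonfinite / acc_n else NA_real_)
}

hb_sample <- function(subjects, loglik, links, uppers, control, seed,
                      n_iter, init_center = NULL) {
  if (is.null(init_center))
    init_center <- matrix(0, length(subjects), length(links))
  chains <- lapply(seq_len(control$chains), function(ch)
    run_hb_chain(subjects, loglik, links, uppers, control, n_iter,
                 chain_seed = as.integer(seed) + 1000L * ch, init_center))
  n_keep <- nrow(chains[[1]]$group)
  P <- length(links); S <- length(subjects)
  group <- array(NA_real_, c(n_keep, control$chains, 2 * P),
                 dimnames = list(NULL, NULL, colnames(chains[[1]]$group)))
  subj <- array(NA_real_, c(n_keep, control$chains, S, P),
                dimnames = list(NULL, NULL, NULL, names(links)))
  for (ch in seq_along(chains)) {
    group[, ch, ] <- chains[[ch]]$group
    subj[, ch, , ] <- chains[[ch]]$subj
  }
  rhat <- apply(group, 3, function(m) split_rhat(m))
  ess <- apply(group, 3, function(m) ess_basic(m))
  list(group = group, subject = subj, rhat = rhat, ess = ess,
       accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept_rate")),
       nonfinite_fraction = mean(vapply(chains, `[[`, numeric(1),
                                        "nonfinite_fraction")))
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends inflate the diagnostic.
#'
#' @param draws A matrix of draws, iterations x chains.
#' @return The split R-hat (1 when the total variance is zero).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  pieces <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[(n - half + 1):n, j])))
  m <- ncol(pieces); nn <- nrow(pieces)
  W <- mean(apply(pieces, 2, stats::var))
  B <- nn * stats::var(colMeans(pieces))
  if (!is.finite(W) || W <= 1e-12) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude effective sample size from lag-autocorrelations (Geyer-style cutoff)
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  total <- 0
  for (j in seq_len(ncol(draws))) {
    x <- draws[, j]
    v <- stats::var(x)
    if (!is.finite(v) || v <= 1e-12) { total <- total + n; next }
    rho <- stats::acf(x, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
    pos <- which(rho < 0.05)
    L <- if (length(pos)) pos[1] else length(rho)
    tau <- 1 + 2 * sum(rho[seq_len(L)])
    total <- total + n / max(tau, 1)
  }
  total
}
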