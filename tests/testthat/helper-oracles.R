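# Independent oracles used across the suite.  These deliberately re-derive
# the quantities from first principles (their own formulas, exhaustive
# enumeration, grid search) rather than calling the package's code paths.

# Exhaustive-pair Harrell concordance: pair (i, j) usable iff the shorter
# observed time ends in an event; concordant when the higher risk belongs to
# the earlier event; risk ties count one half.
oracle_concordance <- function(time, event, risk) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (event[early] != 1) next
      den <- den + 1
      if (risk[early] > risk[late]) num <- num + 1
      else if (risk[early] == risk[late]) num <- num + 0.5
    }
  }
  list(c = num / den, n_pairs = den)
}

# Independent Weibull-PH log-likelihood (lambda/gamma parameterisation,
# written out directly from the density and survivor function).
oracle_loglik <- function(time, event, lambda, gamma, beta = NULL, X = NULL) {
  eta <- if (is.null(beta)) rep(0, length(time)) else drop(X %*% beta)
  h <- log(gamma) + gamma * log(lambda) + (gamma - 1) * log(time) + eta
  H <- (lambda * time)^gamma * exp(eta)
  sum(event * h) - sum(H)
}

# Coarse-to-fine grid maximisation of the Weibull-PH likelihood over
# (lambda, gamma[, beta]).  Independent of the package's Newton solver.
oracle_grid_mle <- function(time, event, x = NULL,
                            lambda_range = c(0.05, 10),
                            gamma_range = c(0.2, 5),
                            beta_range = c(-3, 3),
                            n_grid = 15, n_refine = 9, shrink = 0.35) {
  has_beta <- !is.null(x)
  X <- if (has_beta) matrix(x, ncol = 1) else NULL
  lr <- log(lambda_range)
  gr <- log(gamma_range)
  br <- beta_range
  best <- NULL
  for (step in seq_len(n_refine)) {
    ls <- exp(seq(lr[1], lr[2], length.out = n_grid))
    gs <- exp(seq(gr[1], gr[2], length.out = n_grid))
    bs <- if (has_beta) seq(br[1], br[2], length.out = n_grid) else 0
    for (l in ls) for (g in gs) for (b in bs) {
      ll <- oracle_loglik(time, event, l, g, if (has_beta) b, X)
      if (is.null(best) || ll > best$ll) {
        best <- list(ll = ll, lambda = l, gamma = g, beta = b)
      }
    }
    w_l <- (lr[2] - lr[1]) * shrink / 2
    w_g <- (gr[2] - gr[1]) * shrink / 2
    lr <- log(best$lambda) + c(-w_l, w_l)
    gr <- log(best$gamma) + c(-w_g, w_g)
    if (has_beta) {
      w_b <- (br[2] - br[1]) * shrink / 2
      br <- best$beta + c(-w_b, w_b)
    }
  }
  best
}

# uncensored/censored Weibull-PH test cohort without going through the
# package generator (used where the generator itself is under test elsewhere)
simulate_weibull_direct <- function(n, lambda, gamma, beta = NULL, X = NULL,
                                    censor_max = Inf, seed = 1) {
  withr::with_seed(seed, {
    eta <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
    t0 <- (1 / lambda) * (-log(runif(n)) * exp(-eta))^(1 / gamma)
    cmax <- if (is.finite(censor_max)) runif(n, 0, censor_max) else rep(Inf, n)
    tibble::tibble(
      time_years = pmin(t0, cmax),
      event = as.integer(t0 <= cmax)
    )
  })
}
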