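#' Weibull proportional-hazards log-likelihood
#'
#' Log-likelihood of right-censored data under
#' `S(t | x) = exp{-(lambda * t)^gamma * exp(x' beta)}`:
#' `sum_i d_i [log gamma + gamma log lambda + (gamma - 1) log t_i + x_i' beta]
#'  - (lambda t_i)^gamma exp(x_i' beta)`.
#'
#' Exposed so that independent maximisers (grid searches, profile checks) can
#' be run against the same objective the package optimises.
#'
#' @param time,event Follow-up times (> 0) and 0/1 death indicators.
#' @param lambda,gamma Weibull scale and shape (> 0).
#' @param beta Coefficient vector (may be `NULL` for the empty model).
#' @param X Covariate matrix matching `beta`.
#' @return A single log-likelihood value.
#' @export
weibull_ph_loglik <- function(time, event, lambda, gamma, beta = NULL, X = NULL) {
  eta <- if (!is.null(beta) && length(beta)) drop(X %*% beta) else 0
  lt <- log(time)
  u <- gamma * (lt + log(lambda))
  sum(event * (log(gamma) + u - lt + eta)) - sum(exp(u + eta))
}

# core Newton-Raphson maximizer on theta = (b0, log gamma, beta),
# lambda = exp(-b0).  Returns theta, loglik, observed information.
weibull_ph_newton <- function(time, event, X = NULL, max_iter = 50L, tol = 1e-9) {
  p <- if (is.null(X)) 0L else ncol(X)
  lt <- log(time)
  D <- sum(event)
  th <- c(log(sum(time) / max(D, 1)), 0, rep(0, p))
  llfun <- function(th) {
    eta <- if (p) drop(X %*% th[-(1:2)]) else 0
    g <- exp(th[2])
    u <- g * (lt - th[1])
    sum(event * (th[2] + u - lt + eta)) - sum(exp(u + eta))
  }
  ll <- llfun(th)
  conv <- FALSE
  H <- NULL
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- exp(th[2])
    eta <- if (p) drop(X %*% th[-(1:2)]) else 0
    u <- g * (lt - th[1])
    w <- exp(u + eta)
    r <- event - w
    grad <- c(-g * sum(r), D + sum(u * r), if (p) drop(crossprod(X, r)))
    H <- matrix(0, p + 2, p + 2)
    H[1, 1] <- -g^2 * sum(w)
    H[1, 2] <- H[2, 1] <- -g * sum(r) + g * sum(u * w)
    H[2, 2] <- sum(u * r) - sum(u^2 * w)
    if (p) {
      H[1, -(1:2)] <- H[-(1:2), 1] <- g * colSums(X * w)
      H[2, -(1:2)] <- H[-(1:2), 2] <- -colSums(X * (u * w))
      H[-(1:2), -(1:2)] <- -crossprod(X, X * w)
    }
    if (max(abs(grad)) < 1e-8 * (1 + abs(ll))) {
      conv <- TRUE
      break
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # backtracking line search: never accept a worsening step
    line_search <- function(direction) {
      sf <- 1
      while (sf >= 1e-8) {
        thn <- th + sf * direction
        lln <- llfun(thn)
        if (is.finite(lln) && lln >= ll - 1e-13) return(list(th = thn, ll = lln))
        sf <- sf / 2
      }
      NULL
    }
    got <- line_search(-step)
    if (is.null(got)) {
      # Newton direction useless (Hessian not yet negative definite away
      # from the optimum): fall back to a steepest-ascent step
      got <- line_search(grad / max(abs(grad)))
    }
    if (is.null(got)) break
    thn <- got$th
    lln <- got$ll
    moved <- max(abs(thn - th))
    th <- thn
    ll <- lln
    if (moved < tol) {
      conv <- TRUE
      break
    }
  }
  list(theta = unname(th), loglik = ll, hessian = H, converged = conv,
       iterations = it)
}

# observed-information Hessian of the PH log-likelihood at theta
weibull_ph_hessian <- function(time, event, X, th) {
  p <- if (is.null(X)) 0L else ncol(X)
  lt <- log(time)
  g <- exp(th[2])
  eta <- if (p) drop(X %*% th[-(1:2)]) else 0
  u <- g * (lt - th[1])
  w <- exp(u + eta)
  r <- event - w
  H <- matrix(0, p + 2, p + 2)
  H[1, 1] <- -g^2 * sum(w)
  H[1, 2] <- H[2, 1] <- -g * sum(r) + g * sum(u * w)
  H[2, 2] <- sum(u * r) - sum(u^2 * w)
  if (p) {
    H[1, -(1:2)] <- H[-(1:2), 1] <- g * colSums(X * w)
    H[2, -(1:2)] <- H[-(1:2), 2] <- -colSums(X * (u * w))
    H[-(1:2), -(1:2)] <- -crossprod(X, X * w)
  }
  H
}

#' Fit a Weibull proportional-hazards model by maximum likelihood
#'
#' Maximises the likelihood of [weibull_ph_loglik()] by Newton-Raphson on the
#' unconstrained scale `(beta0, log gamma, beta)` with `lambda =
#' exp(-beta0)`, falling back to BFGS when the Newton step fails.  The
#' covariance matrix comes from the observed information at the maximum.
#' With `center = TRUE`, covariates are centered at their sample means before
#' fitting and the centering constants are stored on the fit; centering
#' leaves the coefficients, shape and log-likelihood unchanged and only
#' shifts the intercept.
#'
#' @param data Data frame with outcome columns and covariates.  Requested
#'   covariates must be complete: impute or drop incomplete rows first.
#' @param covariates Character vector of covariate column names (may be
#'   empty, giving the "empty" baseline model whose `(lambda, gamma)` anchor
#'   the risk score).
#' @param time_col,event_col Outcome column names.
#' @param center Center covariates at their sample means before fitting?
#' @return An object of class `weibull_ph_fit`: coefficients (per original
#'   unit), `lambda`, `gamma`, `loglik`, `aic` (`-2 loglik + 2 * n_par`),
#'   covariance of `(beta0, log gamma, beta)`, per-coefficient Wald table,
#'   convergence status and diagnostics.
#' @examples
#' cohort <- generate_cohort(pdac_cohort_spec(n_patients = 200, seed = 1))
#' fit <- fit_weibull_ph(cohort, c("sdma", "tg15"))
#' tidy(fit)
#' glance(fit)
#' @export
fit_weibull_ph <- function(data, covariates = character(),
                           time_col = "time_years", event_col = "event",
                           center = FALSE) {
  check_outcome(data, time_col, event_col)
  check_covariates_present(data, covariates)
  time <- data[[time_col]]
  event <- data[[event_col]]
  p <- length(covariates)
  X <- NULL
  centering <- NULL
  if (p) {
    X <- as.matrix(data[covariates])
    if (!is.numeric(X)) stop_invalid("All covariates must be numeric.")
    if (anyNA(X)) {
      stop_invalid("Missing values among requested covariates; impute or drop incomplete rows first.")
    }
    if (center) {
      centering <- colMeans(X)
      X <- sweep(X, 2, centering)
    }
  }
  res <- weibull_ph_newton(time, event, X)
  if (!res$converged) {
    # quasi-Newton fallback from the same start
    nll <- function(th) {
      eta <- if (p) drop(X %*% th[-(1:2)]) else 0
      g <- exp(th[2])
      u <- g * (log(time) - th[1])
      -(sum(event * (th[2] + u - log(time) + eta)) - sum(exp(u + eta)))
    }
    opt <- tryCatch(
      optim(res$theta, nll, method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$value) && -opt$value > res$loglik) {
      res$theta <- opt$par
      res$loglik <- -opt$value
      res$converged <- opt$convergence == 0
      res$hessian <- weibull_ph_hessian(time, event, X, opt$par)
    }
  }
  th <- res$theta
  beta <- if (p) setNames(th[-(1:2)], covariates) else setNames(numeric(0), character(0))
  n_par <- p + 2L
  vcov <- tryCatch(solve(-res$hessian), error = function(e) matrix(NA_real_, n_par, n_par))
  dimnames(vcov) <- list(c("beta0", "log_gamma", covariates),
                         c("beta0", "log_gamma", covariates))
  se_beta <- if (p) sqrt(pmax(diag(vcov)[-(1:2)], 0)) else numeric(0)
  z <- beta / se_beta
  fit <- structure(
    list(
      coefficients = beta,
      beta0 = th[1],
      lambda = exp(-th[1]),
      gamma = exp(th[2]),
      loglik = res$loglik,
      aic = -2 * res$loglik + 2 * n_par,
      vcov = vcov,
      wald = tibble(
        term = covariates,
        estimate = unname(beta),
        std.error = unname(se_beta),
        statistic = unname(z),
        p.value = unname(2 * pnorm(-abs(z)))
      ),
      centering = centering,
      n_used = length(time),
      n_events = sum(event),
      converged = res$converged,
      iterations = res$iterations,
      time_col = time_col,
      event_col = event_col
    ),
    class = "weibull_ph_fit"
  )
  if (!fit$converged) {
    warn("Weibull PH fit did not converge; inspect `$converged` and `$iterations`.")
  }
  fit
}

#' Baseline Weibull survivor function
#'
#' `S0(t) = exp{-(lambda * t)^gamma}`, the survivor function of the empty
#' (covariate-free) Weibull model.  With the published empty-model estimates
#' `lambda = 1.7376`, `gamma = 1.0769` this evaluates to 0.1632 at `t = 1`,
#' the multiplicative constant of the one-year risk score.
#'
#' @param lambda,gamma Scale (> 0) and shape (> 0).
#' @param t Time(s), `>= 0` (years).
#' @return Survival probabilities in `[0, 1]`.
#' @examples
#' baseline_survivor(1.7376, 1.0769, 1)
#' @export
baseline_survivor <- function(lambda, gamma, t) {
  if (any(lambda <= 0) || any(gamma <= 0)) {
    stop_invalid("`lambda` and `gamma` must be strictly positive.")
  }
  if (any(t < 0)) stop_invalid("`t` must be non-negative.")
  exp(-(lambda * t)^gamma)
}

#' Hazard ratio per one-SD increase
#'
#' Converts a per-unit PH coefficient into the hazard ratio for a one-SD
#' increment of the covariate, `exp(beta * sd)` --- the scale on which
#' metabolite effects are reported.
#'
#' @param beta Coefficient(s) per original unit.
#' @param sd Covariate standard deviation(s), > 0.
#' @return Hazard ratio(s).
#' @examples
#' hazard_ratio_per_sd(-0.020, 51.73) # lysine
#' @export
hazard_ratio_per_sd <- function(beta, sd) {
  if (any(sd <= 0)) stop_invalid("`sd` must be strictly positive.")
  exp(beta * sd)
}

#' Predict from a Weibull PH fit
#'
#' @param object A `weibull_ph_fit`.
#' @param newdata Data frame containing the fit's covariates.
#' @param t Prediction horizon in years (default 1).
#' @param type `"risk"` for the probability of death by `t`, `"survival"`
#'   for `S(t | x)`, `"lp"` for the linear predictor.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.weibull_ph_fit <- function(object, newdata, t = 1,
                                   type = c("risk", "survival", "lp"), ...) {
  type <- match.arg(type)
  p <- length(object$coefficients)
  lp <- if (p) {
    check_covariates_present(newdata, names(object$coefficients))
    X <- as.matrix(newdata[names(object$coefficients)])
    if (!is.null(object$centering)) X <- sweep(X, 2, object$centering)
    drop(X %*% object$coefficients)
  } else {
    rep(0, nrow(newdata))
  }
  if (type == "lp") return(lp)
  s <- baseline_survivor(object$lambda, object$gamma, t)^exp(lp)
  if (type == "survival") s else 1 - s
}

#' @export
print.weibull_ph_fit <- function(x, ...) {
  cat("Weibull proportional-hazards fit\n")
  cat(sprintf("  scale lambda = %.4f, shape gamma = %.4f\n", x$lambda, x$gamma))
  cat(sprintf("  n = %d, events = %d, logLik = %.3f, AIC = %.3f\n",
              x$n_used, x$n_events, x$loglik, x$aic))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (nrow(x$wald)) {
    print(x$wald)
  } else {
    cat("  (empty model: no covariates)\n")
  }
  invisible(x)
}

#' @rdname fit_weibull_ph
#' @param x A `weibull_ph_fit`.
#' @param ... Unused.
#' @method tidy weibull_ph_fit
#' @export
tidy.weibull_ph_fit <- function(x, ...) x$wald

#' @rdname fit_weibull_ph
#' @method glance weibull_ph_fit
#' @export
glance.weibull_ph_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda, gamma = x$gamma, logLik = x$loglik, AIC = x$aic,
    nobs = x$n_used, n_events = x$n_events, converged = x$converged
  )
}

#' Serialize a Weibull PH fit to JSON (and back)
#'
#' The JSON file is the portable model format consumed by the risk-score
#' builder: coefficient names and values, `lambda`, `gamma`, covariance,
#' AIC/log-likelihood and centering constants, at full precision.
#'
#' @param fit A `weibull_ph_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `weibull_fit_to_json()`: `path` (invisibly) or a JSON string;
#'   `weibull_fit_from_json()`: a `weibull_ph_fit`.
#' @export
weibull_fit_to_json <- function(fit, path = NULL) {
  payload <- list(
    format = "mrscore_weibull_ph_fit", version = 1L,
    terms = names(fit$coefficients),
    coefficients = unname(fit$coefficients),
    beta0 = fit$beta0, lambda = fit$lambda, gamma = fit$gamma,
    loglik = fit$loglik, aic = fit$aic,
    vcov = fit$vcov,
    centering = if (is.null(fit$centering)) NULL else unname(fit$centering),
    n_used = fit$n_used, n_events = fit$n_events, converged = fit$converged
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname weibull_fit_to_json
#' @export
weibull_fit_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  terms <- as.character(x$terms %||% character(0))
  vcov <- as.matrix(x$vcov)
  dimnames(vcov) <- list(c("beta0", "log_gamma", terms),
                         c("beta0", "log_gamma", terms))
  beta <- setNames(as.numeric(x$coefficients %||% numeric(0)), terms)
  se_beta <- if (length(terms)) sqrt(pmax(diag(vcov)[-(1:2)], 0)) else numeric(0)
  z <- beta / se_beta
  structure(
    list(
      coefficients = beta,
      beta0 = x$beta0, lambda = x$lambda, gamma = x$gamma,
      loglik = x$loglik, aic = x$aic, vcov = vcov,
      wald = tibble(term = terms, estimate = unname(beta),
                    std.error = unname(se_beta), statistic = unname(z),
                    p.value = unname(2 * pnorm(-abs(z)))),
      centering = if (is.null(x$centering)) NULL else setNames(as.numeric(x$centering), terms),
      n_used = x$n_used, n_events = x$n_events, converged = x$converged,
      iterations = NA_integer_, time_col = NA_character_, event_col = NA_character_
    ),
    class = "weibull_ph_fit"
  )
}
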