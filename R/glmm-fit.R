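# Two-level random-intercept logistic regression by maximum likelihood.
# The marginal likelihood integrates the area intercept out of the Bernoulli
# likelihood with adaptive Gauss-Hermite quadrature: each area's integral is
# recentred at the conditional mode of its random effect and rescaled by the
# conditional curvature, so a modest node count is accurate even for large
# cluster sizes.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big] + log1p(exp(-x[big]))
  out[!big] <- log1p(exp(x[!big]))
  out
}

# Bernoulli log-likelihood contributions for linear predictor eta
bernoulli_ll <- function(y, eta) y * eta - log1pexp(eta)

# per-group sums of a vector, groups coded 1..J
group_sum <- function(x, gidx, J) {
  drop(rowsum(x, gidx, reorder = TRUE))
}

# Conditional modes of the area random effects and the curvature there.
# Newton iterations on the strictly concave per-area objective
#   h_j(u) = sum_i bernoulli_ll(y_i, eta_i + u) - u^2/(2 sigma^2)
find_modes <- function(y, eta, gidx, J, sigma, u0 = NULL,
                       tol = 1e-11, maxit = 200L) {
  u <- if (is.null(u0)) numeric(J) else u0
  inv_s2 <- 1 / sigma^2
  hval <- function(u) {
    group_sum(bernoulli_ll(y, eta + u[gidx]), gidx, J) - u^2 * inv_s2 / 2
  }
  f_cur <- hval(u)
  for (it in seq_len(maxit)) {
    et <- eta + u[gidx]
    p <- plogis(et)
    g1 <- group_sum(y - p, gidx, J) - u * inv_s2
    h <- -group_sum(p * (1 - p), gidx, J) - inv_s2
    step <- pmin(pmax(-g1 / h, -20), 20)
    # step halving: the per-area objective is strictly concave, so a damped
    # Newton step always admits an increase
    u_new <- u + step
    f_new <- hval(u_new)
    for (k in 1:30) {
      worse <- f_new < f_cur - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      u_new[worse] <- u[worse] + step[worse]
      f_new[worse] <- hval(u_new)[worse]
    }
    u <- u_new
    f_cur <- f_new
    if (max(abs(g1 * step)) < tol) break
  }
  et <- eta + u[gidx]
  p <- plogis(et)
  h <- -group_sum(p * (1 - p), gidx, J) - inv_s2
  list(u = u, scale = 1 / sqrt(-h))
}

# Adaptive GH evaluation. Returns the total log-likelihood; when
# want_grad = TRUE also the score in (beta, log sigma) via the Fisher
# identity with posterior weights taken at the same quadrature nodes.
agq_eval <- function(y, X, gidx, J, beta, sigma, gh, u0 = NULL,
                     want_grad = FALSE) {
  eta <- drop(X %*% beta)
  if (sigma < 1e-10) {
    ll <- sum(bernoulli_ll(y, eta))
    if (!want_grad) return(list(loglik = ll, u = u0))
    return(list(loglik = ll,
                grad = c(drop(crossprod(X, y - plogis(eta))), 0),
                u = u0))
  }
  modes <- find_modes(y, eta, gidx, J, sigma, u0 = u0)
  u <- modes$u
  s <- modes$scale
  K <- length(gh$x)
  logw <- log(gh$w) + gh$x^2
  terms <- matrix(0, J, K)  # log integrand at each node, per area
  resid <- if (want_grad) matrix(0, length(y), K)
  for (k in seq_len(K)) {
    uk <- u + sqrt(2) * s * gh$x[k]
    et <- eta + uk[gidx]
    terms[, k] <- logw[k] +
      group_sum(bernoulli_ll(y, et), gidx, J) +
      dnorm(uk, 0, sigma, log = TRUE)
    if (want_grad) resid[, k] <- y - plogis(et)
  }
  m <- apply(terms, 1, max)
  wexp <- exp(terms - m)
  ll <- sum(m + log(rowSums(wexp)) + 0.5 * log(2) + log(s))
  if (!want_grad) return(list(loglik = ll, u = u))
  pw <- wexp / rowSums(wexp)              # posterior node weights per area
  wrow <- rowSums(resid * pw[gidx, , drop = FALSE])  # E[y - p | y] per record
  grad_beta <- drop(crossprod(X, wrow))
  umat <- outer(u, rep(1, K)) + sqrt(2) * outer(s, gh$x)
  grad_ls <- sum(pw * (umat^2 / sigma^2 - 1))
  list(loglik = ll, grad = c(grad_beta, grad_ls), u = u)
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Sum over areas of the log integral of the Bernoulli likelihood against the
#' Normal(0, sigma^2) random-intercept density, each integral approximated by
#' adaptive Gauss-Hermite quadrature centred at the area's conditional mode.
#' At `sigma = 0` this is exactly the ordinary logistic log-likelihood.
#'
#' @param design A [build_design()] object.
#' @param beta Fixed-effect coefficients, in design-column order.
#' @param sigma Random-intercept standard deviation (>= 0).
#' @param order Number of quadrature nodes (>= 1; odd orders place a node at
#'   the mode).
#' @return The marginal log-likelihood (a single number).
#' @export
glmm_loglik <- function(design, beta, sigma, order = 15) {
  stopifnot(inherits(design, "glmm_design"))
  if (length(beta) != ncol(design$X)) {
    stop(sprintf("`beta` must have %d entries (design columns).",
                 ncol(design$X)), call. = FALSE)
  }
  if (!all(is.finite(beta)) || !is.finite(sigma) || sigma < 0) {
    stop("`beta` must be finite and `sigma` finite and >= 0.", call. = FALSE)
  }
  if (order < 1) stop_field("order", "must be >= 1")
  gidx <- as.integer(design$group)
  J <- nlevels(design$group)
  gh <- pracma::gaussHermite(as.integer(order))
  agq_eval(design$y, design$X, gidx, J, beta, sigma, gh)$loglik
}

#' Fit a two-level random-intercept logistic model by maximum likelihood
#'
#' Persons nested in areas; the marginal likelihood is maximised over
#' (beta, log sigma) by BFGS with analytic scores, starting from the ordinary
#' logistic fit and a small positive sigma. Standard errors come from the
#' inverse of a central-finite-difference Hessian at the optimum. Fits that
#' shrink the random-intercept SD to the boundary are reported with
#' `tau2 = 0` and `boundary = TRUE` (the fixed effects then equal the
#' ordinary logistic fit).
#'
#' @param records Dichotomised person records (see [build_design()]), or a
#'   prebuilt `glmm_design`.
#' @param terms Fixed-effect terms, a subset of
#'   `c("access", "sex", "age", "irsd")`; ignored when `records` is already a
#'   design.
#' @param constants [standardization_constants()] for continuous terms.
#' @param quad_order Gauss-Hermite node count (default 15).
#' @param se Compute standard errors (finite-difference Hessian)? Skipping
#'   them speeds up simulation studies that only need point estimates.
#' @return An object of class `area_glmm`: fixed-effect estimates and SEs,
#'   `tau2`, `loglik`, `aic`, counts, and convergence flags. Methods:
#'   [tidy()], [glance()], [odds_ratios()], `print()`.
#' @export
fit_area_glmm <- function(records, terms = character(), constants = NULL,
                          quad_order = 15, se = TRUE) {
  design <- if (inherits(records, "glmm_design")) {
    records
  } else {
    build_design(records, terms, constants)
  }
  y <- design$y
  X <- design$X
  gidx <- as.integer(design$group)
  J <- nlevels(design$group)
  if (J < 2) {
    stop("A random intercept needs at least 2 areas.", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("Outcome has a single class; the model is not identifiable.",
         call. = FALSE)
  }
  p <- ncol(X)
  gh <- pracma::gaussHermite(as.integer(quad_order))

  glm0 <- glm.fit(X, y, family = binomial())
  theta0 <- c(coef(glm0), log(0.3))

  ustate <- new.env(parent = emptyenv())
  ustate$u <- numeric(J)
  nll <- function(theta) {
    r <- agq_eval(y, X, gidx, J, theta[1:p], exp(theta[p + 1]), gh,
                  u0 = ustate$u)
    if (!is.null(r$u)) ustate$u <- r$u
    -r$loglik
  }
  ngr <- function(theta) {
    r <- agq_eval(y, X, gidx, J, theta[1:p], exp(theta[p + 1]), gh,
                  u0 = ustate$u, want_grad = TRUE)
    if (!is.null(r$u)) ustate$u <- r$u
    g <- -r$grad
    # chain rule already in log sigma; clamp runaway boundary steps
    g
  }
  # log sigma is boxed: below -7 the fit is indistinguishable from the
  # boundary, above 2.5 the latent scale is far outside the logistic range
  lower <- c(rep(-Inf, p), -7)
  upper <- c(rep(Inf, p), 2.5)
  run_opt <- function(start) {
    optim(start, nll, ngr, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 500, factr = 1e4))
  }
  opt <- run_opt(theta0)
  # a quasi-Newton stall with a stale curvature estimate leaves a large
  # score; restarting from the stalled point rebuilds the Hessian
  for (restart in 1:3) {
    if (max(abs(ngr(opt$par))) < 1e-5 * max(1, abs(opt$value))) break
    opt <- run_opt(opt$par)
  }
  beta_hat <- opt$par[1:p]
  sigma_hat <- unname(exp(opt$par[p + 1]))
  boundary <- sigma_hat < 1.1e-3  # at or near the lower box of log sigma
  if (boundary) {
    # variance at the boundary: the fixed effects are the plain logistic MLE
    beta_hat <- coef(glm0)
    sigma_hat <- 0
    loglik <- sum(bernoulli_ll(y, drop(X %*% beta_hat)))
  } else {
    loglik <- -opt$value
  }
  n_params <- p + 1L
  ses <- rep(NA_real_, p)
  if (se) {
    if (boundary) {
      fit_glm <- glm(y ~ X - 1, family = binomial())
      ses <- sqrt(diag(vcov(fit_glm)))
    } else {
      H <- fd_hessian(function(th) {
        agq_eval(y, X, gidx, J, th[1:p], exp(th[p + 1]), gh,
                 u0 = ustate$u)$loglik
      }, opt$par)
      V <- try(solve(-H), silent = TRUE)
      if (!inherits(V, "try-error") && all(diag(V)[1:p] > 0)) {
        ses <- sqrt(diag(V)[1:p])
      }
    }
  }
  gfinal <- if (boundary) NULL else ngr(opt$par)
  grad_ok <- boundary ||
    max(abs(gfinal)) < 1e-5 * max(1, abs(loglik))
  structure(
    list(
      beta = setNames(beta_hat, colnames(X)),
      se = setNames(ses, colnames(X)),
      tau2 = sigma_hat^2,
      sigma = sigma_hat,
      loglik = loglik,
      aic = -2 * loglik + 2 * n_params,
      n_obs = length(y),
      n_groups = J,
      n_params = n_params,
      converged = opt$convergence == 0 && grad_ok,
      boundary = boundary,
      quad_order = as.integer(quad_order),
      terms = design$terms,
      constants = design$constants
    ),
    class = "area_glmm"
  )
}

# Central finite-difference Hessian of a scalar function.
fd_hessian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Odds ratios with Wald intervals
#'
#' Exponentiates the fixed-effect estimates; 95% intervals are
#' `exp(beta +/- 1.96 se)` and p-values are two-sided Wald. Continuous terms
#' are per SD of the area-level distribution by construction of the design.
#'
#' @param fit An `area_glmm` fit.
#' @return A tibble with `term`, `log_odds`, `se`, `or`, `or_low`, `or_high`,
#'   `p_value`.
#' @export
odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "area_glmm"))
  z <- fit$beta / fit$se
  tibble::tibble(
    term = names(fit$beta),
    log_odds = unname(fit$beta),
    se = unname(fit$se),
    or = exp(unname(fit$beta)),
    or_low = exp(unname(fit$beta - 1.96 * fit$se)),
    or_high = exp(unname(fit$beta + 1.96 * fit$se)),
    p_value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_nested,fit_full Two `area_glmm` fits of the same records, the
#'   first with a fixed-effect set strictly contained in the second's.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, plus the two
#'   log-likelihoods.
#' @export
lr_test <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "area_glmm"), inherits(fit_full, "area_glmm"))
  if (fit_nested$n_obs != fit_full$n_obs) {
    stop("Fits use different numbers of observations; not comparable.",
         call. = FALSE)
  }
  if (!all(fit_nested$terms %in% fit_full$terms) ||
      fit_full$n_params <= fit_nested$n_params) {
    stop("`fit_nested` must be strictly nested in `fit_full`.", call. = FALSE)
  }
  statistic <- max(0, 2 * (fit_full$loglik - fit_nested$loglik))
  df <- fit_full$n_params - fit_nested$n_params
  tibble::tibble(
    statistic = statistic,
    df = df,
    p_value = pchisq(statistic, df, lower.tail = FALSE),
    loglik_nested = fit_nested$loglik,
    loglik_full = fit_full$loglik
  )
}

#' @export
print.area_glmm <- function(x, ...) {
  cat("Two-level random-intercept logistic model (adaptive GH quadrature)\n")
  cat(sprintf("  terms: intercept%s\n",
              if (length(x$terms)) paste0(" + ", paste(x$terms, collapse = " + ")) else " (null model)"))
  cat(sprintf("  n = %d persons in %d areas; quadrature order %d\n",
              x$n_obs, x$n_groups, x$quad_order))
  cat(sprintf("  logLik = %.2f  AIC = %.2f  tau2 = %.4g%s\n",
              x$loglik, x$aic, x$tau2,
              if (x$boundary) " (boundary)" else ""))
  if (!x$converged) cat("  WARNING: fit did not meet convergence criteria\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname fit_area_glmm
#' @param x An `area_glmm` fit.
#' @param ... Unused.
#' @export
tidy.area_glmm <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @rdname fit_area_glmm
#' @export
glance.area_glmm <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    n_params = x$n_params,
    logLik = x$loglik,
    AIC = x$aic,
    tau2 = x$tau2,
    icc = icc_latent(x$tau2),
    mor = median_odds_ratio(x$tau2),
    converged = x$converged,
    boundary = x$boundary
  )
}
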