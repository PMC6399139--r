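#' Specify a count-regression model
#'
#' The four families used for incidence modelling: Poisson, negative
#' binomial (NB2, variance `mu + mu^2/theta`), and their zero-inflation
#' extensions, which model structural zeros with a separate logistic
#' component. All families use a log link with `log(e)` as offset, turning
#' counts into incidence rates.
#'
#' @param family one of `"poisson"`, `"negbin"`, `"zip"`, `"zinb"`.
#' @param count_covariates covariate column names of the count component.
#' @param zi_covariates covariate column names of the zero-inflation
#'   logistic component (an intercept is always included); must be empty for
#'   non-zero-inflated families.
#' @param offset_name offset column (at-risk dog population).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "negbin", "zip", "zinb"),
                       count_covariates = character(),
                       zi_covariates = character(),
                       offset_name = "e") {
  family <- match.arg(family)
  if (!family %in% c("zip", "zinb") && length(zi_covariates) > 0)
    stop("zi_covariates must be empty for family ", family)
  structure(list(family = family,
                 count_covariates = as.character(count_covariates),
                 zi_covariates = as.character(zi_covariates),
                 offset_name = offset_name),
            class = "model_spec")
}

spec_has_theta <- function(spec) spec$family %in% c("negbin", "zinb")
spec_has_zi <- function(spec) spec$family %in% c("zip", "zinb")

# Model frame: validated y, offset, design matrices.
spec_frame <- function(spec, table) {
  need <- unique(c(spec$count_covariates, spec$zi_covariates, spec$offset_name))
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("unit table lacks columns: ", paste(miss, collapse = ", "))
  if (!"y" %in% names(table)) stop("unit table lacks outcome column y")
  y <- table$y
  if (anyNA(y) || any(y < 0) || any(y != floor(y)))
    stop("y must be nonnegative integer counts without NA")
  e <- table[[spec$offset_name]]
  if (any(e <= 0)) stop("offset must be positive for all rows")
  design <- function(covars) {
    M <- matrix(1, length(y), 1L + length(covars),
                dimnames = list(NULL, c("(Intercept)", covars)))
    for (v in covars) M[, v] <- as.numeric(table[[v]])
    M
  }
  X <- design(spec$count_covariates)
  Z <- if (spec_has_zi(spec)) design(spec$zi_covariates) else NULL
  const <- function(M) colnames(M)[apply(M, 2, function(x)
    length(x) > 1 && stats::var(x) == 0)]
  badx <- setdiff(const(X), "(Intercept)")
  if (length(badx)) stop("constant covariate column(s): ", paste(badx, collapse = ", "))
  list(y = as.numeric(y), e = as.numeric(e), loge = log(as.numeric(e)),
       X = X, Z = Z, n = length(y))
}

n_params_of <- function(spec) {
  1L + length(spec$count_covariates) + as.integer(spec_has_theta(spec)) +
    if (spec_has_zi(spec)) 1L + length(spec$zi_covariates) else 0L
}

# Parameter packing: [alpha, beta..., log(theta)?, gamma0, gamma...?]
unpack_params <- function(spec, par) {
  kc <- 1L + length(spec$count_covariates)
  i <- kc
  out <- list(count = par[seq_len(kc)])
  if (spec_has_theta(spec)) { i <- i + 1L; out$log_theta <- par[i] }
  if (spec_has_zi(spec)) out$zi <- par[(i + 1L):length(par)]
  out
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# Joint negative log-likelihood and analytic gradient for all four families.
make_nll <- function(spec, fr) {
  y <- fr$y; X <- fr$X; Z <- fr$Z; loge <- fr$loge
  pos <- y > 0
  has_theta <- spec_has_theta(spec)
  has_zi <- spec_has_zi(spec)

  core <- function(par) {
    p <- unpack_params(spec, par)
    # clamp the linear predictor so a wild optimizer step cannot overflow
    # exp(); the likelihood there is astronomically bad either way
    eta <- pmin(drop(X %*% p$count) + loge, 500)
    mu <- exp(eta)
    # theta capped at 1e7, where NB is numerically Poisson; beyond the cap
    # the surface is flat in log(theta) and its gradient exactly zero,
    # instead of floating-point noise amplified by theta
    theta <- if (has_theta) exp(min(p$log_theta, log(1e7))) else NULL
    if (has_theta) {
      llc <- lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * (eta - log(theta + mu))
      logf0 <- theta * (log(theta) - log(theta + mu))
    } else {
      llc <- y * eta - mu - lgamma(y + 1)
      logf0 <- -mu
    }
    if (has_zi) {
      lin <- drop(Z %*% p$zi)
      logpi <- stats::plogis(lin, log.p = TRUE)
      log1mpi <- stats::plogis(-lin, log.p = TRUE)
      ll <- ifelse(pos, log1mpi + llc, logsumexp2(logpi, log1mpi + logf0))
      list(p = p, eta = eta, mu = mu, theta = theta, lin = lin,
           logpi = logpi, log1mpi = log1mpi, logf0 = logf0, llc = llc, ll = ll)
    } else {
      list(p = p, eta = eta, mu = mu, theta = theta, llc = llc, ll = llc)
    }
  }

  nll <- function(par) {
    if (any(!is.finite(par))) return(1e300)
    v <- sum(core(par)$ll)
    if (!is.finite(v)) 1e300 else -v
  }

  grad <- function(par) {
    if (any(!is.finite(par))) stop("nonfinite parameters")
    s <- core(par)
    mu <- s$mu; theta <- s$theta
    th_scale <- if (has_theta && s$p$log_theta < log(1e7)) theta else 0
    if (has_theta) {
      deta <- (y - mu) * theta / (theta + mu)
      dlth <- digamma(y + theta) - digamma(theta) +
        log(theta / (theta + mu)) + 1 - (y + theta) / (theta + mu)
      dlogf0_deta <- -theta * mu / (theta + mu)
      dlogf0_dth <- log(theta / (theta + mu)) + mu / (theta + mu)
    } else {
      deta <- y - mu
      dlogf0_deta <- -mu
    }
    if (has_zi) {
      ll0 <- s$ll
      # posterior weight of the count-zero component on zero rows; both
      # mixture terms are <= ll0, so these exponents never overflow
      w <- exp(s$log1mpi + s$logf0 - ll0)
      pi_ <- exp(s$logpi)
      deta_all <- ifelse(pos, deta, w * dlogf0_deta)
      dlin <- ifelse(pos, -pi_,
                     exp(s$logpi - ll0 + s$log1mpi) * (1 - exp(s$logf0)))
      g <- c(drop(crossprod(X, deta_all)),
             if (has_theta)
               sum(ifelse(pos, dlth, w * dlogf0_dth)) * th_scale,
             drop(crossprod(Z, dlin)))
    } else {
      g <- c(drop(crossprod(X, deta)),
             if (has_theta) sum(dlth) * th_scale)
    }
    -unname(g)
  }

  list(nll = nll, grad = grad, core = core)
}

#' Log-likelihood of a count model at given parameters
#'
#' Evaluates the (zero-inflated) Poisson / negative binomial log-likelihood
#' with log offset at user-supplied parameters — useful for checks and
#' likelihood profiling.
#'
#' @param spec a [model_spec()].
#' @param params list with `alpha`, `beta` (named, matching
#'   `count_covariates`), and where applicable `theta` and `gamma` (named,
#'   `"(Intercept)"` first).
#' @param table unit table with columns `y`, offset, covariates.
#' @return the log-likelihood (scalar).
#' @export
count_log_likelihood <- function(spec, params, table) {
  fr <- spec_frame(spec, table)
  beta <- if (length(spec$count_covariates))
    params$beta[spec$count_covariates] else numeric(0)
  par <- c(params$alpha, beta)
  if (spec_has_theta(spec)) {
    if (is.null(params$theta) || params$theta <= 0) stop("theta must be > 0")
    par <- c(par, log(params$theta))
  }
  n_count <- length(par)
  if (spec_has_zi(spec)) {
    gam <- params$gamma
    par <- c(par, gam[["(Intercept)"]],
             if (length(spec$zi_covariates)) gam[spec$zi_covariates])
  }
  if (any(!is.finite(par[seq_len(n_count)])))
    stop("nonfinite count-component parameters")
  # +/-Inf zero-inflation parameters (pi = 1 or 0) are allowed limiting cases
  if (length(par) > n_count && anyNA(par[-seq_len(n_count)]))
    stop("NA zero-inflation parameters")
  ll <- sum(make_nll(spec, fr)$core(par)$ll)
  ll
}

#' Fit a count-regression model by maximum likelihood
#'
#' Numerical maximum likelihood with a fixed, reproducible strategy: the
#' intercept starts at `log(sum(y)/sum(e))` with zero slopes; negative
#' binomial fits start from the Poisson solution with a method-of-moments
#' dispersion; zero-inflated fits start from the corresponding non-inflated
#' solution with zero logistic coefficients. BFGS with analytic gradients is
#' followed by Newton polishing to a gradient-norm tolerance of 1e-8. Wald
#' standard errors come from the inverse observed information.
#'
#' @param spec a [model_spec()].
#' @param table unit table with outcome `y`, positive offset and covariates.
#' @param control list; `maxit` (BFGS iterations, default 500), `grad_tol`
#'   (default 1e-8), `fail_tol` (gradient norm above which the fit is
#'   declared non-converged, default 1e-4).
#' @return an object of class `count_model_fit` with elements
#'   `coefficients` (count component, intercept first), `zi_coefficients`,
#'   `theta`, `se`, `zi_se`, `theta_se`, `p`, `zi_p`, `loglik`, `aic`,
#'   `deviance`, `n_params`, `n`, `converged`, `grad_norm`, `spec`, `table`.
#' @export
fit_count_model <- function(spec, table, control = list()) {
  ctrl <- utils::modifyList(list(maxit = 500L, grad_tol = 1e-8,
                                 fail_tol = 1e-4), control)
  fr <- spec_frame(spec, table)
  k <- n_params_of(spec)
  if (fr$n <= k)
    stop("degenerate table: ", fr$n, " rows for ", k, " parameters")

  start <- fit_start(spec, fr, ctrl)
  fn <- make_nll(spec, fr)
  opt <- stats::optim(start, fn$nll, fn$grad, method = "BFGS",
                      control = list(maxit = ctrl$maxit, reltol = 1e-12))
  par <- newton_polish(opt$par, fn, ctrl)
  # on equidispersed data theta runs to the +Inf boundary, where the
  # gradient in log(theta) decays like 1/theta without ever vanishing and
  # its vanishing curvature spoils Newton steps for the other parameters;
  # past 1e6 the fit is numerically Poisson: freeze log(theta), polish the
  # rest, and count the fit as boundary-converged
  kc0 <- 1L + length(spec$count_covariates)
  boundary_theta <- function(p) spec_has_theta(spec) && exp(p[kc0 + 1L]) > 1e6
  if (boundary_theta(par)) {
    idx <- setdiff(seq_along(par), kc0 + 1L)
    base <- par
    sub <- list(nll = function(q) { base[idx] <- q; fn$nll(base) },
                grad = function(q) { base[idx] <- q; fn$grad(base)[idx] })
    o2 <- stats::optim(par[idx], sub$nll, sub$grad, method = "BFGS",
                       control = list(maxit = ctrl$maxit, reltol = 1e-12))
    par[idx] <- newton_polish(o2$par, sub, ctrl)
  }
  active <- function(g) {
    if (boundary_theta(par)) g[kc0 + 1L] <- 0
    g
  }
  g_norm <- sqrt(sum(active(fn$grad(par))^2))
  # restart rounds: flat ridges (zero-inflation drift under separation)
  # leave BFGS short of the tolerance; keep restarting while it helps
  for (round in seq_len(6L)) {
    if (g_norm <= ctrl$grad_tol) break
    opt <- stats::optim(par, fn$nll, fn$grad, method = "BFGS",
                        control = list(maxit = ctrl$maxit, reltol = 1e-12))
    cand <- newton_polish(opt$par, fn, ctrl)
    g_new <- sqrt(sum(active(fn$grad(cand))^2))
    # accept only genuine progress: a same-likelihood point further along
    # a flat ridge can carry a worse gradient
    if (fn$nll(cand) < fn$nll(par) - 1e-8 || g_new < g_norm) {
      par <- cand
      if (g_new >= 0.5 * g_norm) { g_norm <- min(g_norm, g_new); break }
      g_norm <- g_new
    } else break
  }
  # failure threshold scales with the objective so large-n fits are not
  # rejected for a gradient that is tiny relative to the log-likelihood
  fail_at <- ctrl$fail_tol * max(1, abs(fn$nll(par)))
  if (!is.finite(fn$nll(par)) || g_norm > fail_at) {
    if (is.finite(fn$nll(par)) && g_norm < 1)
      # restarts could not improve the likelihood any further: a flat
      # ridge, typically zero-inflation quasi-separation; the point is a
      # numerical maximum, but SEs along the ridge are unreliable
      warning("likelihood maximised on a flat ridge (gradient norm ",
              format(g_norm), ", family ", spec$family,
              "); possible zero-inflation separation, SEs may be unreliable")
    else
      stop("optimizer failed to converge (gradient norm ", format(g_norm),
           ", family ", spec$family, ")")
  }

  H <- stats::optimHess(par, fn$nll, fn$grad)
  V <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(V)
  if (singular) {
    # flat likelihood directions (e.g. a zero-inflation component drifting
    # to pi = 0): those parameters get infinite SEs, not spurious zeros
    warning("observed information is singular; ",
            "unidentified parameters get infinite SEs")
    V <- MASS::ginv(H)
  }
  d <- diag(V)
  se_all <- ifelse(d > if (singular) 1e-8 else 0, sqrt(pmax(d, 0)), Inf)

  p <- unpack_params(spec, par)
  kc <- 1L + length(spec$count_covariates)
  cf <- stats::setNames(p$count, colnames(fr$X))
  se <- stats::setNames(se_all[seq_len(kc)], colnames(fr$X))
  i <- kc
  theta <- theta_se <- NULL
  if (spec_has_theta(spec)) {
    i <- i + 1L
    theta <- min(exp(p$log_theta), 1e7) # capped as in the likelihood
    theta_se <- theta * se_all[i] # delta method from log scale
  }
  zi_cf <- zi_se <- NULL
  if (spec_has_zi(spec)) {
    zi_cf <- stats::setNames(p$zi, colnames(fr$Z))
    zi_se <- stats::setNames(se_all[(i + 1L):length(par)], colnames(fr$Z))
  }
  wald_p <- function(est, s) 2 * stats::pnorm(-abs(est / s))
  ll <- -fn$nll(par)

  structure(list(
    spec = spec,
    coefficients = cf, se = se, p = wald_p(cf, se),
    theta = theta, theta_se = theta_se,
    zi_coefficients = zi_cf, zi_se = zi_se,
    zi_p = if (!is.null(zi_cf)) wald_p(zi_cf, zi_se),
    loglik = ll,
    n_params = k,
    aic = 2 * k - 2 * ll,
    deviance = 2 * (saturated_loglik(spec, fr$y, theta) - ll),
    n = fr$n,
    converged = g_norm <= ctrl$grad_tol,
    grad_norm = g_norm,
    vcov = V,
    table = table), class = "count_model_fit")
}

fit_start <- function(spec, fr, ctrl) {
  kc <- 1L + length(spec$count_covariates)
  base_spec <- model_spec("poisson", spec$count_covariates,
                          offset_name = spec$offset_name)
  fnp <- make_nll(base_spec, fr)
  p0 <- c(log(sum(fr$y) / sum(fr$e)), rep(0, kc - 1L))
  if (spec$family == "poisson") return(p0)
  op <- stats::optim(p0, fnp$nll, fnp$grad, method = "BFGS",
                     control = list(maxit = ctrl$maxit, reltol = 1e-12))
  cpar <- op$par
  mu <- exp(drop(fr$X %*% cpar) + fr$loge)
  excess <- sum((fr$y - mu)^2 - mu)
  th0 <- if (excess > 0) sum(mu^2) / excess else 100
  th0 <- min(max(th0, 1e-2), 1e4)
  switch(spec$family,
    negbin = c(cpar, log(th0)),
    zip = c(cpar, rep(0, 1L + length(spec$zi_covariates))),
    zinb = c(cpar, log(th0), rep(0, 1L + length(spec$zi_covariates))))
}

newton_polish <- function(par, fn, ctrl) {
  for (it in seq_len(50L)) {
    g <- fn$grad(par)
    if (sqrt(sum(g^2)) <= ctrl$grad_tol) break
    H <- stats::optimHess(par, fn$nll, fn$grad)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) # ridge fallback
      step <- tryCatch(solve(H + diag(1e-6 * max(1, max(abs(diag(H)))),
                                      nrow(H)), g),
                       error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    f0 <- fn$nll(par)
    lam <- 1
    repeat {
      cand <- par - lam * step
      if (fn$nll(cand) < f0 + 1e-12) { par <- cand; break }
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (lam < 1e-10) break
  }
  par
}

# Saturated log-likelihood (mu = y per row; zero-inflated rows with y = 0
# saturate at probability one).
saturated_loglik <- function(spec, y, theta = NULL) {
  pos <- y > 0
  yp <- y[pos]
  if (spec_has_theta(spec)) {
    stopifnot(!is.null(theta))
    sum(lgamma(yp + theta) - lgamma(theta) - lgamma(yp + 1) +
          theta * log(theta / (theta + yp)) + yp * log(yp / (theta + yp)))
  } else {
    sum(yp * log(yp) - yp - lgamma(yp + 1))
  }
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("<count_model_fit> family %s, n = %d, logLik = %.2f, AIC = %.1f\n",
              x$spec$family, x$n, x$loglik, x$aic))
  tab <- data.frame(estimate = x$coefficients, se = x$se, p = x$p)
  print(round(tab, 4))
  if (!is.null(x$theta))
    cat(sprintf("theta = %.3f (SE %.3f)\n", x$theta, x$theta_se))
  if (!is.null(x$zi_coefficients)) {
    cat("zero-inflation component:\n")
    print(round(data.frame(estimate = x$zi_coefficients, se = x$zi_se,
                           p = x$zi_p), 4))
  }
  invisible(x)
}

#' Coefficient table shaped like a publication table
#'
#' One row per estimated covariate effect with component, estimate, SE,
#' Wald p, and (optionally) percentage deviance reduction.
#'
#' @param fit a `count_model_fit`.
#' @param deviance_reduction optional output of [deviance_reduction()].
#' @return a data frame.
#' @export
coefficient_table <- function(fit, deviance_reduction = NULL) {
  rows <- data.frame(
    component = "count", covariate = names(fit$coefficients),
    estimate = unname(fit$coefficients), se = unname(fit$se),
    p = unname(fit$p), row.names = NULL)
  if (!is.null(fit$zi_coefficients))
    rows <- rbind(rows, data.frame(
      component = "zero_inflation", covariate = names(fit$zi_coefficients),
      estimate = unname(fit$zi_coefficients), se = unname(fit$zi_se),
      p = unname(fit$zi_p), row.names = NULL))
  if (!is.null(fit$theta))
    rows <- rbind(rows, data.frame(component = "dispersion",
                                   covariate = "theta", estimate = fit$theta,
                                   se = fit$theta_se, p = NA_real_))
  if (!is.null(deviance_reduction))
    rows$deviance_reduction_pct <- deviance_reduction$deviance_reduction_pct[
      match(paste(rows$component, rows$covariate),
            paste(deviance_reduction$component, deviance_reduction$covariate))]
  rows
}

#' Multiplicative effect of a coefficient
#'
#' Converts a log-scale coefficient into the percentage change in the
#' incidence rate per unit increase of the covariate: `100 * (exp(b) - 1)`,
#' reported to one decimal; negative values are decreases. Applied to a
#' zero-inflation coefficient the same formula gives the percentage change
#' in the odds of a structural zero.
#'
#' @param coefficient numeric coefficient(s) on the log (or log-odds) scale.
#' @param digits decimals to report (default 1).
#' @return percentage change(s).
#' @export
multiplicative_effect <- function(coefficient, digits = 1) {
  stopifnot(all(is.finite(coefficient)))
  round(100 * expm1(coefficient), digits)
}

#' Square-root variance inflation factors
#'
#' Collinearity screen used before model fitting: for each covariate,
#' `VIF = 1 / (1 - R^2)` from the linear regression of that covariate on all
#' others; the square root is compared against the critical value 2.0.
#'
#' @param table unit table.
#' @param covariates covariate column names (at least two).
#' @return data frame `covariate`, `sqvif`, `ok` (`sqvif < 2`).
#' @export
sqvif <- function(table, covariates) {
  stopifnot(length(covariates) >= 2)
  X <- as.data.frame(table[covariates])
  if (any(vapply(X, stats::var, numeric(1)) == 0))
    stop("constant covariate column")
  out <- vapply(covariates, function(k) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(covariates, k), k),
                            data = X))$r.squared
    if (r2 > 1 - 1e-12) stop("perfectly collinear covariate: ", k)
    sqrt(1 / (1 - r2))
  }, numeric(1))
  data.frame(covariate = covariates, sqvif = unname(out), ok = unname(out) < 2,
             row.names = NULL)
}

#' Per-covariate percentage deviance reduction
#'
#' Effect sizes via drop-one refits: for covariate `k`,
#' `DR_k = 100 * (dev(model without k) - dev(full)) / dev(null)`, where the
#' null model keeps only the offset (and, for zero-inflated families, an
#' intercept-only logistic component). All deviances use the saturated
#' reference of the full fit so that the comparison is internally
#' consistent. Zero-inflation covariates are dropped from the logistic
#' component analogously.
#'
#' @param full_fit a converged `count_model_fit`.
#' @return data frame `component`, `covariate`, `deviance_reduction_pct`.
#' @export
deviance_reduction <- function(full_fit) {
  spec <- full_fit$spec
  table <- full_fit$table
  fr <- spec_frame(spec, table)
  sat <- saturated_loglik(spec, fr$y, full_fit$theta)
  dev_of <- function(fit) 2 * (sat - fit$loglik)
  refit <- function(cc, zc, label) {
    s <- model_spec(spec$family, cc, zc, spec$offset_name)
    tryCatch(fit_count_model(s, table),
             error = function(e) stop("refit without ", label, " failed: ",
                                      conditionMessage(e)))
  }
  null_fit <- refit(character(0),
                    if (spec_has_zi(spec)) character(0) else character(0),
                    "all covariates")
  dev_null <- dev_of(null_fit)
  dev_full <- dev_of(full_fit)
  rows <- lapply(spec$count_covariates, function(k) {
    f <- refit(setdiff(spec$count_covariates, k), spec$zi_covariates, k)
    data.frame(component = "count", covariate = k,
               deviance_reduction_pct = 100 * (dev_of(f) - dev_full) / dev_null)
  })
  if (spec_has_zi(spec))
    rows <- c(rows, lapply(spec$zi_covariates, function(k) {
      f <- refit(spec$count_covariates, setdiff(spec$zi_covariates, k), k)
      data.frame(component = "zero_inflation", covariate = k,
                 deviance_reduction_pct = 100 * (dev_of(f) - dev_full) / dev_null)
    }))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Backward selection of zero-inflation covariates
#'
#' Implements the published model-building rule for the logistic component:
#' start from all candidate covariates, repeatedly drop the least
#' significant one with Wald `p >= alpha` and refit, until every retained
#' zero-inflation covariate is significant. The count component is never
#' touched.
#'
#' @param table unit table.
#' @param candidates candidate zero-inflation covariate names.
#' @param count_covariates count-component covariates (kept fixed).
#' @param family `"zinb"` (default) or `"zip"`.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained names; the final fit is attached as
#'   attribute `"fit"` and the elimination order as attribute `"trace"`.
#' @export
select_zi_covariates <- function(table, candidates, count_covariates,
                                 family = c("zinb", "zip"), alpha = 0.05) {
  family <- match.arg(family)
  retained <- as.character(candidates)
  trace <- character(0)
  repeat {
    fit <- tryCatch(
      fit_count_model(model_spec(family, count_covariates, retained), table),
      error = function(e) stop("zero-inflation selection failed with {",
                               paste(retained, collapse = ", "), "}: ",
                               conditionMessage(e)))
    if (length(retained) == 0) break
    pv <- fit$zi_p[retained]
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    trace <- c(trace, sprintf("dropped %s (p = %.3f)", retained[worst], pv[worst]))
    retained <- retained[-worst]
  }
  structure(retained, fit = fit, trace = trace)
}
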