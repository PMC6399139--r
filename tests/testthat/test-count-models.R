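test_that("log-likelihood closed forms and limiting cases", {
  one <- data.frame(y = 0L, e = 1)
  sp <- model_spec("poisson")
  expect_equal(count_log_likelihood(sp, list(alpha = 0), one), -1)

  tab <- sim_model_table(50, seed = 1, theta = 2, alpha = -5.5)
  pars <- list(alpha = -5.5, beta = c(x1 = 0.3, x2 = -0.2))
  ll_p <- count_log_likelihood(model_spec("poisson", c("x1", "x2")), pars, tab)
  # ZIP with pi = 0 collapses to the Poisson likelihood
  pars_zip <- c(pars, list(gamma = c("(Intercept)" = -Inf)))
  expect_equal(count_log_likelihood(model_spec("zip", c("x1", "x2")),
                                    pars_zip, tab), ll_p)
  # NB at huge theta approaches Poisson
  pars_nb <- c(pars, list(theta = 1e6))
  expect_lt(abs(count_log_likelihood(model_spec("negbin", c("x1", "x2")),
                                     pars_nb, tab) - ll_p), 1e-3)
  expect_error(count_log_likelihood(sp, list(alpha = NaN), one), "nonfinite")
  expect_error(count_log_likelihood(sp, list(alpha = 0),
                                    data.frame(y = -1L, e = 1)), "nonnegative")
})

test_that("analytic gradients agree with numerical differentiation", {
  tab <- sim_model_table(60, seed = 2, theta = 1.2,
                         gamma = c("(Intercept)" = -0.5, x1 = 0.1))
  specs <- list(model_spec("poisson", c("x1", "x2")),
                model_spec("negbin", c("x1", "x2")),
                model_spec("zip", c("x1", "x2"), "x1"),
                model_spec("zinb", c("x1", "x2"), c("x1", "x2")))
  for (sp in specs) {
    fr <- dasycan:::spec_frame(sp, tab)
    fn <- dasycan:::make_nll(sp, fr)
    k <- dasycan:::n_params_of(sp)
    par <- c(-3.5, 0.2, -0.1, if (dasycan:::spec_has_theta(sp)) 0.3,
             if (dasycan:::spec_has_zi(sp))
               rep(0.2, 1 + length(sp$zi_covariates)))
    num <- vapply(seq_len(k), function(j) {
      h <- 1e-6; ep <- numeric(k); ep[j] <- h
      (fn$nll(par + ep) - fn$nll(par - ep)) / (2 * h)
    }, numeric(1))
    expect_equal(fn$grad(par), num, tolerance = 1e-5)
  }
})

test_that("closed-form fits: intercept-only Poisson and the offset contract", {
  tab <- sim_model_table(200, seed = 3, theta = Inf)
  f0 <- fit_count_model(model_spec("poisson"), tab)
  expect_lt(abs(f0$coefficients[["(Intercept)"]] -
                  log(sum(tab$y) / sum(tab$e))), 1e-8)

  # multiplying every offset by c shifts alpha by -log(c), slopes unchanged
  f1 <- fit_count_model(model_spec("poisson", c("x1", "x2")), tab)
  tab2 <- transform(tab, e = e * 10)
  f2 <- fit_count_model(model_spec("poisson", c("x1", "x2")), tab2)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] - log(10), tolerance = 1e-7)
  expect_equal(f2$coefficients[c("x1", "x2")],
               f1$coefficients[c("x1", "x2")], tolerance = 1e-7)
})

test_that("fits agree with independent implementations", {
  tab <- sim_model_table(400, seed = 4, theta = 1.5)
  fp <- fit_count_model(model_spec("poisson", c("x1", "x2")), tab)
  gp <- glm(y ~ x1 + x2 + offset(log(e)), poisson, tab)
  expect_equal(unname(fp$coefficients), unname(coef(gp)), tolerance = 1e-7)
  expect_equal(fp$loglik, as.numeric(logLik(gp)), tolerance = 1e-8)
  expect_equal(unname(fp$se), unname(summary(gp)$coefficients[, 2]),
               tolerance = 1e-4)

  fn <- fit_count_model(model_spec("negbin", c("x1", "x2")), tab)
  gn <- MASS::glm.nb(y ~ x1 + x2 + offset(log(e)), data = tab)
  expect_equal(unname(fn$coefficients), unname(coef(gn)), tolerance = 1e-6)
  expect_equal(fn$theta, gn$theta, tolerance = 1e-5)
  expect_equal(fn$loglik, as.numeric(logLik(gn)), tolerance = 1e-6)
})

test_that("zero-inflated fits agree with glmmTMB", {
  skip_if_not_installed("glmmTMB")
  tab <- sim_model_table(500, seed = 5, theta = 1.5,
                         gamma = c("(Intercept)" = -3, x1 = 0.5))
  fz <- fit_count_model(model_spec("zinb", c("x1", "x2"), "x1"), tab)
  gz <- glmmTMB::glmmTMB(y ~ x1 + x2 + offset(log(e)), ziformula = ~x1,
                         family = glmmTMB::nbinom2, data = tab)
  est <- glmmTMB::fixef(gz)
  expect_equal(unname(fz$coefficients), unname(est$cond), tolerance = 1e-3)
  expect_equal(unname(fz$zi_coefficients), unname(est$zi), tolerance = 1e-3)
  expect_equal(fz$theta, glmmTMB::sigma(gz), tolerance = 1e-3)
  expect_equal(fz$loglik, as.numeric(logLik(gz)), tolerance = 1e-5)
})

test_that("model nesting: richer families never lose log-likelihood", {
  tab <- sim_model_table(300, seed = 6, theta = 0.8,
                         gamma = c("(Intercept)" = -1))
  fits <- lapply(c("poisson", "zip", "negbin", "zinb"), function(fam)
    fit_count_model(model_spec(fam, c("x1", "x2"),
                               if (fam %in% c("zip", "zinb")) "x1"
                               else character(0)), tab))
  names(fits) <- c("poisson", "zip", "negbin", "zinb")
  tol <- 1e-6
  expect_gte(fits$zip$loglik, fits$poisson$loglik - tol)
  expect_gte(fits$zinb$loglik, fits$negbin$loglik - tol)
  expect_gte(fits$negbin$loglik, fits$poisson$loglik - tol)
  # overdispersed data: NB strictly better than Poisson
  expect_gt(fits$negbin$loglik, fits$poisson$loglik + 10)
  # AIC bookkeeping: aic = 2k - 2 loglik with every parameter counted
  expect_equal(fits$zinb$n_params, 1 + 2 + 1 + 2) # alpha, 2 beta, theta, 2 gamma
  expect_equal(fits$zinb$aic, 2 * fits$zinb$n_params - 2 * fits$zinb$loglik)
})

test_that("degenerate tables are rejected", {
  tab <- sim_model_table(30, seed = 7)
  tab$const <- 1
  expect_error(fit_count_model(model_spec("poisson", "const"), tab),
               "constant covariate")
  tiny <- tab[1:3, ]
  expect_error(fit_count_model(model_spec("zinb", c("x1", "x2"), "x1"), tiny),
               "degenerate")
  tab$e[1] <- 0
  expect_error(fit_count_model(model_spec("poisson", "x1"), tab), "offset")
  expect_error(model_spec("poisson", "x1", zi_covariates = "x1"),
               "zi_covariates")
})

test_that("multiplicative effects reproduce the published conversions", {
  expect_equal(multiplicative_effect(-0.19), -17.3)
  expect_equal(multiplicative_effect(-0.21), -18.9)
  expect_equal(multiplicative_effect(0.11), 11.6)
  expect_equal(multiplicative_effect(0.08), 8.3)
  expect_equal(multiplicative_effect(0), 0.0)
  expect_equal(multiplicative_effect(-3.61), -97.3) # odds of a zero count
  expect_equal(multiplicative_effect(-3.69), -97.5)
  # monotone in the coefficient
  b <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(multiplicative_effect(b)) > 0))
  expect_error(multiplicative_effect(Inf))
})

test_that("SQVIF matches its closed form and flags collinearity", {
  withr::with_seed(8, {
    n <- 10000
    x1 <- rnorm(n); z <- rnorm(n)
    tab <- data.frame(x1 = x1, x2 = rnorm(n), y = 0L, e = 1)
    v <- sqvif(tab, c("x1", "x2"))
    expect_true(all(abs(v$sqvif - 1) < 0.02))
    expect_true(all(v$ok))

    # exact empirical correlation 0.9 via orthonormalization
    x1s <- scale(x1)[, 1] / sqrt(n - 1)
    zr <- residuals(lm(z ~ x1))
    zs <- zr / sqrt(sum(zr^2))
    tab2 <- data.frame(x1 = x1s, x2 = 0.9 * x1s + sqrt(1 - 0.81) * zs)
    v2 <- sqvif(tab2, c("x1", "x2"))
    expect_equal(v2$sqvif, rep(sqrt(1 / (1 - 0.81)), 2), tolerance = 1e-10)
    expect_false(any(v2$ok)) # 2.294 > 2 fails the screen

    # near-degenerate: tiny added noise either errors or blows past 2
    tab3 <- data.frame(x1 = x1, x2 = x1 + rnorm(n, sd = 1e-8))
    res3 <- tryCatch(max(sqvif(tab3, c("x1", "x2"))$sqvif),
                     error = function(e) Inf)
    expect_gt(res3, 100)
    tab4 <- data.frame(x1 = x1, x2 = 2 * x1)
    expect_error(sqvif(tab4, c("x1", "x2")), "collinear")
  })
})

test_that("deviance reduction: single-covariate identity and null effects", {
  tab <- sim_model_table(500, seed = 9, theta = Inf,
                         beta = c(x1 = 0.4, x2 = 0))
  f1 <- fit_count_model(model_spec("poisson", "x1"), tab)
  dr1 <- deviance_reduction(f1)
  f_null <- fit_count_model(model_spec("poisson"), tab)
  expect_equal(dr1$deviance_reduction_pct,
               100 * (f_null$deviance - f1$deviance) / f_null$deviance,
               tolerance = 1e-6)

  f2 <- fit_count_model(model_spec("poisson", c("x1", "x2")), tab)
  dr2 <- deviance_reduction(f2)
  expect_gt(dr2$deviance_reduction_pct[dr2$covariate == "x1"], 5)
  expect_lt(abs(dr2$deviance_reduction_pct[dr2$covariate == "x2"]), 2)
})

test_that("zero-inflation covariate selection retains exactly the true driver", {
  tab <- sim_model_table(1500, seed = 10, theta = 2,
                         gamma = c("(Intercept)" = -4, x1 = 0.8))
  sel <- select_zi_covariates(tab, candidates = c("x1", "x2"),
                              count_covariates = c("x1", "x2"))
  expect_identical(as.character(sel), "x1")
  fit <- attr(sel, "fit")
  expect_lt(fit$zi_p[["x1"]], 0.05)

  # no structural zeros at all: nothing survives, intercept-only ZI remains
  # (the drifting ZI component makes the information singular, by design)
  tab0 <- sim_model_table(800, seed = 11, theta = 5)
  sel0 <- suppressWarnings(
    select_zi_covariates(tab0, candidates = c("x1", "x2"),
                         count_covariates = c("x1", "x2")))
  expect_length(sel0, 0)
  expect_s3_class(attr(sel0, "fit"), "count_model_fit")
})
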