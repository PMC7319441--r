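toy_climate <- function(ages = seq(180, 0, by = -3), seed = 1) {
  transform_climate(simulate_climate_series(ages = ages, seed = seed))
}

test_that("climate transforms are ln for CO2 and logit for O2 proportion", {
  cl <- climate_series(data.frame(age = c(10, 0), deltaT = c(2, 0),
                                  pO2 = c(50, 21), cCO2 = c(1000, 400)))
  tcl <- transform_climate(cl)
  expect_equal(tcl$ln_cCO2[1L], log(1000))
  expect_equal(tcl$logit_pO2[1L], 0)
  expect_equal(tcl$logit_pO2[2L], log(0.21 / 0.79))
  expect_equal(tcl$deltaT, cl$deltaT)
  expect_error(climate_series(data.frame(age = c(1, 0), deltaT = 0,
                                         pO2 = c(100, 21), cCO2 = 400)),
               "pO2")
  expect_error(climate_series(data.frame(age = c(1, 0), deltaT = 0,
                                         pO2 = 21, cCO2 = c(-1, 400))),
               "cCO2")
})

test_that("spline harmonisation passes through knots and refuses extrapolation", {
  cl <- toy_climate()
  same <- spline_to_grid(cl, cl$age)
  for (v in c("deltaT", "pO2", "logit_pO2", "ln_cCO2"))
    expect_equal(same[[v]], cl[[v]], tolerance = 1e-10)

  lin <- climate_series(data.frame(age = seq(100, 0, by = -10),
                                   deltaT = seq(5, 0, length.out = 11),
                                   pO2 = 21, cCO2 = 400))
  mid <- spline_to_grid(lin, c(95, 55, 12.5))
  expect_equal(mid$deltaT, c(95, 55, 12.5) * 0.05, tolerance = 1e-9)
  expect_error(spline_to_grid(cl, c(50, 200)), "extrapolation")
})

test_that("the CAR(1) GLS fit recovers OLS in the independence limit", {
  ages <- seq(0, 49) * 1.0
  X <- cbind(`(Intercept)` = 1, x = withr::with_seed(1, rnorm(50)))
  y <- drop(X %*% c(1, 2)) + withr::with_seed(2, rnorm(50, sd = 0.5))
  fit <- fit_gls_car1(y, X, ages)
  ols <- stats::lm(y ~ X[, 2])
  for (j in 1:2)
    expect_lt(abs(fit$coefficients$estimate[j] - stats::coef(ols)[j]),
              2 * summary(ols)$coefficients[j, 2])

  # at large phi the CAR(1) correlation vanishes and the likelihood equals
  # the OLS Gaussian (ML) likelihood; phi = 0 is the opposite, fully
  # correlated, limit
  fit_hi <- fit_gls_car1(y, X, ages, phi_max = 20)
  expect_equal(fit_hi$logLik, as.numeric(stats::logLik(ols)),
               tolerance = 1e-6)
  expect_equal(fit_hi$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)

  expect_error(fit_gls_car1(y, cbind(X, X[, 2]), ages), "singular")
  expect_error(fit_gls_car1(y, X, rep(1, 50)), "distinct")
})

test_that("the fit agrees with an independent CAR(1) GLS implementation", {
  skip_if_not_installed("nlme")
  ages <- sort(withr::with_seed(3, runif(60, 0, 150)), decreasing = TRUE)
  cl <- toy_climate(ages = ages, seed = 4)
  X <- cbind(`(Intercept)` = 1, deltaT = cl$deltaT, ln_cCO2 = cl$ln_cCO2)
  y <- simulate_gls_response(X, c(0.5, 0.1, -0.2), phi = 0.05, sigma = 0.3,
                             ages, seed = 5)
  fit <- fit_gls_car1(y, X, ages)
  dat <- data.frame(y = y, deltaT = cl$deltaT, ln_cCO2 = cl$ln_cCO2,
                    age = ages)
  ref <- nlme::gls(y ~ deltaT + ln_cCO2, data = dat, method = "ML",
                   correlation = nlme::corCAR1(form = ~age))
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ref)),
               tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(exp(-fit$phi),
               stats::coef(ref$modelStruct$corStruct, unconstrained = FALSE),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("pseudo-R2 follows the likelihood-ratio algebra", {
  mk <- function(ll, n) structure(list(logLik = ll, n = n), class = "gls_car1")
  expect_equal(pseudo_r2(mk(-20, 50), mk(-20, 50)), 0)
  expect_equal(pseudo_r2(mk(-15, 50), mk(-20, 50), normalize = FALSE),
               1 - exp(-0.2), tolerance = 1e-12)
  # monotone in the fit's likelihood, bounded in [0, 1)
  r <- vapply(seq(-20, -2.5, by = 2.5),
              function(l) pseudo_r2(mk(l, 50), mk(-20, 50)), 0)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 1))
  expect_error(pseudo_r2(mk(-1, 50), mk(-1, 40)), "different n")
})

test_that("standardized betas rescale by predictor and response spread", {
  ages <- seq(0, 39) * 1.0
  x1 <- withr::with_seed(6, rnorm(40))
  x1 <- (x1 - mean(x1)) / stats::sd(x1)
  y <- 2 * x1 + withr::with_seed(7, rnorm(40, sd = 0.1))
  y <- y / stats::sd(y) * 1.0
  fit <- fit_gls_car1(y, cbind(`(Intercept)` = 1, x1 = x1), ages)
  b <- standardized_betas(fit)
  expect_named(b, "x1")
  expect_equal(unname(b["x1"]),
               fit$coefficients$estimate[2] * stats::sd(x1) / stats::sd(y),
               tolerance = 1e-12)
  expect_equal(unname(b["x1"]), fit$coefficients$estimate[2] * 1 / 1,
               tolerance = 1e-6)
})

test_that("model selection covers all 7 combinations with normalised weights", {
  cl <- toy_climate(seed = 8)
  X <- cbind(1, cl$logit_pO2, cl$ln_cCO2)
  y <- simulate_gls_response(X, c(0, 1, -0.5), phi = 0.1,
                             sigma = stats::sd(drop(X[, -1] %*% c(1, -0.5))) / 2,
                             cl$age, seed = 9)
  mt <- select_models(y, cl, ages = cl$age)
  expect_equal(nrow(mt), 7L)
  expect_equal(sum(mt$w), 1, tolerance = 1e-12)
  expect_equal(mt$dAIC[1L], 0)
  expect_true(all(diff(mt$AIC) >= 0))
  expect_true(mt$co_best[1L])
  expect_true(all(mt$R2pse >= 0 & mt$R2pse < 1, na.rm = TRUE))
  # co-best multiple regressions carry standardized coefficients
  bet <- attr(mt, "betas")
  for (f in names(bet)) expect_gte(length(bet[[f]]), 2L)
})

test_that("staged correlations split at 145 and 66 Ma and match the formula", {
  ages <- seq(180, 0, by = -2)
  a <- withr::with_seed(10, rnorm(length(ages)))
  sc <- staged_correlation(a, 2 * a + 1, ages)
  expect_equal(sc$stage, c("early", "middle", "late"))
  expect_equal(sc$cor, rep(1, 3), tolerance = 1e-12)
  expect_equal(sc$n, c(sum(ages >= 145), sum(ages >= 66 & ages < 145),
                       sum(ages < 66)))

  b <- withr::with_seed(11, rnorm(length(ages)))
  sc2 <- staged_correlation(a, b, ages)
  for (s in c("early", "middle", "late")) {
    i <- if (s == "early") ages >= 145 else if (s == "middle")
      ages >= 66 & ages < 145 else ages < 66
    expect_equal(sc2$cor[sc2$stage == s], oracle_pearson(a[i], b[i]),
                 tolerance = 1e-12)
    ct <- stats::cor.test(a[i], b[i])
    expect_equal(sc2$p[sc2$stage == s], ct$p.value, tolerance = 1e-12)
  }
  # invariant to within-stage reordering
  perm <- withr::with_seed(12, sample(seq_along(ages)))
  sc3 <- staged_correlation(a[perm], b[perm], ages[perm])
  expect_equal(sc3$cor, sc2$cor, tolerance = 1e-12)

  expect_error(staged_correlation(1:5, 1:5, c(150, 148, 30, 20, 10)),
               "at least 3")
  # toy oracle from the direct formula
  expect_equal(oracle_pearson(c(1, 2, 3), c(1, 2, 4)),
               stats::cor(c(1, 2, 3), c(1, 2, 4)))
})
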