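#' Construct/validate a climate series
#'
#' A climate series holds temperature deviation relative to today (`deltaT`,
#' deg C), atmospheric oxygen percentage (`pO2`, %) and CO2 concentration
#' (`cCO2`, ppm) on a monotone age grid (Ma).
#'
#' @param x data.frame with columns `age`, `deltaT`, `pO2`, `cCO2`.
#' @return a `"climate_series"` data.frame.
#' @export
climate_series <- function(x) {
  x <- as.data.frame(x)
  need <- c("age", "deltaT", "pO2", "cCO2")
  if (!all(need %in% names(x)))
    stop_ccl("climate series needs columns: ", paste(need, collapse = ", "))
  d <- diff(x$age)
  if (nrow(x) >= 2L && !(all(d > 0) || all(d < 0)))
    stop_ccl("age grid must be strictly monotone")
  if (any(x$pO2 <= 0 | x$pO2 >= 100))
    stop_ccl("pO2 must lie strictly inside (0, 100) percent")
  if (any(x$cCO2 <= 0)) stop_ccl("cCO2 must be positive")
  class(x) <- c("climate_series", "data.frame")
  x
}

#' Transform climate variables for regression
#'
#' Adds the natural log of CO2 concentration (`ln_cCO2`) and the logit of
#' the oxygen proportion (`logit_pO2 = log((pO2/100) / (1 - pO2/100))`);
#' temperature deviation needs no transform and is passed through.
#'
#' @param x a [climate_series()].
#' @return the series with `ln_cCO2` and `logit_pO2` columns added.
#' @examples
#' transform_climate(climate_series(
#'   data.frame(age = c(10, 0), deltaT = c(2, 0), pO2 = c(50, 21),
#'              cCO2 = c(1000, 400))))
#' @export
transform_climate <- function(x) {
  x <- climate_series(x)
  x$ln_cCO2 <- log(x$cCO2)
  p <- x$pO2 / 100
  x$logit_pO2 <- log(p / (1 - p))
  x
}

#' Interpolate a climate series onto a target age grid
#'
#' Natural cubic spline through the source points, evaluated at the target
#' ages, applied to every value column. Harmonises climate compilations with
#' the node-age grid of the disparity statistics. Extrapolation beyond the
#' source span is refused.
#'
#' @param series a (possibly transformed) [climate_series()].
#' @param target_ages ages (Ma) within the source grid's span.
#' @return the interpolated series on `target_ages`.
#' @export
spline_to_grid <- function(series, target_ages) {
  stopifnot(is.data.frame(series), "age" %in% names(series))
  rng <- range(series$age)
  if (any(target_ages < rng[1L] - 1e-9) || any(target_ages > rng[2L] + 1e-9))
    stop_ccl(sprintf(
      "target age(s) outside the source span [%g, %g] Ma: extrapolation refused",
      rng[1L], rng[2L]))
  target_ages <- pmin(pmax(target_ages, rng[1L]), rng[2L])
  out <- data.frame(age = target_ages)
  for (v in setdiff(names(series), "age"))
    out[[v]] <- stats::spline(series$age, series[[v]], xout = target_ages,
                              method = "natural")$y
  class(out) <- class(series)
  out
}

# Profile log-likelihood machinery: given phi, the CAR(1) correlation matrix
# R is fixed, b is the GLS estimate and sigma2 its ML profile.
gls_profile <- function(y, X, ages, phi) {
  R <- exp(-phi * abs(outer(ages, ages, "-")))
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  # whiten: solve L' u = v
  Wy <- forwardsolve(t(L), y)
  WX <- forwardsolve(t(L), X)
  qrx <- qr(WX)
  if (qrx$rank < ncol(X)) stop_ccl("singular design matrix")
  b <- qr.coef(qrx, Wy)
  r <- Wy - WX %*% b
  n <- length(y)
  s2 <- sum(r^2) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + n) - sum(log(diag(L)))
  XtX <- crossprod(WX)
  list(b = b, sigma2 = s2, logLik = ll, XtX = XtX, phi = phi)
}

#' GLS regression with continuous-time CAR(1) errors
#'
#' Maximum-likelihood fit of `y = X b + e` where the errors follow a
#' continuous-time first-order autoregression on the (possibly irregular)
#' age grid: `cov(e_i, e_j) = sigma^2 * exp(-phi |t_i - t_j|)`. For fixed
#' `phi` the coefficients are the generalized-least-squares solution and
#' `sigma^2` is profiled analytically; `phi` is found by bounded 1-D
#' optimisation of the profile likelihood (coarse grid then local refine).
#' ML rather than REML is used throughout so that AIC is comparable across
#' fixed-effects structures.
#'
#' Coefficient p-values are two-sided t statistics on `n - ncol(X)` degrees
#' of freedom, approximate under the estimated `phi`.
#'
#' @param y response vector.
#' @param X design matrix including the intercept column.
#' @param ages time points (Ma), distinct.
#' @param phi_max upper bound for `phi` (1/Myr); default `50 / span`, i.e.
#'   effectively independent errors at the span scale.
#' @return object of class `"gls_car1"`: `coefficients` table (estimate,
#'   se, t, p), `phi`, `sigma2`, `logLik`, `AIC` (with
#'   `k = ncol(X) + 2` free parameters), `n`, plus the inputs.
#' @export
fit_gls_car1 <- function(y, X, ages, phi_max = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(ages) != n)
    stop_ccl("`y`, `X` rows and `ages` must align")
  if (anyDuplicated(ages)) stop_ccl("`ages` must be distinct")
  if (n <= p + 2L) stop_ccl("need n > ncol(X) + 2 observations")
  span <- diff(range(ages))
  phi_max <- phi_max %||% (50 / span)

  nll <- function(phi) {
    f <- gls_profile(y, X, ages, phi)
    if (is.null(f) || !is.finite(f$logLik)) 1e10 else -f$logLik
  }
  grid <- c(0, exp(seq(log(min(0.01 / span, phi_max)), log(phi_max),
                       length.out = 24L)))
  vals <- vapply(grid, nll, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(nll, c(lo, hi))
  phi <- if (opt$objective < vals[i]) opt$minimum else grid[i]

  f <- gls_profile(y, X, ages, phi)
  vc <- f$sigma2 * solve(f$XtX)
  se <- sqrt(diag(vc))
  est <- drop(f$b)
  tval <- est / se
  df <- n - p
  coefs <- data.frame(term = colnames(X) %||% paste0("x", seq_len(p)),
                      estimate = est, se = se, t = tval,
                      p = 2 * stats::pt(-abs(tval), df),
                      row.names = NULL)
  structure(list(coefficients = coefs, phi = phi, sigma2 = f$sigma2,
                 logLik = f$logLik, k = p + 2L,
                 AIC = -2 * f$logLik + 2 * (p + 2L),
                 n = n, df = df, vcov = vc, y = y, X = X, ages = ages),
            class = "gls_car1")
}

#' @export
print.gls_car1 <- function(x, ...) {
  cat(sprintf("GLS with CAR(1) errors (ML): n = %d, phi = %.4g /Myr, sigma^2 = %.4g\n",
              x$n, x$phi, x$sigma2))
  cat(sprintf("  logLik = %.3f, AIC = %.3f (k = %d)\n", x$logLik, x$AIC, x$k))
  stats::printCoefmat(cbind(Estimate = x$coefficients$estimate,
                     `Std.Error` = x$coefficients$se,
                     `t value` = x$coefficients$t,
                     `Pr(>|t|)` = x$coefficients$p),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Likelihood-ratio pseudo-R-squared
#'
#' The raw likelihood-ratio measure
#' `1 - exp(-(2/n) (logLik_fit - logLik_null))`, optionally rescaled by its
#' attainable maximum `1 - exp((2/n) logLik_null)` (Nagelkerke
#' normalisation; the default). The maximum is a meaningful bound only for
#' non-positive log-likelihoods (as with discrete responses); with a
#' continuous response the log-likelihoods can be positive, the "maximum"
#' then fails to bound the raw measure, and the raw measure is returned
#' unchanged so the result always stays in `[0, 1)`.
#'
#' @param fit a [fit_gls_car1()] fit.
#' @param null_fit the intercept-only fit of the same response, same
#'   correlation structure.
#' @param normalize apply the Nagelkerke rescaling (default `TRUE`).
#' @return pseudo-R-squared in `[0, 1)` (0 iff the fit's likelihood equals
#'   the null's).
#' @export
pseudo_r2 <- function(fit, null_fit, normalize = TRUE) {
  if (fit$n != null_fit$n) stop_ccl("fits have different n")
  raw <- 1 - exp(-(2 / fit$n) * (fit$logLik - null_fit$logLik))
  if (!normalize) return(raw)
  mx <- 1 - exp((2 / fit$n) * null_fit$logLik)
  if (mx <= 0 || raw >= mx) return(raw)  # bound does not bind: see Details
  raw / mx
}

#' Standardized regression coefficients
#'
#' `beta_j = b_j * sd(x_j) / sd(y)` (sample standard deviations, n - 1
#' denominator), excluding the intercept. Dimensionless, so the explanatory
#' power of predictors on different scales can be compared.
#'
#' @param fit a [fit_gls_car1()] fit (its stored design and response are
#'   used).
#' @return named numeric vector of standardized coefficients.
#' @export
standardized_betas <- function(fit) {
  X <- fit$X
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0                              # drops the intercept column
  if (!any(keep)) stop_ccl("no non-constant predictor columns")
  if (any(!keep & seq_len(ncol(X)) > 1L & colnames(X) != "(Intercept)")) {
    bad <- colnames(X)[!keep & colnames(X) != "(Intercept)"]
    if (length(bad)) stop_ccl("zero-variance predictor(s): ",
                              paste(bad, collapse = ", "))
  }
  b <- fit$coefficients$estimate[keep]
  stats::setNames(b * sds[keep] / stats::sd(fit$y),
                  fit$coefficients$term[keep])
}

#' Fit and rank all climate-predictor combinations
#'
#' Fits the CAR(1) GLS regression of `y` on every non-empty subset of the
#' three climate predictors (temperature deviation, logit oxygen, log CO2)
#' — 7 candidate models — plus the intercept-only null used for the
#' pseudo-R-squared. Candidates are ranked by AIC; `dAIC` is the difference
#' from the minimum and the Akaike weight is
#' `w = exp(-dAIC/2) / sum(exp(-dAIC/2))` over the successful fits. Models
#' with `dAIC < 2` are flagged co-best and, when they are multiple
#' regressions, their standardized coefficients are attached.
#'
#' @param y response on the same grid as `climate`.
#' @param climate a transformed, harmonised [climate_series()] whose rows
#'   align with `y` (see [transform_climate()], [spline_to_grid()]).
#' @param ages age grid (defaults to `climate$age`).
#' @param predictors column names of the candidate predictors.
#' @param normalize_r2 passed to [pseudo_r2()].
#' @return a `"model_table"` data.frame (formula, k, logLik, AIC, dAIC, w,
#'   R2pse, co_best) sorted by AIC, with attributes `fits` (named list of
#'   fits), `null` (the intercept-only fit) and `betas` (standardized
#'   coefficients of co-best multiple regressions).
#' @export
select_models <- function(y, climate, ages = climate$age,
                          predictors = c("deltaT", "logit_pO2", "ln_cCO2"),
                          normalize_r2 = TRUE) {
  stopifnot(all(predictors %in% names(climate)))
  if (length(y) != nrow(climate)) stop_ccl("`y` and `climate` rows must align")
  n <- length(y)
  null_fit <- fit_gls_car1(y, matrix(1, n, 1,
                                     dimnames = list(NULL, "(Intercept)")),
                           ages)
  subsets <- unlist(lapply(seq_along(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)

  rows <- list(); fits <- list()
  for (s in subsets) {
    form <- paste(s, collapse = " + ")
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(climate)[, s, drop = FALSE]))
    fit <- tryCatch(fit_gls_car1(y, X, ages), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[form]] <- data.frame(formula = form, k = length(s) + 3L,
                                 logLik = NA, AIC = NA, R2pse = NA,
                                 failed = TRUE)
      next
    }
    fits[[form]] <- fit
    rows[[form]] <- data.frame(formula = form, k = fit$k, logLik = fit$logLik,
                               AIC = fit$AIC,
                               R2pse = pseudo_r2(fit, null_fit,
                                                 normalize = normalize_r2),
                               failed = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  tab$dAIC <- tab$AIC - min(tab$AIC[ok])
  tab$w <- NA_real_
  tab$w[ok] <- exp(-tab$dAIC[ok] / 2) / sum(exp(-tab$dAIC[ok] / 2))
  tab$co_best <- !is.na(tab$dAIC) & tab$dAIC < 2
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL

  betas <- list()
  for (form in tab$formula[tab$co_best]) {
    if (length(strsplit(form, " \\+ ")[[1L]]) >= 2L)
      betas[[form]] <- standardized_betas(fits[[form]])
  }
  structure(tab, fits = fits, null = null_fit, betas = betas,
            class = c("model_table", "data.frame"))
}

#' @export
print.model_table <- function(x, digits = 3, ...) {
  cat("Climate model selection (CAR(1) GLS, ascending AIC)\n")
  df <- as.data.frame(x)
  df$logLik <- round(df$logLik, digits)
  df$AIC <- round(df$AIC, digits)
  df$dAIC <- round(df$dAIC, digits)
  df$w <- round(df$w, digits)
  df$R2pse <- round(df$R2pse, digits)
  print(df[, c("formula", "R2pse", "AIC", "dAIC", "w", "co_best")],
        row.names = FALSE)
  b <- attr(x, "betas")
  if (length(b)) {
    cat("standardized coefficients of co-best multiple regressions:\n")
    for (f in names(b))
      cat(" ", f, ":", paste(sprintf("%s = %.4f", names(b[[f]]), b[[f]]),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Staged Pearson correlations
#'
#' Pearson correlation and two-sided p-value (t distribution, n - 2 df)
#' between two aligned series within geological stages split at the given
#' age boundaries. With the default boundaries the stages are early (root
#' age to 145 Ma, Jurassic), middle (145-66 Ma, Cretaceous) and late (66 Ma
#' to present, Cenozoic); membership is `age >= 145`, `66 <= age < 145`,
#' `age < 66`.
#'
#' @param a,b numeric series on common `ages`.
#' @param ages age grid (Ma).
#' @param boundaries two descending stage boundaries in Ma (default
#'   `c(145, 66)`).
#' @return data.frame (`stage`, `age_from`, `age_to`, `n`, `cor`, `p`).
#' @export
staged_correlation <- function(a, b, ages, boundaries = c(145, 66)) {
  stopifnot(length(a) == length(ages), length(b) == length(ages),
            length(boundaries) == 2L, boundaries[1L] > boundaries[2L])
  stage <- ifelse(ages >= boundaries[1L], "early",
                  ifelse(ages >= boundaries[2L], "middle", "late"))
  out <- lapply(c("early", "middle", "late"), function(s) {
    i <- stage == s
    if (sum(i) < 3L)
      stop_ccl(sprintf("stage %s has %d point(s); need at least 3", s, sum(i)))
    ct <- stats::cor.test(a[i], b[i], method = "pearson")
    data.frame(stage = s,
               age_from = c(early = Inf, middle = boundaries[1L],
                            late = boundaries[2L])[[s]],
               age_to = c(early = boundaries[1L], middle = boundaries[2L],
                          late = 0)[[s]],
               n = sum(i), cor = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Read a climate series from tab-separated text
#'
#' Accepts columns `age, deltaT, pO2, cCO2` or the unit-suffixed spelling
#' `age_Ma, deltaT_C, pO2_pct, cCO2_ppm`.
#'
#' @param path input path.
#' @return a [climate_series()].
#' @export
read_climate_series <- function(path) {
  if (!file.exists(path)) stop_ccl("climate series file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  alias <- c(age_Ma = "age", deltaT_C = "deltaT", pO2_pct = "pO2",
             cCO2_ppm = "cCO2")
  for (nm in names(alias))
    if (nm %in% names(x)) names(x)[names(x) == nm] <- alias[[nm]]
  climate_series(x)
}

#' Write a climate series as tab-separated text
#' @param x a [climate_series()].
#' @param path output path.
#' @export
write_climate_series <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("age", "deltaT", "pO2", "cCO2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
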