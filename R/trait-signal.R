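#' Build a genus-level body-size trait table from raw species records
#'
#' Applies the standard literature-extraction protocol for body length:
#' a species entry is a single reported value, the mid-value (arithmetic mean
#' of the extremes) of a reported range, or the mean of a sample of
#' individual measurements (multiple rows for the same species are pooled as
#' a sample). Species values are transformed as `ln(10 * length_mm)` — the
#' factor of 10 guards against lengths below 1 mm going negative on the log
#' scale — and summarised per genus as mean, sample standard deviation
#' (n - 1 denominator) and standard error `sd/sqrt(n)` over its species.
#' Genera represented by a single species get `sd = se = 0`.
#'
#' @param records `data.frame` with columns `genus`, optionally `species`
#'   (defaults to one species per row), and per row either `length_mm` or a
#'   range `min_mm`/`max_mm`.
#' @return a trait table (`taxon`, `mean`, `sd`, `se`, `n`) with one row per
#'   genus, on the `ln(10 x mm)` scale.
#' @examples
#' preprocess_body_size(data.frame(genus = "Aleochara",
#'                                 min_mm = 2.5, max_mm = 3.5))
#' @export
preprocess_body_size <- function(records) {
  records <- as.data.frame(records)
  if (!"genus" %in% names(records)) stop_ccl("`records` needs a `genus` column")
  nr <- nrow(records)
  if (!"species" %in% names(records))
    records$species <- paste0("sp", seq_len(nr))
  has_len <- "length_mm" %in% names(records)
  has_rng <- all(c("min_mm", "max_mm") %in% names(records))
  if (!has_len && !has_rng)
    stop_ccl("`records` needs `length_mm` and/or `min_mm`+`max_mm` columns")

  val <- rep(NA_real_, nr)
  if (has_len) val <- records$length_mm
  if (has_rng) {
    rng <- !is.na(records$min_mm) & !is.na(records$max_mm)
    if (any(rng & records$min_mm > records$max_mm))
      stop_ccl("range with min_mm > max_mm")
    val[rng & is.na(val)] <-
      (records$min_mm[rng & is.na(val)] + records$max_mm[rng & is.na(val)]) / 2
  }
  if (anyNA(val)) stop_ccl("record(s) with no usable length value")
  if (any(val <= 0)) stop_ccl("body lengths must be positive")

  key <- interaction(records$genus, records$species, drop = TRUE)
  sp_val <- tapply(val, key, mean)                  # pooled sample mean
  sp_genus <- tapply(as.character(records$genus), key, `[`, 1L)
  lnval <- log(10 * as.numeric(sp_val))

  agg <- split(lnval, sp_genus)
  out <- data.frame(
    taxon = names(agg),
    mean = vapply(agg, mean, 0),
    sd = vapply(agg, function(x) if (length(x) > 1L) stats::sd(x) else 0, 0),
    n = vapply(agg, length, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  out$se <- ifelse(out$n > 1L, out$sd / sqrt(out$n), 0)
  out[, c("taxon", "mean", "sd", "se", "n")]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda_signal`, leaving the
#' diagonal untouched. `lambda_signal = 1` recovers the Brownian-motion
#' covariance; `lambda_signal = 0` removes all phylogenetic covariance (star
#' phylogeny).
#'
#' @param C symmetric phylogenetic covariance matrix (e.g. [ape::vcv()]).
#' @param lambda_signal scalar in \[0, 1\].
#' @return the transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda_signal) {
  if (lambda_signal < 0 || lambda_signal > 1)
    stop_ccl("`lambda_signal` must be in [0, 1]")
  out <- lambda_signal * C
  diag(out) <- diag(C)
  out
}

# Multivariate-normal log-likelihood of tip data under the lambda model,
# with z0 profiled out by the GLS mean. Returns -Inf if the covariance is
# not positive definite.
lambda_loglik <- function(y, C, se2, lambda_signal, sigma2) {
  n <- length(y)
  S <- sigma2 * lambda_transform(C, lambda_signal)
  diag(S) <- diag(S) + se2
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  one <- rep(1, n)
  iS1 <- backsolve(L, forwardsolve(t(L), one))
  iSy <- backsolve(L, forwardsolve(t(L), y))
  z0 <- sum(one * iSy) / sum(one * iS1)
  r <- y - z0
  iSr <- backsolve(L, forwardsolve(t(L), r))
  ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r * iSr))
  attr(ll, "z0") <- z0
  ll
}

#' Fit Pagel's lambda to a continuous trait by maximum likelihood
#'
#' Maximises the multivariate-normal likelihood of tip values with mean
#' `z0 * 1` and covariance `sigma2 * C(lambda) + diag(se^2)`, where `C` is
#' the tree's shared-path-length matrix, `lambda` scales its off-diagonals
#' (see [lambda_transform()]) and the optional `diag(se^2)` term treats the
#' per-tip standard errors as known measurement variance. The ancestral
#' state `z0` is profiled analytically by the GLS mean; `(lambda, sigma2)`
#' are found by bounded quasi-Newton optimisation from a grid of starting
#' values to avoid boundary trapping.
#'
#' On a star phylogeny (all off-diagonal covariances zero) the likelihood is
#' constant in lambda; the fit then reports the degeneracy (`lambda = NA`,
#' `degenerate = TRUE`) instead of an arbitrary interior optimum.
#'
#' @param tree a chronogram whose tips match `traits$taxon`.
#' @param traits trait table (`taxon`, `mean`, `se`, ...) or a named numeric
#'   vector of tip values (then `se = 0`).
#' @param use_se logical; include the `diag(se^2)` measurement-error term
#'   (default `TRUE`). Set `FALSE` for sensitivity checks.
#' @param n_starts number of lambda starting values, evenly spaced on
#'   \[0, 1\] (default 5).
#' @return an object of class `"lambda_fit"`: list with `lambda`, `sigma2`,
#'   `z0`, `logLik`, `n`, `use_se`, `degenerate`.
#' @examples
#' tr <- simulate_bd_tree(0.3, 0, n = 40, seed = 7)
#' tt <- simulate_bm_traits(tr, sigma2 = 0.2, lambda_signal = 1, seed = 7)
#' fit_lambda(tr, tt)
#' @export
fit_lambda <- function(tree, traits, use_se = TRUE, n_starts = 5L) {
  tree <- as_chronogram(tree)
  if (is.numeric(traits) && !is.null(names(traits)))
    traits <- data.frame(taxon = names(traits), mean = unname(traits), se = 0)
  idx <- match(tree$tip.label, traits$taxon)
  if (anyNA(idx))
    stop_ccl("trait table is missing tip(s): ",
             paste(utils::head(tree$tip.label[is.na(idx)], 5L), collapse = ", "))
  y <- traits$mean[idx]
  se2 <- if (use_se && !is.null(traits$se)) traits$se[idx]^2 else
    rep(0, length(y))
  n <- length(y)
  if (n < 3L) stop_ccl("need at least 3 tips")
  C <- ape::vcv(tree)

  star <- max(abs(C[upper.tri(C)])) < 1e-12 * max(diag(C))
  s2_0 <- max(stats::var(y) / max(diag(C)), 1e-8)

  if (star) {
    # likelihood does not depend on lambda: profile sigma2 only
    opt <- stats::optimize(function(ls2)
      -lambda_loglik(y, C, se2, 0, exp(ls2)), c(-25, 25))
    ll <- lambda_loglik(y, C, se2, 0, exp(opt$minimum))
    return(structure(list(lambda = NA_real_, sigma2 = exp(opt$minimum),
                          z0 = attr(ll, "z0"), logLik = as.numeric(ll),
                          n = n, use_se = use_se, degenerate = TRUE),
                     class = "lambda_fit"))
  }

  nll <- function(p) {
    v <- lambda_loglik(y, C, se2, p[1L], exp(p[2L]))
    if (!is.finite(v)) 1e10 else -as.numeric(v)
  }
  starts <- seq(0, 1, length.out = max(2L, n_starts))
  best <- NULL
  for (l0 in starts) {
    o <- tryCatch(
      stats::optim(c(l0, log(s2_0)), nll, method = "L-BFGS-B",
                   lower = c(0, -25), upper = c(1, 25)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop_ccl("lambda optimisation failed (singular covariance?)")
  ll <- lambda_loglik(y, C, se2, best$par[1L], exp(best$par[2L]))
  if (!is.finite(ll)) stop_ccl("singular covariance at the optimum")
  structure(list(lambda = best$par[1L], sigma2 = exp(best$par[2L]),
                 z0 = attr(ll, "z0"), logLik = as.numeric(ll),
                 n = n, use_se = use_se, degenerate = FALSE),
            class = "lambda_fit")
}

#' Profile log-likelihood of the lambda model at a fixed lambda
#'
#' Maximises the [fit_lambda()] likelihood over `sigma2` (and the profiled
#' `z0`) with `lambda_signal` held fixed; used for grid checks and profile
#' curves.
#'
#' @inheritParams fit_lambda
#' @param lambda_signal fixed lambda in \[0, 1\].
#' @return the profiled log-likelihood (numeric scalar).
#' @export
lambda_profile_loglik <- function(tree, traits, lambda_signal,
                                  use_se = TRUE) {
  tree <- as_chronogram(tree)
  if (is.numeric(traits) && !is.null(names(traits)))
    traits <- data.frame(taxon = names(traits), mean = unname(traits), se = 0)
  idx <- match(tree$tip.label, traits$taxon)
  y <- traits$mean[idx]
  se2 <- if (use_se && !is.null(traits$se)) traits$se[idx]^2 else
    rep(0, length(y))
  C <- ape::vcv(tree)
  opt <- stats::optimize(function(ls2)
    -lambda_loglik(y, C, se2, lambda_signal, exp(ls2)), c(-25, 25))
  -opt$objective
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda fit (ML)\n")
  if (x$degenerate) {
    cat("  star phylogeny: likelihood constant in lambda (degenerate)\n")
  } else {
    cat(sprintf("  lambda  = %.4f\n", x$lambda))
  }
  cat(sprintf("  sigma^2 = %.6g per Myr\n", x$sigma2))
  cat(sprintf("  z0      = %.4f\n", x$z0))
  cat(sprintf("  logLik  = %.4f  (n = %d tips, measurement error %s)\n",
              x$logLik, x$n, if (x$use_se) "included" else "ignored"))
  invisible(x)
}
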