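#' Simulate a reconstructed birth-death chronogram
#'
#' Forward (Gillespie) simulation of a constant-rate birth-death process
#' started from two crown lineages, stopped either at a target number of
#' extant tips or at a fixed crown span, with extinct lineages pruned so the
#' returned tree is the reconstructed, ultrametric genealogy of the
#' survivors. Replicates that lose the whole clade before the stop condition
#' are rejected and re-run from a derived seed, up to `max_tries` attempts.
#'
#' Under the `n` stop the simulation halts at the instant the n-th extant
#' lineage is born, so for a pure-birth (Yule) process the crown age is the
#' sum of exponential waiting times with rates `k * lambda`, k = 2..n-1.
#'
#' @param lambda speciation rate (events/lineage/Myr), > 0.
#' @param mu extinction rate (events/lineage/Myr), >= 0.
#' @param n target number of extant tips (>= 2); exclusive with `max_age`.
#' @param max_age crown span in Myr at which to stop; exclusive with `n`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param max_tries rejection cap for clade extinction (default 1000).
#' @return an ultrametric binary `"phylo"` chronogram with tips `t1, t2, ...`.
#' @examples
#' tr <- simulate_bd_tree(lambda = 0.2, mu = 0.05, n = 10, seed = 1)
#' root_age(tr)
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n = NULL, max_age = NULL,
                             seed = 1L, max_tries = 1000L) {
  if (!is.null(n) && !is.null(max_age))
    stop_ccl("give exactly one of `n` and `max_age`")
  if (is.null(n) && is.null(max_age))
    stop_ccl("give a stop condition: `n` or `max_age`")
  if (lambda <= 0) stop_ccl("`lambda` must be > 0 (no speciation possible)")
  if (mu < 0) stop_ccl("`mu` must be >= 0")
  if (!is.null(n) && n < 2) stop_ccl("`n` must be >= 2")
  if (!is.null(max_age) && max_age <= 0) stop_ccl("`max_age` must be > 0")

  for (try in seq_len(max_tries)) {
    res <- with_seed(derive_seed(seed, try - 1L),
                     bd_forward(lambda, mu, n, max_age))
    if (!is.null(res)) return(as_chronogram(res))
  }
  stop_ccl("clade went extinct before the stop condition in ", max_tries,
           " attempts; increase lambda/mu ratio or the retry cap")
}

# One forward pass; returns NULL if the clade dies before the stop condition.
# Lineage bookkeeping is flat vectors; the surviving genealogy is assembled
# as Newick and extinct tips dropped afterwards.
bd_forward <- function(lambda, mu, n, max_age) {
  # records: birth time, end time, children indices (0 = none)
  cap <- 64L
  t_birth <- numeric(cap); t_end <- numeric(cap)
  kid1 <- integer(cap); kid2 <- integer(cap)
  side <- integer(cap)                 # which crown lineage each descends from
  t_birth[1:2] <- 0; side[1:2] <- 1:2; alive <- c(1L, 2L); m <- 2L
  t <- 0
  repeat {
    k <- length(alive)
    if (!is.null(n) && k >= n) break
    if (k == 0L) return(NULL)
    dt <- stats::rexp(1L, k * (lambda + mu))
    if (!is.null(max_age) && t + dt >= max_age) { t <- max_age; break }
    t <- t + dt
    i <- alive[sample.int(k, 1L)]
    if (stats::runif(1L) < lambda / (lambda + mu)) {  # speciation
      if (m + 2L > cap) {
        cap <- cap * 2L
        length(t_birth) <- cap; length(t_end) <- cap
        length(kid1) <- cap; length(kid2) <- cap; length(side) <- cap
        kid1[is.na(kid1)] <- 0L; kid2[is.na(kid2)] <- 0L
      }
      t_end[i] <- t; kid1[i] <- m + 1L; kid2[i] <- m + 2L
      t_birth[(m + 1L):(m + 2L)] <- t
      side[(m + 1L):(m + 2L)] <- side[i]
      alive <- c(alive[alive != i], m + 1L, m + 2L)
      m <- m + 2L
    } else {                                          # extinction
      t_end[i] <- t
      alive <- alive[alive != i]
    }
  }
  if (is.null(n)) {
    # for a fixed crown span, both crown lineages must leave survivors so
    # the reconstructed crown age equals the requested span
    if (!all(1:2 %in% side[alive])) return(NULL)
  }
  t_end[alive] <- t

  as_newick <- function(i) {
    if (kid1[i] > 0L)
      sprintf("(%s,%s):%.12g", as_newick(kid1[i]), as_newick(kid2[i]),
              t_end[i] - t_birth[i])
    else sprintf("t%d:%.12g", i, t_end[i] - t_birth[i])
  }
  txt <- sprintf("(%s,%s);", as_newick(1L), as_newick(2L))
  phy <- ape::read.tree(text = txt)
  extant <- paste0("t", alive)
  if (length(extant) < length(phy$tip.label))
    phy <- ape::keep.tip(phy, extant)
  if (length(phy$tip.label) < 2L) return(NULL)
  phy$tip.label <- paste0("t", seq_along(phy$tip.label))
  phy
}

#' Simulate Brownian-motion traits with tunable phylogenetic signal
#'
#' Draws one continuous trait per tip from the multivariate normal model with
#' mean `z0` and covariance `sigma2 * C(lambda_signal) + diag(se^2)`, where
#' `C` is the shared-path-length (vcv) matrix of the chronogram and
#' `lambda_signal` is Pagel's lambda scaling its off-diagonal entries. The
#' draw is generated by summing independent normal increments along the
#' branches of the lambda-rescaled tree (internal branches scaled by lambda,
#' pendant branches stretched to preserve total depth), which realises the
#' lambda covariance exactly — including on trees with zero-length pendant
#' pairs, where the plain vcv matrix is singular.
#'
#' @param tree a binary ultrametric chronogram.
#' @param sigma2 Brownian rate (trait^2/Myr), >= 0.
#' @param z0 root (ancestral) state.
#' @param lambda_signal Pagel's lambda in \[0, 1\].
#' @param se per-tip measurement standard error (scalar or per-tip vector).
#' @param seed integer seed.
#' @return a trait table (`data.frame`: `taxon`, `mean`, `sd`, `se`, `n`) as
#'   used by [fit_lambda()] and [dtt_observed()].
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, z0 = 0, lambda_signal = 1,
                               se = 0, seed = 1L) {
  tree <- as_chronogram(tree)
  if (sigma2 < 0) stop_ccl("`sigma2` must be >= 0")
  if (lambda_signal < 0 || lambda_signal > 1)
    stop_ccl("`lambda_signal` must be in [0, 1]")
  ntip <- length(tree$tip.label)
  se <- rep_len(se, ntip)
  if (any(se < 0)) stop_ccl("`se` must be >= 0")
  x <- with_seed(seed, {
    vals <- z0 + bm_tip_draw(tree, sigma2, lambda_signal)
    vals + stats::rnorm(ntip, 0, se)
  })
  data.frame(taxon = tree$tip.label, mean = x,
             sd = ifelse(se > 0, se * sqrt(2), 0),
             se = se, n = ifelse(se > 0, 2L, 1L),
             stringsAsFactors = FALSE)
}

# One mean-zero draw from N(0, sigma2 * C(lambda)) at the tips, by branch
# increments on the lambda-rescaled tree (preorder accumulation).
bm_tip_draw <- function(tree, sigma2, lambda_signal) {
  ntip <- length(tree$tip.label)
  if (sigma2 == 0) return(numeric(ntip))
  el <- tree$edge.length
  ra <- root_age(tree)
  tip_edge <- tree$edge[, 2L] <= ntip
  el2 <- lambda_signal * el
  el2[tip_edge] <- lambda_signal * el[tip_edge] + (1 - lambda_signal) * ra
  inc <- stats::rnorm(length(el2), 0, sqrt(sigma2 * el2))
  state <- numeric(ntip + tree$Nnode)
  ord <- rev(ape::postorder(tree))            # preorder over edges
  for (e in ord)
    state[tree$edge[e, 2L]] <- state[tree$edge[e, 1L]] + inc[e]
  state[seq_len(ntip)]
}

#' Simulate a posterior-style rate-shift event configuration
#'
#' Assigns every branch of the tree to a diversification-rate process: a root
#' (background) process plus optional shift processes anchored at internal or
#' tip nodes. A shift at node `k` governs all branches within `k`'s subtree
#' unless overridden by a more recent (nested) shift; the process start time
#' is the shift node's age. This mirrors one posterior sample of a rate-shift
#' model with exponentially time-varying speciation.
#'
#' @param tree a chronogram.
#' @param root_process numeric vector `c(lambda0, z, mu0)`: initial speciation
#'   rate, exponential change parameter (per Myr), and extinction rate of the
#'   background process, which starts at the root age.
#' @param shifts optional `data.frame` with columns `node` (node number),
#'   `lambda0`, `z`, `mu0`.
#' @return an [event_configuration()] object.
#' @export
simulate_event_configuration <- function(tree,
                                         root_process = c(0.1, 0, 0.02),
                                         shifts = NULL) {
  procs <- data.frame(node = NA_integer_,
                      lambda0 = root_process[[1L]], z = root_process[[2L]],
                      mu0 = root_process[[3L]])
  if (!is.null(shifts)) {
    shifts <- as.data.frame(shifts)
    stopifnot(all(c("node", "lambda0", "z", "mu0") %in% names(shifts)))
    procs <- rbind(procs, shifts[, c("node", "lambda0", "z", "mu0")])
  }
  event_configuration(tree, procs)
}

#' Simulate smooth autocorrelated paleoclimate series
#'
#' Generates temperature deviation (deltaT, deg C), atmospheric oxygen
#' percentage (pO2, %) and CO2 concentration (cCO2, ppm) on an age grid as a
#' piecewise-linear trend through control points plus exponentially
#' autocorrelated (CAR(1)-kernel) Gaussian noise. pO2 is clipped to the open
#' interval (0, 100) and cCO2 to positive values. Defaults sketch a
#' Mesozoic-to-present greenhouse-to-icehouse history over the last 200 Myr.
#'
#' @param ages age grid in Ma (strictly monotone). Default `seq(200, 0)`.
#' @param trend named list of control-point `data.frame`s (`age`, `value`)
#'   for `deltaT`, `pO2`, `cCO2`; linear interpolation between points.
#' @param noise_sd named numeric vector of marginal noise SDs per variable.
#' @param noise_range autocorrelation length of the noise (Myr): the noise
#'   correlation at lag d is `exp(-d/noise_range)`.
#' @param seed integer seed.
#' @return a `climate_series` data.frame (`age`, `deltaT`, `pO2`, `cCO2`).
#' @export
simulate_climate_series <- function(ages = seq(200, 0, by = -1),
                                    trend = default_climate_trend(),
                                    noise_sd = c(deltaT = 0.6, pO2 = 0.4,
                                                 cCO2 = 60),
                                    noise_range = 10,
                                    seed = 1L) {
  d <- diff(ages)
  if (length(ages) < 2L || !(all(d > 0) || all(d < 0)))
    stop_ccl("`ages` must be strictly monotone")
  if (any(noise_sd < 0)) stop_ccl("`noise_sd` must be >= 0")
  vars <- c("deltaT", "pO2", "cCO2")
  stopifnot(all(vars %in% names(trend)), all(vars %in% names(noise_sd)))
  out <- data.frame(age = ages)
  eps <- with_seed(seed, {
    L <- chol(exp(-abs(outer(ages, ages, "-")) / noise_range))
    sapply(vars, function(v)
      noise_sd[[v]] * drop(crossprod(L, stats::rnorm(length(ages)))))
  })
  for (v in vars) {
    tr <- trend[[v]]
    base <- stats::approx(tr$age, tr$value, xout = ages, rule = 2)$y
    out[[v]] <- base + eps[, v]
  }
  out$pO2 <- pmin(pmax(out$pO2, 1e-6), 100 - 1e-6)
  out$cCO2 <- pmax(out$cCO2, 1e-6)
  climate_series(out)
}

#' Default climate trend control points
#'
#' Piecewise-linear sketches of the last 200 Myr: warm Mesozoic temperatures
#' cooling to the present, oxygen rising from ~16% to ~21%, and CO2 declining
#' from ~2000 ppm to ~400 ppm.
#'
#' @return named list of control-point data.frames for
#'   [simulate_climate_series()].
#' @export
default_climate_trend <- function() {
  list(
    deltaT = data.frame(age = c(200, 145, 90, 66, 35, 0),
                        value = c(6, 8, 10, 6, 4, 0)),
    pO2 = data.frame(age = c(200, 145, 66, 30, 0),
                     value = c(16, 18, 21, 23, 21)),
    cCO2 = data.frame(age = c(200, 145, 66, 30, 0),
                      value = c(2000, 1700, 900, 500, 400))
  )
}

#' Simulate a regression response with CAR(1) errors
#'
#' Ground-truth generator for the GLS fitter: `y = X b + e` with
#' `cov(e_i, e_j) = sigma^2 * exp(-phi * |t_i - t_j|)`.
#'
#' @param X design matrix (rows aligned with `ages`).
#' @param b coefficient vector, `length(b) == ncol(X)`.
#' @param phi autocorrelation decay rate (1/Myr), >= 0.
#' @param sigma residual standard deviation.
#' @param ages time points in Ma.
#' @param seed integer seed.
#' @return numeric response vector.
#' @export
simulate_gls_response <- function(X, b, phi, sigma, ages, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(ages)) stop_ccl("rows of `X` must align with `ages`")
  if (length(b) != ncol(X)) stop_ccl("`b` length must match columns of `X`")
  mu <- drop(X %*% b)
  if (sigma == 0) return(mu)
  eps <- with_seed(seed, {
    R <- exp(-phi * abs(outer(ages, ages, "-")))
    drop(crossprod(chol(R), stats::rnorm(length(ages))))
  })
  mu + sigma * eps
}

#' Write a trait table to tab-separated text
#' @param traits trait table (`taxon`, `mean`, `sd`, `se`, `n`).
#' @param path output path.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trait table from tab-separated text
#' @param path input path (columns `taxon`, `mean`, `sd`, `se`, `n`).
#' @return trait table data.frame.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop_ccl("trait table file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("taxon", "mean", "se")
  if (!all(need %in% names(x)))
    stop_ccl("trait table needs columns: ", paste(need, collapse = ", "))
  x
}
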