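#' Trait disparity of a set of values
#'
#' The disparity of a tip set is the mean over all unordered pairs of the
#' squared difference `(x_i - x_j)^2` (default), or of the absolute
#' difference with `metric = "absolute"`. Sets with fewer than two values
#' have disparity 0.
#'
#' @param x numeric vector of trait values.
#' @param metric `"squared"` (average squared pairwise distance, the usual
#'   disparity-through-time default) or `"absolute"`.
#' @return non-negative scalar.
#' @examples
#' pairwise_disparity(c(0, 2))      # 4
#' pairwise_disparity(c(0, 1, 2))   # 2
#' @export
pairwise_disparity <- function(x, metric = c("squared", "absolute")) {
  metric <- match.arg(metric)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop_ccl("values must be finite")
  n <- length(x)
  if (n < 2L) return(0)
  if (metric == "squared") {
    # (2 / (n(n-1))) * sum_{i<j} (x_i - x_j)^2  ==  2 * var(x)
    return(2 * stats::var(x))
  }
  s <- sort(x)
  tot <- sum(s * (2 * seq_len(n) - 1 - n))   # sum of |x_i - x_j| over pairs
  tot / (n * (n - 1) / 2)
}

# Static tree geometry shared by observed and null DTT curves: the node-age
# grid and, per grid age, the set of nodes subtending a live branch when the
# curve is evaluated just below that age.
dtt_precompute <- function(tree) {
  tree <- as_chronogram(tree)
  ntip <- length(tree$tip.label)
  ages <- node_ages(tree)
  grid <- sort(ages[(ntip + 1L):(ntip + tree$Nnode)], decreasing = TRUE)
  ra <- grid[1L]
  parent_age <- ages[tree$edge[, 1L]]
  child_age <- ages[tree$edge[, 2L]]
  alive <- lapply(seq_along(grid), function(j) {
    if (j == 1L) return(ntip + 1L)           # root: the whole clade
    # "just below t", taken as the limit from above when t = 0 (possible
    # when a simulated tree carries an internal node at exactly age 0)
    t <- max(grid[j], 1e-9 * ra)
    tree$edge[child_age < t & parent_age >= t, 2L]
  })
  # clade membership of every node, as tip index lists
  clades <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) clades[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  list(tree = tree, ntip = ntip, ages = ages, grid = grid, root_age = ra,
       alive = alive, clades = clades)
}

# Disparity of every node's subtended tip set, for a matrix of trait draws
# (tips x nsim). Squared metric only; vectorised across draws.
node_disparity_multi <- function(pre, X) {
  nn <- length(pre$clades)
  # disparity is translation-invariant; centring removes the catastrophic
  # cancellation in m*S2 - S1^2 for traits with a large common offset
  X <- X - rep(colMeans(X), each = nrow(X))
  D <- matrix(0, nn, ncol(X))
  for (k in (pre$ntip + 1L):nn) {
    tips <- pre$clades[[k]]
    m <- length(tips)
    S1 <- colSums(X[tips, , drop = FALSE])
    S2 <- colSums(X[tips, , drop = FALSE]^2)
    # mean squared pairwise difference: 2 * (m * sum(x^2) - sum(x)^2) / (m (m-1))
    D[k, ] <- pmax(0, m * S2 - S1^2) * 2 / (m * (m - 1))
  }
  D
}

dtt_values <- function(pre, D) {
  # D: node x nsim disparity matrix; returns grid x nsim relative curve
  tot <- D[pre$ntip + 1L, ]
  out <- matrix(0, length(pre$grid), ncol(D))
  out[1L, ] <- 1
  for (j in seq_along(pre$grid)[-1L]) {
    rel <- D[pre$alive[[j]], , drop = FALSE]
    out[j, ] <- colMeans(rel) / tot
  }
  out
}

#' Observed disparity-through-time curve
#'
#' Evaluates mean relative subclade disparity at every internal-node age,
#' from the root (where the relative disparity of the whole clade is 1 by
#' definition) towards the present. At an age `t` the curve is evaluated
#' just below `t`: a node splitting exactly at `t` contributes its two
#' daughter lineages separately, each lineage contributing the disparity of
#' its subtended tip set divided by the whole-tree disparity; single-tip
#' lineages contribute 0, which drives the curve towards 0 at the present.
#'
#' @param tree a binary ultrametric chronogram.
#' @param traits trait table (`taxon`, `mean`, ...) or named numeric vector.
#' @param metric disparity metric, see [pairwise_disparity()].
#' @return a `"dtt_curve"`: data.frame with `age` (Ma, descending),
#'   `rel_time` (0 at the root, 1 at the present) and `disparity`.
#' @export
dtt_observed <- function(tree, traits, metric = c("squared", "absolute")) {
  metric <- match.arg(metric)
  pre <- dtt_precompute(tree)
  x <- align_traits(pre$tree, traits)
  new_dtt_curve(pre, dtt_curve_one(pre, x, metric))
}

align_traits <- function(tree, traits) {
  if (is.numeric(traits) && !is.null(names(traits))) {
    x <- traits[tree$tip.label]
  } else {
    x <- traits$mean[match(tree$tip.label, traits$taxon)]
  }
  if (anyNA(x)) stop_ccl("traits missing for some tips")
  as.numeric(x)
}

dtt_curve_one <- function(pre, x, metric = "squared") {
  if (metric == "squared") {
    v <- dtt_values(pre, node_disparity_multi(pre, matrix(x, ncol = 1L)))
    tot <- pairwise_disparity(x)
    if (tot <= 0) stop_ccl("whole-tree disparity is 0 (all traits identical)")
    return(drop(v))
  }
  disp <- vapply(pre$clades, function(tips)
    pairwise_disparity(x[tips], metric = "absolute"), 0)
  tot <- disp[pre$ntip + 1L]
  if (tot <= 0) stop_ccl("whole-tree disparity is 0 (all traits identical)")
  out <- numeric(length(pre$grid))
  out[1L] <- 1
  for (j in seq_along(pre$grid)[-1L])
    out[j] <- mean(disp[pre$alive[[j]]]) / tot
  out
}

new_dtt_curve <- function(pre, values) {
  structure(
    data.frame(age = pre$grid,
               rel_time = (pre$root_age - pre$grid) / pre$root_age,
               disparity = values),
    root_age = pre$root_age, class = c("dtt_curve", "data.frame"))
}

#' Brownian-motion null envelope for a DTT curve
#'
#' Simulates `nsim` Brownian trait sets on the tree (the relative curve is
#' invariant to the Brownian rate), runs each through the observed-curve
#' computation and summarises the simulated curves pointwise by their
#' median, mean, and 2.5%/97.5% quantiles on the same node-age grid.
#'
#' @inheritParams dtt_observed
#' @param nsim number of Brownian simulations (default 10000).
#' @param seed integer seed.
#' @return a `"dtt_null"`: data.frame with `age`, `rel_time`, `median`,
#'   `mean`, `q025`, `q975`; attribute `nsim`.
#' @export
dtt_null <- function(tree, nsim = 10000L, seed = 1L) {
  if (nsim < 2L) stop_ccl("`nsim` must be >= 2")
  pre <- dtt_precompute(tree)
  tree <- pre$tree
  ntip <- pre$ntip
  curves <- with_seed(seed, {
    inc <- matrix(stats::rnorm(nrow(tree$edge) * nsim), nrow(tree$edge))
    inc <- inc * sqrt(tree$edge.length)
    state <- matrix(0, ntip + tree$Nnode, nsim)
    for (e in rev(ape::postorder(tree)))
      state[tree$edge[e, 2L], ] <- state[tree$edge[e, 1L], ] + inc[e, ]
    dtt_values(pre, node_disparity_multi(pre, state[seq_len(ntip), , drop = FALSE]))
  })
  out <- data.frame(
    age = pre$grid,
    rel_time = (pre$root_age - pre$grid) / pre$root_age,
    median = apply(curves, 1L, stats::median),
    mean = rowMeans(curves),
    q025 = apply(curves, 1L, stats::quantile, probs = 0.025, names = FALSE),
    q975 = apply(curves, 1L, stats::quantile, probs = 0.975, names = FALSE))
  structure(out, nsim = nsim, root_age = pre$root_age,
            class = c("dtt_null", "data.frame"))
}

check_dtt_grids <- function(observed, null) {
  if (nrow(observed) != nrow(null) ||
      max(abs(observed$age - null$age)) > 1e-8 * max(observed$age, 1))
    stop_ccl("observed curve and null envelope are on different grids")
}

#' Morphological disparity index (MDI)
#'
#' Signed area between the observed DTT curve and the null reference curve
#' over relative time, by left-step integration on the node-age grid with
#' the terminal segment extended to relative time 1 (both curves held at
#' their last value). Negative values mean the observed disparity sits below
#' the Brownian expectation — disparity partitioned among rather than within
#' subclades.
#'
#' @param observed a `"dtt_curve"` from [dtt_observed()].
#' @param null a `"dtt_null"` from [dtt_null()], on the same grid.
#' @param reference which null summary to integrate against: `"median"`
#'   (default) or `"mean"`.
#' @return the MDI (dimensionless scalar).
#' @export
mdi <- function(observed, null, reference = c("median", "mean")) {
  reference <- match.arg(reference)
  check_dtt_grids(observed, null)
  d <- observed$disparity - null[[reference]]
  s <- c(observed$rel_time, 1)
  sum(d * diff(s))
}

#' Disparity deviation series
#'
#' The per-node-age difference between the observed DTT value and the null
#' reference curve: `DD_i = observed_i - null_i`. Under Brownian evolution
#' the series fluctuates around 0.
#'
#' @inheritParams mdi
#' @return data.frame with `age`, `rel_time`, `dd`.
#' @export
disparity_deviation <- function(observed, null,
                                reference = c("median", "mean")) {
  reference <- match.arg(reference)
  check_dtt_grids(observed, null)
  data.frame(age = observed$age, rel_time = observed$rel_time,
             dd = observed$disparity - null[[reference]])
}

#' Full disparity-through-time analysis
#'
#' Convenience wrapper computing the observed curve, the Brownian null
#' envelope, the MDI and the disparity-deviation series in one call.
#'
#' @inheritParams dtt_observed
#' @inheritParams dtt_null
#' @inheritParams mdi
#' @return a `"dtt_result"` list: `observed`, `null`, `mdi`, `dd`,
#'   `reference`, `nsim`.
#' @examples
#' tr <- simulate_bd_tree(0.3, 0, n = 30, seed = 2)
#' tt <- simulate_bm_traits(tr, sigma2 = 0.5, seed = 2)
#' res <- dtt(tr, tt, nsim = 200, seed = 3)
#' res$mdi
#' @export
dtt <- function(tree, traits, nsim = 10000L, seed = 1L,
                metric = c("squared", "absolute"),
                reference = c("median", "mean")) {
  metric <- match.arg(metric)
  reference <- match.arg(reference)
  obs <- dtt_observed(tree, traits, metric = metric)
  nul <- dtt_null(tree, nsim = nsim, seed = seed)
  structure(list(observed = obs, null = nul,
                 mdi = mdi(obs, nul, reference = reference),
                 dd = disparity_deviation(obs, nul, reference = reference),
                 reference = reference, nsim = nsim),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat("Disparity through time\n")
  cat(sprintf("  grid: %d node ages, root %.2f Ma\n",
              nrow(x$observed), attr(x$observed, "root_age")))
  cat(sprintf("  null: %d BM simulations (reference: %s)\n",
              x$nsim, x$reference))
  cat(sprintf("  MDI = %.4f\n", x$mdi))
  invisible(x)
}

#' Plot a DTT result
#'
#' Observed curve, null reference line and pointwise 95% band against
#' relative time.
#'
#' @param x a `"dtt_result"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dtt_result <- function(x, ...) {
  s <- x$observed$rel_time
  ylim <- range(0, x$observed$disparity, x$null$q975)
  graphics::plot(s, x$observed$disparity, type = "n", ylim = ylim,
                 xlab = "Relative time (root = 0)",
                 ylab = "Mean relative disparity", ...)
  graphics::polygon(c(s, rev(s)), c(x$null$q025, rev(x$null$q975)),
                    col = grDevices::adjustcolor("gold", 0.4), border = NA)
  graphics::lines(s, x$null[[x$reference]], lty = 2, col = "blue")
  graphics::lines(s, x$observed$disparity, col = "red", lwd = 2)
  invisible(x)
}
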