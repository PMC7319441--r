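# Independent brute-force oracles, written from the definitions and kept
# free of the package's internal precomputations.

# Node ages by explicit root-to-node path sums over parent links.
oracle_node_ages <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  root <- length(phy$tip.label) + 1L
  depth <- rep(NA_real_, nn)
  depth[root] <- 0
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      if (!is.na(depth[p]) && is.na(depth[ch])) {
        depth[ch] <- depth[p] + phy$edge.length[e]
        done <- FALSE
      }
    }
    if (done) break
  }
  max(depth[seq_along(phy$tip.label)]) - depth
}

# Tip indices below a node, by naive recursion on the edge table.
oracle_clade_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  ch <- phy$edge[phy$edge[, 1L] == node, 2L]
  sort(unlist(lapply(ch, oracle_clade_tips, phy = phy)))
}

# Mean squared pairwise difference by the double loop.
oracle_disparity <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) tot <- tot + (x[i] - x[j])^2
  tot / (n * (n - 1) / 2)
}

# DTT curve by explicit enumeration: at each internal-node age (just below
# it), average the relative disparity of every branch's subtended tip set.
oracle_dtt <- function(phy, x) {
  ages <- oracle_node_ages(phy)
  ntip <- length(phy$tip.label)
  grid <- sort(ages[(ntip + 1L):length(ages)], decreasing = TRUE)
  total <- oracle_disparity(x)
  out <- numeric(length(grid))
  out[1L] <- 1
  for (j in seq_along(grid)[-1L]) {
    t <- max(grid[j], 1e-9 * max(grid))   # limit from above at age 0
    vals <- c()
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      if (ages[ch] < t && ages[p] >= t)
        vals <- c(vals, oracle_disparity(x[oracle_clade_tips(phy, ch)]))
    }
    out[j] <- mean(vals) / total
  }
  list(age = grid, disparity = out)
}

# Pearson correlation by the direct formula.
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# A random ultrametric tree from a source independent of the package's
# birth-death simulator.
random_coal_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
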