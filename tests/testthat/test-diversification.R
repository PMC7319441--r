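four_tip_tree <- function() read_chronogram("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")

test_that("sampling fractions divide sampled tips by described richness", {
  tr <- simulate_bd_tree(0.3, 0, n = 10, seed = 3)
  cl <- list(left = tr$tip.label[1:5], right = tr$tip.label[6:10])
  sf <- sampling_fractions(tr, c(left = 100, right = 10), cl)
  expect_equal(sf$fraction, c(0.05, 0.5))
  expect_equal(attr(sf, "global"), 1.0)
  expect_error(sampling_fractions(tr, c(left = 3, right = 10), cl),
               "richness 3 < 5")
  expect_error(sampling_fractions(tr, c(left = 100, right = 10, none = 5),
                                  c(cl, list(none = "nope"))), "zero sampled")
})

test_that("branch rates follow the exponential speciation parameterisation", {
  tr <- four_tip_tree()
  cfg <- simulate_event_configuration(tr, root_process = c(0.2, 0, 0.05))
  e <- which(cfg$edges$child == match("C", tr$tip.label))
  r <- branch_rate_at(cfg, e, 0.5)
  expect_equal(unname(r), c(0.2, 0.05, 0.15))

  # lambda0 = 0.1, z = 0.05, 10 Myr elapsed since the process start
  tr2 <- read_chronogram("(A:20,B:20);")
  cfg2 <- simulate_event_configuration(tr2, root_process = c(0.1, 0.05, 0))
  r2 <- branch_rate_at(cfg2, 1L, 10)
  expect_equal(unname(r2["lambda"]), 0.1 * exp(0.5), tolerance = 1e-10)

  expect_error(branch_rate_at(cfg, e, 1.9), "outside branch")
  # a recorded event time younger than the queried age is an error
  cfg3 <- cfg
  cfg3$processes$start_age <- 0.4
  expect_error(branch_rate_at(cfg3, e, 0.5), "older than the process start")
})

test_that("rate through time is flat for a single constant process", {
  tr <- four_tip_tree()
  cfg <- simulate_event_configuration(tr, root_process = c(0.2, 0, 0.05))
  rs <- rate_through_time(tr, cfg, grid = c(0, 0.5, 1.2, 2))
  expect_equal(rs$rate, rep(0.15, 4))
  expect_error(rate_through_time(tr, cfg, grid = 2.5), "outside")
  expect_error(rate_through_time(tr, cfg, grid = numeric(0)), "empty")
})

test_that("rate through time matches the hand-enumerated per-lineage table", {
  tr <- four_tip_tree()
  cfg1 <- simulate_event_configuration(tr, root_process = c(0.2, 0, 0.05))
  ab <- ape::getMRCA(tr, c("A", "B"))
  cfg2 <- simulate_event_configuration(
    tr, root_process = c(0.2, 0, 0.05),
    shifts = data.frame(node = ab, lambda0 = 0.4, z = 0, mu0 = 0.1))
  rs <- rate_through_time(tr, list(cfg1, cfg2), grid = c(0.5, 0.75, 1.25, 2))
  # at 0.5 and 0.75: lineages A, B, C, D; A and B average (0.15 + 0.3)/2,
  # C and D stay at 0.15 -> median = (0.15 + 0.225)/2 = 0.1875.
  # at 1.25: AB stem (root process in both configs), C, D -> all 0.15.
  # at 2 (root age): the two crown branches, both root process -> 0.15.
  expect_equal(rs$rate[rs$age == 0.5], 0.1875)
  expect_equal(rs$rate[rs$age == 0.75], 0.1875)
  expect_equal(rs$rate[rs$age == 1.25], 0.15)
  expect_equal(rs$rate[rs$age == 2], 0.15)
})

test_that("a single time-varying process reproduces its closed form on any tree", {
  for (seed in c(2, 9)) {
    tr <- simulate_bd_tree(0.4, 0.1, n = 12, seed = seed)
    ra <- root_age(tr)
    cfg <- simulate_event_configuration(tr, root_process = c(0.3, -0.04, 0.07))
    grid <- seq(0, ra, length.out = 9)
    rs <- rate_through_time(tr, cfg, grid)
    expect_equal(rs$rate, 0.3 * exp(-0.04 * (ra - rs$age)) - 0.07,
                 tolerance = 1e-10)
  }
})

test_that("the lineage median is invariant to relabeling and zero-length resolutions", {
  tr <- four_tip_tree()
  ab <- ape::getMRCA(tr, c("A", "B"))
  cfg <- simulate_event_configuration(
    tr, root_process = c(0.2, 0.01, 0.05),
    shifts = data.frame(node = ab, lambda0 = 0.4, z = -0.02, mu0 = 0.1))
  grid <- c(0.25, 0.9, 1.4)
  rs <- rate_through_time(tr, cfg, grid)

  tr2 <- tr
  tr2$tip.label <- c("W", "X", "Y", "Z")[match(tr$tip.label,
                                               c("A", "B", "C", "D"))]
  cfg2 <- simulate_event_configuration(
    tr2, root_process = c(0.2, 0.01, 0.05),
    shifts = data.frame(node = ape::getMRCA(tr2, c("W", "X")),
                        lambda0 = 0.4, z = -0.02, mu0 = 0.1))
  expect_equal(rate_through_time(tr2, cfg2, grid)$rate, rs$rate)
})

test_that("restriction to a subtree agrees with computing on the pruned tree", {
  tr <- four_tip_tree()
  ab <- ape::getMRCA(tr, c("A", "B"))
  shift <- c(0.4, 0.05, 0.1)
  cfg <- simulate_event_configuration(
    tr, root_process = c(0.2, 0, 0.05),
    shifts = data.frame(node = ab, lambda0 = shift[1], z = shift[2],
                        mu0 = shift[3]))
  sub <- prune_to_taxa(tr, c("A", "B"))
  cfg_sub <- simulate_event_configuration(sub, root_process = shift)
  grid <- c(0.2, 0.6, 0.95)
  expect_equal(rate_through_time(sub, cfg_sub, grid)$rate,
               0.4 * exp(0.05 * (1 - sort(grid, decreasing = TRUE))) - 0.1,
               tolerance = 1e-10)
  # the full-tree per-lineage rates of A and B at those ages are identical
  ages <- node_ages(tr)
  for (g in grid) {
    edges <- lineages_at(tr, g)
    ab_edges <- edges[names(edges) %in% match(c("A", "B"), tr$tip.label)]
    for (e in ab_edges)
      expect_equal(unname(branch_rate_at(cfg, e, g)["r"]),
                   0.4 * exp(0.05 * (1 - g)) - 0.1, tolerance = 1e-10)
  }
})

test_that("event data files round-trip through the posterior dialect", {
  tr <- simulate_bd_tree(0.3, 0.05, n = 15, seed = 13)
  inner <- (17):(15 + tr$Nnode)
  cfgs <- lapply(1:3, function(i)
    simulate_event_configuration(
      tr, root_process = c(0.1 + 0.01 * i, 0.002, 0.03),
      shifts = data.frame(node = inner[i * 2], lambda0 = 0.2, z = -0.01,
                          mu0 = 0.05)))
  f <- tempfile(fileext = ".txt")
  write_event_data(cfgs, tr, f)
  back <- read_event_data(f, tr)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$processes$lambda0, cfgs[[i]]$processes$lambda0,
                 tolerance = 1e-10)
    expect_equal(back[[i]]$processes$start_age, cfgs[[i]]$processes$start_age,
                 tolerance = 1e-8)
    expect_equal(back[[i]]$edges$process, cfgs[[i]]$edges$process)
  }
  grid <- seq(0, root_age(tr), length.out = 7)
  expect_equal(rate_through_time(tr, back, grid)$rate,
               rate_through_time(tr, cfgs, grid)$rate, tolerance = 1e-8)
})
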