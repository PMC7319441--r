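test_that("simulate_bd_tree meets its stop condition and invariants", {
  tr <- simulate_bd_tree(0.2, 0, n = 10, seed = 1)
  expect_equal(length(tr$tip.label), 10L)
  expect_true(ape::is.ultrametric(tr))
  expect_true(ape::is.binary(tr))
  expect_error(simulate_bd_tree(0, 0, n = 10), "lambda")

  tr2 <- simulate_bd_tree(0.3, 0.1, max_age = 20, seed = 2)
  expect_equal(root_age(tr2), 20, tolerance = 1e-8)

  # with extinction, the reconstructed tree still passes all invariants
  tr3 <- simulate_bd_tree(0.5, 0.4, n = 25, seed = 3)
  expect_equal(length(tr3$tip.label), 25L)
  expect_silent(as_chronogram(tr3))
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulate_bd_tree(0.3, 0.1, n = 15, seed = 7)
  b <- simulate_bd_tree(0.3, 0.1, n = 15, seed = 7)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_false(identical(ape::write.tree(a),
                         ape::write.tree(simulate_bd_tree(0.3, 0.1, n = 15,
                                                          seed = 8))))
  t1 <- simulate_bm_traits(a, 0.5, 2, 0.8, se = 0.1, seed = 5)
  expect_identical(t1, simulate_bm_traits(a, 0.5, 2, 0.8, se = 0.1, seed = 5))
  c1 <- simulate_climate_series(seed = 9)
  expect_identical(c1, simulate_climate_series(seed = 9))
  expect_false(identical(c1$deltaT, simulate_climate_series(seed = 10)$deltaT))
})

test_that("Yule crown ages match the closed-form waiting-time sum", {
  crown <- vapply(1:1000, function(i)
    root_age(simulate_bd_tree(1, 0, n = 10, seed = i)), 0)
  expected <- sum(1 / (2:9))             # sum of Exp(k * lambda) means
  mc_se <- stats::sd(crown) / sqrt(length(crown))
  expect_lt(abs(mean(crown) - expected), 3.5 * mc_se)
})

test_that("event configurations assign branches to the most recent ancestral shift", {
  tr <- read_chronogram("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  cfg0 <- simulate_event_configuration(tr, root_process = c(0.2, 0, 0.05))
  expect_true(all(cfg0$edges$process == 1L))

  ab <- ape::getMRCA(tr, c("A", "B"))
  cfg1 <- simulate_event_configuration(
    tr, root_process = c(0.2, 0, 0.05),
    shifts = data.frame(node = ab, lambda0 = 0.4, z = 0.01, mu0 = 0.1))
  shifted <- cfg1$edges$process == 2L
  expect_equal(sort(cfg1$edges$child[shifted]),
               sort(match(c("A", "B"), tr$tip.label)))
  expect_equal(cfg1$processes$start_age[2L], 1)  # shift starts at node age

  expect_error(simulate_event_configuration(
    tr, shifts = data.frame(node = 99, lambda0 = 1, z = 0, mu0 = 0)),
    "not in tree")
  expect_error(simulate_event_configuration(
    tr, shifts = data.frame(node = c(ab, ab), lambda0 = 1, z = 0, mu0 = 0)),
    "duplicate")
})

test_that("BM traits have the lambda-scaled phylogenetic covariance", {
  tr <- read_chronogram("((A:2,B:2):3,(C:4,D:4):1);")
  # degenerate rate: every tip equals the root state
  t0 <- simulate_bm_traits(tr, sigma2 = 0, z0 = 1.5, seed = 1)
  expect_equal(t0$mean, rep(1.5, 4))

  C <- ape::vcv(tr)
  n_rep <- 2000
  draws <- vapply(seq_len(n_rep), function(i)
    simulate_bm_traits(tr, sigma2 = 1, z0 = 0, lambda_signal = 1,
                       seed = 20000 + i)$mean, numeric(4))
  Chat <- stats::cov(t(draws))
  se_entry <- sqrt((outer(diag(C), diag(C)) + C^2) / n_rep)
  expect_true(all(abs(Chat - C) < 5 * se_entry))

  # lambda = 0: cross-covariances vanish (star-tree limit)
  draws0 <- vapply(seq_len(n_rep), function(i)
    simulate_bm_traits(tr, sigma2 = 1, z0 = 0, lambda_signal = 0,
                       seed = 40000 + i)$mean, numeric(4))
  C0 <- stats::cov(t(draws0))
  off <- C0[upper.tri(C0)]
  expect_true(all(abs(off) < 5 * sqrt((outer(diag(C), diag(C)))[upper.tri(C)] / n_rep)))
  expect_equal(unname(diag(C0)), unname(diag(C)), tolerance = 0.3)
})

test_that("climate generator follows its trend and bounds", {
  cl <- simulate_climate_series(noise_sd = c(deltaT = 0, pO2 = 0, cCO2 = 0),
                                seed = 1)
  trend <- default_climate_trend()
  expect_equal(cl$deltaT,
               stats::approx(trend$deltaT$age, trend$deltaT$value,
                             xout = cl$age, rule = 2)$y)
  expect_equal(nrow(cl), 201L)           # 200 -> 0 Ma in 1-Myr steps
  cl2 <- simulate_climate_series(seed = 2)
  expect_true(all(cl2$pO2 > 0 & cl2$pO2 < 100))
  expect_true(all(cl2$cCO2 > 0))
  expect_error(simulate_climate_series(ages = c(1, 3, 2)), "monotone")
})

test_that("GLS response generator realises the CAR(1) error model", {
  ages <- seq(0, 59)
  X <- cbind(1, ages / 10)
  b <- c(2, -0.5)
  y0 <- simulate_gls_response(X, b, phi = 0.3, sigma = 0, ages, seed = 1)
  expect_equal(y0, drop(X %*% b))

  phi <- 0.25
  reps <- vapply(1:200, function(i)
    simulate_gls_response(X, c(0, 0), phi = phi, sigma = 1, ages,
                          seed = 300 + i), numeric(60))
  # empirical correlation at lags 1 and 4 Myr vs exp(-phi d), pooled over
  # positions and replicates (the process is stationary with mean 0)
  for (d in c(1, 4)) {
    a <- as.vector(reps[1:(60 - d), ])
    b <- as.vector(reps[(1 + d):60, ])
    expect_lt(abs(oracle_pearson(a, b) - exp(-phi * d)), 0.05)
  }
  expect_error(simulate_gls_response(X, c(1), 0.1, 1, ages), "length")
})
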