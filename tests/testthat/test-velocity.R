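test_that("exact steady state gives the slope and zero velocity", {
  withr::with_seed(12, S <- matrix(runif(60, 0.5, 5), 20, 3))
  U <- 2 * S
  vm <- fit_steady_state(S, U, quantile = 0.25)
  expect_equal(unname(vm$gamma), rep(2, 3), tolerance = 1e-12)
  expect_lt(max(abs(vm$velocity)), 1e-12)
  expect_true(all(vm$valid_genes))
})

test_that("degenerate genes are masked, not errors", {
  withr::with_seed(13, {
    S <- cbind(runif(20, 1, 3), 0, runif(20, 1, 3))
    U <- cbind(2 * S[, 1], runif(20, 1, 2), 2 * S[, 3])
  })
  vm <- fit_steady_state(S, U)
  expect_false(vm$valid_genes[2])       # S == 0 throughout
  expect_true(is.na(vm$gamma[2]))
  expect_equal(vm$velocity[, 2], rep(0, 20))
  # an all-zero gene is masked too
  S[, 3] <- 0; U[, 3] <- 0
  vm2 <- fit_steady_state(S, U)
  expect_false(vm2$valid_genes[3])
})

test_that("degradation ratios are recovered from simulated kinetics", {
  for (gamma_star in c(0.3, 0.8, 1.5)) {
    cfg <- simulation_config(n_ref_cells = 300, n_genes = 1,
                             gamma_range = c(gamma_star, gamma_star),
                             noise_sd = 0, seed = 101)
    km <- simulate_kinetics(cfg)
    vm <- fit_steady_state(km$S, km$U, quantile = 0.05, min_cells = 5)
    expect_true(vm$valid_genes[1])
    expect_lt(abs(vm$gamma[1] - gamma_star) / gamma_star, 0.10)
  }
})

test_that("transition rows are stochastic and respect velocity direction", {
  # 4 obs on a line in expression space; velocity of obs 1 points at obs 2
  S <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1))
  V <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0))
  suppressMessages(g <- velocity_graph(V, S, neighbors = 3, sigma = 0.05))
  P <- as.matrix(g$transition)
  # only neighbor 2 has positive cosine with obs 1's velocity
  expect_equal(P[1, 2], 1)
  # zero-velocity obs take a uniform row over their 3 neighbors
  expect_true(g$uniform[2])
  expect_equal(sort(P[2, P[2, ] > 0]), rep(1/3, 3))
  expect_rows_sum_to(P, 1)
})

test_that("transition probabilities match a brute-force softmax oracle", {
  withr::with_seed(31, {
    S <- matrix(rnorm(12), 6, 2)
    V <- matrix(rnorm(12), 6, 2)
  })
  k <- 3; sigma <- 0.05
  suppressMessages(g <- velocity_graph(V, S, neighbors = k, sigma = sigma))
  P <- as.matrix(g$transition)
  for (i in 1:6) {
    d <- colSums((t(S) - S[i, ])^2); d[i] <- Inf
    nb <- order(d)[1:k]
    cs <- sapply(nb, function(j) {
      disp <- S[j, ] - S[i, ]
      sum(V[i, ] * disp) / sqrt(sum(V[i, ]^2) * sum(disp^2))
    })
    pos <- cs > 0
    expected <- rep(0, 6)
    if (any(pos)) {
      w <- exp(cs[pos] / sigma)
      expected[nb[pos]] <- w / sum(w)
    } else {
      expected[nb] <- 1 / k
    }
    expect_lt(max(abs(P[i, ] - expected)), 1e-12)
  }
})

test_that("common rescaling of S and U leaves the transition graph unchanged", {
  cfg <- simulation_config(n_ref_cells = 60, n_genes = 20, seed = 41)
  km <- simulate_kinetics(cfg)
  vm1 <- fit_steady_state(km$S, km$U, min_cells = 5)
  vm2 <- fit_steady_state(3.7 * km$S, 3.7 * km$U, min_cells = 5)
  expect_equal(vm2$velocity, 3.7 * vm1$velocity, tolerance = 1e-10)
  suppressMessages({
    g1 <- velocity_graph(vm1, km$S, neighbors = 10)
    g2 <- velocity_graph(vm2, 3.7 * km$S, neighbors = 10)
  })
  expect_equal(as.matrix(g1$transition), as.matrix(g2$transition),
               tolerance = 1e-10)
})

test_that("arrow projection matches the hand-computed estimator", {
  withr::with_seed(51, {
    E <- matrix(rnorm(10), 5, 2)
    S <- matrix(rnorm(15), 5, 3)
    V <- matrix(rnorm(15), 5, 3)
  })
  suppressMessages(g <- velocity_graph(V, S, neighbors = 3))
  f <- project_velocity(g, E)
  P <- as.matrix(g$transition)
  for (i in 1:5) {
    nb <- g$neighbors[i, ]
    disp <- t(t(E[nb, , drop = FALSE]) - E[i, ])
    disp <- disp / sqrt(rowSums(disp^2))
    expected <- colSums(disp * P[i, nb]) - colMeans(disp)
    if (g$uniform[i]) expected <- c(0, 0)
    expect_lt(max(abs(f$arrows[i, ] - expected)), 1e-12)
  }
})

test_that("arrows point toward the transition target and vanish under uniformity", {
  E <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  S <- E  # expression space mirrors embedding
  V <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  suppressMessages(g <- velocity_graph(V, S, neighbors = 4))
  f <- project_velocity(g, E)
  # obs 1 transitions fully toward obs 2 at (1, 0)
  expect_gt(sum(f$arrows[1, ] * c(1, 0)), 0)
  # uniform rows cancel against the correction term
  expect_equal(f$arrows[2, ], c(0, 0))
})

test_that("pseudotime orders a deterministic chain and flags degeneracy", {
  P <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 3, 3), x = 1,
                            dims = c(3, 3))
  g <- structure(list(transition = P, neighbors = cbind(c(2L, 3L, 2L)),
                      uniform = rep(FALSE, 3)), class = "velocity_graph")
  expect_equal(velocity_pseudotime(g), c(0, 0.5, 1))
  # identity transition: no diffusion anywhere
  I3 <- Matrix::Diagonal(3)
  gi <- structure(list(transition = I3, neighbors = cbind(1:3),
                       uniform = rep(FALSE, 3)), class = "velocity_graph")
  w <- capture_warnings(pt <- velocity_pseudotime(gi))
  expect_true(any(grepl("pseudotime set to 0", w)))
  expect_equal(pt, c(0, 0, 0))
})

test_that("pseudotime tracks simulation time along a trajectory", {
  cfg <- simulation_config(n_ref_cells = 60, n_genes = 40, noise_sd = 0.05,
                           seed = 71)
  km <- simulate_kinetics(cfg)
  vm <- fit_steady_state(km$S, km$U, min_cells = 5)
  suppressMessages(g <- velocity_graph(vm, km$S, neighbors = 10))
  pt <- suppressWarnings(velocity_pseudotime(g))
  rho <- cor(pt, km$truth$time, method = "spearman")
  expect_gt(abs(rho), 0.9)
})

test_that("projected arrows follow the spatial gradient on synthetic data", {
  sim <- simulate_paired(simulation_config(
    n_ref_cells = 200, n_spots = 150, n_genes = 80, n_shared_genes = 80,
    noise_sd = 0.05, seed = 81))
  vm <- fit_steady_state(as_mat(sim$ref$spliced), as_mat(sim$ref$unspliced),
                         min_cells = 5)
  suppressMessages(g <- velocity_graph(vm, as_mat(sim$ref$spliced),
                                       neighbors = 20))
  # embed reference cells on the same time-gradient layout as spots
  E <- cbind(sim$truth$ref_time, 0.5)
  f <- project_velocity(g, E)
  moving <- sqrt(rowSums(f$arrows^2)) > 1e-9
  # true motion is toward increasing time, i.e. +x
  cos_grad <- f$arrows[moving, 1] / sqrt(rowSums(f$arrows[moving, ]^2))
  expect_gt(mean(cos_grad), 0.8)
})
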