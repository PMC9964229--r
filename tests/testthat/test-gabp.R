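# helper: flatten weight matrices in the package's layer-major layout
flat_theta <- function(W, b) {
  unlist(lapply(seq_along(W), function(l) c(as.numeric(W[[l]]), b[[l]])))
}

test_that("min-max scaling maps features exactly onto [0.10, 0.90]", {
  sc <- scale_minmax(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(sc$scaled), c(0.10, 0.50, 0.90))

  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc2 <- scale_minmax(X)
  expect_equal(as.numeric(sc2$scaled[, "b"]), rep(0.5, 3))
  expect_true(sc2$params$constant[["b"]])

  set.seed(1)
  M <- matrix(rnorm(40), 10, 4)
  sc3 <- scale_minmax(M)
  expect_equal(apply(sc3$scaled, 2, min), rep(0.10, 4),
               ignore_attr = TRUE)
  expect_equal(apply(sc3$scaled, 2, max), rep(0.90, 4),
               ignore_attr = TRUE)
  expect_equal(inverse_scaling(sc3$scaled, sc3$params), M,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(scale_minmax(matrix(1, 1, 2)), ">= 2 rows")
})

test_that("forward pass is a bounded logsig cascade", {
  cfg <- network_config(layer_sizes = c(2, 3, 1))
  zero <- list(theta = numeric(2 * 3 + 3 + 3 + 1), layer_sizes = c(2, 3, 1),
               config = cfg)
  expect_equal(forward(zero, c(0.4, 0.6)), 0.5)

  toy <- list(theta = c(1, 0, 1, 0), layer_sizes = c(1, 1, 1),
              config = network_config(layer_sizes = c(1, 1, 1)))
  expect_equal(forward(toy, 0), 1 / (1 + exp(-0.5)), tolerance = 1e-12)

  set.seed(2)
  rnd <- list(theta = rnorm(2 * 3 + 3 + 3 + 1, 0, 3),
              layer_sizes = c(2, 3, 1), config = cfg)
  outs <- forward(rnd, matrix(runif(40), ncol = 2))
  expect_true(all(outs > 0 & outs < 1))
  expect_error(forward(rnd, c(1, 2, 3)), "columns")
})

test_that("GA fitness is non-decreasing and beats random initialization", {
  X <- matrix(c(0.2, 0.8), 1, 2)
  y <- 0.3
  for (s in 1:3) {
    cfg <- network_config(layer_sizes = c(2, 3, 1),
                          ga = list(population = 12L, generations = 15L),
                          seed = s)
    g <- ga_optimize(X, y, cfg)
    expect_true(all(diff(g$fitness_trace) >= 0))
  }

  sse_ga <- sse_rand <- numeric(20)
  for (s in 1:20) {
    cfg <- network_config(layer_sizes = c(2, 3, 1),
                          ga = list(population = 12L, generations = 15L),
                          seed = 100 + s)
    g <- ga_optimize(X, y, cfg)
    sse_ga[s] <- g$sse
    set.seed(200 + s)
    theta0 <- rnorm(length(g$theta), 0, 0.5)
    net0 <- list(theta = theta0, layer_sizes = c(2, 3, 1), config = cfg)
    sse_rand[s] <- (forward(net0, X) - y)^2
  }
  expect_lt(median(sse_ga), median(sse_rand))

  # zero generations degenerates to best-of-initial-population
  cfg0 <- network_config(layer_sizes = c(2, 3, 1),
                         ga = list(population = 8L, generations = 0L),
                         seed = 1)
  g0 <- ga_optimize(X, y, cfg0)
  expect_length(g0$fitness_trace, 1L)
  expect_equal(g0$sse, 1 / g0$fitness_trace[1] - 1, tolerance = 1e-12)

  expect_error(ga_optimize(X, y, network_config(
    layer_sizes = c(2, 3, 1), ga = list(population = 1L))), ">= 2")
})

test_that("convergence rule enforces both stated criteria strictly", {
  expect_false(check_convergence(rep(0.02, 10), delta = 0.02))  # boundary
  expect_true(check_convergence(rep(0, 5)))
  expect_true(check_convergence(rep(0.01, 10), delta = 0.02))
  expect_false(check_convergence(c(rep(0.001, 9), 0.2), delta = 0.02))
  expect_error(check_convergence(numeric(0)), "empty")
  expect_error(check_convergence(c(0.1, 0.1), n = 3), "length")
})

test_that("a zero learning rate leaves the network untouched", {
  X <- matrix(runif(20), 10, 2)
  y <- runif(10, 0.2, 0.8)
  cfg <- network_config(layer_sizes = c(2, 3, 1),
                        bp = list(learning_rate = 0, max_epochs = 50L))
  set.seed(3)
  theta0 <- rnorm(2 * 3 + 3 + 3 + 1, 0, 0.5)
  net <- bp_train(theta0, X, y, cfg)
  expect_equal(net$theta, theta0)
  expect_equal(length(unique(net$error_trace)), 1L)
})

test_that("backpropagation error trace never increases", {
  set.seed(4)
  X <- matrix(runif(60, 0.1, 0.9), 20, 3)
  y <- 0.1 + 0.8 * plogis(2 * (X[, 1] - 0.5))
  cfg <- network_config(layer_sizes = c(3, 6, 1),
                        bp = list(max_epochs = 300L), seed = 4)
  g <- ga_optimize(X, y, network_config(
    layer_sizes = c(3, 6, 1), ga = list(population = 20L,
                                        generations = 10L), seed = 4))
  net <- bp_train(g$theta, X, y, cfg)
  expect_true(all(diff(net$error_trace) <= 0))
  expect_lte(net$sse, g$sse)
})

test_that("an XOR-style dataset is learned by most seeds", {
  X <- matrix(c(0.1, 0.1, 0.9, 0.9, 0.1, 0.9, 0.1, 0.9), 4, 2)
  y <- c(0.1, 0.9, 0.9, 0.1)
  ok <- 0L
  for (s in 1:10) {
    cfg <- network_config(layer_sizes = c(2, 4, 1),
                          ga = list(population = 30L, generations = 30L),
                          bp = list(max_epochs = 5000L,
                                    learning_rate = 0.5), seed = s)
    g <- ga_optimize(X, y, cfg)
    net <- bp_train(g$theta, X, y, cfg)
    if (net$mae < 0.02) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("training is deterministic for a fixed seed", {
  cl <- gen_climate(20, seed = 8)
  r <- gen_response(cl, effect_spec(linear = c(SD = 1), noise_sd = 0.05),
                    seed = 9)
  cfg <- network_config(layer_sizes = c(8, 6, 1),
                        ga = list(population = 10L, generations = 10L),
                        bp = list(max_epochs = 200L), seed = 5)
  n1 <- suppressWarnings(train_gabp(as.matrix(cl[, climate_factors()]),
                                    r$response, cfg))
  n2 <- suppressWarnings(train_gabp(as.matrix(cl[, climate_factors()]),
                                    r$response, cfg))
  expect_identical(n1$theta, n2$theta)
  s1 <- sensitivity(n1, apply_scaling(as.matrix(cl[, climate_factors()]),
                                      n1$input_scaling))
  s2 <- sensitivity(n2, apply_scaling(as.matrix(cl[, climate_factors()]),
                                      n2$input_scaling))
  expect_identical(unclass(s1), unclass(s2))
})

test_that("sensitivity ignores dead inputs and sums to one", {
  W1 <- matrix(rnorm(12), 3, 4)
  W1[3, ] <- 0  # third input disconnected
  b1 <- rnorm(4)
  W2 <- matrix(rnorm(4), 4, 1)
  b2 <- 0.2
  net <- list(theta = flat_theta(list(W1, W2), list(b1, b2)),
              layer_sizes = c(3, 4, 1),
              config = network_config(layer_sizes = c(3, 4, 1)))
  X <- matrix(runif(30, 0.1, 0.9), 10, 3)
  s <- sensitivity(net, X)
  expect_equal(unname(s[3]), 0)
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_error(sensitivity(net, X, perturbation = 0), "> 0")
})

test_that("sensitivity is equivariant under input reordering", {
  set.seed(6)
  W1 <- matrix(rnorm(12), 3, 4)
  b1 <- rnorm(4)
  W2 <- matrix(rnorm(4), 4, 1)
  b2 <- 0.1
  perm <- c(2, 1, 3)  # self-inverse transposition
  net <- list(theta = flat_theta(list(W1, W2), list(b1, b2)),
              layer_sizes = c(3, 4, 1),
              config = network_config(layer_sizes = c(3, 4, 1)))
  netp <- list(theta = flat_theta(list(W1[perm, ], W2), list(b1, b2)),
               layer_sizes = c(3, 4, 1),
               config = network_config(layer_sizes = c(3, 4, 1)))
  X <- matrix(runif(24, 0.1, 0.9), 8, 3)
  # netp sees input j wired to the original net's factor perm[j]
  s <- sensitivity(net, X[, perm, drop = FALSE])
  sp <- sensitivity(netp, X)
  expect_equal(as.numeric(sp), as.numeric(s)[perm], tolerance = 1e-10)
})

test_that("a two-factor 1:2 linear response yields a ~1:2 sensitivity", {
  cl <- gen_climate(200, seed = 10)
  r <- gen_response(cl, effect_spec(linear = c(SD = 1, ARH = 2),
                                    noise_sd = 0.01), seed = 11)
  X <- as.matrix(cl[, c("SD", "ARH")])
  cfg <- network_config(layer_sizes = c(2, 8, 1),
                        ga = list(population = 20L, generations = 20L),
                        bp = list(max_epochs = 2000L), seed = 12)
  net <- train_gabp(X, r$response, cfg)
  s <- sensitivity(net, apply_scaling(X, net$input_scaling))
  ratio <- s[["ARH"]] / s[["SD"]]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})
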