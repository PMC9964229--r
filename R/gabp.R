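# GA-initialized backpropagation network.
#
# A multilayer feed-forward net with logistic-sigmoid (logsig) units on every
# non-input layer, default topology 8-50-30-1. A real-coded genetic algorithm
# first optimizes the full weight/bias vector (fitness 1/(1+SSE)); batch
# gradient descent with momentum and an adaptive learning rate then fine-tunes
# from the GA optimum. Inputs and outputs are min-max scaled to [0.10, 0.90]
# so targets stay inside the sigmoid's range.

logsig <- function(z) 1 / (1 + exp(-z))

#' Network and training configuration
#'
#' @param layer_sizes Integer vector, first entry = number of input factors,
#'   last entry must be 1; default `c(8, 50, 30, 1)`.
#' @param input_range Target bounds of the min-max scaling, default
#'   `c(0.10, 0.90)` for both inputs and outputs.
#' @param ga List of genetic-algorithm settings: `population` (40),
#'   `generations` (100), `crossover_p` (0.8), `mutation_p` (0.05),
#'   `mutation_sd` (0.1), `tournament_size` (2).
#' @param bp List of backpropagation settings: `learning_rate` (0.05),
#'   `momentum` (0.9), `lr_up` (1.05), `lr_down` (0.7), `max_epochs` (5000).
#' @param delta Per-sample error tolerance used by the convergence rule
#'   (default 0.02).
#' @param seed Integer seed for GA initialization and operators.
#' @return Object of class `network_config`.
#' @export
network_config <- function(layer_sizes = c(8, 50, 30, 1),
                           input_range = c(0.10, 0.90),
                           ga = list(), bp = list(), delta = 0.02,
                           seed = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L) ||
      layer_sizes[length(layer_sizes)] != 1L) {
    stop("layer_sizes must have >= 2 entries, all positive, ending in 1",
         call. = FALSE)
  }
  ga <- utils::modifyList(list(population = 40L, generations = 100L,
                               crossover_p = 0.8, mutation_p = 0.05,
                               mutation_sd = 0.1, tournament_size = 2L), ga)
  bp <- utils::modifyList(list(learning_rate = 0.05, momentum = 0.9,
                               lr_up = 1.05, lr_down = 0.7,
                               max_epochs = 5000L), bp)
  probs <- c(ga$crossover_p, ga$mutation_p, bp$momentum)
  if (any(probs < 0) || any(probs > 1)) {
    stop("crossover_p, mutation_p and momentum must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0",
                                             call. = FALSE)
  structure(list(layer_sizes = layer_sizes, input_range = input_range,
                 ga = ga, bp = bp, delta = delta,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Min-max scale features onto a target interval
#'
#' Maps each non-constant column affinely so its minimum hits `lo` and its
#' maximum hits `hi`; constant columns are mapped to the interval midpoint
#' and flagged. The returned parameters invert the transform exactly.
#'
#' @param X Numeric matrix or data.frame (>= 2 rows).
#' @param lo,hi Target bounds, default 0.10 and 0.90.
#' @return List with `scaled` (matrix) and `params` (class
#'   `scaling_params`: per-column `min`, `max`, `constant`, plus `lo`, `hi`).
#' @export
scale_minmax <- function(X, lo = 0.10, hi = 0.90) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 rows to scale", call. = FALSE)
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  constant <- maxs == mins
  span <- ifelse(constant, 1, maxs - mins)
  scaled <- sweep(sweep(X, 2L, mins), 2L, span, "/") * (hi - lo) + lo
  scaled[, constant] <- (lo + hi) / 2
  params <- structure(list(min = mins, max = maxs, constant = constant,
                           lo = lo, hi = hi), class = "scaling_params")
  list(scaled = scaled, params = params)
}

#' Apply stored min-max parameters to new data
#' @param X Matrix/data.frame with the training columns.
#' @param params A `scaling_params` object.
#' @return Scaled matrix (constant training columns map to the midpoint).
#' @export
apply_scaling <- function(X, params) {
  X <- as.matrix(X)
  span <- ifelse(params$constant, 1, params$max - params$min)
  scaled <- sweep(sweep(X, 2L, params$min), 2L, span, "/") *
    (params$hi - params$lo) + params$lo
  scaled[, params$constant] <- (params$lo + params$hi) / 2
  scaled
}

#' Invert a min-max scaling
#' @param S Scaled matrix.
#' @param params A `scaling_params` object.
#' @return Matrix on the original scale (constant columns restored to their
#'   training value).
#' @export
inverse_scaling <- function(S, params) {
  S <- as.matrix(S)
  span <- ifelse(params$constant, 1, params$max - params$min)
  X <- sweep(sweep((S - params$lo) / (params$hi - params$lo), 2L, span, "*"),
             2L, params$min, "+")
  for (j in which(params$constant)) X[, j] <- params$min[j]
  X
}

# --- weight-vector layout -------------------------------------------------

.n_params <- function(sizes) {
  sum(vapply(seq_len(length(sizes) - 1L),
             function(l) sizes[l] * sizes[l + 1L] + sizes[l + 1L],
             numeric(1)))
}

.unflatten <- function(theta, sizes) {
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nw <- sizes[l] * sizes[l + 1L]
    W[[l]] <- matrix(theta[pos + seq_len(nw)], sizes[l], sizes[l + 1L])
    pos <- pos + nw
    b[[l]] <- theta[pos + seq_len(sizes[l + 1L])]
    pos <- pos + sizes[l + 1L]
  }
  list(W = W, b = b)
}

.forward_theta <- function(theta, sizes, X) {
  wb <- .unflatten(theta, sizes)
  A <- X
  for (l in seq_along(wb$W)) {
    A <- logsig(sweep(A %*% wb$W[[l]], 2L, wb$b[[l]], "+"))
  }
  A
}

.sse_theta <- function(theta, sizes, X, y) {
  sum((.forward_theta(theta, sizes, X) - y)^2)
}

#' Forward pass through a trained network
#'
#' Repeated affine map plus logsig through every layer. Operates on the
#' scaled input space; use `scale = TRUE` (default when the network carries
#' scaling parameters) to feed raw factor values and recover raw responses.
#'
#' @param net A `trained_network` (or list with `theta`, `layer_sizes`).
#' @param x Input vector or matrix (rows = samples) with
#'   `layer_sizes[1]` columns.
#' @param scale If `TRUE`, apply the network's stored input scaling before
#'   and invert its output scaling after (requires both to be present).
#' @return Numeric vector of outputs, strictly in (0, 1) on the scaled
#'   output space.
#' @export
forward <- function(net, x, scale = FALSE) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != net$layer_sizes[1]) {
    stop("input has ", ncol(x), " columns; network expects ",
         net$layer_sizes[1], call. = FALSE)
  }
  if (scale) {
    if (is.null(net$input_scaling) || is.null(net$output_scaling)) {
      stop("network carries no scaling parameters", call. = FALSE)
    }
    x <- apply_scaling(x, net$input_scaling)
  }
  out <- .forward_theta(net$theta, net$layer_sizes, x)
  if (scale) out <- inverse_scaling(out, net$output_scaling)
  as.numeric(out)
}

#' Genetic-algorithm pre-optimization of the weight vector
#'
#' Real-coded GA over the concatenated weights and biases. Fitness is
#' 1/(1 + SSE) on the scaled training set; tournament selection, arithmetic
#' crossover, additive Gaussian mutation, elitism of one. Best-of-run is
#' returned; with elitism the best fitness is non-decreasing across
#' generations.
#'
#' @param X Scaled input matrix (rows = samples).
#' @param y Scaled target vector.
#' @param config A [network_config()].
#' @return List with `theta` (best weight vector), `sse`, and
#'   `fitness_trace` (best fitness per generation, length generations + 1
#'   including the initial population).
#' @export
ga_optimize <- function(X, y, config = network_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("training set is empty", call. = FALSE)
  ga <- config$ga
  if (ga$population < 2L) stop("population must be >= 2", call. = FALSE)
  sizes <- config$layer_sizes
  L <- .n_params(sizes)

  set.seed(config$seed)
  pop <- matrix(stats::rnorm(ga$population * L, 0, 0.5), ga$population, L)
  sse <- apply(pop, 1L, function(th) .sse_theta(th, sizes, X, y))
  fitness <- 1 / (1 + sse)
  trace <- max(fitness)

  if (ga$generations > 0L) {
    for (g in seq_len(ga$generations)) {
      elite_i <- which.max(fitness)
      newpop <- matrix(0, ga$population, L)
      newpop[1L, ] <- pop[elite_i, ]
      for (i in seq.int(2L, ga$population)) {
        pick <- function() {
          cand <- sample.int(ga$population, ga$tournament_size,
                             replace = TRUE)
          cand[which.max(fitness[cand])]
        }
        p1 <- pop[pick(), ]
        child <- if (stats::runif(1) < ga$crossover_p) {
          a <- stats::runif(1)
          a * p1 + (1 - a) * pop[pick(), ]
        } else p1
        mut <- stats::runif(L) < ga$mutation_p
        if (any(mut)) {
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0,
                                                  ga$mutation_sd)
        }
        newpop[i, ] <- child
      }
      pop <- newpop
      sse <- apply(pop, 1L, function(th) .sse_theta(th, sizes, X, y))
      fitness <- 1 / (1 + sse)
      trace <- c(trace, max(fitness))
    }
  }
  best <- which.max(fitness)
  list(theta = pop[best, ], sse = sse[best], fitness_trace = trace)
}

#' Training-convergence rule
#'
#' Converged when both stated criteria hold on the scaled outputs: the sum
#' of squared per-sample errors is strictly below `delta^2 * n`, and the
#' mean absolute error is below 0.02.
#'
#' @param errors Per-sample output errors (target minus prediction, scaled).
#' @param delta Per-sample tolerance, default 0.02.
#' @param n Sample count; must equal `length(errors)`.
#' @return Logical.
#' @export
check_convergence <- function(errors, delta = 0.02, n = length(errors)) {
  if (length(errors) == 0L) stop("`errors` is empty", call. = FALSE)
  if (n != length(errors)) stop("`n` must equal length(errors)",
                                call. = FALSE)
  sum(errors^2) < delta^2 * n && mean(abs(errors)) < 0.02
}

#' Backpropagation fine-tuning from an initial weight vector
#'
#' Batch gradient descent with momentum on the SSE of the scaled training
#' set. After each epoch the new SSE is evaluated: an epoch that reduces it
#' is accepted and the learning rate is multiplied by `lr_up`; otherwise the
#' update is rejected (weights reverted, momentum reset) and the rate is
#' multiplied by `lr_down`, so the error trace never increases. Training
#' stops at [check_convergence()] or `max_epochs`.
#'
#' @param init_theta Initial weight vector (e.g. from [ga_optimize()]),
#'   length matching the topology.
#' @param X Scaled input matrix.
#' @param y Scaled target vector.
#' @param config A [network_config()].
#' @return Object of class `trained_network`: `theta`, `weights` (list form),
#'   `layer_sizes`, `error_trace` (SSE per epoch), `mae`, `converged`,
#'   `config`; scaling slots are filled by [train_gabp()].
#' @export
bp_train <- function(init_theta, X, y, config = network_config()) {
  X <- as.matrix(X)
  y <- matrix(as.numeric(y), ncol = 1L)
  sizes <- config$layer_sizes
  L <- .n_params(sizes)
  if (length(init_theta) != L) {
    stop("init_theta has length ", length(init_theta), "; topology needs ",
         L, call. = FALSE)
  }
  bp <- config$bp
  theta <- init_theta
  velocity <- numeric(L)
  lr <- bp$learning_rate
  nlay <- length(sizes) - 1L

  sse_of <- function(th) .sse_theta(th, sizes, X, y)
  grad_of <- function(th) {
    wb <- .unflatten(th, sizes)
    acts <- vector("list", nlay + 1L)
    acts[[1L]] <- X
    for (l in seq_len(nlay)) {
      acts[[l + 1L]] <- logsig(sweep(acts[[l]] %*% wb$W[[l]], 2L,
                                     wb$b[[l]], "+"))
    }
    # dSSE/dout = 2 (out - y); chain through logsig derivative a(1-a)
    delta <- 2 * (acts[[nlay + 1L]] - y) *
      acts[[nlay + 1L]] * (1 - acts[[nlay + 1L]])
    gW <- vector("list", nlay)
    gb <- vector("list", nlay)
    for (l in rev(seq_len(nlay))) {
      gW[[l]] <- crossprod(acts[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(wb$W[[l]])) * acts[[l]] * (1 - acts[[l]])
      }
    }
    unlist(lapply(seq_len(nlay),
                  function(l) c(as.numeric(gW[[l]]), gb[[l]])))
  }

  sse <- sse_of(theta)
  trace <- sse
  converged <- FALSE
  for (epoch in seq_len(bp$max_epochs)) {
    g <- grad_of(theta)
    if (any(!is.finite(g))) {
      stop("training diverged (non-finite gradient) at epoch ", epoch,
           call. = FALSE)
    }
    velocity <- bp$momentum * velocity - lr * g
    cand <- theta + velocity
    cand_sse <- sse_of(cand)
    if (is.finite(cand_sse) && cand_sse < sse) {
      theta <- cand
      sse <- cand_sse
      lr <- lr * bp$lr_up
    } else {
      velocity <- numeric(L)
      lr <- lr * bp$lr_down
    }
    trace <- c(trace, sse)
    err <- y - .forward_theta(theta, sizes, X)
    if (check_convergence(as.numeric(err), delta = config$delta)) {
      converged <- TRUE
      break
    }
    if (lr < 1e-12) break  # step size underflow; no further progress
  }

  err <- as.numeric(y - .forward_theta(theta, sizes, X))
  structure(list(theta = theta, weights = .unflatten(theta, sizes),
                 layer_sizes = sizes, error_trace = trace,
                 mae = mean(abs(err)), sse = sse, converged = converged,
                 input_scaling = NULL, output_scaling = NULL,
                 config = config),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf(
    "trained network %s: SSE %.4g, MAE %.4g, %s after %d epochs\n",
    paste(x$layer_sizes, collapse = "-"), x$sse, x$mae,
    if (x$converged) "converged" else "not converged",
    length(x$error_trace) - 1L))
  invisible(x)
}

#' Train a GA-initialized BP network on raw factors and response
#'
#' Convenience wrapper around the full chain: min-max scale inputs and
#' output to `config$input_range`, run [ga_optimize()], fine-tune with
#' [bp_train()], and attach the scaling parameters to the returned network.
#' With fewer than about 10 samples a warning flags that the fit is
#' training-set only and statistically fragile.
#'
#' @param X Raw feature matrix/data.frame (sites x climate factors).
#' @param y Raw response vector.
#' @param config A [network_config()] whose first layer width matches
#'   `ncol(X)`.
#' @return A `trained_network` with `input_scaling`, `output_scaling` and
#'   `ga_trace` filled in.
#' @export
train_gabp <- function(X, y, config = network_config()) {
  X <- as.matrix(X)
  if (ncol(X) != config$layer_sizes[1]) {
    stop("config expects ", config$layer_sizes[1], " input factors; got ",
         ncol(X), call. = FALSE)
  }
  if (nrow(X) < 10L) {
    warning("fewer than 10 samples: training-set fit only, no held-out ",
            "error is possible", call. = FALSE)
  }
  sx <- scale_minmax(X, config$input_range[1], config$input_range[2])
  sy <- scale_minmax(matrix(y, ncol = 1L), config$input_range[1],
                     config$input_range[2])
  ga <- ga_optimize(sx$scaled, sy$scaled, config)
  net <- bp_train(ga$theta, sx$scaled, as.numeric(sy$scaled), config)
  net$input_scaling <- sx$params
  net$output_scaling <- sy$params
  net$ga_trace <- ga$fitness_trace
  net
}

#' One-at-a-time sensitivity analysis of a trained network
#'
#' Central-difference perturbation on the scaled input space: for factor j,
#' `s_j = mean over samples of |f(x + d e_j) - f(x - d e_j)| / (2 d)` with
#' `d = perturbation x (hi - lo)`. The profile is normalized to sum to 1; a
#' network that is flat in every factor yields a uniform profile with a
#' warning.
#'
#' @param net A `trained_network`.
#' @param X Scaled training inputs (rows = samples). If the network carries
#'   input scaling and `X` is on the raw scale, set `scale = TRUE`.
#' @param perturbation Fraction of the scaled range, default 0.10 (> 0).
#' @param scale Apply the network's input scaling to `X` first.
#' @param response Optional response name carried in the result.
#' @return Object of class `sensitivity_profile`: named non-negative values
#'   summing to 1, with attributes `perturbation` and `response`.
#' @export
sensitivity <- function(net, X, perturbation = 0.10, scale = FALSE,
                        response = NA_character_) {
  if (!is.numeric(perturbation) || perturbation <= 0) {
    stop("`perturbation` must be > 0", call. = FALSE)
  }
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("X is empty", call. = FALSE)
  if (scale) X <- apply_scaling(X, net$input_scaling)
  rng <- net$config$input_range
  d <- perturbation * (rng[2] - rng[1])
  p <- ncol(X)
  s <- vapply(seq_len(p), function(j) {
    Xp <- X; Xp[, j] <- Xp[, j] + d
    Xm <- X; Xm[, j] <- Xm[, j] - d
    mean(abs(.forward_theta(net$theta, net$layer_sizes, Xp) -
               .forward_theta(net$theta, net$layer_sizes, Xm)) / (2 * d))
  }, numeric(1))
  tot <- sum(s)
  if (tot == 0) {
    warning("network output is flat in every factor; uniform profile",
            call. = FALSE)
    s <- rep(1 / p, p)
  } else {
    s <- s / tot
  }
  names(s) <- colnames(X) %||% paste0("x", seq_len(p))
  structure(s, class = c("sensitivity_profile", "numeric"),
            perturbation = perturbation, response = response)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensitivity_profile <- function(x, ...) {
  resp <- attr(x, "response")
  cat("sensitivity profile",
      if (!is.na(resp)) paste0("for ", resp) else "", "\n")
  v <- sort(unclass(x), decreasing = TRUE)
  for (nm in names(v)) cat(sprintf("  %-4s %.3f\n", nm, v[[nm]]))
  invisible(x)
}
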