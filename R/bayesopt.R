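#' Squared-exponential kernel
#'
#' `k(u, u') = alpha exp(-gamma ||u - u'||^2)`.  The inverse-squared-length
#' convention is `gamma = 1 / (2 l^2)`.
#'
#' @param u,u_prime points in `[0, 1]^d` (vectors, or matrices with one point
#'   per row)
#' @param h hyperparameter list with `alpha`, `gamma` (see [kernel_hyperparams()])
#' @return covariance value (or matrix for matrix inputs)
#' @export
se_kernel <- function(u, u_prime, h) {
  if (is.matrix(u) || is.matrix(u_prime)) {
    U <- if (is.matrix(u)) u else matrix(u, nrow = 1)
    V <- if (is.matrix(u_prime)) u_prime else matrix(u_prime, nrow = 1)
    d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * tcrossprod(U, V)
    h$alpha * exp(-h$gamma * pmax(d2, 0))
  } else {
    h$alpha * exp(-h$gamma * sum((u - u_prime)^2))
  }
}

#' Kernel and acquisition hyperparameters
#'
#' @param alpha signal variance (> 0)
#' @param gamma inverse-squared-length-scale (> 0)
#' @param eps2 observation noise variance (>= 0); simulations are
#'   deterministic, so the default is a small jitter proportional to `alpha`
#' @param beta UCB exploration/exploitation tradeoff (the working default
#'   is 0.01)
#' @return object of class `kernel_hyperparams`
#' @export
kernel_hyperparams <- function(alpha = 1, gamma = 1, eps2 = 1e-6 * alpha,
                               beta = 0.01) {
  stopifnot(alpha > 0, gamma > 0, eps2 >= 0, beta >= 0)
  structure(list(alpha = alpha, gamma = gamma, eps2 = eps2, beta = beta),
            class = "kernel_hyperparams")
}

#' Evaluation dataset of (stimulation, total cost) pairs
#'
#' @param U matrix of evaluated points, one per row
#' @param y numeric vector of total-cost values
#' @param provenance `"init"`, `"bo"` or `"random"` per record
#' @return object of class `eval_dataset`
#' @export
eval_dataset <- function(U, y, provenance = rep("init", length(y))) {
  U <- as.matrix(U)
  stopifnot(nrow(U) == length(y), all(is.finite(y)),
            all(U >= 0), all(U <= 1))
  structure(list(U = U, y = as.numeric(y),
                 provenance = as.character(provenance)),
            class = "eval_dataset")
}

dataset_append <- function(D, u, y, provenance) {
  eval_dataset(rbind(D$U, matrix(u, nrow = 1)), c(D$y, y),
               c(D$provenance, provenance))
}

#' Gaussian-process posterior over the cost surface
#'
#' Zero-mean GP with the squared-exponential kernel.  With `standardize =
#' TRUE` (default) the targets are centred and scaled internally and the
#' posterior is mapped back, so the zero prior mean refers to the centred
#' data.  The posterior mean interpolates noiseless training targets; far
#' from all data the mean reverts to the prior and the variance to `alpha`
#' (on the standardized scale).
#'
#' @param D [eval_dataset()] with n >= 1 records
#' @param h [kernel_hyperparams()]
#' @param standardize centre/scale the targets internally
#' @return object of class `gp_posterior`: functions `mu(u)`, `var(u)`,
#'   `sd(u)` accepting a vector or a matrix of rows, plus the cached
#'   factorization
#' @export
gp_posterior <- function(D, h, standardize = TRUE) {
  n <- length(D$y)
  stopifnot(n >= 1)
  ym <- 0; ys <- 1
  if (standardize && n >= 2) {
    ym <- mean(D$y)
    ys <- stats::sd(D$y)
    if (!is.finite(ys) || ys < 1e-12) ys <- 1
  }
  yt <- (D$y - ym) / ys
  K <- se_kernel(D$U, D$U, h)
  L <- NULL
  jitter <- 0
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    L <- tryCatch(chol(K + diag(h$eps2 + j * h$alpha, n)),
                  error = function(e) NULL)
    if (!is.null(L)) { jitter <- j; break }
  }
  if (is.null(L))
    stop("GP factorization failed: kernel matrix numerically singular ",
         "even after jitter escalation")
  w <- backsolve(L, backsolve(L, yt, transpose = TRUE))
  Q <- chol2inv(L)
  kx <- function(u) {
    Um <- if (is.matrix(u)) u else matrix(u, nrow = 1)
    se_kernel(D$U, Um, h)  # n x m
  }
  mu <- function(u) {
    drop(crossprod(kx(u), w)) * ys + ym
  }
  varf <- function(u) {
    kk <- kx(u)
    v <- h$alpha - colSums(kk * (Q %*% kk))
    pmax(v, 0) * ys^2
  }
  structure(list(mu = mu, var = varf, sd = function(u) sqrt(varf(u)),
                 L = L, Q = Q, w = w, y_mean = ym, y_sd = ys, h = h,
                 U = D$U, jitter = jitter, n = n),
            class = "gp_posterior")
}

# negative log marginal likelihood on (log alpha, log gamma); yt standardized
gp_nll <- function(log_par, U, yt, eps2_rel) {
  alpha <- exp(log_par[1]); gamma <- exp(log_par[2])
  n <- length(yt)
  K <- alpha * exp(-gamma * pmax(
    outer(rowSums(U^2), rowSums(U^2), "+") - 2 * tcrossprod(U), 0))
  L <- tryCatch(chol(K + diag(eps2_rel * alpha + 1e-10 * alpha, n)),
                error = function(e) NULL)
  if (is.null(L)) return(1e10)
  w <- backsolve(L, backsolve(L, yt, transpose = TRUE))
  0.5 * sum(yt * w) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

#' Fit kernel hyperparameters by maximum marginal likelihood
#'
#' Multi-start bound-constrained quasi-Newton (L-BFGS-B) maximization of the
#' log marginal likelihood over `(alpha, gamma)` in log space; the targets are
#' standardized internally, matching [gp_posterior()].
#'
#' @param D [eval_dataset()] with n >= 3
#' @param bounds list with `alpha` and `gamma` ranges (on the standardized
#'   target scale)
#' @param restarts number of random starts in addition to the default start
#' @param seed RNG seed for the starts
#' @param start optional warm start `c(alpha, gamma)`
#' @param eps2_rel relative observation-noise jitter
#' @param beta carried through to the returned hyperparameters
#' @return [kernel_hyperparams()] maximizing the likelihood over all starts
#' @export
fit_hyperparameters <- function(D, bounds = list(alpha = c(1e-2, 1e2),
                                                 gamma = c(5e-2, 5e2)),
                                restarts = 5, seed = 1, start = NULL,
                                eps2_rel = 1e-6, beta = 0.01) {
  n <- length(D$y)
  stopifnot(n >= 3)
  ys <- stats::sd(D$y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  yt <- (D$y - mean(D$y)) / ys
  lo <- log(c(bounds$alpha[1], bounds$gamma[1]))
  hi <- log(c(bounds$alpha[2], bounds$gamma[2]))
  starts <- list(log(c(1, 1)))
  if (!is.null(start)) starts <- c(list(log(start)), starts)
  if (restarts > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    for (i in seq_len(restarts))
      starts[[length(starts) + 1]] <- lo + runif(2) * (hi - lo)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(s, lo), hi), gp_nll, U = D$U, yt = yt,
            eps2_rel = eps2_rel, method = "L-BFGS-B",
            lower = lo, upper = hi, control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("all hyperparameter fits failed; keeping previous/default values")
    prev <- if (!is.null(start)) start else c(1, 1)
    return(kernel_hyperparams(alpha = prev[1], gamma = prev[2],
                              eps2 = eps2_rel * prev[1], beta = beta))
  }
  alpha <- exp(best$par[1]); gamma <- exp(best$par[2])
  kernel_hyperparams(alpha = alpha, gamma = gamma,
                     eps2 = eps2_rel * alpha, beta = beta)
}

#' Upper-confidence-bound acquisition
#'
#' `a_UCB(u) = beta sigma_n(u) - mu_n(u)`, to be maximized (the cost is
#' minimized, so low predicted mean is good and high uncertainty is worth
#' exploring).
#'
#' @param u point (vector) or points (matrix rows) in `[0, 1]^d`
#' @param post [gp_posterior()]
#' @param beta exploration/exploitation tradeoff
#' @return acquisition value(s)
#' @export
acquisition_ucb <- function(u, post, beta = post$h$beta) {
  beta * post$sd(u) - post$mu(u)
}

# acquisition value and analytic gradient at a single point, sharing the
# O(n^2) posterior solves (the box optimizer queries value and gradient at
# the same point back to back)
acquisition_value_grad <- function(u, post, beta = post$h$beta) {
  h <- post$h
  diffs <- sweep(post$U, 2, u)            # n x d, (u_i - u)
  kk <- h$alpha * exp(-h$gamma * rowSums(diffs^2))
  dk <- 2 * h$gamma * diffs * kk          # d k(u, u_i) / du
  mu <- sum(kk * post$w) * post$y_sd + post$y_mean
  gmu <- drop(crossprod(dk, post$w)) * post$y_sd
  qk <- drop(post$Q %*% kk)
  v <- max(h$alpha - sum(kk * qk), 0)
  sdv <- sqrt(v) * post$y_sd
  gsd <- drop(crossprod(dk, qk)) * (-1 / sqrt(max(v, 1e-12))) * post$y_sd
  list(value = beta * sdv - mu, grad = beta * gsd - gmu)
}

# analytic gradient of the acquisition at a single point
acquisition_ucb_grad <- function(u, post, beta = post$h$beta) {
  acquisition_value_grad(u, post, beta)$grad
}

#' Propose the next stimulation by maximizing the acquisition
#'
#' Best of `restarts` bound-constrained quasi-Newton (L-BFGS-B with analytic
#' gradients) ascents of the UCB acquisition from uniform random starts,
#' clipped to the box.
#'
#' @param D [eval_dataset()]
#' @param h [kernel_hyperparams()]
#' @param restarts number of uniform random starts
#' @param seed RNG seed
#' @param post optional precomputed [gp_posterior()] for `D`, `h`
#' @return proposed point in `[0, 1]^d`
#' @export
propose_next <- function(D, h, restarts = 30, seed = 1, post = NULL) {
  if (is.null(post)) post <- gp_posterior(D, h)
  d <- ncol(D$U)
  set.seed(seed)
  starts <- matrix(runif(restarts * d), ncol = d)
  last <- new.env(parent = emptyenv())
  vg <- function(u) {
    key <- last$u
    if (!is.null(key) && identical(key, u)) return(last$vg)
    out <- acquisition_value_grad(u, post)
    last$u <- u
    last$vg <- out
    out
  }
  negf <- function(u) -vg(u)$value
  negg <- function(u) -vg(u)$grad
  best_u <- NULL; best_v <- -Inf
  for (i in seq_len(restarts)) {
    u0 <- starts[i, ]
    fit <- tryCatch(
      optim(u0, negf, negg, method = "L-BFGS-B", lower = rep(0, d),
            upper = rep(1, d), control = list(maxit = 30)),
      error = function(e) list(par = u0, value = negf(u0)))
    v <- -fit$value
    v0 <- acquisition_ucb(u0, post)
    if (v0 > v) { v <- v0; fit$par <- u0 }   # never worse than the start
    if (v > best_v) { best_v <- v; best_u <- pmin(1, pmax(0, fit$par)) }
  }
  best_u
}

#' Bayesian-optimization run result
#' @keywords internal
bo_result <- function(dataset, seed, provenance, hyperparam_trace = list()) {
  best_so_far <- cummin(dataset$y)
  ib <- which.min(dataset$y)
  structure(list(dataset = dataset, best_so_far = best_so_far,
                 best_u = dataset$U[ib, ], best_y = dataset$y[ib],
                 seed = seed, iterations = length(dataset$y),
                 provenance = provenance,
                 hyperparam_trace = hyperparam_trace),
            class = "bo_result")
}

safe_cost <- function(cost_callable, u, D) {
  y <- tryCatch(cost_callable(u), error = function(e) NA_real_)
  if (!is.finite(y)) {
    penalty <- if (length(D$y) > 0)
      max(D$y) + max(stats::sd(D$y), 1e-8) else 1e6
    message("cost evaluation failed; recording penalty ", signif(penalty, 4))
    y <- penalty
  }
  y
}

#' Run Gaussian-process Bayesian optimization
#'
#' The loop: initialize with `n_init` uniform random samples, then repeatedly
#' refit the GP on all data, maximize the UCB acquisition, evaluate the cost
#' there, and append the record.  The GP is updated every iteration; the
#' likelihood fit is warm-started from the previous optimum with a full
#' multi-start refresh every `multistart_every` iterations (and on the first
#' fit).
#'
#' @param cost_callable function mapping a point in `[0, 1]^d` to a finite
#'   cost; failures are recorded as a penalty (worst observed + 1 sd)
#' @param maxIter number of optimization iterations after initialization
#' @param n_init number of uniform random initialization samples
#' @param beta UCB tradeoff
#' @param seed RNG seed (controls initialization and all restarts)
#' @param d search-space dimension
#' @param restarts acquisition L-BFGS restarts per iteration
#' @param refit_every refit hyperparameters every k-th iteration
#' @param multistart_every full multi-start likelihood refresh cadence
#' @param eps2_rel relative observation-noise jitter
#' @return object of class `bo_result` with the [eval_dataset()], per-iteration
#'   running minimum `best_so_far`, `best_u`, `best_y` and the seed
#' @export
run_bayesopt <- function(cost_callable, maxIter = 600, n_init = 10,
                         beta = 0.01, seed = 1, d = 6, restarts = 30,
                         refit_every = 1, multistart_every = 25,
                         eps2_rel = 1e-6) {
  set.seed(seed)
  U0 <- matrix(runif(n_init * d), ncol = d)
  y0 <- numeric(n_init)
  D <- eval_dataset(matrix(numeric(0), 0, d), numeric(0), character(0))
  for (i in seq_len(n_init)) {
    y0[i] <- safe_cost(cost_callable, U0[i, ], D)
    D <- dataset_append(D, U0[i, ], y0[i], "init")
  }
  h <- kernel_hyperparams(beta = beta, eps2 = eps2_rel)
  hw <- c(1, 1)
  htrace <- list()
  for (n in seq_len(maxIter)) {
    # the posterior is refit on all data every iteration; the likelihood
    # maximization (hyperparameters) thins out once the dataset is large and
    # the estimates have stabilized
    cadence <- if (length(D$y) <= 150) refit_every else 5 * refit_every
    if (n == 1 || (n - 1) %% cadence == 0) {
      full <- (n == 1 || (n - 1) %% multistart_every == 0)
      h <- fit_hyperparameters(D, restarts = if (full) 4 else 0,
                               seed = seed + 7 * n, start = hw,
                               eps2_rel = eps2_rel, beta = beta)
      hw <- c(h$alpha, h$gamma)
      htrace[[length(htrace) + 1]] <- c(iteration = n, alpha = h$alpha,
                                        gamma = h$gamma)
    }
    post <- gp_posterior(D, h)
    u_next <- propose_next(D, h, restarts = restarts, seed = seed + 131 * n,
                           post = post)
    y_next <- safe_cost(cost_callable, u_next, D)
    D <- dataset_append(D, u_next, y_next, "bo")
  }
  bo_result(D, seed, "bo", htrace)
}

#' Uniform random-search baseline
#'
#' Same record format as [run_bayesopt()], with i.i.d. uniform samples in the
#' box.
#'
#' @inheritParams run_bayesopt
#' @return object of class `bo_result`
#' @export
run_random_search <- function(cost_callable, maxIter = 600, seed = 1, d = 6) {
  set.seed(seed)
  U <- matrix(runif(maxIter * d), ncol = d)
  D <- eval_dataset(matrix(numeric(0), 0, d), numeric(0), character(0))
  for (i in seq_len(maxIter)) {
    y <- safe_cost(cost_callable, U[i, ], D)
    D <- dataset_append(D, U[i, ], y, "random")
  }
  bo_result(D, seed, "random")
}
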