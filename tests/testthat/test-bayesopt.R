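test_that("squared-exponential kernel has the stated values and shape", {
  h <- kernel_hyperparams(alpha = 1, gamma = 1)
  u <- runif(6)
  expect_equal(se_kernel(u, u, h), 1)
  # ||u - u'||^2 = 1 at gamma = 1 gives exp(-1)
  u2 <- u + c(1, 0, 0, 0, 0, 0)
  expect_equal(se_kernel(u, u2, h), exp(-1))
  # monotone decay with distance
  ds <- seq(0, 2, by = 0.1)
  ks <- vapply(ds, function(d) se_kernel(c(0, 0, 0, 0, 0, 0),
                                         c(d, 0, 0, 0, 0, 0), h), numeric(1))
  expect_true(all(diff(ks) < 0))
  h2 <- kernel_hyperparams(alpha = 2.5, gamma = 3)
  expect_equal(se_kernel(u, u, h2), 2.5)
})

test_that("GP posterior matches the dense direct implementation", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    U <- matrix(runif(n * 6), ncol = 6)
    y <- apply(U, 1, function(u) sum(u^2) + sin(3 * u[1]))
    alpha <- runif(1, 0.5, 3); gamma <- runif(1, 0.5, 10)
    eps2 <- 1e-8
    h <- kernel_hyperparams(alpha = alpha, gamma = gamma, eps2 = eps2)
    post <- gp_posterior(eval_dataset(U, y), h, standardize = FALSE)
    u_star <- runif(6)
    oracle <- oracle_gp(U, y, u_star, alpha, gamma, eps2)
    expect_equal(post$mu(u_star), oracle$mu, tolerance = 1e-10)
    expect_equal(post$var(u_star), max(oracle$var, 0), tolerance = 1e-10)
  }
})

test_that("GP interpolates noiselessly and reverts to the prior", {
  h <- kernel_hyperparams(alpha = 1.7, gamma = 4, eps2 = 0)
  U <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), nrow = 1)
  D <- eval_dataset(U, 3.2)
  post <- gp_posterior(D, h, standardize = FALSE)
  expect_equal(post$mu(U[1, ]), 3.2, tolerance = 1e-9)
  expect_equal(post$var(U[1, ]), 0, tolerance = 1e-9)
  # far away (gamma ||d||^2 > 40): prior mean 0, prior variance alpha
  far <- rep(-3, 6)
  expect_equal(post$mu(far), 0, tolerance = 1e-12)
  expect_equal(post$var(far), 1.7, tolerance = 1e-12)
  # variance never negative on a sweep
  set.seed(6)
  n <- 40
  U2 <- matrix(runif(n * 6), ncol = 6)
  post2 <- gp_posterior(eval_dataset(U2, rnorm(n)), h)
  probes <- matrix(runif(600), ncol = 6)
  expect_true(all(post2$var(probes) >= 0))
})

test_that("hyperparameter fitting recovers a known generator", {
  set.seed(8)
  n <- 200
  U <- matrix(runif(n * 6), ncol = 6)
  alpha_true <- 2; gamma_true <- 5
  K <- se_kernel(U, U, kernel_hyperparams(alpha = alpha_true,
                                          gamma = gamma_true))
  y <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n))
  D <- eval_dataset(U, y)
  h <- fit_hyperparameters(D, restarts = 4, seed = 1)
  # recovery on the standardized scale: gamma is scale-free, alpha rescaled
  expect_lt(abs(log(h$gamma) - log(gamma_true)), 0.5)
  expect_lt(abs(log(h$alpha * stats::var(y)) - log(alpha_true)), 0.5)
  # achieved likelihood at the optimum beats the default start
  ys <- (y - mean(y)) / stats::sd(y)
  nll_fit <- reachopt:::gp_nll(log(c(h$alpha, h$gamma)), U, ys, 1e-6)
  nll_def <- reachopt:::gp_nll(log(c(1, 1)), U, ys, 1e-6)
  expect_lte(nll_fit, nll_def + 1e-8)
})

test_that("constant targets drive the signal variance to its floor", {
  set.seed(9)
  U <- matrix(runif(20 * 6), ncol = 6)
  y <- rep(2.5, 20)
  h <- fit_hyperparameters(eval_dataset(U, y), restarts = 3, seed = 2)
  expect_lte(h$alpha, 0.011)  # lower bound of the alpha box
})

test_that("the UCB acquisition is the stated linear combination", {
  set.seed(10)
  U <- matrix(runif(8 * 6), ncol = 6)
  y <- apply(U, 1, sum)
  h <- kernel_hyperparams(alpha = 1, gamma = 2, eps2 = 0)
  post <- gp_posterior(eval_dataset(U, y), h, standardize = FALSE)
  u <- runif(6)
  expect_equal(acquisition_ucb(u, post, beta = 0.7),
               0.7 * post$sd(u) - post$mu(u))
  expect_equal(acquisition_ucb(u, post, beta = 0), -post$mu(u))
  # at a noiseless training point the acquisition is -y_i
  expect_equal(acquisition_ucb(U[3, ], post, beta = 0.5), -y[3],
               tolerance = 1e-7)
  # far from all data: beta * sqrt(alpha)
  expect_equal(acquisition_ucb(rep(5, 6), post, beta = 0.5), 0.5,
               tolerance = 1e-10)
})

test_that("propose_next beats dense random probing and is deterministic", {
  set.seed(11)
  U <- matrix(runif(12 * 6), ncol = 6)
  y <- apply(U, 1, function(u) sum((u - 0.3)^2))
  D <- eval_dataset(U, y)
  h <- kernel_hyperparams(alpha = 1, gamma = 3)
  post <- gp_posterior(D, h)
  u_star <- propose_next(D, h, restarts = 30, seed = 3)
  expect_true(all(u_star >= 0 & u_star <= 1))
  probes <- matrix(runif(1e4 * 6), ncol = 6)
  a_probe <- max(acquisition_ucb(probes, post))
  expect_gte(acquisition_ucb(u_star, post), a_probe - 1e-9)
  expect_identical(u_star, propose_next(D, h, restarts = 30, seed = 3))
  # beta = 0 with one high-cost datum pushes the proposal away from it
  D1 <- eval_dataset(matrix(rep(0.5, 6), 1), 5)
  h1 <- kernel_hyperparams(alpha = 1, gamma = 2, beta = 0)
  u1 <- propose_next(D1, h1, restarts = 30, seed = 4)
  expect_gt(sqrt(sum((u1 - 0.5)^2)), 0.5)
})

test_that("Bayesian optimization minimizes the analytic sphere", {
  tc <- toy_costs()
  res <- run_bayesopt(tc$sphere$f, maxIter = 100, n_init = 10, seed = 12)
  expect_equal(length(res$dataset$y), 110)
  expect_lt(res$best_y, 1e-3)
  expect_true(all(diff(res$best_so_far) <= 0))
  expect_equal(res$best_y, min(res$dataset$y))
  # determinism of the whole record sequence
  res2 <- run_bayesopt(tc$sphere$f, maxIter = 15, n_init = 5, seed = 13)
  res3 <- run_bayesopt(tc$sphere$f, maxIter = 15, n_init = 5, seed = 13)
  expect_identical(res2$dataset$U, res3$dataset$U)
  expect_identical(res2$dataset$y, res3$dataset$y)
})

test_that("failed cost evaluations are absorbed as penalties", {
  flaky <- function(u) if (u[1] > 0.9) stop("boom") else sum(u^2)
  res <- suppressMessages(run_bayesopt(flaky, maxIter = 10, n_init = 10,
                                       seed = 21))
  expect_true(all(is.finite(res$dataset$y)))
  expect_equal(length(res$dataset$y), 20)
})

test_that("random search samples the box uniformly and reproducibly", {
  f <- function(u) sum(u)
  res <- run_random_search(f, maxIter = 400, seed = 14)
  expect_true(all(res$dataset$U >= 0 & res$dataset$U <= 1))
  expect_equal(colMeans(res$dataset$U), rep(0.5, 6), tolerance = 0.08)
  res2 <- run_random_search(f, maxIter = 400, seed = 14)
  expect_identical(res$dataset$U, res2$dataset$U)
})

test_that("BO dominates random search over paired seeds on analytic costs", {
  tc <- toy_costs()
  n_pairs <- 10
  wins <- 0
  for (s in seq_len(n_pairs)) {
    bo <- run_bayesopt(tc$mixture$f, maxIter = 40, n_init = 10,
                       seed = 100 + s, restarts = 10)
    rd <- run_random_search(tc$mixture$f, maxIter = 50, seed = 200 + s)
    if (bo$best_y < rd$best_y) wins <- wins + 1
  }
  # one-sided sign test at alpha = 0.05
  p <- stats::pbinom(n_pairs - wins, n_pairs, 0.5)
  expect_lt(p, 0.05)
})
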