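sym_sqrt <- function(A, inv = FALSE) {
  e <- eigen(A, symmetric = TRUE)
  p <- if (inv) -0.5 else 0.5
  e$vectors %*% (t(e$vectors) * e$values^p)
}

test_that("IRLS diagonal: formula, zero-row guard, surrogate identity", {
  T <- rbind(c(3, 0), c(0, 0), c(0, 4))
  z <- irls_diag_l21(T, eps = 1e-12)
  expect_equal(z[1], 1 / 6)
  expect_equal(z[3], 1 / 8)
  expect_true(is.finite(z[2]) && z[2] <= 1 / (2 * 1e-12))

  # 2 tr(T' Z T) = ||T||_{2,1} when no row is zero
  T <- rand_matrix(7, 3, 21)
  Z <- irls_diag_l21(T)
  expect_equal(2 * sum(Z * rowSums(T^2)), sum(sqrt(rowSums(T^2))),
               tolerance = 1e-12)
})

test_that("trace-norm weight: closed form and spectral identity", {
  expect_equal(trace_norm_weight(matrix(2, 1, 1))[1, 1], 0.25,
               tolerance = 1e-10)

  # 2 tr(W' U W) = ||W||_* for full-rank W as eps -> 0
  W <- rand_matrix(4, 6, 31)
  U <- trace_norm_weight(W, eps = 1e-14)
  expect_equal(2 * sum(W * (U %*% W)), sum(svd(W)$d), tolerance = 1e-6)

  U0 <- trace_norm_weight(matrix(0, 3, 2), eps = 1e-12)
  expect_true(all(is.finite(U0)))
  expect_equal(U0, t(U0))
})

test_that("closed-form simplex weights match their oracles", {
  expect_equal(update_theta(c(1, 1), 2), c(0.5, 0.5))
  expect_equal(update_theta(c(1, 3), 2), c(0.75, 0.25))
  expect_equal(update_theta(c(1, 2, 4), 2), c(4, 2, 1) / 7)
  expect_equal(update_eta(c(4, 1), 2), c(0.2, 0.8))

  # zero-loss sources take all the weight, shared uniformly
  expect_equal(update_theta(c(0, 2, 0), 2), c(0.5, 0, 0.5))
  expect_error(update_theta(c(-1, 1), 2), "non-negative")

  # brute-force grid minimizer of sum w^q g over the simplex
  set.seed(41)
  for (i in 1:5) {
    g <- runif(3, 0.2, 5)
    expect_equal(update_theta(g, 2), grid_simplex_min(g, 2, 1e-3),
                 tolerance = 2e-3)
  }
  g <- runif(2, 0.2, 5)
  expect_equal(update_eta(g, 3), grid_simplex_min(g, 3, 1e-4),
               tolerance = 1e-4)
})

test_that("reference-model update zeroes the alignment gradient", {
  W_list <- lapply(1:3, function(i) rand_matrix(4, 2, i))
  expect_equal(update_w0(W_list[1], 1, 2), W_list[[1]])
  expect_equal(update_w0(W_list, rep(1 / 3, 3), 2),
               Reduce(`+`, W_list) / 3)

  set.seed(51)
  eta <- runif(3); eta <- eta / sum(eta)
  W0 <- update_w0(W_list, eta, 2)
  grad <- Reduce(`+`, Map(function(W, e) -2 * e^2 * (W - W0), W_list, eta))
  expect_lt(max(abs(grad)), 1e-10)
})

test_that("window stopping rule", {
  expect_true(window_stop(rep(5, 6), window = 6, tol = 1e-5))
  expect_false(window_stop(c(3, 2, 1), window = 6, tol = 1e-5))
  expect_false(window_stop(c(100, 50, 10, 5, 2, 1), window = 6, tol = 1e-5))
  expect_true(window_stop(c(100, rep(1, 6) * (1 + 1e-7)), window = 6,
                          tol = 1e-5))
})

test_that("W update reduces to weighted least squares and descends", {
  cfg <- maci_config(beta = 0, lambda = 0, alpha = 0)
  tp <- tiny_problem(config = cfg)
  st <- tp$state; pr <- tp$prob
  st$eta <- 0
  pr$per_source[[1]]$C <- matrix(0, tp$N, tp$N)
  st$lambdaU <- matrix(0, tp$N, tp$N)
  W <- maci:::update_W_block(1, st, pr)
  K <- pr$per_source[[1]]$K
  Z <- irls_diag_l21(crossprod(K, st$W_list[[1]]) - st$F_list[[1]])
  KZ <- K %*% diag(Z)
  A <- KZ %*% t(K)
  diag(A) <- diag(A) + 1e-8 * sum(diag(A)) / nrow(A)  # same ridge rule
  direct <- solve(A, KZ %*% st$F_list[[1]])
  expect_equal(W, direct, tolerance = 1e-6)

  # fixed point: refitting from the solution returns the same solution
  st2 <- st; st2$W_list[[1]] <- W
  st2$F_list[[1]] <- st$F_list[[1]]
  W2 <- maci:::update_W_block(1, st2, pr)
  obj_drop <- function(state) maci_objective(state, pr)$total
  expect_lt(obj_drop(st2) - obj_drop(st), 1e-8 * abs(obj_drop(st)))

  # MM descent of the true objective after a W update, generic parameters
  tp <- tiny_problem(seed = 8, config = maci_config(beta = 2, lambda = 3))
  before <- maci_objective(tp$state, tp$prob)$total
  st <- tp$state
  st$W_list[[1]] <- maci:::update_W_block(1, st, tp$prob)
  after <- maci_objective(st, tp$prob)$total
  expect_lte(after, before * (1 + 1e-10))
})

test_that("F update preserves nonnegativity, descends, and settles at KKT", {
  tp <- tiny_problem(seed = 13)
  st <- tp$state; pr <- tp$prob
  part <- function(F) maci:::objective_F_part(
    F, st$W_list[[1]], pr$per_source[[1]], st$theta[1], pr$config)

  vals <- part(st$F_list[[1]])
  for (i in 1:5) {
    Fn <- maci:::update_F_block(1, st, pr)
    expect_true(all(Fn >= 0))
    vals <- c(vals, part(Fn))
    st$F_list[[1]] <- Fn
  }
  expect_true(all(diff(vals) <= 1e-8 * abs(vals[-length(vals)]) + 1e-10))

  # iterate the raw (unsafeguarded) multiplicative update to convergence,
  # then check the KKT residual F * (num - den) ~ 0 at its fixed point
  for (i in 1:2000)
    st$F_list[[1]] <- maci:::update_F_block(1, st, pr, safeguard = FALSE)
  F <- st$F_list[[1]]
  ps <- pr$per_source[[1]]; cfg <- pr$config
  Z <- irls_diag_l21(crossprod(ps$K, st$W_list[[1]]) - F)
  P <- st$theta[1]^cfg$q1 * (Z * crossprod(ps$K, st$W_list[[1]]))
  num <- pmax(P, 0) + ps$conf * ps$Y + cfg$alpha * (ps$Pi %*% F) +
    cfg$zeta * F
  den <- st$theta[1]^cfg$q1 * (Z * F) + pmax(-P, 0) + ps$conf * F +
    cfg$alpha * (ps$deg * F) + cfg$zeta * (F %*% crossprod(F)) + 1e-12
  expect_lt(max(abs(F * (num - den))) / max(den), 1e-4)
})

test_that("objective equals the sum of independently recomputed parts", {
  cfg <- maci_config(beta = 0.7, lambda = 1.3, alpha = 10)
  tp <- tiny_problem(seed = 17, config = cfg)
  st <- tp$state; ps <- tp$prob$per_source[[1]]
  st$theta <- 0.6; st$eta <- 0.4
  st$W0 <- rand_matrix(tp$N, tp$c, 99)
  out <- maci_objective(st, tp$prob)

  W <- st$W_list[[1]]; F <- st$F_list[[1]]
  T <- crossprod(ps$K, W) - F
  manual <- 0.6^2 * (sum(sqrt(rowSums(T^2))) + sum(diag(t(W) %*% ps$C %*% W))) +
    sum(diag(t(F - ps$Y) %*% diag(ps$conf) %*% (F - ps$Y))) +
    10 * sum(diag(t(F) %*% ps$L %*% F)) +
    0.7 * sum(sqrt(rowSums(W^2))) +
    0.4^2 * sum((W - st$W0)^2) +
    1.3 / 2 * sum(svd(W)$d)
  expect_equal(out$total, manual, tolerance = 1e-10)
  expect_equal(out$total, sum(unlist(out$parts)), tolerance = 1e-12)

  st$F_list[[1]][1, 1] <- NaN
  expect_error(maci_objective(st, tp$prob), "non-finite")
})

test_that("convergence lemmas hold numerically", {
  set.seed(61)
  # vector inequality behind the l2,1 majorization
  for (i in 1:50) {
    v1 <- rnorm(5); v2 <- rnorm(5)
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    expect_lte(n1 - n1^2 / (2 * n2), n2 - n2^2 / (2 * n2) + 1e-12)
  }
  # matrix inequality behind the trace-norm majorization
  for (i in 1:20) {
    A <- rand_matrix(4, 4); P <- crossprod(A) + diag(4) * 0.1
    B <- rand_matrix(4, 4); Q <- crossprod(B) + diag(4) * 0.1
    lhs <- sum(diag(P %*% sym_sqrt(Q, inv = TRUE))) / 2 -
      sum(diag(sym_sqrt(P)))
    rhs <- sum(diag(Q %*% sym_sqrt(Q, inv = TRUE))) / 2 -
      sum(diag(sym_sqrt(Q)))
    expect_gte(lhs, rhs - 1e-9)
  }
})

test_that("solver: separable toy, determinism, identical-source symmetry", {
  set.seed(71)
  X <- rbind(matrix(rnorm(20, -3, 0.5), 10, 2), matrix(rnorm(20, 3, 0.5), 10, 2))
  src <- domain_dataset(X, rep(1:2, each = 10), name = "toy")
  tgt <- domain_dataset(X, name = "toy_t")
  cfg <- maci_config(lambda = 0, max_iter = 30, k_neighbors = 3, seed = 5)
  fit <- maci_fit(src, tgt, cfg)
  expect_equal(unname(predict(fit, X)), rep(1:2, each = 10))

  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)]) + 1e-10))

  # bit-identical refit under the same seed
  fit2 <- maci_fit(src, tgt, cfg)
  expect_identical(fit2$objective_trace, fit$objective_trace)
  expect_identical(fit2$W_list, fit$W_list)

  # two identical sources stay exactly exchangeable
  dat <- synth_generate(synth_config(S = 1, c = 2, d = 4, n_per_class = 10,
                                     seed = 3))
  fit3 <- maci_solve(list(dat$sources[[1]], dat$sources[[1]]), dat$target,
                     pseudo_label(dat$sources, dat$target),
                     maci_config(max_iter = 10, seed = 2))
  expect_equal(fit3$theta[1], fit3$theta[2], tolerance = 1e-12)
  expect_equal(fit3$eta[1], fit3$eta[2], tolerance = 1e-12)
  expect_equal(fit3$W_list[[1]], fit3$W_list[[2]], tolerance = 1e-12)

  # simplex invariants after every sweep are implied by construction of the
  # closed-form updates; spot-check the final state
  expect_equal(sum(fit3$theta), 1, tolerance = 1e-12)
  expect_equal(sum(fit3$eta), 1, tolerance = 1e-12)
  expect_true(all(fit3$theta >= 0) && all(fit3$eta >= 0))
})

test_that("solver errors on unequal kernel-map dimensions across sources", {
  s1 <- domain_dataset(rand_matrix(8, 3, 1), rep(1:2, 4))
  s2 <- domain_dataset(rand_matrix(6, 3, 2), rep(1:2, 3))
  tgt <- domain_dataset(rand_matrix(5, 3, 3))
  expect_error(maci_solve(list(s1, s2), tgt, rep(1:2, length.out = 5),
                          maci_config(max_iter = 2)),
               "equal source sizes")
})
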