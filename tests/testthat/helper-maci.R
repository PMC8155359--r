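# Shared fixtures: everything is generated in code, nothing on disk.

rand_matrix <- function(n, m, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * m, sd = sd), n, m)
}

# A tiny labeled domain pair sharing d, for kernel/alignment/solver tests.
tiny_pair <- function(n_a = 6, n_t = 4, d = 3, c = 2, seed = 1) {
  set.seed(seed)
  src <- domain_dataset(rand_matrix(n_a, d),
                        labels = rep_len(seq_len(c), n_a), name = "src")
  tgt <- domain_dataset(rand_matrix(n_t, d), name = "tgt")
  pl <- rep_len(seq_len(c), n_t)
  list(source = src, target = tgt, pseudo = pl, c = c)
}

# Minimal `prob`/`state` pair for objective and block-update tests, built
# from first principles (no solver involvement).
tiny_problem <- function(n_a = 5, n_t = 4, d = 3, c = 2, seed = 2,
                         config = maci_config()) {
  tp <- tiny_pair(n_a, n_t, d, c, seed)
  ek <- build_empirical_kernel(tp$source, tp$target, kernel_spec("gaussian"))
  ops <- build_alignment(ek, tp$source$labels, tp$pseudo)
  packed <- c(tp$source$labels, tp$pseudo)
  gr <- knn_affinity(ek$packed_data, packed, k = 2,
                     gamma = gamma_heuristic(ek$packed_data, c))
  Y <- one_hot(packed, c, varsigma = 1)$indicator
  conf <- config$varsigma * ifelse(ek$source_mask, 1, config$rho)
  N <- n_a + n_t
  set.seed(seed + 100)
  W <- rand_matrix(N, c, sd = 0.1)
  state <- list(W_list = list(W), F_list = list(pmax(crossprod(ek$map, W), 0)),
                W0 = W, theta = 1, eta = 1,
                lambdaU = config$lambda * trace_norm_weight(W))
  prob <- list(per_source = list(list(K = ek$map, C = ops$C,
                                      L = gr$laplacian, Pi = gr$weights,
                                      deg = gr$degree, Y = Y, conf = conf)),
               config = config)
  list(state = state, prob = prob, ek = ek, N = N, c = c)
}

# Brute-force minimizer of sum_a w_a^q * g_a over the simplex (grid search
# over barycentric coordinates at the given step); oracle for the
# closed-form weight updates.
grid_simplex_min <- function(g, q, step = 1e-3) {
  S <- length(g)
  if (S == 2) {
    t1 <- seq(0, 1, by = step)
    vals <- t1^q * g[1] + (1 - t1)^q * g[2]
    i <- which.min(vals)
    return(c(t1[i], 1 - t1[i]))
  }
  stopifnot(S == 3)
  best <- NULL; bestv <- Inf
  for (t1 in seq(0, 1, by = step)) {
    t2 <- seq(0, 1 - t1, by = step)
    vals <- t1^q * g[1] + t2^q * g[2] + (1 - t1 - t2)^q * g[3]
    i <- which.min(vals)
    if (vals[i] < bestv) { bestv <- vals[i]; best <- c(t1, t2[i], 1 - t1 - t2[i]) }
  }
  best
}
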