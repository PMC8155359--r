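# Alternating IRLS solver for the multi-source co-adaptation objective
#
#   sum_a [ theta_a^q1 ( ||K_a' W_a - F_a||_{2,1} + tr(W_a' C_a W_a) )
#           + g(F_a) + beta ||W_a||_{2,1} ]
#   + sum_a eta_a^q2 ||W_a - W0||_F^2 + (lambda/2) ||W||_*
#
# with g(F) = tr((F - Y)' U* (F - Y)) + alpha tr(F' L F), U* the diagonal
# label-confidence matrix, F >= 0, and W = [W_1, ..., W_S] the horizontal
# concatenation entering the trace norm. Each block update minimizes a
# majorizing surrogate frozen at the current iterate, so the objective is
# monotonically non-increasing sweep over sweep.

l21_norm <- function(M) sum(sqrt(rowSums(M^2)))

#' IRLS diagonal for an l2,1 surrogate
#'
#' Entries `1 / (2 ||T_i,:||)`; an (effectively) zero row is guarded by
#' adding `eps` to its norm so the weight stays finite. At the
#' linearization point `2 tr(T' Z T) = ||T||_{2,1}` (exactly, when no row
#' needed the guard).
#'
#' @param T numeric matrix.
#' @param eps small positive guard.
#' @return numeric vector of diagonal entries (length `nrow(T)`).
#' @export
irls_diag_l21 <- function(T, eps = 1e-12) {
  if (eps <= 0) stop("eps must be positive")
  nrm <- sqrt(rowSums(T^2))
  1 / (2 * (nrm + ifelse(nrm < eps, eps, 0)))
}

#' Trace-norm majorization weight
#'
#' `U = (1/2) (W W' + eps I)^{-1/2}` via symmetric eigendecomposition; at
#' the linearization point `tr(W' U W) = (1/2) ||W||_*` (eps -> 0 limit).
#'
#' @param W numeric matrix (`R x m`).
#' @param eps ridge regularizing rank deficiency.
#' @return symmetric `R x R` matrix.
#' @export
trace_norm_weight <- function(W, eps = 1e-12) {
  if (eps <= 0) stop("eps must be positive")
  A <- tcrossprod(W)
  diag(A) <- diag(A) + eps
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  U <- e$vectors %*% (t(e$vectors) / sqrt(vals)) / 2
  (U + t(U)) / 2
}

#' Closed-form simplex weights for the source-loss terms
#'
#' Minimizes `sum_a theta_a^q1 g_a` over the probability simplex:
#' `theta_a = g_a^{1/(1-q1)} / sum g^{1/(1-q1)}`. Sources with (numerically)
#' zero loss share all weight uniformly among themselves, the limit of the
#' formula.
#'
#' @param g non-negative per-source losses.
#' @param q1 exponent > 1.
#' @return simplex vector of length `length(g)`.
#' @export
update_theta <- function(g, q1) {
  if (any(g < 0)) stop("losses must be non-negative")
  tol <- 1e-12 * max(g, 1e-300)
  zero <- g <= tol
  th <- numeric(length(g))
  if (any(zero)) {
    th[zero] <- 1 / sum(zero)
  } else {
    w <- g^(1 / (1 - q1))
    th <- w / sum(w)
  }
  th
}

#' Closed-form simplex weights for the model-alignment gaps
#'
#' Same functional form as [update_theta()] with exponent `q2`, applied to
#' `h_a = ||W_a - W0||_F^2`.
#'
#' @param h non-negative per-source alignment gaps.
#' @param q2 exponent > 1.
#' @return simplex vector.
#' @export
update_eta <- function(h, q2) update_theta(h, q2)

#' Reference model update
#'
#' `W0 = sum_a eta_tilde_a W_a` with `eta_tilde_a = eta_a^q2 / sum eta^q2`,
#' the stationary point of the alignment term in W0.
#'
#' @param W_list per-source model matrices (same shape).
#' @param eta simplex weights.
#' @param q2 exponent.
#' @return matrix of the common shape.
#' @export
update_w0 <- function(W_list, eta, q2) {
  w <- eta^q2
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  Reduce(`+`, Map(`*`, W_list, w))
}

#' Window-based stopping rule
#'
#' Stops once the trace holds at least `window` values and the relative
#' spread `(max - min) / max` over the trailing window is below `tol`.
#'
#' @param trace numeric objective history.
#' @param window window length.
#' @param tol relative tolerance.
#' @return logical flag.
#' @export
window_stop <- function(trace, window = 6L, tol = 1e-5) {
  n <- length(trace)
  if (n < window) return(FALSE)
  w <- trace[(n - window + 1L):n]
  hi <- max(w)
  if (hi <= 0) return(TRUE)
  (hi - min(w)) / hi < tol
}

# --- objective ------------------------------------------------------------

#' Evaluate the co-adaptation objective
#'
#' Exact value (true l2,1 and trace norms, never the IRLS surrogates) plus
#' its six named parts: per-source regression loss, MMD alignment,
#' label smoothness, row sparsity, model alignment, trace norm.
#'
#' @param state list with `W_list`, `F_list`, `W0`, `theta`, `eta`.
#' @param prob list with `config` (a [maci_config()]) and `per_source`, a
#'   list per source of `K` (R x N map), `C` (R x R alignment operator),
#'   `L` (N x N Laplacian), `Y` (N x c label indicator), `conf` (length-N
#'   confidence diagonal).
#' @return list with `total` and `parts`.
#' @export
maci_objective <- function(state, prob) {
  cfg <- prob$config
  S <- length(prob$per_source)
  parts <- list(regression = 0, mmd = 0, smoothness = 0, sparsity = 0,
                alignment = 0, trace_norm = 0)
  for (a in seq_len(S)) {
    ps <- prob$per_source[[a]]
    W <- state$W_list[[a]]; F <- state$F_list[[a]]
    T <- crossprod(ps$K, W) - F
    parts$regression <- parts$regression + state$theta[a]^cfg$q1 * l21_norm(T)
    parts$mmd <- parts$mmd + state$theta[a]^cfg$q1 * sum(W * (ps$C %*% W))
    R <- F - ps$Y
    parts$smoothness <- parts$smoothness +
      sum(ps$conf * rowSums(R^2)) + cfg$alpha * sum(F * (ps$L %*% F))
    parts$sparsity <- parts$sparsity + cfg$beta * l21_norm(W)
    parts$alignment <- parts$alignment +
      state$eta[a]^cfg$q2 * sum((W - state$W0)^2)
  }
  Wcat <- do.call(cbind, state$W_list)
  parts$trace_norm <- cfg$lambda / 2 * sum(svd(Wcat, nu = 0, nv = 0)$d)
  total <- sum(unlist(parts))
  for (nm in names(parts)) if (!is.finite(parts[[nm]]))
    stop("non-finite objective part: ", nm)
  list(total = total, parts = parts)
}

# F-dependent part of the objective for source a (used by the monotone
# safeguard on the multiplicative F update).
objective_F_part <- function(F, W, ps, theta_a, cfg) {
  T <- crossprod(ps$K, W) - F
  R <- F - ps$Y
  theta_a^cfg$q1 * l21_norm(T) +
    sum(ps$conf * rowSums(R^2)) + cfg$alpha * sum(F * (ps$L %*% F))
}

# --- block updates --------------------------------------------------------

# SPD solve for W_a with all surrogate weights frozen:
#   [theta^q1 (C + K Z K') + beta G + eta^q2 I + lambda U + ridge I] W
#     = theta^q1 K Z F + eta^q2 W0
update_W_block <- function(a, state, prob) {
  cfg <- prob$config
  ps <- prob$per_source[[a]]
  W <- state$W_list[[a]]; F <- state$F_list[[a]]
  thq <- state$theta[a]^cfg$q1
  etq <- state$eta[a]^cfg$q2
  Z <- irls_diag_l21(crossprod(ps$K, W) - F)
  G <- irls_diag_l21(W)
  KZ <- ps$K * rep(Z, each = nrow(ps$K))      # K diag(Z), K is R x N
  A <- thq * (ps$C + tcrossprod(KZ, ps$K)) + state$lambdaU
  diag(A) <- diag(A) + cfg$beta * G + etq
  ridge <- 1e-8 * sum(diag(A)) / nrow(A)
  diag(A) <- diag(A) + ridge
  B <- thq * (KZ %*% F) + etq * state$W0
  ch <- tryCatch(chol(A), error = function(e)
    stop("W-update system not SPD after ridge (source ", a, ")"))
  backsolve(ch, forwardsolve(t(ch), B))
}

# Multiplicative nonnegative update for F_a (W fixed), with the standard
# positive/negative split of the Z K' W term and a monotone safeguard.
update_F_block <- function(a, state, prob, delta = 1e-12, safeguard = TRUE) {
  cfg <- prob$config
  ps <- prob$per_source[[a]]
  W <- state$W_list[[a]]; F <- state$F_list[[a]]
  thq <- state$theta[a]^cfg$q1
  Z <- irls_diag_l21(crossprod(ps$K, W) - F)
  P <- thq * (Z * crossprod(ps$K, W))          # theta^q1 Z K' W, N x c
  num <- pmax(P, 0) + ps$conf * ps$Y + cfg$alpha * (ps$Pi %*% F) +
    cfg$zeta * F
  den <- thq * (Z * F) + pmax(-P, 0) + ps$conf * F +
    cfg$alpha * (ps$deg * F) + cfg$zeta * (F %*% crossprod(F)) + delta
  cand <- pmax(F * num / den, 0)
  if (!safeguard) return(cand)
  old <- objective_F_part(F, W, ps, state$theta[a], cfg)
  new <- objective_F_part(cand, W, ps, state$theta[a], cfg)
  if (new <= old * (1 + 1e-12) + 1e-12) cand else F
}

# --- full solver ----------------------------------------------------------

#' Fit the multi-source co-adaptation solver
#'
#' Runs the alternating scheme: precompute per source the empirical kernel
#' map, the combined alignment operator, the class-aware graph Laplacian
#' over the packed source + target data, and the confidence-weighted label
#' matrix (true source labels at confidence `varsigma`, target
#' pseudo-labels at `varsigma * rho`); then sweep
#' \{W0, U, per-source (theta, F, W), eta\} until the windowed objective
#' spread falls below `tol` or `max_iter` is reached. Every step minimizes
#' a majorizer touching the objective at the current iterate, so the
#' recorded objective trace is non-increasing.
#'
#' @param sources list of labeled `domain_dataset`s (equal sizes so the
#'   per-source kernel maps share their row dimension).
#' @param target unlabeled `domain_dataset`.
#' @param pseudo_labels integer pseudo-labels for the target samples.
#' @param config a [maci_config()].
#' @return object of class `maci_state`: `W_list`, `F_list`, `W0`, `theta`,
#'   `eta`, `objective_trace`, `parts`, `iter`, `converged`, `kernels`,
#'   `operators`, `n_classes`.
#' @export
maci_solve <- function(sources, target, pseudo_labels, config = maci_config()) {
  if (inherits(sources, "domain_dataset")) sources <- list(sources)
  S <- length(sources)
  cls <- max(unlist(lapply(sources, `[[`, "labels")), pseudo_labels)
  specs <- lapply(config$kernel, kernel_spec, sigma = config$sigma)
  cfg <- config

  per_source <- vector("list", S)
  for (a in seq_len(S)) {
    src <- sources[[a]]
    ek <- build_empirical_kernel(src, target, specs,
                                 standardize = cfg$standardize)
    ops <- build_alignment(ek, src$labels, pseudo_labels)
    packed_labels <- c(src$labels, pseudo_labels)
    gam <- if (identical(cfg$graph_gamma, "auto"))
      gamma_heuristic(ek$packed_data, cls) else cfg$graph_gamma
    gr <- knn_affinity(ek$packed_data, packed_labels, k = cfg$k_neighbors,
                       gamma = gam, label_aware = cfg$label_aware)
    Y <- one_hot(packed_labels, cls, varsigma = 1)$indicator
    conf <- cfg$varsigma * ifelse(ek$source_mask, 1, cfg$rho)
    per_source[[a]] <- list(K = ek$map, C = ops$C, L = gr$laplacian,
                            Pi = gr$weights, deg = gr$degree,
                            Y = Y, conf = conf, ek = ek, ops = ops)
  }
  Rdims <- vapply(per_source, function(p) nrow(p$K), 1L)
  if (length(unique(Rdims)) != 1L)
    stop("kernel-map dimensions differ across sources (",
         paste(Rdims, collapse = ", "),
         "); the trace-norm coupling requires equal source sizes")
  R <- Rdims[[1L]]

  set.seed(cfg$seed)
  # one shared random init for all blocks: identical sources then stay
  # exactly symmetric throughout the sweeps
  W_init <- matrix(stats::rnorm(R * cls, sd = 1e-2), R, cls)
  W_list <- replicate(S, W_init, simplify = FALSE)
  F_list <- lapply(seq_len(S), function(a)
    pmax(crossprod(per_source[[a]]$K, W_list[[a]]), 1e-8))
  theta <- rep(1 / S, S)
  eta <- rep(1 / S, S)
  W0 <- update_w0(W_list, eta, cfg$q2)

  prob <- list(per_source = per_source, config = cfg)
  state <- list(W_list = W_list, F_list = F_list, W0 = W0,
                theta = theta, eta = eta)
  trace <- maci_objective(state, prob)$total
  increases <- 0L
  iter <- 0L
  converged <- FALSE

  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    state$W0 <- update_w0(state$W_list, state$eta, cfg$q2)
    Wcat <- do.call(cbind, state$W_list)
    state$lambdaU <- cfg$lambda * trace_norm_weight(Wcat)

    g <- vapply(seq_len(S), function(a) {
      ps <- prob$per_source[[a]]
      W <- state$W_list[[a]]
      l21_norm(crossprod(ps$K, W) - state$F_list[[a]]) +
        sum(W * (ps$C %*% W))
    }, 0)
    state$theta <- update_theta(g, cfg$q1)

    # per-block monotone safeguard: the F check is local (F enters only its
    # own source's regression + smoothness terms); the W check is global
    # (trace norm couples the blocks, and the ridge shifts the surrogate
    # minimizer by O(1e-8)), so candidates that fail to descend are dropped
    for (a in seq_len(S)) {
      state$F_list[[a]] <- update_F_block(a, state, prob)
      cand <- update_W_block(a, state, prob)
      trial <- state
      trial$W_list[[a]] <- cand
      if (maci_objective(trial, prob)$total <=
            maci_objective(state, prob)$total * (1 + 1e-12) + 1e-12)
        state$W_list[[a]] <- cand
    }

    h <- vapply(state$W_list, function(W) sum((W - state$W0)^2), 0)
    state$eta <- update_eta(h, cfg$q2)

    obj <- maci_objective(state, prob)$total
    if (obj > trace[length(trace)] * (1 + 1e-8) + 1e-10) {
      increases <- increases + 1L
      if (increases >= 3L)
        stop("objective increased in 3 consecutive sweeps; trace: ",
             paste(signif(utils::tail(c(trace, obj), 5), 8), collapse = " "))
    } else increases <- 0L
    trace <- c(trace, obj)
    if (window_stop(trace, cfg$window, cfg$tol)) { converged <- TRUE; break }
  }

  final <- maci_objective(state, prob)
  structure(list(W_list = state$W_list, F_list = state$F_list,
                 W0 = state$W0, theta = state$theta, eta = state$eta,
                 objective_trace = trace, parts = final$parts,
                 iter = iter, converged = converged,
                 kernels = lapply(per_source, `[[`, "ek"),
                 operators = lapply(per_source, `[[`, "ops"),
                 n_classes = cls),
            class = "maci_state")
}
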