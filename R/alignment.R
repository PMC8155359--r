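#' Marginal MMD coefficient matrix
#'
#' The `N x N` block-constant matrix M with entries `1/n_src^2` on the
#' source-source block, `1/n_tgt^2` on the target-target block and
#' `-1/(n_src n_tgt)` on the cross blocks, so that
#' `tr(W' K M K' W)` is the squared kernel mean-embedding discrepancy of
#' the decision function between the two domains. M = v v' for
#' v = (1/n_src, ..., -1/n_tgt, ...), hence rank one, PSD, zero row sums.
#'
#' @param n_source,n_target positive domain sizes.
#' @return `(n_source + n_target)` square matrix.
#' @export
mmd_coeff_marginal <- function(n_source, n_target) {
  if (n_source < 1L || n_target < 1L)
    stop("both domain sizes must be at least 1")
  v <- c(rep(1 / n_source, n_source), rep(-1 / n_target, n_target))
  tcrossprod(v)
}

#' Class-conditional MMD coefficient matrices
#'
#' One marginal-structured coefficient matrix per class, restricted to the
#' samples of that class. Classes with zero members in either domain are
#' skipped (their 1/n^2 coefficients are undefined); if no class survives a
#' warning is raised and an empty list returned, dropping the conditional
#' term gracefully.
#'
#' @param class_sizes_source,class_sizes_target integer vectors of per-class
#'   counts (length c).
#' @return named list of matrices, one per surviving class, each of size
#'   `class_sizes_source[l] + class_sizes_target[l]`.
#' @export
mmd_coeff_conditional <- function(class_sizes_source, class_sizes_target) {
  if (length(class_sizes_source) != length(class_sizes_target))
    stop("class size vectors must have equal length")
  keep <- which(class_sizes_source > 0L & class_sizes_target > 0L)
  if (length(keep) == 0L) {
    warning("no class is present in both domains; conditional term omitted")
    return(list())
  }
  out <- lapply(keep, function(l)
    mmd_coeff_marginal(class_sizes_source[l], class_sizes_target[l]))
  names(out) <- as.character(keep)
  out
}

#' Combined marginal + conditional alignment operator
#'
#' Builds `C = K M K' + sum_l K[, idx_l] M_l K[, idx_l]'` where K is the
#' `R x N` empirical kernel map, M the marginal coefficient matrix and each
#' conditional block is embedded back into the full coordinate frame through
#' its class index set (source samples by true label, target samples by
#' pseudo-label). `tr(W' C W)` is then the sum of the squared marginal and
#' per-class conditional mean-embedding discrepancies of the decision
#' function. C is symmetrized against round-off; it is PSD as a sum of
#' `K v v' K'` terms.
#'
#' @param ek an [build_empirical_kernel()] result.
#' @param source_labels integer labels of the source samples.
#' @param target_pseudo_labels integer pseudo-labels of the target samples.
#' @return object of class `alignment_operators`: `M_marginal`, `M_class`
#'   (class-restricted coefficient matrices), `C` (`R x R`),
#'   `class_index_sets`.
#' @export
build_alignment <- function(ek, source_labels, target_pseudo_labels) {
  n_a <- ek$n_source; n_t <- ek$n_target
  if (length(source_labels) != n_a || length(target_pseudo_labels) != n_t)
    stop("label vectors must match the packed domain sizes")
  K <- ek$map                                   # R x N
  M0 <- mmd_coeff_marginal(n_a, n_t)
  C <- K %*% M0 %*% t(K)
  cls <- sort(unique(c(source_labels, target_pseudo_labels)))
  idx_sets <- list(); M_class <- list()
  for (l in cls) {
    is_ <- which(source_labels == l)
    it <- n_a + which(target_pseudo_labels == l)
    if (length(is_) == 0L || length(it) == 0L) next
    idx <- c(is_, it)
    Ml <- mmd_coeff_marginal(length(is_), length(it))
    Kl <- K[, idx, drop = FALSE]
    C <- C + Kl %*% Ml %*% t(Kl)
    idx_sets[[as.character(l)]] <- idx
    M_class[[as.character(l)]] <- Ml
  }
  if (length(M_class) == 0L)
    warning("no class shared between source labels and target pseudo-labels; ",
            "conditional alignment omitted")
  C <- (C + t(C)) / 2
  structure(list(M_marginal = M0, M_class = M_class, C = C,
                 class_index_sets = idx_sets),
            class = "alignment_operators")
}

#' Model discriminant discrepancy
#'
#' Squared Frobenius distance between two model matrices.
#'
#' @param W_P,W_Q matrices of identical shape.
#' @return non-negative scalar.
#' @export
mdd <- function(W_P, W_Q) {
  if (!all(dim(W_P) == dim(W_Q))) stop("W_P and W_Q must have the same shape")
  sum((W_P - W_Q)^2)
}

#' Model alignment function
#'
#' `sum_a eta_a ||W_a - W0||_F^2` for a simplex weight vector eta. With
#' `W0 = "convex"` the reference is the eta-convex combination of the
#' models, in which case (for two models) the value equals
#' `eta_1 * eta_2 * mdd(W_1, W_2)`; with uniform weights it upper-bounds
#' `eta * mdd` for any reference.
#'
#' @param W_list list of model matrices of identical shape.
#' @param eta non-negative weights summing to 1.
#' @param W0 reference matrix, or `"convex"`.
#' @return non-negative scalar.
#' @export
maf <- function(W_list, eta = rep(1 / length(W_list), length(W_list)),
                W0 = "convex") {
  if (abs(sum(eta) - 1) > 1e-8 || any(eta < -1e-12))
    stop("eta must be a probability vector over the sources")
  if (identical(W0, "convex")) {
    W0 <- Reduce(`+`, Map(`*`, W_list, eta))
  }
  sum(vapply(seq_along(W_list),
             function(a) eta[a] * sum((W_list[[a]] - W0)^2), 0))
}
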