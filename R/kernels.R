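#' Kernel specification
#'
#' Supported families and their formulas (sigma > 0, squared Euclidean
#' distance written dist2):
#' \itemize{
#'   \item `gaussian`: exp(-sigma * dist2)
#'   \item `laplacian`: exp(-sigma * sqrt(dist2))
#'   \item `inverse_square_distance`: 1 / (1 + sigma * dist2)
#'   \item `inverse_distance`: 1 / (1 + sigma * sqrt(dist2))
#'   \item `linear`: plain inner product (no bandwidth)
#' }
#' `sigma = "auto"` resolves to the reciprocal of the feature dimension,
#' `1/d`, for every non-linear family.
#'
#' @param family kernel family name.
#' @param sigma positive bandwidth or `"auto"`.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "linear", "laplacian",
                                   "inverse_square_distance",
                                   "inverse_distance"),
                        sigma = "auto") {
  family <- match.arg(family)
  if (!identical(sigma, "auto")) {
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
      stop("sigma must be a positive scalar or \"auto\"")
  }
  structure(list(family = family, sigma = sigma), class = "kernel_spec")
}

resolve_sigma <- function(spec, d) {
  if (identical(spec$sigma, "auto")) 1 / d else spec$sigma
}

# Squared Euclidean distances between columns of A (d x m) and B (d x n).
cross_dist2 <- function(A, B) {
  D2 <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

#' Kernel (Gram) matrix between two point sets
#'
#' @param spec a [kernel_spec()].
#' @param A,B numeric matrices with points as columns (`d x m`, `d x n`).
#' @return the `m x n` matrix of pairwise kernel evaluations.
#' @export
gram_matrix <- function(spec, A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must share the feature dimension d")
  if (spec$family == "linear") return(crossprod(A, B))
  s <- resolve_sigma(spec, nrow(A))
  D2 <- cross_dist2(A, B)
  switch(spec$family,
         gaussian = exp(-s * D2),
         laplacian = exp(-s * sqrt(D2)),
         inverse_square_distance = 1 / (1 + s * D2),
         inverse_distance = 1 / (1 + s * sqrt(D2)))
}

#' Empirical kernel over packed source + target data
#'
#' Packs one source and the target column-wise into `X = [X_src | X_tgt]`
#' (`d x N`, `N = n_src + n_tgt`) and evaluates the empirical kernel map of
#' every packed point against all packed points. For a single non-linear
#' kernel the map matrix is the symmetric `N x N` Gram matrix; several
#' specs are concatenated vertically (multi-kernel), and a `linear` spec
#' contributes the raw `d x N` features (the empirical map of a linear
#' kernel is the identity representation).
#'
#' @param source,target `domain_dataset`s sharing `d`.
#' @param specs a `kernel_spec` or list of them.
#' @param standardize z-score the packed features (statistics from the
#'   packed data) before any distance computation.
#' @return object of class `empirical_kernel` with fields `packed_data`
#'   (`d x N`), `map` (`R x N` map matrix, `R = sum` of block heights),
#'   `specs`, `source_mask`, `n_source`, `n_target`.
#' @export
build_empirical_kernel <- function(source, target, specs,
                                   standardize = FALSE) {
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("at least one kernel spec is required")
  if (n_features(source) != n_features(target))
    stop("source and target must share the feature dimension d")
  X <- t(rbind(source$features, target$features))   # d x N
  ctr <- rep(0, nrow(X)); scl <- rep(1, nrow(X))
  if (standardize) {
    ctr <- rowMeans(X)
    scl <- apply(X, 1L, stats::sd)
    scl[scl == 0] <- 1
    X <- (X - ctr) / scl
  }
  blocks <- lapply(specs, function(sp)
    if (sp$family == "linear") X else gram_matrix(sp, X, X))
  structure(list(packed_data = X, map = do.call(rbind, blocks),
                 specs = specs,
                 source_mask = rep(c(TRUE, FALSE),
                                   c(n_samples(source), n_samples(target))),
                 n_source = n_samples(source), n_target = n_samples(target),
                 center = ctr, scale = scl, standardize = standardize),
            class = "empirical_kernel")
}

#' Empirical kernel map of new points
#'
#' Represents each column of `x` by its kernel evaluations against all `N`
#' packed training points, stacked over the kernel specs; a `linear` block
#' passes the (possibly standardized) raw features through unchanged.
#'
#' @param ek an [build_empirical_kernel()] result.
#' @param x `d x m` matrix (or a length-`d` vector) of new points.
#' @return `R x m` matrix of mapped representations.
#' @export
empirical_map <- function(ek, x) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(ek$packed_data))
    stop("dimension mismatch: expected d = ", nrow(ek$packed_data),
         ", got ", nrow(x))
  if (ek$standardize) x <- (x - ek$center) / ek$scale
  blocks <- lapply(ek$specs, function(sp)
    if (sp$family == "linear") x else gram_matrix(sp, ek$packed_data, x))
  do.call(rbind, blocks)
}
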