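#' Heat-kernel width heuristic for the affinity graph
#'
#' theta-bar is the square root of the mean Euclidean norm of the samples;
#' the returned width is theta-bar / c, damping the heat kernel as the
#' number of classes grows. All-zero data falls back to 1 with a warning.
#'
#' @param X `d x N` matrix, samples as columns.
#' @param c number of classes.
#' @return positive scalar gamma.
#' @export
gamma_heuristic <- function(X, c) {
  X <- as.matrix(X)
  theta_bar <- sqrt(mean(sqrt(colSums(X^2))))
  if (theta_bar == 0) {
    warning("all-zero data; falling back to gamma = 1")
    return(1)
  }
  theta_bar / c
}

#' Class-aware k-nearest-neighbor affinity graph
#'
#' Vertices are the columns of `X`; an edge joins i and j when either is
#' among the other's k nearest Euclidean neighbors (ties broken by lower
#' sample index). With `label_aware = TRUE` an edge between
#' differently-labeled vertices gets weight 0, otherwise every edge gets the
#' heat-kernel weight exp(-gamma * ||x_i - x_j||^2). The diagonal is zero
#' and the weight matrix symmetric by construction.
#'
#' @param X `d x N` matrix, samples as columns.
#' @param labels integer class vector of length N (pseudo-labels allowed);
#'   ignored when `label_aware = FALSE`.
#' @param k neighborhood size, `1 <= k < N`.
#' @param gamma heat-kernel width (see [gamma_heuristic()]).
#' @param label_aware zero cross-class edges?
#' @return object of class `affinity_graph`: `weights`, `degree`,
#'   `laplacian`, `gamma`, `k`.
#' @export
knn_affinity <- function(X, labels = NULL, k, gamma, label_aware = TRUE) {
  X <- as.matrix(X)
  N <- ncol(X)
  if (k >= N) stop("k must be smaller than the number of samples N = ", N)
  if (k < 1L) stop("k must be at least 1")
  D2 <- cross_dist2(X, X)
  adj <- matrix(FALSE, N, N)
  for (j in seq_len(N)) {
    ord <- order(D2[, j], seq_len(N))        # index tie-break: determinism
    nn <- setdiff(ord, j)[seq_len(k)]
    adj[nn, j] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  W <- ifelse(adj, exp(-gamma * D2), 0)
  if (label_aware) {
    if (is.null(labels)) stop("label_aware graph requires labels")
    same <- outer(labels, labels, "==")
    W[!same] <- 0
  }
  deg <- rowSums(W)
  structure(list(weights = W, degree = deg,
                 laplacian = diag(deg, N) - W, gamma = gamma, k = k),
            class = "affinity_graph")
}

#' Graph Laplacian L = Lambda - W
#'
#' @param graph an [knn_affinity()] result.
#' @return symmetric positive semi-definite `N x N` matrix with zero row sums.
#' @export
graph_laplacian <- function(graph) graph$laplacian
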