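# User-facing estimator: pseudo-labeling, end-to-end fit, ensemble
# prediction, row (feature/prototype) ranking, empirical chance level.

# Regularized least-squares scorer on raw features: the built-in base
# classifier for pseudo-labeling (no external dependency; any callable can
# be plugged in instead).
ridge_scorer <- function(X_train, labels, X_test, lambda = 1e-2) {
  c <- max(labels)
  Y <- one_hot(labels, c, varsigma = 1)$indicator
  Xc <- cbind(1, X_train)
  A <- crossprod(Xc) / nrow(Xc)
  diag(A) <- diag(A) + lambda
  W <- solve(A, crossprod(Xc, Y) / nrow(Xc))
  cbind(1, X_test) %*% W
}

one_nn_labels <- function(X_train, labels, X_test) {
  D2 <- cross_dist2(t(X_train), t(X_test))
  labels[apply(D2, 2L, which.min)]
}

#' Pseudo-label the target domain
#'
#' Trains a base classifier on the pooled labeled source data and predicts
#' a class for every target sample; these pseudo-labels drive the
#' class-conditional alignment and the graph construction. The default base
#' classifier is a built-in regularized least-squares scorer; `"1nn"` uses
#' the nearest pooled source sample; or supply
#' `function(X_train, labels, X_test) -> integer labels`.
#'
#' @param sources list of labeled `domain_dataset`s.
#' @param target `domain_dataset`.
#' @param base `"ridge"`, `"1nn"`, or a function (see above).
#' @return integer pseudo-label vector (length `n_target`).
#' @export
pseudo_label <- function(sources, target, base = "ridge") {
  if (inherits(sources, "domain_dataset")) sources <- list(sources)
  X <- do.call(rbind, lapply(sources, `[[`, "features"))
  y <- unlist(lapply(sources, `[[`, "labels"))
  Xt <- target$features
  if (nrow(Xt) == 0L) return(integer(0))
  lab <- if (is.function(base)) {
    as.integer(base(X, y, Xt))
  } else if (identical(base, "1nn")) {
    one_nn_labels(X, y, Xt)
  } else {
    scores <- ridge_scorer(X, y, Xt)
    max.col(scores, ties.method = "first")
  }
  missing <- setdiff(seq_len(max(y)), unique(lab))
  if (length(missing))
    warning("class(es) never pseudo-predicted on target: ",
            paste(missing, collapse = ", "),
            " (their conditional alignment term is skipped)")
  lab
}

#' Fit a multi-source co-adaptation model
#'
#' End-to-end: validates the problem, pseudo-labels the target with the
#' base classifier, runs the alternating solver, and packages everything
#' needed for prediction (per-source packed training data and kernel specs,
#' the fitted models `W_a`, source weights theta, reference model `W0`,
#' class codebook, configuration snapshot, objective trace).
#'
#' @param sources list of labeled `domain_dataset`s.
#' @param target unlabeled `domain_dataset`.
#' @param config a [maci_config()].
#' @param base base classifier for [pseudo_label()].
#' @return object of class `maci_model`.
#' @export
maci_fit <- function(sources, target, config = maci_config(),
                     base = "ridge") {
  if (inherits(sources, "domain_dataset")) sources <- list(sources)
  info <- validate_problem(sources, target)
  pl <- pseudo_label(sources, target, base = base)
  state <- maci_solve(sources, target, pl, config)
  codebook <- NULL
  for (s in sources) if (!is.null(s$codebook)) { codebook <- s$codebook; break }
  structure(list(kernels = state$kernels, W_list = state$W_list,
                 theta = state$theta, eta = state$eta, W0 = state$W0,
                 codebook = codebook, config = config,
                 objective_trace = state$objective_trace,
                 parts = state$parts, converged = state$converged,
                 iter = state$iter, n_classes = state$n_classes,
                 pseudo_labels = pl, problem = info),
            class = "maci_model")
}

#' @export
print.maci_model <- function(x, ...) {
  cat(sprintf(paste0("<maci_model> S = %d sources, c = %d classes, d = %d ",
                     "features\n  theta = %s\n  %d sweeps, objective %.6g ",
                     "-> %.6g (%s)\n"),
              x$problem$S, x$n_classes, x$problem$d,
              paste(signif(x$theta, 4), collapse = " "),
              x$iter, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)],
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Predict target classes by weighted source voting
#'
#' Each test sample is mapped through every source's empirical kernel map
#' and scored by `sum_a theta_a k_a' W_a`, the closed-form minimizer of the
#' theta-weighted residue to the per-source projections; the class is the
#' argmax (ties to the lowest class index). `mode = "w0"` scores with the
#' shared reference model alone.
#'
#' @param object a fitted `maci_model`.
#' @param newdata `m x d` matrix of test samples (rows).
#' @param mode `"ensemble"` (default) or `"w0"`.
#' @param type `"class"` for labels (codebook-decoded when available) or
#'   `"scores"` for the `m x c` score matrix.
#' @param ... unused.
#' @return label vector or score matrix.
#' @export
predict.maci_model <- function(object, newdata, mode = c("ensemble", "w0"),
                               type = c("class", "scores"), ...) {
  mode <- match.arg(mode); type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$problem$d)
    stop("newdata has d = ", ncol(newdata), ", model expects ",
         object$problem$d)
  Xt <- t(newdata)
  scores <- matrix(0, nrow(newdata), object$n_classes)
  if (mode == "w0") {
    k <- empirical_map(object$kernels[[1L]], Xt)
    scores <- crossprod(k, object$W0)
  } else {
    for (a in seq_along(object$W_list)) {
      k <- empirical_map(object$kernels[[a]], Xt)
      scores <- scores + object$theta[a] * crossprod(k, object$W_list[[a]])
    }
  }
  if (type == "scores") return(scores)
  idx <- max.col(scores, ties.method = "first")
  if (!is.null(object$codebook)) object$codebook[idx] else idx
}

#' Rank model rows by l2 norm
#'
#' Rows of a fitted `W_a` sorted by decreasing l2 norm (stable: ties keep
#' the lower index first). With a linear kernel the rows are the original
#' features, so this is the joint feature-selection output; with an
#' empirical kernel map the rows are training prototypes.
#'
#' @param W a model matrix (`R x c`).
#' @return data.frame with columns `row` and `norm`, sorted.
#' @export
rank_rows <- function(W) {
  nrm <- sqrt(rowSums(as.matrix(W)^2))
  ord <- order(-nrm, seq_along(nrm))
  data.frame(row = ord, norm = nrm[ord])
}

#' Empirical chance level by label permutation
#'
#' Re-runs an evaluation pipeline with independently permuted labels and
#' summarizes the resulting accuracy distribution: its mean and the upper
#' bound of the normal-approximation confidence interval of that mean
#' (`mean + z * sd / sqrt(R)`).
#'
#' @param labels the class-label vector whose permutations feed the pipeline.
#' @param pipeline `function(permuted_labels) -> accuracy in [0, 1]`.
#' @param repetitions number of permutations, at least 20.
#' @param confidence confidence level of the interval.
#' @param seed RNG seed.
#' @return list with `mean`, `sd`, `upper`, `accuracies`.
#' @export
empirical_chance_level <- function(labels, pipeline, repetitions = 100L,
                                   confidence = 0.95, seed = 1L) {
  if (repetitions < 20L) stop("at least 20 repetitions are required")
  if (length(unique(labels)) < 2L)
    stop("chance level is undefined for single-class labels")
  set.seed(seed)
  acc <- vapply(seq_len(repetitions),
                function(i) pipeline(sample(labels)), 0)
  m <- mean(acc); s <- stats::sd(acc)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(mean = m, sd = s, upper = m + z * s / sqrt(repetitions),
       accuracies = acc)
}

#' Save / load a fitted model archive
#'
#' The archive contains every matrix needed for prediction plus the
#' codebook and configuration; `load_maci(save_maci(m))` predicts
#' bit-identically to `m`.
#'
#' @param model a `maci_model`.
#' @param path archive path.
#' @return `save_maci` the path, invisibly; `load_maci` the model.
#' @export
save_maci <- function(model, path) {
  stopifnot(inherits(model, "maci_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_maci
#' @export
load_maci <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "maci_model")) stop("not a maci model archive: ", path)
  model
}
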