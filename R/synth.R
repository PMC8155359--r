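# Synthetic multi-source benchmark: Gaussian class clusters with per-domain
# rigid motions (rotation + translation), optional class-conditional target
# shift, optional outlier contamination of the sources, and optionally one
# deliberately unrelated source. This is the simplest generative family
# exhibiting both the covariate and the conditional shift the marginal +
# conditional alignment terms target; it does not emulate EEG spectral
# structure.

#' Synthetic benchmark configuration
#'
#' Defaults are the moderate-shift regime used throughout the test suite:
#' unit-variance clusters whose class means sit `class_separation = 3`
#' apart (per-domain Bayes accuracy well above chance but below 1), random
#' per-domain translations of magnitude `source_shift = 1` and rotations up
#' to `rotation_max = 0.3` radians.
#'
#' @param S number of source domains.
#' @param c number of classes (>= 2).
#' @param d feature dimension.
#' @param n_per_class samples per class in every domain.
#' @param class_separation distance scale between class means.
#' @param source_shift magnitude of each domain's random mean translation.
#' @param rotation_max per-domain rotation angle bound (radians).
#' @param conditional_shift extra class-dependent translation applied to
#'   the target only (conditional shift).
#' @param outlier_fraction fraction of source rows replaced by uniform
#'   background points that keep their labels (sources only).
#' @param irrelevant_source add one extra source drawn with a translation
#'   ten times `source_shift` (a planted unrelated domain).
#' @param informative_dims restrict class-mean placement (and rotations) to
#'   the first `informative_dims` coordinates; remaining features are pure
#'   noise. `NULL` = use all `d`.
#' @param seed RNG seed; all randomness flows from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(S = 3L, c = 3L, d = 10L, n_per_class = 30L,
                         class_separation = 3, source_shift = 1,
                         rotation_max = 0.3, conditional_shift = 0,
                         outlier_fraction = 0, irrelevant_source = FALSE,
                         informative_dims = NULL, seed = 1L) {
  if (S < 1L || c < 2L || d < 1L || n_per_class < 1L)
    stop("invalid sizes in synth_config")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)")
  structure(list(S = as.integer(S), c = as.integer(c), d = as.integer(d),
                 n_per_class = as.integer(n_per_class),
                 class_separation = class_separation,
                 source_shift = source_shift, rotation_max = rotation_max,
                 conditional_shift = conditional_shift,
                 outlier_fraction = outlier_fraction,
                 irrelevant_source = isTRUE(irrelevant_source),
                 informative_dims = informative_dims,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Class means: scaled standard-basis placement when c <= m, otherwise a
# random orthonormal frame (warn). For m == 2 a regular polygon keeps all
# pairwise separations comparable.
class_means <- function(cfg) {
  m <- if (is.null(cfg$informative_dims)) cfg$d else cfg$informative_dims
  sep <- cfg$class_separation
  M <- matrix(0, cfg$c, cfg$d)
  if (m == 2L) {
    ang <- 2 * pi * (seq_len(cfg$c) - 1) / cfg$c
    M[, 1:2] <- sep * cbind(cos(ang), sin(ang))
  } else if (cfg$c <= m) {
    for (l in seq_len(cfg$c)) M[l, l] <- sep
  } else {
    warning("more classes than informative dimensions; ",
            "placing means on a random frame")
    Q <- qr.Q(qr(matrix(stats::rnorm(m * cfg$c), m, cfg$c)))
    dirs <- matrix(stats::rnorm(cfg$c * ncol(Q)), cfg$c, ncol(Q))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    M[, seq_len(m)] <- sep * dirs %*% t(Q)
  }
  M
}

# Rotation by Givens rotations on disjoint coordinate pairs inside the
# informative block; angles uniform in [-rotation_max, rotation_max].
random_rotation <- function(cfg) {
  m <- if (is.null(cfg$informative_dims)) cfg$d else cfg$informative_dims
  Q <- diag(cfg$d)
  if (cfg$rotation_max <= 0 || m < 2L) return(Q)
  pairs <- matrix(seq_len(m - m %% 2L), ncol = 2L, byrow = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    th <- stats::runif(1, -cfg$rotation_max, cfg$rotation_max)
    G <- diag(cfg$d)
    G[i, i] <- cos(th); G[j, j] <- cos(th)
    G[i, j] <- -sin(th); G[j, i] <- sin(th)
    Q <- Q %*% G
  }
  Q
}

unit_direction <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# One domain: balanced Gaussian clusters, then the domain's rigid motion.
draw_domain <- function(cfg, means, shift_magnitude, name,
                        conditional_shift = 0, outlier_fraction = 0) {
  n <- cfg$n_per_class * cfg$c
  labels <- rep(seq_len(cfg$c), each = cfg$n_per_class)
  X <- means[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * cfg$d), n, cfg$d)
  Q <- random_rotation(cfg)
  tr <- shift_magnitude * unit_direction(cfg$d)
  X <- X %*% t(Q) + matrix(tr, n, cfg$d, byrow = TRUE)
  if (conditional_shift > 0) {
    for (l in seq_len(cfg$c)) {
      delta <- conditional_shift * unit_direction(cfg$d)
      rows <- labels == l
      X[rows, ] <- X[rows, ] + matrix(delta, sum(rows), cfg$d, byrow = TRUE)
    }
  }
  outlier_rows <- integer(0)
  if (outlier_fraction > 0) {
    n_out <- floor(outlier_fraction * n)
    if (n_out > 0L) {
      outlier_rows <- sample(n, n_out)
      lim <- cfg$class_separation + 3
      X[outlier_rows, ] <- matrix(stats::runif(n_out * cfg$d, -lim, lim),
                                  n_out, cfg$d)
    }
  }
  ds <- domain_dataset(X, labels, label_kind = "true", name = name)
  attr(ds, "outlier_rows") <- outlier_rows
  ds
}

#' Generate a synthetic multi-source adaptation problem
#'
#' @param config a [synth_config()].
#' @return list with `sources` (labeled `domain_dataset`s), `target`
#'   (unlabeled), and `target_truth` (the held-back target labels).
#' @export
synth_generate <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  means <- class_means(cfg)
  S_total <- cfg$S + if (cfg$irrelevant_source) 1L else 0L
  sources <- vector("list", S_total)
  for (a in seq_len(cfg$S))
    sources[[a]] <- draw_domain(cfg, means, cfg$source_shift,
                                paste0("source", a),
                                outlier_fraction = cfg$outlier_fraction)
  if (cfg$irrelevant_source)
    sources[[S_total]] <- draw_domain(cfg, means, 10 * cfg$source_shift,
                                      "irrelevant_source",
                                      outlier_fraction = cfg$outlier_fraction)
  tgt <- draw_domain(cfg, means, cfg$source_shift, "target",
                     conditional_shift = cfg$conditional_shift)
  truth <- tgt$labels
  target <- domain_dataset(tgt$features, name = "target")
  list(sources = sources, target = target, target_truth = truth)
}

accuracy <- function(pred, truth) mean(pred == truth)

# Baselines: pooled no-adaptation ridge classifier, and a uniform vote of
# per-source ridge classifiers.
baseline_pooled <- function(sources, target) {
  X <- do.call(rbind, lapply(sources, `[[`, "features"))
  y <- unlist(lapply(sources, `[[`, "labels"))
  max.col(ridge_scorer(X, y, target$features), ties.method = "first")
}

baseline_vote <- function(sources, target) {
  cls <- max(unlist(lapply(sources, `[[`, "labels")))
  scores <- matrix(0, n_samples(target), cls)
  for (s in sources) {
    sc <- ridge_scorer(s$features, s$labels, target$features)
    scores[, seq_len(ncol(sc))] <- scores[, seq_len(ncol(sc))] + sc
  }
  max.col(scores, ties.method = "first")
}

#' Run the synthetic benchmark
#'
#' For each seed, regenerates the problem, fits the co-adaptation model and
#' the two no-adaptation baselines (a pooled-source ridge classifier and a
#' uniform vote of per-source ridge classifiers), and records the target
#' accuracies against the held-back truth.
#'
#' @param config a [synth_config()] (its seed field is overridden per run).
#' @param params a [maci_config()].
#' @param seeds integer vector (>= 2 seeds).
#' @return list with `results` (data.frame seed x method accuracy), `theta`
#'   (matrix of fitted source weights, seeds x sources), and `summary`
#'   (mean and sd per method).
#' @export
benchmark_run <- function(config, params = maci_config(), seeds = 1:10) {
  if (length(seeds) < 2L) stop("at least 2 seeds are required")
  rows <- list(); thetas <- NULL
  for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    dat <- synth_generate(cfg)
    par <- params; par$seed <- as.integer(s)
    fit <- maci_fit(dat$sources, dat$target, par)
    preds <- list(
      maci = predict(fit, dat$target$features),
      pooled = baseline_pooled(dat$sources, dat$target),
      vote = baseline_vote(dat$sources, dat$target))
    for (m in names(preds))
      rows[[length(rows) + 1L]] <-
        data.frame(seed = s, method = m,
                   accuracy = accuracy(preds[[m]], dat$target_truth))
    thetas <- rbind(thetas, fit$theta)
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ method, results,
                              function(x) c(mean = mean(x), sd = stats::sd(x)))
  rownames(thetas) <- seeds
  list(results = results, theta = thetas, summary = summary)
}
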