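#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes `P(score_pos > score_neg) + 0.5 * P(tie)` directly from ranks,
#' which equals the area under the empirical ROC curve. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4), c(1, 0, 1))  # 0.5
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- as_binary_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have two levels", call. = FALSE)
    return(labels == levels(labels)[2L])
  }
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("labels must have exactly two distinct values",
                            call. = FALSE)
  labels == u[2L]
}

# Macro-averaged one-vs-rest AUC from a score matrix (columns = classes).
macro_auc <- function(score_matrix, labels) {
  cls <- colnames(score_matrix)
  mean(vapply(cls, function(cl) {
    roc_auc(score_matrix[, cl], labels == cl)
  }, numeric(1L)))
}

# ---- classifier registry ---------------------------------------------------
# Each entry: function(x_train, y_train, x_test, seed) -> score matrix
# (rows = test samples, columns = class levels, entries ~ P(class)).

classifier_registry <- function() {
  list(
    logistic = function(x_train, y_train, x_test, seed) {
      # ridge-regularized so p > n is well-posed; fixed small lambda
      fam <- if (nlevels(y_train) == 2L) "binomial" else "multinomial"
      fit <- glmnet::glmnet(x_train, y_train, family = fam, alpha = 0,
                            lambda = 0.01, standardize = TRUE)
      p <- stats::predict(fit, newx = x_test, type = "response")
      if (fam == "binomial") {
        p1 <- as.numeric(p)
        out <- cbind(1 - p1, p1)
        colnames(out) <- levels(y_train)
        out
      } else {
        out <- p[, , 1L]
        out[, levels(y_train), drop = FALSE]
      }
    },
    knn = function(x_train, y_train, x_test, seed) {
      set.seed(seed)  # knn breaks ties at random
      pred <- class::knn(x_train, x_test, y_train, k = 5L, prob = TRUE)
      win <- attr(pred, "prob")
      lev <- levels(y_train)
      out <- matrix((1 - win) / (length(lev) - 1L),
                    nrow = length(pred), ncol = length(lev),
                    dimnames = list(NULL, lev))
      out[cbind(seq_along(pred), as.integer(pred))] <- win
      out
    },
    rf = function(x_train, y_train, x_test, seed) {
      df <- data.frame(x_train, check.names = FALSE)
      df$.y <- y_train
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            probability = TRUE, num.trees = 200L,
                            seed = seed, num.threads = 1L)
      p <- stats::predict(fit, data.frame(x_test, check.names = FALSE),
                          num.threads = 1L)$predictions
      p[, levels(y_train), drop = FALSE]
    }
  )
}

# Stratified fold assignment: within each class, folds 1..k recycled and
# shuffled.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Resampled, cross-validated classification benchmark
#'
#' The evaluation protocol for one feature matrix: for each of
#' `n_resamples` random resamplings, draw a balanced stratified sample
#' without replacement (`per_class` rows per class), run repeated
#' stratified k-fold cross-validation, pool the out-of-fold class scores
#' within each repeat, compute the AUC per repeat (macro-averaged
#' one-vs-rest for more than two classes) and average over repeats. The
#' per-resample metrics, their mean and a normal-approximation 95%
#' confidence interval form the report.
#'
#' @param fm A feature matrix with a `class` column (from
#'   [build_feature_matrix()] or [read_matrix_csv()]).
#' @param n_resamples Number of random resamplings (the study protocol
#'   uses 50).
#' @param per_class Sequences sampled per class per resampling (study
#'   protocol: 500). Lowered with a warning when a class has fewer rows.
#' @param classifier One of `"knn"` (default; 5-nearest-neighbour),
#'   `"logistic"` (ridge logistic regression) or `"rf"` (probability
#'   random forest).
#' @param folds,repeats Cross-validation design (default 10-fold, 3
#'   repeats).
#' @param seed Master integer seed; every sampling, fold split and
#'   classifier tie-break derives from it.
#' @param feature_name Display name for the report (e.g. `"(2,1)-mer"`).
#' @return An object of class `"eval_report"`: list with `feature_name`,
#'   `classifier`, `per_resample_metric`, `per_resample_accuracy`, `mean`,
#'   `ci95`, `n_resamples`.
#' @export
resample_classify <- function(fm, n_resamples = 50L, per_class = 500L,
                              classifier = c("knn", "logistic", "rf"),
                              folds = 10L, repeats = 3L, seed = 1L,
                              feature_name = "features") {
  classifier <- match.arg(classifier)
  if (!"class" %in% names(fm)) stop("feature matrix has no 'class' column",
                                    call. = FALSE)
  y_all <- factor(fm$class)
  if (nlevels(y_all) < 2L) stop("need at least two classes", call. = FALSE)
  x_all <- as.matrix(fm[, feature_columns(fm), drop = FALSE])
  storage.mode(x_all) <- "double"
  n_by_class <- table(y_all)
  if (min(n_by_class) < per_class) {
    per_class <- min(n_by_class)
    warning(sprintf("per_class lowered to %d (smallest class size)", per_class),
            call. = FALSE)
  }
  clf <- classifier_registry()[[classifier]]
  binary <- nlevels(y_all) == 2L

  metric <- numeric(n_resamples)
  accuracy <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    set.seed(derive_seed(seed, r))
    take <- unlist(lapply(levels(y_all), function(cl) {
      sample(which(y_all == cl), per_class)
    }), use.names = FALSE)
    x <- x_all[take, , drop = FALSE]
    y <- droplevels(y_all[take])
    rep_metric <- numeric(repeats)
    rep_acc <- numeric(repeats)
    for (rp in seq_len(repeats)) {
      fold <- stratified_folds(y, folds)
      scores <- matrix(NA_real_, nrow = length(y), ncol = nlevels(y),
                       dimnames = list(NULL, levels(y)))
      for (f in seq_len(folds)) {
        te <- fold == f
        scores[te, ] <- clf(x[!te, , drop = FALSE], y[!te],
                            x[te, , drop = FALSE],
                            seed = derive_seed(seed, r * 1000L + rp * 100L + f))
      }
      rep_metric[rp] <- if (binary) {
        roc_auc(scores[, levels(y)[2L]], y)
      } else {
        macro_auc(scores, y)
      }
      pred <- levels(y)[max.col(scores, ties.method = "first")]
      rep_acc[rp] <- mean(pred == as.character(y))
    }
    metric[r] <- mean(rep_metric)
    accuracy[r] <- mean(rep_acc)
  }

  m <- mean(metric)
  se <- stats::sd(metric) / sqrt(n_resamples)
  structure(list(feature_name = feature_name, classifier = classifier,
                 per_resample_metric = metric,
                 per_resample_accuracy = accuracy,
                 mean = m, ci95 = c(m - 1.96 * se, m + 1.96 * se),
                 n_resamples = as.integer(n_resamples)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s [%s]: mean AUC %.4f (95%% CI %.4f-%.4f, %d resamplings)\n",
              x$feature_name, x$classifier, x$mean,
              x$ci95[1L], x$ci95[2L], x$n_resamples))
  invisible(x)
}

#' Ternary win/tie/loss test between two evaluation reports
#'
#' Welch's two-sided t test on the per-resample metrics; when the null of
#' equal means is rejected at `alpha` the verdict follows the sign of the
#' mean difference, otherwise the comparison is a tie.
#'
#' @param report_a,report_b [resample_classify()] reports (or bare numeric
#'   metric vectors) with equal numbers of resamples.
#' @param alpha Significance level (default 0.05).
#' @return A list with `verdict` (`"A_wins"`, `"tie"` or `"B_wins"`),
#'   `p_value`, `mean_diff` and `alpha`.
#' @export
mean_difference_test <- function(report_a, report_b, alpha = 0.05) {
  a <- if (inherits(report_a, "eval_report")) report_a$per_resample_metric
       else as.numeric(report_a)
  b <- if (inherits(report_b, "eval_report")) report_b$per_resample_metric
       else as.numeric(report_b)
  if (length(a) != length(b)) stop("reports have different n_resamples",
                                   call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 resamples per report", call. = FALSE)
  d <- mean(a) - mean(b)
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
    # degenerate: constant metrics on both sides
    p <- if (abs(d) < 1e-12) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  verdict <- if (p >= alpha || abs(d) < 1e-12) "tie"
             else if (d > 0) "A_wins" else "B_wins"
  list(verdict = verdict, p_value = p, mean_diff = d, alpha = alpha)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement,
#' `(Index - Expected) / (Max - Expected)` over the contingency table of
#' the two labelings: 1 for identical partitions (up to label
#' permutation), about 0 for independent ones. The degenerate case where
#' the correction denominator vanishes (e.g. both partitions trivial)
#' returns 1, as the partitions then agree exactly.
#'
#' @param a,b Cluster labelings of equal length (any atomic type).
#' @return The ARI, a real number <= 1.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1: same partition
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  npairs <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / npairs
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps * npairs) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# ---- clustering registry ---------------------------------------------------

cluster_registry <- function() {
  list(
    kmeans = function(x, k, seed) {
      set.seed(seed)
      stats::kmeans(x, centers = k, nstart = 5L, iter.max = 50L)$cluster
    },
    agglomerative = function(x, k, seed) {
      # deterministic; seed unused
      stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = k)
    },
    spectral = function(x, k, seed) {
      set.seed(seed)
      as.integer(kernlab::specc(as.matrix(x), centers = k))
    }
  )
}

#' Clustering evaluation by mean adjusted Rand index
#'
#' Runs the named clustering algorithm over the feature columns with
#' distinct seeded initializations per replicate and scores each replicate
#' against the true `class` labels by ARI.
#'
#' @param fm A feature matrix with a `class` column (the reference
#'   partition).
#' @param algorithm `"kmeans"`, `"agglomerative"` (Ward linkage; fully
#'   deterministic, replicates coincide) or `"spectral"`.
#' @param n_clusters Number of clusters to request; defaults to the number
#'   of distinct classes.
#' @param replicates Replicate runs (study protocol: 3).
#' @param seed Master integer seed.
#' @return A list with `algorithm`, `per_replicate_ari`, `mean_ari`.
#' @export
cluster_eval <- function(fm, algorithm = c("kmeans", "agglomerative", "spectral"),
                         n_clusters = NULL, replicates = 3L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (!"class" %in% names(fm)) stop("feature matrix has no 'class' column",
                                    call. = FALSE)
  x <- as.matrix(fm[, feature_columns(fm), drop = FALSE])
  truth <- fm$class
  if (is.null(n_clusters)) n_clusters <- length(unique(truth))
  if (nrow(x) < n_clusters) stop("fewer rows than clusters", call. = FALSE)
  alg <- cluster_registry()[[algorithm]]
  ari <- vapply(seq_len(replicates), function(i) {
    part <- if (n_clusters == 1L) rep(1L, nrow(x))
            else alg(x, n_clusters, seed = derive_seed(seed, i))
    adjusted_rand_index(part, truth)
  }, numeric(1L))
  list(algorithm = algorithm, per_replicate_ari = ari, mean_ari = mean(ari))
}
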