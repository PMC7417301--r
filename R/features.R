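# PCA decomposition of a feature matrix and ensemble feature selection over
# the PC scores: six ranking techniques vote; PCs in the top-k list of at
# least half of them are retained, capped at floor(sqrt(n)).

.RANKERS <- c("pearson", "chi2", "rfe", "lasso", "random_forest", "gbt")

#' Fit a principal component analysis
#'
#' Mean-centred (never score-standardized) full-rank decomposition via the
#' singular value decomposition; components are sorted by explained
#' variance, loadings are orthonormal, and the number of components is at
#' most `min(rows - 1, features)`.
#'
#' @param matrix A [feature_matrix()] or plain numeric matrix (>= 2 rows).
#' @return An object of class `pca_model` with elements `center`,
#'   `loadings` (features x components), `sdev`, `explained` (fractions
#'   summing to 1), `n_rows` and `scores` (rows x components).
#' @export
fit_pca <- function(matrix) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else matrix
  n <- nrow(X)
  if (is.null(n) || n < 2L) stop("PCA requires at least 2 rows")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  k <- min(n - 1L, ncol(X))
  sv <- La.svd(Xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  keep <- d > max(d[1], .Machine$double.eps) * 1e-9
  d <- d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- t(sv$vt[keep, , drop = FALSE])
  scores <- U %*% diag(d, nrow = length(d))
  rownames(scores) <- rownames(X)
  total_var <- sum(Xc^2)
  structure(list(center = center, loadings = V,
                 sdev = d / sqrt(n - 1),
                 explained = if (total_var > 0) d^2 / total_var else
                   rep(NA_real_, length(d)),
                 n_rows = n, scores = scores),
            class = "pca_model")
}

#' @exportS3Method base::print
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components from %d rows x %d features\n",
              ncol(x$loadings), x$n_rows, nrow(x$loadings)))
  invisible(x)
}

#' Project rows into a fitted PCA space
#'
#' `(row - center) %*% loadings`; the model is never modified, so held-out
#' athletes can be projected into a space fitted on training athletes only.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param rows Numeric vector (one row) or matrix of rows, feature width
#'   matching the model.
#' @return Score matrix (rows x components).
#' @export
project <- function(model, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (inherits(rows, "feature_matrix")) rows <- rows$values
  if (ncol(rows) != length(model$center))
    stop("width mismatch: model has ", length(model$center),
         " features, rows have ", ncol(rows))
  sweep(rows, 2L, model$center) %*% model$loadings
}

# Gram-matrix PCA used inside the cross-validation loop: with far more
# features than rows, the n x n Gram eigendecomposition gives the same
# centred scores as the SVD route in fit_pca (up to component sign) and
# projects held-out rows through inner products with the training rows,
# without ever forming the feature-space loadings.
.pca_scores_gram <- function(Xtr, xte) {
  n <- nrow(Xtr)
  center <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2L, center)
  G <- tcrossprod(Xc)
  e <- eigen(G, symmetric = TRUE)
  k <- min(n - 1L, sum(e$values > max(e$values[1], 0) * 1e-12))
  lam <- e$values[seq_len(k)]
  U <- e$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(lam)
  S <- U * rep(d, each = n)
  v <- drop(Xc %*% (drop(xte) - center))
  s <- drop(crossprod(U, v)) / d
  list(S = S, s = matrix(s, 1L))
}

.check_binary_labels <- function(labels) {
  lv <- unique(as.character(labels))
  if (length(lv) < 2L)
    stop("labels contain a single class; two classes are required")
  if (length(lv) > 2L)
    stop("labels must be binary; got ", length(lv), " classes")
  as.integer(as.character(labels) == "elite")
}

# each ranker returns a permutation of 1..p, best feature first;
# deterministic given `seed`
.rank_pearson <- function(S, y01) {
  r <- suppressWarnings(abs(cor(S, y01)))
  r[is.na(r)] <- 0
  order(-r, seq_len(ncol(S)))
}

.rank_chi2 <- function(S, y01) {
  # requires non-negative inputs: min-shift per feature (training minimum)
  Sp <- sweep(S, 2L, apply(S, 2L, min))
  n <- nrow(Sp)
  stat <- numeric(ncol(Sp))
  for (cls in c(0L, 1L)) {
    obs <- colSums(Sp[y01 == cls, , drop = FALSE])
    expd <- colSums(Sp) * mean(y01 == cls)
    ok <- expd > 0
    stat[ok] <- stat[ok] + (obs[ok] - expd[ok])^2 / expd[ok]
  }
  order(-stat, seq_len(ncol(Sp)))
}

# recursive feature elimination under a ridge-regularized linear
# discriminant direction; 20% of the surviving features are dropped per
# round, ranked by standardized coefficient magnitude
.rank_rfe <- function(S, y01) {
  p <- ncol(S)
  sds <- apply(S, 2L, sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(S, 2L, colMeans(S)), 2L, sds, "/")
  yc <- y01 - mean(y01)
  alive <- seq_len(p)
  elim <- integer(0)
  while (length(alive) > 0L) {
    Za <- Z[, alive, drop = FALSE]
    G <- crossprod(Za)
    lam <- 1e-6 * max(sum(diag(G)) / length(alive), .Machine$double.eps)
    beta <- solve(G + diag(lam + 1e-3, length(alive)), crossprod(Za, yc))
    ord <- order(abs(beta), seq_along(alive))
    n_drop <- if (length(alive) > 1L) max(1L, floor(0.2 * length(alive)))
      else 1L
    drop_local <- ord[seq_len(n_drop)]
    # among the dropped, worse coefficients are eliminated first
    elim <- c(elim, alive[drop_local])
    alive <- alive[-drop_local]
  }
  rev(elim)  # eliminated last = best
}

.rank_lasso <- function(S, y01) {
  p <- ncol(S)
  if (p < 2L) return(seq_len(p))
  lam <- 0.01  # fixed path point; no internal cross-validation
  fit <- suppressWarnings(
    glmnet::glmnet(S, y01, family = "binomial", standardize = TRUE,
                   lambda = c(0.1, 0.03, lam)))
  beta <- abs(as.numeric(coef(fit, s = lam))[-1L])
  order(-beta, seq_len(p))
}

.rank_random_forest <- function(S, y01, seed) {
  df <- data.frame(.y = factor(y01), S)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = 100L, importance = "impurity",
                        seed = seed, num.threads = 1L)
  imp <- fit$variable.importance[colnames(S)]
  imp[is.na(imp)] <- 0
  order(-imp, seq_len(ncol(S)))
}

.rank_gbt <- function(S, y01, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(S, label = y01)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3L,
                  eta = 0.3, nthread = 1L, seed = seed,
                  tree_method = "hist", max_bin = 63L),
    data = dtrain, nrounds = 50L, verbose = 0)
  imp <- rep(0, ncol(S))
  tab <- xgboost::xgb.importance(model = fit)
  if (!is.null(tab) && nrow(tab) > 0L) {
    idx <- match(tab$Feature, colnames(S))
    imp[idx[!is.na(idx)]] <- tab$Gain[!is.na(idx)]
  }
  order(-imp, seq_len(ncol(S)))
}

#' Rank PC scores by one feature-selection technique
#'
#' Six techniques are available: absolute Pearson correlation with the 0/1
#' class label; the chi-squared statistic on min-shifted scores; recursive
#' feature elimination under a linear model; the lasso coefficient
#' magnitude at a fixed regularization point (zero coefficients rank last);
#' random-forest impurity importance; and gradient-boosted-tree gain
#' importance. The stochastic rankers are seed-fixed and single-threaded,
#' so rankings are reproducible.
#'
#' @param scores Rows x PCs score matrix (training rows only).
#' @param labels Binary class labels (`"elite"` / `"novice"`).
#' @param technique One of `"pearson"`, `"chi2"`, `"rfe"`, `"lasso"`,
#'   `"random_forest"`, `"gbt"`.
#' @param seed Integer seed for the stochastic rankers.
#' @return Integer vector: PC indices ordered best first.
#' @export
rank_features <- function(scores, labels,
                          technique = .RANKERS, seed = 1L) {
  technique <- match.arg(technique)
  y01 <- .check_binary_labels(labels)
  if (min(table(y01)) < 2L)
    stop("supervised ranking requires at least 2 rows per class")
  S <- as.matrix(scores)
  if (is.null(colnames(S))) colnames(S) <- paste0("PC", seq_len(ncol(S)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  switch(technique,
         pearson = .rank_pearson(S, y01),
         chi2 = .rank_chi2(S, y01),
         rfe = .rank_rfe(S, y01),
         lasso = .rank_lasso(S, y01),
         random_forest = .rank_random_forest(S, y01, seed),
         gbt = .rank_gbt(S, y01, seed))
}

#' Ensemble feature selection by rank voting
#'
#' Each of the six rankers nominates its top `top_k` PCs; PCs nominated by
#' at least `vote_threshold` rankers are candidates, ordered by votes
#' (descending), then mean rank across the six rankers (ascending), then PC
#' index. At most `floor(sqrt(n))` candidates are retained (overfitting
#' guard); if fewer candidates exist the retained list is shorter, never
#' padded.
#'
#' @param rankings List of exactly six ranked index vectors over a common
#'   PC set (as returned by [rank_features()]).
#' @param n Cohort size used for the cap `floor(sqrt(n))`.
#' @param top_k Nomination depth per ranker (25 by default).
#' @param vote_threshold Minimum number of nominating rankers (3 = half).
#' @return An object of class `selection_result`: `votes` (per-PC vote
#'   count), `mean_rank`, `candidates`, `retained` (ordered), `cap`.
#' @export
ensemble_select <- function(rankings, n, top_k = 25L, vote_threshold = 3L) {
  if (length(rankings) != 6L)
    stop("exactly six rankings are required (vote threshold semantics ",
         "depend on the ranker count); got ", length(rankings))
  if (n < 1L) stop("cohort size n must be >= 1")
  p <- length(rankings[[1L]])
  if (!all(vapply(rankings, length, integer(1)) == p) ||
      !all(vapply(rankings, function(r) setequal(r, seq_len(p)),
                  logical(1))))
    stop("rankings must all be permutations of a common PC index set")
  k <- min(top_k, p)
  votes <- integer(p)
  rank_sum <- numeric(p)
  for (r in rankings) {
    votes[r[seq_len(k)]] <- votes[r[seq_len(k)]] + 1L
    rank_sum[r] <- rank_sum[r] + seq_len(p)
  }
  mean_rank <- rank_sum / length(rankings)
  candidates <- which(votes >= vote_threshold)
  ord <- candidates[order(-votes[candidates], mean_rank[candidates],
                          candidates)]
  cap <- floor(sqrt(n))
  structure(list(votes = votes, mean_rank = mean_rank,
                 candidates = candidates,
                 retained = head(ord, cap), cap = cap,
                 top_k = k, vote_threshold = vote_threshold),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result> %d candidate PCs (>= %d/6 votes), ",
                     "%d retained (cap %d)\n"),
              length(x$candidates), x$vote_threshold, length(x$retained),
              x$cap))
  if (length(x$retained))
    cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Full vote tallies are kept for auditability.
#'
#' @param x A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
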