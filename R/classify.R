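# Leave-one-out protocol: for every held-out athlete the full stack —
# robust scaling (sIMU), PCA, the six rankings, ensemble selection and the
# classifier — is re-fitted on the remaining athletes; the held-out row is
# then projected through the fitted spaces. Nothing estimated on the full
# cohort is reused inside a fold (the only exception, by design, is the
# sweep bound K in sweep_k, which never enters any fold's fitting).

#' Cross-validation options
#'
#' @param top_k Nomination depth per ranker (25).
#' @param vote_threshold Minimum nominating rankers (3).
#' @param scale `NULL` to scale sIMU matrices and leave OPT matrices
#'   unscaled (the default discipline), or TRUE/FALSE to force.
#' @param scale_discipline `"per_fold"` fits the robust scaler inside each
#'   training fold (no leakage); `"global"` fits it once on the full matrix
#'   before cross-validation.
#' @param seed Integer seed; every stochastic component inside every fold
#'   derives its own substream from it.
#' @return An object of class `cv_options`.
#' @export
cv_options <- function(top_k = 25L, vote_threshold = 3L, scale = NULL,
                       scale_discipline = c("per_fold", "global"),
                       seed = 1L) {
  scale_discipline <- match.arg(scale_discipline)
  structure(list(top_k = as.integer(top_k),
                 vote_threshold = as.integer(vote_threshold),
                 scale = scale, scale_discipline = scale_discipline,
                 seed = as.integer(seed)),
            class = "cv_options")
}

.wants_scaling <- function(fm, opts) {
  if (!is.null(opts$scale)) return(isTRUE(opts$scale))
  inherits(fm, "feature_matrix") && fm$variant == "sIMU"
}

# One pass over the folds computing everything that does not depend on the
# classifier: per-fold retained training scores, the projected held-out
# score vector, and the retained-PC order. Classifier fits then reuse this.
.cv_fold_stack <- function(fm, labels, opts, folds = NULL) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out requires a cohort of at least 3")
  y <- as.character(labels)
  if (length(y) != n) stop("labels length must match matrix rows")
  .check_binary_labels(y)
  if (is.null(folds)) folds <- seq_len(n)
  do_scale <- .wants_scaling(fm, opts)
  if (do_scale && opts$scale_discipline == "global") {
    st <- robust_scale_fit(X)
    X <- robust_scale_apply(X, st)
  }
  lapply(seq_along(folds), function(fold_idx) {
    i <- folds[fold_idx]
    # the tree rankers hold native (off-R-heap) memory that only their
    # finalizers release; collect periodically so long fold loops cannot
    # exhaust the allocator
    if (fold_idx %% 50L == 0L) gc(verbose = FALSE)
    Xtr <- X[-i, , drop = FALSE]
    xte <- X[i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop("training fold ", i, " contains a single class")
    if (do_scale && opts$scale_discipline == "per_fold") {
      st <- robust_scale_fit(Xtr)
      Xtr <- robust_scale_apply(Xtr, st)
      xte <- robust_scale_apply(xte, st)
    }
    g <- .pca_scores_gram(Xtr, xte)
    Str <- g$S
    ste <- g$s
    fold_seed <- .substream(opts$seed, i, 424243)
    rankings <- lapply(.RANKERS, function(tech)
      rank_features(Str, ytr, tech, seed = fold_seed))
    sel <- ensemble_select(rankings, n = nrow(Xtr),
                           top_k = opts$top_k,
                           vote_threshold = opts$vote_threshold)
    list(fold = i,
         S = Str[, sel$retained, drop = FALSE],
         s = ste[, sel$retained, drop = FALSE],
         retained = sel$retained, ytr = ytr)
  })
}

.eval_stack <- function(stack, y, spec, k, fm, task = NULL) {
  n_trunc <- 0L
  preds <- vapply(stack, function(f) {
    r <- length(f$retained)
    if (r == 0L) return(NA_character_)
    kk <- if (is.null(k)) r else min(k, r)
    if (!is.null(k) && k > r) n_trunc <<- n_trunc + 1L
    sp <- spec
    sp$seed <- .substream(spec$seed, f$fold, 7L)
    model <- fit_classifier(f$S[, seq_len(kk), drop = FALSE], f$ytr, sp)
    predict_classifier(model, f$s[, seq_len(kk), drop = FALSE])
  }, character(1))
  if (n_trunc > 0L)
    warning("k = ", k, " exceeded the retained-PC count in ", n_trunc,
            " fold(s); truncated to the fold's retained length",
            call. = FALSE)
  idx <- vapply(stack, `[[`, integer(1), "fold")
  truth <- as.character(y)[idx]
  ids <- rownames(if (inherits(fm, "feature_matrix")) fm$values else fm)
  if (!is.null(ids)) names(preds) <- ids[idx] else names(preds) <- idx
  acc <- 100 * mean(preds == truth, na.rm = TRUE)
  structure(list(predictions = preds, labels = setNames(truth, names(preds)),
                 accuracy = acc, classifier = spec$kind,
                 k = if (is.null(k)) NA_integer_ else as.integer(k),
                 variant = if (inherits(fm, "feature_matrix")) fm$variant
                   else NA_character_,
                 task = task, n = length(preds), n_truncated = n_trunc),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s %s/%s: accuracy %.2f%% (n = %d, k = %s)\n",
              x$classifier, x$variant %||% "?", x$task %||% "?",
              x$accuracy, x$n,
              if (is.na(x$k)) "all retained" else x$k))
  invisible(x)
}

#' Leave-one-out cross-validation with per-fold re-fitting
#'
#' @param matrix A [feature_matrix()] (or plain matrix with athlete row
#'   names).
#' @param labels Class labels aligned with the rows.
#' @param spec A [classifier_spec()].
#' @param k Number of retained PCs to use: the first `k` entries of each
#'   fold's vote-ordered retained list (`NULL` = all retained). If a fold
#'   retains fewer than `k`, `k` is truncated for that fold with a warning.
#' @param opts A [cv_options()].
#' @param folds Optional integer subset of rows to hold out (all rows by
#'   default); useful for audits of single folds.
#' @param task Optional task name recorded in the result.
#' @return A `cv_result`: per-athlete held-out predictions and true labels,
#'   accuracy in percent, and protocol metadata.
#' @export
loocv <- function(matrix, labels, spec, k = NULL, opts = cv_options(),
                  folds = NULL, task = NULL) {
  stack <- .cv_fold_stack(matrix, labels, opts, folds)
  .eval_stack(stack, labels, spec, k, matrix, task)
}

#' Sweep the number of retained PCs
#'
#' Runs the leave-one-out protocol for every k from 1 to K, where K is the
#' retained-PC count of a full-cohort selection pass (used only to bound
#' the sweep; every fold still re-selects internally). The optimal model is
#' the one with the highest classification rate, ties broken by the
#' smallest k. Note the optimum is selected on the same leave-one-out
#' estimate it reports, so the reported accuracy carries the usual model-
#' selection optimism.
#'
#' @inheritParams loocv
#' @return A list: `curve` (data frame of k vs accuracy), `results` (one
#'   `cv_result` per k), `optimal` (the best `cv_result`), `K`.
#' @export
sweep_k <- function(matrix, labels, spec, opts = cv_options(), task = NULL) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else
    as.matrix(matrix)
  y <- as.character(labels)
  # full-cohort pass, only to bound the sweep
  Xb <- X
  if (.wants_scaling(matrix, opts))
    Xb <- robust_scale_apply(X, robust_scale_fit(X))
  pca <- fit_pca(Xb)
  rankings <- lapply(.RANKERS, function(tech)
    rank_features(pca$scores, y, tech,
                  seed = .substream(opts$seed, 0L, 424243)))
  K <- length(ensemble_select(rankings, n = nrow(X), top_k = opts$top_k,
                              vote_threshold = opts$vote_threshold)$retained)
  if (K < 1L)
    stop("no PCs survived ensemble selection on the full cohort")
  stack <- .cv_fold_stack(matrix, labels, opts)
  results <- lapply(seq_len(K), function(k)
    suppressWarnings(.eval_stack(stack, labels, spec, k, matrix, task)))
  accs <- vapply(results, `[[`, numeric(1), "accuracy")
  best <- which.max(accs)  # which.max takes the first maximum: smallest k
  list(curve = data.frame(k = seq_len(K), accuracy = accs),
       results = results, optimal = results[[best]], K = K)
}

#' Evaluate several classifiers on the same folds
#'
#' The fold stack (scaling, PCA, rankings, selection) is computed once and
#' shared; only the classifier fits differ, exactly as in [loocv()].
#'
#' @inheritParams loocv
#' @param specs Named list of [classifier_spec()]s.
#' @return Named list of `cv_result`s.
#' @export
compare_classifiers <- function(matrix, labels, specs, k = NULL,
                                opts = cv_options(), task = NULL) {
  stack <- .cv_fold_stack(matrix, labels, opts)
  out <- lapply(specs, function(sp)
    .eval_stack(stack, labels, sp, k, matrix, task))
  if (is.null(names(out)))
    names(out) <- vapply(specs, `[[`, character(1), "kind")
  out
}

#' Summarize per-task results
#'
#' Builds the per-task summary table: one row per task plus an unweighted
#' `Average` row and a `STD` row (sample standard deviation, n - 1
#' denominator) over tasks.
#'
#' @param results Either a named list of `cv_result`s (names are tasks; SDT
#'   metrics are computed from the stored predictions), or a data frame
#'   with a `task` column and numeric columns to summarize.
#' @return A data frame with the task rows followed by `Average` and `STD`.
#' @export
summarize_tasks <- function(results) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    if (length(results) < 1L) stop("at least one task result is required")
    rows <- lapply(seq_along(results), function(i) {
      r <- results[[i]]
      s <- sdt_metrics(r$predictions, r$labels)
      nm <- names(results)[i]
      if (is.null(nm) || is.na(nm) || !nzchar(nm))
        nm <- r$task %||% as.character(i)
      data.frame(task = nm,
                 n = r$n, n_pcs = r$k, accuracy = r$accuracy,
                 hit = s$hit, miss = s$miss, fa = s$fa, cr = s$cr,
                 d_prime = s$d_prime, c = s$c)
    })
    df <- do.call(rbind, rows)
  }
  num <- vapply(df, is.numeric, logical(1))
  avg <- df[1L, , drop = FALSE]
  std <- df[1L, , drop = FALSE]
  avg[, !num] <- "Average"; std[, !num] <- "STD"
  avg[, num] <- vapply(df[, num, drop = FALSE], mean, numeric(1))
  std[, num] <- vapply(df[, num, drop = FALSE], sd, numeric(1))
  out <- rbind(df, avg, std)
  rownames(out) <- NULL
  out
}
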