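# The seven classifier kinds operating on retained PC scores. Each is
# wrapped behind a common fit/predict surface so the cross-validation
# protocol can treat them interchangeably.

.CLASSIFIERS <- c("BLR", "DT", "KNN", "LDA", "NB", "SVM", "RBF")

#' Specify a classifier
#'
#' @param kind One of `"BLR"` (binary logistic regression, L2-penalized),
#'   `"DT"` (decision tree), `"KNN"` (k-nearest neighbours), `"LDA"`
#'   (linear discriminant analysis), `"NB"` (Gaussian naive Bayes),
#'   `"SVM"` (support vector machine, linear kernel), `"RBF"` (SVM with a
#'   radial basis function kernel). Case-insensitive.
#' @param knn_k Neighbours for KNN (5).
#' @param C Inverse regularization strength for BLR (1).
#' @param cost SVM cost parameter (1).
#' @param gamma RBF kernel width; `NULL` uses `1 / (k * mean score
#'   variance)`.
#' @param max_depth Maximum tree depth for DT (`NULL` = unlimited).
#' @param seed Seed for the stochastic pieces (KNN tie-breaking, tree
#'   surrogate order).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind, knn_k = 5L, C = 1, cost = 1,
                            gamma = NULL, max_depth = NULL, seed = 1L) {
  kind <- toupper(kind)
  if (!kind %in% .CLASSIFIERS)
    stop("unknown classifier kind '", kind, "'; one of: ",
         paste(.CLASSIFIERS, collapse = ", "))
  if (knn_k < 1L) stop("knn_k must be >= 1")
  if (C <= 0 || cost <= 0) stop("C and cost must be > 0")
  structure(list(kind = kind, knn_k = as.integer(knn_k), C = C, cost = cost,
                 gamma = gamma, max_depth = max_depth,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# ridge-penalized logistic regression by IRLS; intercept unpenalized.
# Works for a single predictor, where path-based solvers refuse to fit.
.fit_ridge_logistic <- function(X, y01, lambda) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(50L)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    H <- crossprod(Xd * w, Xd) + pen
    new_beta <- solve(H, crossprod(Xd * w, z))
    if (max(abs(new_beta - beta)) < 1e-10) { beta <- new_beta; break }
    beta <- new_beta
  }
  drop(beta)
}

#' Fit one classifier on PC scores
#'
#' @param scores Rows x k numeric matrix of retained PC scores.
#' @param labels Class labels (`"elite"` / `"novice"`), both present.
#' @param spec A [classifier_spec()].
#' @return An object of class `omat_classifier` whose decision function is
#'   applied with [predict_classifier()]; deterministic given the spec seed.
#' @export
fit_classifier <- function(scores, labels, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(scores)
  colnames(X) <- paste0("PC", seq_len(ncol(X)))
  y <- as.character(labels)
  lev <- sort(unique(y))
  if (length(lev) < 2L)
    stop("single-class training set; both classes are required")
  yf <- factor(y, levels = lev)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    BLR = .fit_ridge_logistic(X, as.integer(yf) - 1L, 1 / spec$C),
    DT = {
      df <- data.frame(.y = yf, X)
      ctrl <- if (is.null(spec$max_depth)) rpart::rpart.control(cp = 0.01)
        else rpart::rpart.control(maxdepth = spec$max_depth, cp = 0.01)
      rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
    },
    KNN = list(X = X, y = yf, k = min(spec$knn_k, nrow(X))),
    LDA = MASS::lda(X, grouping = yf),
    NB = e1071::naiveBayes(data.frame(X), yf),
    SVM = e1071::svm(X, yf, kernel = "linear", cost = spec$cost,
                     scale = FALSE),
    RBF = {
      g <- spec$gamma
      if (is.null(g)) g <- 1 / (ncol(X) * max(mean(apply(X, 2L, var)),
                                              .Machine$double.eps))
      e1071::svm(X, yf, kernel = "radial", cost = spec$cost, gamma = g,
                 scale = FALSE)
    })
  structure(list(kind = spec$kind, fit = fit, levels = lev,
                 spec = spec, k = ncol(X)),
            class = "omat_classifier")
}

#' Predict class labels from a fitted classifier
#'
#' @param model An `omat_classifier` from [fit_classifier()].
#' @param scores Numeric vector (one row) or matrix of rows with the same
#'   PC width the model was fitted on.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(model, scores) {
  X <- if (is.null(dim(scores))) matrix(scores, nrow = 1L) else
    as.matrix(scores)
  if (ncol(X) != model$k)
    stop("width mismatch: model fitted on ", model$k, " PCs, got ", ncol(X))
  colnames(X) <- paste0("PC", seq_len(ncol(X)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(model$spec$seed)
  out <- switch(model$kind,
    BLR = {
      eta <- drop(cbind(1, X) %*% model$fit)
      model$levels[ifelse(eta > 0, 2L, 1L)]
    },
    DT = as.character(predict(model$fit, data.frame(X), type = "class")),
    KNN = as.character(class::knn(model$fit$X, X, model$fit$y,
                                  k = model$fit$k)),
    LDA = as.character(predict(model$fit, X)$class),
    NB = as.character(predict(model$fit, data.frame(X))),
    SVM = as.character(predict(model$fit, X)),
    RBF = as.character(predict(model$fit, X)))
  out
}
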