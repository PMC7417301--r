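test_that("all seven classifier kinds fit and predict separable data", {
  set.seed(20)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 5), 20, 2))
  y <- rep(c("novice", "elite"), each = 20)
  for (kind in c("BLR", "DT", "KNN", "LDA", "NB", "SVM", "RBF")) {
    m <- fit_classifier(X, y, classifier_spec(kind, seed = 2))
    expect_equal(mean(predict_classifier(m, X) == y), 1,
                 info = kind)
  }
  expect_error(fit_classifier(X, rep("elite", 40), classifier_spec("LDA")),
               "single-class")
  expect_error(classifier_spec("PERCEPTRON"), "unknown classifier")
})

test_that("LDA recovers the closed-form discriminant direction", {
  # identical spherical within-class scatter around means (0,0) and (4,2):
  # the pooled covariance is a multiple of the identity, so the LDA
  # direction is the mean difference (4,2) and the boundary is orthogonal
  # to it through the midpoint
  pat <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- rbind(pat, sweep(pat, 2, c(4, 2), "+"))
  y <- rep(c("novice", "elite"), each = 4)
  m <- fit_classifier(X, y, classifier_spec("LDA"))
  mid <- c(2, 1)
  w <- c(4, 2)
  perp <- c(-2, 4)
  probes <- rbind(mid + 0.01 * w, mid - 0.01 * w,
                  mid + 3 * perp + 0.01 * w, mid - 3 * perp - 0.01 * w)
  expect_equal(predict_classifier(m, probes),
               c("elite", "novice", "elite", "novice"))
})

test_that("1-NN memorizes training data perfectly", {
  set.seed(21)
  X <- matrix(rnorm(60), 30, 2)
  y <- sample(rep(c("elite", "novice"), 15))
  m <- fit_classifier(X, y, classifier_spec("KNN", knn_k = 1))
  expect_equal(predict_classifier(m, X), y)
})

test_that("leave-one-out runs one fold per athlete and needs 3 athletes", {
  set.seed(22)
  X <- matrix(rnorm(3 * 30), 3, 30,
              dimnames = list(c("a", "b", "c"), NULL))
  y <- c("elite", "elite", "novice")
  # holding out the lone novice leaves a single-class training fold
  expect_error(loocv(X, y, classifier_spec("LDA"),
                     opts = cv_options(scale = FALSE), folds = 3),
               "single class")
  X6 <- matrix(rnorm(6 * 30), 6, 30,
               dimnames = list(letters[1:6], NULL))
  y6 <- rep(c("elite", "novice"), 3)
  r <- suppressWarnings(loocv(X6, y6, classifier_spec("KNN", knn_k = 1),
                              opts = cv_options(scale = FALSE)))
  expect_equal(r$n, 6)
  expect_named(r$predictions, letters[1:6])
  expect_error(loocv(X[1:2, ], y[1:2], classifier_spec("LDA")),
               "at least 3")
})

test_that("requesting more PCs than retained truncates with a warning", {
  set.seed(23)
  X <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(sprintf("a%02d", 1:20), NULL))
  y <- rep(c("elite", "novice"), 10)
  expect_warning(
    loocv(X, y, classifier_spec("LDA"), k = 50,
          opts = cv_options(scale = FALSE)),
    "truncated")
})

test_that("cross-validation is deterministic given the seed", {
  co <- fixture("gap2_n16", function()
    small_cohort(8, 8, seed = 4, duration_range = c(1, 1.5)))
  fm <- fixture("gap2_n16_fm", function()
    task_matrices(co, "drop_jump", preprocess_config(target_frames = 40),
                  "sIMU"))
  y <- cohort_labels(co, fm)
  r1 <- loocv(fm, y, classifier_spec("LDA"), opts = cv_options(seed = 9))
  r2 <- loocv(fm, y, classifier_spec("LDA"), opts = cv_options(seed = 9))
  expect_identical(r1, r2)
})

test_that("the k sweep bounds at the full-cohort retained count and
           breaks accuracy ties toward small k", {
  # only the first direction carries signal; later PCs are noise
  set.seed(24)
  n <- 40
  y <- rep(c("elite", "novice"), each = n / 2)
  X <- cbind(ifelse(y == "elite", 2, -2) + rnorm(n, 0, 0.8),
             matrix(rnorm(n * 19), n, 19))
  X <- X %*% qr.Q(qr(matrix(rnorm(400), 20, 20)))  # mix into all columns
  rownames(X) <- sprintf("a%02d", 1:n)
  sw <- suppressWarnings(
    sweep_k(X, y, classifier_spec("LDA"), cv_options(scale = FALSE)))
  expect_equal(nrow(sw$curve), sw$K)
  expect_equal(sw$optimal$accuracy, max(sw$curve$accuracy))
  expect_equal(sw$optimal$k, min(sw$curve$k[sw$curve$accuracy ==
                                              max(sw$curve$accuracy)]))
  # noise dilution: k = 1 performs within 5 points of the full set
  expect_gte(sw$curve$accuracy[1], sw$curve$accuracy[sw$K] - 5)
})

test_that("per-task summaries append Average and sample-SD rows", {
  df <- data.frame(task = c("t1", "t2", "t3"),
                   accuracy = c(70, 80, 90), n = c(10, 10, 10))
  s <- summarize_tasks(df)
  expect_equal(nrow(s), 5)
  expect_equal(s$accuracy[4], 80)
  expect_equal(s$accuracy[5], sd(c(70, 80, 90)))
  expect_equal(s$task[4:5], c("Average", "STD"))
})
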