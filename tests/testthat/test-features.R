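test_that("PCA reconstructs the data and normalizes explained variance", {
  set.seed(10)
  X <- matrix(rnorm(15 * 40), 15, 40)
  p <- fit_pca(X)
  recon <- sweep(p$scores %*% t(p$loadings), 2, p$center, "+")
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(p$loadings) - diag(ncol(p$loadings)))), 1e-8)
  expect_lte(ncol(p$loadings), 14)
})

test_that("a rank-1 matrix concentrates all variance in PC1", {
  u <- rnorm(10); v <- rnorm(30)
  p <- fit_pca(outer(u, v))
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
})

test_that("projection is centred, faithful on training rows, and checked", {
  set.seed(11)
  X <- matrix(rnorm(12 * 25), 12, 25)
  p <- fit_pca(X)
  expect_lt(max(abs(project(p, p$center))), 1e-9)
  expect_lt(max(abs(project(p, X) - p$scores)), 1e-9)
  expect_error(project(p, rnorm(10)), "width mismatch")
})

test_that("the Gram-route scores match the SVD route", {
  set.seed(12)
  for (i in 1:3) {
    X <- matrix(rnorm(20 * 100), 20, 100)
    g <- omat:::.pca_scores_gram(X[-1, ], X[1, , drop = FALSE])
    p <- fit_pca(X[-1, ])
    s <- project(p, X[1, , drop = FALSE])
    sgn <- sign(colSums(g$S * p$scores))
    expect_lt(max(abs(sweep(g$S, 2, sgn, "*") - p$scores)), 1e-8)
    expect_lt(max(abs(g$s * sgn - s)), 1e-8)
  }
})

test_that("a perfectly separating PC ranks first under pearson", {
  set.seed(13)
  y <- rep(c("elite", "novice"), each = 10)
  S <- matrix(rnorm(20 * 8), 20, 8)
  S[, 5] <- ifelse(y == "elite", 1, -1) + rnorm(20, 0, 0.01)
  expect_equal(rank_features(S, y, "pearson")[1], 5)
})

test_that("pearson ranking equals a brute-force correlation sort", {
  set.seed(14)
  S <- matrix(rnorm(30 * 10), 30, 10)
  y <- rep(c("elite", "novice"), 15)
  got <- rank_features(S, y, "pearson")
  r <- vapply(1:10, function(j)
    abs(cor(S[, j], as.integer(y == "elite"))), numeric(1))
  expect_equal(got, order(-r, 1:10))
})

test_that("all six rankers are deterministic and total", {
  set.seed(15)
  S <- matrix(rnorm(24 * 12), 24, 12)
  y <- rep(c("elite", "novice"), each = 12)
  for (tech in c("pearson", "chi2", "rfe", "lasso", "random_forest",
                 "gbt")) {
    r1 <- rank_features(S, y, tech, seed = 5)
    r2 <- rank_features(S, y, tech, seed = 5)
    expect_identical(r1, r2)
    expect_setequal(r1, 1:12)
  }
  expect_error(rank_features(S, rep("elite", 24), "pearson"),
               "single class")
})

test_that("ensemble selection counts votes and applies the cohort cap", {
  # unanimity: all rankers agree -> first floor(sqrt(n)) retained
  base <- 1:40
  sel <- ensemble_select(rep(list(base), 6), n = 401)
  expect_equal(sel$cap, 20)
  expect_equal(sel$retained, 1:20)
  expect_true(all(sel$votes[1:25] == 6))

  # PC7 nominated by exactly 3 rankers, PC9 by exactly 2
  move_out <- function(r, pc) c(setdiff(r, pc), pc)  # push past top-25
  r_in <- 1:30
  rk <- list(r_in, r_in, move_out(r_in, 9), move_out(r_in, c(7, 9)),
             move_out(r_in, c(7, 9)), move_out(r_in, c(7, 9)))
  sel2 <- ensemble_select(rk, n = 10000)
  expect_equal(sel2$votes[7], 3)
  expect_equal(sel2$votes[9], 2)
  expect_true(7 %in% sel2$retained)
  expect_false(9 %in% sel2$retained)
})

test_that("selection is invariant to the order rankings are supplied", {
  set.seed(16)
  rk <- lapply(1:6, function(i) sample(40))
  a <- ensemble_select(rk, n = 100)
  b <- ensemble_select(rev(rk), n = 100)
  expect_identical(a$retained, b$retained)
  expect_lte(length(a$retained), floor(sqrt(100)))
})

test_that("selection needs exactly six rankings and never pads", {
  expect_error(ensemble_select(rep(list(1:10), 5), n = 50), "six")
  # disjoint nominations -> no candidate reaches 3 votes
  rk <- lapply(0:5, function(i) c((i * 5 + 1):(i * 5 + 5),
                                  setdiff(1:60, (i * 5 + 1):(i * 5 + 5))))
  sel <- ensemble_select(rk, n = 10000, top_k = 5)
  expect_length(sel$retained, 0)
})
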