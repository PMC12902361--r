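test_that("R-squared identities hold", {
  X <- with_seed_test(1, matrix(rnorm(300), 100, 3,
                                dimnames = list(NULL, c("u", "v", "w"))))
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  expect_equal(ols_r2(y, X), 1, tolerance = 1e-12)
  # single predictor: squared correlation
  y2 <- with_seed_test(2, X[, 1] + rnorm(100))
  expect_equal(ols_r2(y2, X[, 1, drop = FALSE]),
               cor(y2, X[, 1])^2, tolerance = 1e-12)
  # independent noise explains nothing
  y3 <- with_seed_test(3, rnorm(10000))
  X3 <- with_seed_test(4, matrix(rnorm(30000), 10000, 3))
  expect_lt(ols_r2(y3, X3), 0.01)
  # collinearity is reported by name
  Xd <- cbind(X, dup = X[, 1])
  expect_error(ols_r2(y2, Xd), "dup")
})

test_that("LMG equals the explicit permutation average", {
  perm_oracle <- function(y, X) {
    p <- ncol(X)
    perms <- as.matrix(expand.grid(rep(list(1:p), p)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == p), ,
                   drop = FALSE]
    acc <- numeric(p)
    for (r in seq_len(nrow(perms))) {
      prev <- 0
      for (k in seq_len(p)) {
        cols <- perms[r, 1:k]
        r2 <- ols_r2(y, X[, cols, drop = FALSE])
        acc[perms[r, k]] <- acc[perms[r, k]] + (r2 - prev)
        prev <- r2
      }
    }
    acc / nrow(perms)
  }
  for (seed in 1:5) {
    X <- with_seed_test(seed, matrix(rnorm(120), 40, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
    y <- with_seed_test(seed + 50,
                        X %*% c(1, 0.5, -0.2) + rnorm(40, 0, 0.5))
    fit <- lmg_shares(y, X)
    expect_equal(unname(fit$lmg), perm_oracle(y, X), tolerance = 1e-12)
    expect_equal(sum(fit$lmg), fit$r2, tolerance = 1e-12)
    expect_true(all(fit$lmg >= 0))
  }
})

test_that("orthogonal predictors get their marginal R-squared", {
  X <- with_seed_test(7, {
    raw <- scale(matrix(rnorm(600), 200, 3), scale = FALSE)
    q <- qr.Q(qr(raw))  # orthonormal and mean-zero
    colnames(q) <- c("a", "b", "c")
    q
  })
  y <- with_seed_test(8, as.numeric(X %*% c(2, -1, 0.5) + rnorm(200)))
  fit <- lmg_shares(y, X)
  for (k in 1:3) {
    expect_equal(unname(fit$lmg[k]), cor(y, X[, k])^2, tolerance = 1e-8)
  }
})

test_that("LMG shares are invariant to predictor order", {
  X <- with_seed_test(9, matrix(rnorm(150), 50, 3,
                                dimnames = list(NULL, c("a", "b", "c"))))
  y <- with_seed_test(10, X %*% c(1, 1, 1) + rnorm(50))
  f1 <- lmg_shares(y, X)
  f2 <- lmg_shares(y, X[, c(3, 1, 2)])
  expect_equal(f1$lmg[c("a", "b", "c")], f2$lmg[c("a", "b", "c")],
               tolerance = 1e-12)
})

test_that("node-matrix assembly applies the missing and constant rules", {
  d <- tibble::tibble(
    branch_id = paste0("B", 1:8),
    gcf = c(90, 70, 55, 80, 60, 75, 85, 50),
    theta = c(1, 3, 5, 2, 4, 2.5, 1.5, NA),
    bp = c(99, 95, 80, 97, 90, 96, 98, 85),
    ri = c(0.1, 0.2, 0.5, 0.1, 0.3, 0.2, 0.15, 0.6)
  )
  nm <- assemble_node_matrix(d)
  expect_equal(nm$n_dropped_rows, 1)
  expect_equal(length(nm$y), 7)
  expect_equal(unname(colMeans(nm$X)), rep(0, 3), tolerance = 1e-12)
  # constant predictor dropped and reported as zero share
  d$ri <- 0
  expect_warning(nm0 <- assemble_node_matrix(d[!is.na(d$theta), ]),
                 "constant")
  dec <- suppressWarnings(decompose_heterogeneity(d[!is.na(d$theta), ]))
  expect_equal(unname(dec$shares["ri"]), 0)
  expect_error(assemble_node_matrix(d[1:4, ]), "at least 5")
})

test_that("a dominant simulated factor earns the dominant share", {
  hits <- 0
  for (seed in 1:10) {
    d <- with_seed_test(seed, {
      theta <- runif(20, 0, 5)
      tibble::tibble(
        branch_id = paste0("B", 1:20), gcf = 100 - 2 * theta * 5 -
          rnorm(20, 0, 0.5),
        theta = theta, bp = 100 - runif(20, 0, 3), ri = runif(20, 0, 0.2)
      )
    })
    dec <- decompose_heterogeneity(d)
    hits <- hits + (dec$percent["theta"] >= 80)
  }
  expect_gte(hits, 9)
})

test_that("the decomposition is internally consistent and tidyable", {
  d <- with_seed_test(11, tibble::tibble(
    branch_id = paste0("B", 1:15),
    gcf = runif(15, 40, 95),
    theta = runif(15, 0.5, 5),
    bp = runif(15, 70, 100),
    ri = runif(15, 0, 0.6)
  ))
  nm <- assemble_node_matrix(d)
  dec <- decompose_heterogeneity(nm)
  expect_equal(dec$r2, ols_r2(nm$y, nm$X), tolerance = 1e-12)
  expect_equal(sum(dec$shares), dec$r2, tolerance = 1e-10)
  expect_equal(sum(dec$percent), 100, tolerance = 1e-8)
  td <- tidy(dec)
  expect_equal(nrow(td), 3)
  expect_equal(glance(dec)$r2, dec$r2)
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
})
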