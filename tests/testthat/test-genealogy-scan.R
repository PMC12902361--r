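test_that("window distances match brute-force column counting", {
  w <- with_seed_test(1, {
    base <- sample(c("A", "C", "G", "T"), 100, TRUE)
    mutate <- function(x, p) {
      hit <- runif(100) < p
      x[hit] <- sample(c("A", "C", "G", "T", "N"), sum(hit), TRUE)
      x
    }
    m <- rbind(P1 = mutate(base, 0.1), P2 = mutate(base, 0.2),
               P3 = mutate(base, 0.3), O = mutate(base, 0.4))
    m
  })
  d <- window_distances(w)
  ok <- w[1, ] %in% c("A", "C", "G", "T") & w[2, ] %in% c("A", "C", "G", "T") &
    w[3, ] %in% c("A", "C", "G", "T")
  brute <- function(i, j) {
    p <- mean(w[i, ok] != w[j, ok])
    -0.75 * log(1 - 4 * p / 3)
  }
  expect_equal(d$d12, brute(1, 2), tolerance = 1e-12)
  expect_equal(d$d13, brute(1, 3), tolerance = 1e-12)
  expect_equal(d$d23, brute(2, 3), tolerance = 1e-12)
})

test_that("identical sequences give zero distances and a tie flag", {
  w <- dna_alignment(c(P1 = "ACGT", P2 = "ACGT", P3 = "ACGT", O = "ACGT"))
  d <- window_distances(w)
  expect_equal(unlist(d), c(0, 0, 0), ignore_attr = TRUE)
  cl <- classify_window(d$d12, d$d13, d$d23, tau = 0.01)
  expect_true(cl$tie)
  expect_equal(cl$state, "V0")  # deterministic priority under ties
})

test_that("tau estimation uses the low quantile of the P3 distances", {
  d <- tibble::tibble(d12 = rep(0.01, 30), d13 = rep(0.03, 30),
                      d23 = rep(0.05, 30))
  expect_equal(estimate_tau_anc(d), 0.03)
  expect_error(estimate_tau_anc(d[1:5, ]), "at least 20")
})

test_that("tau recovers the ancestral divergence on simulated presets", {
  nw <- quartet_network(1, scale = 0.01)  # ancestral speciation at 2 units
  true_div <- 2 * 0.01 * 2                # 2 s t_anc
  taus <- sapply(1:5, function(s) {
    wg <- simulate_windowed_genome(nw, 150, 5000, seed = 40 + s)
    sc <- scan_genealogies(wg)
    sc$tau
  })
  expect_lt(abs(mean(taus) - true_div) / true_div, 0.15)
})

test_that("classification follows the distance rules", {
  expect_equal(classify_window(0.01, 0.05, 0.05, tau = 0.03)$state, "V0")
  expect_equal(classify_window(0.04, 0.05, 0.05, tau = 0.03)$state, "V1")
  expect_equal(classify_window(0.05, 0.02, 0.06, tau = 0.03)$state, "V2")
  expect_equal(classify_window(0.05, 0.06, 0.02, tau = 0.03)$state, "V3")
  expect_true(classify_window(0.02, 0.02, 0.05, tau = 0.03)$tie)
})

test_that("noiseless emission leaves decoded states unchanged", {
  states <- c("V0", "V0", "V2", "V3", "V1", "V0")
  sm <- hmm_smooth(states, rho = 0.8, eps = 0)
  expect_equal(sm$decoded, states)
  expect_true(all(abs(rowSums(sm$posterior) - 1) < 1e-12))
})

test_that("posterior decoding matches exhaustive enumeration", {
  states <- c("V0", "V2", "V2", "V0", "V3")
  rho <- 0.85
  eps <- 0.15
  sm <- hmm_smooth(states, rho = rho, eps = eps)
  # brute force over all 4^5 hidden paths
  n <- length(states)
  obs <- match(states, c("V0", "V1", "V2", "V3"))
  A <- matrix((1 - rho) / 3, 4, 4)
  diag(A) <- rho
  E <- matrix(eps / 3, 4, 4)
  diag(E) <- 1 - eps
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  pr <- rep(0.25, nrow(paths)) * E[paths[, 1], obs[1]]
  for (i in 2:n) {
    pr <- pr * A[cbind(paths[, i - 1], paths[, i])] * E[paths[, i], obs[i]]
  }
  post <- matrix(0, n, 4)
  for (i in 1:n) for (s in 1:4) post[i, s] <- sum(pr[paths[, i] == s])
  post <- post / rowSums(post)
  expect_equal(unname(sm$posterior), post, tolerance = 1e-12)
})

test_that("smoothing denoises corrupted labels of an autocorrelated truth", {
  # truth follows the HMM's own Markov chain; 10% of labels corrupted
  wins <- 0
  for (seed in 1:10) {
    res <- with_seed_test(seed, {
      n <- 300
      truth <- integer(n)
      truth[1] <- sample.int(4, 1)
      for (i in 2:n) {
        truth[i] <- if (runif(1) < 0.9) truth[i - 1] else sample.int(4, 1)
      }
      obs <- truth
      flip <- runif(n) < 0.1
      obs[flip] <- sapply(truth[flip], function(s) sample(setdiff(1:4, s), 1))
      states <- c("V0", "V1", "V2", "V3")
      sm <- hmm_smooth(states[obs], rho = 0.9, eps = 0.1)
      c(raw = mean(obs == truth), dec = mean(sm$decoded == states[truth]))
    })
    wins <- wins + (res["dec"] >= res["raw"])
  }
  expect_gte(wins, 9)
})

test_that("z-standardization is an exact normalization", {
  z <- z_standardized_ils(rep(c(0, 1), 10))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  zc <- z_standardized_ils(rep(0.5, 10))
  expect_true(attr(zc, "zero_variance"))
  expect_true(all(zc == 0))
  expect_error(z_standardized_ils(0.5), "at least 2")
})

test_that("scan fractions sum to one and ILS% is the V2+V3 share", {
  wg <- simulate_windowed_genome(quartet_network(0.5), 120, 1500, seed = 50)
  sc <- scan_genealogies(wg)
  s <- sc$summary
  expect_equal(s$f_v0 + s$f_v1 + s$f_v2 + s$f_v3, 1, tolerance = 1e-12)
  expect_equal(s$ils_percent, 100 * (s$f_v2 + s$f_v3), tolerance = 1e-12)
  expect_equal(nrow(sc$windows), 120)
  expect_equal(ils_percent(0.2, 0.1), 30)
  # windows z track normalized
  expect_equal(mean(sc$windows$z_ils), 0, tolerance = 1e-9)
  expect_equal(stats::sd(sc$windows$z_ils), 1, tolerance = 1e-9)
})

test_that("tidy and autoplot interfaces expose scan results", {
  wg <- simulate_windowed_genome(quartet_network(1), 40, 500, seed = 51)
  sc <- scan_genealogies(wg)
  expect_s3_class(tidy(sc), "tbl_df")
  expect_equal(nrow(glance(sc)), 1)
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
})
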