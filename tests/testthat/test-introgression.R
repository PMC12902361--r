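test_that("site patterns are classified per the ABBA/BABA/BBAA rules", {
  w <- dna_alignment(c(P1 = "ACCTAG", P2 = "AGCTAG", P3 = "AGCTTG",
                       O = "ACCTTG"))
  cc <- count_site_patterns(w)
  expect_equal(cc$n_abba, 1)  # column 2: C G G C
  expect_equal(cc$n_baba, 0)
  expect_equal(cc$n_bbaa, 1)  # column 5: A A T T
  # invariant or gapped columns contribute nothing
  w2 <- dna_alignment(c(P1 = "AAAN", P2 = "AAA-", P3 = "AAAA", O = "AAAA"))
  expect_equal(unlist(count_site_patterns(w2)), c(0, 0, 0),
               ignore_attr = TRUE)
  w3 <- dna_alignment(c(P1 = "CN", P2 = "GN", P3 = "GN", O = "CN"))
  expect_equal(count_site_patterns(w3)$n_abba, 1)
  expect_error(count_site_patterns(w3[1:3, ]), "4 rows")
})

test_that("D statistic arithmetic and degenerate cases", {
  expect_equal(d_statistic(50, 50), 0)
  expect_equal(d_statistic(100, 50), 1 / 3, tolerance = 1e-12)
  expect_warning(d <- d_statistic(0, 0), "undefined")
  expect_true(is.na(d))
})

test_that("D is antisymmetric under swapping P1 and P2", {
  # swapping P1 and P2 exchanges the ABBA and BABA roles
  nw <- quartet_network(1, events = data.frame(
    recipient = "P2", donor = "P3", time = 0.5, gamma = 0.3
  ))
  wg <- simulate_windowed_genome(nw, 60, 1000, seed = 21)
  pc <- pattern_counts(wg)
  d_fwd <- d_statistic(sum(pc$n_abba), sum(pc$n_baba))
  swapped <- wg
  swapped$alignments <- lapply(wg$alignments, function(a) a[c(2, 1, 3, 4), ])
  pc2 <- pattern_counts(swapped)
  d_rev <- d_statistic(sum(pc2$n_abba), sum(pc2$n_baba))
  expect_equal(d_fwd, -d_rev, tolerance = 1e-12)
})

test_that("block jackknife handles identical and degenerate blocks", {
  blocks <- tibble::tibble(n_abba = rep(5, 10), n_baba = rep(5, 10))
  r <- jackknife_z(blocks)
  expect_equal(r$D, 0)
  expect_equal(r$Z, 0)
  expect_error(jackknife_z(blocks[1, ]), "at least 2")
  # equal-count blocks: jackknife equals the classic delete-one formula
  b2 <- tibble::tibble(n_abba = c(10, 14, 8, 11), n_baba = c(9, 7, 12, 10))
  r2 <- jackknife_z(b2)
  dj <- sapply(1:4, function(j) {
    d_statistic(sum(b2$n_abba[-j]), sum(b2$n_baba[-j]))
  })
  expect_equal(r2$SE, sqrt(3 / 4 * sum((dj - mean(dj))^2)), tolerance = 1e-12)
})

test_that("bonferroni correction spans the arrangements of one call", {
  nw <- quartet_network(1)
  wgs <- lapply(1:3, function(s) simulate_windowed_genome(nw, 30, 500,
                                                          seed = 30 + s))
  res <- d_stat(wgs)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_bonferroni, pmin(res$p * 3, 1))
})

test_that("reticulation index matches binomial oracle values", {
  r <- reticulation_index(200, 200)
  expect_equal(r$ri, 0)
  expect_gt(r$p, 0.9)
  r2 <- reticulation_index(469, 99)
  expect_equal(r2$ri, 0.651, tolerance = 1e-3)
  expect_lt(r2$p, 1e-10)
  expect_equal(r2$p, stats::binom.test(469, 568, 0.5)$p.value)
  r3 <- reticulation_index(10, 0)
  expect_equal(r3$ri, 1)
  expect_equal(r3$p, 2 * 0.5^10, tolerance = 1e-12)
  r0 <- reticulation_index(0, 0)
  expect_equal(r0$ri, 0)
  expect_true(r0$low_signal)
  expect_error(reticulation_index(-1, 3), "nonnegative")
  # scale invariance
  expect_equal(reticulation_index(30, 10)$ri, reticulation_index(300, 100)$ri)
})

test_that("ILS/IH split conserves total discordance", {
  expect_equal(unlist(ils_ih_split(0.6, 0.2, 0.2)), c(0.4, 0),
               ignore_attr = TRUE)
  expect_equal(unlist(ils_ih_split(0.5, 0.3, 0.2)), c(0.4, 0.1),
               ignore_attr = TRUE)
  expect_error(ils_ih_split(0.5, 0.2, 0.2), "sum to 1")
  for (seed in 1:20) {
    f <- with_seed_test(seed, {
      x <- runif(3)
      x / sum(x)
    })
    s <- ils_ih_split(f[1], f[2], f[3])
    expect_equal(s$ils_share + s$ih_share, f[2] + f[3], tolerance = 1e-12)
  }
})

test_that("estimated ih_share grows with the admixture proportion", {
  means <- sapply(c(0, 0.2, 0.4), function(g) {
    ev <- if (g > 0) data.frame(recipient = "P2", donor = "P3",
                                time = 0.5, gamma = g)
    ih <- sapply(1:5, function(s) {
      sims <- simulate_gene_trees(quartet_network(1, events = ev), 800,
                                  seed = 100 * g + s)
      f <- table(factor(sims$class, levels = c("V0", "V1", "V2", "V3"))) / 800
      unname(abs(f[3] - f[4]))
    })
    mean(ih)
  })
  expect_true(all(diff(means) > 0))
})
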