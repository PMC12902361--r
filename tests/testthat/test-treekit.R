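test_that("JC distances match the closed form and brute-force counting", {
  aln <- fixture_two_seq(0.1)
  dm <- jc_distance_matrix(aln)
  expect_equal(dm["x", "y"], 0.10732, tolerance = 1e-4)
  # brute force column counting
  m <- unclass(aln)
  p <- mean(m[1, ] != m[2, ])
  expect_equal(dm["x", "y"], -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  expect_equal(dm["x", "x"], 0)
})

test_that("JC saturation and missing data are handled", {
  dm <- jc_distance_matrix(fixture_two_seq(0.75), cap = 5)
  expect_equal(dm["x", "y"], 5)
  expect_true(attr(dm, "saturated")["x", "y"])
  # pairwise deletion: N/gap columns dropped per pair
  aln <- dna_alignment(rbind(a = c("A", "N", "C", "G"),
                             b = c("A", "T", "C", "-"),
                             c = c("A", "T", "G", "G")))
  dm2 <- jc_distance_matrix(aln)
  expect_equal(dm2["a", "b"], 0)          # 2 comparable, both match
  expect_gt(dm2["a", "c"], 0)             # 1 mismatch of 3 comparable
  aln3 <- dna_alignment(rbind(a = c("A", "N"), b = c("N", "C"),
                              c = c("A", "C")))
  expect_error(jc_distance_matrix(aln3), "no comparable sites between a and b")
})

test_that("JC distance is strictly increasing in p below saturation", {
  ps <- seq(0.05, 0.7, by = 0.05)
  ds <- sapply(ps, function(p) jc_distance_matrix(
    fixture_two_seq(p, n = 2000)
  )["x", "y"])
  expect_true(all(diff(ds) > 0))
})

test_that("NJ recovers additive trees exactly", {
  for (seed in 1:10) {
    ntax <- sample(6:10, 1)
    tr <- with_seed_test(seed, {
      t <- ape::rtree(ntax)
      t$edge.length <- runif(nrow(t$edge), 0.05, 1)
      t
    })
    dm <- ape::cophenetic.phylo(tr)
    est <- nj_tree(dm)
    expect_equal(as.numeric(phangorn::RF.dist(est, ape::unroot(tr))), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-9)
  }
})

test_that("NJ resolves the hand-computed four-taxon case", {
  dm <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 0.2
  dm["c", "d"] <- dm["d", "c"] <- 0.2
  diag(dm) <- 0
  tr <- nj_tree(dm)
  expect_equal(bipartitions(tr), "a,b|c,d")
  # four-point condition: cross = 2 x 0.1 external + internal = 0.5
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal[internal > 0], 0.3, tolerance = 1e-9)
})

test_that("NJ three-taxon lengths follow the three-point formulas", {
  dm <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dm["a", "b"] <- dm["b", "a"] <- 0.3
  dm["a", "c"] <- dm["c", "a"] <- 0.5
  dm["b", "c"] <- dm["c", "b"] <- 0.6
  tr <- nj_tree(dm)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(len[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(len[["c"]], (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
  dm["a", "b"] <- 0.9
  expect_error(nj_tree(dm), "symmetric")
})

test_that("Newick parse/write round-trips and reports errors", {
  tr <- parse_newick("((A:1,B:1):0.5,C:1);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$edge.length[tr$edge[, 2] > 3], 0.5)
  rt <- parse_newick(write_newick(tr))
  expect_equal(write_newick(rt), write_newick(tr))
  expect_error(parse_newick("((A,B)"), "unbalanced")
  expect_error(parse_newick("((A,B),C));"), "position")
  expect_error(parse_newick("((A,A),B);"), "duplicate")
  # round-trip of simulated trees preserves topology and lengths
  sims <- simulate_gene_trees(quartet_network(1), 5, seed = 1)
  for (tr in sims$tree) {
    back <- parse_newick(write_newick(tr))
    expect_equal(as.numeric(phangorn::RF.dist(back, tr)), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("bipartitions enumerate exactly the internal splits", {
  expect_equal(bipartitions(parse_newick("((A,B),(C,D));")), "A,B|C,D")
  for (n in c(5, 8)) {
    tr <- random_chronogram(n, seed = n)
    expect_equal(length(bipartitions(tr)), n - 3)
  }
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(length(bipartitions(star)), 0)
})

test_that("OLS branch lengths recover additive inputs and flag noise", {
  tr <- fixture_tree6()
  dm <- ape::cophenetic.phylo(tr)
  fit <- ls_branch_lengths(tr, dm)
  expect_equal(ape::cophenetic.phylo(fit)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)
  noisy <- dm + with_seed_test(1, {
    e <- matrix(rnorm(36, 0, 1e-4), 6, 6)
    e <- (e + t(e)) / 2
    diag(e) <- 0
    e
  })
  fit2 <- ls_branch_lengths(tr, noisy)
  d2 <- ape::cophenetic.phylo(fit2)[rownames(dm), colnames(dm)]
  expect_lt(max(abs(d2 - dm)), 1e-3)
  expect_error(ls_branch_lengths(tr, dm[1:5, 1:5]), "same taxa")
})
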