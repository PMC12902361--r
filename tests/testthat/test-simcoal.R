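test_that("a deep internal branch leaves essentially no discordance", {
  nw <- quartet_network(50)
  sims <- simulate_gene_trees(nw, 300, seed = 1)
  expect_true(all(sims$class %in% c("V0", "V1")))
  expect_gte(sum(sims$class == "V0"), 299)
})

test_that("a zero-length internal branch gives the star-tree thirds", {
  nw <- quartet_network(0)
  sims <- simulate_gene_trees(nw, 3000, seed = 2)
  f <- table(factor(sims$class, levels = c("V0", "V1", "V2", "V3"))) / 3000
  expect_equal(unname(f[["V0"]]), 0, tolerance = 1e-12)
  expect_equal(unname(f[["V1"]]), 1 / 3, tolerance = 0.03)
  expect_equal(unname(f[["V2"]]), 1 / 3, tolerance = 0.03)
  expect_equal(unname(f[["V3"]]), 1 / 3, tolerance = 0.03)
})

test_that("concordance matches 1 - (2/3) exp(-t) across branch lengths", {
  n <- 4000
  for (t in c(0.5, 2)) {
    sims <- simulate_gene_trees(quartet_network(t), n, seed = 30 + t)
    conc <- mean(sims$class %in% c("V0", "V1"))
    expected <- 1 - (2 / 3) * exp(-t)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(conc - expected), 3 * se)
  }
})

test_that("class fractions sum to one and discordants balance without gene flow", {
  sims <- simulate_gene_trees(quartet_network(1), 4000, seed = 4)
  f <- table(factor(sims$class, levels = c("V0", "V1", "V2", "V3"))) / 4000
  expect_equal(sum(f), 1, tolerance = 1e-12)
  n23 <- sum(sims$class %in% c("V2", "V3"))
  expect_gt(stats::binom.test(sum(sims$class == "V2"), n23)$p.value, 0.001)
})

test_that("gene flow P3 -> P2 inflates the V3 class", {
  ev <- data.frame(recipient = "P2", donor = "P3", time = 0.5, gamma = 0.3)
  s0 <- simulate_gene_trees(quartet_network(1), 1500, seed = 5)
  s1 <- simulate_gene_trees(quartet_network(1, events = ev), 1500, seed = 5)
  expect_gt(mean(s1$class == "V3"), mean(s0$class == "V3") + 0.1)
  # full replacement: the P2-P3 pairing dominates
  ev1 <- data.frame(recipient = "P2", donor = "P3", time = 0.5, gamma = 1)
  s2 <- simulate_gene_trees(quartet_network(1, events = ev1), 400, seed = 6)
  # moved lineage pairs with P3 unless it escapes the shared branch:
  # expected V3 = (1 - E) + E/3 with E = exp(-1.5), about 0.85
  expect_gt(mean(s2$class == "V3"), 0.78)
})

test_that("simulation is deterministic and locus streams depend on index only", {
  nw <- quartet_network(1)
  a <- simulate_gene_trees(nw, 50, seed = 7)
  b <- simulate_gene_trees(nw, 50, seed = 7)
  expect_identical(lapply(a$tree, write_newick), lapply(b$tree, write_newick))
  expect_identical(a$class, b$class)
  c_long <- simulate_gene_trees(nw, 80, seed = 7)
  expect_identical(lapply(a$tree, write_newick),
                   lapply(c_long$tree[1:50], write_newick))
})

test_that("network validation enforces structure and event geometry", {
  expect_error(quartet_network(1, events = data.frame(
    recipient = "P2", donor = "P3", time = 0.5, gamma = 1.2
  )), "gamma")
  expect_error(quartet_network(1, events = data.frame(
    recipient = "P2", donor = "P3", time = 3, gamma = 0.1
  )), "lifetime")
  expect_error(quartet_network(1, events = data.frame(
    recipient = "nope", donor = "P3", time = 0.5, gamma = 0.1
  )), "unknown branch")
  expect_error(species_network("((A:1,B:2):1,C:2);", outgroup = "C"),
               "ultrametric")
  expect_error(species_network("((A:1,B:1):1,C:2);", outgroup = "Z"),
               "outgroup")
})

test_that("per-branch scale overrides change mutation-unit lengths only", {
  nw_fast <- species_network("((P1:1,P2:1):1,O:2);", outgroup = "O",
                             scale = 0.01,
                             branch_scale = c(P1 = 0.1),
                             roles = c(P1 = "P1", P2 = "P2", P3 = "O",
                                       O = "O"))
  sims <- simulate_gene_trees(nw_fast, 200, seed = 8)
  dm <- average_patristic_dm(sims)
  # P1's pendant branch accrues 10x the mutations of P2's
  expect_gt(dm["P1", "O"] / dm["P2", "O"], 2)
})

test_that("waterfowl presets are structurally sound", {
  full <- waterfowl_preset("full24")
  expect_equal(length(full$tree$tip.label), 25)
  expect_true(ape::is.binary(full$tree))
  expect_true(all(full$tree$edge.length > 0))
  expect_error(waterfowl_preset("nonexistent"))
  # gamma override: symmetric discordance
  nw <- waterfowl_preset("screamer_magpie", gamma = 0)
  sims <- simulate_gene_trees(nw, 2500, seed = 9)
  c2 <- sum(sims$class == "V2")
  c3 <- sum(sims$class == "V3")
  expect_gt(stats::binom.test(c2, c2 + c3)$p.value, 0.001)
})

test_that("network round-trips through Newick + event TSV", {
  nw <- waterfowl_preset("mallard_complex")
  stem <- file.path(withr::local_tempdir(), "net")
  write_network(nw, stem)
  back <- read_network(stem)
  expect_equal(back$scale, nw$scale)
  expect_equal(back$outgroup, nw$outgroup)
  expect_equal(back$roles, nw$roles)
  expect_equal(back$events$gamma, nw$events$gamma)
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(back$tree),
                                            ape::unroot(nw$tree))), 0)
})
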