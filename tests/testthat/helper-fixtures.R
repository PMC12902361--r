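# Shared fixtures built in code.

# A small ultrametric 6-taxon chronogram (coalescent units).
fixture_tree6 <- function() {
  ape::read.tree(text = paste0(
    "(((a:1,b:1):0.5,(c:0.8,d:0.8):0.7):1.5,(e:2,f:2):1):0;"
  ))
}

# Random ultrametric tree via coalescent (for property tests).
random_chronogram <- function(n, seed) {
  with_seed_test(seed, ape::rcoal(n, tip.label = paste0("t", seq_len(n))))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Alignment with known pairwise mismatch proportion between two taxa.
fixture_two_seq <- function(p, n = 1000) {
  k <- round(p * n)
  a <- rep("A", n)
  b <- c(rep("C", k), rep("A", n - k))
  dna_alignment(rbind(x = a, y = b))
}
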