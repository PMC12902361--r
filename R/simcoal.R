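# Multispecies-coalescent simulation with introgression pulses.
#
# Time runs root-ward from 0 at the tips, in coalescent units of 2N
# generations. Each species-tree branch hosts a population identified by
# the node at its tipward end; within a population k lineages coalesce at
# rate k(k-1)/2 per unit. At a species-tree node the two child populations
# merge; at an introgression pulse every lineage on the recipient branch
# independently relocates to the donor branch with probability gamma. The
# root population runs unbounded until a single lineage remains.

build_schedule <- function(network) {
  tree <- network$tree
  ntip <- length(tree$tip.label)
  m <- ntip + tree$Nnode
  ages <- network$ages
  internal <- (ntip + 1L):m

  b_time <- ages[internal]
  b_type <- rep(1L, length(internal))   # 1 = merge
  b_a <- internal
  b_b <- rep(0L, length(internal))
  b_gamma <- rep(0, length(internal))
  # equal-time merges must run child-before-parent so no population is
  # merged away before receiving its lineages; break time ties by
  # postorder rank (pulses cannot coincide with merges by validation)
  post <- ape::reorder.phylo(tree, "postorder")
  rank_of <- integer(m)
  rank_of[unique(post$edge[, 1])] <- seq_along(unique(post$edge[, 1]))
  tie_rank <- rank_of[internal]
  if (nrow(network$events)) {
    b_time <- c(b_time, network$events$time)
    b_type <- c(b_type, rep(2L, nrow(network$events)))  # 2 = pulse
    b_a <- c(b_a, network$events$recipient_node)
    b_b <- c(b_b, network$events$donor_node)
    b_gamma <- c(b_gamma, network$events$gamma)
    tie_rank <- c(tie_rank, rep(m + 1L, nrow(network$events)))
  }
  o <- order(b_time, tie_rank)

  children <- vector("list", m)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }

  pop_scale <- rep(network$scale, m)
  if (!is.null(network$branch_scale)) {
    idx <- match(names(network$branch_scale), network$node_names)
    pop_scale[idx] <- network$branch_scale
  }

  roles_info <- NULL
  if (!is.null(network$roles)) {
    trio <- match(network$roles[c("P1", "P2", "P3")], tree$tip.label)
    anc <- ape::getMRCA(tree, trio)
    roles_info <- list(trio = trio, t_anc = ages[anc])
  }

  list(
    ntip = ntip, m = m,
    b_time = b_time[o], b_type = b_type[o], b_a = b_a[o], b_b = b_b[o],
    b_gamma = b_gamma[o],
    children = children, pop_scale = pop_scale, roles = roles_info,
    tip_label = tree$tip.label
  )
}

# Simulate one gene genealogy. Returns parent pointers, node ages
# (coalescent units) and per-edge mutation-unit lengths.
sim_locus_raw <- function(sch) {
  n <- sch$ntip
  m <- 2L * n - 1L
  gparent <- integer(m)
  gage <- numeric(m)
  mlen <- numeric(m)     # mutation-unit length of the edge above each node
  acc <- numeric(m)      # accrued mutation length since node creation
  t_last <- numeric(m)   # time of last accrual
  pop_of <- integer(m)
  pop_of[seq_len(n)] <- seq_len(n)
  nxt <- n
  t_cur <- 0
  nb <- length(sch$b_time)

  for (bi in seq_len(nb + 1L)) {
    t_end <- if (bi <= nb) sch$b_time[bi] else Inf
    if (t_end > t_cur) {
      for (p in unique(pop_of[pop_of > 0L])) {
        lin <- which(pop_of == p)
        k <- length(lin)
        s <- sch$pop_scale[p]
        t <- t_cur
        while (k >= 2L) {
          dt <- stats::rexp(1L, k * (k - 1L) / 2)
          if (t + dt >= t_end) break
          t <- t + dt
          pair <- lin[sample.int(k, 2L)]
          acc[pair] <- acc[pair] + (t - t_last[pair]) * s
          t_last[pair] <- t
          mlen[pair] <- acc[pair]
          nxt <- nxt + 1L
          gparent[pair] <- nxt
          gage[nxt] <- t
          t_last[nxt] <- t
          pop_of[pair] <- 0L
          pop_of[nxt] <- p
          lin <- c(lin[!lin %in% pair], nxt)
          k <- k - 1L
        }
        if (is.finite(t_end) && k >= 1L) {
          acc[lin] <- acc[lin] + (t_end - t_last[lin]) * s
          t_last[lin] <- t_end
        }
      }
      t_cur <- t_end
    }
    if (bi <= nb) {
      if (sch$b_type[bi] == 1L) {
        kids <- sch$children[[sch$b_a[bi]]]
        pop_of[pop_of %in% kids] <- sch$b_a[bi]
      } else {
        rec <- which(pop_of == sch$b_a[bi])
        if (length(rec)) {
          move <- rec[stats::runif(length(rec)) < sch$b_gamma[bi]]
          pop_of[move] <- sch$b_b[bi]
        }
      }
    }
  }
  list(gparent = gparent, gage = gage, mlen = mlen)
}

# Age of the MRCA of tips a and b given parent pointers.
pair_tmrca <- function(gparent, gage, a, b) {
  anc <- integer(0)
  x <- a
  while (x != 0L) {
    anc <- c(anc, x)
    x <- gparent[x]
  }
  x <- b
  while (!x %in% anc) x <- gparent[x]
  gage[x]
}

# V0-V3 class of a quartet genealogy given trio tip ids and the ancestral
# speciation age.
locus_class <- function(loc, trio, t_anc) {
  t12 <- pair_tmrca(loc$gparent, loc$gage, trio[1], trio[2])
  t13 <- pair_tmrca(loc$gparent, loc$gage, trio[1], trio[3])
  t23 <- pair_tmrca(loc$gparent, loc$gage, trio[2], trio[3])
  i <- which.min(c(t12, t13, t23))
  if (i == 2L) return("V2")
  if (i == 3L) return("V3")
  if (t12 < t_anc) "V0" else "V1"
}

# Convert a raw simulated genealogy to an ape phylo (cladewise edge order,
# root = ntip + 1). Branch lengths in mutation units (substitutions/site).
raw_to_phylo <- function(loc, tip_label) {
  n <- length(tip_label)
  m <- 2L * n - 1L
  new_id <- c(seq_len(n), (m):(n + 1L))  # internal ids reversed: root first
  root_old <- m
  kids <- vector("list", m)
  for (x in seq_len(m - 1L)) {
    p <- loc$gparent[x]
    kids[[p]] <- c(kids[[p]], x)
  }
  edge <- matrix(0L, m - 1L, 2L)
  elen <- numeric(m - 1L)
  stack <- root_old
  r <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (ch in kids[[v]]) {
      r <- r + 1L
      edge[r, ] <- c(new_id[v], new_id[ch])
      elen[r] <- loc$mlen[ch]
      if (ch > n) stack <- c(stack, ch)
    }
  }
  structure(
    list(edge = edge, edge.length = elen, tip.label = tip_label,
         Nnode = n - 1L),
    class = "phylo", order = "cladewise"
  )
}

#' Simulate gene trees under the multispecies coalescent with introgression
#'
#' Each locus is an independent draw from the structured coalescent on the
#' species network: lineages coalesce within branches at rate
#' `k(k-1)/2` per coalescent unit, pass to the parent branch when
#' uncoalesced, and relocate across introgression pulses with probability
#' `gamma`. Branch lengths of the returned trees are in substitutions per
#' site (coalescent times multiplied by the network's per-branch scale).
#'
#' For four-taxon networks with assigned roles, the true genealogy class
#' is recorded per locus: `V0` (species topology, sister coalescence below
#' the ancestral speciation), `V1` (species topology, deep coalescence),
#' `V2` (P1 pairs with P3), `V3` (P2 pairs with P3).
#'
#' @param network A [species_network()].
#' @param n_loci Number of independent loci.
#' @param seed Master seed; per-locus seeds are derived deterministically
#'   by locus index, so locus `i` is reproducible regardless of `n_loci`.
#' @return A tibble with columns `locus`, `tree` (list of `phylo`) and
#'   `class` (character, `NA` when the network has no quartet roles).
#' @examples
#' nw <- quartet_network(1.0)
#' sims <- simulate_gene_trees(nw, 100, seed = 1)
#' table(sims$class)
#' @export
simulate_gene_trees <- function(network, n_loci, seed = NULL) {
  stopifnot(inherits(network, "species_network"))
  if (!is.numeric(n_loci) || n_loci < 1) stop_bad("n_loci must be >= 1")
  sch <- build_schedule(network)
  seeds <- derive_seeds(seed, n_loci)
  trees <- vector("list", n_loci)
  cls <- rep(NA_character_, n_loci)
  for (i in seq_len(n_loci)) {
    loc <- with_seed(seeds[i], sim_locus_raw(sch))
    trees[[i]] <- raw_to_phylo(loc, sch$tip_label)
    if (!is.null(sch$roles)) {
      cls[i] <- locus_class(loc, sch$roles$trio, sch$roles$t_anc)
    }
  }
  out <- tibble::tibble(locus = seq_len(n_loci), tree = trees, class = cls)
  attr(out, "network") <- network
  out
}

#' Write simulated gene trees to a Newick file (one tree per line)
#'
#' @param gene_trees A tibble from [simulate_gene_trees()] or a list of
#'   `phylo` objects.
#' @param path Output file.
#' @export
write_gene_trees <- function(gene_trees, path) {
  trees <- if (is.data.frame(gene_trees)) gene_trees$tree else gene_trees
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}
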