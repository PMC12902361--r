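# Per-branch genealogical concordance: gCF, quartet frequencies f1/f2/f3,
# coalescent-unit branch lengths from f1, and the Theta ratio.

#' Internal branches of a reference tree with their four adjacent clades
#'
#' Enumerates the internal branches of the (unrooted) reference tree. For
#' each branch the four adjacent clades are reported: A and B on one side,
#' C and D on the other (each side's pair ordered by its lexicographically
#' smallest taxon). Quartet classification pairs one representative per
#' clade: the species resolution is AB|CD, `alt1` pairs A with C, `alt2`
#' pairs A with D.
#'
#' @param ref_tree A `phylo` with >= 4 leaves (rooted trees are unrooted
#'   internally).
#' @return A tibble with `branch_id`, `split` (canonical bipartition) and
#'   list-columns `clade_a` .. `clade_d`.
#' @export
ref_branches <- function(ref_tree) {
  stopifnot(inherits(ref_tree, "phylo"))
  n <- length(ref_tree$tip.label)
  if (n < 4) stop_bad("need at least 4 leaves")
  un <- if (ape::is.rooted(ref_tree)) ape::unroot(ref_tree) else ref_tree
  un <- ape::reorder.phylo(un, "cladewise")
  labs <- un$tip.label
  m <- n + un$Nnode
  root <- un$edge[1, 1]

  # tip sets below each node
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- labs[i]
  for (e in rev(seq_len(nrow(un$edge)))) {
    p <- un$edge[e, 1]
    ch <- un$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  kids <- vector("list", m)
  for (e in seq_len(nrow(un$edge))) {
    kids[[un$edge[e, 1]]] <- c(kids[[un$edge[e, 1]]], un$edge[e, 2])
  }

  ord_pair <- function(x, y) {
    if (min(y) < min(x)) list(y, x) else list(x, y)
  }
  rows <- list()
  for (e in seq_len(nrow(un$edge))) {
    v <- un$edge[e, 2]
    if (v <= n) next  # pendant branch
    u <- un$edge[e, 1]
    ab <- ord_pair(below[[kids[[v]][1]]], below[[kids[[v]][2]]])
    if (u == root) {
      others <- setdiff(kids[[u]], v)
      cd <- ord_pair(below[[others[1]]], below[[others[2]]])
    } else {
      sib <- setdiff(kids[[u]], v)
      cd <- ord_pair(below[[sib[1]]], setdiff(labs, below[[u]]))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      split = canonical_split(unlist(ab), labs),
      clade_a = list(ab[[1]]), clade_b = list(ab[[2]]),
      clade_c = list(cd[[1]]), clade_d = list(cd[[2]])
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tibble::tibble(branch_id = paste0("B", seq_len(nrow(out)))),
                   out)
}

# Clade membership matrix of a gene tree (one row per clade incl. root).
gene_tree_clades <- function(gt) {
  pp <- ape::prop.part(gt)
  nt <- length(gt$tip.label)
  L <- matrix(FALSE, length(pp), nt)
  for (k in seq_along(pp)) L[k, pp[[k]]] <- TRUE
  colnames(L) <- attr(pp, "labels")
  L
}

classify_quartet <- function(L, idx) {
  sub <- L[, idx, drop = FALSE]
  rs <- rowSums(sub)
  cand <- which(rs == 2L)
  for (r in cand) {
    v <- sub[r, ]
    if (v[1] && v[2]) return("concordant")
    if (v[3] && v[4]) return("concordant")
    if (v[1] && v[3]) return("alt1")
    if (v[2] && v[4]) return("alt1")
    if (v[1] && v[4]) return("alt2")
    if (v[2] && v[3]) return("alt2")
  }
  "non_decisive"
}

#' Classify one gene tree at one reference branch
#'
#' Picks one representative per adjacent clade (the lexicographically
#' smallest leaf present in the gene tree) and reads the induced quartet
#' resolution off the gene tree: `concordant` (AB|CD), `alt1` (AC|BD),
#' `alt2` (AD|BC), or `non_decisive` when a clade has no representative or
#' the quartet is unresolved.
#'
#' @param ref_tree Reference `phylo` (or a [ref_branches()] tibble).
#' @param branch_id Branch id as in [ref_branches()].
#' @param gene_tree A `phylo`; its leaf set may be a subset of the
#'   reference leaves.
#' @return One of `"concordant"`, `"alt1"`, `"alt2"`, `"non_decisive"`.
#' @export
classify_gene_tree_at_branch <- function(ref_tree, branch_id, gene_tree) {
  br <- if (is.data.frame(ref_tree)) ref_tree else ref_branches(ref_tree)
  row <- br[br$branch_id == branch_id, ]
  if (nrow(row) != 1) stop_bad("unknown or non-internal branch: ", branch_id)
  L <- gene_tree_clades(gene_tree)
  tips <- colnames(L)
  reps <- vapply(
    list(row$clade_a[[1]], row$clade_b[[1]], row$clade_c[[1]],
         row$clade_d[[1]]),
    function(cl) {
      pres <- sort(intersect(cl, tips))
      if (length(pres)) pres[1] else NA_character_
    },
    ""
  )
  if (anyNA(reps)) return("non_decisive")
  classify_quartet(L, match(reps, tips))
}

as_tree_list <- function(gene_trees) {
  if (is.data.frame(gene_trees)) return(gene_trees$tree)
  if (inherits(gene_trees, "phylo")) return(list(gene_trees))
  gene_trees
}

#' Gene concordance factors and quartet frequencies per branch
#'
#' For every internal branch of the reference tree, counts the decisive
#' gene trees supporting the species resolution (`c1`) and the two
#' alternatives (`c2`, `c3`), and reports the frequencies `f1`, `f2`, `f3`
#' and `gCF = 100 f1` over decisive trees only. Branches with no decisive
#' gene tree get `NA` frequencies.
#'
#' @param ref_tree Reference `phylo`.
#' @param gene_trees A tibble from [simulate_gene_trees()], a list of
#'   `phylo`, or a `multiPhylo`.
#' @return A tibble: `branch_id`, `split`, `n_decisive`, `c1`, `c2`, `c3`,
#'   `f1`, `f2`, `f3`, `gcf`.
#' @examples
#' nw <- quartet_network(1)
#' sims <- simulate_gene_trees(nw, 200, seed = 1)
#' gcf_table(nw$tree, sims)
#' @export
gcf_table <- function(ref_tree, gene_trees) {
  trees <- as_tree_list(gene_trees)
  if (!length(trees)) stop_bad("need at least one gene tree")
  br <- ref_branches(ref_tree)
  nb <- nrow(br)
  counts <- matrix(0L, nb, 4,
                   dimnames = list(NULL, c("concordant", "alt1", "alt2",
                                           "non_decisive")))
  # default representatives (lexicographic minimum of each clade) apply
  # whenever a gene tree carries the full reference leaf set
  all_taxa <- sort(unique(c(unlist(br$clade_a), unlist(br$clade_b),
                            unlist(br$clade_c), unlist(br$clade_d))))
  rep_def <- cbind(
    vapply(br$clade_a, function(x) sort(x)[1], ""),
    vapply(br$clade_b, function(x) sort(x)[1], ""),
    vapply(br$clade_c, function(x) sort(x)[1], ""),
    vapply(br$clade_d, function(x) sort(x)[1], "")
  )
  for (gt in trees) {
    L <- gene_tree_clades(gt)
    tips <- colnames(L)
    complete <- length(tips) == length(all_taxa) && all(all_taxa %in% tips)
    for (b in seq_len(nb)) {
      if (complete) {
        reps <- rep_def[b, ]
        ok <- TRUE
      } else {
        reps <- character(4)
        ok <- TRUE
        cls <- list(br$clade_a[[b]], br$clade_b[[b]], br$clade_c[[b]],
                    br$clade_d[[b]])
        for (q in 1:4) {
          pres <- intersect(cls[[q]], tips)
          if (!length(pres)) {
            ok <- FALSE
            break
          }
          reps[q] <- sort(pres)[1]
        }
      }
      cl <- if (ok) classify_quartet(L, match(reps, tips)) else "non_decisive"
      counts[b, cl] <- counts[b, cl] + 1L
    }
  }
  nd <- rowSums(counts[, 1:3, drop = FALSE])
  f1 <- ifelse(nd > 0, counts[, 1] / nd, NA_real_)
  f2 <- ifelse(nd > 0, counts[, 2] / nd, NA_real_)
  f3 <- ifelse(nd > 0, counts[, 3] / nd, NA_real_)
  tibble::tibble(
    branch_id = br$branch_id, split = br$split,
    n_decisive = as.integer(nd),
    c1 = counts[, 1], c2 = counts[, 2], c3 = counts[, 3],
    f1 = f1, f2 = f2, f3 = f3, gcf = 100 * f1
  )
}

#' Coalescent-unit branch length from the concordant quartet frequency
#'
#' Inverts the multispecies-coalescent concordance law
#' `f1 = 1 - (2/3) exp(-t)`: `t = -log(3 (1 - f1) / 2)`. Frequencies at or
#' below the star-tree value 1/3 give `t = 0` with a `low_signal` flag;
#' `f1 = 1` is capped (`saturated` flag).
#'
#' @param f1 Concordant-topology frequency in `[0, 1]` (vectorized).
#' @param cap Cap for `f1 = 1` (default 10 coalescent units).
#' @return Numeric vector of coalescent-unit lengths with attribute
#'   `"flag"` (`"ok"`, `"low_signal"`, `"saturated"`; `NA` input gives
#'   `"undefined"`).
#' @export
coalescent_length_from_f1 <- function(f1, cap = 10) {
  if (any(stats::na.omit(f1) < 0 | stats::na.omit(f1) > 1)) {
    stop_bad("f1 must lie in [0, 1]")
  }
  t <- -log(3 * (1 - f1) / 2)
  flag <- rep("ok", length(f1))
  flag[!is.na(f1) & f1 <= 1 / 3] <- "low_signal"
  t[!is.na(f1) & f1 <= 1 / 3] <- 0
  sat <- !is.na(f1) & t > cap
  t[sat] <- cap
  flag[sat] <- "saturated"
  flag[is.na(f1)] <- "undefined"
  structure(t, flag = flag)
}

#' Theta: mutation-unit over coalescent-unit branch length
#'
#' The per-branch population-mutation proxy: the ratio of a branch's
#' length in substitutions/site to its length in coalescent units.
#' Undefined (NA) when the coalescent length is zero.
#'
#' @param mut_len Branch length in substitutions/site (>= 0, vectorized).
#' @param coal_len Branch length in coalescent units.
#' @return Numeric vector; `NA` where undefined.
#' @export
theta_per_branch <- function(mut_len, coal_len) {
  if (any(stats::na.omit(mut_len) < 0) || any(stats::na.omit(coal_len) < 0)) {
    stop_bad("negative branch lengths")
  }
  ifelse(is.na(coal_len) | coal_len == 0, NA_real_, mut_len / coal_len)
}

#' Average patristic distance matrix over gene trees
#'
#' Mean pairwise tip-to-tip path length (substitutions/site) across loci;
#' the mutation-unit distance input for [ls_branch_lengths()].
#'
#' @param gene_trees As in [gcf_table()]; all trees must share one leaf set.
#' @return A symmetric numeric matrix.
#' @export
average_patristic_dm <- function(gene_trees) {
  trees <- as_tree_list(gene_trees)
  taxa <- sort(trees[[1]]$tip.label)
  acc <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  for (gt in trees) {
    cp <- ape::cophenetic.phylo(gt)
    acc <- acc + cp[taxa, taxa]
  }
  acc / length(trees)
}

#' Mutation-unit lengths of internal branches
#'
#' Fits OLS branch lengths on the reference topology from a mutation-unit
#' distance matrix (by default the average patristic distances of the gene
#' trees) and returns the internal-branch lengths keyed by bipartition.
#'
#' @param ref_tree Reference `phylo`.
#' @param gene_trees Gene trees used to build the distance matrix; ignored
#'   when `dm` is given.
#' @param dm Optional precomputed mutation-unit distance matrix.
#' @return A tibble `split`, `mut_len`.
#' @export
branch_mut_lengths <- function(ref_tree, gene_trees = NULL, dm = NULL) {
  if (is.null(dm)) {
    if (is.null(gene_trees)) stop_bad("supply gene_trees or dm")
    dm <- average_patristic_dm(gene_trees)
  }
  fit <- ls_branch_lengths(ref_tree, dm)
  n <- length(fit$tip.label)
  labs <- fit$tip.label
  below <- vector("list", n + fit$Nnode)
  for (i in seq_len(n)) below[[i]] <- labs[i]
  ord <- ape::reorder.phylo(fit, "cladewise")
  for (e in rev(seq_len(nrow(ord$edge)))) {
    p <- ord$edge[e, 1]
    below[[p]] <- c(below[[p]], below[[ord$edge[e, 2]]])
  }
  rows <- list()
  for (e in seq_len(nrow(ord$edge))) {
    v <- ord$edge[e, 2]
    if (v <= n) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      split = canonical_split(below[[v]], labs),
      mut_len = ord$edge.length[e]
    )
  }
  dplyr::bind_rows(rows)
}
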