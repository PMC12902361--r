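# Desk-scale tree machinery: JC distances, neighbor joining, Newick I/O,
# bipartitions, and least-squares branch lengths on a fixed topology.

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise deletion: each pair of taxa is compared only on columns where
#' both carry an unambiguous A/C/G/T. The JC69 correction
#' `d = -(3/4) log(1 - 4p/3)` is applied to the mismatch proportion `p`;
#' pairs at or beyond the JC saturation point (`p >= 0.75`) are flagged and
#' assigned the documented cap.
#'
#' @param aln A [dna_alignment()] or coercible matrix.
#' @param cap Distance assigned to saturated pairs (default 5).
#' @return A symmetric numeric matrix of class `jc_dist` with a logical
#'   attribute `"saturated"` marking capped pairs.
#' @export
jc_distance_matrix <- function(aln, cap = 5) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 2) stop_bad("need at least 2 taxa")
  code <- matrix(match(m, DNA_STATES), nrow(m), ncol(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    xi <- code[i, ]
    for (j in (i + 1):n) {
      xj <- code[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      nc <- sum(ok)
      if (nc == 0) {
        stop_bad("no comparable sites between ", rownames(m)[i], " and ",
                 rownames(m)[j])
      }
      p <- sum(xi[ok] != xj[ok]) / nc
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- cap
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  structure(d, saturated = sat, class = c("jc_dist", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape's NJ implementation) with negative
#' estimated branch lengths clipped to zero.
#'
#' @param dm A symmetric nonnegative distance matrix with taxon dimnames.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(dm) {
  dm <- unclass(dm)
  attr(dm, "saturated") <- NULL
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop_bad("dm must be square")
  if (nrow(dm) < 3) stop_bad("need at least 3 taxa")
  if (any(dm < 0)) stop_bad("negative distances")
  if (max(abs(dm - t(dm))) > 1e-8) stop_bad("distance matrix must be symmetric")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Parse / write Newick
#'
#' Wrappers over ape's Newick reader/writer adding position-reporting
#' checks for unbalanced parentheses and duplicate leaf names.
#'
#' @param text A Newick string.
#' @param tree A `phylo`.
#' @return `parse_newick()` a `phylo`; `write_newick()` a Newick string.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop_bad("unbalanced ')' at position ", i)
  }
  if (depth != 0L) {
    stop_bad("unbalanced '(': ", depth, " unclosed at end of string")
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop_bad("could not parse Newick string")
  if (anyDuplicated(tr$tip.label)) {
    stop_bad("duplicate leaf names: ",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = " "))
  }
  tr
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

canonical_split <- function(side, all_taxa) {
  side <- sort(side)
  other <- sort(setdiff(all_taxa, side))
  if (other[1] < side[1]) {
    tmp <- side
    side <- other
    other <- tmp
  }
  paste0(paste(side, collapse = ","), "|", paste(other, collapse = ","))
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal branch of the unrooted tree, in canonical
#' form (the side containing the lexicographically smallest taxon first,
#' taxa sorted within sides). Trivial (single-leaf) splits are excluded.
#'
#' @param tree A `phylo` with >= 4 leaves.
#' @return A character vector of canonical split strings.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4) stop_bad("need at least 4 leaves")
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pp <- ape::prop.part(un)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (k in seq_along(pp)) {
    sz <- length(pp[[k]])
    if (sz >= 2 && sz <= n - 2) {
      out <- c(out, canonical_split(labs[pp[[k]]], labs))
    }
  }
  unique(out)
}

#' Ordinary-least-squares branch lengths on a fixed topology
#'
#' Solves the path-incidence system `A b = d` for branch lengths `b` given
#' pairwise distances `d`, by OLS. Negative estimates are clipped to zero
#' (flagged via the `"clipped"` attribute).
#'
#' @param topology A `phylo`; its branch lengths are ignored.
#' @param dm Distance matrix over the same taxa.
#' @return The topology with OLS `edge.length`.
#' @export
ls_branch_lengths <- function(topology, dm) {
  stopifnot(inherits(topology, "phylo"))
  dm <- unclass(dm)
  taxa <- topology$tip.label
  if (!all(taxa %in% rownames(dm)) || length(taxa) != nrow(dm)) {
    stop_bad("topology and distance matrix must cover the same taxa")
  }
  dm <- dm[taxa, taxa]
  # the two root edges of a rooted topology are not separately identifiable
  # from path lengths; fit on the unrooted tree
  tr <- if (ape::is.rooted(topology)) ape::unroot(topology) else topology
  n <- length(taxa)
  ne <- nrow(tr$edge)
  # edge chains tip -> root
  parent_edge <- integer(n + tr$Nnode)
  parent_edge[tr$edge[, 2]] <- seq_len(ne)
  parent_node <- integer(n + tr$Nnode)
  parent_node[tr$edge[, 2]] <- tr$edge[, 1]
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  chain <- function(tip) {
    e <- integer(0)
    v <- tip
    while (v != root) {
      e <- c(e, parent_edge[v])
      v <- parent_node[v]
    }
    e
  }
  chains <- lapply(seq_len(n), chain)
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), ne)
  dvec <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    path <- c(setdiff(chains[[i]], chains[[j]]),
              setdiff(chains[[j]], chains[[i]]))
    A[k, path] <- 1
    dvec[k] <- dm[i, j]
  }
  qrA <- qr(A)
  if (qrA$rank < ne) stop_bad("singular path-incidence system")
  b <- qr.coef(qrA, dvec)
  clipped <- b < 0
  b[clipped] <- 0
  tr$edge.length <- as.numeric(b)
  attr(tr, "clipped") <- any(clipped)
  tr
}
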