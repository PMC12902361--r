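#' Simulate a sequence alignment along a gene tree
#'
#' Evolves nucleotide states along a fixed tree: the root sequence is drawn
#' from the model's equilibrium frequencies and each branch applies the
#' model's transition probabilities for its length (expected substitutions
#' per site). Deterministic given `seed`.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param length Number of sites (>= 1).
#' @param model A [sub_model()]; default JC69.
#' @param seed Optional seed.
#' @return A [dna_alignment()] with one row per tip.
#' @examples
#' nw <- quartet_network(1)
#' tr <- simulate_gene_trees(nw, 1, seed = 1)$tree[[1]]
#' aln <- simulate_alignment(tr, 100, seed = 1)
#' @export
simulate_alignment <- function(tree, length, model = sub_model("JC69"),
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length < 1) stop_bad("alignment length must be >= 1")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop_bad("tree needs nonnegative branch lengths in substitutions/site")
  }
  if (!inherits(model, "sub_model")) stop_bad("invalid substitution model")
  if (is.null(attr(tree, "order")) || attr(tree, "order") != "cladewise") {
    tree <- ape::reorder.phylo(tree, "cladewise")
  }
  with_seed(seed, {
    n <- length(tree$tip.label)
    m <- n + tree$Nnode
    states <- vector("list", m)
    root <- tree$edge[1, 1]
    states[[root]] <- sample.int(4L, length, replace = TRUE,
                                 prob = model$base_freqs)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      P <- transition_matrix(model, tree$edge.length[e])
      c1 <- P[, 1]
      c2 <- c1 + P[, 2]
      c3 <- c2 + P[, 3]
      ps <- states[[par]]
      # inverse-CDF draw vectorized over sites
      u <- stats::runif(length)
      states[[ch]] <- 1L + (u > c1[ps]) + (u > c2[ps]) + (u > c3[ps])
    }
    out <- matrix("", n, length, dimnames = list(tree$tip.label, NULL))
    for (i in seq_len(n)) out[i, ] <- DNA_STATES[states[[i]]]
    structure(out, class = c("dna_alignment", class(matrix())))
  })
}

#' Simulate a windowed four-taxon "genome": independent MSC windows
#'
#' Emulates the non-overlapping-window structure of a whole-genome
#' alignment: each window draws an independent genealogy from the species
#' network (free recombination between windows, none within) and a
#' sequence alignment along it. The true genealogy class (V0--V3, see
#' [scan_genealogies()]) is recorded per window so classification accuracy
#' can be measured against the simulation truth.
#'
#' @param network A [species_network()].
#' @param n_windows Number of windows.
#' @param window_len Sites per window.
#' @param quartet Optional four taxon names in role order `(P1, P2, P3,
#'   outgroup)`; defaults to the network's own roles (4-taxon networks).
#' @param model A [sub_model()].
#' @param seed Master seed (per-window streams derived by window index).
#' @return A `windowed_genome`: list with `windows` (tibble: `window`
#'   0-based index, `start`, `end` 0-based half-open, `true_class`),
#'   `alignments` (list of [dna_alignment()] with rows P1, P2, P3, O),
#'   `roles`, and `window_len`.
#' @export
simulate_windowed_genome <- function(network, n_windows, window_len,
                                     quartet = NULL,
                                     model = sub_model("JC69"),
                                     seed = NULL) {
  stopifnot(inherits(network, "species_network"))
  if (window_len < 1) stop_bad("window_len must be >= 1")
  if (n_windows < 1) stop_bad("n_windows must be >= 1")
  tips <- network$tree$tip.label
  if (is.null(quartet)) {
    if (is.null(network$roles)) {
      stop_bad("supply `quartet` (P1, P2, P3, O) for networks with > 4 taxa")
    }
    roles <- network$roles
  } else {
    if (length(quartet) != 4 || !all(quartet %in% tips)) {
      stop_bad("quartet must name 4 taxa of the network")
    }
    roles <- c(P1 = quartet[1], P2 = quartet[2], P3 = quartet[3],
               O = quartet[4])
  }
  sch <- build_schedule(network)
  trio <- match(roles[c("P1", "P2", "P3")], tips)
  anc <- ape::getMRCA(network$tree, trio)
  t_anc <- network$ages[anc]
  prune <- length(tips) > 4

  seeds <- derive_seeds(seed, n_windows)
  alns <- vector("list", n_windows)
  cls <- character(n_windows)
  for (i in seq_len(n_windows)) {
    res <- with_seed(seeds[i], {
      loc <- sim_locus_raw(sch)
      k <- locus_class(loc, trio, t_anc)
      tr <- raw_to_phylo(loc, sch$tip_label)
      if (prune) tr <- ape::keep.tip(tr, unname(roles))
      a <- simulate_alignment(tr, window_len, model)
      list(cls = k, aln = a[unname(roles), , drop = FALSE])
    })
    cls[i] <- res$cls
    alns[[i]] <- res$aln
  }
  structure(
    list(
      windows = tibble::tibble(
        window = seq_len(n_windows) - 1L,
        start = (seq_len(n_windows) - 1L) * window_len,
        end = seq_len(n_windows) * window_len,
        true_class = cls
      ),
      alignments = alns, roles = roles, window_len = window_len
    ),
    class = "windowed_genome"
  )
}

#' @export
print.windowed_genome <- function(x, ...) {
  cat("<windowed_genome> ", nrow(x$windows), " windows x ", x$window_len,
      " sites; roles ", paste(names(x$roles), x$roles, sep = "=",
                              collapse = " "), "\n", sep = "")
  print(table(x$windows$true_class))
  invisible(x)
}

#' Write / read a windowed genome as FASTA + BED + truth TSV
#'
#' Writes `alignment.fasta` (windows concatenated per taxon, rows in role
#' order), `windows.bed` (0-based half-open window coordinates) and
#' `windows.tsv` (window index, coordinates, true class).
#'
#' @param wg A `windowed_genome`.
#' @param dir Output directory (created if needed).
#' @export
write_windowed_genome <- function(wg, dir) {
  stopifnot(inherits(wg, "windowed_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  concat <- do.call(cbind, wg$alignments)
  write_fasta(concat, file.path(dir, "alignment.fasta"))
  bed <- data.frame(chrom = "sim", start = wg$windows$start,
                    end = wg$windows$end)
  utils::write.table(bed, file.path(dir, "windows.bed"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(window_index = wg$windows$window, start = wg$windows$start,
               end = wg$windows$end, true_class = wg$windows$true_class),
    file.path(dir, "windows.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  invisible(dir)
}

#' @rdname write_windowed_genome
#' @export
read_windowed_genome <- function(dir) {
  aln <- read_fasta(file.path(dir, "alignment.fasta"))
  tab <- utils::read.table(file.path(dir, "windows.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  alns <- lapply(seq_len(nrow(tab)), function(i) {
    dna_alignment(aln[, (tab$start[i] + 1):tab$end[i], drop = FALSE])
  })
  roles <- stats::setNames(rownames(aln), c("P1", "P2", "P3", "O"))
  structure(
    list(
      windows = tibble::tibble(
        window = tab$window_index, start = tab$start, end = tab$end,
        true_class = as.character(tab$true_class)
      ),
      alignments = alns, roles = roles,
      window_len = tab$end[1] - tab$start[1]
    ),
    class = "windowed_genome"
  )
}
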