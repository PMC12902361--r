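#' Species network: a coalescent-unit species tree plus introgression pulses
#'
#' The simulation backbone of the package. The species tree is a rooted,
#' binary, ultrametric `phylo` whose branch lengths are in coalescent units
#' (time / 2N generations, increasing root-ward). Introgression is modeled
#' as instantaneous pulses: at a given time point, every gene lineage
#' present on the recipient branch independently relocates to the donor
#' branch with probability `gamma`.
#'
#' Branches are identified by the name of the node at their tipward end:
#' the taxon name for terminal branches, the node label (assigned
#' automatically as `N1`, `N2`, ... in ape node order when absent) for
#' internal branches.
#'
#' @param tree A rooted binary ultrametric `phylo` with branch lengths in
#'   coalescent units, or a Newick string.
#' @param scale Substitutions per site per coalescent unit used to convert
#'   simulated gene-tree branch lengths to mutation units. Default 0.01.
#' @param events A data frame with columns `recipient`, `donor` (branch
#'   ids), `time` (coalescent units before present) and `gamma` (admixture
#'   proportion in `[0, 1]`), or `NULL`.
#' @param outgroup Name of the outgroup leaf.
#' @param roles Optional named character vector with entries `P1`, `P2`,
#'   `P3`, `O` fixing the taxon roles of a four-taxon quartet (used for
#'   V0--V3 genealogy labeling). Inferred automatically for 4-leaf trees.
#' @param branch_scale Optional named numeric vector of per-branch
#'   substitutions/site per coalescent unit overriding `scale`.
#' @return An object of class `species_network`.
#' @seealso [waterfowl_preset()], [quartet_network()],
#'   [simulate_gene_trees()]
#' @export
species_network <- function(tree, scale = 0.01, events = NULL, outgroup,
                            roles = NULL, branch_scale = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop_bad("tree must be a phylo or Newick string")
  if (!ape::is.rooted(tree)) stop_bad("species tree must be rooted")
  if (!ape::is.binary(tree)) stop_bad("species tree must be binary")
  if (is.null(tree$edge.length)) stop_bad("species tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop_bad("negative coalescent branch length")
  ntip <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) stop_bad("duplicate taxon names")
  if (missing(outgroup) || !outgroup %in% tree$tip.label) {
    stop_bad("outgroup must be a leaf of the species tree")
  }
  if (!is.numeric(scale) || scale <= 0) stop_bad("scale must be > 0")

  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  }

  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_len(ntip)]
  if (diff(range(tip_depth)) > 1e-6 * max(tip_depth, 1)) {
    stop_bad("species tree must be ultrametric (a chronogram in coalescent units)")
  }
  ages <- max(tip_depth) - depth  # age 0 at tips, increasing root-ward
  ages[seq_len(ntip)] <- 0

  node_names <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(node_names)) stop_bad("branch ids (tip + node labels) must be unique")

  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L

  events <- validate_events(events, node_names, ages, parent_of, root)

  if (is.null(roles) && ntip == 4) roles <- infer_roles(tree, outgroup)
  if (!is.null(roles)) {
    if (!all(c("P1", "P2", "P3", "O") %in% names(roles)) ||
        !all(roles %in% tree$tip.label)) {
      stop_bad("roles must name P1, P2, P3, O among the leaves")
    }
    roles <- roles[c("P1", "P2", "P3", "O")]
  }

  if (!is.null(branch_scale)) {
    if (is.null(names(branch_scale)) ||
        !all(names(branch_scale) %in% node_names)) {
      stop_bad("branch_scale must be named by branch ids")
    }
    if (any(branch_scale <= 0)) stop_bad("negative or zero branch scale")
  }

  structure(
    list(
      tree = tree, ages = ages, parent_of = parent_of, root = root,
      node_names = node_names, scale = scale, branch_scale = branch_scale,
      events = events, outgroup = outgroup, roles = roles
    ),
    class = "species_network"
  )
}

validate_events <- function(events, node_names, ages, parent_of, root) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0) {
    return(tibble::tibble(
      recipient = character(), donor = character(),
      time = numeric(), gamma = numeric(),
      recipient_node = integer(), donor_node = integer()
    ))
  }
  events <- tibble::as_tibble(events)
  need <- c("recipient", "donor", "time", "gamma")
  if (!all(need %in% names(events))) {
    stop_bad("events need columns recipient, donor, time, gamma")
  }
  if (any(events$gamma < 0 | events$gamma > 1)) {
    stop_bad("gamma must lie in [0, 1]")
  }
  idx <- function(id) {
    i <- match(id, node_names)
    if (anyNA(i)) stop_bad("unknown branch id: ", paste(id[is.na(i)], collapse = " "))
    i
  }
  events$recipient_node <- idx(events$recipient)
  events$donor_node <- idx(events$donor)
  on_branch <- function(node, time) {
    top <- if (node == root) Inf else ages[parent_of[node]]
    time > ages[node] & time < top
  }
  ok <- mapply(on_branch, events$recipient_node, events$time) &
    mapply(on_branch, events$donor_node, events$time)
  if (!all(ok)) {
    stop_bad("event time(s) outside the lifetime of recipient or donor branch")
  }
  dplyr::arrange(events, .data$time)
}

# For a 4-leaf quartet tree, derive taxon roles: O = outgroup, (P1, P2) =
# the ingroup cherry in tip order, P3 = the remaining ingroup taxon.
infer_roles <- function(tree, outgroup) {
  tips <- tree$tip.label
  trio <- setdiff(tips, outgroup)
  ntip <- length(tips)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  trio_id <- match(trio, tips)
  pars <- parent_of[trio_id]
  cherry_par <- pars[duplicated(pars)]
  if (length(cherry_par) != 1) stop_bad("cannot infer quartet roles; supply `roles`")
  pair <- trio[pars == cherry_par]
  p3 <- setdiff(trio, pair)
  c(P1 = pair[1], P2 = pair[2], P3 = p3, O = outgroup)
}

#' Add an introgression pulse to a species network
#'
#' @param network A [species_network()].
#' @param recipient,donor Branch ids (tip name or internal node label).
#' @param time Event time in coalescent units before present; must fall
#'   strictly within the lifetime of both branches.
#' @param gamma Admixture proportion in `[0, 1]`: the probability that a
#'   lineage on the recipient branch relocates to the donor branch.
#' @return The updated `species_network`.
#' @export
add_introgression_event <- function(network, recipient, donor, time, gamma) {
  stopifnot(inherits(network, "species_network"))
  ev <- dplyr::bind_rows(
    network$events[, c("recipient", "donor", "time", "gamma")],
    tibble::tibble(recipient = recipient, donor = donor,
                   time = time, gamma = gamma)
  )
  species_network(network$tree, scale = network$scale, events = ev,
                  outgroup = network$outgroup, roles = network$roles,
                  branch_scale = network$branch_scale)
}

#' Four-taxon quartet network ((P1,P2),P3,O)
#'
#' Convenience constructor for the asymmetric quartet used throughout the
#' windowed-genealogy machinery: P1 and P2 split at `t12`, their ancestor
#' joins P3 after an internal branch of length `t_internal`, and the
#' outgroup O diverges at `t_out` (all coalescent units).
#'
#' @param t_internal Internal branch length in coalescent units; controls
#'   the expected level of incomplete lineage sorting
#'   (discordance probability `(2/3) exp(-t_internal)`).
#' @param t12 Age of the P1--P2 split.
#' @param t_out Age of the outgroup split; default
#'   `max(5, t12 + t_internal + 3)`.
#' @param taxa Names for P1, P2, P3, O in that order.
#' @param scale,events Passed to [species_network()].
#' @return A `species_network` with roles set.
#' @export
quartet_network <- function(t_internal, t12 = 1, t_out = NULL,
                            taxa = c("P1", "P2", "P3", "O"),
                            scale = 0.01, events = NULL) {
  if (is.null(t_out)) t_out <- max(5, t12 + t_internal + 3)
  stopifnot(t_internal >= 0, t12 > 0, t_out > t12 + t_internal)
  t_anc <- t12 + t_internal
  nw <- sprintf(
    "(((%s:%.10g,%s:%.10g):%.10g,%s:%.10g):%.10g,%s:%.10g);",
    taxa[1], t12, taxa[2], t12, t_internal, taxa[3], t_anc,
    t_out - t_anc, taxa[4], t_out
  )
  species_network(nw, scale = scale, events = events, outgroup = taxa[4],
                  roles = c(P1 = taxa[1], P2 = taxa[2], P3 = taxa[3],
                            O = taxa[4]))
}

#' @export
print.species_network <- function(x, ...) {
  cat("<species_network> ", length(x$tree$tip.label), " taxa, outgroup ",
      x$outgroup, "\n", sep = "")
  cat("  scale:", x$scale, "subs/site per coalescent unit\n")
  if (nrow(x$events)) {
    cat("  introgression events:\n")
    print(as.data.frame(x$events[, c("recipient", "donor", "time", "gamma")]))
  } else {
    cat("  no introgression events\n")
  }
  if (!is.null(x$roles)) {
    cat("  roles:", paste(names(x$roles), x$roles, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a species network as Newick + TSV event table
#'
#' The tree (coalescent-unit chronogram, node labels = branch ids) goes to
#' `<stem>.nwk`; events, outgroup, roles and scale go to `<stem>_events.tsv`
#' with header comment lines.
#'
#' @param network A `species_network`.
#' @param stem Output path stem.
#' @return `write_network()` the stem, invisibly; `read_network()` a
#'   `species_network`.
#' @export
write_network <- function(network, stem) {
  ape::write.tree(network$tree, file = paste0(stem, ".nwk"))
  con <- file(paste0(stem, "_events.tsv"), "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# outgroup=", network$outgroup),
    paste0("# scale=", format(network$scale, digits = 15)),
    if (!is.null(network$roles)) {
      paste0("# roles=", paste(names(network$roles), network$roles,
                               sep = ":", collapse = ","))
    }
  ), con)
  utils::write.table(
    as.data.frame(network$events[, c("recipient", "donor", "time", "gamma")]),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(stem)
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  tree <- ape::read.tree(paste0(stem, ".nwk"))
  lines <- readLines(paste0(stem, "_events.tsv"))
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  outgroup <- get_field("outgroup")
  scale <- as.numeric(get_field("scale"))
  roles <- get_field("roles")
  if (!is.null(roles)) {
    kv <- strsplit(strsplit(roles, ",")[[1]], ":")
    roles <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  body <- lines[!grepl("^#", lines)]
  ev <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(ev)) ev <- NULL
  species_network(tree, scale = scale, events = ev, outgroup = outgroup,
                  roles = roles)
}
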