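# End-to-end orchestration: simulate -> gene trees -> gCF/theta -> error
# BP -> RI / D statistics -> genealogy scan -> LMG decomposition.

#' Pipeline configuration
#'
#' Collects every knob of [run_pipeline()] with reproducible defaults. All
#' randomness is funneled through `seed`; stage seeds are derived from it
#' deterministically.
#'
#' @param preset A [waterfowl_preset()] name, used when `network` is NULL.
#' @param network Optional [species_network()] overriding `preset`.
#' @param n_loci Gene trees to simulate for the concordance stage.
#' @param n_windows,window_len Windowed-genome dimensions for the
#'   genealogy scan and D statistic.
#' @param n_reps,seq_len Replicates and sites for the error (BP) stage.
#' @param model Substitution model name or [sub_model()].
#' @param seed Master seed.
#' @param tau_q,rho,eps Genealogy-scan parameters (see
#'   [scan_genealogies()]).
#' @param quartets Optional list of 4-taxon role vectors (P1, P2, P3, O)
#'   to scan; defaults to the network's own roles when present.
#' @param estimate_trees Re-estimate every locus tree from simulated
#'   sequence (JC distances + NJ) before the concordance stage, so
#'   gene-tree estimation error contributes to discordance; default uses
#'   the true simulated genealogies.
#' @param locus_seq_len Sites per locus for `estimate_trees`.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "mallard_complex", network = NULL,
                            n_loci = 2000, n_windows = 500,
                            window_len = 5000, n_reps = 100, seq_len = 1500,
                            model = "JC69", seed = 1, tau_q = 0.05,
                            rho = 0.9, eps = 0.1, quartets = NULL,
                            estimate_trees = FALSE, locus_seq_len = 1500,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  for (k in c("n_loci", "n_windows", "window_len", "n_reps", "seq_len")) {
    if (cfg[[k]] < 1) stop_bad(k, " must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full discordance-decomposition pipeline
#'
#' Executes all stages on one species network and collects their tables:
#' per-branch NodeStats (gCF, quartet frequencies, coalescent and
#' mutation-unit lengths, theta, BP, RI, ILS/IH shares), the genealogy
#' scan(s) with ILS%, the ABBA-BABA D tests, and — when the network has
#' at least five usable internal branches — the LMG decomposition of
#' discordance. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param ... Named overrides of config entries.
#' @return A `discord_report`: list with `config`, `node_stats`,
#'   `decomposition` (or NULL), `scans`, `dstat`, `network`.
#' @examples
#' rep <- run_pipeline(pipeline_config(
#'   preset = "mallard_complex", n_loci = 200, n_windows = 40,
#'   window_len = 500, n_reps = 20, seed = 1
#' ))
#' rep$scans[[1]]$summary
#' @export
run_pipeline <- function(config = pipeline_config(), ...) {
  over <- list(...)
  if (length(over)) config[names(over)] <- over
  network <- config$network %||% waterfowl_preset(config$preset)
  model <- if (inherits(config$model, "sub_model")) config$model else
    sub_model(config$model)
  seeds <- derive_seeds(config$seed, 4)

  ref <- network$tree
  sims <- simulate_gene_trees(network, config$n_loci, seed = seeds[1])
  if (isTRUE(config$estimate_trees)) {
    # re-estimate every locus tree from simulated sequence, so gene-tree
    # estimation error enters the concordance stage as it does for real
    # per-locus trees
    lseeds <- derive_seeds(seeds[4], config$n_loci)
    sims$tree <- lapply(seq_len(config$n_loci), function(i) {
      aln <- simulate_alignment(sims$tree[[i]], config$locus_seq_len,
                                model, seed = lseeds[i])
      nj_tree(jc_distance_matrix(aln))
    })
  }

  gcf <- gcf_table(ref, sims)
  coal <- coalescent_length_from_f1(gcf$f1)
  gcf$coal_len <- as.numeric(coal)
  gcf$coal_flag <- attr(coal, "flag")
  dm <- average_patristic_dm(sims)
  gcf <- dplyr::left_join(gcf, branch_mut_lengths(ref, dm = dm),
                          by = "split")
  gcf$theta <- theta_per_branch(gcf$mut_len, gcf$coal_len)

  mut_tree <- ls_branch_lengths(ref, dm)
  bp <- estimate_bp(mut_tree, model = model, n_reps = config$n_reps,
                    seq_len = config$seq_len, seed = seeds[2])
  gcf <- dplyr::left_join(gcf, bp[, c("split", "bp")], by = "split")

  ri <- reticulation_index(gcf$c2, gcf$c3)
  gcf$ri <- ri$ri
  gcf$ri_p <- ri$p
  # noise-corrected asymmetry for the regression: subtracts the binomial
  # noise floor E[(c2-c3)^2] = c2+c3 so pure-ILS branches score near zero
  n23 <- gcf$c2 + gcf$c3
  gcf$ri_adj <- sqrt(pmax(0, (gcf$c2 - gcf$c3)^2 - n23)) / pmax(n23, 1)
  sp <- ils_ih_split(gcf$f1, gcf$f2, gcf$f3)
  gcf$ils_share <- sp$ils_share
  gcf$ih_share <- sp$ih_share
  node_stats <- gcf

  quartets <- config$quartets
  if (is.null(quartets) && !is.null(network$roles)) {
    quartets <- list(unname(network$roles))
  }
  scans <- list()
  dstat <- NULL
  if (!is.null(quartets)) {
    wseeds <- derive_seeds(seeds[3], length(quartets))
    wgs <- lapply(seq_along(quartets), function(i) {
      simulate_windowed_genome(network, config$n_windows,
                               config$window_len, quartet = quartets[[i]],
                               model = model, seed = wseeds[i])
    })
    scans <- lapply(wgs, scan_genealogies, q = config$tau_q,
                    rho = config$rho, eps = config$eps)
    dstat <- d_stat(wgs)
  }

  usable <- sum(stats::complete.cases(
    node_stats[, c("gcf", "theta", "bp", "ri")]
  ))
  decomposition <- if (usable >= 5) {
    decompose_heterogeneity(node_stats)
  } else {
    NULL
  }

  report <- structure(
    list(config = config, node_stats = node_stats,
         decomposition = decomposition, scans = scans, dstat = dstat,
         network = network),
    class = "discord_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) {
    utils::write.table(as.data.frame(d), file.path(dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(report$node_stats, "node_stats.tsv")
  if (!is.null(report$dstat)) tsv(report$dstat, "dstat.tsv")
  for (i in seq_along(report$scans)) {
    tsv(report$scans[[i]]$windows, sprintf("scan_%d_windows.tsv", i))
  }
  summ <- list(
    seed = report$config$seed,
    n_loci = report$config$n_loci,
    scan_summaries = lapply(report$scans, function(s) as.list(s$summary)),
    decomposition = if (!is.null(report$decomposition)) {
      d <- report$decomposition
      list(r2 = d$r2, shares = as.list(d$shares),
           percent = as.list(d$percent), n_nodes = d$n_nodes)
    }
  )
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.discord_report <- function(x, ...) {
  cat("<discord_report> seed", x$config$seed, "\n")
  cat(" node_stats:", nrow(x$node_stats), "internal branches\n")
  for (s in x$scans) {
    cat(sprintf(" scan: ILS%% = %.1f (V0 %.3f V1 %.3f V2 %.3f V3 %.3f)\n",
                s$summary$ils_percent, s$summary$f_v0, s$summary$f_v1,
                s$summary$f_v2, s$summary$f_v3))
  }
  if (!is.null(x$dstat)) {
    cat(sprintf(" D = %.4f, Z = %.2f (%d blocks)\n", x$dstat$D[1],
                x$dstat$Z[1], x$dstat$n_blocks[1]))
  }
  if (!is.null(x$decomposition)) print(x$decomposition)
  invisible(x)
}
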