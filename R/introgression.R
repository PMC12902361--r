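# Introgression statistics: ABBA-BABA D with weighted block-jackknife Z,
# the reticulation index, and the symmetric/asymmetric (ILS/IH) split of
# quartet discordance.

#' Count ABBA / BABA / BBAA site patterns in a four-taxon window
#'
#' Rows must be in the fixed role order (P1, P2, P3, outgroup). Only
#' biallelic columns where all four taxa carry an unambiguous base and the
#' outgroup allele defines the ancestral state "A" are counted: ABBA is
#' (A,B,B,A) across (P1,P2,P3,O), BABA is (B,A,B,A), BBAA is (B,B,A,A).
#' Columns with gaps, Ns, or any other pattern are ignored.
#'
#' @param window A 4-row [dna_alignment()] (or coercible matrix), rows
#'   ordered P1, P2, P3, O.
#' @return A one-row tibble: `n_abba`, `n_baba`, `n_bbaa`.
#' @export
count_site_patterns <- function(window) {
  cc <- count_patterns_raw(as_aln_matrix(window))
  tibble::tibble(n_abba = cc[1], n_baba = cc[2], n_bbaa = cc[3])
}

count_patterns_raw <- function(m) {
  if (nrow(m) != 4) stop_bad("window must have exactly 4 rows (P1, P2, P3, O)")
  p1 <- m[1, ]; p2 <- m[2, ]; p3 <- m[3, ]; o <- m[4, ]
  valid <- p1 %in% DNA_STATES & p2 %in% DNA_STATES &
    p3 %in% DNA_STATES & o %in% DNA_STATES
  p1 <- p1[valid]; p2 <- p2[valid]; p3 <- p3[valid]; o <- o[valid]
  abba <- p1 == o & p2 == p3 & p1 != p2
  baba <- p2 == o & p1 == p3 & p1 != p2
  bbaa <- p3 == o & p1 == p2 & p1 != p3
  c(sum(abba), sum(baba), sum(bbaa))
}

#' Per-block site-pattern counts for a windowed genome
#'
#' Counts patterns per simulation window and pools consecutive windows
#' into jackknife blocks. `block_size = 1` keeps one window per block;
#' larger values emulate genomic blocks spanning several gene
#' genealogies, as real recombining blocks do.
#'
#' @param wg A `windowed_genome` from [simulate_windowed_genome()].
#' @param block_size Consecutive windows pooled per block.
#' @return A tibble: `block`, `start`, `end`, `n_abba`, `n_baba`, `n_bbaa`.
#' @export
pattern_counts <- function(wg, block_size = 1) {
  stopifnot(inherits(wg, "windowed_genome"))
  if (block_size < 1) stop_bad("block_size must be >= 1")
  counts <- t(vapply(wg$alignments, count_patterns_raw, numeric(3)))
  out <- tibble::tibble(
    block = wg$windows$window %/% block_size,
    start = wg$windows$start, end = wg$windows$end,
    n_abba = counts[, 1], n_baba = counts[, 2], n_bbaa = counts[, 3]
  )
  dplyr::summarise(
    dplyr::group_by(out, .data$block),
    start = min(.data$start), end = max(.data$end),
    n_abba = sum(.data$n_abba), n_baba = sum(.data$n_baba),
    n_bbaa = sum(.data$n_bbaa), .groups = "drop"
  )
}

#' D statistic from total site-pattern counts
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; `NA` with a warning when no
#' informative sites exist.
#'
#' @param n_abba,n_baba Total counts.
#' @return The D statistic in `[-1, 1]`, or `NA`.
#' @export
d_statistic <- function(n_abba, n_baba) {
  tot <- n_abba + n_baba
  if (tot == 0) {
    warning("no informative (ABBA/BABA) sites; D undefined")
    return(NA_real_)
  }
  (n_abba - n_baba) / tot
}

#' Block-jackknife test of the D statistic
#'
#' Delete-one-block jackknife over equal-sized genomic blocks: each
#' leave-one-out replicate recomputes D from the remaining blocks' pooled
#' counts (so every block enters with the weight of its informative
#' sites), and the jackknife variance of the replicates gives the
#' standard error. `Z = D / SE`; the normal two-sided p-value is
#' reported. Because a window shares a single genealogy, informative
#' sites are strongly clustered within blocks; the delete-one variance
#' over whole blocks is the calibration-robust choice here.
#'
#' @param blocks A data frame with per-block `n_abba`, `n_baba` (e.g. from
#'   [pattern_counts()]). Blocks with no informative sites are dropped.
#' @return A one-row tibble: `n_abba`, `n_baba`, `D`, `SE`, `Z`,
#'   `n_blocks`, `p`. `SE = 0` (identical blocks) flags `Z` as `NA`.
#' @export
jackknife_z <- function(blocks) {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("n_abba", "n_baba") %in% names(blocks)))
  m_j <- blocks$n_abba + blocks$n_baba
  keep <- m_j > 0
  ab <- blocks$n_abba[keep]
  ba <- blocks$n_baba[keep]
  m_j <- m_j[keep]
  B <- length(m_j)
  if (B < 2) stop_bad("need at least 2 blocks with informative sites")
  n <- sum(m_j)
  d_hat <- (sum(ab) - sum(ba)) / n
  d_del <- vapply(seq_len(B), function(j) {
    (sum(ab[-j]) - sum(ba[-j])) / (n - m_j[j])
  }, 0)
  se <- sqrt((B - 1) / B * sum((d_del - mean(d_del))^2))
  # identical blocks give SE 0: Z is 0 for a null D, undefined otherwise
  z <- if (se == 0) {
    if (d_hat == 0) 0 else NA_real_
  } else {
    d_hat / se
  }
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    n_abba = sum(ab), n_baba = sum(ba), D = d_hat, SE = se, Z = z,
    n_blocks = B, p = p
  )
}

#' ABBA-BABA D test for one or more four-taxon arrangements
#'
#' Runs [pattern_counts()] + [jackknife_z()] on each windowed genome and
#' applies a Bonferroni correction across all arrangements tested in the
#' one invocation.
#'
#' @param wgs A `windowed_genome` or a (possibly named) list of them, one
#'   per (P1, P2, P3, O) arrangement.
#' @param block_size Windows pooled per jackknife block (see
#'   [pattern_counts()]).
#' @return A tibble with one row per arrangement: the taxon roles, total
#'   counts, `D`, `SE`, `Z`, `p` and `p_bonferroni`.
#' @export
d_stat <- function(wgs, block_size = 1) {
  if (inherits(wgs, "windowed_genome")) wgs <- list(wgs)
  rows <- lapply(wgs, function(wg) {
    res <- jackknife_z(pattern_counts(wg, block_size = block_size))
    dplyr::bind_cols(
      tibble::tibble(P1 = wg$roles[["P1"]], P2 = wg$roles[["P2"]],
                     P3 = wg$roles[["P3"]], O = wg$roles[["O"]]),
      res
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

#' Reticulation index: normalized asymmetry of the discordant topologies
#'
#' Under pure incomplete lineage sorting the two discordant quartet
#' topologies are equally frequent; introgression skews them. The index is
#' `RI = |c2 - c3| / (c2 + c3)` with an exact two-sided binomial test of
#' `c2` versus `c3` against 0.5 (the ILS-symmetry null).
#'
#' @param c2,c3 Counts of gene trees supporting the two alternative
#'   topologies (vectorized).
#' @return A tibble: `ri`, `p`, `low_signal` (`TRUE` when both counts are
#'   zero, where `ri = 0` by convention).
#' @export
reticulation_index <- function(c2, c3) {
  if (any(c2 < 0) || any(c3 < 0)) stop_bad("counts must be nonnegative")
  tot <- c2 + c3
  ri <- ifelse(tot == 0, 0, abs(c2 - c3) / tot)
  p <- vapply(seq_along(tot), function(i) {
    if (tot[i] == 0) return(1)
    stats::binom.test(c2[i], tot[i], p = 0.5)$p.value
  }, 0)
  tibble::tibble(ri = ri, p = p, low_signal = tot == 0)
}

#' Split quartet discordance into symmetric (ILS) and asymmetric (IH) parts
#'
#' The symmetric part of the two discordant frequencies, `2 min(f2, f3)`,
#' is attributable to incomplete lineage sorting; the asymmetric excess
#' `|f2 - f3|` to introgression/hybridization. The two shares sum exactly
#' to the total discordance `f2 + f3`.
#'
#' @param f1,f2,f3 Quartet-topology frequencies summing to 1 (vectorized).
#' @return A tibble: `ils_share`, `ih_share`.
#' @export
ils_ih_split <- function(f1, f2, f3) {
  s <- f1 + f2 + f3
  if (any(abs(stats::na.omit(s) - 1) > 1e-8)) {
    stop_bad("frequencies must sum to 1")
  }
  tibble::tibble(ils_share = 2 * pmin(f2, f3), ih_share = abs(f2 - f3))
}
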