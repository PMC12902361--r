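# LMG relative-importance regression: partition per-node discordance
# (100 - gCF) among ILS (theta), tree estimation error (100 - BP) and
# introgression (RI).

#' Coefficient of determination of an OLS fit
#'
#' Ordinary least squares with intercept; errors on rank deficiency,
#' naming the collinear columns.
#'
#' @param y Response vector.
#' @param X Numeric predictor matrix (columns named).
#' @return R-squared.
#' @export
ols_r2 <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_bad("y and X sizes differ")
  Xi <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xi)
  if (q$rank < ncol(Xi)) {
    drop <- setdiff(colnames(Xi), colnames(Xi)[q$pivot[seq_len(q$rank)]])
    stop_bad("rank-deficient design; collinear column(s): ",
             paste(drop, collapse = ", "))
  }
  res <- qr.resid(q, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop_bad("response has zero variance")
  1 - sum(res^2) / tss
}

# R^2 of every predictor subset, indexed by bitmask + 1.
subset_r2 <- function(y, X) {
  p <- ncol(X)
  out <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    out[mask + 1] <- ols_r2(y, X[, cols, drop = FALSE])
  }
  out
}

#' LMG relative-importance shares
#'
#' The LMG (Lindeman-Merenda-Gold) share of a predictor is its sequential
#' R-squared increment averaged over all `p!` orderings of the predictors.
#' Computed exactly by subset enumeration with the closed-form ordering
#' weights `|S|! (p - |S| - 1)! / p!`; shares are nonnegative and sum to
#' the full-model R-squared. The marginal (`first`) and last-added
#' (`last`) increments are reported alongside.
#'
#' @param y Response vector.
#' @param X Predictor matrix, at most 8 columns.
#' @return A list: `r2`, `lmg` (named shares), `first`, `last`.
#' @export
lmg_shares <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (p < 1 || p > 8) stop_bad("LMG enumeration supports 1..8 predictors")
  r2s <- subset_r2(y, X)
  full <- r2s[2^p]
  lf <- lfactorial(0:p)
  shares <- first <- last <- stats::setNames(numeric(p), colnames(X))
  for (i in seq_len(p)) {
    bit <- 2^(i - 1)
    acc <- 0
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      k <- sum(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
      w <- exp(lf[k + 1] + lf[p - k] - lf[p + 1])
      acc <- acc + w * (r2s[bitwOr(mask, bit) + 1] - r2s[mask + 1])
    }
    shares[i] <- acc
    first[i] <- r2s[bit + 1]
    last[i] <- full - r2s[bitwXor(2^p - 1, bit) + 1]
  }
  list(r2 = full, lmg = shares, first = first, last = last)
}

#' Assemble the per-node regression matrix
#'
#' Builds the design for the heterogeneity decomposition from a per-branch
#' statistics table: response `y = 100 - gCF` (percent discordance),
#' predictors theta, `100 - BP` (error) and RI, each standardized to zero
#' mean and unit variance. Rows with any undefined entry are dropped (count
#' reported); constant predictors are dropped with a warning and later
#' reported as zero-share.
#'
#' @param node_stats A data frame with columns `branch_id`, `gcf`,
#'   `theta`, `bp`, `ri`. When a noise-corrected asymmetry column
#'   `ri_adj` is present (as produced by [run_pipeline()]) it is used as
#'   the introgression predictor: the raw index has a sampling-noise
#'   floor of order `1/sqrt(c2 + c3)` that varies systematically with
#'   discordance and destabilizes the regression.
#' @return A `node_matrix`: list with `y`, `X` (standardized), `data`,
#'   `n_dropped_rows`, `dropped_predictors`.
#' @export
assemble_node_matrix <- function(node_stats) {
  d <- tibble::as_tibble(node_stats)
  need <- c("branch_id", "gcf", "theta", "bp", "ri")
  if (!all(need %in% names(d))) {
    stop_bad("node_stats needs columns ", paste(need, collapse = ", "))
  }
  if ("ri_adj" %in% names(d)) d$ri <- d$ri_adj
  d$y <- 100 - d$gcf
  d$error <- 100 - d$bp
  keep <- stats::complete.cases(d[, c("y", "theta", "error", "ri")])
  dropped <- sum(!keep)
  d <- d[keep, ]
  if (nrow(d) < 5) stop_bad("need at least 5 complete rows")
  X <- as.matrix(d[, c("theta", "error", "ri")])
  const <- apply(X, 2, function(x) stats::sd(x) == 0)
  dropped_preds <- colnames(X)[const]
  if (length(dropped_preds)) {
    warning("constant predictor(s) dropped: ",
            paste(dropped_preds, collapse = ", "),
            "; reported as zero share")
    X <- X[, !const, drop = FALSE]
  }
  if (!ncol(X)) stop_bad("all predictors constant")
  X <- scale(X)
  structure(
    list(y = d$y, X = X, data = d, n_dropped_rows = dropped,
         dropped_predictors = dropped_preds),
    class = "node_matrix"
  )
}

#' Decompose gene-tree heterogeneity into factor contributions
#'
#' Runs the LMG relative-importance regression of per-node discordance
#' (`100 - gCF`) on standardized theta (ILS), `100 - BP` (estimation
#' error) and RI (introgression). Percent contributions normalize the LMG
#' shares by the model R-squared; predictors dropped as constant appear
#' with zero share.
#'
#' @param x A `node_matrix` from [assemble_node_matrix()], or a node-stats
#'   data frame (assembled on the fly).
#' @return A `discord_decomposition`: list with `r2`, `shares`, `percent`,
#'   `first`, `last`, `n_nodes`, `n_dropped_rows`, `dropped_predictors`.
#' @examples
#' d <- tibble::tibble(
#'   branch_id = paste0("B", 1:8), gcf = c(90, 70, 55, 80, 60, 75, 85, 50),
#'   theta = c(1, 3, 5, 2, 4, 2.5, 1.5, 6), bp = 100 - c(1:8),
#'   ri = c(0.1, 0.2, 0.5, 0.1, 0.3, 0.2, 0.15, 0.6)
#' )
#' decompose_heterogeneity(d)
#' @export
decompose_heterogeneity <- function(x) {
  nm <- if (inherits(x, "node_matrix")) x else assemble_node_matrix(x)
  fit <- lmg_shares(nm$y, nm$X)
  all_preds <- c("theta", "error", "ri")
  shares <- first <- last <- stats::setNames(rep(0, 3), all_preds)
  shares[names(fit$lmg)] <- fit$lmg
  first[names(fit$first)] <- fit$first
  last[names(fit$last)] <- fit$last
  percent <- if (fit$r2 > 0) 100 * shares / fit$r2 else shares * 0
  structure(
    list(
      r2 = fit$r2, shares = shares, percent = percent,
      first = first, last = last,
      n_nodes = length(nm$y), n_dropped_rows = nm$n_dropped_rows,
      dropped_predictors = nm$dropped_predictors
    ),
    class = "discord_decomposition"
  )
}

#' @export
print.discord_decomposition <- function(x, ...) {
  cat("<discord_decomposition> R2 =", signif(x$r2, 4), "over", x$n_nodes,
      "nodes\n")
  lab <- c(theta = "ILS (theta)", error = "error (100-BP)",
           ri = "introgression (RI)")
  for (k in names(x$shares)) {
    cat(sprintf("  %-20s share %.4f  (%.2f%% of R2)\n", lab[k],
                x$shares[k], x$percent[k]))
  }
  if (x$n_dropped_rows) cat("  rows dropped (missing values):",
                            x$n_dropped_rows, "\n")
  invisible(x)
}
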