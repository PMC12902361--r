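# Windowed four-state genealogy decoding. Each 4-taxon window is
# classified into V0 (species topology, sister coalescence below the
# ancestral speciation), V1 (species topology, deep coalescence), V2
# (P1-P3 pairing) or V3 (P2-P3 pairing) from the three ingroup JC
# distances; ILS% is the V2+V3 share. Optional HMM smoothing shares
# information between neighboring windows.

GEN_STATES <- c("V0", "V1", "V2", "V3")

#' Ingroup JC distances of one four-taxon window
#'
#' Pairwise JC distances among P1, P2, P3 computed on jointly ungapped
#' columns (all three ingroup taxa unambiguous).
#'
#' @param window A 4-row alignment, rows ordered P1, P2, P3, O.
#' @param cap Saturation cap passed through to the JC correction.
#' @return A one-row tibble `d12`, `d13`, `d23` (`NA`s when no comparable
#'   columns exist; such windows are unclassifiable).
#' @export
window_distances <- function(window, cap = 5) {
  d <- window_distances_raw(as_aln_matrix(window), cap)
  tibble::tibble(d12 = d[1], d13 = d[2], d23 = d[3])
}

window_distances_raw <- function(m, cap = 5) {
  if (nrow(m) != 4) stop_bad("window must have exactly 4 rows (P1, P2, P3, O)")
  code <- matrix(match(m[1:3, ], DNA_STATES), 3)
  ok <- !is.na(code[1, ]) & !is.na(code[2, ]) & !is.na(code[3, ])
  if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_))
  code <- code[, ok, drop = FALSE]
  jc <- function(a, b) {
    p <- mean(a != b)
    if (p >= 0.75) cap else -0.75 * log(1 - 4 * p / 3)
  }
  c(jc(code[1, ], code[2, ]), jc(code[1, ], code[3, ]),
    jc(code[2, ], code[3, ]))
}

#' Estimate the V0/V1 divergence threshold tau
#'
#' The ancestral-speciation divergence floor is estimated as a low
#' quantile of `min(d13, d23)` across windows: distances to P3 cannot
#' coalesce below the ancestral speciation, so their minimum tracks the
#' ancestral divergence plus noise.
#'
#' @param distances A data frame with columns `d13`, `d23` over windows.
#' @param q Quantile (default 0.05).
#' @return The threshold tau (substitutions/site).
#' @export
estimate_tau_anc <- function(distances, q = 0.05) {
  d <- tibble::as_tibble(distances)
  lo <- pmin(d$d13, d$d23)
  lo <- lo[!is.na(lo)]
  if (length(lo) < 20) {
    stop_bad("need at least 20 classifiable windows to estimate tau")
  }
  as.numeric(stats::quantile(lo, q))
}

#' Classify one window into V0-V3
#'
#' The sister pair is the argmin of the three ingroup distances; pairing
#' (P1,P2) is the species topology, split into V0 (`d12 < tau`) versus V1
#' (deep coalescence); (P1,P3) is V2 and (P2,P3) is V3. Exact ties are
#' resolved deterministically (priority V0 > V2 > V3) and flagged.
#'
#' @param d12,d13,d23 Ingroup JC distances.
#' @param tau V0/V1 threshold from [estimate_tau_anc()].
#' @return A one-row tibble `state`, `tie` (logical tie flag; `state` is
#'   `NA` for windows without distances).
#' @export
classify_window <- function(d12, d13, d23, tau) {
  if (anyNA(c(d12, d13, d23))) {
    return(tibble::tibble(state = NA_character_, tie = TRUE))
  }
  d <- c(d12, d13, d23)
  lo <- min(d)
  tie <- sum(d == lo) > 1
  i <- which(d == lo)[1]  # priority order: (P1,P2) -> V0/V1, then V2, V3
  state <- if (i == 1) {
    if (d12 < tau) "V0" else "V1"
  } else if (i == 2) "V2" else "V3"
  tibble::tibble(state = state, tie = tie)
}

# vectorized classification over a 3-column distance matrix
classify_windows_raw <- function(dd, tau) {
  lo <- pmin(dd[, 1], dd[, 2], dd[, 3])
  tie <- (dd[, 1] == lo) + (dd[, 2] == lo) + (dd[, 3] == lo) > 1
  state <- character(nrow(dd))
  sis12 <- !is.na(lo) & dd[, 1] == lo
  state[sis12] <- ifelse(dd[sis12, 1] < tau, "V0", "V1")
  state[!is.na(lo) & !sis12 & dd[, 2] == lo] <- "V2"
  state[!is.na(lo) & !sis12 & dd[, 2] != lo & dd[, 3] == lo] <- "V3"
  state[is.na(lo)] <- NA_character_
  tie[is.na(lo)] <- TRUE
  tibble::tibble(state = state, tie = tie)
}

#' Forward-backward smoothing of window genealogy states
#'
#' A 4-state HMM over the window sequence: uniform initial distribution,
#' self-transition `rho` (and `(1 - rho)/3` to each other state), and an
#' emission model in which the observed class equals the hidden class with
#' probability `1 - eps` (else uniform over the other three). Posteriors
#' come from exact forward-backward; the decoded state is the posterior
#' argmax.
#'
#' @param states Character vector of observed window states (`V0`..`V3`);
#'   `NA`s are treated as uninformative (flat emission).
#' @param rho Self-transition probability, strictly inside (0, 1).
#' @param eps Misclassification probability in `[0, 1)`.
#' @return A list: `posterior` (n x 4 matrix), `decoded` (character).
#' @export
hmm_smooth <- function(states, rho = 0.9, eps = 0.1) {
  if (rho <= 0 || rho >= 1) stop_bad("rho must lie strictly inside (0, 1)")
  if (eps < 0 || eps >= 1) stop_bad("eps must lie in [0, 1)")
  n <- length(states)
  if (n < 1) stop_bad("need at least one window")
  obs <- match(states, GEN_STATES)
  A <- matrix((1 - rho) / 3, 4, 4)
  diag(A) <- rho
  emit <- function(i) {
    if (is.na(obs[i])) return(rep(1, 4))
    e <- rep(eps / 3, 4)
    e[obs[i]] <- 1 - eps
    e
  }
  fwd <- matrix(0, n, 4)
  sc <- numeric(n)
  f <- rep(0.25, 4) * emit(1)
  sc[1] <- sum(f)
  fwd[1, ] <- f / sc[1]
  if (n > 1) {
    for (i in 2:n) {
      f <- as.numeric(fwd[i - 1, ] %*% A) * emit(i)
      sc[i] <- sum(f)
      fwd[i, ] <- f / sc[i]
    }
  }
  bwd <- matrix(0, n, 4)
  bwd[n, ] <- 1
  if (n > 1) {
    for (i in (n - 1):1) {
      b <- as.numeric(A %*% (emit(i + 1) * bwd[i + 1, ]))
      bwd[i, ] <- b / max(b)
    }
  }
  post <- fwd * bwd
  post <- post / rowSums(post)
  colnames(post) <- GEN_STATES
  list(posterior = post, decoded = GEN_STATES[max.col(post, "first")])
}

#' z-standardize per-window ILS values
#'
#' @param ils Numeric vector (e.g. posterior `P(V2) + P(V3)` per window).
#' @return z-scores with mean 0, sd 1; all zeros with attribute
#'   `"zero_variance" = TRUE` when the input is constant.
#' @export
z_standardized_ils <- function(ils) {
  ils <- as.numeric(ils)
  if (sum(!is.na(ils)) < 2) stop_bad("need at least 2 windows")
  s <- stats::sd(ils, na.rm = TRUE)
  if (s == 0) {
    return(structure(rep(0, length(ils)), zero_variance = TRUE))
  }
  (ils - mean(ils, na.rm = TRUE)) / s
}

#' Scan a windowed genome for V0-V3 genealogy classes
#'
#' Computes ingroup distances per window, estimates (or accepts) the V0/V1
#' threshold tau, classifies every window, optionally smooths the state
#' sequence with [hmm_smooth()], and summarizes class fractions.
#' `ILS% = 100 (fraction V2 + fraction V3)` over classifiable windows;
#' tie-flagged and distance-less windows are excluded from the fraction
#' denominator by default.
#'
#' @param wg A `windowed_genome` (or an object with `windows` +
#'   `alignments` in role order).
#' @param tau Optional fixed threshold; default estimated via
#'   [estimate_tau_anc()] at quantile `q`.
#' @param q Quantile for tau estimation.
#' @param smooth Apply HMM smoothing (default TRUE).
#' @param rho,eps HMM parameters, see [hmm_smooth()].
#' @param include_ties Count tie-flagged windows in the fractions.
#' @return A `genealogy_scan`: list with `windows` (per-window tibble:
#'   coordinates, distances, `state`, `tie`, posterior columns `p_v0` ..
#'   `p_v3`, `ils_posterior`, `z_ils`), `summary` (one-row tibble of class
#'   fractions, `ils_percent`, `n_classifiable`, `n_unclassifiable`) and
#'   `tau`.
#' @examples
#' nw <- waterfowl_preset("mallard_complex")
#' wg <- simulate_windowed_genome(nw, 50, 1000, seed = 1)
#' sc <- scan_genealogies(wg)
#' sc$summary
#' @export
scan_genealogies <- function(wg, tau = NULL, q = 0.05, smooth = TRUE,
                             rho = 0.9, eps = 0.1, include_ties = FALSE) {
  stopifnot(inherits(wg, "windowed_genome"))
  dd <- t(vapply(wg$alignments, window_distances_raw, numeric(3)))
  dists <- tibble::tibble(d12 = dd[, 1], d13 = dd[, 2], d23 = dd[, 3])
  if (all(is.na(dists$d12))) stop_bad("no classifiable windows")
  if (is.null(tau)) tau <- estimate_tau_anc(dists, q)
  cl <- classify_windows_raw(dd, tau)
  win <- dplyr::bind_cols(wg$windows, dists, cl)

  if (smooth && nrow(win) > 1) {
    sm <- hmm_smooth(win$state, rho = rho, eps = eps)
    post <- sm$posterior
    win$state_smoothed <- sm$decoded
  } else {
    post <- matrix(0, nrow(win), 4, dimnames = list(NULL, GEN_STATES))
    idx <- match(win$state, GEN_STATES)
    post[cbind(which(!is.na(idx)), idx[!is.na(idx)])] <- 1
    post[is.na(idx), ] <- NA
    win$state_smoothed <- win$state
  }
  win$p_v0 <- post[, 1]; win$p_v1 <- post[, 2]
  win$p_v2 <- post[, 3]; win$p_v3 <- post[, 4]
  win$ils_posterior <- win$p_v2 + win$p_v3
  ok_ils <- !is.na(win$ils_posterior)
  win$z_ils <- NA_real_
  if (sum(ok_ils) >= 2) {
    win$z_ils[ok_ils] <- z_standardized_ils(win$ils_posterior[ok_ils])
  }

  usable <- !is.na(win$state) & (include_ties | !win$tie)
  st <- factor(win$state[usable], levels = GEN_STATES)
  frac <- as.numeric(table(st)) / max(sum(usable), 1)
  summary <- tibble::tibble(
    f_v0 = frac[1], f_v1 = frac[2], f_v2 = frac[3], f_v3 = frac[4],
    ils_percent = ils_percent(frac[3], frac[4]),
    n_classifiable = sum(usable),
    n_unclassifiable = sum(!usable),
    tau = tau
  )
  structure(list(windows = win, summary = summary, tau = tau),
            class = "genealogy_scan")
}

#' Genome-wide ILS percentage from discordant-class fractions
#'
#' The total ILS share of the genome is the percentage of windows in
#' either discordant class: `100 (V2 + V3)`.
#'
#' @param f_v2,f_v3 Fractions of the two discordant classes.
#' @return ILS percentage.
#' @examples
#' ils_percent(0.469, 0.099)  # 56.8
#' @export
ils_percent <- function(f_v2, f_v3) {
  100 * (f_v2 + f_v3)
}

#' @export
print.genealogy_scan <- function(x, ...) {
  cat("<genealogy_scan> ", nrow(x$windows), " windows, tau = ",
      signif(x$tau, 4), "\n", sep = "")
  print(as.data.frame(x$summary))
  invisible(x)
}
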