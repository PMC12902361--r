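#' Nucleotide substitution models
#'
#' Constructs a continuous-time reversible substitution model (JC69, HKY or
#' GTR) with its rate matrix scaled so that branch lengths are expected
#' substitutions per site. Exchangeabilities follow the usual lower-triangle
#' order AC, AG, AT, CG, CT, GT; state order is A, C, G, T.
#'
#' @param name One of `"JC69"`, `"HKY"`, `"GTR"`.
#' @param base_freqs Equilibrium base frequencies (length 4, sums to 1).
#'   Forced to uniform for JC69.
#' @param kappa Transition/transversion rate ratio (HKY only).
#' @param rates Six GTR exchangeabilities, order AC, AG, AT, CG, CT, GT
#'   (GTR only).
#' @return An object of class `sub_model` holding the scaled rate matrix and
#'   its spectral decomposition.
#' @examples
#' m <- sub_model("HKY", base_freqs = c(0.3, 0.2, 0.2, 0.3), kappa = 4)
#' transition_matrix(m, 0.1)
#' @export
sub_model <- function(name = c("JC69", "HKY", "GTR"),
                      base_freqs = NULL, kappa = 2, rates = NULL) {
  name <- match.arg(name)
  if (name == "JC69") {
    if (!is.null(base_freqs) && max(abs(base_freqs - 0.25)) > 1e-12) {
      stop_bad("JC69 requires equal base frequencies")
    }
    base_freqs <- rep(0.25, 4)
    rates <- rep(1, 6)
  } else if (name == "HKY") {
    base_freqs <- base_freqs %||% rep(0.25, 4)
    if (!is.numeric(kappa) || kappa <= 0) stop_bad("kappa must be > 0")
    # transitions are A<->G and C<->T
    rates <- c(1, kappa, 1, 1, kappa, 1)
  } else {
    base_freqs <- base_freqs %||% rep(0.25, 4)
    if (is.null(rates) || length(rates) != 6) {
      stop_bad("GTR requires 6 exchangeability rates")
    }
  }
  if (length(base_freqs) != 4 || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    stop_bad("base_freqs must be 4 positive values summing to 1")
  }
  if (any(rates <= 0)) stop_bad("all exchangeability rates must be > 0")

  R <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  R[lower.tri(R)] <- rates[c(1, 2, 3, 4, 5, 6)]
  # lower.tri fills column-wise: (2,1)=AC,(3,1)=AG,(4,1)=AT,(3,2)=CG,(4,2)=CT,(4,3)=GT
  R <- R + t(R)
  Q <- R %*% diag(base_freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))  # mean instantaneous rate
  Q <- Q / mu

  # reversible Q: symmetrize with sqrt(pi) for a stable eigendecomposition
  sp <- sqrt(base_freqs)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(
    list(
      name = name, base_freqs = base_freqs, rates = rates, Q = Q,
      eig_values = e$values,
      eig_right = diag(1 / sp) %*% e$vectors,
      eig_left = t(e$vectors) %*% diag(sp)
    ),
    class = "sub_model"
  )
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [sub_model()].
#' @param t Branch length in expected substitutions per site.
#' @return A 4x4 row-stochastic matrix over states A, C, G, T.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "sub_model"))
  if (t < 0) stop_bad("branch length must be >= 0")
  P <- model$eig_right %*% (exp(model$eig_values * t) * model$eig_left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' @export
print.sub_model <- function(x, ...) {
  cat("<sub_model>", x$name, "\n")
  cat("  base freqs:", paste(signif(x$base_freqs, 4), collapse = " "), "\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(x$rates, 4), collapse = " "), "\n")
  invisible(x)
}
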