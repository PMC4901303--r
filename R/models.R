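# Amino-acid substitution models for pruning likelihood.
#
# Reversible GTR-form models: Q_ij = s_ij * pi_j (i != j), diagonal set so
# rows sum to zero, scaled so the expected rate is one substitution per
# site. Probability matrices come from the symmetric eigendecomposition
# B = D^{1/2} Q D^{-1/2}, P(t) = D^{-1/2} U exp(Lambda t) U' D^{1/2}.
#
# Poisson (uniform exchangeabilities and frequencies) is the default and
# the model used by the exhaustive-enumeration oracles; JTT ships as a
# static table of the published Jones-Taylor-Thornton (1992)
# exchangeabilities and stationary frequencies (the standard jones.dat
# constants), in ARNDCQEGHILKMFPSTWYV order.

# lower triangle, column-wise: (2,1),(3,1),...,(20,1),(3,2),...
JTT_RATES <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101,
  64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15,
  503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59,
  38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209,
  62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26,
  12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24,
  201, 33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229,
  21, 479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52,
  24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323,
  17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21,
  112, 71, 25, 16
)

JTT_FREQS <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005
)

#' Amino-acid substitution model
#'
#' @param name `"poisson"` (uniform exchangeabilities and frequencies; the
#'   default) or `"jtt"` (published Jones-Taylor-Thornton constants).
#' @return A list of class `subst_model`: `name`, `freqs` (stationary
#'   frequencies, named by amino acid, summing to 1), `S` (symmetric
#'   exchangeability matrix, zero diagonal), `Q` (rate matrix scaled to
#'   one expected substitution per site), plus a cached
#'   eigendecomposition.
#' @export
subst_model <- function(name = c("poisson", "jtt")) {
  name <- match.arg(name)
  n <- 20L
  if (name == "poisson") {
    S <- matrix(1, n, n); diag(S) <- 0
    freqs <- rep(1 / n, n)
  } else {
    S <- matrix(0, n, n)
    S[lower.tri(S)] <- JTT_RATES
    S <- S + t(S)
    freqs <- JTT_FREQS / sum(JTT_FREQS)
  }
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  names(freqs) <- AA_ALPHABET
  Q <- S * rep(freqs, each = n)          # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))            # expected rate
  Q <- Q / mu
  d <- sqrt(freqs)
  B <- (d %o% (1 / d)) * Q               # symmetric similarity transform
  B <- (B + t(B)) / 2                    # clean numerical asymmetry
  eig <- eigen(B, symmetric = TRUE)
  out <- list(name = name, freqs = freqs, S = S, Q = Q,
              eig_values = eig$values,
              eig_left = (1 / d) * eig$vectors,       # D^{-1/2} U
              eig_right = t(eig$vectors * d))         # U' D^{1/2}
  class(out) <- "subst_model"
  out
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` for a [subst_model()]; rows sum to 1.
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @return A 20 x 20 probability matrix.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$S)
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s (20 states, mean rate 1)\n", x$name))
  invisible(x)
}
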