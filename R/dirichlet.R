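# Dirichlet-mixture smoothing of amino-acid counts.
#
# Observed (weighted) residue counts at one alignment column are turned into
# strictly positive probability estimates via a Dirichlet mixture prior over
# amino-acid frequency vectors: component responsibilities come from the
# Dirichlet-multinomial evidence (gamma-function ratios, valid for
# non-integer counts), and the estimate is the responsibility-weighted
# posterior mean. Strict positivity is what allows symmetric KL divergence
# downstream.

#' Construct a Dirichlet mixture prior
#'
#' @param alpha numeric matrix (K components x 20 amino acids, columns in
#'   [AA20] order) of Dirichlet parameters, all > 0.
#' @param mixture numeric vector of K mixture coefficients (sum 1).
#' @return object of class `dirichlet_mixture`.
#' @export
dirichlet_mixture <- function(alpha, mixture = rep(1 / nrow(alpha), nrow(alpha))) {
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != 20L) stop("alpha must have 20 columns")
  if (any(alpha <= 0)) stop("Dirichlet parameters must be > 0")
  if (length(mixture) != nrow(alpha) || any(mixture < 0))
    stop("mixture coefficients must be non-negative, one per component")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture coefficients must sum to 1")
  colnames(alpha) <- AA20
  structure(list(alpha = alpha, mixture = as.numeric(mixture)),
            class = "dirichlet_mixture")
}

#' @export
print.dirichlet_mixture <- function(x, ...) {
  cat(sprintf("dirichlet_mixture: %d component(s), |alpha| = %s\n",
              nrow(x$alpha),
              paste(signif(rowSums(x$alpha), 4), collapse = ", ")))
  invisible(x)
}

# Typical amino-acid background frequencies (average composition of globular
# proteins), used to center the default prior.
aa_background_frequencies <- function() {
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
         E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.090, K = 0.057,
         M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
         Y = 0.032, V = 0.064)
  f / sum(f)
}

#' Default amino-acid prior
#'
#' Single-component Dirichlet centered on typical amino-acid background
#' frequencies with total concentration `strength` (default 1: the prior
#' carries the evidence of one background-distributed pseudo-observation).
#' Any mixture in the [read_dirichlet_mixture()] format may be supplied
#' instead wherever a prior is accepted.
#'
#' @param strength total concentration (sum of the Dirichlet parameters).
#' @return a [dirichlet_mixture()].
#' @export
default_aa_prior <- function(strength = 1) {
  stopifnot(strength > 0)
  dirichlet_mixture(matrix(aa_background_frequencies() * strength, 1L,
                           dimnames = list(NULL, AA20)),
                    mixture = 1)
}

#' Read a Dirichlet mixture from a text table
#'
#' One row per component: the mixture coefficient followed by 20 Dirichlet
#' parameters in [AA20] order, whitespace-separated; `#` comments allowed.
#'
#' @param path file path.
#' @return a [dirichlet_mixture()].
#' @export
read_dirichlet_mixture <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 21L)
    stop("prior file must have 21 columns: mixture coefficient + 20 alphas")
  dirichlet_mixture(as.matrix(tab[, -1L]), mixture = tab[[1L]] / sum(tab[[1L]]))
}

#' Estimate amino-acid probabilities from counts under a Dirichlet mixture
#'
#' Computes posterior component responsibilities from the
#' Dirichlet-multinomial evidence of each component and returns the
#' responsibility-weighted posterior mean
#' `p_i = sum_k P(k | n) * (n_i + alpha_ki) / (N + |alpha_k|)`.
#' Counts may be non-integer (weighted counts rescaled to pseudo-observation
#' units). Zero counts return the prior predictive mean.
#'
#' @param counts numeric 20-vector of non-negative counts ([AA20] order).
#' @param prior a [dirichlet_mixture()].
#' @return strictly positive named 20-vector summing to 1.
#' @export
estimate_site_probabilities <- function(counts, prior = default_aa_prior()) {
  if (length(counts) != 20L) stop("counts must be a 20-vector")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!inherits(prior, "dirichlet_mixture")) stop("prior must be a dirichlet_mixture")
  n <- as.numeric(counts)
  N <- sum(n)
  A <- prior$alpha
  Asum <- rowSums(A)
  # log Dirichlet-multinomial evidence per component (combinatorial factor
  # independent of k omitted)
  loge <- log(prior$mixture) + lgamma(Asum) - lgamma(N + Asum) +
    rowSums(lgamma(sweep(A, 2L, n, "+")) - lgamma(A))
  resp <- exp(loge - max(loge))
  resp <- resp / sum(resp)
  post <- sweep(sweep(A, 2L, n, "+"), 1L, N + Asum, "/")
  p <- as.numeric(resp %*% post)
  stats::setNames(p / sum(p), AA20)
}
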