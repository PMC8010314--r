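#' Magnitude spectrum of an expression time series
#'
#' Computes the `N`-point magnitude spectrum of a length-`M` series, where
#' component `t` (for `t = 0..N-1`) is
#' `|sum_{y=1..M} x_y * exp(-i 2 pi t y / M)|`. The complex exponential keeps
#' period `M` even when `N > M`, so longer spectra repeat the `M`-point
#' magnitudes periodically; with `N = M` the spectrum satisfies Parseval's
#' identity `sum_t |DF(t)|^2 = M * sum_y x_y^2`.
#'
#' @param series Numeric vector of expression values (length `M >= 1`).
#' @param n_points Spectrum length `N`; must satisfy `N >= M`. Defaults to `M`.
#' @return Nonnegative numeric vector of length `n_points`.
#' @export
#' @examples
#' dft_spectrum(c(1, 1, 1, 1))      # constant signal: all mass at t = 0
#' dft_spectrum(c(1, 0, 0, 0), 8)   # impulse: flat unit spectrum, repeated
dft_spectrum <- function(series, n_points = length(series)) {
  M <- length(series)
  if (M < 1L) stop("series must have at least one time point", call. = FALSE)
  if (n_points < M) stop("n_points must be at least the series length", call. = FALSE)
  # the y-index offset relative to the textbook DFT is a unit-modulus phase,
  # so magnitudes coincide with |fft|
  base_mag <- Mod(stats::fft(as.numeric(series)))
  base_mag[((seq_len(n_points) - 1L) %% M) + 1L]
}

#' Gaussian interaction-profile kernel over expression spectra
#'
#' The bandwidth is `alpha_prime` divided by the mean squared spectrum norm
#' across all covered proteins; the kernel between two proteins is
#' `exp(-bandwidth * ||DF_i - DF_j||^2)`.
#'
#' @param spectra Numeric matrix, one row per protein with an expression
#'   profile (rownames are protein ids), columns the spectrum points.
#' @param alpha_prime Positive bandwidth scaling.
#' @return List with `kernel` (symmetric matrix with unit diagonal over the
#'   covered proteins) and `bandwidth` (the realized `alpha_p`).
#' @export
gk_matrix <- function(spectra, alpha_prime = 1) {
  if (is.null(dim(spectra)) || nrow(spectra) == 0L) {
    stop("spectra must be a nonempty matrix", call. = FALSE)
  }
  sq_norms <- rowSums(spectra^2)
  denom <- mean(sq_norms)
  if (denom == 0) {
    stop("degenerate input: all spectra are identically zero", call. = FALSE)
  }
  bw <- alpha_prime / denom
  d2 <- outer(sq_norms, sq_norms, "+") - 2 * tcrossprod(spectra)
  d2[d2 < 0] <- 0 # numerical guard
  k <- exp(-bw * d2)
  dimnames(k) <- list(rownames(spectra), rownames(spectra))
  list(kernel = k, bandwidth = bw)
}

#' Topological similarity between two proteins
#'
#' `(|common neighbours| + 1) / ((deg_i + 1) * (deg_j + 1))`, computed on the
#' original binary network. Symmetric; equals 1 for two isolated proteins.
#'
#' @param network A [protein_network()].
#' @param i,j Protein ids or indices, `i != j`.
#' @return A value in `(0, 1]`.
#' @export
tfp_score <- function(network, i, j) {
  A <- network$adjacency
  if (is.character(i)) i <- match(i, network$protein_ids)
  if (is.character(j)) j <- match(j, network$protein_ids)
  if (is.na(i) || is.na(j)) stop("unknown protein id", call. = FALSE)
  if (i == j) stop("tfp_score requires two distinct proteins", call. = FALSE)
  common <- sum(A[i, ] * A[j, ])
  (common + 1) / ((sum(A[i, ]) + 1) * (sum(A[j, ]) + 1))
}

#' Build the weighted PPI matrix
#'
#' Known edges are weighted `beta * PA + (1 - beta)` where `PA` is the
#' expression-spectrum kernel when both endpoints have expression profiles and
#' the topological similarity otherwise. Non-adjacent pairs that share at
#' least one neighbour and both have expression receive the product of the
#' topological similarity and the kernel; all remaining non-adjacent pairs are
#' zero, which keeps the matrix supported on the 2-hop neighbourhood.
#'
#' @param network A [protein_network()].
#' @param expression An `expression_table` (may be empty).
#' @param config A [pipeline_config()] supplying `beta`, `alpha_prime` and
#'   `dft_length`.
#' @return A `weighted_ppi`: list with `matrix` (symmetric, zero diagonal,
#'   dimnames = protein ids) and `bandwidth` (the kernel bandwidth, `NA` when
#'   no protein has expression).
#' @export
build_weighted_ppi <- function(network, expression, config = pipeline_config()) {
  ids <- network$protein_ids
  O <- length(ids)
  if (O == 0L) stop("network has no proteins", call. = FALSE)
  A <- network$adjacency
  deg <- rowSums(A)
  C2 <- A %*% A                  # common-neighbour counts
  TFP <- (C2 + 1) / outer(deg + 1, deg + 1)

  covered <- intersect(ids, expression$coverage)
  bw <- NA_real_
  GK <- matrix(NA_real_, O, O, dimnames = list(ids, ids))
  if (length(covered) > 0L) {
    M <- expression$series_length
    N <- if (is.null(config$dft_length)) M else as.integer(config$dft_length)
    if (N < M) stop("dft_length must be at least the series length", call. = FALSE)
    spectra <- t(apply(expression$profiles[covered, , drop = FALSE], 1L,
                       dft_spectrum, n_points = N))
    if (length(covered) == 1L) spectra <- matrix(spectra, nrow = 1L,
                                                 dimnames = list(covered, NULL))
    gk <- gk_matrix(spectra, config$alpha_prime)
    bw <- gk$bandwidth
    GK[covered, covered] <- gk$kernel
  }
  has_expr <- ids %in% covered
  both_expr <- outer(has_expr, has_expr, "&")

  beta <- config$beta
  PA <- ifelse(both_expr, GK, TFP)
  W <- matrix(0, O, O, dimnames = list(ids, ids))
  edge <- A == 1L
  W[edge] <- beta * PA[edge] + (1 - beta)
  two_hop <- !edge & C2 > 0 & both_expr
  diag(two_hop) <- FALSE
  W[two_hop] <- TFP[two_hop] * GK[two_hop]
  diag(W) <- 0
  structure(list(matrix = W, bandwidth = bw), class = "weighted_ppi")
}
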