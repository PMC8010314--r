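#' Directed weight-allocation matrix
#'
#' For each ordered protein pair (i, j) sharing at least one neighbour in the
#' weighted PPI network (neighbours = nonzero entries), the raw allocation is
#' the product `WppiM(i, pT) * WppiM(pT, j)` where `pT` is the common
#' neighbour with the largest weight towards j (ties broken by ascending
#' protein id). Rows with a nonzero sum are rescaled to sum exactly `rho`;
#' pairs without common neighbours, and whole rows without any, stay zero.
#' The matrix is asymmetric in general.
#'
#' @param wppi A `weighted_ppi` from [build_weighted_ppi()].
#' @param rho Total allocation mass per nonzero row, in `(0, 1]`.
#' @return A `weight_allocation` list with `matrix` (row sums `rho` or 0),
#'   `raw` (pre-normalization products) and `rho`.
#' @export
weight_allocation_matrix <- function(wppi, rho = 0.85) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1) {
    stop("rho must lie in (0, 1]", call. = FALSE)
  }
  W <- wppi$matrix
  O <- nrow(W)
  ids <- rownames(W)
  B <- W > 0
  raw <- matrix(0, O, O, dimnames = dimnames(W))
  id_order <- order(ids, method = "radix") # ascending-id tie-break
  id_rank <- integer(O); id_rank[id_order] <- seq_len(O)
  for (i in seq_len(O)) {
    Ni <- which(B[i, ])
    if (!length(Ni)) next
    reach <- colSums(B[Ni, , drop = FALSE]) > 0
    reach[i] <- FALSE
    for (j in which(reach)) {
      cn <- Ni[B[Ni, j]]
      if (!length(cn)) next
      vals <- W[cbind(cn, j)]
      best <- cn[vals == max(vals)]
      pT <- best[which.min(id_rank[best])]
      raw[i, j] <- W[i, pT] * W[pT, j]
    }
  }
  rs <- rowSums(raw)
  mat <- raw * rho / ifelse(rs == 0, 1, rs)
  structure(list(matrix = mat, raw = raw, rho = rho),
            class = "weight_allocation")
}

#' Iterate protein scores to their fixed point
#'
#' Runs `S_{t+1} = mu * WAPM %*% S_t + (1 - mu) * S0` from `S_0 = s0` until
#' the squared Euclidean norm of the update falls below `epsilon`. Because
#' row sums of the allocation matrix are at most `rho` and `mu * rho < 1`,
#' the map is a contraction and converges geometrically to the solution of
#' `(I - mu * WAPM) S = (1 - mu) * s0`.
#'
#' @param wapm A `weight_allocation` (or a plain matrix).
#' @param s0 Initial (restart) score vector.
#' @param mu Damping weight in `(0, 1)`.
#' @param epsilon Positive convergence threshold on the squared update norm.
#' @param max_iter Iteration cap; exceeding it without convergence is an
#'   error reporting the final residual.
#' @return A `score_vector`: list with `scores` (named), `iterations`,
#'   `converged` and `residual` (final squared update norm).
#' @export
iterate_scores <- function(wapm, s0, mu = 0.4, epsilon = 1e-6,
                           max_iter = 10000L) {
  M <- if (is.list(wapm)) wapm$matrix else wapm
  stopifnot(nrow(M) == length(s0))
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  s <- as.numeric(s0)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s_next <- mu * as.numeric(M %*% s) + (1 - mu) * as.numeric(s0)
    resid <- sum((s_next - s)^2)
    s <- s_next
    if (resid < epsilon) {
      return(structure(list(scores = stats::setNames(s, names(s0)),
                            iterations = it, converged = TRUE,
                            residual = resid),
                       class = "score_vector"))
    }
  }
  stop("score iteration did not converge within ", max_iter,
       " iterations (residual ", format(resid), ")", call. = FALSE)
}

#' Rank proteins by score
#'
#' Descending by score with ties broken by ascending protein id; the order is
#' deterministic and invariant to positive rescaling of the scores.
#'
#' @param scores A `score_vector` from [iterate_scores()], or a named numeric
#'   vector.
#' @param ids Protein ids; defaults to the score names.
#' @return A `ranked_list` data frame with columns `rank`, `protein_id`,
#'   `score`.
#' @export
rank_proteins <- function(scores, ids = NULL) {
  s <- if (inherits(scores, "score_vector")) scores$scores else scores
  if (is.null(ids)) ids <- names(s)
  stopifnot(length(ids) == length(s))
  ord <- order(-as.numeric(s), ids, method = "radix")
  structure(data.frame(rank = seq_along(ord), protein_id = ids[ord],
                       score = as.numeric(s)[ord]),
            class = c("ranked_list", "data.frame"))
}
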