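#' Build the weighted domain-domain similarity matrix
#'
#' Each domain's interaction profile is its column of the binary
#' protein-by-domain annotation matrix; the similarity between two domains is
#' a Gaussian interaction-profile kernel over these columns, with bandwidth
#' `delta_prime` divided by the mean squared profile norm. The diagonal is
#' identically one.
#'
#' @param domains A `domain_annotation` (from [load_domain_annotation()]);
#'   every domain must annotate at least one protein.
#' @param delta_prime Positive bandwidth scaling.
#' @return A `weighted_ddi`: list with `matrix` (Q x Q, symmetric, unit
#'   diagonal, entries in (0, 1]) and `bandwidth`.
#' @export
build_weighted_ddi <- function(domains, delta_prime = 1) {
  Q <- length(domains$domain_ids)
  if (Q == 0L) stop("no domains: cannot build a domain-domain network", call. = FALSE)
  IP <- domains$matrix # O x Q, columns are the profiles
  sq_norms <- colSums(IP^2)
  if (any(sq_norms == 0)) {
    stop("every domain must annotate at least one protein", call. = FALSE)
  }
  bw <- delta_prime / mean(sq_norms)
  d2 <- outer(sq_norms, sq_norms, "+") - 2 * crossprod(IP)
  d2[d2 < 0] <- 0
  k <- exp(-bw * d2)
  dimnames(k) <- list(domains$domain_ids, domains$domain_ids)
  structure(list(matrix = k, bandwidth = bw), class = "weighted_ddi")
}

#' Assemble the weighted protein-domain block matrix
#'
#' The heterogeneous network over `O` proteins and `Q` domains is an
#' `(O+Q) x (O+Q)` block matrix: the protein-protein block is the weighted
#' PPI matrix and the domain-domain block the weighted DDI matrix, copied
#' unchanged. The protein-domain block averages two propagations of the
#' binary annotations: through weighted PPI rows
#' (`sum_k WppiM(i,k) OpdiM(k,j) / sum_k WppiM(i,k)`, zero when the protein
#' has an all-zero row) and through weighted DDI columns
#' (`sum_k OpdiM(i,k) WddiM(k,j) / sum_k WddiM(k,j)`). The domain-protein
#' block is its transpose, making the whole matrix symmetric.
#'
#' @param wppi A `weighted_ppi` from [build_weighted_ppi()].
#' @param wddi A `weighted_ddi` from [build_weighted_ddi()].
#' @param domains The `domain_annotation` supplying the binary annotations.
#' @return A `weighted_pdi`: list with `matrix` (the full block matrix,
#'   dimnames protein ids then domain ids), `pd` (the O x Q protein-domain
#'   block), `n_proteins`, `n_domains`.
#' @export
build_weighted_pdi <- function(wppi, wddi, domains) {
  W <- wppi$matrix
  D <- wddi$matrix
  OpdiM <- domains$matrix
  O <- nrow(W); Q <- nrow(D)
  if (nrow(OpdiM) != O || ncol(OpdiM) != Q) {
    stop("dimension mismatch between PPI (", O, "), DDI (", Q,
         ") and the annotation matrix (", nrow(OpdiM), " x ", ncol(OpdiM), ")",
         call. = FALSE)
  }
  rs <- rowSums(W)
  wpd <- (W %*% OpdiM) / ifelse(rs == 0, 1, rs) # 0/0 -> 0: nothing to propagate
  cs <- colSums(D)                              # >= 1 because diag(D) = 1
  wdp <- (OpdiM %*% D) / rep(cs, each = O)
  pd <- (wpd + wdp) / 2
  dimnames(pd) <- list(rownames(W), colnames(D))
  full <- rbind(cbind(W, pd), cbind(t(pd), D))
  ids <- c(rownames(W), rownames(D))
  dimnames(full) <- list(ids, ids)
  structure(list(matrix = full, pd = pd, n_proteins = O, n_domains = Q),
            class = "weighted_pdi")
}
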