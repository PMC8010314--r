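#' Domain-to-protein allocation probability matrix
#'
#' Each domain holds one unit of score and distributes it over its member
#' proteins proportionally to the corresponding protein-domain entries of the
#' weighted heterogeneous network; non-members receive zero. A domain whose
#' member weights are all zero allocates uniformly over its members, so every
#' row sums to exactly one.
#'
#' @param wpdi A `weighted_pdi` from [build_weighted_pdi()].
#' @param domains The `domain_annotation` giving membership.
#' @return Q x O matrix with rows summing to one (dimnames: domain ids,
#'   protein ids).
#' @export
allocation_matrix <- function(wpdi, domains) {
  OpdiM <- domains$matrix
  members <- t(OpdiM)                  # Q x O
  if (any(rowSums(members) == 0)) {
    stop("every domain must have at least one member protein", call. = FALSE)
  }
  numer <- t(wpdi$pd) * members
  rs <- rowSums(numer)
  apm <- numer / ifelse(rs == 0, 1, rs)
  zero <- which(rs == 0)
  if (length(zero)) {
    apm[zero, ] <- members[zero, , drop = FALSE] /
      rowSums(members[zero, , drop = FALSE])
  }
  apm
}

#' Domain-derived protein scores
#'
#' With one unit of score per domain, each protein collects the allocation
#' shares of all domains it belongs to: `PSD = t(APM) %*% 1`. The vector sums
#' to the number of domains.
#'
#' @param apm Allocation matrix from [allocation_matrix()].
#' @return Named numeric vector of length O.
#' @export
domain_derived_scores <- function(apm) {
  colSums(apm)
}

#' Subcellular-localization feature score
#'
#' Compartments containing many proteins score highly: the score of a
#' compartment is its protein count divided by the mean count over all
#' compartments, and a protein's feature is the sum of the scores of the
#' compartments it occupies. Unannotated proteins (or an empty annotation)
#' score zero.
#'
#' @param annotation A `subcellular_annotation`.
#' @param protein_ids Protein universe fixing output order.
#' @return Named nonnegative numeric vector over `protein_ids`.
#' @export
subcellular_feature <- function(annotation, protein_ids) {
  fs <- stats::setNames(numeric(length(protein_ids)), protein_ids)
  counts <- annotation$counts
  if (!length(counts)) return(fs)
  s_sl <- counts / mean(counts)
  for (p in intersect(names(annotation$membership), protein_ids)) {
    fs[[p]] <- sum(s_sl[annotation$membership[[p]]])
  }
  fs
}

#' Triangle feature score
#'
#' For each protein, every incident edge contributes one plus the number of
#' triangles it closes (shared neighbours with that neighbour); the per-edge
#' average is then normalized by its maximum over all proteins, so the score
#' lies in `[0, 1]` with maximum one. Degree-zero proteins score zero.
#'
#' @param network A [protein_network()].
#' @return Named numeric vector over the network's proteins.
#' @export
triangle_feature <- function(network) {
  A <- network$adjacency
  deg <- rowSums(A)
  fs <- stats::setNames(numeric(nrow(A)), network$protein_ids)
  pos <- deg > 0
  if (!any(pos)) return(fs)
  C2 <- A %*% A
  tri_sum <- rowSums(A * C2) + deg   # sum over neighbours of (shared + 1)
  avg <- tri_sum[pos] / deg[pos]
  fs[pos] <- avg / max(avg)
  fs
}

#' Orthology feature score
#'
#' Orthology counts normalized by their maximum; all-zero input yields all
#' zeros.
#'
#' @param orthology Named numeric vector of per-protein orthology counts.
#' @param protein_ids Protein universe fixing output order; proteins missing
#'   from `orthology` count as zero.
#' @return Named numeric vector in `[0, 1]` over `protein_ids`.
#' @export
orthology_feature <- function(orthology, protein_ids) {
  f <- stats::setNames(numeric(length(protein_ids)), protein_ids)
  hit <- intersect(names(orthology), protein_ids)
  f[hit] <- orthology[hit]
  m <- max(f)
  if (m > 0) f <- f / m
  f
}

#' Combine feature scores into the initial score vector
#'
#' The combined feature score is `phi * FS_SL + theta * FS_TRI + tau *
#' FS_ORT` (with optional renormalization of the three weights to unit sum),
#' and the initial score mixes it with the domain-derived score:
#' `S0 = omega * PSD + (1 - omega) * FS`.
#'
#' @param psd Domain-derived score vector from [domain_derived_scores()].
#' @param fs_sl,fs_tri,fs_ort The three feature vectors, same length/order.
#' @param config A [pipeline_config()] supplying `phi`, `theta`, `tau`,
#'   `omega` and `normalize_feature_weights`.
#' @return Named numeric vector `S0` with attribute `features`, a data frame
#'   of the per-protein components.
#' @export
initial_score_vector <- function(psd, fs_sl, fs_tri, fs_ort,
                                 config = pipeline_config()) {
  n <- length(psd)
  stopifnot(length(fs_sl) == n, length(fs_tri) == n, length(fs_ort) == n)
  w <- c(config$phi, config$theta, config$tau)
  if (any(w < 0)) stop("feature weights must be nonnegative", call. = FALSE)
  if (config$normalize_feature_weights && sum(w) > 0) w <- w / sum(w)
  fs <- w[1] * fs_sl + w[2] * fs_tri + w[3] * fs_ort
  s0 <- config$omega * psd + (1 - config$omega) * fs
  attr(s0, "features") <- data.frame(protein_id = names(psd), psd = unname(psd),
                                     fs_sl = unname(fs_sl), fs_tri = unname(fs_tri),
                                     fs_ort = unname(fs_ort), fs = unname(fs),
                                     s0 = unname(s0))
  s0
}

#' Initial scores for a whole input bundle
#'
#' Convenience wrapper running the allocation matrix and the three feature
#' scores for a bundle and the corresponding weighted heterogeneous network.
#' When the bundle has no domains the domain-derived component is zero.
#'
#' @param bundle An `input_bundle`.
#' @param wpdi A `weighted_pdi`, or `NULL` when the bundle has no domains.
#' @return The initial score vector (see [initial_score_vector()]).
#' @export
initial_scores <- function(bundle, wpdi) {
  ids <- bundle$network$protein_ids
  psd <- stats::setNames(numeric(length(ids)), ids)
  if (!is.null(wpdi) && length(bundle$domains$domain_ids) > 0L) {
    apm <- allocation_matrix(wpdi, bundle$domains)
    psd <- domain_derived_scores(apm)[ids]
  }
  initial_score_vector(psd,
                       subcellular_feature(bundle$subcellular, ids),
                       triangle_feature(bundle$network),
                       orthology_feature(bundle$orthology, ids),
                       bundle$config)
}
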