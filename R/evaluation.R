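#' Essential hits among top-ranked fractions
#'
#' For each fraction `f` the candidate count is `ceiling(f * O)` and the hits
#' are the essentials among the first `k` ranked proteins.
#'
#' @param ranking A `ranked_list` from [rank_proteins()].
#' @param essentials Character vector of essential protein ids.
#' @param fractions Fractions in `(0, 1]`; default the six conventional
#'   cutoffs 1/5/10/15/20/25 percent.
#' @return Data frame with `fraction`, `k`, `hits`, `hit_rate`.
#' @export
top_fraction_hits <- function(ranking, essentials,
                              fractions = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25)) {
  O <- nrow(ranking)
  stopifnot(O >= 1L)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  k <- as.integer(ceiling(fractions * O))
  hits <- vapply(k, function(kk) {
    sum(ranking$protein_id[seq_len(kk)] %in% essentials)
  }, integer(1))
  data.frame(fraction = fractions, k = k, hits = hits, hit_rate = hits / k)
}

#' Jackknife curve of cumulative essential counts
#'
#' @param ranking A `ranked_list`.
#' @param essentials Character vector of essential protein ids.
#' @param n_top Number of leading ranks to cover (at most the ranking size).
#' @return Data frame with `rank` (1..n_top) and non-decreasing `cumulative`.
#' @export
jackknife_curve <- function(ranking, essentials, n_top = nrow(ranking)) {
  stopifnot(n_top >= 1L, n_top <= nrow(ranking))
  hit <- ranking$protein_id[seq_len(n_top)] %in% essentials
  data.frame(rank = seq_len(n_top), cumulative = cumsum(as.integer(hit)))
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps thresholds over the distinct score values (descending); tied scores
#' move together, so the ROC area equals the probability that a random
#' essential outscores a random non-essential, with half credit for ties.
#' Both areas are trapezoidal.
#'
#' @param scores Named numeric score vector (a `score_vector` is accepted).
#' @param essentials Character vector of essential protein ids; both classes
#'   must be present among the scored proteins.
#' @return List with `roc` (fpr, tpr), `pr` (recall, precision), `auc_roc`,
#'   `auc_pr`.
#' @export
roc_pr_auc <- function(scores, essentials) {
  s <- if (inherits(scores, "score_vector")) scores$scores else scores
  lab <- names(s) %in% essentials
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one essential and one non-essential protein", call. = FALSE)
  }
  ord <- order(-s)
  s_ord <- s[ord]; lab_ord <- lab[ord]
  last_of_tie <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)
  tp <- cumsum(lab_ord)[last_of_tie]
  fp <- cumsum(!lab_ord)[last_of_tie]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # prepend the first attainable point at its own precision (standard PR start)
  recall_c <- c(0, recall); precision_c <- c(precision[1], precision)
  auc_pr <- sum(diff(recall_c) *
                  (utils::head(precision_c, -1) + utils::tail(precision_c, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = recall_c, precision = precision_c),
       auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Classical centrality baselines
#'
#' Five standard topology-only predictors: degree (DC), shortest-path
#' betweenness (BC), closeness (CC, computed per connected component with the
#' usual reachable-only normalization, isolated nodes 0), eigenvector
#' centrality (EC, on the largest component, 0 elsewhere), and neighbour
#' centrality (NC, the sum over incident edges of the edge clustering
#' coefficient `|N(u) inter N(v)| / min(deg(u) - 1, deg(v) - 1)`, with 0 when
#' the denominator vanishes).
#'
#' @param network A [protein_network()].
#' @param method One of `"DC"`, `"BC"`, `"CC"`, `"EC"`, `"NC"`.
#' @return Named numeric score vector over the network's proteins.
#' @export
baseline_centrality <- function(network, method = c("DC", "BC", "CC", "EC", "NC")) {
  method <- match.arg(method)
  ids <- network$protein_ids
  A <- network$adjacency
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  out <- stats::setNames(numeric(length(ids)), ids)
  if (method == "DC") {
    out[] <- igraph::degree(g)
  } else if (method == "BC") {
    out[] <- igraph::betweenness(g, directed = FALSE)
  } else if (method == "CC") {
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      if (length(vs) < 2L) next
      sub <- igraph::induced_subgraph(g, vs)
      d <- igraph::distances(sub)
      out[ids[vs]] <- (length(vs) - 1) / rowSums(d)
    }
  } else if (method == "EC") {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    vs <- which(comp$membership == big)
    if (length(vs) >= 2L) {
      sub <- igraph::induced_subgraph(g, vs)
      out[ids[vs]] <- igraph::eigen_centrality(sub)$vector
    }
  } else { # NC
    deg <- rowSums(A)
    C2 <- A %*% A
    denom <- outer(deg - 1, deg - 1, pmin)
    ecc <- matrix(0, nrow(A), ncol(A))
    ok <- A == 1L & denom > 0
    ecc[ok] <- C2[ok] / denom[ok]
    out[] <- rowSums(ecc)
  }
  out
}

#' Overlap between two top-k ranked sets
#'
#' Compares the leading `cutoff` proteins of two rankings; optionally reports
#' the essential-protein percentage inside each difference set.
#'
#' @param ranking_a,ranking_b `ranked_list` data frames (or paths readable by
#'   [read_ranking()]).
#' @param cutoff Number of leading proteins to compare.
#' @param essentials Optional essential id vector.
#' @return List with `cutoff`, `n_common`, `n_a_only`, `n_b_only` and, when
#'   essentials are given, `pct_essential_a_only`, `pct_essential_b_only`.
#' @export
ranking_overlap <- function(ranking_a, ranking_b, cutoff = 500L,
                            essentials = NULL) {
  if (is.character(ranking_a)) ranking_a <- read_ranking(ranking_a)
  if (is.character(ranking_b)) ranking_b <- read_ranking(ranking_b)
  cutoff <- min(cutoff, nrow(ranking_a), nrow(ranking_b))
  a <- ranking_a$protein_id[seq_len(cutoff)]
  b <- ranking_b$protein_id[seq_len(cutoff)]
  common <- intersect(a, b)
  a_only <- setdiff(a, b); b_only <- setdiff(b, a)
  res <- list(cutoff = cutoff, n_common = length(common),
              n_a_only = length(a_only), n_b_only = length(b_only))
  if (!is.null(essentials)) {
    pct <- function(x) if (length(x)) 100 * mean(x %in% essentials) else NA_real_
    res$pct_essential_a_only <- pct(a_only)
    res$pct_essential_b_only <- pct(b_only)
  }
  res
}

#' Write an evaluation report
#'
#' Long-format TSV of `(metric, cutoff, value)` rows covering the top-k
#' fractions, the area metrics and the jackknife terminal count.
#'
#' @param ranking A `ranked_list`.
#' @param scores Score vector matching the ranking.
#' @param essentials Essential id vector.
#' @param path Output TSV path.
#' @param n_top Jackknife depth (default min(600, O)).
#' @return Invisibly, the report data frame.
#' @export
write_evaluation_report <- function(ranking, scores, essentials, path,
                                    n_top = min(600L, nrow(ranking))) {
  tk <- top_fraction_hits(ranking, essentials)
  rp <- roc_pr_auc(scores, essentials)
  jk <- jackknife_curve(ranking, essentials, n_top)
  rows <- rbind(
    data.frame(metric = "top_fraction_hit_rate", cutoff = tk$fraction,
               value = tk$hit_rate),
    data.frame(metric = "top_fraction_hits", cutoff = tk$fraction,
               value = as.numeric(tk$hits)),
    data.frame(metric = "auc_roc", cutoff = NA_real_, value = rp$auc_roc),
    data.frame(metric = "auc_pr", cutoff = NA_real_, value = rp$auc_pr),
    data.frame(metric = "jackknife_cumulative", cutoff = n_top,
               value = as.numeric(jk$cumulative[n_top])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
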