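# Independent oracles and small builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive quadratic evaluation of the magnitude spectrum:
# |sum_{y=1..M} x_y exp(-i 2 pi t y / M)| for t = 0..N-1
naive_spectrum <- function(x, n_points = length(x)) {
  M <- length(x)
  vapply(0:(n_points - 1L), function(t) {
    acc <- 0 + 0i
    for (y in seq_len(M)) {
      acc <- acc + x[y] * exp(-1i * 2 * pi * t * y / M)
    }
    Mod(acc)
  }, numeric(1))
}

# AUC as the exact concordant-pair probability with half credit for ties
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# network from a two-column matrix-like list of edges
net_from_edges <- function(...) {
  e <- do.call(rbind, list(...))
  protein_network(e[, 1], e[, 2])
}

# expression table from a named list of numeric vectors
expr_from_list <- function(profiles) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  structure(list(series_length = ncol(m), profiles = m,
                 coverage = rownames(m)),
            class = "expression_table")
}

# domain annotation from a named list: protein id -> character domain ids
domains_from_list <- function(members, protein_ids) {
  domain_ids <- unique(unlist(members, use.names = FALSE))
  m <- matrix(0L, length(protein_ids), length(domain_ids),
              dimnames = list(protein_ids, domain_ids))
  for (p in names(members)) m[p, members[[p]]] <- 1L
  structure(list(domain_ids = domain_ids, matrix = m),
            class = "domain_annotation")
}

# minimal in-memory bundle with empty optional parts filled in
tiny_bundle <- function(network, expression = NULL, domains = NULL,
                        subcellular = list(), orthology = NULL,
                        essentials = NULL, config = pipeline_config()) {
  ids <- network$protein_ids
  if (is.null(expression)) {
    expression <- structure(list(series_length = 0L,
                                 profiles = matrix(numeric(0), 0, 0),
                                 coverage = character(0)),
                            class = "expression_table")
  }
  if (is.null(domains)) {
    domains <- structure(list(domain_ids = character(0),
                              matrix = matrix(0L, length(ids), 0,
                                              dimnames = list(ids, NULL))),
                         class = "domain_annotation")
  }
  counts <- if (length(subcellular)) {
    tb <- table(unlist(subcellular, use.names = FALSE))
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  structure(list(network = network, expression = expression,
                 domains = domains,
                 subcellular = structure(list(localization_ids = names(counts),
                                              membership = subcellular,
                                              counts = counts),
                                         class = "subcellular_annotation"),
                 orthology = orthology %||%
                   stats::setNames(numeric(0), character(0)),
                 essentials = essentials, config = config),
            class = "input_bundle")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
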