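# ---- domain-type constructors ------------------------------------------------

#' Build a protein interaction network from an edge list
#'
#' Protein order is first-appearance order in the edge list (column-major
#' within a line, line order across lines), which fixes the node indexing used
#' by every downstream matrix. Self-loops are dropped; duplicated and reversed
#' duplicate pairs collapse to one undirected edge.
#'
#' @param from,to Character vectors of interacting protein identifiers.
#' @return A `protein_network`: list with `protein_ids`, `edges` (two-column
#'   character matrix, one row per undirected edge) and `adjacency` (binary
#'   symmetric matrix with zero diagonal, dimnames = protein ids).
#' @export
protein_network <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- trimws(as.character(from))
  to <- trimws(as.character(to))
  keep <- from != to
  a <- from[keep]; b <- to[keep]
  # unordered string key so reversed duplicates collapse; keep first occurrence
  dup <- duplicated(paste(pmin(a, b), pmax(a, b), sep = "\r"))
  a <- a[!dup]; b <- b[!dup]
  # index order = first appearance among surviving edges, so a written-back
  # edge list reloads to the identical network; proteins seen only in
  # self-loops are appended as isolated nodes
  ids <- unique(as.vector(rbind(a, b)))
  ids <- c(ids, setdiff(unique(c(from, to)), ids))
  O <- length(ids)
  adj <- matrix(0L, O, O, dimnames = list(ids, ids))
  if (length(a)) {
    adj[cbind(match(a, ids), match(b, ids))] <- 1L
    adj[cbind(match(b, ids), match(a, ids))] <- 1L
  }
  structure(list(protein_ids = ids,
                 edges = cbind(a, b, deparse.level = 0),
                 adjacency = adj),
            class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat("protein_network:", length(x$protein_ids), "proteins,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

new_expression_table <- function(profiles, series_length) {
  structure(list(series_length = as.integer(series_length),
                 profiles = profiles,
                 coverage = rownames(profiles)),
            class = "expression_table")
}

empty_expression_table <- function() {
  new_expression_table(matrix(numeric(0), 0, 0), 0L)
}

new_domain_annotation <- function(domain_ids, matrix) {
  structure(list(domain_ids = domain_ids, matrix = matrix),
            class = "domain_annotation")
}

new_subcellular_annotation <- function(membership) {
  counts <- if (length(membership)) {
    table(unlist(membership, use.names = FALSE))
  } else {
    table(character(0))
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(localization_ids = names(counts),
                 membership = membership,
                 counts = counts),
            class = "subcellular_annotation")
}

# ---- parsing helpers ---------------------------------------------------------

# whitespace-delimited two-column file; errors name file and line
read_pairs <- function(path, n_cols = 2L) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != n_cols)
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    stop("parse error in ", path, " line ", lineno, ": expected ",
         n_cols, " columns, found ", lengths(fields)[bad[1]], call. = FALSE)
  }
  do.call(rbind, fields)
}

drop_unknown <- function(pairs, known, path, what) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(pairs)
  keep <- pairs[, 1] %in% known
  if (any(!keep)) {
    message("dropped ", sum(!keep), " ", what, " record(s) in ", basename(path),
            " for proteins absent from the PPI network")
  }
  pairs[keep, , drop = FALSE]
}

# ---- loaders -----------------------------------------------------------------

#' Load a PPI network edge list
#'
#' @param path Two-column whitespace-delimited file of protein id pairs, no
#'   header.
#' @return A [protein_network()].
#' @export
load_ppi_network <- function(path) {
  pairs <- read_pairs(path)
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty PPI edge list: ", path, call. = FALSE)
  protein_network(pairs[, 1], pairs[, 2])
}

#' Load an expression-time-series table
#'
#' First column is the protein id, remaining columns the numeric series. The
#' first row fixes the series length `M`; rows of any other length are an
#' error. Rows for proteins absent from `network` are dropped with a message.
#'
#' @param path Whitespace-delimited file, no header.
#' @param network The [protein_network()] fixing the protein universe.
#' @return An `expression_table` with fields `series_length`, `profiles`
#'   (matrix, one row per covered protein) and `coverage`.
#' @export
load_expression_table <- function(path, network) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) return(empty_expression_table())
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  M <- lengths(fields)[1] - 1L
  if (M < 1L) stop("parse error in ", path, " line ", keep[1],
                   ": expression row needs an id plus at least one value", call. = FALSE)
  bad <- which(lengths(fields) != M + 1L)
  if (length(bad)) {
    stop("dimension error in ", path, " line ", keep[bad[1]], ": expected ",
         M, " expression values, found ", lengths(fields)[bad[1]] - 1L, call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  vals <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(M)))
  if (anyNA(vals)) stop("non-numeric expression value in ", path, call. = FALSE)
  known <- ids %in% network$protein_ids
  if (any(!known)) {
    message("dropped ", sum(!known), " expression row(s) in ", basename(path),
            " for proteins absent from the PPI network")
  }
  ids <- ids[known]
  vals <- vals[known, , drop = FALSE]
  dup <- duplicated(ids)
  ids <- ids[!dup]
  vals <- vals[!dup, , drop = FALSE]
  rownames(vals) <- ids
  new_expression_table(vals, M)
}

#' Load protein-domain annotations
#'
#' Two-column file (protein id, domain id). Pairs for proteins outside the
#' network are dropped with a message; domains are indexed in first-appearance
#' order among the kept pairs, so every retained domain has at least one
#' annotated protein.
#'
#' @param path Annotation file.
#' @param network The [protein_network()].
#' @return A `domain_annotation` with `domain_ids` and the binary
#'   protein-by-domain `matrix`.
#' @export
load_domain_annotation <- function(path, network) {
  pairs <- read_pairs(path)
  pairs <- drop_unknown(pairs, network$protein_ids, path, "domain annotation")
  ids <- network$protein_ids
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(new_domain_annotation(character(0),
                                 matrix(0L, length(ids), 0, dimnames = list(ids, NULL))))
  }
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  domain_ids <- unique(pairs[, 2])
  m <- matrix(0L, length(ids), length(domain_ids),
              dimnames = list(ids, domain_ids))
  m[cbind(match(pairs[, 1], ids), match(pairs[, 2], domain_ids))] <- 1L
  new_domain_annotation(domain_ids, m)
}

#' Load subcellular-localization annotations
#'
#' @param path Two-column file (protein id, compartment name).
#' @param network The [protein_network()].
#' @return A `subcellular_annotation` with per-protein compartment sets and
#'   per-compartment protein counts.
#' @export
load_subcellular_annotation <- function(path, network) {
  pairs <- read_pairs(path)
  pairs <- drop_unknown(pairs, network$protein_ids, path, "subcellular")
  if (is.null(pairs) || nrow(pairs) == 0L) return(new_subcellular_annotation(list()))
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  membership <- split(pairs[, 2], pairs[, 1])
  new_subcellular_annotation(membership)
}

#' Load orthology scores
#'
#' @param path Two-column file (protein id, nonnegative count of reference
#'   species with an ortholog).
#' @param network The [protein_network()].
#' @return Named numeric vector of orthology scores; proteins absent from the
#'   file are implicitly zero.
#' @export
load_orthology_scores <- function(path, network) {
  pairs <- read_pairs(path)
  pairs <- drop_unknown(pairs, network$protein_ids, path, "orthology")
  if (is.null(pairs) || nrow(pairs) == 0L) return(stats::setNames(numeric(0), character(0)))
  vals <- as.numeric(pairs[, 2])
  if (anyNA(vals) || any(vals < 0)) {
    stop("orthology scores in ", path, " must be nonnegative numbers", call. = FALSE)
  }
  dup <- duplicated(pairs[, 1])
  stats::setNames(vals[!dup], pairs[!dup, 1])
}

#' Load the gold-standard essential-protein set
#'
#' @param path File with one protein id per line.
#' @param network The [protein_network()]; ids absent from it are dropped
#'   with a message.
#' @return Character vector of essential protein ids.
#' @export
load_essential_set <- function(path, network) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  keep <- ids %in% network$protein_ids
  if (any(!keep)) {
    message("dropped ", sum(!keep), " essential id(s) in ", basename(path),
            " absent from the PPI network")
  }
  ids[keep]
}

#' Load a complete input bundle
#'
#' The PPI edge list is required; the five other inputs are optional and an
#' absent file yields an empty structure (its feature then contributes zero)
#' with a warning. All annotation files are reconciled against the PPI protein
#' set, which is the single source of node ordering.
#'
#' @param dir Directory holding default file names `ppi.tsv`, `domains.tsv`,
#'   `expression.tsv`, `subcellular.tsv`, `orthology.tsv`, `essentials.txt`;
#'   or `NULL` when paths are given explicitly.
#' @param ppi,domains,expression,subcellular,orthology,essentials Explicit
#'   file paths overriding the defaults.
#' @param config A [pipeline_config()].
#' @return An `input_bundle` holding all six parsed components plus config.
#' @export
load_input_bundle <- function(dir = NULL, ppi = NULL, domains = NULL,
                              expression = NULL, subcellular = NULL,
                              orthology = NULL, essentials = NULL,
                              config = pipeline_config()) {
  pick <- function(explicit, default) {
    if (!is.null(explicit)) return(explicit)
    if (is.null(dir)) return(NULL)
    p <- file.path(dir, default)
    if (file.exists(p)) p else NULL
  }
  ppi <- pick(ppi, "ppi.tsv")
  if (is.null(ppi) || !file.exists(ppi)) stop("PPI edge list is required", call. = FALSE)
  network <- load_ppi_network(ppi)
  opt <- function(path, loader, empty, what) {
    if (is.null(path)) {
      warning("no ", what, " file supplied; proceeding with empty ", what,
              call. = FALSE)
      return(empty)
    }
    loader(path, network)
  }
  ids <- network$protein_ids
  bundle <- list(
    network = network,
    expression = opt(pick(expression, "expression.tsv"), load_expression_table,
                     empty_expression_table(), "expression"),
    domains = opt(pick(domains, "domains.tsv"), load_domain_annotation,
                  new_domain_annotation(character(0),
                                        matrix(0L, length(ids), 0,
                                               dimnames = list(ids, NULL))),
                  "domain annotation"),
    subcellular = opt(pick(subcellular, "subcellular.tsv"),
                      load_subcellular_annotation,
                      new_subcellular_annotation(list()), "subcellular"),
    orthology = opt(pick(orthology, "orthology.tsv"), load_orthology_scores,
                    stats::setNames(numeric(0), character(0)), "orthology"),
    essentials = if (is.null(pick(essentials, "essentials.txt"))) NULL else
      load_essential_set(pick(essentials, "essentials.txt"), network),
    config = config)
  structure(bundle, class = "input_bundle")
}

#' @export
print.input_bundle <- function(x, ...) {
  cat("input_bundle:", length(x$network$protein_ids), "proteins,",
      nrow(x$network$edges), "edges,",
      length(x$domains$domain_ids), "domains,",
      length(x$expression$coverage), "expression profiles\n")
  invisible(x)
}

# ---- ranking I/O -------------------------------------------------------------

#' Write a protein ranking to a TSV file
#'
#' Columns `rank`, `protein_id`, `score`, `is_essential`; scores are written
#' with full double precision so a written file reloads losslessly. The
#' essential column is blank when no gold standard is available.
#'
#' @param ranking A ranking data frame from [rank_proteins()].
#' @param path Output path.
#' @param essentials Optional character vector of essential protein ids.
#' @return Invisibly, the path.
#' @export
write_ranking <- function(ranking, path, essentials = NULL) {
  stopifnot(nrow(ranking) >= 1L)
  ess <- if (is.null(essentials)) rep("", nrow(ranking)) else
    as.integer(ranking$protein_id %in% essentials)
  out <- data.frame(rank = seq_len(nrow(ranking)),
                    protein_id = ranking$protein_id,
                    score = sprintf("%.17g", ranking$score),
                    is_essential = ess)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking file written by [write_ranking()]
#'
#' @param path Ranking TSV.
#' @return Data frame with `rank`, `protein_id`, `score` and, when present,
#'   `is_essential`.
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "numeric", "character"))
  df$is_essential <- suppressWarnings(as.integer(df$is_essential))
  df
}
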