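#' Configuration for the synthetic input generator
#'
#' Defines the simulated study conditions: a degree-skewed interactome with
#' planted essential proteins that are enriched (by the stated ratios) in
#' attachment mass, domain annotations, compartment memberships and orthology
#' counts, plus periodic expression series with shared phase on a fraction of
#' edges. Setting every ratio to 1 and `cophase_fraction` to 0 removes all
#' planted signal, which is the ablation condition used in testing.
#'
#' @param n_proteins,n_domains Numbers of proteins and domains.
#' @param essential_fraction Fraction of proteins planted as essential.
#' @param attach_edges Edges each new protein adds during preferential
#'   attachment (target mean degree is about twice this).
#' @param attachment_ratio Multiplier (>= 1) on essential proteins'
#'   attachment mass.
#' @param expression_length Time points per expression series.
#' @param expression_noise Gaussian noise s.d. added to the unit-amplitude
#'   periodic signal.
#' @param domain_rate Mean annotation count per non-essential protein.
#' @param domain_ratio Essential:non-essential annotation-rate ratio (>= 1).
#' @param n_compartments,compartment_rate,compartment_ratio Compartment
#'   count, mean memberships per non-essential protein, and essential
#'   enrichment ratio.
#' @param orthology_mean,orthology_ratio Mean orthology count for
#'   non-essentials and essential enrichment ratio.
#' @param missing_expression_fraction Fraction of proteins lacking an
#'   expression profile.
#' @param cophase_fraction Fraction of edges whose endpoints share the
#'   expression phase.
#' @param seed Integer random seed; generation is fully deterministic.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_proteins = 300L, n_domains = 60L,
                           essential_fraction = 0.2, attach_edges = 3L,
                           attachment_ratio = 2, expression_length = 36L,
                           expression_noise = 0.25, domain_rate = 1.5,
                           domain_ratio = 2, n_compartments = 8L,
                           compartment_rate = 1.5, compartment_ratio = 2,
                           orthology_mean = 3, orthology_ratio = 2,
                           missing_expression_fraction = 0.1,
                           cophase_fraction = 0.5, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_domains = as.integer(n_domains),
              essential_fraction = essential_fraction,
              attach_edges = as.integer(attach_edges),
              attachment_ratio = attachment_ratio,
              expression_length = as.integer(expression_length),
              expression_noise = expression_noise,
              domain_rate = domain_rate, domain_ratio = domain_ratio,
              n_compartments = as.integer(n_compartments),
              compartment_rate = compartment_rate,
              compartment_ratio = compartment_ratio,
              orthology_mean = orthology_mean,
              orthology_ratio = orthology_ratio,
              missing_expression_fraction = missing_expression_fraction,
              cophase_fraction = cophase_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_proteins >= 2L, n_domains >= 1L, attach_edges >= 1L,
              expression_length >= 1L, n_compartments >= 1L,
              essential_fraction > 0, essential_fraction < 1,
              missing_expression_fraction >= 0, missing_expression_fraction < 1,
              cophase_fraction >= 0, cophase_fraction <= 1,
              attachment_ratio >= 1, domain_ratio >= 1,
              compartment_ratio >= 1, orthology_ratio >= 1)
  })
  if (cfg$domain_rate * cfg$domain_ratio > cfg$n_domains) {
    stop("infeasible config: mean annotation count exceeds the number of domains",
         call. = FALSE)
  }
  structure(cfg, class = "fixture_config")
}

#' Generate a complete synthetic input bundle
#'
#' Grows a preferential-attachment interactome in a random node order where
#' planted essentials carry `attachment_ratio` times the attachment mass, so
#' they end up as hubs; repairs connectivity by linking any stray component
#' back to the largest one; plants enrichment in domain annotations,
#' compartment memberships and orthology counts; and simulates periodic
#' expression (three cycles over the series, unit amplitude, Gaussian noise)
#' with shared phase on a fraction of edges, leaving a stated fraction of
#' proteins without expression. Deterministic given `config$seed`.
#'
#' @param config A [fixture_config()].
#' @param pipeline A [pipeline_config()] embedded in the returned bundle.
#' @return An `input_bundle` whose `essentials` field is the planted
#'   ground-truth essential set.
#' @export
generate_fixture_bundle <- function(config = fixture_config(),
                                    pipeline = pipeline_config()) {
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  n_ess <- round(n * config$essential_fraction)
  ess_idx <- sort(sample.int(n, n_ess))
  is_ess <- seq_len(n) %in% ess_idx
  mass <- ifelse(is_ess, config$attachment_ratio, 1)

  # --- topology: preferential attachment in a random growth order ---
  grow <- sample.int(n)
  deg <- numeric(n)
  from <- character(0); to <- character(0)
  for (k in 2:n) {
    v <- grow[k]
    existing <- grow[seq_len(k - 1L)]
    m <- min(config$attach_edges, k - 1L)
    targets <- if (length(existing) == 1L) existing else
      sample(existing, m, prob = (deg[existing] + 1) * mass[existing])
    from <- c(from, rep(ids[v], length(targets)))
    to <- c(to, ids[targets])
    deg[v] <- deg[v] + length(targets)
    deg[targets] <- deg[targets] + 1
  }
  network <- protein_network(from, to)
  # attachment growth is connected by construction; repair defensively anyway
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    big <- which.max(comp$csize)
    anchor <- network$protein_ids[which(comp$membership == big)[1]]
    for (cid in setdiff(seq_len(comp$no), big)) {
      v <- network$protein_ids[which(comp$membership == cid)[1]]
      from <- c(from, anchor); to <- c(to, v)
    }
    network <- protein_network(from, to)
  }

  # --- expression: co-phased sinusoids, some proteins uncovered ---
  M <- config$expression_length
  phase <- stats::runif(n, 0, 2 * pi)
  edge_idx <- match(network$edges[, 1], ids)
  edge_jdx <- match(network$edges[, 2], ids)
  n_cophase <- round(config$cophase_fraction * length(edge_idx))
  if (n_cophase > 0L) {
    sel <- sample.int(length(edge_idx), n_cophase)
    for (e in sel) phase[edge_jdx[e]] <- phase[edge_idx[e]]
  }
  tt <- seq_len(M)
  profiles <- t(vapply(seq_len(n), function(i) {
    5 + sin(2 * pi * 3 * tt / M + phase[i]) +
      stats::rnorm(M, 0, config$expression_noise)
  }, numeric(M)))
  rownames(profiles) <- ids
  n_missing <- round(n * config$missing_expression_fraction)
  missing <- if (n_missing > 0L) sort(sample.int(n, n_missing)) else integer(0)
  covered <- setdiff(seq_len(n), missing)
  # reorder to the network's protein ordering for the in-memory bundle
  net_ids <- network$protein_ids
  expression <- new_expression_table(
    profiles[intersect(net_ids, ids[covered]), , drop = FALSE], M)

  # --- domain annotations, enriched for essentials ---
  d_ids <- sprintf("D%03d", seq_len(config$n_domains))
  n_dom_per <- pmin(config$n_domains,
                    stats::rpois(n, config$domain_rate *
                                   ifelse(is_ess, config$domain_ratio, 1)))
  dom_of <- lapply(seq_len(n), function(i) {
    if (n_dom_per[i] == 0L) integer(0) else
      sort(sample.int(config$n_domains, n_dom_per[i]))
  })
  used <- sort(unique(unlist(dom_of)))
  for (d in setdiff(seq_len(config$n_domains), used)) { # memberless repair
    p <- sample.int(n, 1L)
    dom_of[[p]] <- sort(c(dom_of[[p]], d))
  }
  dmat <- matrix(0L, n, config$n_domains, dimnames = list(net_ids, d_ids))
  for (i in seq_len(n)) dmat[ids[i], dom_of[[i]]] <- 1L
  domains <- new_domain_annotation(d_ids, dmat)

  # --- compartments and orthology ---
  c_ids <- sprintf("C%02d", seq_len(config$n_compartments))
  n_cmp_per <- pmin(config$n_compartments,
                    stats::rpois(n, config$compartment_rate *
                                   ifelse(is_ess, config$compartment_ratio, 1)))
  membership <- list()
  for (i in seq_len(n)) {
    if (n_cmp_per[i] > 0L) {
      membership[[ids[i]]] <- c_ids[sort(sample.int(config$n_compartments,
                                                    n_cmp_per[i]))]
    }
  }
  subcellular <- new_subcellular_annotation(membership)
  orth <- stats::setNames(
    as.numeric(stats::rpois(n, config$orthology_mean *
                              ifelse(is_ess, config$orthology_ratio, 1))),
    ids)

  structure(list(network = network, expression = expression,
                 domains = domains, subcellular = subcellular,
                 orthology = orth, essentials = ids[ess_idx],
                 config = pipeline, fixture = config),
            class = "input_bundle")
}

#' Write a bundle to disk in the package's input dialects
#'
#' Produces `ppi.tsv`, `domains.tsv`, `expression.tsv`, `subcellular.tsv`,
#' `orthology.tsv` and `essentials.txt` under `dir`, exactly the files
#' [load_input_bundle()] reads. Output is byte-deterministic for a given
#' bundle.
#'
#' @param bundle An `input_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file) writeLines(x, file.path(dir, file))
  wt(paste(bundle$network$edges[, 1], bundle$network$edges[, 2], sep = "\t"),
     "ppi.tsv")
  dm <- bundle$domains$matrix
  if (ncol(dm) > 0L) {
    hits <- which(dm == 1L, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    wt(paste(rownames(dm)[hits[, 1]], colnames(dm)[hits[, 2]], sep = "\t"),
       "domains.tsv")
  } else wt(character(0), "domains.tsv")
  pr <- bundle$expression$profiles
  wt(vapply(seq_len(nrow(pr)), function(i) {
    paste(c(rownames(pr)[i], sprintf("%.17g", pr[i, ])), collapse = "\t")
  }, character(1)), "expression.tsv")
  mem <- bundle$subcellular$membership
  wt(unlist(lapply(names(mem), function(p) paste(p, mem[[p]], sep = "\t")),
            use.names = FALSE) %||% character(0), "subcellular.tsv")
  orth <- bundle$orthology
  wt(paste(names(orth), sprintf("%.17g", orth), sep = "\t"), "orthology.tsv")
  wt(bundle$essentials %||% character(0), "essentials.txt")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
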