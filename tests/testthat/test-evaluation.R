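fake_ranking <- function(n, essential_ranks = integer(0)) {
  ids <- sprintf("y%05d", seq_len(n))
  list(ranking = structure(data.frame(rank = seq_len(n), protein_id = ids,
                                      score = seq(n, 1)),
                           class = c("ranked_list", "data.frame")),
       essentials = ids[essential_ranks])
}

test_that("top-fraction candidate counts use the ceiling convention", {
  fr <- fake_ranking(1855)
  tk <- top_fraction_hits(fr$ranking, character(0))
  # canonical candidate counts for a 1,855-protein interactome
  expect_equal(tk$k, c(19L, 93L, 186L, 279L, 371L, 464L))
  expect_equal(top_fraction_hits(fake_ranking(100)$ranking, character(0),
                                 fractions = 0.01)$k, 1L)
  fr10 <- fake_ranking(10, essential_ranks = 1:3)
  tk10 <- top_fraction_hits(fr10$ranking, fr10$essentials, fractions = 0.20)
  expect_equal(tk10$k, 2L)
  expect_equal(tk10$hits, 2L)
  expect_equal(tk10$hit_rate, 1)
  expect_error(top_fraction_hits(fr10$ranking, fr10$essentials, fractions = 1.5),
               "fractions")
})

test_that("jackknife curves count essentials cumulatively with unit steps", {
  fr <- fake_ranking(5, essential_ranks = c(1, 3))
  jk <- jackknife_curve(fr$ranking, fr$essentials, n_top = 3)
  expect_equal(jk$cumulative, c(1, 1, 2))
  expect_equal(jackknife_curve(fr$ranking, character(0))$cumulative, rep(0, 5))
  all_ess <- fake_ranking(4, essential_ranks = 1:4)
  expect_equal(jackknife_curve(all_ess$ranking, all_ess$essentials)$cumulative,
               1:4)
  # terminal value agrees with the top-fraction count at the same cutoff
  fr2 <- fake_ranking(50, essential_ranks = c(2, 5, 9, 30))
  jk2 <- jackknife_curve(fr2$ranking, fr2$essentials, n_top = 10)
  tk2 <- top_fraction_hits(fr2$ranking, fr2$essentials, fractions = 0.2)
  expect_equal(jk2$cumulative[10], tk2$hits)
  expect_true(all(diff(jk2$cumulative) %in% c(0, 1)))
})

test_that("ROC area matches concordant-pair counting with half credit for ties", {
  s <- c(g1 = 0.9, g2 = 0.8, g3 = 0.7, g4 = 0.6)
  res <- roc_pr_auc(s, c("g1", "g3"))
  expect_equal(res$auc_roc, 3 / 4)
  expect_equal(res$roc$fpr[1], 0); expect_equal(res$roc$tpr[1], 0)
  expect_equal(utils::tail(res$roc$fpr, 1), 1)
  expect_equal(utils::tail(res$roc$tpr, 1), 1)
  # perfect separation and the all-tied convention
  expect_equal(roc_pr_auc(c(a = 1, b = 0.9, c = 0.1), c("a", "b"))$auc_roc, 1)
  expect_equal(roc_pr_auc(c(a = 1, b = 1, c = 1), c("a"))$auc_roc, 0.5)
  expect_error(roc_pr_auc(c(a = 1, b = 2), character(0)), "at least one")
})

test_that("ROC area equals the brute-force pairwise oracle and pROC on random scores", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 150
    ids <- sprintf("p%03d", seq_len(n))
    scores <- stats::setNames(round(stats::runif(n), 2), ids) # forces ties
    ess <- sample(ids, 40)
    got <- roc_pr_auc(scores, ess)$auc_roc
    expect_equal(got, pairwise_auc(scores, ids %in% ess), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(ids %in% ess, as.numeric(scores),
                                            quiet = TRUE, direction = "<")))
      expect_equal(got, ref, tolerance = 1e-10)
    }
  }
})

test_that("centrality baselines reproduce hand-computed values", {
  k3 <- net_from_edges(c("a", "b"), c("b", "c"), c("a", "c"))
  expect_equal(unname(baseline_centrality(k3, "DC")), rep(2, 3))
  expect_equal(unname(baseline_centrality(k3, "NC")), rep(2, 3))
  path <- net_from_edges(c("a", "b"), c("b", "c"))
  bc <- baseline_centrality(path, "BC")
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
  cc <- baseline_centrality(path, "CC")
  expect_equal(unname(cc[c("a", "b", "c")]), c(2 / 3, 1, 2 / 3),
               tolerance = 1e-12)
  # disconnected handling: isolated node scores zero for CC and EC
  two <- protein_network(c("a", "b", "x"), c("b", "c", "x"))
  expect_equal(unname(baseline_centrality(two, "CC")["x"]), 0)
  ec <- baseline_centrality(two, "EC")
  expect_equal(unname(ec["x"]), 0)
  expect_equal(max(ec), 1)
  expect_error(baseline_centrality(k3, "XX"))
})

test_that("overlap analysis partitions each top set exactly", {
  set.seed(23)
  ids <- sprintf("p%03d", 1:200)
  ra <- rank_proteins(stats::setNames(stats::runif(200), ids))
  rb <- rank_proteins(stats::setNames(stats::runif(200), ids))
  ov <- ranking_overlap(ra, rb, cutoff = 50)
  expect_equal(ov$n_common + ov$n_a_only, 50)
  expect_equal(ov$n_common + ov$n_b_only, 50)
  ov2 <- ranking_overlap(ra, ra, cutoff = 50, essentials = ids[1:20])
  expect_equal(ov2$n_common, 50)
  expect_equal(ov2$n_a_only, 0)
})
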