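test_that("magnitude spectra match closed forms on simple signals", {
  expect_equal(dft_spectrum(c(1, 1, 1, 1)), c(4, 0, 0, 0), tolerance = 1e-12)
  # impulse: unit magnitude at every frequency
  expect_equal(dft_spectrum(c(1, 0, 0, 0)), rep(1, 4), tolerance = 1e-12)
  # Parseval on a ramp: sum |DF|^2 = M * sum x^2 = 4 * 30 = 120
  expect_equal(sum(dft_spectrum(c(1, 2, 3, 4))^2), 120, tolerance = 1e-9)
  expect_error(dft_spectrum(c(1, 2, 3), n_points = 2), "at least")
})

test_that("spectra agree with the naive quadratic oracle, including zero-padded lengths", {
  set.seed(42)
  for (rep in 1:10) {
    x <- stats::rnorm(12)
    expect_equal(dft_spectrum(x), naive_spectrum(x), tolerance = 1e-9)
    expect_equal(dft_spectrum(x, 20), naive_spectrum(x, 20), tolerance = 1e-9)
  }
})

test_that("kernel bandwidth is the scaled inverse mean squared norm", {
  one <- matrix(c(4, 0, 0, 0), 1, dimnames = list("p1", NULL))
  expect_equal(gk_matrix(one)$bandwidth, 1 / 16)
  two <- rbind(p1 = c(1, 0), p2 = c(0, 1))
  gk <- gk_matrix(two)
  expect_equal(gk$bandwidth, 1)
  expect_equal(gk$kernel["p1", "p2"], exp(-2), tolerance = 1e-12)
  expect_equal(unname(diag(gk$kernel)), c(1, 1))
  expect_error(gk_matrix(matrix(0, 2, 3)), "degenerate")
})

test_that("kernel decreases monotonically with spectral distance and ignores row order", {
  base <- c(1, 2, 0)
  sp <- rbind(a = base, b = base + c(0.1, 0, 0), c = base + c(1, 0, 0),
              d = base + c(3, 0, 0))
  k <- gk_matrix(sp)$kernel
  expect_true(k["a", "b"] > k["a", "c"])
  expect_true(k["a", "c"] > k["a", "d"])
  k2 <- gk_matrix(sp[c("d", "b", "a", "c"), ])$kernel
  expect_equal(k2["a", "c"], k["a", "c"], tolerance = 1e-15)
})

test_that("topological similarity follows the common-neighbour formula", {
  # square p1-p2-p3-p4-p1: p1 and p3 have degree 2, common neighbours p2, p4
  sq <- net_from_edges(c("p1", "p2"), c("p2", "p3"), c("p3", "p4"), c("p4", "p1"))
  # degree-2/degree-2 pair with one common neighbour
  chain <- net_from_edges(c("a", "b"), c("b", "c"), c("a", "d"), c("c", "e"))
  expect_equal(tfp_score(chain, "a", "c"), 2 / 9, tolerance = 1e-12)
  # adjacent degree-1 pair, no common neighbour
  pair <- net_from_edges(c("x", "y"), c("u", "v"))
  expect_equal(tfp_score(pair, "x", "y"), 1 / 4)
  expect_equal(tfp_score(sq, "p1", "p3"), tfp_score(sq, "p3", "p1"))
  expect_error(tfp_score(pair, "x", "x"), "distinct")
})

test_that("weighted PPI entries follow the edge and two-hop branches", {
  # triangle-free path a-b-c with expression for all three
  net <- net_from_edges(c("a", "b"), c("b", "c"))
  expr <- expr_from_list(list(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1),
                              c = c(1, 2, 3, 4)))
  cfg <- pipeline_config(beta = 0.5)
  w <- build_weighted_ppi(net, expr, cfg)$matrix
  # recompute both branches from first principles
  sp <- t(apply(expr$profiles, 1, naive_spectrum))
  alpha <- 1 / mean(rowSums(sp^2))
  gk <- function(i, j) exp(-alpha * sum((sp[i, ] - sp[j, ])^2))
  expect_equal(w["a", "b"], 0.5 * gk("a", "b") + 0.5, tolerance = 1e-10)
  # a and c share neighbour b but are not adjacent: TFP * GK
  tfp_ac <- (1 + 1) / ((1 + 1) * (1 + 1))
  expect_equal(w["a", "c"], tfp_ac * gk("a", "c"), tolerance = 1e-10)
  expect_equal(w, t(w))
  expect_equal(unname(diag(w)), rep(0, 3))
})

test_that("edges fall back to topological similarity when expression is missing", {
  net <- net_from_edges(c("a", "b"), c("b", "c"))
  expr <- expr_from_list(list(a = c(1, 0, 0), b = c(0, 1, 0))) # c uncovered
  w <- build_weighted_ppi(net, expr, pipeline_config(beta = 0.5))$matrix
  tfp_bc <- (0 + 1) / ((2 + 1) * (1 + 1))
  expect_equal(w["b", "c"], 0.5 * tfp_bc + 0.5, tolerance = 1e-12)
  # two-hop pair a-c lacks expression on one side: entry stays zero
  expect_equal(w["a", "c"], 0)
  # without any expression the matrix still builds from topology alone
  empty_expr <- structure(list(series_length = 0L,
                               profiles = matrix(numeric(0), 0, 0),
                               coverage = character(0)),
                          class = "expression_table")
  w0 <- build_weighted_ppi(net, empty_expr, pipeline_config())$matrix
  expect_true(all(w0[net$adjacency == 1] >= 0.5))
})

test_that("known-edge weights stay within [(1 - beta), 1] on random fixtures", {
  for (s in 1:3) {
    b <- generate_fixture_bundle(fixture_config(n_proteins = 60, n_domains = 10,
                                                seed = s))
    w <- build_weighted_ppi(b$network, b$expression, b$config)$matrix
    edge_w <- w[b$network$adjacency == 1]
    expect_true(all(edge_w >= 0.5 - 1e-12 & edge_w <= 1 + 1e-12))
    expect_identical(w, t(w))
    expect_true(all(w >= 0))
  }
})
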