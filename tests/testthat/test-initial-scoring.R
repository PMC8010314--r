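test_that("allocation rows normalize member weights and handle degenerate domains", {
  ids <- c("p1", "p2", "p3")
  dom <- domains_from_list(list(p1 = "d1", p2 = "d1"), ids)
  pd <- matrix(0, 3, 1, dimnames = list(ids, "d1"))
  pd[c("p1", "p2"), "d1"] <- c(0.2, 0.6)
  wpdi <- structure(list(pd = pd, n_proteins = 3, n_domains = 1),
                    class = "weighted_pdi")
  apm <- allocation_matrix(wpdi, dom)
  expect_equal(unname(apm["d1", ]), c(0.25, 0.75, 0))
  # single-member domain allocates everything to that member
  dom1 <- domains_from_list(list(p3 = "d2"), ids)
  pd1 <- matrix(0, 3, 1, dimnames = list(ids, "d2")); pd1["p3", 1] <- 0.4
  apm1 <- allocation_matrix(structure(list(pd = pd1), class = "weighted_pdi"),
                            dom1)
  expect_equal(unname(apm1["d2", "p3"]), 1)
  # all-zero member weights fall back to a uniform split
  pd0 <- matrix(0, 3, 1, dimnames = list(ids, "d1"))
  apm0 <- allocation_matrix(structure(list(pd = pd0), class = "weighted_pdi"),
                            dom)
  expect_equal(unname(apm0["d1", ]), c(0.5, 0.5, 0))
})

test_that("domain-derived scores are column sums and conserve total domain mass", {
  apm <- rbind(d1 = c(0.25, 0.75), d2 = c(1, 0))
  colnames(apm) <- c("p1", "p2")
  psd <- domain_derived_scores(apm)
  expect_equal(unname(psd), c(1.25, 0.75))
  expect_equal(sum(psd), 2)
  # conservation on a generated fixture
  b <- generate_fixture_bundle(fixture_config(n_proteins = 80, n_domains = 15,
                                              seed = 2))
  wppi <- build_weighted_ppi(b$network, b$expression, b$config)
  wpdi <- build_weighted_pdi(wppi, build_weighted_ddi(b$domains), b$domains)
  apm2 <- allocation_matrix(wpdi, b$domains)
  expect_equal(unname(rowSums(apm2)), rep(1, nrow(apm2)), tolerance = 1e-10)
  expect_equal(sum(domain_derived_scores(apm2)), 15, tolerance = 1e-8)
  # entries only where the protein belongs to the domain
  expect_true(all(apm2[t(b$domains$matrix) == 0] == 0))
})

test_that("subcellular feature rewards membership in well-populated compartments", {
  ids <- c("x", "y", "z", "w")
  membership <- list(x = c("c1", "c2"), y = c("c1", "c2"), z = "c2", w = "c2")
  ann <- structure(list(localization_ids = c("c1", "c2"),
                        membership = membership,
                        counts = c(c1 = 2L, c2 = 4L)),
                   class = "subcellular_annotation")
  fs <- subcellular_feature(ann, ids)
  expect_equal(unname(fs["x"]), 2 / 3 + 4 / 3, tolerance = 1e-12)
  expect_equal(unname(fs["z"]), 4 / 3, tolerance = 1e-12)
  expect_equal(unname(subcellular_feature(ann, c(ids, "none"))["none"]), 0)
  # single compartment: every annotated protein scores exactly one
  one <- structure(list(localization_ids = "c", membership = list(x = "c"),
                        counts = c(c = 1L)),
                   class = "subcellular_annotation")
  expect_equal(unname(subcellular_feature(one, ids)), c(1, 0, 0, 0))
})

test_that("triangle feature matches hand-computed per-edge triangle averages", {
  k3 <- net_from_edges(c("a", "b"), c("b", "c"), c("a", "c"))
  expect_equal(unname(triangle_feature(k3)), rep(1, 3))
  pend <- net_from_edges(c("a", "b"), c("b", "c"), c("a", "c"), c("a", "d"))
  fs <- triangle_feature(pend)
  expect_equal(fs[c("a", "b", "c", "d")],
               c(a = 5 / 6, b = 1, c = 1, d = 1 / 2), tolerance = 1e-12)
  iso <- protein_network(c("a", "x"), c("b", "x")) # x-x self loop -> isolated
  expect_equal(unname(triangle_feature(iso)["x"]), 0)
})

test_that("orthology feature is max-normalized with an all-zero guard", {
  expect_equal(unname(orthology_feature(c(p1 = 3, p2 = 6), c("p1", "p2"))),
               c(0.5, 1.0))
  expect_equal(unname(orthology_feature(c(p1 = 0), c("p1", "p2"))), c(0, 0))
  f <- orthology_feature(c(p2 = 8, p1 = 2), c("p1", "p2"))
  expect_equal(unname(f[which.max(f)]), 1)
})

test_that("initial scores combine the canonical feature weights verbatim", {
  cfg <- pipeline_config()
  s0 <- initial_score_vector(c(p = 2), c(p = 1), c(p = 1), c(p = 1), cfg)
  # feature weights sum to 1.05 by design; omega mixes in the domain score
  expect_equal(as.numeric(s0), 0.7 * 2 + 0.3 * 1.05, tolerance = 1e-12)
  cfg_norm <- pipeline_config(normalize_feature_weights = TRUE)
  s0n <- initial_score_vector(c(p = 2), c(p = 1), c(p = 1), c(p = 1), cfg_norm)
  expect_equal(as.numeric(s0n), 0.7 * 2 + 0.3 * 1, tolerance = 1e-12)
  # all features zero: S0 reduces to omega * PSD
  s00 <- initial_score_vector(c(p = 2), c(p = 0), c(p = 0), c(p = 0), cfg)
  expect_equal(as.numeric(s00), 1.4, tolerance = 1e-12)
  expect_error(initial_score_vector(c(p = 1), c(p = 1), c(p = 1), c(p = 1),
                                    within(cfg, phi <- -1)))
})

test_that("feature vectors are equivariant under protein input reordering", {
  edges <- rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d"),
                 c("d", "e"), c("b", "e"))
  net1 <- protein_network(edges[, 1], edges[, 2])
  perm <- c(5, 2, 6, 1, 3, 4)
  net2 <- protein_network(edges[perm, 2], edges[perm, 1])
  f1 <- triangle_feature(net1)
  f2 <- triangle_feature(net2)
  expect_equal(f2[names(f1)], f1, tolerance = 1e-12)
  orth <- c(a = 1, b = 5, c = 2, d = 0, e = 3)
  expect_equal(orthology_feature(orth, net2$protein_ids)[names(f1)],
               orthology_feature(orth, net1$protein_ids)[names(f1)])
})
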