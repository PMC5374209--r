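test_that("generators are fully deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 5, n_universe = 500, n_reference_sets = 10,
                          set_size_range = c(10, 50), n_planted_pairs = 2, rho = 3,
                          planted_query_size_range = c(10, 20),
                          planted_ref_size_range = c(20, 60),
                          corpus = list(n_articles = 100),
                          graph = list(n_nodes = 40, n_hubs = 1, hub_degree = 5))
  c1 <- make_collection(cfg); c2 <- make_collection(cfg)
  expect_identical(lapply(c1$collection$sets, `[[`, "members"),
                   lapply(c2$collection$sets, `[[`, "members"))
  expect_identical(c1$truth, c2$truth)
  k1 <- make_corpus(cfg); k2 <- make_corpus(cfg)
  expect_identical(k1$corpus$gene_links, k2$corpus$gene_links)
  expect_identical(k1$corpus$mesh_links, k2$corpus$mesh_links)
  g1 <- make_graph(cfg); g2 <- make_graph(cfg)
  expect_identical(as.data.frame(g1$edges), as.data.frame(g2$edges))
})

test_that("planted pairs carry the exact configured overlap count", {
  cfg <- synthetic_config(seed = 9, n_universe = 2000, n_reference_sets = 8,
                          set_size_range = c(20, 100), n_planted_pairs = 3, rho = 4,
                          planted_query_size_range = c(30, 30),
                          planted_ref_size_range = c(100, 100))
  out <- make_collection(cfg)
  expect_equal(nrow(out$truth), 3L)
  for (i in seq_len(nrow(out$truth))) {
    q <- out$collection$sets[[out$truth$query[i]]]
    r <- out$collection$sets[[out$truth$reference[i]]]
    expect_equal(overlap(q, r)$n_common, out$truth$n_overlap[i])
    expect_equal(out$truth$n_overlap[i], ceiling(4 * 30 * 100 / 2000))
  }
})

test_that("planted overlap means match the analytic expectation (rho = 5 design)", {
  # |A| = 200, |B| = 400, N = 20000, rho = 5 -> exact-count overlap 20
  overlaps <- vapply(1:25, function(s) {
    cfg <- synthetic_config(seed = s, n_universe = 20000, n_reference_sets = 1,
                            n_planted_pairs = 1, rho = 5,
                            planted_query_size_range = c(200, 200),
                            planted_ref_size_range = c(400, 400))
    out <- make_collection(cfg)
    overlap(out$collection$sets[[out$truth$query]],
            out$collection$sets[[out$truth$reference]])$n_common
  }, numeric(1))
  expect_equal(mean(overlaps), 5 * 200 * 400 / 20000)
})

test_that("infeasible planted overlaps are rejected", {
  cfg <- synthetic_config(seed = 1, n_universe = 100, n_reference_sets = 2,
                          set_size_range = c(10, 20), n_planted_pairs = 1, rho = 10,
                          planted_query_size_range = c(50, 50),
                          planted_ref_size_range = c(50, 50))
  expect_error(make_collection(cfg), "infeasible planted overlap")
})

test_that("graph hubs have exactly the configured degree and expansion recovers them", {
  cfg <- synthetic_config(seed = 2, graph = list(n_nodes = 100, edge_density = 0.02,
                                                 n_hubs = 2, hub_degree = 10))
  g <- make_graph(cfg)
  for (h in names(g$hubs)) {
    nb <- expand_ppi(h, g$edges)
    expect_equal(length(nb$members$members), 11L)   # hub + 10 neighbors
    expect_equal(setdiff(nb$members$members, h), g$hubs[[h]])
  }
  # zero density: expansion of a non-hub seed returns the seed only
  cfg0 <- synthetic_config(seed = 3, graph = list(n_nodes = 50, edge_density = 0,
                                                  n_hubs = 1, hub_degree = 4))
  g0 <- make_graph(cfg0)
  seed_node <- setdiff(sprintf("G%04d", 2:50), g0$hubs[[1]])[1]
  nb0 <- suppressWarnings(expand_ppi(seed_node, g0$edges))
  expect_equal(nb0$members$members, seed_node)
})

test_that("null corpus has no heading-dependent gene skew", {
  cfg <- synthetic_config(seed = 8, n_universe = 300,
                          corpus = list(n_articles = 2000, n_headings = 2,
                                        cocitation_boost = 0, planted_set_size = 30))
  out <- make_corpus(cfg)
  expect_equal(nrow(out$truth), 0L)
  expect_null(out$planted_set)
  # with boost 0, per-heading co-citation rates for a random set should be
  # similar across headings (within loose sampling tolerance)
  set.seed(123)
  genes <- gene_set(sample(unique(out$corpus$gene_links$gene), 30))
  n1 <- cocite(out$corpus, genes, "Heading 01")$n_articles
  n2 <- cocite(out$corpus, genes, "Heading 02")$n_articles
  arts1 <- length(unique(out$corpus$mesh_links$article[
    out$corpus$mesh_links$heading_norm == "heading 01"]))
  arts2 <- length(unique(out$corpus$mesh_links$article[
    out$corpus$mesh_links$heading_norm == "heading 02"]))
  expect_lt(abs(n1 / arts1 - n2 / arts2), 0.1)
})

test_that("recovery metrics score reports against truth labels", {
  cfg <- synthetic_config(seed = 14, n_universe = 5000, n_reference_sets = 20,
                          set_size_range = c(50, 200), n_planted_pairs = 2, rho = 10,
                          planted_query_size_range = c(100, 100),
                          planted_ref_size_range = c(200, 200))
  out <- make_collection(cfg)
  qnames <- out$truth$query
  reports <- lapply(stats::setNames(qnames, qnames), enrich, collection = out$collection)
  ev <- evaluate_recovery(reports, out$truth, k = 1)
  expect_equal(ev$recall_at_k, 1)           # strong planting: rank 1 for both
  expect_true(ev$mean_fdp >= 0 && ev$mean_fdp <= 1)

  # empty truth: recall undefined, FDP is the pure-null proportion
  empty_truth <- out$truth[0, ]
  ev0 <- evaluate_recovery(reports[1], empty_truth)
  expect_true(is.na(ev0$recall_at_k))

  # mismatched run: truth names a query with no report
  bad_truth <- data.frame(query = "NoSuchQuery", reference = "RefSet001_200")
  expect_error(evaluate_recovery(reports, bad_truth), "mismatched")
})

test_that("recall is monotone non-decreasing in the planting strength", {
  recalls <- vapply(c(1, 2, 5, 10), function(rho) {
    hits <- vapply(1:12, function(s) {
      cfg <- synthetic_config(seed = s, n_universe = 5000, n_reference_sets = 30,
                              set_size_range = c(50, 300), n_planted_pairs = 1, rho = rho,
                              planted_query_size_range = c(100, 100),
                              planted_ref_size_range = c(200, 200))
      out <- make_collection(cfg)
      rep1 <- enrich(out$truth$query, out$collection)
      evaluate_recovery(rep1, out$truth, k = 5)$recall_at_k
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(recalls) >= -1e-9))
  expect_gte(recalls[4], recalls[1])
})
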