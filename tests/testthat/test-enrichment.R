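test_that("fisher right tail reproduces enumeration on worked examples", {
  expect_equal(fisher_right_tail(100, 10, 10, 0), 1.0)
  expect_equal(fisher_right_tail(50, 50, 7, 7), 1.0)   # query = universe forces full overlap
  expect_equal(fisher_right_tail(20, 5, 5, 4), 76 / 15504, tolerance = 1e-12)
  expect_error(fisher_right_tail(20, 5, 5, 6), "impossible")
  expect_error(fisher_right_tail(20, 5, 18, 2), "impossible")  # k < q+r-N
  expect_error(fisher_right_tail(10, 12, 3, 1), "larger than universe")
})

test_that("fisher right tail agrees with enumeration for all tables, N <= 18", {
  for (N in c(1, 2, 5, 9, 14, 18)) {
    for (q in 0:N) for (r in 0:q) {   # symmetry covers r > q
      kmin <- max(0, q + r - N)
      for (k in kmin:min(q, r)) {
        p <- fisher_right_tail(N, q, r, k)
        expect_equal(p, brute_fisher(N, q, r, k), tolerance = 1e-12,
                     info = sprintf("N=%d q=%d r=%d k=%d", N, q, r, k))
      }
    }
  }
})

test_that("fisher right tail is symmetric in the two set sizes", {
  set.seed(11)
  for (i in 1:50) {
    N <- sample(20:500, 1); q <- sample(0:N, 1); r <- sample(0:N, 1)
    ks <- max(0, q + r - N):min(q, r)
    k <- ks[sample.int(length(ks), 1)]
    a <- fisher_right_tail(N, q, r, k, log.p = TRUE)
    b <- fisher_right_tail(N, r, q, k, log.p = TRUE)
    expect_lt(abs(a - b), 1e-9 * max(1, abs(a)))
  }
})

test_that("fisher right tail matches the independent distribution-function route", {
  set.seed(13)
  for (i in 1:50) {
    N <- sample(50:5000, 1); q <- sample(1:N, 1); r <- sample(1:N, 1)
    ks <- max(0, q + r - N):min(q, r)
    k <- ks[sample.int(length(ks), 1)]
    lp <- fisher_right_tail(N, q, r, k, log.p = TRUE)
    lp_ref <- phyper(k - 1, r, N - r, q, lower.tail = FALSE, log.p = TRUE)
    expect_lt(abs(lp - lp_ref), 1e-9 * max(1, abs(lp)))
  }
})

test_that("BH step-up reproduces hand-worked vectors", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5, 0.03)), c(0.015, 0.5, 0.045))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("BH adjustment is order-preserving, >= raw, <= 1, and matches p.adjust", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-preserving w.r.t. raw p
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("log-space BH agrees with plain BH on ordinary scales", {
  set.seed(22)
  for (i in 1:20) {
    p <- runif(sample(2:100, 1))
    expect_equal(exp(bh_adjust_log(log(p))), bh_adjust(p), tolerance = 1e-12)
  }
})

test_that("neg_log10 handles the boundary and cutoff scales", {
  expect_equal(neg_log10(1), 0)
  expect_equal(neg_log10(1e-10), 10)
  expect_equal(neg_log10(2.1e-112), 111.678, tolerance = 1e-3)
  expect_error(neg_log10(0), "in \\(0, 1\\]")
})

test_that("extreme overlaps keep finite, accurate -log10 FDR (no underflow)", {
  # a table at the 1e-300 scale: check against the independent
  # distribution-function route in log space
  lp <- fisher_right_tail(20000, 2000, 3782, 1600, log.p = TRUE)
  lp_ref <- phyper(1599, 3782, 20000 - 3782, 2000, lower.tail = FALSE, log.p = TRUE)
  expect_lt(lp / log(10), -300)
  expect_equal(-lp / log(10), -lp_ref / log(10), tolerance = 1e-3)

  # through enrich(): the fdr double underflows but neg_log_fdr stays exact
  u <- gene_set(as.character(1:20000), name = "U")
  q <- gene_set(as.character(1:2000), name = "Q_2000")
  r1 <- gene_set(as.character(401:4182), name = "Hit_3782")
  r2 <- gene_set(as.character(10001:10100), name = "Null_100")
  col <- gene_set_collection(list(Q_2000 = q, Hit_3782 = r1, Null_100 = r2),
                             universe = u,
                             roles = c(Q_2000 = "query", Hit_3782 = "reference",
                                       Null_100 = "reference"))
  rep1 <- enrich("Q_2000", col)
  hit <- rep1[rep1$reference == "Hit_3782", ]
  expect_true(is.finite(hit$neg_log_fdr))
  expect_gt(hit$neg_log_fdr, 300)
})

test_that("enrich builds a ranked per-query report with BH within the query family", {
  u <- gene_set(as.character(1:1000), name = "U")
  q <- gene_set(as.character(1:50), name = "Q_50")
  refs <- list(
    Big_200 = gene_set(as.character(1:200), name = "Big_200"),
    Mid_100 = gene_set(as.character(26:125), name = "Mid_100"),
    Null_80 = gene_set(as.character(901:980), name = "Null_80")
  )
  col <- gene_set_collection(c(list(Q_50 = q), refs), universe = u,
                             roles = c(Q_50 = "query", Big_200 = "reference",
                                       Mid_100 = "reference", Null_80 = "reference"))
  r <- enrich("Q_50", col)
  expect_s3_class(r, "enrichment_report")
  expect_equal(nrow(r), 3L)
  expect_equal(attr(r, "n_universe"), 1000L)
  expect_true(all(diff(r$neg_log_fdr) <= 1e-12))
  expect_equal(r$fdr, bh_adjust(r$p_value), tolerance = 1e-9)
  expect_true(all(r$p_value <= r$fdr + 1e-15))
  expect_equal(r$neg_log_fdr, -log10(r$fdr), tolerance = 1e-9)
  # percent columns recompute from the counts
  expect_equal(r$pct_of_query, percent_of_set(r$n_common, r$n_query))

  # single reference set: fdr equals p
  r1 <- enrich("Q_50", col, refs = "Null_80")
  expect_equal(r1$fdr, r1$p_value)

  # cutoff filtering keeps only rows at or above the threshold
  rc <- enrich("Q_50", col, cutoff = 10)
  expect_true(all(rc$neg_log_fdr >= 10))
})

test_that("enrich tie-break is deterministic: n_common desc then name asc", {
  u <- gene_set(as.character(1:100), name = "U")
  q <- gene_set(as.character(1:10), name = "Q_10")
  refs <- list(
    B_ref = gene_set(as.character(c(1:5, 50:54)), name = "B_ref"),
    A_ref = gene_set(as.character(c(1:5, 60:64)), name = "A_ref")
  )
  col <- gene_set_collection(c(list(Q_10 = q), refs), universe = u,
                             roles = c(Q_10 = "query", A_ref = "reference",
                                       B_ref = "reference"))
  r <- enrich("Q_10", col)
  expect_equal(r$reference, c("A_ref", "B_ref"))
})

test_that("enrich rejects degenerate universes and disjoint queries", {
  u <- gene_set(as.character(1:100), name = "U")
  q <- gene_set(as.character(200:210), name = "Qout")
  ref <- gene_set(as.character(1:10), name = "R_10")
  col <- gene_set_collection(list(R_10 = ref), universe = u,
                             roles = c(R_10 = "reference"))
  expect_error(enrich(q, col), "disjoint")
  q2 <- gene_set(as.character(1:5), name = "Q_5")
  expect_error(enrich(q2, col, universe = 3), "smaller")
  expect_error(enrich("NoSuchSet", col), "unknown query")
})
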