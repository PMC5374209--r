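test_that("gene_set deduplicates, trims and validates the size suffix", {
  s <- gene_set(c(" 7157", "7157", "672"), name = "Two_2")
  expect_equal(s$members, c("672", "7157"))
  expect_warning(gene_set(c("1", "2"), name = "Wrong_5"), "declares size 5")
  expect_error(gene_set(c("TP53"), namespace = "entrez"), "integer")
})

test_that("normalization collapses case/duplicates and maps orthologs one-to-many", {
  map <- data.frame(raw = "TP53", human = "7157")
  r <- normalize_gene_ids(c("TP53", "tp53", "7157"), map)
  expect_equal(r$set$members, "7157")
  expect_equal(r$n_excluded, 0L)

  # one fly token mapping to two closely related human orthologs: both kept
  fly <- data.frame(raw = c("Shi", "Shi"), human = c("1759", "1785"))
  r2 <- normalize_gene_ids(c("shi"), fly)
  expect_setequal(r2$set$members, c("1759", "1785"))

  # no match under strict policy: excluded and counted
  r3 <- normalize_gene_ids("unknownX", NULL, policy = "strict_entrez")
  expect_equal(length(r3$set$members), 0L)
  expect_equal(r3$n_excluded, 1L)
  expect_equal(r3$excluded, "unknownX")

  expect_error(normalize_gene_ids(character(0)), "empty")
})

test_that("normalization is idempotent", {
  map <- data.frame(raw = c("a", "b", "b"), human = c("10", "20", "21"))
  for (rep_i in 1:10) {
    raw <- sample(c("a", "b", "A", "xyz", "7157", "99"), sample(1:6, 1), replace = TRUE)
    r1 <- normalize_gene_ids(raw, map)
    r2 <- normalize_gene_ids(r1$set$members, map)
    expect_equal(r2$set$members, r1$set$members)
    expect_equal(r2$n_excluded, 0L)
  }
})

test_that("overlap counts obey set identities", {
  o <- overlap(gene_set(1:3), gene_set(3:4))
  expect_equal(unlist(o), c(n_a = 3, n_b = 2, n_common = 1, n_union = 4))
  s <- gene_set(sample(1:100, 30))
  o2 <- overlap(s, s)
  expect_equal(o2$n_common, 30)
  expect_equal(o2$n_union, 30)
})

test_that("percent_of_set uses nearest-integer, half away from zero", {
  expect_identical(percent_of_set(49, 80), 61L)
  expect_identical(percent_of_set(24, 357), 7L)
  expect_identical(percent_of_set(0, 100), 0L)
  # half-cases round up: 37.5 -> 38, 29.75 -> 30
  expect_identical(percent_of_set(3, 8), 38L)
  expect_identical(percent_of_set(123, 328), 38L)
  expect_error(percent_of_set(1, 0), "positive")
  expect_error(percent_of_set(5, 4), "exceeds")
})

test_that("percent_of_set is bounded and monotone in the overlap", {
  set.seed(42)
  for (i in 1:20) {
    n_set <- sample(1:500, 1)
    p <- percent_of_set(0:n_set, n_set)
    expect_true(all(p >= 0L & p <= 100L))
    expect_true(all(diff(p) >= 0L))
  }
})

test_that("venn regions partition the union and reproduce per-set sizes", {
  v <- venn_regions(list(A = gene_set(1:3), B = gene_set(4:7)))
  expect_equal(unname(v$regions[c("A", "B", "A&B")]), c(3L, 4L, 0L))
  expect_true(is.na(v$neither))  # no frame supplied: undefined, not zero

  set.seed(7)
  universe <- as.character(1:40)
  for (i in 1:25) {
    sets <- random_sets(3, universe, 1L, 10L)
    v <- venn_regions(sets)
    union_n <- length(unique(unlist(lapply(sets, function(s) s$members))))
    expect_equal(sum(v$regions), union_n)
    for (nm in names(sets)) {
      in_regions <- grepl(nm, names(v$regions), fixed = TRUE)
      expect_equal(sum(v$regions[in_regions]), length(sets[[nm]]$members))
    }
    # brute-force per-gene classification
    memb <- lapply(sets, function(s) s$members)
    pool <- unique(unlist(memb))
    brute <- table(vapply(pool, function(g) {
      paste(names(sets)[vapply(memb, function(m) g %in% m, logical(1))], collapse = "&")
    }, character(1)))
    for (r in names(brute)) expect_equal(unname(v$regions[r]), unname(as.integer(brute[r])))
  }
})

test_that("venn regions reject more than 3 sets and namespace mixes", {
  expect_error(venn_regions(lapply(1:4, function(i) gene_set(i))), "2 or 3")
  expect_error(venn_regions(list(A = gene_set("1"), B = gene_set("X", namespace = "symbol"))),
               "namespace")
})

test_that("collections enforce the universe invariant", {
  sets <- list(A = gene_set(1:5, name = "A"), B = gene_set(4:8, name = "B"))
  col <- gene_set_collection(sets)
  expect_equal(universe_size(col), 8L)
  expect_error(gene_set_collection(sets, universe = 6), "smaller")
  u <- gene_set(1:6, name = "U_6")
  expect_error(gene_set_collection(sets, universe = u), "not in the universe")
  expect_message(col2 <- gene_set_collection(sets, universe = u, restrict = TRUE),
                 "dropping 2")
  expect_equal(col2$sets$B$members, c("4", "5", "6"))
})
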