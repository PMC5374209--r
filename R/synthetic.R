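# Planted-structure synthetic data: gene-set collections with known
# enriched pairs, citation corpora with known co-cited (set, heading)
# pairs, and PPI graphs with hubs of known degree. Truth labels make
# every pipeline stage testable without any download.

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the observed scale of the curated datasets the pipeline
#' is designed for: a ~20,000-gene universe (roughly the human
#' protein-coding complement), reference sets of 50-4,500 members (the
#' span from the smallest PPI set, ~50 genes, to the largest curated
#' database, ~4,000-4,500), and a reference collection of 100 sets
#' (scalable toward the ~2,000 of a full production collection).
#'
#' Planted query sets share exactly `ceiling(rho * |A||B| / N)` members
#' with their target reference set -- `rho` is the multiplier over the
#' null hypergeometric expectation `|A||B|/N`, and exact-count
#' construction keeps truth overlaps known exactly. Feasibility requires
#' `rho * max(|A|,|B|) <= N`, hence the narrower default planted size
#' ranges.
#'
#' @param seed RNG seed (integer).
#' @param n_universe universe size (default 20000).
#' @param n_reference_sets number of null reference sets (default 100).
#' @param set_size_range size range for null reference sets (default
#'   c(50, 4500), clamped to the universe size).
#' @param n_planted_pairs number of (query, reference) pairs with planted
#'   overlap (default 0).
#' @param rho planted overlap enrichment factor, `>= 1`; 1 reduces to the
#'   null.
#' @param planted_query_size_range,planted_ref_size_range size ranges for
#'   the planted queries and their target references.
#' @param n_null_queries number of additional query sets drawn uniformly
#'   from the universe (for null calibration).
#' @param null_query_size size of each null query (default 100).
#' @param corpus list of corpus parameters: `n_articles`,
#'   `genes_per_article` (Poisson mean), `n_headings`,
#'   `planted_set_size`, `cocitation_boost` (0 = independence null),
#'   `zipf_exponent` (citation counts per gene are Zipf-like).
#' @param graph list of graph parameters: `n_nodes`, `edge_density`,
#'   `n_hubs`, `hub_degree`.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_universe = 20000L,
                             n_reference_sets = 100L,
                             set_size_range = NULL,
                             n_planted_pairs = 0L,
                             rho = 1,
                             planted_query_size_range = c(100L, 500L),
                             planted_ref_size_range = c(200L, 1500L),
                             n_null_queries = 0L,
                             null_query_size = 100L,
                             corpus = list(),
                             graph = list()) {
  corpus_defaults <- list(n_articles = 2000L, genes_per_article = 3,
                          n_headings = 10L, planted_set_size = 100L,
                          cocitation_boost = 0, zipf_exponent = 1.1)
  graph_defaults <- list(n_nodes = 300L, edge_density = 0.01,
                         n_hubs = 2L, hub_degree = 15L)
  corpus <- utils::modifyList(corpus_defaults, corpus)
  graph <- utils::modifyList(graph_defaults, graph)
  if (is.null(set_size_range)) {
    # default 50-4500 at the reference 20,000-gene scale, clamped for
    # smaller universes
    set_size_range <- c(min(50L, n_universe), min(4500L, n_universe))
  }
  cfg <- list(seed = as.integer(seed), n_universe = as.integer(n_universe),
              n_reference_sets = as.integer(n_reference_sets),
              set_size_range = as.integer(set_size_range),
              n_planted_pairs = as.integer(n_planted_pairs), rho = rho,
              planted_query_size_range = as.integer(planted_query_size_range),
              planted_ref_size_range = as.integer(planted_ref_size_range),
              n_null_queries = as.integer(n_null_queries),
              null_query_size = as.integer(null_query_size),
              corpus = corpus, graph = graph)
  with(cfg, {
    stopifnot(n_universe > 0, n_reference_sets > 0, rho >= 1,
              length(set_size_range) == 2L, set_size_range[1L] > 0,
              set_size_range[2L] >= set_size_range[1L],
              set_size_range[2L] <= n_universe,
              n_planted_pairs >= 0, n_null_queries >= 0,
              null_query_size > 0, null_query_size <= n_universe,
              corpus$n_articles > 0, corpus$genes_per_article > 0,
              corpus$n_headings > 0, corpus$cocitation_boost >= 0,
              graph$n_nodes > 2, graph$edge_density >= 0,
              graph$n_hubs >= 0, graph$hub_degree >= 0)
  })
  structure(cfg, class = "synthetic_config")
}

sample_size <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n) else
    sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a gene-set collection with planted overlap enrichment
#'
#' Null reference sets are sampled uniformly without replacement from the
#' universe. Each planted pair consists of a query set constructed to
#' share exactly `ceiling(rho * |A||B| / N)` members with its target
#' reference set (the remaining query members are drawn from outside the
#' target), so at `rho = 1` planted pairs are indistinguishable from the
#' null in expectation. Fully deterministic under a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `collection` (a [gene_set_collection] whose
#'   universe is the full synthetic universe), `truth` (data frame
#'   `query`, `reference`, `n_overlap`, `rho` -- the planted pairs) and
#'   `config`.
#' @export
make_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  N <- config$n_universe
  universe_ids <- as.character(seq_len(N))
  universe <- gene_set(universe_ids, name = sprintf("Universe_%d", N))

  sets <- list()
  roles <- character(0)

  np <- config$n_planted_pairs
  ref_sizes <- integer(config$n_reference_sets)
  if (np > config$n_reference_sets) {
    stop("more planted pairs than reference sets", call. = FALSE)
  }
  if (np > 0L) ref_sizes[seq_len(np)] <- sample_size(config$planted_ref_size_range, np)
  rest <- (np + 1L):config$n_reference_sets
  if (np < config$n_reference_sets) {
    ref_sizes[rest] <- sample_size(config$set_size_range, length(rest))
  }
  ref_members <- vector("list", config$n_reference_sets)
  for (i in seq_len(config$n_reference_sets)) {
    ref_members[[i]] <- sample(universe_ids, ref_sizes[i])
    nm <- sprintf("RefSet%03d_%d", i, ref_sizes[i])
    sets[[nm]] <- gene_set(ref_members[[i]], name = nm)
    roles[nm] <- "reference"
  }
  ref_names <- names(sets)

  truth <- data.frame(query = character(0), reference = character(0),
                      n_overlap = integer(0), rho = numeric(0),
                      stringsAsFactors = FALSE)
  if (np > 0L) {
    for (j in seq_len(np)) {
      qsize <- sample_size(config$planted_query_size_range)
      rsize <- ref_sizes[j]
      m <- as.integer(ceiling(config$rho * qsize * rsize / N))
      if (m > min(qsize, rsize)) {
        stop(sprintf("infeasible planted overlap: need %d shared members for sizes (%d, %d)",
                     m, qsize, rsize), call. = FALSE)
      }
      shared <- sample(ref_members[[j]], m)
      outside <- sample(setdiff(universe_ids, ref_members[[j]]), qsize - m)
      nm <- sprintf("Query%02d_%d", j, qsize)
      sets[[nm]] <- gene_set(c(shared, outside), name = nm)
      roles[nm] <- "query"
      truth <- rbind(truth, data.frame(query = nm, reference = ref_names[j],
                                       n_overlap = m, rho = config$rho,
                                       stringsAsFactors = FALSE))
    }
  }
  if (config$n_null_queries > 0L) {
    for (j in seq_len(config$n_null_queries)) {
      nm <- sprintf("NullQuery%03d_%d", j, config$null_query_size)
      sets[[nm]] <- gene_set(sample(universe_ids, config$null_query_size), name = nm)
      roles[nm] <- "query"
    }
  }
  collection <- gene_set_collection(sets, universe = universe, roles = roles)
  list(collection = collection, truth = truth, config = config)
}

#' Generate a citation corpus with a planted co-citation pair
#'
#' Per-gene citation propensities are Zipf-distributed (rank^-s over a
#' seeded permutation of the universe), emulating the heavy skew of
#' real literature coverage. Each article cites `max(1, Poisson(mean))`
#' genes and carries 1-3 of the available headings. When
#' `cocitation_boost > 0`, articles carrying the planted heading draw
#' each gene slot from the planted gene set with probability
#' `min(0.9, boost * w0)`, where `w0` is the planted set's baseline Zipf
#' mass -- at `boost = 0` gene draws are independent of headings and the
#' corpus is an exact null.
#'
#' @param config a [synthetic_config()]; see its `corpus` entry.
#' @return list with `corpus` (a [citation_corpus]), `planted_set` (a
#'   [gene_set], or NULL when `cocitation_boost == 0`), `truth` (data
#'   frame `set`, `heading`, `boost`) and `config`.
#' @export
make_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cc <- config$corpus
  N <- config$n_universe
  universe_ids <- as.character(seq_len(N))
  w <- (seq_len(N))^(-cc$zipf_exponent)
  w <- w[sample.int(N)]                  # seeded permutation of propensities
  w <- w / sum(w)

  headings <- sprintf("Heading %02d", seq_len(cc$n_headings))
  planted <- cc$cocitation_boost > 0
  planted_set <- NULL
  truth <- data.frame(set = character(0), heading = character(0),
                      boost = numeric(0), stringsAsFactors = FALSE)
  p_draw <- 0
  planted_members <- character(0)
  if (planted) {
    planted_members <- sample(universe_ids, cc$planted_set_size)
    planted_set <- gene_set(planted_members,
                            name = sprintf("PlantedSet_%d", cc$planted_set_size))
    w0 <- sum(w[match(planted_members, universe_ids)])
    p_draw <- min(0.9, cc$cocitation_boost * w0)
    truth <- data.frame(set = planted_set$name, heading = headings[1L],
                        boost = cc$cocitation_boost, stringsAsFactors = FALSE)
  }

  n_art <- cc$n_articles
  n_genes <- pmax(1L, stats::rpois(n_art, cc$genes_per_article))
  n_heads <- sample(seq_len(min(3L, cc$n_headings)), n_art, replace = TRUE)
  mesh_art <- rep(seq_len(n_art), n_heads)
  mesh_heading <- unlist(lapply(n_heads, function(k) sample(headings, k)))

  has_planted_heading <- vapply(split(mesh_heading, mesh_art) ,
                                function(h) headings[1L] %in% h, logical(1))
  gene_art <- rep(seq_len(n_art), n_genes)
  total <- sum(n_genes)
  genes <- sample(universe_ids, total, replace = TRUE, prob = w)
  if (planted) {
    boosted_slot <- has_planted_heading[gene_art] & stats::runif(total) < p_draw
    if (any(boosted_slot)) {
      genes[boosted_slot] <- sample(planted_members, sum(boosted_slot), replace = TRUE)
    }
  }
  gene_links <- unique(data.frame(article = gene_art, gene = genes,
                                  stringsAsFactors = FALSE))
  mesh_links <- data.frame(article = mesh_art, heading = mesh_heading,
                           stringsAsFactors = FALSE)
  corpus <- citation_corpus(gene_links, mesh_links)
  list(corpus = corpus, planted_set = planted_set, truth = truth, config = config)
}

#' Generate a PPI graph with hubs of known degree
#'
#' Random (Erdos-Renyi) edges among non-hub nodes at the configured
#' density, plus `n_hubs` designated hub nodes each connected to exactly
#' `hub_degree` distinct non-hub nodes (hubs share no edges with each
#' other), so expanding a hub recovers exactly its recorded neighbor
#' list.
#'
#' @param config a [synthetic_config()]; see its `graph` entry.
#' @return list with `edges` (a `"ppi_edges"` data frame), `hubs` (named
#'   list: hub id -> character vector of its neighbors) and `config`.
#' @export
make_graph <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- config$graph
  nodes <- sprintf("G%04d", seq_len(g$n_nodes))
  hubs <- if (g$n_hubs > 0L) nodes[seq_len(g$n_hubs)] else character(0)
  others <- setdiff(nodes, hubs)
  if (g$hub_degree > length(others)) {
    stop("hub_degree exceeds the number of non-hub nodes", call. = FALSE)
  }

  a <- character(0); b <- character(0)
  m <- length(others)
  n_pairs <- as.integer(round(g$edge_density * m * (m - 1) / 2))
  if (n_pairs > 0L) {
    idx <- sample.int(m * (m - 1) / 2, n_pairs)
    # unrank upper-triangle pair index
    i <- ceiling((2 * m - 1 - sqrt((2 * m - 1)^2 - 8 * idx)) / 2)
    j <- idx - (i - 1) * (2 * m - i) / 2 + i
    a <- c(a, others[i]); b <- c(b, others[j])
  }
  hub_neighbors <- list()
  for (h in hubs) {
    nb <- sort(sample(others, g$hub_degree))
    hub_neighbors[[h]] <- nb
    a <- c(a, rep(h, length(nb))); b <- c(b, nb)
  }
  score <- stats::runif(length(a))
  edges <- ppi_edges(a, b, score = round(score, 3), source = "synthetic")
  list(edges = edges, hubs = hub_neighbors, config = config)
}

#' Recovery and false-discovery metrics against planted truth
#'
#' Scores enrichment reports against the generator's truth labels:
#' `recall@k` is the fraction of planted (query, reference) pairs whose
#' reference ranks in the top `k` rows of that query's report; the
#' false-discovery proportion (FDP) of a report is the fraction of its
#' discoveries at `fdr < fdr_threshold` that are not planted, and
#' `mean_fdp` averages over reports (`FDP = V / max(R, 1)`).
#'
#' With empty truth, recall is undefined and reported as `NA`; the FDP is
#' then the pure-null false-discovery proportion.
#'
#' @param reports a single `"enrichment_report"` or a named list of them
#'   (names = query set names).
#' @param truth data frame with columns `query`, `reference` (as returned
#'   by [make_collection()]); may have zero rows.
#' @param k rank depth for recall (default 5).
#' @param fdr_threshold discovery threshold on `fdr` (default 0.05).
#' @return list with `recall_at_k`, `k`, `mean_fdp`, `n_discoveries`,
#'   `per_query` (data frame of per-report counts).
#' @export
evaluate_recovery <- function(reports, truth, k = 5L, fdr_threshold = 0.05) {
  if (inherits(reports, "enrichment_report")) {
    reports <- stats::setNames(list(reports), attr(reports, "query_name"))
  }
  stopifnot(is.list(reports), length(reports) > 0L)
  if (is.null(names(reports))) {
    names(reports) <- vapply(reports, attr, character(1), "query_name")
  }
  if (nrow(truth) > 0L && !all(truth$query %in% names(reports))) {
    stop("truth refers to queries with no report: mismatched generation run?",
         call. = FALSE)
  }

  hits <- logical(0)
  if (nrow(truth) > 0L) {
    hits <- vapply(seq_len(nrow(truth)), function(i) {
      rep_i <- reports[[truth$query[i]]]
      truth$reference[i] %in% utils::head(rep_i$reference, k)
    }, logical(1))
  }
  per_query <- do.call(rbind, lapply(names(reports), function(qn) {
    rep_i <- reports[[qn]]
    disc <- rep_i$reference[rep_i$fdr < fdr_threshold]
    true_refs <- truth$reference[truth$query == qn]
    v <- length(setdiff(disc, true_refs))
    data.frame(query = qn, n_discoveries = length(disc), n_false = v,
               fdp = v / max(length(disc), 1L), stringsAsFactors = FALSE)
  }))
  list(recall_at_k = if (length(hits) > 0L) mean(hits) else NA_real_,
       k = as.integer(k),
       mean_fdp = mean(per_query$fdp),
       n_discoveries = sum(per_query$n_discoveries),
       per_query = per_query)
}
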