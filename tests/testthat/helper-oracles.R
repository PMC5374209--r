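# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (direct enumeration / linear scans) and
# share no code with the implementation paths they check.

# Right-tail hypergeometric by direct binomial-coefficient enumeration.
brute_fisher <- function(N, q, r, k) {
  kmax <- min(q, r)
  if (k > kmax) stop("impossible table")
  total <- choose(N, q)
  sum(vapply(k:kmax, function(i) choose(r, i) * choose(N - r, q - i), numeric(1))) / total
}

# Brute-force co-citation: scan every article in the corpus.
brute_cocite_ids <- function(corpus, members, heading) {
  hn <- tolower(gsub("[[:space:]]+", " ", trimws(heading)))
  arts <- unique(c(corpus$gene_links$article, corpus$mesh_links$article))
  hits <- vapply(arts, function(a) {
    cites <- corpus$gene_links$gene[corpus$gene_links$article == a]
    heads <- corpus$mesh_links$heading_norm[corpus$mesh_links$article == a]
    any(cites %in% members) && hn %in% heads
  }, logical(1))
  sort(arts[hits])
}

# Brute-force first-neighbor expansion: linear scan of the edge list.
brute_neighbors <- function(seeds, edges, include_seeds = TRUE) {
  nb <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (edges$a[i] %in% seeds) nb <- c(nb, edges$b[i])
    if (edges$b[i] %in% seeds) nb <- c(nb, edges$a[i])
  }
  if (include_seeds) sort(unique(c(nb, seeds))) else sort(setdiff(unique(nb), seeds))
}

# Random gene sets over a small universe.
random_sets <- function(n_sets, universe, min_size = 1L, max_size = length(universe)) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sz <- sample(min_size:max_size, 1L)
    gene_set(sample(universe, sz), name = sprintf("S%d_%d", i, sz))
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

# Tiny gene2pubmed / mesh files written to a temp dir.
write_gene2pubmed_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("#tax_id\tGeneID\tPubMed_ID", lines), path)
  path
}
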