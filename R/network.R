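# Protein-protein interaction neighborhoods: load an edge list, expand
# seed genes to their first neighbors, merge neighborhoods into disease sets.

canonicalize_edges <- function(a, b, score = NA_real_, source = NA_character_) {
  a <- trimws(as.character(a)); b <- trimws(as.character(b))
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  score <- rep_len(as.numeric(score), length(keep))[keep]
  source <- rep_len(as.character(source), length(keep))[keep]
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self]); b2 <- pmax(a[!self], b[!self])
  df <- data.frame(a = a2, b = b2, score = score[!self], source = source[!self],
                   stringsAsFactors = FALSE)
  # duplicate edges: keep the maximum score, first source
  if (nrow(df) > 0L) {
    key <- paste(df$a, df$b, sep = "\t")
    o <- order(key, -ifelse(is.na(df$score), -Inf, df$score))
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(paste(df$a, df$b, sep = "\t")), , drop = FALSE]
    df <- df[order(df$a, df$b), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_self_loops") <- n_self
  df
}

#' Load a protein-protein interaction edge list
#'
#' Reads a HIPPIE-style tab-separated edge file: two identifier columns,
#' an optional numeric confidence score in `[0, 1]`, an optional free-text
#' source tag. Edges are stored undirected in canonical order, duplicates
#' are collapsed keeping the maximum score, and self-loops are dropped
#' (counted in the `n_self_loops` attribute). No score threshold is
#' applied unless `min_score` is given -- curation deliberately imposes no
#' further selection criteria by default.
#'
#' @param path file path (`#`-prefixed lines skipped).
#' @param min_score optional minimum confidence; edges below it (or with
#'   no score) are dropped.
#' @return object of class `"ppi_edges"`: data frame with columns `a`,
#'   `b`, `score`, `source`; attributes `n_self_loops`, `n_malformed`.
#' @export
load_edges <- function(path, min_score = NULL) {
  lines <- read_tab_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  n_malformed <- sum(!ok)
  parts <- parts[ok]
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  score <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[[3L]])) else NA_real_
  }, numeric(1))
  source <- vapply(parts, function(p) {
    if (length(p) >= 4L) p[[4L]] else NA_character_
  }, character(1))
  df <- canonicalize_edges(a, b, score, source)
  if (!is.null(min_score)) {
    df <- df[!is.na(df$score) & df$score >= min_score, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (nrow(df) == 0L) stop(sprintf("no parseable edges in '%s'", path), call. = FALSE)
  structure(df, n_malformed = n_malformed, class = c("ppi_edges", "data.frame"))
}

#' In-memory PPI edge list
#'
#' Same canonicalization as [load_edges()] for edges already in R.
#'
#' @param a,b character vectors of interactor identifiers.
#' @param score optional numeric confidence.
#' @param source optional source tag.
#' @return a `"ppi_edges"` data frame.
#' @export
ppi_edges <- function(a, b, score = NA_real_, source = NA_character_) {
  df <- canonicalize_edges(a, b, score, source)
  structure(df, class = c("ppi_edges", "data.frame"))
}

#' Expand seed genes to their first PPI neighborhood
#'
#' Builds the first-neighbor protein network around one or more seed
#' genes: members are the seeds plus every gene sharing an edge with a
#' seed (or neighbors only with `include_seeds = FALSE`; both conventions
#' are supported because published set sizes do not always say whether
#' the seed counted itself). Only direct interactors are taken -- no
#' multi-hop expansion. Per-member provenance records which seed(s)
#' contributed each gene.
#'
#' @param seeds a [gene_set] or character vector of seed genes.
#' @param edges a `"ppi_edges"` data frame.
#' @param include_seeds include the seeds in the member set (default TRUE).
#' @param name optional name for the resulting set.
#' @return object of class `"neighborhood_set"`: list with `seeds`,
#'   `members` (a [gene_set]), `provenance` (named list: member ->
#'   contributing seeds) and `include_seeds`.
#' @export
expand_ppi <- function(seeds, edges, include_seeds = TRUE, name = NULL) {
  seed_ids <- as_gene_members(seeds)
  if (length(seed_ids) == 0L) stop("seeds must be non-empty", call. = FALSE)
  stopifnot(is.data.frame(edges), all(c("a", "b") %in% names(edges)))

  touched <- edges$a %in% seed_ids | edges$b %in% seed_ids
  if (!any(touched) && nrow(edges) > 0L) {
    warning("no seed gene present in the edge list", call. = FALSE)
  }
  e <- edges[touched, , drop = FALSE]
  prov <- list()
  add_prov <- function(member, seed) {
    prov[[member]] <<- sort(unique(c(prov[[member]], seed)))
  }
  for (i in seq_len(nrow(e))) {
    if (e$a[i] %in% seed_ids) add_prov(e$b[i], e$a[i])
    if (e$b[i] %in% seed_ids) add_prov(e$a[i], e$b[i])
  }
  members <- names(prov)
  if (include_seeds) {
    for (s in seed_ids) add_prov(s, "seed")
    members <- sort(unique(c(members, seed_ids)))
  } else {
    members <- sort(setdiff(members, seed_ids))
    prov <- prov[members]
  }
  ns <- if (all(grepl("^[0-9]+$", members)) && length(members) > 0L) "entrez" else "symbol"
  if (is.null(name)) {
    name <- sprintf("%s_PPI_%d", paste(utils::head(seed_ids, 3L), collapse = "+"),
                    length(members))
  }
  structure(list(seeds = seed_ids,
                 members = gene_set(members, name = name, namespace = ns),
                 provenance = prov, include_seeds = include_seeds),
            class = "neighborhood_set")
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat(sprintf("<neighborhood_set> %d seed(s) -> %d members (seeds %s)\n",
              length(x$seeds), length(x$members$members),
              if (x$include_seeds) "included" else "excluded"))
  invisible(x)
}

#' Merge PPI neighborhoods into one disease gene set
#'
#' Unions the member sets of several seed-gene neighborhoods into a single
#' disease- or mechanism-level gene set (the way per-gene PPI sets are
#' combined into their cognate disease set), carrying per-gene provenance:
#' the list of contributing seed genes. The operation is associative and
#' commutative up to provenance ordering.
#'
#' @param neighborhoods named list of `"neighborhood_set"` objects (bare
#'   [gene_set] objects are accepted too).
#' @param name optional name for the merged set; defaults to
#'   `"<name>_<size>"` from the neighborhood names.
#' @return a [gene_set] whose `provenance` maps each member to the seeds
#'   (or source neighborhoods) that contributed it.
#' @export
merge_disease_set <- function(neighborhoods, name = NULL) {
  if (length(neighborhoods) == 0L) stop("need at least one neighborhood", call. = FALSE)
  if (inherits(neighborhoods, "neighborhood_set") || inherits(neighborhoods, "gene_set")) {
    neighborhoods <- list(neighborhoods)
  }
  prov <- list()
  spaces <- character(0)
  for (i in seq_along(neighborhoods)) {
    nb <- neighborhoods[[i]]
    label <- names(neighborhoods)[i]
    if (inherits(nb, "neighborhood_set")) {
      ms <- nb$members$members
      spaces <- c(spaces, nb$members$namespace)
      for (m in ms) {
        contrib <- nb$provenance[[m]]
        if (is.null(contrib)) contrib <- label
        contrib[contrib == "seed"] <- m
        prov[[m]] <- sort(unique(c(prov[[m]], contrib)))
      }
    } else if (inherits(nb, "gene_set")) {
      spaces <- c(spaces, nb$namespace)
      for (m in nb$members) {
        prov[[m]] <- sort(unique(c(prov[[m]],
                                   if (is.null(label) || is.na(label)) "set" else label)))
      }
    } else {
      stop("neighborhoods must be neighborhood_set or gene_set objects", call. = FALSE)
    }
  }
  members <- sort(names(prov))
  ns <- unique(spaces)
  ns <- if (length(ns) == 1L) ns else "symbol"
  if (is.null(name)) name <- sprintf("Merged_%d", length(members))
  gene_set(members, name = name, namespace = ns, provenance = prov[members])
}
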