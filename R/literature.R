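# Literature co-citation index: gene -> article links (gene2pubmed dialect)
# joined on article with article -> MeSH heading annotations.

normalize_heading <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Load gene-to-article links in the gene2pubmed dialect
#'
#' Reads the NCBI-style three-column tab-separated table
#' (`tax_id`, `GeneID`, `PubMed_ID`; a `#`-prefixed header line is
#' tolerated), keeps only rows of the requested taxon, collapses duplicate
#' (gene, article) pairs and counts malformed rows instead of failing on
#' them.
#'
#' @param path file path.
#' @param taxon NCBI taxonomy id to keep (default 9606, human).
#' @return data frame with columns `article` (integer) and `gene`
#'   (character); attributes `n_malformed` and `n_duplicates`.
#' @export
load_gene2pubmed <- function(path, taxon = 9606) {
  lines <- read_tab_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 3L
  n_malformed <- sum(!ok)
  parts <- parts[ok]
  tax <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
  gene <- trimws(vapply(parts, `[[`, character(1), 2L))
  art <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  good <- !is.na(tax) & !is.na(art) & art > 0L & nzchar(gene)
  n_malformed <- n_malformed + sum(!good)
  keep <- good & tax == taxon
  df <- data.frame(article = art[keep], gene = gene[keep], stringsAsFactors = FALSE)
  n_dup <- sum(duplicated(df))
  df <- unique(df)
  if (nrow(df) == 0L) {
    stop(sprintf("no gene-article links for taxon %d in '%s'", taxon, path), call. = FALSE)
  }
  df <- df[order(df$article, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_malformed = n_malformed, n_duplicates = n_dup)
}

#' Load article-to-MeSH annotations
#'
#' Two-column tab-separated table (`PubMed_ID`, `MeSH heading`), with an
#' optional `#`-prefixed header. Headings are whitespace-normalized;
#' duplicate (article, heading) pairs -- compared case-insensitively -- are
#' collapsed.
#'
#' @param path file path.
#' @return data frame with columns `article` (integer), `heading`
#'   (original spelling) and `heading_norm` (matching key).
#' @export
load_mesh_links <- function(path) {
  lines <- read_tab_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  n_malformed <- sum(!ok)
  parts <- parts[ok]
  art <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
  heading <- gsub("[[:space:]]+", " ", trimws(vapply(parts, `[[`, character(1), 2L)))
  good <- !is.na(art) & art > 0L & nzchar(heading)
  n_malformed <- n_malformed + sum(!good)
  df <- data.frame(article = art[good], heading = heading[good],
                   stringsAsFactors = FALSE)
  df$heading_norm <- normalize_heading(df$heading)
  df <- df[!duplicated(df[c("article", "heading_norm")]), , drop = FALSE]
  if (nrow(df) == 0L) stop(sprintf("no article-heading links in '%s'", path), call. = FALSE)
  df <- df[order(df$article, df$heading_norm), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_malformed = n_malformed)
}

#' Build a citation corpus
#'
#' Combines gene-to-article links with article-to-MeSH annotations into a
#' corpus supporting co-citation queries. The two link tables need not
#' cover the same articles; co-citation is a join on article id.
#'
#' @param gene_links data frame with columns `article`, `gene` (as from
#'   [load_gene2pubmed()]).
#' @param mesh_links data frame with columns `article`, `heading` (as from
#'   [load_mesh_links()]; a `heading_norm` column is added if absent).
#' @return object of class `"citation_corpus"`.
#' @export
citation_corpus <- function(gene_links, mesh_links) {
  stopifnot(all(c("article", "gene") %in% names(gene_links)),
            all(c("article", "heading") %in% names(mesh_links)))
  gl <- data.frame(article = as.integer(gene_links$article),
                   gene = as.character(gene_links$gene), stringsAsFactors = FALSE)
  if (any(is.na(gl$article)) || any(gl$article <= 0L)) {
    stop("article ids must be positive integers", call. = FALSE)
  }
  gl <- unique(gl)
  ml <- data.frame(article = as.integer(mesh_links$article),
                   heading = as.character(mesh_links$heading), stringsAsFactors = FALSE)
  if (any(is.na(ml$article)) || any(ml$article <= 0L)) {
    stop("article ids must be positive integers", call. = FALSE)
  }
  ml$heading_norm <- normalize_heading(ml$heading)
  ml <- ml[!duplicated(ml[c("article", "heading_norm")]), , drop = FALSE]
  structure(list(gene_links = gl, mesh_links = ml), class = "citation_corpus")
}

#' @export
print.citation_corpus <- function(x, ...) {
  cat(sprintf("<citation_corpus> %d gene-article links (%d articles, %d genes); %d article-heading links (%d headings)\n",
              nrow(x$gene_links), length(unique(x$gene_links$article)),
              length(unique(x$gene_links$gene)),
              nrow(x$mesh_links), length(unique(x$mesh_links$heading_norm))))
  invisible(x)
}

#' Articles co-citing a gene set and a MeSH heading
#'
#' Finds every article that cites at least one member of the gene set
#' *and* carries the MeSH heading (matched exactly, case-insensitively,
#' after whitespace normalization; no MeSH-tree descendant expansion).
#' A heading absent from the corpus yields an empty result with
#' `heading_found = FALSE` -- a valid survey outcome, not an error.
#'
#' @param corpus a [citation_corpus].
#' @param genes a [gene_set] or character vector; must be non-empty.
#' @param heading a single MeSH heading.
#' @return object of class `"cocitation_result"`: list with
#'   `gene_set_name`, `heading`, `article_ids` (sorted integer vector),
#'   `n_articles`, `per_gene_counts` (named integer vector, co-citing
#'   articles per member gene) and `heading_found`.
#' @export
cocite <- function(corpus, genes, heading) {
  stopifnot(inherits(corpus, "citation_corpus"), length(heading) == 1L)
  members <- as_gene_members(genes)
  if (length(members) == 0L) stop("gene set is empty", call. = FALSE)
  gname <- if (inherits(genes, "gene_set") && !is.null(genes$name)) genes$name else "gene_set"
  hn <- normalize_heading(heading)
  heading_found <- hn %in% corpus$mesh_links$heading_norm
  if (!heading_found) {
    warning(sprintf("heading '%s' not present in corpus", heading), call. = FALSE)
    return(structure(list(gene_set_name = gname, heading = heading,
                          article_ids = integer(0), n_articles = 0L,
                          per_gene_counts = integer(0), heading_found = FALSE),
                     class = "cocitation_result"))
  }
  gl <- corpus$gene_links[corpus$gene_links$gene %in% members, , drop = FALSE]
  arts_g <- unique(gl$article)
  arts_h <- corpus$mesh_links$article[corpus$mesh_links$heading_norm == hn]
  ids <- sort(intersect(arts_g, arts_h))
  gl_hit <- gl[gl$article %in% ids, , drop = FALSE]
  per_gene <- integer(0)
  if (nrow(gl_hit) > 0L) {
    tab <- table(gl_hit$gene)
    per_gene <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(gene_set_name = gname, heading = heading,
                 article_ids = ids, n_articles = length(ids),
                 per_gene_counts = per_gene, heading_found = TRUE),
            class = "cocitation_result")
}

#' @export
print.cocitation_result <- function(x, ...) {
  cat(sprintf("<cocitation_result> '%s' x \"%s\": %d co-citing articles%s\n",
              x$gene_set_name, x$heading, x$n_articles,
              if (!x$heading_found) " (heading not in corpus)" else ""))
  invisible(x)
}

#' Survey a gene set across several MeSH headings
#'
#' One [cocite()] call per heading, returned as a table sorted by
#' descending article count with alphabetical tie-break -- the repeated,
#' human-in-the-loop survey step used to pick literature corners worth
#' reading.
#'
#' @param corpus a [citation_corpus].
#' @param genes a [gene_set] or character vector.
#' @param headings non-empty character vector of MeSH headings.
#' @return data frame with columns `heading`, `n_articles`,
#'   `heading_found`, sorted (count desc, heading asc).
#' @export
mesh_survey <- function(corpus, genes, headings) {
  if (length(headings) == 0L) stop("headings must be non-empty", call. = FALSE)
  res <- lapply(headings, function(h) {
    r <- suppressWarnings(cocite(corpus, genes, h))
    data.frame(heading = h, n_articles = r$n_articles,
               heading_found = r$heading_found, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$n_articles, out$heading), , drop = FALSE]
  rownames(out) <- NULL
  out
}
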