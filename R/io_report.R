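# Readers/writers for gene-set formats, packaged fixtures, and the
# table-style outputs (overlap summaries, relative-percent matrices).

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then one member per
#' column. CRLF line endings are accepted; lines with fewer than three
#' fields are reported (with their line numbers) and skipped.
#'
#' @param path file path.
#' @param namespace namespace to assign to the sets.
#' @return named list of [gene_set] objects; attribute `descriptions`
#'   carries the description field per set, `bad_lines` the skipped line
#'   numbers.
#' @export
read_gmt <- function(path, namespace = "entrez") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(lines)
  sets <- list()
  descriptions <- character(0)
  bad <- integer(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) { bad <- c(bad, i); next }
    nm <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[nm]] <- gene_set(members, name = nm, namespace = namespace)
    descriptions[nm] <- fields[2L]
  }
  if (length(bad) > 0L) {
    warning(sprintf("skipped %d malformed GMT line(s): %s", length(bad),
                    paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  if (length(sets) == 0L) stop(sprintf("no gene sets in '%s'", path), call. = FALSE)
  structure(sets, descriptions = descriptions, bad_lines = bad)
}

#' Write gene sets in GMT format
#'
#' Tabs inside descriptions would corrupt the format and are replaced by
#' single spaces. Member order is not significant in GMT; members are
#' written sorted, so write-read round trips are identity on the sets.
#'
#' @param sets named list of [gene_set] objects, or a
#'   [gene_set_collection] (its universe is not written).
#' @param path output path.
#' @param descriptions optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  nms <- names(sets)
  lines <- vapply(nms, function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    d <- gsub("\t", " ", d, fixed = TRUE)
    paste(c(gsub("\t", " ", nm, fixed = TRUE), d, sets[[nm]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a two-column TSV
#'
#' Alternative loader: tab-separated `set_name`, `gene`, one membership
#' per row; `#`-prefixed header tolerated.
#'
#' @param path file path.
#' @param namespace namespace to assign.
#' @return named list of [gene_set] objects.
#' @export
read_tsv_sets <- function(path, namespace = "entrez") {
  lines <- read_tab_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (any(!ok)) {
    warning(sprintf("skipped %d malformed line(s): %s", sum(!ok),
                    paste(utils::head(which(!ok), 10L), collapse = ", ")), call. = FALSE)
  }
  parts <- parts[ok]
  if (length(parts) == 0L) stop(sprintf("no set rows in '%s'", path), call. = FALSE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  by_set <- split(gene, nm)
  sets <- lapply(names(by_set), function(s) {
    gene_set(by_set[[s]], name = s, namespace = namespace)
  })
  stats::setNames(sets, names(by_set))
}

#' Pairwise overlap summary table
#'
#' One row per (query, reference) pair with the standard column
#' semantics of a published overlap table: sizes, shared-member count,
#' Fisher right-tail p, per-query BH FDR over the supplied references,
#' `-log10 FDR`, and integer percents of each side. Rows are grouped by
#' query in input order, references ranked within each query
#' deterministically (see [enrich()]).
#'
#' @param collection a [gene_set_collection].
#' @param queries,refs character vectors of set names in `collection`.
#' @param universe optional universe override passed to [enrich()].
#' @return data frame (one `enrich()` report per query, row-bound).
#' @export
summarize_overlaps <- function(collection, queries, refs, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  unknown <- setdiff(c(queries, refs), names(collection$sets))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown set name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  out <- lapply(queries, function(q) {
    as.data.frame(enrich(q, collection, universe = universe, refs = refs))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative percent-overlap matrix
#'
#' Entry (i, j) is `percent_of_set(|t_i ∩ a_j|, |t_i|)`: the integer
#' percentage of target set i covered by set j -- the data behind
#' relative-percent-overlap bar charts.
#'
#' @param targets,against named lists of [gene_set] objects (percent is
#'   relative to the target).
#' @return integer matrix, rows = targets, columns = against.
#' @export
relative_percent_table <- function(targets, against) {
  if (length(targets) == 0L || length(against) == 0L) {
    stop("targets and against must be non-empty", call. = FALSE)
  }
  if (any(vapply(targets, function(s) length(as_gene_members(s)) == 0L, logical(1)))) {
    stop("empty target set", call. = FALSE)
  }
  tn <- names(targets); an <- names(against)
  if (is.null(tn)) tn <- paste0("target", seq_along(targets))
  if (is.null(an)) an <- paste0("against", seq_along(against))
  m <- matrix(0L, nrow = length(targets), ncol = length(against),
              dimnames = list(tn, an))
  for (i in seq_along(targets)) {
    ti <- as_gene_members(targets[[i]])
    for (j in seq_along(against)) {
      m[i, j] <- percent_of_set(length(intersect(ti, as_gene_members(against[[j]]))),
                                length(ti))
    }
  }
  m
}

#' Write an enrichment report or overlap summary to disk
#'
#' TSV columns: query, reference, n_universe, n_query, n_ref, n_common,
#' p_value, fdr, neg_log_fdr, pct_of_query, pct_of_ref. JSON output
#' carries the same rows plus the report attributes.
#'
#' @param report an `"enrichment_report"` or data frame from
#'   [summarize_overlaps()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- c("query", "reference", "n_universe", "n_query", "n_ref", "n_common",
            "p_value", "fdr", "neg_log_fdr", "pct_of_query", "pct_of_ref")
  df <- as.data.frame(report)[, intersect(cols, names(report)), drop = FALSE]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(query = attr(report, "query_name"),
                    n_universe = attr(report, "n_universe"),
                    rows = df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

setlink_extdata <- function(file) {
  path <- system.file("extdata", file, package = "setlink")
  if (!nzchar(path)) stop(sprintf("packaged fixture '%s' not found", file), call. = FALSE)
  path
}

#' The 27-gene exosome-function fixture table
#'
#' The curated set of 27 genes required for exosome release, uptake and
#' multi-vesicular-body trafficking in the neuronal context, with
#' verbatim membership tags for the perturbation database (experimental
#' platform tags such as `"HD Fly; Aggreg"`) and the interactome.
#'
#' @return data frame with columns `row`, `exosome_function`, `dme_gene`,
#'   `symbol`, `gene_name`, `perturbdb`, `interactome`.
#' @export
exosome_table1 <- function() {
  df <- utils::read.delim(setlink_extdata("table1_exosome_genes.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = NULL)
  df$perturbdb[is.na(df$perturbdb)] <- ""
  df$interactome[is.na(df$interactome)] <- ""
  df
}

#' Gene sets derived from the exosome-function fixture
#'
#' Parses the verbatim platform tags of [exosome_table1()] into boolean
#' membership and returns the three symbol-namespace gene sets: the full
#' 27-gene exosome-function set, its members flagged in the perturbation
#' database, and its members flagged in the interactome.
#'
#' @return named list of [gene_set] objects: `exosome`, `perturbdb`,
#'   `interactome`.
#' @export
table1_gene_sets <- function() {
  df <- exosome_table1()
  list(
    exosome = gene_set(df$symbol, name = sprintf("ExosomeFunctional_%d", nrow(df)),
                       namespace = "symbol"),
    perturbdb = gene_set(df$symbol[nzchar(df$perturbdb)],
                         name = "ExosomeFunctional_in_PerturbDB", namespace = "symbol"),
    interactome = gene_set(df$symbol[df$interactome == "Yes"],
                           name = "ExosomeFunctional_in_Interactome", namespace = "symbol")
  )
}

#' Printed overlap-count fixture rows
#'
#' Set sizes, shared-member counts, printed FDRs and printed
#' percent-of-set values transcribed from the reference overlap tables.
#' The printed FDRs depend on the original private ~2,000-set reference
#' collection and unstated universe, so they are reference values only;
#' the count and percent arithmetic is fully recomputable (see
#' [percent_of_set()]). Rows whose printed percent is inconsistent with
#' its own counts carry a non-empty `note`.
#'
#' @return data frame with columns `table`, `set_a`, `n_a`, `set_b`,
#'   `n_b`, `n_common`, `printed_fdr`, `printed_percent`, `note`.
#' @export
printed_overlap_counts <- function() {
  df <- utils::read.delim(setlink_extdata("printed_overlap_counts.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$note[is.na(df$note)] <- ""
  df
}
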