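#' Construct a gene set
#'
#' A gene set is a named, deduplicated, unordered collection of normalized
#' gene identifiers. Members are stored as a sorted character vector; Entrez
#' identifiers are plain integer strings, symbols are upper-case, and miRNA
#' identifiers live in their own namespace and are never intersected with
#' protein-coding sets by the higher-level drivers.
#'
#' By convention set names may carry a size suffix (`"PerturbDB_1218"`). The
#' suffix is advisory metadata: a mismatch with the actual member count
#' raises a warning, not an error, because downstream filtering (for example
#' restriction to an analysis universe) legitimately shrinks sets.
#'
#' @param members character (or coercible) vector of gene identifiers.
#' @param name optional set label; `"<Name>_<size>"` convention supported.
#' @param namespace one of `"entrez"`, `"symbol"`, `"mirna"`.
#' @param provenance optional named list or character vector of free-text
#'   source tags, named by member.
#' @return an object of class `"gene_set"`.
#' @export
gene_set <- function(members, name = NULL, namespace = c("entrez", "symbol", "mirna"),
                     provenance = NULL) {
  namespace <- match.arg(namespace)
  members <- as.character(members)
  members <- trimws(members)
  members <- members[!is.na(members) & nzchar(members)]
  members <- sort(unique(members))
  if (namespace == "entrez" && length(members) > 0L &&
      !all(grepl("^[0-9]+$", members))) {
    stop("entrez members must be positive integer identifiers", call. = FALSE)
  }
  if (!is.null(name)) {
    suffix <- sub("^.*_([0-9]+)$", "\\1", name)
    if (suffix != name && nzchar(suffix)) {
      declared <- as.integer(suffix)
      if (!is.na(declared) && declared != length(members)) {
        warning(sprintf("set '%s' declares size %d but has %d members",
                        name, declared, length(members)), call. = FALSE)
      }
    }
  }
  if (!is.null(provenance)) {
    provenance <- as.list(provenance)
    extra <- setdiff(names(provenance), members)
    if (length(extra) > 0L) provenance <- provenance[setdiff(names(provenance), extra)]
  }
  structure(list(name = name, members = members, namespace = namespace,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members (%s)\n",
              if (is.null(x$name)) "<unnamed>" else x$name,
              length(x$members), x$namespace))
  shown <- utils::head(x$members, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$members) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

as_gene_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else sort(unique(trimws(as.character(x))))
}

#' Normalize raw gene identifiers to human gene IDs
#'
#' Applies the ortholog-aware normalization policy used when assembling
#' cross-species perturbation databases: raw tokens with an entry in the
#' ortholog map contribute *all* of their mapped human identifiers (a fly or
#' worm gene mapping to several closely related human orthologs yields every
#' one of them); tokens with no map entry are kept if they already look like
#' human identifiers (integer Entrez IDs always; upper-cased symbols under
#' the default lenient policy) and excluded otherwise. Exclusions are
#' counted and reported, never silently dropped.
#'
#' Normalization is idempotent: running the output through the same map
#' again returns the identical set.
#'
#' @param raw_ids character vector of raw tokens (symbols, IDs, mixed case).
#' @param ortholog_map `NULL` (identity mapping) or a data frame with
#'   columns `raw` and `human`, one row per mapping; repeat `raw` for
#'   one-to-many mappings. Matching on `raw` is case-insensitive.
#' @param policy `"lenient"` keeps unmapped non-numeric tokens as upper-case
#'   symbols; `"strict_entrez"` excludes them.
#' @param name optional name for the resulting set.
#' @param namespace namespace of the resulting set (default `"entrez"` when
#'   strict, `"symbol"` when lenient output contains any non-numeric token).
#' @return a list with elements `set` (a [gene_set]), `excluded` (character
#'   vector of excluded raw tokens) and `n_excluded`.
#' @export
normalize_gene_ids <- function(raw_ids, ortholog_map = NULL,
                               policy = c("lenient", "strict_entrez"),
                               name = NULL, namespace = NULL) {
  policy <- match.arg(policy)
  if (length(raw_ids) == 0L) stop("raw_ids is empty: nothing to normalize", call. = FALSE)
  raw <- trimws(as.character(raw_ids))
  raw <- raw[!is.na(raw)]
  if (length(raw) == 0L || !any(nzchar(raw))) {
    stop("raw_ids is empty after trimming whitespace", call. = FALSE)
  }

  map_keys <- character(0)
  if (!is.null(ortholog_map) && nrow(ortholog_map) > 0L) {
    if (!all(c("raw", "human") %in% names(ortholog_map))) {
      stop("ortholog_map must have columns 'raw' and 'human'", call. = FALSE)
    }
    map_keys <- toupper(trimws(as.character(ortholog_map$raw)))
    map_vals <- trimws(as.character(ortholog_map$human))
  }

  out <- character(0)
  excluded <- character(0)
  for (tok in raw) {
    if (!nzchar(tok)) { excluded <- c(excluded, tok); next }
    key <- toupper(tok)
    hit <- which(map_keys == key)
    if (length(hit) > 0L) {
      out <- c(out, map_vals[hit])         # one-to-many: include all orthologs
    } else if (grepl("^[0-9]+$", tok)) {
      out <- c(out, tok)
    } else if (policy == "lenient") {
      out <- c(out, key)
    } else {
      excluded <- c(excluded, tok)
    }
  }
  out <- sort(unique(out))
  if (is.null(namespace)) {
    namespace <- if (length(out) > 0L && all(grepl("^[0-9]+$", out))) "entrez" else "symbol"
  }
  list(set = gene_set(out, name = name, namespace = namespace),
       excluded = excluded, n_excluded = length(excluded))
}

#' Overlap counts of two gene sets
#'
#' @param a,b [gene_set] objects or character vectors.
#' @return named list with `n_a`, `n_b`, `n_common`, `n_union`.
#' @export
overlap <- function(a, b) {
  ma <- as_gene_members(a); mb <- as_gene_members(b)
  n_common <- length(intersect(ma, mb))
  list(n_a = length(ma), n_b = length(mb),
       n_common = n_common, n_union = length(ma) + length(mb) - n_common)
}

#' Integer percent of a set covered by an overlap
#'
#' Computes `100 * n_common / n_set` rounded to the nearest integer, half
#' away from zero -- the rounding rule consistent with every printed
#' percent-of-set column in the reference tables (e.g. 49/80 -> 61,
#' 24/357 -> 7, 436/1619 -> 27, 123/328 -> 38 from 37.5).
#'
#' @param n_common overlap count(s); vectorized.
#' @param n_set set size(s); must be positive, `n_common <= n_set`.
#' @return integer percent(s) in `[0, 100]`.
#' @export
percent_of_set <- function(n_common, n_set) {
  if (length(n_set) == 1L) n_set <- rep(n_set, length(n_common))
  if (any(is.na(n_common)) || any(is.na(n_set))) stop("NA counts", call. = FALSE)
  if (any(n_set <= 0)) stop("n_set must be positive", call. = FALSE)
  if (any(n_common < 0)) stop("n_common must be non-negative", call. = FALSE)
  if (any(n_common > n_set)) stop("n_common exceeds n_set", call. = FALSE)
  as.integer(floor(100 * n_common / n_set + 0.5))
}

#' Disjoint Venn/Euler region cardinalities for 2 or 3 gene sets
#'
#' Classifies every gene of the union into its disjoint membership region
#' (3 regions for two sets, 7 for three). A "neither" count is computed
#' only when an explicit frame set is supplied; without a frame it is
#' undefined (`NA`), not zero.
#'
#' @param sets named list of 2 or 3 [gene_set] objects (or character
#'   vectors); all in the same identifier namespace.
#' @param frame optional frame [gene_set] relative to which the
#'   "neither" region is counted.
#' @return an object of class `"venn_regions"`: list with `set_names`,
#'   `regions` (named integer vector; names are the member sets of each
#'   region joined by `"&"`), `neither`, `frame_name`.
#' @export
venn_regions <- function(sets, frame = NULL) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop("venn_regions supports exactly 2 or 3 sets", call. = FALSE)
  }
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(seq_along(sets), function(i) {
      s <- sets[[i]]
      if (inherits(s, "gene_set") && !is.null(s$name)) s$name else paste0("set", i)
    }, character(1))
  }
  spaces <- vapply(sets, function(s) {
    if (inherits(s, "gene_set")) s$namespace else NA_character_
  }, character(1))
  if (length(unique(stats::na.omit(spaces))) > 1L) {
    stop("sets must share one identifier namespace", call. = FALSE)
  }
  memb <- lapply(sets, as_gene_members)
  pool <- sort(unique(unlist(memb)))
  flags <- vapply(memb, function(m) pool %in% m, logical(length(pool)))
  if (length(pool) == 1L) flags <- matrix(flags, nrow = 1L)
  n <- length(sets)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), n))[, n:1, drop = FALSE]
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  region_names <- apply(patterns, 1L, function(p) paste(nms[as.logical(p)], collapse = "&"))
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(flags, 1L, function(f) all(f == as.logical(p))))
  })
  if (length(pool) == 0L) counts <- rep(0L, nrow(patterns))
  regions <- stats::setNames(as.integer(counts), region_names)

  neither <- NA_integer_
  frame_name <- NULL
  if (!is.null(frame)) {
    fm <- as_gene_members(frame)
    frame_name <- if (inherits(frame, "gene_set") && !is.null(frame$name)) frame$name else "frame"
    neither <- length(setdiff(fm, pool))
  }
  structure(list(set_names = nms, regions = regions,
                 neither = neither, frame_name = frame_name),
            class = "venn_regions")
}

#' @export
print.venn_regions <- function(x, ...) {
  cat("<venn_regions>", paste(x$set_names, collapse = " / "), "\n")
  for (i in seq_along(x$regions)) {
    cat(sprintf("  %-40s %d\n", names(x$regions)[i], x$regions[i]))
  }
  if (!is.na(x$neither)) {
    cat(sprintf("  %-40s %d  (frame: %s)\n", "neither", x$neither, x$frame_name))
  }
  invisible(x)
}

#' Assemble a gene-set collection over an analysis universe
#'
#' A collection holds a universe, a named list of sets, and a per-set role
#' tag (`"query"`, `"reference"`, or `"both"`) used by [enrich()] to decide
#' which sets form a query's test family. The universe may be an explicit
#' [gene_set] (every member of every set must belong to it; use
#' `restrict = TRUE` to drop outside members rather than fail), the string
#' `"union"` (default: the union of all loaded sets), or a fixed positive
#' integer used only as the total count `N` in contingency tables.
#'
#' The choice of universe is consequential for overlap testing -- a
#' too-large universe inflates significance -- so the resolved universe is
#' recorded in every enrichment report.
#'
#' @param sets named list of [gene_set] objects.
#' @param universe `"union"`, a [gene_set], or a single positive number.
#' @param roles named character vector (`query`/`reference`/`both`);
#'   defaults to `"both"` for every set.
#' @param restrict if `TRUE`, members outside an explicit universe are
#'   dropped (with a message); if `FALSE` (default) they are an error.
#' @return object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe = "union", roles = NULL,
                                restrict = FALSE) {
  if (length(sets) == 0L) stop("empty collection", call. = FALSE)
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  if (is.null(roles)) {
    roles <- stats::setNames(rep("both", length(sets)), nms)
  } else {
    if (!all(nms %in% names(roles))) stop("roles must cover every set", call. = FALSE)
    roles <- roles[nms]
    if (!all(roles %in% c("query", "reference", "both"))) {
      stop("roles must be 'query', 'reference' or 'both'", call. = FALSE)
    }
  }

  all_members <- sort(unique(unlist(lapply(sets, function(s) s$members))))
  if (identical(universe, "union")) {
    universe <- gene_set(all_members, name = sprintf("Union_%d", length(all_members)),
                         namespace = sets[[1L]]$namespace)
  } else if (is.numeric(universe) && length(universe) == 1L) {
    n <- as.integer(universe)
    if (is.na(n) || n < length(all_members)) {
      stop("fixed universe size is smaller than the union of the sets", call. = FALSE)
    }
    universe <- n                           # count-only universe
  } else if (inherits(universe, "gene_set")) {
    outside <- setdiff(all_members, universe$members)
    if (length(outside) > 0L) {
      if (!restrict) {
        stop(sprintf("%d set members are not in the universe (restrict = TRUE to drop them)",
                     length(outside)), call. = FALSE)
      }
      message(sprintf("restricting sets to universe: dropping %d outside members",
                      length(outside)))
      sets <- lapply(sets, function(s) {
        gene_set(intersect(s$members, universe$members), name = s$name,
                 namespace = s$namespace, provenance = s$provenance)
      })
      names(sets) <- nms
    }
  } else {
    stop("universe must be 'union', a gene_set, or a single number", call. = FALSE)
  }
  structure(list(universe = universe, sets = sets, roles = roles),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, universe size %d\n",
              length(x$sets), universe_size(x)))
  tab <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Size of a collection's universe
#' @param collection a [gene_set_collection].
#' @return integer universe size N.
#' @export
universe_size <- function(collection) {
  u <- collection$universe
  if (inherits(u, "gene_set")) length(u$members) else as.integer(u)
}

collection_sets <- function(collection, role) {
  keep <- collection$roles %in% c(role, "both")
  collection$sets[keep]
}
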