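# Statistical engine: exact Fisher right-tail overlap test computed in log
# space, per-query Benjamini-Hochberg FDR, -log10 FDR ranking.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_hyper_pmf_first <- function(N, q, r, i) {
  lchoose(r, i) + lchoose(N - r, q - i) - lchoose(N, q)
}

# log PMF over i = from..to via the term ratio
#   pmf(i+1)/pmf(i) = (r-i)(q-i) / ((i+1)(N-r-q+i+1))
# one lchoose evaluation for the first term, cheap multiplicative updates after.
log_hyper_pmf_range <- function(N, q, r, from, to) {
  if (to < from) return(numeric(0))
  i <- from:to
  first <- log_hyper_pmf_first(N, q, r, from)
  if (to == from) return(first)
  j <- from:(to - 1L)
  steps <- log(r - j) + log(q - j) - log(j + 1) - log(N - r - q + j + 1)
  c(first, first + cumsum(steps))
}

#' Fisher right-tail (hypergeometric) overlap probability
#'
#' Exact probability that two sets drawn from a universe of `n_universe`
#' genes share at least `n_common` members: `P(X >= k)` for `X`
#' hypergeometric with `n_universe` genes, `n_query` draws and `n_ref`
#' successes. This is the one-sided Fisher exact test for enrichment;
#' depletion (left tail) is deliberately not offered.
#'
#' The tail is accumulated directly in log space (log-gamma for the first
#' term, multiplicative ratio updates after, then log-sum-exp), never via
#' the complement of the left tail, so probabilities far below the double
#' underflow threshold keep accurate logarithms -- overlaps of large
#' curated sets routinely reach the 1e-300 scale.
#'
#' @param n_universe universe size N.
#' @param n_query,n_ref the two set sizes.
#' @param n_common observed overlap k.
#' @param log.p return the natural log of the probability?
#' @return the right-tail probability (or its log).
#' @export
fisher_right_tail <- function(n_universe, n_query, n_ref, n_common, log.p = FALSE) {
  N <- as.numeric(n_universe); q <- as.numeric(n_query)
  r <- as.numeric(n_ref); k <- as.numeric(n_common)
  if (any(is.na(c(N, q, r, k)))) stop("NA in contingency counts", call. = FALSE)
  if (N < 0 || q < 0 || r < 0 || k < 0) stop("negative contingency count", call. = FALSE)
  if (q > N || r > N) stop("set larger than universe", call. = FALSE)
  kmin <- max(0, q + r - N); kmax <- min(q, r)
  if (k > kmax || k < kmin) {
    stop(sprintf("impossible table: k=%g outside support [%g, %g]", k, kmin, kmax),
         call. = FALSE)
  }
  if (k <= kmin) {                     # full right tail
    return(if (log.p) 0 else 1)
  }
  # direct right-tail accumulation: no complement, so no cancellation even
  # when the tail mass sits far below double precision of the left tail
  lp <- min(logsumexp(log_hyper_pmf_range(N, q, r, k, kmax)), 0)
  if (log.p) lp else exp(lp)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: sort the p-values, multiply each by
#' `m / rank`, enforce monotone non-increase from the largest rank down,
#' cap at 1 and restore input order. Adjustment is always applied within
#' one query's test family (one query against all reference sets), never
#' pooled across queries.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return adjusted values, same order as the input.
#' @seealso [bh_adjust_log()] for the log-space variant used internally
#'   when p-values underflow double precision.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)       # largest p first: rank m, m-1, ...
  ranks <- m:1
  adj <- cummin(p[o] * m / ranks)
  adj <- pmin(adj, 1)
  adj[order(o)]
}

#' Benjamini-Hochberg adjustment of log p-values
#'
#' Log-space version of [bh_adjust()]: takes natural-log p-values and
#' returns natural-log adjusted values, so FDRs at the 1e-300 scale keep
#' accurate `-log10` representations.
#'
#' @param log_p vector of natural-log p-values (all `<= 0`).
#' @return natural-log adjusted values, input order.
#' @export
bh_adjust_log <- function(log_p) {
  if (length(log_p) == 0L) stop("empty p-value vector", call. = FALSE)
  lp <- as.numeric(log_p)
  if (any(is.na(lp)) || any(lp > 0)) stop("log p-values must be <= 0", call. = FALSE)
  m <- length(lp)
  o <- order(lp, decreasing = TRUE)
  ranks <- m:1
  adj <- cummin(lp[o] + log(m) - log(ranks))
  adj <- pmin(adj, 0)
  adj[order(o)]
}

#' Negative base-10 logarithm of an FDR
#'
#' The ranking statistic of the pipeline: `-log10(fdr)`, 0 for `fdr = 1`.
#'
#' @param fdr probability in (0, 1].
#' @return non-negative real.
#' @export
neg_log10 <- function(fdr) {
  if (any(is.na(fdr)) || any(fdr <= 0) || any(fdr > 1)) {
    stop("fdr must lie in (0, 1]", call. = FALSE)
  }
  -log10(fdr)
}

#' Overlap enrichment of one query set against a reference collection
#'
#' The core analysis step: for one query set and every reference set in a
#' collection, computes the overlap contingency counts against the resolved
#' universe, the exact Fisher right-tail p-value, the Benjamini-Hochberg
#' FDR within this query's test family only, the `-log10 FDR` ranking
#' statistic, and integer percent-of-set values for both sides. Rows are
#' ranked by descending `neg_log_fdr`, ties broken by descending
#' `n_common`, then ascending reference name, so output order is fully
#' deterministic.
#'
#' With an explicit (membership) universe the query and references are
#' first restricted to it; a query disjoint from the universe is an error.
#' With a count-only universe (a fixed N) the memberships are used as
#' given and N only scales the test.
#'
#' `p_value` and `fdr` are reported as doubles and underflow to 0 below
#' roughly 1e-308; `neg_log_fdr` (and `neg_log_p`) are computed in log
#' space and remain finite and accurate at any scale.
#'
#' @param query a [gene_set], or the name of a set in `collection`.
#' @param collection a [gene_set_collection].
#' @param universe override of the collection universe: `NULL` (use the
#'   collection's), a single number (fixed N), or a [gene_set].
#' @param refs optional character vector of reference set names; default:
#'   all sets with role `reference` or `both`.
#' @param cutoff optional minimum `neg_log_fdr`; rows below it are dropped
#'   (the conventional screening cutoff in this workflow is 10).
#' @return an `"enrichment_report"`: a data frame with columns `query`,
#'   `reference`, `n_universe`, `n_query`, `n_ref`, `n_common`, `p_value`,
#'   `fdr`, `neg_log_p`, `neg_log_fdr`, `pct_of_query`, `pct_of_ref`, plus
#'   attributes recording the query name, resolved universe size and cutoff.
#' @export
enrich <- function(query, collection, universe = NULL, refs = NULL, cutoff = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.character(query) && length(query) == 1L) {
    if (!query %in% names(collection$sets)) {
      stop(sprintf("unknown query set '%s'", query), call. = FALSE)
    }
    query <- collection$sets[[query]]
  }
  stopifnot(inherits(query, "gene_set"))
  qname <- if (is.null(query$name)) "query" else query$name

  if (is.null(universe)) universe <- collection$universe
  if (is.numeric(universe) && length(universe) == 1L) {
    N <- as.integer(universe)
    umembers <- NULL
  } else if (inherits(universe, "gene_set")) {
    N <- length(universe$members)
    umembers <- universe$members
  } else {
    stop("universe must be NULL, a number, or a gene_set", call. = FALSE)
  }

  ref_sets <- collection_sets(collection, "reference")
  if (!is.null(refs)) {
    missing <- setdiff(refs, names(collection$sets))
    if (length(missing) > 0L) {
      stop(sprintf("unknown reference set(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    ref_sets <- collection$sets[refs]
  }
  if (length(ref_sets) == 0L) stop("no reference sets to test against", call. = FALSE)

  qm <- query$members
  if (!is.null(umembers)) {
    qm <- intersect(qm, umembers)
    if (length(qm) == 0L) stop("query is disjoint from the universe", call. = FALSE)
  }
  nq <- length(qm)
  if (nq == 0L) stop("query set is empty", call. = FALSE)
  if (nq > N) stop("universe smaller than the query set", call. = FALSE)

  rows <- lapply(names(ref_sets), function(rn) {
    rm <- ref_sets[[rn]]$members
    if (!is.null(umembers)) rm <- intersect(rm, umembers)
    nr <- length(rm)
    if (nr > N) stop(sprintf("universe smaller than reference set '%s'", rn), call. = FALSE)
    k <- length(intersect(qm, rm))
    lp <- fisher_right_tail(N, nq, nr, k, log.p = TRUE)
    data.frame(query = qname, reference = rn, n_universe = N,
               n_query = nq, n_ref = nr, n_common = k, log_p = lp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$log_fdr <- bh_adjust_log(res$log_p)
  res$p_value <- exp(res$log_p)
  res$fdr <- exp(res$log_fdr)
  res$neg_log_p <- -res$log_p / log(10)
  res$neg_log_fdr <- -res$log_fdr / log(10)
  res$pct_of_query <- percent_of_set(res$n_common, res$n_query)
  res$pct_of_ref <- percent_of_set(res$n_common, res$n_ref)
  res$log_p <- NULL; res$log_fdr <- NULL

  ord <- order(-res$neg_log_fdr, -res$n_common, res$reference)
  res <- res[ord, , drop = FALSE]
  if (!is.null(cutoff)) {
    stopifnot(cutoff >= 0)
    res <- res[res$neg_log_fdr >= cutoff, , drop = FALSE]
  }
  rownames(res) <- NULL
  structure(res,
            class = c("enrichment_report", "data.frame"),
            query_name = qname, n_universe = N,
            cutoff = if (is.null(cutoff)) NA_real_ else cutoff)
}

#' @export
print.enrichment_report <- function(x, n = 10L, ...) {
  cat(sprintf("<enrichment_report> query '%s' vs %d reference sets (universe N = %d",
              attr(x, "query_name"), nrow(x), attr(x, "n_universe")))
  co <- attr(x, "cutoff")
  if (!is.na(co)) cat(sprintf(", -log FDR cutoff %.3g", co))
  cat(")\n")
  top <- utils::head(as.data.frame(x)[, c("reference", "n_ref", "n_common",
                                          "fdr", "neg_log_fdr", "pct_of_query")], n)
  print(top, digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.enrichment_report <- function(object, cutoff = 10, ...) {
  hits <- sum(object$neg_log_fdr >= cutoff)
  cat(sprintf("query '%s': %d reference sets tested, %d at -log FDR >= %.3g\n",
              attr(object, "query_name"), nrow(object), hits, cutoff))
  if (hits > 0L) {
    print(utils::head(as.data.frame(object)[object$neg_log_fdr >= cutoff,
                                            c("reference", "n_common", "neg_log_fdr")], 20L),
          digits = 4)
  }
  invisible(object)
}

#' @export
plot.enrichment_report <- function(x, n = 15L, ...) {
  top <- utils::head(x, n)
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(top$neg_log_fdr), names.arg = rev(top$reference),
                    horiz = TRUE, las = 1, xlab = "-log10 FDR",
                    main = attr(x, "query_name"), ...)
  invisible(x)
}
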