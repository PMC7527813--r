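## proteome_screen: whole-proteome application of the N-terminal classifier
## plus compartment / pathway over-representation statistics.

#' Scan a proteome for DPP8/9 substrate candidates
#'
#' Applies [classify_nterm()] to every record; one outcome row per record,
#' order preserved, deterministic.
#'
#' @param records a `protein_records` data frame (see [read_fasta()]).
#' @param rules a [motif_rules()] object.
#' @param degron_table residue-to-branch mapping.
#' @return a `processing_outcomes` data frame with columns `id`, `pattern`,
#'   `route`, `released` (`+`-joined peptides), `neo_residue`, `neo_prefix`,
#'   `degron_branch`, `degron_note`; fields of non-hits are empty strings.
#'   The rule variant used is attached as attribute `"variant"`.
#' @export
scan_proteome <- function(records, rules = motif_rules(),
                          degron_table = default_degron_table()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no protein records to scan")
  fields <- classify_fields(records$sequence, rules, degron_table)
  out <- cbind(data.frame(id = records$id, stringsAsFactors = FALSE),
               fields)
  class(out) <- c("processing_outcomes", "data.frame")
  attr(out, "variant") <- rules$variant
  out
}

#' Upper-tail hypergeometric over-representation probability
#'
#' Probability of observing `k` or more category members among `n` draws
#' without replacement from a population of `N` containing `K` category
#' members, i.e. `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.  Computed
#' via [stats::phyper()], numerically stable for `N` up to at least 1e5.
#'
#' @param k observed hits in the category.
#' @param K category size.
#' @param n total hits drawn.
#' @param N population (proteome) size.
#' @return the upper-tail probability, vectorised over the arguments.
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  k <- as.numeric(k); K <- as.numeric(K)
  n <- as.numeric(n); N <- as.numeric(N)
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 0 &
    K <= N & n <= N & k <= pmin(K, n)
  if (any(!ok | is.na(ok)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Summarize a proteome screen
#'
#' Computes the proteome-level summary: total and per-pattern hit counts,
#' the hit-by-MTS cross-tabulation, and one-sided hypergeometric
#' over-representation probabilities per compartment and per pathway label
#' with Benjamini-Hochberg adjustment across the tested categories (raw
#' values are always reported alongside).  Proteins without an annotation
#' row are counted under compartment `"unknown"` (and as carrying no MTS
#' flag) so totals always match the scanned collection.  Categories with
#' zero members are skipped, not reported.
#'
#' @param outcomes a `processing_outcomes` data frame from
#'   [scan_proteome()].
#' @param annotations an `annotation_table` data frame (see
#'   [read_annotation_table()]).
#' @return a `screen_summary` object: list with `n_total`, `n_hits`,
#'   `n_P3`, `n_P4`, `variant`, `n_unmatched_ids`, `mts_crosstab` (2x2
#'   matrix), `by_compartment` and `by_pathway` (data frames with category
#'   size, hit count, raw and BH-adjusted p-values).
#' @export
summarize_screen <- function(outcomes, annotations) {
  if (!is.data.frame(outcomes) || nrow(outcomes) == 0L)
    stop("no outcomes to summarize")
  if (anyDuplicated(annotations$id))
    stop("duplicate id(s) in annotation table")
  idx <- match(outcomes$id, annotations$id)
  unmatched <- is.na(idx)
  compartment <- ifelse(unmatched, "unknown", annotations$compartment[idx])
  mts <- ifelse(unmatched, FALSE, annotations$has_n_terminal_mts[idx])
  pathways <- vector("list", nrow(outcomes))
  pathways[!unmatched] <- annotations$pathways[idx[!unmatched]]
  pathways[unmatched] <- list(character())

  hit <- outcomes$pattern != "none"
  n_total <- nrow(outcomes)
  n_hits <- sum(hit)

  mts_crosstab <- matrix(c(sum(hit & mts), sum(hit & !mts),
                           sum(!hit & mts), sum(!hit & !mts)),
                         nrow = 2L, byrow = TRUE,
                         dimnames = list(c("hit", "no_hit"),
                                         c("mts", "no_mts")))

  enrich_table <- function(category) {
    cats <- sort(unique(category[!is.na(category)]))
    K <- vapply(cats, function(cc) sum(category == cc, na.rm = TRUE),
                integer(1L))
    keep <- K > 0L
    cats <- cats[keep]; K <- K[keep]
    if (length(cats) == 0L)
      return(data.frame(category = character(), n_in_category = integer(),
                        n_hits_in_category = integer(), p_value = numeric(),
                        p_adjust = numeric(), stringsAsFactors = FALSE))
    k <- vapply(cats, function(cc) sum(hit & category == cc, na.rm = TRUE),
                integer(1L))
    p <- hypergeom_enrichment(k, K, n_hits, n_total)
    data.frame(category = cats, n_in_category = K,
               n_hits_in_category = k, p_value = p,
               p_adjust = p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  by_compartment <- enrich_table(compartment)
  names(by_compartment)[1L] <- "compartment"

  labels <- sort(unique(unlist(pathways)))
  by_pathway <- if (length(labels) == 0L) {
    data.frame(pathway = character(), n_in_category = integer(),
               n_hits_in_category = integer(), p_value = numeric(),
               p_adjust = numeric(), stringsAsFactors = FALSE)
  } else {
    K <- vapply(labels, function(lab)
      sum(vapply(pathways, function(p) lab %in% p, logical(1L))),
      integer(1L))
    k <- vapply(labels, function(lab)
      sum(hit & vapply(pathways, function(p) lab %in% p, logical(1L))),
      integer(1L))
    p <- hypergeom_enrichment(k, K, n_hits, n_total)
    data.frame(pathway = labels, n_in_category = K,
               n_hits_in_category = k, p_value = p,
               p_adjust = p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  structure(list(n_total = n_total, n_hits = n_hits,
                 n_P3 = sum(outcomes$pattern == "P3"),
                 n_P4 = sum(outcomes$pattern == "P4"),
                 variant = attr(outcomes, "variant") %||% "legend",
                 n_unmatched_ids = sum(unmatched),
                 mts_crosstab = mts_crosstab,
                 by_compartment = by_compartment,
                 by_pathway = by_pathway),
            class = "screen_summary")
}

## JSON-friendly representation used by write_results().
summary_to_list <- function(summary) {
  stopifnot(inherits(summary, "screen_summary"))
  list(n_total = summary$n_total, n_hits = summary$n_hits,
       n_P3 = summary$n_P3, n_P4 = summary$n_P4,
       variant = summary$variant,
       n_unmatched_ids = summary$n_unmatched_ids,
       mts_crosstab = list(
         hit = as.list(summary$mts_crosstab["hit", ]),
         no_hit = as.list(summary$mts_crosstab["no_hit", ])),
       by_compartment = summary$by_compartment,
       by_pathway = summary$by_pathway)
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Proteome screen (%s variant): %d/%d motif-positive (P3 %d, P4 %d)\n",
              x$variant, x$n_hits, x$n_total, x$n_P3, x$n_P4))
  if (x$n_unmatched_ids > 0L)
    cat("  ids without annotation:", x$n_unmatched_ids, "\n")
  cat("  hit x MTS cross-tab:\n")
  print(x$mts_crosstab)
  if (nrow(x$by_compartment) > 0L) {
    cat("  compartment over-representation:\n")
    print(x$by_compartment, row.names = FALSE)
  }
  if (nrow(x$by_pathway) > 0L) {
    cat("  pathway over-representation:\n")
    print(x$by_pathway, row.names = FALSE)
  }
  invisible(x)
}
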