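## conservation: per-column residue profiles, information content, logo
## matrices and motif-conservation fractions for ortholog alignments.

#' Per-column residue profile of an ortholog alignment
#'
#' For each column, residue frequencies are computed over the 20 canonical
#' letters with `pseudocount` added per residue before normalisation.  Gaps
#' (and ambiguity letters) are excluded from the denominator; the gap
#' fraction is stored separately.  Information content per column is
#' `log2(20) - H` where `H` is the Shannon entropy (bits) of the column's
#' residue distribution; no small-sample correction is applied.
#'
#' @param alignment an `ortholog_alignment` object.
#' @param pseudocount non-negative value added per residue (default 0,
#'   matching raw-abundance logos).
#' @return an `alignment_profile` object: list with `name`, `n_sequences`,
#'   `n_columns`, `pseudocount`, `frequencies` (20 x n_columns matrix),
#'   `gap_fraction`, `information_bits`, `consensus` (string) and
#'   `consensus_tie` (logical per column, TRUE where the top frequency was
#'   tied and broken alphabetically).
#' @export
column_profile <- function(alignment, pseudocount = 0) {
  stopifnot(inherits(alignment, "ortholog_alignment"),
            length(pseudocount) == 1L, pseudocount >= 0)
  mat <- do.call(rbind, strsplit(alignment$sequences, "", fixed = TRUE))
  n_col <- ncol(mat)
  freq <- matrix(0, nrow = 20L, ncol = n_col,
                 dimnames = list(AA20, NULL))
  gap_fraction <- numeric(n_col)
  info <- numeric(n_col)
  consensus <- character(n_col)
  tie <- logical(n_col)
  for (j in seq_len(n_col)) {
    col <- mat[, j]
    gap_fraction[j] <- mean(col == "-")
    counts <- vapply(AA20, function(a) sum(col == a), numeric(1L))
    total <- sum(counts) + 20 * pseudocount
    if (total == 0)
      stop("column ", j, " has no canonical residues; ",
           "all-gap columns should have been trimmed on ingest")
    f <- (counts + pseudocount) / total
    freq[, j] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    info[j] <- log2(20) - h
    top <- which(f == max(f))
    consensus[j] <- AA20[top[1L]]  # ties broken alphabetically
    tie[j] <- length(top) > 1L
  }
  structure(list(name = alignment$name,
                 n_sequences = alignment$n_rows,
                 n_columns = n_col, pseudocount = pseudocount,
                 frequencies = freq, gap_fraction = gap_fraction,
                 information_bits = info,
                 consensus = paste(consensus, collapse = ""),
                 consensus_tie = tie),
            class = "alignment_profile")
}

#' Fraction of ortholog rows carrying the DPP8/9 motif
#'
#' Each row is degapped and its ungapped N-terminus matched with
#' [match_motif()]; the matched-row fraction is returned.  Inserting
#' gap-only columns does not change the result.
#'
#' @param alignment an `ortholog_alignment` object.
#' @param rules a [motif_rules()] object.
#' @return fraction in `[0, 1]`.
#' @export
motif_conservation <- function(alignment, rules = motif_rules()) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  degapped <- gsub("-", "", alignment$sequences, fixed = TRUE)
  if (length(degapped) == 0L || any(!nzchar(degapped)))
    stop("alignment contains empty rows")
  mean(match_motif(degapped, rules) != "none")
}

#' Residue-height matrix for sequence logos
#'
#' In `probability` mode heights are the residue frequencies; in
#' `information` mode each height is the residue frequency multiplied by
#' the column's information content, so heights in a column sum to that
#' column's information (bits).
#'
#' @param profile an `alignment_profile` from [column_profile()].
#' @param mode `"probability"` or `"information"`.
#' @return a 20 x n_columns numeric matrix (rows named by residue).
#' @export
logo_matrix <- function(profile, mode = c("probability", "information")) {
  stopifnot(inherits(profile, "alignment_profile"))
  mode <- match.arg(mode)
  if (mode == "probability") profile$frequencies
  else sweep(profile$frequencies, 2L, profile$information_bits, `*`)
}

#' Export an alignment profile
#'
#' Writes a per-column TSV (column index, 20 residue frequencies, gap
#' fraction, information content) and, optionally, a JSON file with the
#' consensus string and tie flags.
#'
#' @param profile an `alignment_profile`.
#' @param tsv_path output TSV path.
#' @param json_path optional JSON path for the consensus.
#' @return the written paths, invisibly.
#' @export
write_profile <- function(profile, tsv_path, json_path = NULL) {
  stopifnot(inherits(profile, "alignment_profile"))
  df <- data.frame(column = seq_len(profile$n_columns),
                   t(profile$frequencies),
                   gap_fraction = profile$gap_fraction,
                   information_bits = profile$information_bits,
                   check.names = FALSE)
  names(df)[2:21] <- paste0("freq_", AA20)
  write_tsv(df, tsv_path)
  paths <- tsv_path
  if (!is.null(json_path)) {
    jsonlite::write_json(list(name = profile$name,
                              n_sequences = profile$n_sequences,
                              consensus = profile$consensus,
                              consensus_tie = profile$consensus_tie),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, json_path)
  }
  invisible(paths)
}

#' Convenience sequence-logo plot
#'
#' Quick stacked-letter rendering of a logo matrix via ggplot2 (listed in
#' Suggests).  The exported matrix, not this plot, is the tested interface.
#'
#' @param profile an `alignment_profile`.
#' @param mode logo mode, see [logo_matrix()].
#' @return a ggplot object.
#' @export
plot_logo <- function(profile, mode = "information") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_logo() needs the ggplot2 package")
  m <- logo_matrix(profile, mode)
  df <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    h <- m[, j]
    h <- h[h > 0]
    if (length(h) == 0L) return(NULL)
    h <- sort(h)
    data.frame(column = j, residue = names(h), height = unname(h),
               y = cumsum(h) - h / 2, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$y,
                                   label = .data$residue,
                                   size = .data$height,
                                   colour = .data$residue)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::labs(x = "alignment column",
                  y = if (mode == "information") "bits" else "frequency",
                  title = profile$name) +
    ggplot2::theme_minimal()
}
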