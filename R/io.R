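## io_formats: FASTA / annotation-TSV / alignment ingest and result export.

#' Construct a protein record collection
#'
#' A protein record collection is a plain `data.frame` with columns
#' `id`, `description`, `sequence` and `length`.  Sequences are upper-cased
#' and validated against the 20 canonical amino-acid letters plus the
#' ambiguity letters `X, B, Z, U, J, O`.  Position numbering is 1-based with
#' the initiator residue at position 1.
#'
#' @param id character vector of unique, non-empty accessions.
#' @param sequence character vector of amino-acid sequences (length >= 1
#'   residue each).
#' @param description optional free-text descriptions (default `""`).
#' @return a `data.frame` of class `protein_records`.
#' @export
protein_records <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  description <- rep_len(as.character(description), length(id))
  if (length(id) == 0L) stop("no protein records")
  if (length(sequence) != length(id)) stop("id and sequence lengths differ")
  if (any(!nzchar(id))) stop("empty protein id")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L)
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("zero-length sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  ## a single trailing stop codon symbol is tolerated and stripped
  sequence <- sub("\\*$", "", sequence)
  for (i in seq_along(sequence)) {
    ch <- strsplit(sequence[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% AA_ALLOWED))
    if (length(bad) > 0L)
      stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                   ch[bad[1L]], bad[1L], id[i]))
  }
  out <- data.frame(id = id, description = description,
                    sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' One record per header, order preserved, wrapped lines concatenated,
#' sequences upper-cased.  The record id is the header token up to the first
#' whitespace; the remainder becomes the description.
#'
#' @param path path to a FASTA file.
#' @return a `protein_records` data frame (see [protein_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  protein_records(id = id, sequence = as.character(set),
                  description = description)
}

#' Write protein records as FASTA
#'
#' @param records a `protein_records` data frame.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a proteome annotation table
#'
#' Tab-separated with a header; required columns `id`, `compartment`,
#' `has_n_terminal_mts`; optional `symbol` and `pathways`
#' (semicolon-separated labels).  Compartment values outside the vocabulary
#' `matrix, IMS, IMM, OMM, membrane, unknown` are mapped to `"unknown"` with
#' a warning.  The boolean column accepts `0/1/true/false/yes/no`
#' case-insensitively.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `annotation_table` with columns `id`,
#'   `symbol`, `compartment`, `has_n_terminal_mts` (logical) and `pathways`
#'   (list column of character vectors).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character())
  required <- c("id", "compartment", "has_n_terminal_mts")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  compartment <- tab$compartment
  bad <- !(compartment %in% COMPARTMENT_VOCAB)
  if (any(bad)) {
    warning("unknown compartment value(s) mapped to 'unknown': ",
            paste(unique(compartment[bad]), collapse = ", "))
    compartment[bad] <- "unknown"
  }
  mts <- parse_boolean(tab$has_n_terminal_mts, "has_n_terminal_mts")
  pathways <- if ("pathways" %in% names(tab)) {
    lapply(strsplit(tab$pathways, ";", fixed = TRUE),
           function(p) p[nzchar(p)])
  } else {
    rep(list(character()), nrow(tab))
  }
  out <- data.frame(id = tab$id,
                    symbol = if ("symbol" %in% names(tab)) tab$symbol else "",
                    compartment = compartment,
                    has_n_terminal_mts = mts,
                    stringsAsFactors = FALSE)
  out$pathways <- pathways
  class(out) <- c("annotation_table", "data.frame")
  out
}

parse_boolean <- function(x, column) {
  v <- tolower(trimws(x))
  truthy <- v %in% c("1", "true", "yes")
  falsy <- v %in% c("0", "false", "no")
  if (any(!truthy & !falsy))
    stop(sprintf("column '%s' has non-boolean value(s): %s", column,
                 paste(unique(x[!truthy & !falsy]), collapse = ", ")))
  truthy
}

#' Write an annotation table as TSV
#'
#' Inverse of [read_annotation_table()]; pathway sets are joined with `;`.
#'
#' @param annotations an `annotation_table` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  stopifnot(is.data.frame(annotations), nrow(annotations) >= 1L)
  flat <- data.frame(id = annotations$id,
                     symbol = annotations$symbol,
                     compartment = annotations$compartment,
                     has_n_terminal_mts = as.integer(annotations$has_n_terminal_mts),
                     pathways = vapply(annotations$pathways, paste,
                                       character(1L), collapse = ";"),
                     stringsAsFactors = FALSE)
  write_tsv(flat, path)
  invisible(path)
}

#' Read a pre-computed ortholog alignment from aligned FASTA
#'
#' Rows must be equal width, use `-` as the gap character (`.` is accepted
#' and converted) and number at least two.  Columns that are entirely gaps
#' are trimmed on ingest.
#'
#' @param path path to an aligned FASTA file.
#' @param name family label (default: file name without extension).
#' @return an object of class `ortholog_alignment`: a list with elements
#'   `name`, `species`, `sequences` (aligned, upper-case), `n_rows`,
#'   `n_columns`.
#' @export
read_alignment <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no alignment records in file: ", path)
  ortholog_alignment(species = sub("\\s.*$", "", names(set)),
                     sequences = as.character(set),
                     name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct an ortholog alignment object
#'
#' @param species character vector of row labels.
#' @param sequences character vector of aligned sequences (gap `-`).
#' @param name family label.
#' @return an `ortholog_alignment` object; all-gap columns are trimmed.
#' @export
ortholog_alignment <- function(species, sequences, name = "alignment") {
  sequences <- toupper(as.character(sequences))
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  if (length(sequences) < 2L) stop("alignment needs at least 2 rows")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal widths: ",
         paste(unique(widths), collapse = ", "))
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bad <- !(mat %in% c(AA_ALLOWED, "-"))
  if (any(bad))
    stop("illegal alignment character(s): ",
         paste(unique(mat[bad]), collapse = ", "))
  all_gap <- colSums(mat != "-") == 0L
  if (any(all_gap)) {
    message("trimmed ", sum(all_gap), " all-gap column(s)")
    mat <- mat[, !all_gap, drop = FALSE]
    sequences <- apply(mat, 1L, paste, collapse = "")
  }
  if (ncol(mat) == 0L) stop("alignment has no non-gap columns")
  structure(list(name = name, species = as.character(species),
                 sequences = unname(sequences), n_rows = length(sequences),
                 n_columns = ncol(mat)),
            class = "ortholog_alignment")
}

#' Write an ortholog alignment as aligned FASTA
#'
#' @param alignment an `ortholog_alignment` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  set <- Biostrings::BStringSet(alignment$sequences)
  names(set) <- alignment$species
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

## Deterministic TSV writer shared by all outputs: UTF-8, '\t', '\n'.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write screen results to a directory
#'
#' Writes a per-protein TSV (`outcomes.tsv`: id, pattern, route, released
#' peptides, neo-N-terminal residue and prefix, degron class) and a JSON
#' summary (`summary.json`: counts, cross-tabs, enrichment tables).  Output
#' is byte-stable for identical inputs.
#'
#' @param outcomes a `processing_outcomes` data frame from
#'   [scan_proteome()].
#' @param summary a `screen_summary` from [summarize_screen()], or `NULL`
#'   to write only the per-protein table.
#' @param out_dir output directory (created if missing).
#' @return paths of the written files, invisibly.
#' @export
write_results <- function(outcomes, summary, out_dir) {
  if (!is.data.frame(outcomes) || nrow(outcomes) == 0L)
    stop("no outcomes to write")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  tsv <- file.path(out_dir, "outcomes.tsv")
  write_tsv(as.data.frame(outcomes), tsv)
  paths <- tsv
  if (!is.null(summary)) {
    json <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_to_list(summary), json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, json)
  }
  invisible(paths)
}

#' Read back a per-protein outcome TSV
#'
#' Inverse of the per-protein table written by [write_results()]; round-trips
#' the in-memory collection exactly.
#'
#' @param path path to `outcomes.tsv`.
#' @return a `processing_outcomes` data frame.
#' @export
read_outcomes <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = character())
  out <- data.frame(id = tab$id, pattern = tab$pattern, route = tab$route,
                    released = tab$released, neo_residue = tab$neo_residue,
                    neo_prefix = tab$neo_prefix,
                    degron_branch = tab$degron_branch,
                    degron_note = tab$degron_note, stringsAsFactors = FALSE)
  class(out) <- c("processing_outcomes", "data.frame")
  out
}
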