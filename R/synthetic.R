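## synthetic_data: generators for planted-motif proteomes with annotations
## and for substitution-model ortholog sets.  All randomness is local to a
## call (seed in the spec; caller RNG state is preserved).

#' Specification of a synthetic annotated proteome
#'
#' The generator emulates the structure of a mitochondrial-inventory screen:
#' N-terminal sequences with a controlled background residue distribution
#' and a planted fraction of motif-bearing N-termini that differs by
#' subcompartment (and optionally by pathway membership).
#'
#' Defaults encode the conditions the screen is validated under: 1,000
#' proteins of 30-60 residues, uniform background, compartment shares
#' matrix/IMM/IMS/OMM/membrane/unknown = 0.44/0.25/0.08/0.10/0.08/0.05 with
#' the planted motif probability 0.5 in the IMS against a 0.05 baseline
#' elsewhere, one pathway label (`disulfide_relay_substrate`, membership
#' 0.04, planted 0.3) and an independent MTS-flag probability of 0.4.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer min/max residue counts (min >= 4).
#' @param background_frequencies named numeric over the 20 canonical
#'   residues, summing to 1 (default uniform).
#' @param compartments data frame with columns `compartment`, `proportion`
#'   (summing to 1) and `planted_probability`.
#' @param pathways data frame with columns `pathway`,
#'   `membership_probability` and `planted_probability` (may have 0 rows).
#' @param mts_probability probability that a protein carries the
#'   N-terminal-MTS flag (drawn independently).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_proteins = 1000L,
                           length_range = c(30L, 60L),
                           background_frequencies = NULL,
                           compartments = NULL,
                           pathways = NULL,
                           mts_probability = 0.4,
                           seed = 1L) {
  if (is.null(background_frequencies))
    background_frequencies <- setNames(rep(1 / 20, 20L), AA20)
  if (is.null(compartments))
    compartments <- data.frame(
      compartment = c("matrix", "IMM", "IMS", "OMM", "membrane", "unknown"),
      proportion = c(0.44, 0.25, 0.08, 0.10, 0.08, 0.05),
      planted_probability = c(0.05, 0.05, 0.5, 0.05, 0.05, 0.05),
      stringsAsFactors = FALSE)
  if (is.null(pathways))
    pathways <- data.frame(pathway = "disulfide_relay_substrate",
                           membership_probability = 0.04,
                           planted_probability = 0.3,
                           stringsAsFactors = FALSE)
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L])
  if (length_range[1L] < 4L)
    stop("minimum protein length must be at least 4 (motif window)")
  if (!setequal(names(background_frequencies), AA20) ||
      abs(sum(background_frequencies) - 1) > 1e-9 ||
      any(background_frequencies < 0))
    stop("background_frequencies must be a distribution over the 20 canonical residues")
  if (abs(sum(compartments$proportion) - 1) > 1e-9)
    stop("compartment proportions must sum to 1")
  probs <- c(compartments$proportion, compartments$planted_probability,
             pathways$membership_probability, pathways$planted_probability,
             mts_probability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background_frequencies = background_frequencies[AA20],
                 compartments = compartments, pathways = pathways,
                 mts_probability = mts_probability,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Cached enumeration of all 4-mers matching a rule variant; planted
## N-termini are drawn uniformly from this set.
motif_4mer_cache <- new.env(parent = emptyenv())

#' All canonical 4-mers matching the motif
#'
#' Enumerates the 160,000 length-4 sequences over the canonical alphabet
#' and returns those that [match_motif()] accepts under `rules` (as a
#' 4-residue window; the 3-residue pattern contributes 4-mers whose fourth
#' residue is free).
#'
#' @param rules a [motif_rules()] object.
#' @return character vector of matching 4-mers.
#' @export
motif_4mers <- function(rules = motif_rules()) {
  key <- rules$variant
  if (!is.null(motif_4mer_cache[[key]])) return(motif_4mer_cache[[key]])
  grid <- expand.grid(p4 = AA20, p3 = AA20, p2 = AA20, p1 = AA20,
                      stringsAsFactors = FALSE)
  all4 <- paste0(grid$p1, grid$p2, grid$p3, grid$p4)
  hits <- all4[match_motif(all4, rules) != "none"]
  motif_4mer_cache[[key]] <- hits
  hits
}

#' Closed-form accidental motif-match rate of a background model
#'
#' Probability that an i.i.d. background N-terminus (length >= 4) matches
#' the motif by chance:
#' `P(M) * P(pos2 allowed) * P(P) * P(pos4 != P)` for the 4-residue
#' pattern plus `P(M) * P(P) * P(pos3 != P)` for the 3-residue pattern
#' (the two events are disjoint through position 3).
#'
#' @param background_frequencies named distribution over the 20 canonical
#'   residues.
#' @param rules a [motif_rules()] object.
#' @return the match probability.
#' @export
accidental_match_rate <- function(background_frequencies = NULL,
                                  rules = motif_rules()) {
  if (is.null(background_frequencies))
    background_frequencies <- setNames(rep(1 / 20, 20L), AA20)
  b <- background_frequencies[AA20]
  p4 <- b[["M"]] * sum(b[setdiff(AA20, rules$pos2_excluded)]) *
    b[["P"]] * (1 - b[["P"]])
  p3 <- b[["M"]] * b[["P"]] * (1 - b[["P"]])
  unname(p4 + p3)
}

#' Generate a synthetic annotated proteome
#'
#' For each protein a compartment is drawn from the spec proportions and
#' pathway memberships from their probabilities; with the largest planted
#' probability among its compartment and pathways the N-terminal 4-mer is
#' forced to a uniformly drawn motif-matching 4-mer (legend variant),
#' otherwise the whole sequence is i.i.d. background.  Accidental motif
#' matches among unplanted proteins are kept and recorded, so the analytic
#' background rate stays exact.
#'
#' @param spec a [synthetic_spec()] object.
#' @return list with `records` (a `protein_records` data frame),
#'   `annotations` (an `annotation_table`) and `truth` (data frame with
#'   per-protein `id`, `compartment`, `planted`, `planted_prefix`,
#'   `pattern` as observed by the legend-variant matcher, and `accidental`).
#' @export
gen_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    comp <- sample(spec$compartments$compartment, n, replace = TRUE,
                   prob = spec$compartments$proportion)
    planted_p <- spec$compartments$planted_probability[
      match(comp, spec$compartments$compartment)]
    memberships <- matrix(FALSE, nrow = n, ncol = nrow(spec$pathways))
    if (nrow(spec$pathways) > 0L)
      for (j in seq_len(nrow(spec$pathways))) {
        memberships[, j] <- runif(n) < spec$pathways$membership_probability[j]
        in_path <- memberships[, j]
        planted_p[in_path] <- pmax(planted_p[in_path],
                                   spec$pathways$planted_probability[j])
      }
    planted <- runif(n) < planted_p
    len <- sample(seq(spec$length_range[1L], spec$length_range[2L]),
                  n, replace = TRUE)
    residues <- sample(AA20, sum(len), replace = TRUE,
                       prob = spec$background_frequencies)
    seqs <- vapply(split(residues, rep.int(seq_len(n), len)),
                   paste, character(1L), collapse = "")
    pool <- motif_4mers(motif_rules("legend"))
    prefix <- sample(pool, n, replace = TRUE)
    seqs[planted] <- paste0(prefix[planted],
                            substr(seqs[planted], 5L, len[planted]))
    mts <- runif(n) < spec$mts_probability

    id <- sprintf("SYN%05d", seq_len(n))
    records <- protein_records(id = id, sequence = seqs,
                               description = "synthetic protein")
    pathways <- lapply(seq_len(n), function(i)
      spec$pathways$pathway[memberships[i, ]])
    annotations <- data.frame(id = id, symbol = paste0("G", seq_len(n)),
                              compartment = comp,
                              has_n_terminal_mts = mts,
                              stringsAsFactors = FALSE)
    annotations$pathways <- pathways
    class(annotations) <- c("annotation_table", "data.frame")
    pattern <- match_motif(seqs, motif_rules("legend"))
    truth <- data.frame(id = id, compartment = comp, planted = planted,
                        planted_prefix = ifelse(planted, prefix, ""),
                        pattern = pattern,
                        accidental = !planted & pattern != "none",
                        stringsAsFactors = FALSE)
    list(records = records, annotations = annotations, truth = truth)
  })
}

#' Specification of a synthetic ortholog set
#'
#' Substitution-only model (no indels, so rows are trivially aligned).
#' With `motif_conservation_probability` the 4-residue N-terminal block of
#' a row is copied intact from the base sequence; otherwise every block
#' position is redrawn from the background, which keeps the generating
#' probability identifiable from the matched-row fraction up to the small
#' closed-form accidental-match rate.  Positions beyond the block are
#' substituted independently with `substitution_probability`.
#'
#' @param base_sequence base amino-acid sequence (length >= 4).
#' @param n_species number of rows (default 11, a typical small ortholog
#'   panel).
#' @param substitution_probability per-position substitution probability
#'   outside the motif block (default 0.1).
#' @param motif_conservation_probability probability the motif block is
#'   copied intact (default 0.9).
#' @param background_frequencies substitution target distribution (default
#'   uniform over the 20 canonical residues).
#' @param seed integer seed.
#' @return an `ortholog_spec` object.
#' @export
ortholog_spec <- function(base_sequence, n_species = 11L,
                          substitution_probability = 0.1,
                          motif_conservation_probability = 0.9,
                          background_frequencies = NULL,
                          seed = 1L) {
  base_sequence <- toupper(base_sequence)
  if (nchar(base_sequence) < 4L)
    stop("base_sequence must be at least 4 residues")
  if (is.null(background_frequencies))
    background_frequencies <- setNames(rep(1 / 20, 20L), AA20)
  stopifnot(n_species >= 2L,
            substitution_probability >= 0, substitution_probability <= 1,
            motif_conservation_probability >= 0,
            motif_conservation_probability <= 1)
  structure(list(base_sequence = base_sequence,
                 n_species = as.integer(n_species),
                 substitution_probability = substitution_probability,
                 motif_conservation_probability = motif_conservation_probability,
                 background_frequencies = background_frequencies[AA20],
                 seed = as.integer(seed)),
            class = "ortholog_spec")
}

#' Generate a synthetic ortholog alignment
#'
#' @param spec an [ortholog_spec()] object.
#' @return an `ortholog_alignment` (gap-free; rows `species_001`, ...).
#' @export
gen_ortholog_set <- function(spec) {
  stopifnot(inherits(spec, "ortholog_spec"))
  with_seed(spec$seed, {
    base <- strsplit(spec$base_sequence, "", fixed = TRUE)[[1L]]
    L <- length(base)
    n <- spec$n_species
    rows <- matrix(rep(base, each = n), nrow = n)
    if (L > 4L) {
      tail_idx <- 5:L
      mutate <- matrix(runif(n * length(tail_idx)) <
                         spec$substitution_probability,
                       nrow = n)
      repl <- sample(AA20, sum(mutate), replace = TRUE,
                     prob = spec$background_frequencies)
      rows[, tail_idx][mutate] <- repl
    }
    conserved <- runif(n) < spec$motif_conservation_probability
    n_redraw <- sum(!conserved)
    if (n_redraw > 0L)
      rows[!conserved, 1:4] <- sample(AA20, 4L * n_redraw, replace = TRUE,
                                      prob = spec$background_frequencies)
    sequences <- apply(rows, 1L, paste, collapse = "")
    ortholog_alignment(species = sprintf("species_%03d", seq_len(n)),
                       sequences = sequences,
                       name = paste0("synthetic_orthologs_",
                                     substr(spec$base_sequence, 1L, 4L)))
  })
}

#' Write a synthetic proteome to a directory
#'
#' Writes `proteome.fasta`, `annotations.tsv` and `truth.tsv`; all outputs
#' pass the package's own ingest validation.
#'
#' @param proteome result of [gen_proteome()].
#' @param out_dir output directory (created if missing).
#' @return the written paths, invisibly.
#' @export
write_proteome <- function(proteome, out_dir) {
  stopifnot(is.list(proteome),
            all(c("records", "annotations", "truth") %in% names(proteome)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  fasta <- file.path(out_dir, "proteome.fasta")
  ann <- file.path(out_dir, "annotations.tsv")
  truth <- file.path(out_dir, "truth.tsv")
  write_fasta(proteome$records, fasta)
  write_annotation_table(proteome$annotations, ann)
  write_tsv(proteome$truth, truth)
  invisible(c(fasta, ann, truth))
}
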