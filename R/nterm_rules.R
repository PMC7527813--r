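## nterm_rules: DPP8/9 recognition-motif matching, two-step N-terminal
## maturation, neo-N-terminus derivation and N-degron classification.
##
## Two motif variants are first-class.  Both encode the post-proline
## dipeptidase constraint that a dipeptide can only be released when the
## residue following the cleavage site is not itself a proline:
##   P4 ("MYPX"): initiator M, variable position 2 (with an excluded set),
##                P at position 3, position 4 not P.  Maturation route:
##                methionine aminopeptidase removes M, then DPP8/9 release
##                the dipeptide at positions 2-3, exposing residue 4.
##   P3 ("MPX"):  initiator M, P at position 2, position 3 not P.
##                DPP8/9 release the "MP" dipeptide directly, exposing
##                residue 3.
## The "legend" variant excludes only D at the variable P4 position; the
## "text" variant excludes D and E.  Every text-variant hit is therefore
## also a legend-variant hit.

#' Motif rule set for DPP8/9 recognition
#'
#' @param variant `"legend"` (position-2 excluded set `{D}`; the criterion
#'   used for the published mitochondrial screen) or `"text"` (excluded set
#'   `{D, E}`).
#' @return a `motif_rules` object with elements `variant`, `pos2_excluded`,
#'   `pos4_excluded` (always `{P}`) and `pos3_excluded_p3` (always `{P}`).
#' @export
motif_rules <- function(variant = c("legend", "text")) {
  variant <- match.arg(variant)
  structure(list(variant = variant,
                 pos2_excluded = if (variant == "legend") "D" else c("D", "E"),
                 pos4_excluded = "P",
                 pos3_excluded_p3 = "P"),
            class = "motif_rules")
}

#' Match the DPP8/9 recognition motif at an N-terminus
#'
#' Vectorised over sequences.  Returns `"P4"` for the 4-residue motif
#' (M, allowed residue, P, non-P), `"P3"` for the 3-residue motif
#' (M, P, non-P) and `"none"` otherwise.  The two patterns are mutually
#' exclusive (P4 requires P at position 3, P3 forbids it).  Ambiguity
#' letters (`X, B, Z, U, J, O`) never satisfy a constrained position.
#'
#' @param sequence character vector of amino-acid sequences (length >= 1
#'   residue each).
#' @param rules a [motif_rules()] object.
#' @return character vector over `{"none", "P3", "P4"}`.
#' @export
match_motif <- function(sequence, rules = motif_rules()) {
  stopifnot(inherits(rules, "motif_rules"))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) == 0L) return(character())
  if (any(is.na(sequence)) || any(!nzchar(sequence)))
    stop("empty sequence")
  n <- nchar(sequence)
  s1 <- substr(sequence, 1L, 1L)
  s2 <- substr(sequence, 2L, 2L)
  s3 <- substr(sequence, 3L, 3L)
  s4 <- substr(sequence, 4L, 4L)
  canonical <- function(x) x %in% AA20
  p4 <- n >= 4L & s1 == "M" &
    canonical(s2) & !(s2 %in% rules$pos2_excluded) &
    s3 == "P" &
    canonical(s4) & !(s4 %in% rules$pos4_excluded)
  p3 <- n >= 3L & s1 == "M" & s2 == "P" &
    canonical(s3) & !(s3 %in% rules$pos3_excluded_p3)
  out <- rep("none", length(sequence))
  out[p3] <- "P3"
  out[p4] <- "P4"
  out
}

#' Default N-degron classification table
#'
#' Maps the neo-N-terminal residue exposed by DPP8/9 cleavage to an
#' N-end-rule branch.  Ser/Thr/Cys/Ala feed the Ac/N-degron pathway via
#' N-terminal acetylation; Arg/Lys/His are primary Arg/N destabilizers;
#' Asp/Glu secondary (arginylation); Asn/Gln tertiary (deamidation to
#' Asp/Glu, then arginylation).  Gly and Val are listed as stabilizing,
#' following the observed stabilization of S4G/S4V neo-termini; the table
#' is fully overridable.
#'
#' @return named character vector mapping each canonical residue to a
#'   branch in `{AcN, ArgN_primary, ArgN_secondary, ArgN_tertiary,
#'   stabilizing}`.
#' @export
default_degron_table <- function() {
  tab <- c(S = "AcN", T = "AcN", C = "AcN", A = "AcN",
           R = "ArgN_primary", K = "ArgN_primary", H = "ArgN_primary",
           D = "ArgN_secondary", E = "ArgN_secondary",
           N = "ArgN_tertiary", Q = "ArgN_tertiary")
  stabilizing <- setdiff(AA20, names(tab))
  tab <- c(tab, setNames(rep("stabilizing", length(stabilizing)),
                         stabilizing))
  tab[AA20]
}

degron_notes <- c(
  AcN = "N-terminal acetylation by N-acetyltransferases creates the Ac/N-degron",
  ArgN_primary = "primary destabilizing residue, direct UBR-box recognition",
  ArgN_secondary = "secondary destabilizing residue, arginylation by ATE1 then UBR recognition",
  ArgN_tertiary = "tertiary destabilizing residue, deamidation (N to D, Q to E) then arginylation path",
  stabilizing = "no destabilizing N-degron expected")

#' Classify a neo-N-terminal residue into an N-degron branch
#'
#' @param neo_residue a single canonical amino-acid letter.
#' @param degron_table residue-to-branch mapping (default
#'   [default_degron_table()]).
#' @return a `degron_class` object: list with `branch` and `note`.
#' @export
degron_class <- function(neo_residue, degron_table = default_degron_table()) {
  stopifnot(length(neo_residue) == 1L)
  neo_residue <- toupper(neo_residue)
  if (!(neo_residue %in% names(degron_table)) || !(neo_residue %in% AA20))
    stop("cannot classify non-canonical residue: ", neo_residue)
  branch <- unname(degron_table[[neo_residue]])
  structure(list(branch = branch,
                 note = unname(degron_notes[[branch]] %||% "")),
            class = "degron_class")
}

#' Initiator methionine excision
#'
#' Annotation utility modelling methionine aminopeptidase: the leading M is
#' removed iff the penultimate residue is in the small-residue set
#' (default `A, C, G, P, S, T, V`).  The motif classifier applies its rule
#' set directly and does not chain through this function.
#'
#' @param sequence character vector of sequences, each length >= 2.
#' @param small_residue_set residues permitting excision.
#' @return a list with `sequence` (processed) and `excised` (logical),
#'   each vectorised over the input.
#' @export
met_excision <- function(sequence,
                         small_residue_set = c("A", "C", "G", "P", "S",
                                               "T", "V")) {
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) < 2L)) stop("sequence shorter than 2 residues")
  excised <- substr(sequence, 1L, 1L) == "M" &
    substr(sequence, 2L, 2L) %in% small_residue_set
  list(sequence = ifelse(excised, substr(sequence, 2L, nchar(sequence)),
                         sequence),
       excised = excised)
}

## Vectorised core shared by classify_nterm() and scan_proteome().
classify_fields <- function(sequence, rules, degron_table) {
  pattern <- match_motif(sequence, rules)
  n <- nchar(sequence)
  route <- c(none = "none", P3 = "dpp_direct",
             P4 = "map_then_dpp")[pattern]
  released <- rep("", length(sequence))
  released[pattern == "P3"] <- "MP"
  released[pattern == "P4"] <- paste0("M+", substr(sequence, 2L, 3L))[pattern == "P4"]
  neo_pos <- ifelse(pattern == "P4", 4L, ifelse(pattern == "P3", 3L, NA_integer_))
  neo_residue <- ifelse(is.na(neo_pos), "",
                        substr(sequence, neo_pos, neo_pos))
  neo_prefix <- ifelse(is.na(neo_pos), "",
                       substr(sequence, neo_pos, pmin(neo_pos + 1L, n)))
  branch <- rep("", length(sequence))
  note <- rep("", length(sequence))
  hit <- pattern != "none"
  if (any(hit)) {
    res <- neo_residue[hit]
    known <- res %in% names(degron_table) & res %in% AA20
    b <- rep("unclassified", sum(hit))
    b[known] <- unname(degron_table[res[known]])
    branch[hit] <- b
    note[hit] <- ifelse(b %in% names(degron_notes),
                        unname(degron_notes[b]), "")
  }
  data.frame(pattern = unname(pattern), route = unname(route),
             released = released, neo_residue = neo_residue,
             neo_prefix = neo_prefix, degron_branch = branch,
             degron_note = note, stringsAsFactors = FALSE)
}

#' Classify one N-terminus
#'
#' Composes motif matching, maturation-route assignment, released-peptide
#' derivation, neo-N-terminus extraction and N-degron lookup for a single
#' sequence.  Sequences not starting with M (or not matching either motif)
#' yield pattern `"none"` with all downstream fields `NULL`.
#'
#' @param sequence a single amino-acid sequence.
#' @param rules a [motif_rules()] object.
#' @param degron_table residue-to-branch mapping.
#' @param id optional accession carried into the result.
#' @return a `processing_outcome` object: list with `id`, `pattern`,
#'   `route`, `released` (character vector of released peptides, in order),
#'   `neo_residue`, `neo_prefix` and `degron` (a `degron_class` or `NULL`).
#' @export
classify_nterm <- function(sequence, rules = motif_rules(),
                           degron_table = default_degron_table(),
                           id = NA_character_) {
  stopifnot(length(sequence) == 1L)
  f <- classify_fields(toupper(sequence), rules, degron_table)
  released <- if (f$pattern == "P4") c("M", substr(toupper(sequence), 2L, 3L))
              else if (f$pattern == "P3") "MP"
              else character()
  degron <- if (f$pattern != "none" && nzchar(f$degron_branch) &&
                f$degron_branch != "unclassified")
    structure(list(branch = f$degron_branch, note = f$degron_note),
              class = "degron_class")
  else NULL
  structure(list(id = id, pattern = f$pattern, route = f$route,
                 released = released,
                 neo_residue = if (nzchar(f$neo_residue)) f$neo_residue else NULL,
                 neo_prefix = if (nzchar(f$neo_prefix)) f$neo_prefix else NULL,
                 degron = degron),
            class = "processing_outcome")
}

#' @export
print.processing_outcome <- function(x, ...) {
  cat("N-terminal processing outcome",
      if (!is.na(x$id)) paste0("for ", x$id) else "", "\n")
  cat("  pattern:", x$pattern, " route:", x$route, "\n")
  if (x$pattern != "none") {
    cat("  released:", paste(x$released, collapse = ", "),
        " neo-N-terminus:", paste0(x$neo_prefix, "-"), "\n")
    if (!is.null(x$degron))
      cat("  degron:", x$degron$branch, "(", x$degron$note, ")\n")
  }
  invisible(x)
}
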