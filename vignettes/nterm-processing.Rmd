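---
title: "Predicting DPP8/9 N-terminal processing and its degradation consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DPP8/9 N-terminal processing and its degradation consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppscreen)
```

## The biological model

Many mitochondrial proteins — in particular substrates of the
intermembrane-space (IMS) disulfide relay — lack an N-terminal
mitochondrial targeting sequence and are imported slowly, leaving their
precursors exposed in the cytosol.  The cytosolic dipeptidyl peptidases
DPP8 and DPP9 can clip a dipeptide off such precursors: they cleave the
peptide bond *after* a proline at position 2 of the presented N-terminus,
provided the next residue is not itself a proline.  For a protein whose
initiator methionine is first removed by methionine aminopeptidase (MAP),
the presented N-terminus starts at residue 2, so a protein beginning
`M-X-P-Y` matures in two steps:

```
M X P Y ...   --MAP-->   X P Y ...   --DPP8/9-->   Y ...
```

releasing first `M`, then the dipeptide `XP`, and exposing residue 4 as
the *neo-N-terminus*.  A protein beginning `M-P-Y` is a direct DPP8/9
substrate: the `MP` dipeptide is released and residue 3 is exposed.  The
adenylate kinase 2 (AK2) N-terminus `MAPS...` is the canonical worked
example: the observable species are `MAPS-`, `APS-` and `S-` (the latter
also in an N-acetylated form).

The identity of the exposed residue decides the protein's cytosolic fate
through the N-degron (N-end rule) pathways: Ser/Thr/Cys/Ala feed the
Ac/N-degron branch via N-terminal acetylation; Arg/Lys/His are primary
Arg/N-degron residues; Asp/Glu secondary (arginylation by ATE1); Asn/Gln
tertiary (deamidation to Asp/Glu first).  Processing thereby acts as a
cytosolic timer: a precursor that reaches the IMS before being clipped
escapes degradation, one that lingers is destroyed.

## The motif rule set and its two variants

The recognition motif is represented as positional constraints on the
first four residues:

* **P4** (`MYPX` style): position 1 `M`; position 2 any canonical residue
  outside an excluded set; position 3 `P`; position 4 any canonical
  residue except `P`.
* **P3** (`MPX` style): position 1 `M`; position 2 `P`; position 3 any
  canonical residue except `P`.

The two patterns are mutually exclusive (P4 requires `P` at position 3,
P3 forbids it), so every sequence maps to exactly one of
`{none, P3, P4}`.  Ambiguity letters (`X B Z U J O`) are retained in
sequences but never satisfy a constrained position.

Two excluded-set conventions for the variable P4 position are in
circulation — `{D}` (the `legend` variant) and `{D, E}` (the `text`
variant) — and published hit counts do not state which was used.  Both
are therefore first-class `motif_rules()` variants; `legend` is the
default because it is the stated search criterion of the screen figure
that reports the headline count, and the command-line tool can report
both.  Because `text` only adds an exclusion, its hits are always a
subset of `legend`'s: over all 160,000 canonical 4-mers the two variants
admit 741 and 722 motifs respectively.

A deliberate design choice: `classify_nterm()` applies the motif rules
directly rather than chaining `met_excision()` with a dipeptidase
simulation.  The canonical MAP small-residue set (`A C G P S T V`)
includes `P`, so a literal two-enzyme chain would excise the methionine
of `MPX...` proteins and contradict the direct-cleavage P3 pattern.
`met_excision()` is kept as a separate annotation utility.  Only a
single cleavage round is modelled — one dipeptide per substrate, no
iterative trimming.

The degron lookup table places Gly and Val among the stabilizing
residues, reflecting the observed stabilization of engineered `S4G` and
`S4V` neo-termini, even though canonical N-acetyltransferase substrate
ranges would admit more residues; the table is an argument everywhere it
is used and can be overridden entry by entry.  N-terminal acetylation of
the neo-N-terminus is recorded as the mechanism note of the `AcN`
branch, not predicted per protein.

## The proteome screen

`scan_proteome()` classifies every record of a FASTA collection;
`summarize_screen()` joins the outcomes to a MitoCarta-style annotation
table (accession, subcompartment, N-terminal-MTS flag,
semicolon-separated pathway labels) and computes hit counts, the
hit-by-MTS cross-tabulation and category over-representation.  The test
is the one-sided hypergeometric upper tail
\(P(X \ge k)\) for \(X \sim \mathrm{Hypergeom}(N, K, n)\) — the standard
choice for category over-representation with fixed margins; the source
analysis reported enrichment qualitatively only, so the test is this
package's choice.  Raw p-values are always reported next to
Benjamini–Hochberg-adjusted ones; the adjustment is applied separately
across the compartment and the pathway families.  Proteins without an
annotation row are counted under compartment `unknown` rather than
dropped, so every total matches the scanned FASTA; categories with zero
members are skipped rather than reported at p = 1.  One sequence per
accession is scanned, as provided — no isoform selection and no minimum
length beyond the 4-residue motif window.

The published screen inputs (the MitoCarta2.0 inventory and a curated
list of roughly 40–50 disulfide-relay substrates) are not redistributed
with the package; users supply them as FASTA + TSV, and the README
describes the expected layout.

## Conservation profiles and logos

`column_profile()` turns a pre-computed ortholog alignment into
per-column residue frequencies.  Alignments are consumed, never built:
alignment construction is external tooling and the conservation math is
independent of it.  Gaps are excluded from the frequency denominator
(the logo convention — letter heights reflect residue abundance among
observed residues) with the gap fraction reported separately; ambiguity
letters are likewise excluded.  Column information content is
\(\log_2 20 - H_i\) bits, with \(H_i\) the Shannon entropy of the column
distribution; the ceiling is fixed at the 20-letter alphabet and no
small-sample correction is applied.  The pseudocount defaults to 0,
matching raw-abundance logos, and is configurable for downstream
scoring.  Consensus ties are broken alphabetically and flagged.
`logo_matrix()` returns letter heights in probability mode
(frequencies) or information mode (frequency × column information, so a
column's heights sum to its information content).  Every row counts
once — no phylogenetic or duplicate-row weighting.
`motif_conservation()` degaps each row and reports the fraction whose
N-terminus matches the motif, which makes it invariant to gap-only
column insertion.

## What the synthetic generator emulates — and what it does not

`gen_proteome()` produces the structure the screen assumes: proteins are
assigned a subcompartment by the spec proportions, and with a
compartment-specific (or pathway-specific, whichever is larger) planted
probability their first four residues are forced to a uniformly drawn
motif-matching 4-mer; everything else is i.i.d. background.  Accidental
motif matches among unplanted proteins are *kept and recorded* in the
truth table, so the analytic accidental-match rate

\[
P(\text{match}) = b_M \, s_2 \, b_P (1 - b_P) + b_M \, b_P (1 - b_P),
\qquad s_2 = \sum_{a \notin \text{excluded}} b_a ,
\]

stays exact (`accidental_match_rate()`; ≈ 0.0046 under a uniform
background and the `legend` rules).  Default conditions, chosen once:
1,000 proteins of 30–60 residues, uniform background, compartment shares
matrix/IMM/IMS/OMM/membrane/unknown = 0.44/0.25/0.08/0.10/0.08/0.05,
planted probability 0.5 in the IMS against a 0.05 baseline elsewhere
(an enriched-IMS condition at screen scale), one pathway label
(`disulfide_relay_substrate`, membership 0.04 ≈ 45/1158, planted 0.3 ≈
13/45) and an MTS flag drawn independently at 0.4.  A MitoCarta-scale
run uses n = 1,158.

`gen_ortholog_set()` is a substitution-only model — no indels, so rows
are born aligned, which is exactly what is wanted when the conservation
math rather than an aligner is under test.  Positions beyond the motif
block substitute independently at `substitution_probability` (default
0.1) toward the background.  The 4-residue motif block is copied intact
with `motif_conservation_probability` (default 0.9); otherwise *every*
block position is redrawn from the background.  The redraw (rather than
per-position Bernoulli substitution) is deliberate: it makes the
conservation probability identifiable from the matched-row fraction —
under lazier mutation a "non-conserved" block would usually still match,
and the parameter would not be recoverable from data.  The residual bias
is the accidental rate of a random block, ≈ 0.005.

What the generator does **not** emulate: realistic amino-acid
composition (configurable but uniform by default), length distributions
of real proteomes, correlated residues, phylogenetic structure among
ortholog rows, indels, or any coupling between the MTS flag and
compartment.  Tests passing on synthetic data therefore certify the
*machinery* — motif logic, counting, enrichment calibration,
conservation estimation — not the biological hit list; the published
counts can only be checked against the real external inputs.

All generators take a single integer seed, use one local random stream
per call and restore the caller's RNG state, so identical spec + seed
gives byte-identical output files.

## Numerical choices and degenerate inputs

* Hypergeometric tails go through `stats::phyper`, stable to proteome
  sizes of at least 1e5; its agreement with exhaustive enumeration of
  all hit-set placements is verified to 1e-12 for populations up to 12.
* Profile frequency columns sum to 1 within 1e-9; information-mode logo
  heights sum to the column information within 1e-9.
* Empty sequences error; sequences shorter than the motif window
  classify as `none`; sequences not starting with `M` classify as
  `none` without error.
* All-gap alignment columns are trimmed on ingest with a message; a
  column with no canonical residue at profile time is an error.
* A single trailing `*` in FASTA input is stripped; any other
  non-alphabet character errors with its record and position.
* Unknown compartment labels fall back to `unknown` with a warning, so a
  screen never silently drops proteins.

## Problem sizes used in the checks

The shipped validation exercises the full 160,000-sequence 4-mer space
for the motif oracle, populations up to N = 12 for the enumeration
check, 100 generator seeds at 1,000 proteins each for the enrichment
power/type-I calibration, 5,000 proteins for the background-rate
calibration and 200-row ortholog sets for conservation recovery — sizes
at which the binomial 3σ bounds used by the tests are tight enough to be
informative while the whole suite stays fast.

## Known limitations

* No DPP8-vs-DPP9 distinction: the recognition motif is treated as
  shared, matching how the substrate screen was defined.
* No prediction of acetylation efficiency, MTS presence, import or
  degradation kinetics; the MTS flag is consumed from the annotation
  table.
* Conservation outputs are validated on synthetic ortholog sets; the
  species panels behind published logos are not distributed, so letter
  heights of specific published figures are not regression targets.
* The convenience `plot_logo()` rendering is untested surface; the
  exported matrices and TSVs are the contract.
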