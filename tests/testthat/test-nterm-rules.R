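test_that("motif matching reproduces the worked N-termini", {
  legend <- motif_rules("legend")
  text <- motif_rules("text")
  expect_equal(match_motif("MAPSVPAA", legend), "P4")
  expect_equal(match_motif("MAPSVPAA", text), "P4")
  expect_equal(match_motif("MPGLVDSN", legend), "P3")
  ## the variable pre-proline position: D always excluded, E only by the
  ## stricter variant
  expect_equal(match_motif("MEPS", legend), "P4")
  expect_equal(match_motif("MEPS", text), "none")
  expect_equal(match_motif("MDPS", legend), "none")
  expect_equal(match_motif("MDPS", text), "none")
  ## proline after the cleavage site blocks release
  expect_equal(match_motif("MAPP", legend), "none")
  expect_equal(match_motif("MPPA", legend), "P4")
  expect_equal(match_motif("MKKT", legend), "none")
  ## too short for the window
  expect_equal(match_motif("MA", legend), "none")
  expect_equal(match_motif("MP", legend), "none")
  expect_error(match_motif("", legend), "empty")
})

test_that("ambiguity letters never satisfy a constrained position", {
  legend <- motif_rules("legend")
  expect_equal(match_motif(c("MXPS", "MAPX", "MPXS", "XAPS"), legend),
               rep("none", 4L))
  ## unconstrained downstream positions may carry ambiguity letters
  expect_equal(match_motif("MAPSXXXX", legend), "P4")
  expect_equal(match_motif("MPGX", legend), "P3")
})

test_that("motif matcher agrees with the brute-force checker on sampled 4-mers", {
  pool <- all_4mers()
  set.seed(42)
  sample4 <- sample(pool, 5000L)
  for (variant in c("legend", "text")) {
    expected <- vapply(sample4, brute_match, character(1L),
                       variant = variant, USE.NAMES = FALSE)
    expect_identical(match_motif(sample4, motif_rules(variant)), expected)
  }
})

test_that("P3 and P4 are disjoint and text hits nest inside legend hits", {
  seqs <- random_sequences(2000L, 6L, seed = 7)
  legend <- match_motif(seqs, motif_rules("legend"))
  text <- match_motif(seqs, motif_rules("text"))
  ## a single call never returns both patterns, and the P3/P4 conditions
  ## are incompatible through position 3
  p3_legend <- seqs[legend == "P3"]
  expect_true(all(substr(p3_legend, 3L, 3L) != "P"))
  p4_legend <- seqs[legend == "P4"]
  expect_true(all(substr(p4_legend, 3L, 3L) == "P"))
  ## nesting: every text hit is a legend hit
  expect_true(all(legend[text != "none"] != "none"))
  expect_lte(sum(text != "none"), sum(legend != "none"))
})

test_that("classification derives routes, released peptides and neo-termini", {
  out <- classify_nterm("MAPSVPAA", id = "AK2")
  expect_equal(out$pattern, "P4")
  expect_equal(out$route, "map_then_dpp")
  expect_equal(out$released, c("M", "AP"))
  expect_equal(out$neo_residue, "S")
  expect_equal(out$neo_prefix, "SV")
  expect_equal(out$degron$branch, "AcN")

  out <- classify_nterm("MPGIVELP")
  expect_equal(out$pattern, "P3")
  expect_equal(out$route, "dpp_direct")
  expect_equal(out$released, "MP")
  expect_equal(out$neo_prefix, "GI")

  out <- classify_nterm("MPGLVDSN")
  expect_equal(out$neo_prefix, "GL")

  out <- classify_nterm("MDPSVPAA")
  expect_equal(out$pattern, "none")
  expect_equal(out$route, "none")
  expect_length(out$released, 0L)
  expect_null(out$neo_residue)
  expect_null(out$degron)

  ## sequences not starting with M classify as none without error
  expect_equal(classify_nterm("APSVPAA")$pattern, "none")

  ## neo-prefix falls back to a single residue at the sequence end
  expect_equal(classify_nterm("MPG")$neo_prefix, "G")
})

test_that("classification is a pure function of its inputs", {
  seqs <- random_sequences(200L, 8L, seed = 11)
  a <- vapply(seqs, function(s) classify_nterm(s)$pattern, character(1L))
  b <- vapply(seqs, function(s) classify_nterm(s)$pattern, character(1L))
  expect_identical(a, b)
})

test_that("methionine excision follows the small-residue rule", {
  expect_equal(met_excision("MAPS"), list(sequence = "APS", excised = TRUE))
  expect_equal(met_excision("MDPS"),
               list(sequence = "MDPS", excised = FALSE))
  expect_equal(met_excision("AAPS"),
               list(sequence = "AAPS", excised = FALSE))
  expect_error(met_excision("M"), "shorter than 2")
  ## override of the small-residue set
  expect_true(met_excision("MDPS", small_residue_set = c("D"))$excised)
})

test_that("degron lookup matches the default branch table", {
  expect_equal(degron_class("S")$branch, "AcN")
  expect_equal(degron_class("T")$branch, "AcN")
  expect_equal(degron_class("C")$branch, "AcN")
  expect_equal(degron_class("A")$branch, "AcN")
  for (r in c("R", "K", "H"))
    expect_equal(degron_class(r)$branch, "ArgN_primary")
  for (r in c("D", "E"))
    expect_equal(degron_class(r)$branch, "ArgN_secondary")
  nq <- degron_class("N")
  expect_equal(nq$branch, "ArgN_tertiary")
  expect_match(nq$note, "deamidation")
  for (r in c("G", "V", "M", "P", "I", "L", "F", "W", "Y"))
    expect_equal(degron_class(r)$branch, "stabilizing")
  expect_error(degron_class("X"), "non-canonical")
  ## the table is overridable by configuration
  custom <- default_degron_table()
  custom[["G"]] <- "AcN"
  expect_equal(degron_class("G", custom)$branch, "AcN")
  out <- classify_nterm("MAPGVPAA", degron_table = custom)
  expect_equal(out$degron$branch, "AcN")
})
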