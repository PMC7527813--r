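test_that("proteome generation is deterministic under a fixed seed", {
  spec <- synthetic_spec(n_proteins = 100L, seed = 123L)
  a <- gen_proteome(spec)
  b <- gen_proteome(spec)
  expect_identical(a, b)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_proteome(a, dir1)
  write_proteome(b, dir2)
  f1 <- file.path(dir1, "proteome.fasta")
  f2 <- file.path(dir2, "proteome.fasta")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## the generator call does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(1)); gen_proteome(spec); after <- runif(2)
  expect_identical(before, c(before[1L], after))
})

test_that("generated outputs pass ingest validation without warnings", {
  out_dir <- withr::local_tempdir()
  write_proteome(gen_proteome(synthetic_spec(n_proteins = 50L, seed = 2L)),
                 out_dir)
  expect_no_warning(rec <- read_fasta(file.path(out_dir, "proteome.fasta")))
  expect_no_warning(
    ann <- read_annotation_table(file.path(out_dir, "annotations.tsv")))
  expect_equal(nrow(rec), 50L)
  expect_equal(ann$id, rec$id)
  expect_true(all(ann$compartment %in%
                    c("matrix", "IMS", "IMM", "OMM", "membrane", "unknown")))
})

test_that("planted N-termini are always recovered by the scan", {
  pr <- gen_proteome(synthetic_spec(n_proteins = 500L, seed = 31L))
  out <- scan_proteome(pr$records, motif_rules("legend"))
  hit <- out$pattern != "none"
  ## truth-table recovery: hit set contains the planted set
  expect_true(all(hit[pr$truth$planted]))
  ## planted prefixes are the first four residues and legend-valid
  planted <- pr$truth$planted
  expect_equal(substr(pr$records$sequence[planted], 1L, 4L),
               pr$truth$planted_prefix[planted])
  expect_true(all(match_motif(pr$truth$planted_prefix[planted],
                              motif_rules("legend")) != "none"))
  ## accidental hits are recorded, not rejected
  expect_equal(pr$truth$accidental, !planted & hit)
})

test_that("unplanted proteomes match the analytic accidental rate", {
  comps <- data.frame(compartment = c("matrix", "IMS"),
                      proportion = c(0.5, 0.5),
                      planted_probability = c(0, 0))
  paths <- data.frame(pathway = character(),
                      membership_probability = numeric(),
                      planted_probability = numeric())
  spec <- synthetic_spec(n_proteins = 3000L, compartments = comps,
                         pathways = paths, seed = 17L)
  pr <- gen_proteome(spec)
  expect_false(any(pr$truth$planted))
  q <- accidental_match_rate(spec$background_frequencies,
                             motif_rules("legend"))
  observed <- mean(pr$truth$pattern != "none")
  expect_lt(abs(observed - q), 3 * sqrt(q * (1 - q) / 3000))
})

test_that("fully planted compartments dominate the enrichment ranking", {
  comps <- data.frame(compartment = c("matrix", "IMS", "OMM"),
                      proportion = c(0.6, 0.2, 0.2),
                      planted_probability = c(0, 1, 0))
  paths <- data.frame(pathway = character(),
                      membership_probability = numeric(),
                      planted_probability = numeric())
  spec <- synthetic_spec(n_proteins = 400L, compartments = comps,
                         pathways = paths, seed = 5L)
  pr <- gen_proteome(spec)
  out <- scan_proteome(pr$records)
  summ <- summarize_screen(out, pr$annotations)
  tab <- summ$by_compartment
  ims <- tab[tab$compartment == "IMS", ]
  n_planted_ims <- sum(pr$truth$planted & pr$truth$compartment == "IMS")
  expect_gte(ims$n_hits_in_category, n_planted_ims)
  expect_equal(min(tab$p_value), ims$p_value)
})

test_that("ortholog generation honours its substitution model", {
  base <- "MAPSVPAAEQLKRT"
  ## no substitutions, full conservation: every row equals the base
  al <- gen_ortholog_set(ortholog_spec(base, n_species = 6L,
                                       substitution_probability = 0,
                                       motif_conservation_probability = 1,
                                       seed = 3L))
  expect_equal(al$sequences, rep(base, 6L))
  expect_equal(motif_conservation(al), 1.0)
  expect_equal(al$n_columns, nchar(base))

  ## deterministic under seed
  spec <- ortholog_spec(base, n_species = 20L, seed = 9L)
  expect_identical(gen_ortholog_set(spec), gen_ortholog_set(spec))

  ## motif-conservation probability is recovered within 3 sigma binomial
  p <- 0.7
  spec <- ortholog_spec(base, n_species = 200L,
                        substitution_probability = 0.1,
                        motif_conservation_probability = p, seed = 21L)
  frac <- motif_conservation(gen_ortholog_set(spec))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 200))

  expect_error(ortholog_spec("MAP"), "at least 4")
})

test_that("infeasible proteome specs are rejected", {
  expect_error(synthetic_spec(length_range = c(3L, 10L)), "at least 4")
  expect_error(synthetic_spec(compartments = data.frame(
    compartment = "IMS", proportion = 0.5, planted_probability = 0.1)),
    "sum to 1")
  bad_bg <- setNames(rep(0.1, 20L), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
  expect_error(synthetic_spec(background_frequencies = bad_bg),
               "distribution")
})
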