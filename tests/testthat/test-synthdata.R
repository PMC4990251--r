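test_that("synthetic precursor proteins embed the requested peptide units", {
  spec <- precursor_spec("pedal", data.frame(sequence = "SFDSIGNGPIGL",
                                             copies = 3L, flank = "KR"))
  built <- build_precursor_protein(spec, rng_seed = 101)
  hits <- gregexpr("SFDSIGNGPIGLKR", built$protein, fixed = TRUE)[[1]]
  expect_length(hits, 3L)
  expect_equal(built$expected_peptides, rep("SFDSIGNGPIGL", 3))
  expect_equal(substr(built$protein, 1, 1), "M")
  # the designed (-3,-1) motif sits at the signal boundary
  expect_equal(substr(built$protein, spec$signal_length - 2,
                      spec$signal_length), "ASA")
  # determinism under a fixed seed
  again <- build_precursor_protein(spec, rng_seed = 101)
  expect_identical(again$protein, built$protein)
  other <- build_precursor_protein(spec, rng_seed = 102)
  expect_false(identical(other$protein, built$protein))
})

test_that("precursor specs validate their flank motifs", {
  expect_error(precursor_spec("x", data.frame(sequence = "AAA", copies = 1,
                                              flank = "KP")), "flank")
  expect_error(precursor_spec("x", data.frame(sequence = "AAA", copies = 1,
                                              flank = "KR"),
                              signal_length = 10), "signal_length")
})

test_that("back-translation roundtrips through the genetic code", {
  spec <- precursor_spec("x", data.frame(sequence = "AAA", copies = 1,
                                         flank = "KR"), utr5 = 0, utr3 = 0)
  prot <- "MDFEHMCVHEDFSRSGAYSSC"
  tx <- back_translate_and_embed(prot, spec, rng_seed = 7)
  expect_equal(nchar(tx$sequence), 3 * nchar(prot) + 3)  # CDS + stop, no UTRs
  translated <- six_frame_translate(tx$sequence)[["+1"]]
  expect_equal(translated, paste0(prot, "*"))
  # different seeds: different codons, same translation
  tx2 <- back_translate_and_embed(prot, spec, rng_seed = 8)
  expect_false(identical(tx$sequence, tx2$sequence))
  expect_equal(six_frame_translate(tx2$sequence)[["+1"]], paste0(prot, "*"))
})

test_that("datasets have the requested cardinality and truth flags", {
  ds <- generate_dataset(5, 20, seed = 7)
  expect_equal(nrow(ds$transcripts), 25L)
  expect_equal(sum(ds$truth$is_precursor), 5L)
  expect_equal(ds$transcripts$id, ds$truth$id)
  expect_length(ds$queries, 5L)
  # regeneration under the same seed is identical
  ds2 <- generate_dataset(5, 20, seed = 7)
  expect_identical(ds$transcripts, ds2$transcripts)
  expect_identical(ds$truth, ds2$truth)
})

test_that("dinucleotide shuffling preserves length and composition", {
  set.seed(61)
  for (k in 1:15) {
    s <- random_dna(sample(50:300, 1))
    sh <- npminer:::.dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(table(strsplit(sh, "")[[1]]), table(strsplit(s, "")[[1]]))
  }
})

test_that("truth peptide lists are reproduced by the package's own rules", {
  ds <- generate_dataset(5, 5, seed = 17)
  tr <- ds$truth[ds$truth$is_precursor, ]
  for (i in seq_len(nrow(tr))) {
    sig <- list(present = TRUE, cleavage_after = tr$signal_length[i])
    mature <- substr(tr$protein[i], tr$signal_length[i] + 1,
                     nchar(tr$protein[i]))
    peps <- derive_mature_peptides(tr$protein[i], sig,
                                   find_cleavage_sites(mature))
    expect_equal(paste(peps$peptide, collapse = ";"),
                 tr$expected_peptides[i], info = tr$id[i])
  }
  # and the truth CDS translates back to the truth protein
  for (i in seq_len(nrow(tr))) {
    tx <- ds$transcripts$sequence[ds$transcripts$id == tr$id[i]]
    cds <- substr(tx, tr$cds_start[i] + 1, tr$cds_end[i])
    expect_equal(six_frame_translate(cds)[["+1"]],
                 paste0(tr$protein[i], "*"))
  }
})

test_that("recovery scoring handles perfect, empty and mismatched reports", {
  truth <- data.frame(id = c("t1", "t2", "t3"),
                      is_precursor = c(TRUE, TRUE, FALSE),
                      family = c("NPF", "GPB5", NA),
                      protein = c("MA", "MA", NA),
                      signal_length = c(20L, 22L, NA),
                      expected_peptides = c("AAA;BBB", "CCC", NA),
                      stringsAsFactors = FALSE)
  perfect <- list(
    precursors = data.frame(transcript_id = c("t1", "t2"),
                            signal_cleavage_after = c(20L, 22L),
                            stringsAsFactors = FALSE),
    peptides = data.frame(transcript_id = c("t1", "t1", "t2"),
                          peptide = c("BBB", "AAA", "CCC"),
                          stringsAsFactors = FALSE))
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$signal_boundary_rate, 1)
  expect_equal(ev$peptide_set_rate, 1)

  empty <- list(precursors = data.frame(transcript_id = character(0),
                                        signal_cleavage_after = integer(0)),
                peptides = data.frame(transcript_id = character(0),
                                      peptide = character(0)))
  expect_equal(evaluate_recovery(empty, truth)$recall, 0)

  bad_ids <- list(precursors = data.frame(transcript_id = "zz",
                                          signal_cleavage_after = 1L),
                  peptides = perfect$peptides)
  expect_error(evaluate_recovery(bad_ids, truth), "id spaces")
})

test_that("datasets write to FASTA plus truth TSV and read back", {
  ds <- generate_dataset(2, 2, seed = 19)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tt <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, fa, tt)
  back <- read_transcripts(fa)
  expect_equal(back$id, ds$transcripts$id)
  expect_equal(back$sequence, ds$transcripts$sequence)
  truth_back <- utils::read.delim(tt)
  expect_equal(nrow(truth_back), 4L)
  expect_equal(sum(truth_back$is_precursor), 2L)
})
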