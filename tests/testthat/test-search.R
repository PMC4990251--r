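test_that("six-frame translation follows the standard code", {
  expect_equal(six_frame_translate("ATGAAA")[["+1"]], "MK")
  expect_equal(six_frame_translate("ATGTAA")[["+1"]], "M*")
  expect_equal(six_frame_translate("AATGAAA")[["+2"]], "MK")
  # codons containing N translate to X; trailing partial codons are dropped
  expect_equal(six_frame_translate("ATGANA")[["+1"]], "MX")
  expect_equal(six_frame_translate("ATGAAAC")[["+1"]], "MK")
  expect_error(six_frame_translate("ATGU"), "outside")
})

test_that("negative frames translate the reverse complement", {
  set.seed(11)
  for (k in 1:10) {
    dna <- random_dna(sample(10:40, 1))
    fr <- six_frame_translate(dna)
    rc <- six_frame_translate(reverse_complement(dna))
    expect_equal(fr[["-1"]], rc[["+1"]])
    expect_equal(fr[["-2"]], rc[["+2"]])
    expect_equal(fr[["-3"]], rc[["+3"]])
  }
})

test_that("self-alignment score is the sum of diagonal matrix entries", {
  p <- search_params()
  S <- p$substitution_matrix
  al <- local_align("FDSIG", "FDSIG", p)
  expect_equal(al$score,
               sum(S["F", "F"], S["D", "D"], S["S", "S"], S["I", "I"],
                   S["G", "G"]))
  expect_equal(al$q_aln, "FDSIG")
  expect_equal(al$t_aln, "FDSIG")
  expect_equal(al$q_start, 0L)
  expect_equal(al$t_end, 5L)
})

test_that("alignments with no positive-scoring pair are empty", {
  p <- search_params()
  al <- local_align("WWW", "PPP", p)
  expect_equal(al$score, 0)
  expect_equal(al$length, 0L)
  expect_equal(al$q_aln, "")
  expect_error(local_align("", "AA", p), "non-empty")
})

test_that("local alignment score is symmetric and matches the brute-force oracle", {
  p <- search_params()
  set.seed(19)
  for (k in 1:60) {
    a <- random_peptide(sample(2:8, 1))
    b <- random_peptide(sample(2:8, 1))
    sw <- local_align(a, b, p)$score
    expect_equal(local_align(b, a, p)$score, sw)
    expect_equal(sw, bf_local_score(a, b, p), info = paste(a, b))
  }
})

test_that("E-value plumbing has the stated closed form and monotonicity", {
  p <- search_params()
  e0 <- estimate_evalue(0, 20, 1000, p)
  expect_equal(e0$evalue, p$k_param * 20 * 1000)
  expect_equal(estimate_evalue(10, 20, 2000, p)$evalue,
               2 * estimate_evalue(10, 20, 1000, p)$evalue)
  ev <- vapply(0:50, function(s) estimate_evalue(s, 20, 1000, p)$evalue,
               numeric(1))
  expect_true(all(diff(ev) < 0))
  expect_error(estimate_evalue(5, 0, 100, p), ">= 1")
})

test_that("an embedded query dominates the search in its embedding frame", {
  set.seed(23)
  pep <- "MDFEHMCVHEDFSRSGAYSSC"
  spec <- precursor_spec("x", data.frame(sequence = "AAA", copies = 1,
                                         flank = "KR"), utr5 = 13, utr3 = 20)
  tx <- back_translate_and_embed(pep, spec, rng_seed = 5)
  decoys <- vapply(1:5, function(i) random_dna(nchar(tx$sequence)), "")
  transcripts <- data.frame(id = c("emb", paste0("d", 1:5)),
                            sequence = c(tx$sequence, decoys),
                            stringsAsFactors = FALSE)
  hits <- run_search(transcripts, c(q = pep))
  expect_equal(hits$transcript_id[1], "emb")
  # utr5 of 13 bases puts the CDS in frame +2
  expect_equal(hits$frame[1], 2L)
  # and the embedded transcript outranks every decoy hit
  expect_true(all(hits$evalue[1] < hits$evalue[hits$transcript_id != "emb"]))
})

test_that("alignments never cross a stop codon", {
  # two halves of the query sit in stop-separated segments; the reported
  # hit must come from one segment only
  left <- "MDFEHMCVHED"
  right <- "GAYSSCGSRLT"
  cds <- function(p) paste(vapply(strsplit(p, "")[[1]], function(aa) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa][1]
  }, ""), collapse = "")
  tx <- paste0(cds(left), "TAA", cds(right))
  hits <- run_search(data.frame(id = "t", sequence = tx),
                     c(q = paste0(left, right)))
  h <- hits[hits$frame == 1, ]
  expect_true(nrow(h) >= 1)
  expect_false(grepl("\\*", h$t_aln[1]))
  expect_lte(h$t_end[1] - h$t_start[1], nchar(left) + 1)
})

test_that("candidate selection keeps the three lowest E-values under the threshold", {
  hits <- data.frame(
    query_id = "q1",
    transcript_id = paste0("t", 1:5),
    frame = 1L, raw_score = c(50, 45, 30, 28, 20), bit_score = 0,
    evalue = c(1e-5, 1e-4, 5e-3, 8e-3, 2e-2),
    q_start = 0L, q_end = 10L, t_start = 0L, t_end = 10L,
    q_aln = "A", t_aln = "A", stringsAsFactors = FALSE)
  sel <- select_candidates(hits, search_params())
  expect_equal(sel$hits$transcript_id, c("t1", "t2", "t3"))
  expect_false("t4" %in% sel$hits$transcript_id)  # rank-excluded
  expect_false("t5" %in% sel$hits$transcript_id)  # threshold-excluded

  all_high <- transform(hits, evalue = evalue + 1)
  expect_equal(nrow(select_candidates(all_high, search_params())$hits), 0L)
})

test_that("equal E-values break ties by raw score then transcript id", {
  hits <- data.frame(
    query_id = "q1", transcript_id = c("tb", "ta", "tc"),
    frame = 1L, raw_score = c(40, 40, 45), bit_score = 0,
    evalue = 1e-6, q_start = 0L, q_end = 8L, t_start = 0L, t_end = 8L,
    q_aln = "A", t_aln = "A", stringsAsFactors = FALSE)
  ord <- order(hits$query_id, hits$evalue, -hits$raw_score, hits$transcript_id)
  sel <- select_candidates(hits[ord, ], search_params())
  expect_equal(sel$hits$transcript_id, c("tc", "ta", "tb"))
})

test_that("lowering the E-value threshold never adds candidates", {
  ds <- generate_dataset(2, 3, seed = 31)
  hits <- run_search(ds$transcripts, ds$queries)
  loose <- select_candidates(hits, search_params(evalue_max = 0.01))
  strict <- select_candidates(hits, search_params(evalue_max = 1e-6))
  expect_true(all(strict$candidates$transcript_id %in%
                  loose$candidates$transcript_id))
})

test_that("hit tables export as 1-based TSV", {
  ds <- generate_dataset(1, 1, seed = 13)
  hits <- run_search(ds$transcripts, ds$queries)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$q_start, hits$q_start + 1L)
  expect_equal(back$t_end, hits$t_end)
})
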