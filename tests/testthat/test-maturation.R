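test_that("excision trims the flanking basic run from printed peptide units", {
  segs <- process_printed_row("SFDSIGNGPIGLKR")
  expect_equal(segs$peptide, "SFDSIGNGPIGL")
  expect_equal(nchar(segs$peptide), 12L)
  expect_equal(segs$flank, "KR")

  tab <- read_mature_peptide_table()
  npfl <- tab$sequence[tab$precursor == "BnNPFL"]
  segs2 <- process_printed_row(npfl)
  expect_equal(nchar(segs2$peptide), 35L)
  expect_equal(segs2$flank, "KR")
})

test_that("precursor reconstruction from signal + segments + flanks is exact", {
  set.seed(47)
  for (k in 1:25) {
    prot <- paste0("M", random_peptide(sample(40:120, 1)))
    sig <- predict_signal_peptide(prot)
    sig_end <- if (isTRUE(sig$present)) sig$cleavage_after else 0L
    mature <- substr(prot, sig_end + 1, nchar(prot))
    sites <- find_cleavage_sites(mature)
    segs <- suppressMessages(excise_peptides(prot, sig, sites))
    rebuilt <- paste0(substr(prot, 1, sig_end),
                      paste(segs$raw, collapse = ""))
    expect_equal(rebuilt, prot)
  }
})

test_that("terminal PTMs follow the Gly-amide and pyroGlu rules", {
  amide <- apply_terminal_ptms("YLERIGSGNELVG", "KR")
  expect_true(amide$amidated)
  expect_equal(amide$sequence, "YLERIGSGNELV")
  expect_equal(amide$pre_amidation_length, 13L)

  pg <- apply_terminal_ptms("QHLKGSGENSLP", "KKR")
  expect_true(pg$pyroglutamate)
  expect_equal(pg$sequence, "QHLKGSGENSLP")  # flag only, sequence unchanged

  plain <- apply_terminal_ptms("SFDSIGNGPIGL", "KR")
  expect_false(plain$amidated)
  expect_false(plain$pyroglutamate)

  # a terminal Gly with no flank is a genuine C-terminus, not an amide donor
  expect_false(apply_terminal_ptms("SFDSIG", "")$amidated)

  # Glu-derived pyroglutamate only when enabled
  expect_false(apply_terminal_ptms("EHLKG", "KR")$pyroglutamate)
  expect_true(apply_terminal_ptms("EHLKG", "KR", pyroglu_from_E = TRUE)$pyroglutamate)
})

test_that("amidated peptides never end in Gly; trimmed peptides never end basic", {
  set.seed(53)
  sig <- list(present = FALSE, cleavage_after = NA)
  for (k in 1:25) {
    prot <- random_peptide(sample(30:90, 1))
    segs <- suppressMessages(
      excise_peptides(prot, sig, find_cleavage_sites(prot)))
    for (i in seq_len(nrow(segs))) {
      expect_false(grepl("[KR]$", segs$peptide[i]))
      mp <- apply_terminal_ptms(segs$peptide[i], segs$flank[i])
      if (mp$amidated) expect_false(grepl("G$", mp$sequence))
    }
  }
})

test_that("tyrosine sulfation requires an acidic residue within two positions", {
  expect_equal(predict_tyr_sulfation("EYE"), 2L)
  expect_equal(predict_tyr_sulfation("KLMNP"), integer(0))
  expect_equal(predict_tyr_sulfation("YAAE"), integer(0))  # acidic too far
  expect_equal(predict_tyr_sulfation("YAE"), 1L)
})

test_that("sulfation reproduces the printed sulfotyrosine marks exactly", {
  tab <- read_mature_peptide_table()
  row <- tab[tab$precursor == "BnNPFL", ]
  marked <- as.integer(strsplit(row$soh_positions, ",")[[1]])
  expect_equal(predict_tyr_sulfation(row$sequence), marked)
  # and the unmarked Tyr (neutral context) is not called
  chars <- strsplit(row$sequence, "")[[1]]
  all_tyr <- which(chars == "Y")
  expect_true(length(setdiff(all_tyr, marked)) > 0)
})

test_that("disulfide counting pairs cysteines across chains", {
  tab <- read_mature_peptide_table()
  ilpa <- tab[tab$precursor == "BnILP-A", ]
  chains <- vapply(ilpa$sequence, function(s) sub("[KR]+$", "", s), "",
                   USE.NAMES = FALSE)
  expect_equal(sum(vapply(chains, count_cysteines, integer(1))), 8L)
  ds <- predict_disulfides(chains)
  expect_equal(ds$bridge_count, 4L)
  expect_equal(ds$unpaired, 0L)
  # bridge count is invariant to chain order
  expect_equal(predict_disulfides(rev(chains))$bridge_count, 4L)

  vp <- tab$sequence[tab$precursor == "BnVP-like" &
                     tab$peptide_name == "Vasopressin-like"]
  vp_mature <- sub("[KR]+$", "", vp)
  dvp <- predict_disulfides(vp_mature)
  expect_equal(dvp$bridge_count, 1L)
  expect_equal(dvp$pairing$pos1, 1L)
  expect_equal(dvp$pairing$pos2, 6L)

  expect_equal(predict_disulfides("ALGVK")$bridge_count, 0L)
  expect_equal(nrow(predict_disulfides("ALGVK")$pairing), 0L)
})

test_that("insulin B-C-A architecture detection enforces chain rules", {
  tab <- read_mature_peptide_table()
  ilpa <- tab[tab$precursor == "BnILP-A", ]
  chains <- vapply(ilpa$sequence, function(s) sub("[KR]+$", "", s), "",
                   USE.NAMES = FALSE)  # fixture order is B, C, A
  arch <- detect_insulin_architecture(chains)
  expect_false(is.null(arch))
  expect_equal(count_cysteines(arch$c_chain), 0L)
  expect_equal(arch$disulfide_count, 4L)

  expect_null(detect_insulin_architecture(c("ACA", "DDD", "AEA")))  # no CC
  expect_null(detect_insulin_architecture(chains[1:2]))             # two chains
  # a Cys-rich middle chain breaks the C-chain rule
  expect_null(detect_insulin_architecture(c(chains[1], "ACCA", chains[3])))
})
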