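# turn one fixture precursor group (printed rows with flanks) into the
# mature-peptide table classify_family() expects
fixture_group_peptides <- function(group) {
  rows <- lapply(group$sequences, function(s) {
    flank_m <- regmatches(s, regexpr("[KR]+$", s))
    flank <- if (length(flank_m)) flank_m else ""
    trimmed <- substr(s, 1, nchar(s) - nchar(flank))
    mp <- apply_terminal_ptms(trimmed, flank)
    data.frame(peptide = mp$sequence,
               pre_amidation_length = mp$pre_amidation_length,
               amidated = mp$amidated, pyroglutamate = mp$pyroglutamate,
               sulfo_positions = paste(predict_tyr_sulfation(trimmed),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
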