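# Brute-force local alignment oracle: exhaustive enumeration over all
# order-preserving residue matchings. A local alignment is a set of matched
# index pairs (i1<...<ik, j1<...<jk); its score is the sum of substitution
# scores minus an affine cost (open + extend * L) for every run of skipped
# residues between consecutive matches on either sequence. Leading/trailing
# unmatched residues are free (local). Independent of the dynamic program
# under test.
bf_local_score <- function(query, target, params) {
  S <- params$substitution_matrix
  a <- strsplit(query, "", fixed = TRUE)[[1]]
  b <- strsplit(target, "", fixed = TRUE)[[1]]
  m <- length(a)
  n <- length(b)
  best <- 0
  gap_cost <- function(len) {
    if (len <= 0) 0 else params$gap_open + params$gap_extend * len
  }
  extend <- function(i, j, score) {
    if (score > best) best <<- score
    if (i < m && j < n) {
      for (ni in (i + 1):m) {
        for (nj in (j + 1):n) {
          g <- gap_cost(ni - i - 1) + gap_cost(nj - j - 1)
          extend(ni, nj, score + S[a[ni], b[nj]] - g)
        }
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      extend(i, j, S[a[i], b[j]])
    }
  }
  best
}

random_peptide <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Table 2 fixture grouped into complete precursors with their expected
# profile family, for classification tests.
fixture_precursor_groups <- function() {
  tab <- read_mature_peptide_table()
  fam <- c("BnFDSIG-like" = "pedal_orcokinin_FDSIG",
           "BnPep-like" = "pedal_orcokinin_FDSIG",
           "BnVP-like" = "vasopressin",
           "BnGHB5" = "GPB5",
           "BnNPFL" = "NPF",
           "BnILP-A" = "insulin_like", "BnILP-B" = "insulin_like",
           "BnILP-C" = "insulin_like", "BnILP-D" = "insulin_like",
           "BnILP-E" = "insulin_like", "BnILP-F" = "insulin_like")
  groups <- split(tab, tab$precursor)
  lapply(groups, function(g) {
    list(precursor = g$precursor[1],
         sequences = g$sequence,
         partial = any(g$partial),
         family = unname(fam[g$precursor[1]]))
  })
}

# process one printed fixture row the way the maturation module would:
# trim the trailing basic run, then apply terminal PTMs and sulfation
process_printed_row <- function(printed) {
  sig <- list(present = FALSE, cleavage_after = NA_integer_)
  sites <- find_cleavage_sites(printed)
  segs <- excise_peptides(printed, sig, sites)
  segs
}
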