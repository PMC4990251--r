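#' Count cysteine residues
#'
#' @param sequence amino-acid string.
#' @return Number of `C` characters.
#' @examples
#' count_cysteines("CC")  # 2
#' @export
count_cysteines <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  lengths(regmatches(sequence, gregexpr("C", sequence, fixed = TRUE)))
}

#' Load family classification profiles
#'
#' Profiles are data, not code: rule parameters (motifs, length windows, Cys
#' requirements, precedence) are read from a YAML file. The packaged default
#' encodes five families: insulin-like (B-C-A architecture), vasopressin
#' (Cys at positions 1 and 6 of a short peptide), GPB5 (a single long
#' Cys-rich mature region with no internal cleavage), pedal/orcokinin
#' (IGxG-core motif in a short peptide), and NPF (C-terminal RXR(F/Y) amide
#' or, for divergent members, a 30-40 residue peptide with two
#' sulfation-eligible tyrosines).
#'
#' @param path YAML file; defaults to the packaged profile set.
#' @return A named list of rule parameter lists plus `precedence`.
#' @export
family_profiles <- function(path = system.file("extdata", "family_profiles.yaml",
                                               package = "npminer")) {
  prof <- yaml::read_yaml(path)
  needed <- c("precedence", "vasopressin", "GPB5", "pedal_orcokinin_FDSIG", "NPF")
  missing <- setdiff(needed, names(prof))
  if (length(missing)) stop("profile file lacks: ", paste(missing, collapse = ", "))
  prof
}

# evaluate all family rules for one precursor; returns list of satisfied rules
.family_evidence <- function(peptides, n_internal_sites, insulin, prof) {
  ev <- character(0)
  if (!is.null(insulin)) ev <- c(ev, "insulin_like: B-C-A chain architecture")
  vp <- prof$vasopressin
  seqs <- peptides$peptide
  lens <- nchar(seqs)
  is_vp <- lens >= vp$length_min & lens <= vp$length_max &
    substr(seqs, 1, 1) == "C" & substr(seqs, 6, 6) == "C"
  if (any(is_vp)) ev <- c(ev, "vasopressin: Cys at positions 1 and 6")
  gp <- prof$GPB5
  if (nrow(peptides) == 1 && n_internal_sites == 0 &&
      peptides$pre_amidation_length[1] >= gp$length_min &&
      peptides$pre_amidation_length[1] <= gp$length_max &&
      count_cysteines(seqs[1]) >= gp$min_cys) {
    ev <- c(ev, "GPB5: single uncleaved Cys-rich mature region")
  }
  pd <- prof$pedal_orcokinin_FDSIG
  is_pd <- grepl(pd$motif, seqs) & lens >= pd$length_min & lens <= pd$length_max
  if (any(is_pd)) ev <- c(ev, "pedal_orcokinin_FDSIG: IGxG core motif")
  np <- prof$NPF
  motif_hit <- any(peptides$amidated & grepl(np$cterm_motif, seqs))
  if (motif_hit) ev <- c(ev, "NPF: C-terminal RXR(F/Y) amide")
  n_sulfo <- vapply(peptides$sulfo_positions, function(s) {
    if (!nzchar(s)) 0L else length(strsplit(s, ",", fixed = TRUE)[[1]])
  }, integer(1))
  fallback <- any(peptides$pre_amidation_length >= np$length_min &
                  peptides$pre_amidation_length <= np$length_max &
                  n_sulfo >= np$min_sulfated_tyr)
  if (fallback) ev <- c(ev, "NPF: 30-40 residues with >= 2 sulfation-eligible Tyr")
  ev
}

#' Classify a precursor's mature peptides into a family
#'
#' Rules fire in precedence order (insulin-like, vasopressin, GPB5,
#' pedal/orcokinin, NPF); the first match names the family and all satisfied
#' rules are recorded as evidence. When no rule fires the call is
#' `unclassified` with empty evidence.
#'
#' @param peptides a mature-peptide data frame from
#'   [derive_mature_peptides()], or a character vector of processed peptide
#'   sequences (annotations are then derived with default options).
#' @param n_internal_sites number of cleavage sites found inside the mature
#'   region (used by the GPB5 rule).
#' @param insulin result of [detect_insulin_architecture()] for this
#'   precursor, or `NULL`; when missing it is computed from `peptides`.
#' @param profiles a [family_profiles()] list.
#' @param subject_id identifier copied into the call.
#' @return A list of class `family_call`: `subject_id`, `family`,
#'   `evidence` (character vector of satisfied rules), `confidence`
#'   (`"motif+architecture"`, `"motif-only"` or `"positional-only"`).
#' @examples
#' classify_family("SFDSIGNGPIGL")$family  # pedal_orcokinin_FDSIG
#' @export
classify_family <- function(peptides, n_internal_sites = NULL, insulin = NULL,
                            profiles = family_profiles(), subject_id = NA_character_) {
  if (is.character(peptides)) {
    peptides <- data.frame(
      peptide = peptides, pre_amidation_length = nchar(peptides),
      amidated = FALSE, pyroglutamate = FALSE,
      sulfo_positions = vapply(peptides, function(p)
        paste(predict_tyr_sulfation(p), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  if (is.null(n_internal_sites)) n_internal_sites <- max(0L, nrow(peptides) - 1L)
  if (is.null(insulin) && nrow(peptides) == 3) {
    insulin <- detect_insulin_architecture(peptides$peptide)
  }
  ev <- .family_evidence(peptides, n_internal_sites, insulin, profiles)
  family <- "unclassified"
  for (fam in profiles$precedence) {
    if (any(startsWith(ev, paste0(fam, ":")))) {
      family <- fam
      break
    }
  }
  confidence <- if (family == "unclassified") {
    NA_character_
  } else if (family == "insulin_like") {
    "motif+architecture"
  } else if (family %in% c("vasopressin", "GPB5")) {
    "positional-only"
  } else if (family == "pedal_orcokinin_FDSIG") {
    "motif-only"
  } else if (any(startsWith(ev, "NPF: C-terminal"))) {
    "motif-only"
  } else {
    "positional-only"
  }
  structure(list(subject_id = subject_id, family = family,
                 evidence = if (family == "unclassified") character(0) else ev,
                 confidence = confidence),
            class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat("family_call:", x$subject_id, "->", x$family,
      if (!is.na(x$confidence)) paste0("(", x$confidence, ")"), "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Read the packaged precursor inventory fixture
#'
#' Eleven precursor records (name, family label, transcript length, search
#' statistics, archive accession) transcribed from the source inventory.
#'
#' @return A data frame with one row per precursor.
#' @export
read_precursor_inventory <- function() {
  path <- system.file("extdata", "table1_precursors.tsv", package = "npminer")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read the packaged mature-peptide fixture table
#'
#' Printed predicted mature peptides (with their flanking basic residues and
#' any `(SOH)` sulfotyrosine tokens) for each precursor. `sequence` is the
#' printed sequence with tokens stripped; `soh_positions` gives the 1-based
#' positions of the `(SOH)`-marked tyrosines in the stripped sequence.
#'
#' @return A data frame with columns `precursor`, `peptide_name`, `partial`,
#'   `printed_sequence`, `sequence`, `soh_positions`.
#' @export
read_mature_peptide_table <- function() {
  path <- system.file("extdata", "table2_mature_peptides.tsv", package = "npminer")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$sequence <- gsub("(SOH)", "", tab$printed_sequence, fixed = TRUE)
  tab$soh_positions <- vapply(tab$printed_sequence, function(s) {
    pos <- integer(0)
    aa <- 0L
    i <- 1L
    while (i <= nchar(s)) {
      if (substr(s, i, i + 4L) == "(SOH)") {
        pos <- c(pos, aa)  # the tag follows the modified residue
        i <- i + 5L
      } else {
        aa <- aa + 1L
        i <- i + 1L
      }
    }
    paste(pos, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  tab
}

#' Map a printed family label to a profile family name
#'
#' @param label family label as printed in the precursor inventory.
#' @return Profile family name used by [classify_family()].
#' @export
family_label_to_profile <- function(label) {
  map <- c("Arginine-vasotocine" = "vasopressin",
           "Pedal peptide/orcokinin neuropeptide" = "pedal_orcokinin_FDSIG",
           "Neuropeptide Y" = "NPF",
           "Glycoprotein hormone-beta5-I" = "GPB5",
           "Insulin-like peptide" = "insulin_like")
  out <- unname(map[label])
  if (any(is.na(out))) stop("unknown family label: ",
                            paste(label[is.na(out)], collapse = ", "))
  out
}
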