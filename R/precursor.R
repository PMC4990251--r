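#' Find Met-initiated open reading frames in all six frames
#'
#' Reports every ORF (`ATG` ... stop, or `ATG` ... frame end for 3'-partial
#' frames) of at least `min_aa` residues, longest first. Nested ORFs sharing
#' a stop codon report only the longest unless `include_nested` is set.
#' Nucleotide spans are 0-based half-open on the input transcript; for
#' negative frames they are mirrored onto the forward strand.
#'
#' @param sequence nucleotide string over `A,C,G,T,N`.
#' @param min_aa minimum protein length in residues.
#' @param include_nested also report ORFs from internal Met codons.
#' @param transcript_id optional id copied into the result.
#' @return A data frame with columns `transcript_id`, `frame`, `nt_start`,
#'   `nt_end`, `protein`, `has_start`, `has_stop`, sorted by decreasing
#'   protein length.
#' @examples
#' find_orfs("ATGAAATAA")$protein  # "MK"
#' @export
find_orfs <- function(sequence, min_aa = 1L, include_nested = FALSE,
                      transcript_id = NA_character_) {
  stopifnot(min_aa >= 1)
  frames <- six_frame_translate(sequence)
  L <- nchar(sequence)
  rows <- list()
  frame_num <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (fi in seq_along(frames)) {
    pep <- frames[[fi]]
    if (!nzchar(pep)) next
    f <- frame_num[fi]
    off <- abs(f) - 1L
    chars <- strsplit(pep, "", fixed = TRUE)[[1]]
    stops <- c(which(chars == "*"), length(chars) + 1L)
    chunk_start <- 1L
    for (stp in stops) {
      if (stp > chunk_start) {
        chunk <- chars[chunk_start:(stp - 1L)]
        mets <- which(chunk == "M")
        if (length(mets) > 0 && !include_nested) mets <- mets[1L]
        for (mpos in mets) {
          s_aa <- chunk_start + mpos - 1L   # 1-based aa pos in frame
          e_aa <- stp - 1L                  # last coding aa (1-based)
          plen <- e_aa - s_aa + 1L
          if (plen < min_aa) next
          has_stop <- stp <= length(chars)
          nt_s <- off + 3L * (s_aa - 1L)
          nt_e <- off + 3L * e_aa + (if (has_stop) 3L else 0L)
          if (f < 0) {
            tmp <- nt_s
            nt_s <- L - nt_e
            nt_e <- L - tmp
          }
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = transcript_id, frame = f,
            nt_start = nt_s, nt_end = nt_e,
            protein = paste(chars[s_aa:e_aa], collapse = ""),
            has_start = TRUE, has_stop = has_stop,
            stringsAsFactors = FALSE)
        }
      }
      chunk_start <- stp + 1L
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      protein = character(0), has_start = logical(0),
                      has_stop = logical(0), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  ord <- order(-nchar(orfs$protein), orfs$frame, orfs$nt_start)
  orfs <- orfs[ord, , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

# Kyte-Doolittle hydropathy scale; X scores neutral
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

.SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Predict an N-terminal signal peptide by a hydropathy heuristic
#'
#' Scans candidate cleavage positions 15-45: each position scores the mean
#' Kyte-Doolittle hydropathy of the preceding 8-residue window, plus a bonus
#' when the residues at -3 and -1 relative to the cut are both small
#' (A, G, S, C, T; the (-3,-1) rule). The highest-scoring position at or
#' above `threshold` is returned. This is a stated stand-alone heuristic;
#' no equivalence with HMM/network signal-peptide predictors is claimed.
#'
#' @param protein amino-acid string starting with Met, length >= 25 for a
#'   call to be attempted.
#' @param threshold minimum score (hydropathy units + bonus) for a positive
#'   call.
#' @param bonus score added when the (-3,-1) rule is satisfied. The default
#'   makes the (-3,-1) rule decisive against cut points inside the
#'   hydrophobic core (which otherwise win on raw hydropathy), reflecting
#'   signal peptidase's strong small-residue preference at those positions.
#' @return A list with `present`, `cleavage_after` (1-based index of the
#'   last signal residue, `NA` when absent), `score` (best score over the
#'   scanned positions, reported even when absent), and `reason`.
#' @export
predict_signal_peptide <- function(protein, threshold = 1.6, bonus = 2.5) {
  n <- nchar(protein)
  if (n < 25) {
    return(list(present = FALSE, cleavage_after = NA_integer_,
                score = NA_real_, reason = "protein shorter than 25 residues"))
  }
  if (substr(protein, 1, 1) != "M") {
    return(list(present = FALSE, cleavage_after = NA_integer_,
                score = NA_real_, reason = "no N-terminal Met"))
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  kd <- unname(.KD[chars])
  kd[is.na(kd)] <- 0
  positions <- 15:min(45L, n - 1L)
  best_p <- NA_integer_
  best_s <- -Inf
  for (p in positions) {
    s <- mean(kd[(p - 7L):p])
    if (chars[p] %in% .SMALL_RESIDUES && chars[p - 2L] %in% .SMALL_RESIDUES) {
      s <- s + bonus
    }
    if (s > best_s) {
      best_s <- s
      best_p <- p
    }
  }
  if (best_s >= threshold) {
    list(present = TRUE, cleavage_after = best_p, score = best_s, reason = "")
  } else {
    list(present = FALSE, cleavage_after = NA_integer_, score = best_s,
         reason = "no candidate position reached the score threshold")
  }
}

#' Prohormone convertase cleavage rules
#'
#' The default ruleset is the conservative dibasic subset
#' \{KR, RR, KK\} plus multibasic runs, with monobasic R off: it reproduces
#' the dibasic and multibasic flanks seen on classical precursors
#' (KR, KK, RR, KKR, RRRR, RRKR all end in an accepted pair). RK is
#' accepted only if added explicitly.
#'
#' @param accept_dibasic subset of `c("KR","RR","KK","RK")`.
#' @param allow_multibasic_runs treat any basic run of length >= 3 as a site.
#' @param allow_monobasic_R also cleave after single Arg residues.
#' @param min_peptide_len dibasic/multibasic sites closer than this to the
#'   previous kept dibasic/multibasic site are suppressed.
#' @return A list of class `cleavage_rules`.
#' @export
cleavage_rules <- function(accept_dibasic = c("KR", "RR", "KK"),
                           allow_multibasic_runs = TRUE,
                           allow_monobasic_R = FALSE,
                           min_peptide_len = 3L) {
  accept_dibasic <- match.arg(accept_dibasic, c("KR", "RR", "KK", "RK"),
                              several.ok = TRUE)
  if (length(accept_dibasic) == 0) stop("at least one dibasic motif required")
  structure(list(accept_dibasic = accept_dibasic,
                 allow_multibasic_runs = isTRUE(allow_multibasic_runs),
                 allow_monobasic_R = isTRUE(allow_monobasic_R),
                 min_peptide_len = as.integer(min_peptide_len)),
            class = "cleavage_rules")
}

#' Find prohormone convertase cleavage sites
#'
#' Scans the mature region (the precursor after the signal peptide) for
#' maximal runs of K/R. A run of length 2 is a site when it is an accepted
#' dibasic motif; any run of length >= 3 is a site when multibasic runs are
#' allowed; single R residues are sites only when monobasic cleavage is
#' enabled. Cleavage is placed C-terminal to the entire run (one site per
#' run). A dibasic/multibasic site closer than `min_peptide_len` residues
#' to the previous kept dibasic/multibasic site is suppressed; monobasic
#' sites are exempt from spacing suppression in both directions, so enabling
#' them can only add sites (over-short segments are instead dropped at
#' excision).
#'
#' @param protein_after_signal amino-acid string (mature region).
#' @param rules a [cleavage_rules()].
#' @return A data frame with columns `position` (0-based index of the first
#'   residue after the run), `motif` (the matched run), `cls`
#'   (`dibasic`/`multibasic`/`monobasic`).
#' @examples
#' find_cleavage_sites("SFDSIGNGPIGLKRSFDGIGNGPIGLKR")
#' @export
find_cleavage_sites <- function(protein_after_signal, rules = cleavage_rules()) {
  if (!nzchar(protein_after_signal)) stop("empty mature region")
  m <- gregexpr("[KR]+", protein_after_signal)[[1]]
  empty <- data.frame(position = integer(0), motif = character(0),
                      cls = character(0), stringsAsFactors = FALSE)
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  motifs <- substring(protein_after_signal, starts, starts + lens - 1L)
  rows <- list()
  prev_site_end <- NA_integer_   # 1-based end of previous kept di/multibasic run
  mono <- list()
  for (k in seq_along(starts)) {
    run <- motifs[k]
    len <- lens[k]
    cls <- NULL
    if (len >= 3 && rules$allow_multibasic_runs) {
      cls <- "multibasic"
    } else if (len >= 2) {
      pair <- substr(run, len - 1L, len)
      if (pair %in% rules$accept_dibasic) {
        cls <- if (len == 2) "dibasic" else "multibasic"
      }
    } else if (len == 1 && run == "R" && rules$allow_monobasic_R) {
      cls <- "monobasic"
    }
    if (is.null(cls)) next
    site <- data.frame(position = starts[k] + len - 1L,  # 0-based, after run
                       motif = run, cls = cls, stringsAsFactors = FALSE)
    if (cls == "monobasic") {
      # monobasic sites are exempt from spacing suppression in both
      # directions, so enabling them can only add sites
      mono[[length(mono) + 1L]] <- site
    } else {
      suppressed <- !is.na(prev_site_end) &&
        (starts[k] - 1L - prev_site_end) < rules$min_peptide_len
      if (!suppressed) {
        rows[[length(rows) + 1L]] <- site
        prev_site_end <- starts[k] + len - 1L
      }
    }
  }
  rows <- c(rows, mono)
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write precursor annotation as JSON and a GFF3-like TSV
#'
#' @param annotation a per-precursor annotation list as produced by
#'   [annotate_precursor()].
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#'   Coordinates in both outputs are 1-based inclusive.
#' @return Invisibly, the annotation.
#' @export
write_precursor_annotation <- function(annotation, json_path = NULL,
                                       tsv_path = NULL) {
  if (!is.null(json_path)) {
    plain <- annotation
    plain$call <- if (!is.null(plain$call)) unclass(plain$call)
    jsonlite::write_json(plain, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  if (!is.null(tsv_path)) {
    rows <- list()
    tid <- annotation$transcript_id %||% "."
    if (!is.null(annotation$orf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = tid, type = "ORF",
        start = annotation$orf$nt_start + 1L, end = annotation$orf$nt_end,
        attr = paste0("frame=", annotation$orf$frame),
        stringsAsFactors = FALSE)
    }
    if (isTRUE(annotation$signal$present)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = tid, type = "signal_peptide", start = 1L,
        end = annotation$signal$cleavage_after,
        attr = sprintf("score=%.3f", annotation$signal$score),
        stringsAsFactors = FALSE)
    }
    if (!is.null(annotation$sites) && nrow(annotation$sites) > 0) {
      off <- if (isTRUE(annotation$signal$present)) annotation$signal$cleavage_after else 0L
      s <- annotation$sites
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = tid, type = "cleavage_site",
        start = off + s$position - nchar(s$motif) + 1L,
        end = off + s$position,
        attr = paste0("motif=", s$motif, ";class=", s$cls),
        stringsAsFactors = FALSE)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(seqid = character(0), type = character(0),
                 start = integer(0), end = integer(0), attr = character(0))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(annotation)
}
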