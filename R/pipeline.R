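#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage. Defaults reproduce the
#' packaged fixture behaviour.
#'
#' @param search a [search_params()].
#' @param cleavage a [cleavage_rules()].
#' @param signal_threshold,signal_bonus passed to
#'   [predict_signal_peptide()].
#' @param pyroglu_from_E also flag N-terminal Glu as pyroglutamate.
#' @param min_orf_aa minimum ORF length considered a precursor candidate.
#' @param profiles a [family_profiles()] list.
#' @param seed optional integer seed recorded in reports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(search = search_params(),
                            cleavage = cleavage_rules(),
                            signal_threshold = 1.6, signal_bonus = 2.5,
                            pyroglu_from_E = FALSE, min_orf_aa = 30L,
                            profiles = family_profiles(), seed = NULL) {
  structure(list(search = search, cleavage = cleavage,
                 signal_threshold = signal_threshold,
                 signal_bonus = signal_bonus,
                 pyroglu_from_E = isTRUE(pyroglu_from_E),
                 min_orf_aa = as.integer(min_orf_aa),
                 profiles = profiles, seed = seed),
            class = "pipeline_config")
}

#' Annotate one candidate transcript as a precursor
#'
#' Picks the candidate ORF, predicts the signal peptide, finds cleavage
#' sites in the mature region, derives the processed peptides, and
#' classifies the peptide family. When the homology hit that promoted the
#' transcript is supplied, the ORF is chosen as the longest Met-initiated
#' ORF in the hit's reading frame that overlaps the hit span (the hit
#' defines the coding frame); otherwise, and as a fallback, the longest ORF
#' overall is used.
#'
#' @param sequence nucleotide sequence of the candidate transcript.
#' @param transcript_id id copied into the annotation.
#' @param config a [pipeline_config()].
#' @param hit_frame,hit_t_start,hit_t_end frame and span (translated-frame
#'   residue coordinates, 0-based half-open) of the supporting hit;
#'   optional.
#' @return A list with `transcript_id`, `orf` (single-row data frame),
#'   `signal`, `sites`, `peptides`, `insulin`, `call`; or `NULL` when the
#'   transcript has no ORF of at least `min_orf_aa` residues.
#' @export
annotate_precursor <- function(sequence, transcript_id = NA_character_,
                               config = pipeline_config(), hit_frame = NULL,
                               hit_t_start = NULL, hit_t_end = NULL) {
  orfs <- find_orfs(sequence, min_aa = config$min_orf_aa,
                    transcript_id = transcript_id)
  if (nrow(orfs) == 0) return(NULL)
  orf <- orfs[1, , drop = FALSE]
  if (!is.null(hit_frame) && !is.null(hit_t_start) && !is.null(hit_t_end)) {
    L <- nchar(sequence)
    nt_s <- (abs(hit_frame) - 1L) + 3L * hit_t_start
    nt_e <- (abs(hit_frame) - 1L) + 3L * hit_t_end
    if (hit_frame < 0) {
      tmp <- nt_s
      nt_s <- L - nt_e
      nt_e <- L - tmp
    }
    in_frame <- orfs$frame == hit_frame &
      orfs$nt_start < nt_e & orfs$nt_end > nt_s
    if (any(in_frame)) orf <- orfs[which(in_frame)[1L], , drop = FALSE]
  }
  signal <- predict_signal_peptide(orf$protein,
                                   threshold = config$signal_threshold,
                                   bonus = config$signal_bonus)
  sig_end <- if (isTRUE(signal$present)) signal$cleavage_after else 0L
  mature <- substr(orf$protein, sig_end + 1L, nchar(orf$protein))
  sites <- find_cleavage_sites(mature, config$cleavage)
  peptides <- derive_mature_peptides(orf$protein, signal, sites,
                                     rules = config$cleavage,
                                     pyroglu_from_E = config$pyroglu_from_E)
  insulin <- if (nrow(peptides) == 3) {
    detect_insulin_architecture(peptides$peptide)
  } else NULL
  call <- classify_family(peptides, n_internal_sites = nrow(sites),
                          insulin = insulin, profiles = config$profiles,
                          subject_id = transcript_id)
  list(transcript_id = transcript_id, orf = orf, signal = signal,
       sites = sites, peptides = peptides, insulin = insulin, call = call)
}

#' Run the full discovery pipeline
#'
#' Query filtering is assumed done (see [filter_annotation_records()]); this
#' runs search, candidate selection, precursor annotation, maturation and
#' family classification, and returns a structured report. An empty query
#' set or an empty candidate set yields an empty report, not an error.
#'
#' @param transcripts nucleotide FASTA path or a data frame with `id`,
#'   `sequence`.
#' @param queries protein FASTA path, a query table, or a named character
#'   vector of peptides.
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_report` with `precursors` (one row per
#'   candidate), `peptides` (one row per processed peptide), `hits` (the
#'   selected per-query hits), and `summary`.
#' @export
run_pipeline <- function(transcripts, queries, config = pipeline_config()) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- read_transcripts(transcripts)
  }
  if (is.character(queries) && length(queries) == 1 && file.exists(queries)) {
    queries <- read_fasta(queries, alphabet = "AA")
  }
  empty_report <- function(hits) {
    structure(list(
      precursors = data.frame(
        transcript_id = character(0), best_query = character(0),
        evalue = numeric(0), frame = integer(0), orf_length = integer(0),
        orf_frame = integer(0), orf_nt_start = integer(0),
        orf_nt_end = integer(0),
        signal_present = logical(0), signal_cleavage_after = integer(0),
        n_cleavage_sites = integer(0), n_peptides = integer(0),
        family = character(0), confidence = character(0),
        stringsAsFactors = FALSE),
      peptides = data.frame(
        transcript_id = character(0), peptide = character(0),
        pre_amidation_length = integer(0), flank = character(0),
        start = integer(0), end = integer(0), amidated = logical(0),
        pyroglutamate = logical(0), sulfo_positions = character(0),
        stringsAsFactors = FALSE),
      hits = hits,
      summary = list(n_candidates = 0L, n_with_signal = 0L,
                     n_peptides = 0L, families = list())),
      class = "pipeline_report")
  }
  n_queries <- if (is.data.frame(queries)) nrow(queries) else length(queries)
  if (n_queries == 0) return(empty_report(.empty_hits()))
  hits <- run_search(transcripts, queries, config$search)
  sel <- select_candidates(hits, config$search)
  if (nrow(sel$candidates) == 0) return(empty_report(sel$hits))
  seq_by_id <- stats::setNames(transcripts$sequence, transcripts$id)
  prec_rows <- list()
  pep_rows <- list()
  for (k in seq_len(nrow(sel$candidates))) {
    cand <- sel$candidates[k, ]
    ann <- annotate_precursor(seq_by_id[[cand$transcript_id]],
                              transcript_id = cand$transcript_id,
                              config = config, hit_frame = cand$frame,
                              hit_t_start = cand$t_start,
                              hit_t_end = cand$t_end)
    if (is.null(ann)) next
    prec_rows[[length(prec_rows) + 1L]] <- data.frame(
      transcript_id = cand$transcript_id, best_query = cand$best_query,
      evalue = cand$evalue, frame = cand$frame,
      orf_length = nchar(ann$orf$protein),
      orf_frame = ann$orf$frame,
      orf_nt_start = ann$orf$nt_start, orf_nt_end = ann$orf$nt_end,
      signal_present = isTRUE(ann$signal$present),
      signal_cleavage_after = if (isTRUE(ann$signal$present))
        ann$signal$cleavage_after else NA_integer_,
      n_cleavage_sites = nrow(ann$sites),
      n_peptides = nrow(ann$peptides),
      family = ann$call$family, confidence = ann$call$confidence,
      stringsAsFactors = FALSE)
    if (nrow(ann$peptides) > 0) {
      pep <- ann$peptides
      pep <- cbind(data.frame(transcript_id = cand$transcript_id,
                              stringsAsFactors = FALSE), pep)
      pep_rows[[length(pep_rows) + 1L]] <- pep
    }
  }
  if (length(prec_rows) == 0) return(empty_report(sel$hits))
  precursors <- do.call(rbind, prec_rows)
  peptides <- if (length(pep_rows)) do.call(rbind, pep_rows) else
    empty_report(sel$hits)$peptides
  rownames(precursors) <- NULL
  rownames(peptides) <- NULL
  fam_counts <- table(precursors$family)
  structure(list(
    precursors = precursors, peptides = peptides, hits = sel$hits,
    summary = list(n_candidates = nrow(precursors),
                   n_with_signal = sum(precursors$signal_present),
                   n_peptides = nrow(peptides),
                   families = as.list(fam_counts))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", x$summary$n_candidates, "candidate precursor(s),",
      x$summary$n_peptides, "mature peptide(s)\n")
  if (x$summary$n_candidates > 0) {
    print(x$precursors[, c("transcript_id", "best_query", "evalue",
                           "signal_present", "n_peptides", "family")])
  }
  invisible(x)
}

#' Write a pipeline report to files
#'
#' TSV (`<prefix>_precursors.tsv`, `<prefix>_peptides.tsv`) and JSON
#' (`<prefix>.json`) are always written; `"fasta"` adds a mature-peptide
#' FASTA with PTM annotations in the headers. All coordinates in the
#' outputs are 1-based inclusive.
#'
#' @param report a `pipeline_report`.
#' @param prefix output path prefix.
#' @param formats subset of `c("tsv", "json", "fasta")`.
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(report, prefix, formats = c("tsv", "json")) {
  unknown <- setdiff(formats, c("tsv", "json", "fasta"))
  if (length(unknown)) stop("unknown format key(s): ",
                            paste(unknown, collapse = ", "))
  written <- character(0)
  if ("tsv" %in% formats) {
    f1 <- paste0(prefix, "_precursors.tsv")
    f2 <- paste0(prefix, "_peptides.tsv")
    utils::write.table(report$precursors, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(report$peptides, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f1, f2)
  }
  if ("json" %in% formats) {
    f <- paste0(prefix, ".json")
    jsonlite::write_json(unclass(report), f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "rows")
    written <- c(written, f)
  }
  if ("fasta" %in% formats) {
    f <- paste0(prefix, "_peptides.fasta")
    p <- report$peptides
    if (nrow(p) > 0) {
      hdr <- sprintf("%s_pep%02d span=%d-%d amidated=%s pyroglu=%s sulfoY=%s",
                     p$transcript_id, stats::ave(seq_len(nrow(p)),
                                                 p$transcript_id,
                                                 FUN = seq_along),
                     p$start, p$end, p$amidated, p$pyroglutamate,
                     ifelse(nzchar(p$sulfo_positions), p$sulfo_positions, "none"))
      write_fasta(hdr, p$peptide, f)
    } else {
      file.create(f)
    }
    written <- c(written, f)
  }
  invisible(written)
}
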