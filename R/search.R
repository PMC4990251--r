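#' Search parameters for the translated homology search
#'
#' Defaults follow common protein-search practice: BLOSUM62 with affine gap
#' costs 11/1 and the standard gapped-BLOSUM62 Karlin-Altschul constants
#' (lambda 0.267, K 0.041). A gap of length L costs
#' `gap_open + gap_extend * L`. Candidate selection keeps at most
#' `max_hits_per_query` hits per query, all below `evalue_max`.
#'
#' @param substitution_matrix name of a matrix shipped with Biostrings
#'   (default `"BLOSUM62"`), or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend positive affine gap costs.
#' @param lambda_param,k_param Karlin-Altschul-style constants used by
#'   [estimate_evalue()].
#' @param evalue_max E-value threshold for candidate selection.
#' @param max_hits_per_query hits kept per query during selection.
#' @param min_alignment_length minimum aligned columns for a reported hit.
#' @return A list of class `search_params`.
#' @export
search_params <- function(substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          lambda_param = 0.267, k_param = 0.041,
                          evalue_max = 0.01, max_hits_per_query = 3L,
                          min_alignment_length = 8L) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda_param > 0, k_param > 0,
            evalue_max > 0, max_hits_per_query >= 1)
  if (is.character(substitution_matrix)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    substitution_matrix <- get(substitution_matrix, envir = e)
  }
  stopifnot(is.matrix(substitution_matrix),
            !is.null(rownames(substitution_matrix)))
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda_param = lambda_param, k_param = k_param,
                 evalue_max = evalue_max,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 min_alignment_length = as.integer(min_alignment_length)),
            class = "search_params")
}

#' Translate a transcript in all six reading frames
#'
#' Frames `+1,+2,+3` read the given strand from offsets 0,1,2; frames
#' `-1,-2,-3` read the reverse complement the same way. Translation uses the
#' standard genetic code; stop codons are rendered `*`; codons containing `N`
#' translate to `X`; trailing partial codons are dropped.
#'
#' @param sequence a nucleotide string over `A,C,G,T,N`.
#' @return A named character vector with names `+1,+2,+3,-1,-2,-3`.
#' @examples
#' six_frame_translate("ATGAAATAA")[["+1"]]  # "MK*"
#' @export
six_frame_translate <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains letters outside A,C,G,T,N")
  }
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(dna, off) {
    len <- length(dna) - off
    len <- len - (len %% 3)
    if (len < 3) return("")
    as.character(Biostrings::translate(Biostrings::subseq(dna, off + 1, off + len),
                                       if.fuzzy.codon = "X"))
  }
  out <- c(one(fwd, 0), one(fwd, 1), one(fwd, 2),
           one(rev, 0), one(rev, 1), one(rev, 2))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# encode a peptide as 1-based row indices of the substitution matrix
.encode_pep <- function(pep, mat) {
  idx <- match(strsplit(pep, "", fixed = TRUE)[[1]], rownames(mat))
  if (anyNA(idx)) stop("residue not covered by the substitution matrix in: ", pep)
  idx
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman with affine gaps under the parameters' substitution matrix.
#' Traceback is deterministic (ties prefer the diagonal move, then the gap in
#' the target, then the gap in the query). Spans are 0-based half-open.
#'
#' @param query_pep,target_pep non-empty amino-acid strings.
#' @param params a [search_params()].
#' @return A list with `score`, `q_start`, `q_end`, `t_start`, `t_end`,
#'   `q_aln`, `t_aln`, and `length` (aligned columns). A score of 0 reports
#'   an empty alignment.
#' @export
local_align <- function(query_pep, target_pep, params = search_params()) {
  if (!nzchar(query_pep) || !nzchar(target_pep)) {
    stop("local_align requires non-empty peptides")
  }
  mat <- params$substitution_matrix
  a <- .encode_pep(query_pep, mat)
  b <- .encode_pep(target_pep, mat)
  r <- .sw_align_c(a, b, mat, params$gap_open, params$gap_extend)
  if (r$score <= 0) {
    return(list(score = 0, q_start = 0L, q_end = 0L, t_start = 0L, t_end = 0L,
                q_aln = "", t_aln = "", length = 0L))
  }
  ops <- strsplit(r$ops, "", fixed = TRUE)[[1]]
  nq <- sum(ops != "L")
  nt <- sum(ops != "U")
  q_end <- r$q_end; t_end <- r$t_end
  q_start <- q_end - nq  # 0-based
  t_start <- t_end - nt
  qa <- character(length(ops)); ta <- character(length(ops))
  qi <- q_start; ti <- t_start
  qchars <- strsplit(query_pep, "", fixed = TRUE)[[1]]
  tchars <- strsplit(target_pep, "", fixed = TRUE)[[1]]
  for (k in seq_along(ops)) {
    if (ops[k] == "D") {
      qi <- qi + 1; ti <- ti + 1
      qa[k] <- qchars[qi]; ta[k] <- tchars[ti]
    } else if (ops[k] == "U") {
      qi <- qi + 1
      qa[k] <- qchars[qi]; ta[k] <- "-"
    } else {
      ti <- ti + 1
      qa[k] <- "-"; ta[k] <- tchars[ti]
    }
  }
  list(score = r$score, q_start = q_start, q_end = as.integer(q_end),
       t_start = t_start, t_end = as.integer(t_end),
       q_aln = paste(qa, collapse = ""), t_aln = paste(ta, collapse = ""),
       length = length(ops))
}

#' E-value and bit score for a raw alignment score
#'
#' Uses the closed form `E = K * m * n * exp(-lambda * S)` with the search
#' constants held in `params`; the bit score is
#' `(lambda * S - ln K) / ln 2`. These constants approximate gapped
#' BLOSUM62 statistics and are plumbing for ranking, not a reproduction of
#' BLAST's internal edge-corrected statistics.
#'
#' @param raw_score raw alignment score.
#' @param query_len,database_len lengths (residues) of the query and of the
#'   searched translated database; both must be at least 1.
#' @param params a [search_params()].
#' @return A list with `evalue` and `bit_score`.
#' @export
estimate_evalue <- function(raw_score, query_len, database_len,
                            params = search_params()) {
  if (query_len < 1 || database_len < 1) {
    stop("query_len and database_len must be >= 1")
  }
  evalue <- params$k_param * query_len * database_len *
    exp(-params$lambda_param * raw_score)
  bit <- (params$lambda_param * raw_score - log(params$k_param)) / log(2)
  list(evalue = evalue, bit_score = bit)
}

# split a translated frame at stop codons into alignable segments;
# returns data.frame(offset (0-based residue offset in frame), seq)
.frame_segments <- function(frame_pep, min_len = 1L) {
  if (!nzchar(frame_pep)) {
    return(data.frame(offset = integer(0), seq = character(0)))
  }
  parts <- strsplit(frame_pep, "*", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  offsets <- cumsum(c(0L, lens + 1L))[seq_along(parts)]
  keep <- lens >= min_len
  data.frame(offset = offsets[keep], seq = parts[keep],
             stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(query_id = character(0), transcript_id = character(0),
             frame = integer(0), raw_score = numeric(0),
             bit_score = numeric(0), evalue = numeric(0),
             q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0),
             q_aln = character(0), t_aln = character(0),
             stringsAsFactors = FALSE)
}

#' Six-frame translated homology search
#'
#' Every query is aligned against every stop-delimited segment of every
#' translated frame of every transcript; the best local alignment per
#' (query, transcript, frame) with at least `min_alignment_length` aligned
#' columns is scored and assigned an E-value against the full translated
#' database size. Hits are sorted per query by ascending E-value, ties broken
#' by descending raw score then transcript id.
#'
#' @param transcripts a data frame with columns `id`, `sequence` (see
#'   [read_transcripts()]) or a named character vector of nucleotide
#'   sequences.
#' @param queries a `query_set`/`annotation_records` data frame, a data frame
#'   with columns `accession`, `sequence`, or a named character vector of
#'   peptides.
#' @param params a [search_params()].
#' @return A hit table (one row per retained alignment) with columns
#'   `query_id`, `transcript_id`, `frame`, `raw_score`, `bit_score`,
#'   `evalue`, `q_start`, `q_end`, `t_start`, `t_end` (0-based half-open,
#'   residue coordinates of the translated frame), `q_aln`, `t_aln`.
#' @export
run_search <- function(transcripts, queries, params = search_params()) {
  transcripts <- .as_seq_table(transcripts, c("id", "sequence"))
  queries <- .as_seq_table(queries, c("accession", "sequence"))
  if (nrow(transcripts) == 0 || nrow(queries) == 0) {
    stop("run_search requires non-empty transcripts and queries")
  }
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  frames <- lapply(transcripts$sequence, six_frame_translate)
  segs <- lapply(frames, function(fr) lapply(fr, .frame_segments))
  database_len <- sum(vapply(frames, function(fr) sum(nchar(gsub("*", "", fr, fixed = TRUE))), numeric(1)))
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$sequence[qi]
    qlen <- nchar(qseq)
    for (ti in seq_len(nrow(transcripts))) {
      for (fi in seq_along(frame_names)) {
        sg <- segs[[ti]][[fi]]
        best <- NULL
        for (si in seq_len(nrow(sg))) {
          al <- local_align(qseq, sg$seq[si], params)
          if (al$score > 0 && al$length >= params$min_alignment_length &&
              (is.null(best) || al$score > best$score)) {
            best <- al
            best$offset <- sg$offset[si]
          }
        }
        if (!is.null(best)) {
          ev <- estimate_evalue(best$score, qlen, database_len, params)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = queries$accession[qi],
            transcript_id = transcripts$id[ti],
            frame = c(1L, 2L, 3L, -1L, -2L, -3L)[fi],
            raw_score = best$score, bit_score = ev$bit_score,
            evalue = ev$evalue,
            q_start = best$q_start, q_end = best$q_end,
            t_start = best$t_start + best$offset,
            t_end = best$t_end + best$offset,
            q_aln = best$q_aln, t_aln = best$t_aln,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(.empty_hits())
  hits <- do.call(rbind, rows)
  ord <- order(hits$query_id, hits$evalue, -hits$raw_score, hits$transcript_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# coerce queries/transcripts input to a two-column data.frame
.as_seq_table <- function(x, cols) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequence vectors must be named")
    out <- data.frame(a = names(x), b = unname(x), stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  stopifnot(is.data.frame(x))
  if (!all(cols %in% names(x))) {
    # tolerate id/sequence naming for query tables
    alt <- c("id", "sequence")
    if (all(alt %in% names(x))) {
      out <- x[, alt, drop = FALSE]
      names(out) <- cols
      return(out)
    }
    stop("expected columns ", paste(cols, collapse = ", "))
  }
  x[, cols, drop = FALSE]
}

#' Select candidate hits per query
#'
#' Keeps, per query, at most `max_hits_per_query` hits with E-value below
#' `evalue_max` (hits are assumed sorted as produced by [run_search()]).
#' A transcript hit by several queries appears once in the merged candidate
#' list with its best (query, E-value) evidence.
#'
#' @param hits a hit table from [run_search()].
#' @param params a [search_params()].
#' @return A list with `hits` (the retained per-query hits) and `candidates`
#'   (one row per candidate transcript: `transcript_id`, `best_query`,
#'   `frame`, `evalue`, `raw_score`, `t_start`, `t_end` — the best hit's
#'   span in translated-frame residue coordinates, 0-based half-open).
#' @export
select_candidates <- function(hits, params = search_params()) {
  keep <- hits[hits$evalue < params$evalue_max, , drop = FALSE]
  if (nrow(keep) > 0) {
    kept <- lapply(split(keep, keep$query_id), function(h) {
      h[seq_len(min(nrow(h), params$max_hits_per_query)), , drop = FALSE]
    })
    keep <- do.call(rbind, kept)
    ord <- order(keep$query_id, keep$evalue, -keep$raw_score, keep$transcript_id)
    keep <- keep[ord, , drop = FALSE]
    rownames(keep) <- NULL
  }
  if (nrow(keep) == 0) {
    cands <- data.frame(transcript_id = character(0), best_query = character(0),
                        frame = integer(0), evalue = numeric(0),
                        raw_score = numeric(0), t_start = integer(0),
                        t_end = integer(0), stringsAsFactors = FALSE)
    return(list(hits = keep, candidates = cands))
  }
  ord2 <- order(keep$evalue, -keep$raw_score, keep$transcript_id)
  best <- keep[ord2, , drop = FALSE]
  best <- best[!duplicated(best$transcript_id), , drop = FALSE]
  cands <- data.frame(transcript_id = best$transcript_id,
                      best_query = best$query_id, frame = best$frame,
                      evalue = best$evalue, raw_score = best$raw_score,
                      t_start = best$t_start, t_end = best$t_end,
                      stringsAsFactors = FALSE)
  ord3 <- order(cands$evalue, -cands$raw_score, cands$transcript_id)
  cands <- cands[ord3, , drop = FALSE]
  rownames(cands) <- NULL
  list(hits = keep, candidates = cands)
}

#' Write a hit table as TSV
#'
#' A BLAST outfmt-6-like dialect with named columns; all coordinates are
#' converted to 1-based inclusive.
#'
#' @param hits a hit table from [run_search()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits[, c("query_id", "transcript_id", "frame", "raw_score",
                  "bit_score", "evalue", "q_start", "q_end",
                  "t_start", "t_end"), drop = FALSE]
  out$q_start <- out$q_start + 1L
  out$t_start <- out$t_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
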