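#' Excise raw peptide segments from an annotated precursor
#'
#' Cuts the mature region (after the signal peptide) at the cleavage sites
#' and trims each segment's trailing K/R run, recording it as the removed
#' flank (carboxypeptidase trimming removes every exposed C-terminal basic
#' residue). Segments shorter than `min_peptide_len` after trimming are
#' flagged `kept = FALSE` but still returned, so that
#' `signal + sum(segment + flank)` always reconstructs the precursor
#' exactly.
#'
#' @param protein the full precursor protein.
#' @param signal a [predict_signal_peptide()] result (or a list with
#'   `present` and `cleavage_after`).
#' @param sites a cleavage-site data frame from [find_cleavage_sites()],
#'   positioned on the mature region.
#' @param rules a [cleavage_rules()] (supplies `min_peptide_len`).
#' @return A data frame with one row per segment: `peptide` (trimmed),
#'   `flank` (removed basic run, possibly empty), `raw` (peptide + flank),
#'   `start`, `end` (1-based inclusive span of `raw` on the precursor),
#'   `kept`.
#' @examples
#' sig <- list(present = FALSE, cleavage_after = NA)
#' sites <- find_cleavage_sites("SFDSIGNGPIGLKR")
#' excise_peptides("SFDSIGNGPIGLKR", sig, sites)
#' @export
excise_peptides <- function(protein, signal, sites, rules = cleavage_rules()) {
  sig_end <- if (isTRUE(signal$present)) signal$cleavage_after else 0L
  mature <- substr(protein, sig_end + 1L, nchar(protein))
  if (!nzchar(mature)) {
    return(data.frame(peptide = character(0), flank = character(0),
                      raw = character(0), start = integer(0), end = integer(0),
                      kept = logical(0), stringsAsFactors = FALSE))
  }
  pos <- sort(unique(sites$position))
  if (any(duplicated(sites$position))) stop("overlapping cleavage sites")
  bounds <- c(0L, pos, nchar(mature))
  bounds <- unique(bounds[bounds <= nchar(mature)])
  rows <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k] + 1L         # 1-based in mature region
    b <- bounds[k + 1L]
    if (b < a) next
    raw <- substr(mature, a, b)
    flank_m <- regmatches(raw, regexpr("[KR]+$", raw))
    flank <- if (length(flank_m)) flank_m else ""
    peptide <- substr(raw, 1L, nchar(raw) - nchar(flank))
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = peptide, flank = flank, raw = raw,
      start = sig_end + a, end = sig_end + b,
      kept = nchar(peptide) >= rules$min_peptide_len,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- sum(!out$kept)
  if (dropped > 0) {
    message(dropped, " segment(s) shorter than min_peptide_len dropped")
  }
  out
}

#' Apply terminal post-translational modifications to a trimmed segment
#'
#' A segment that ended in Gly followed by a (removed) basic flank is
#' amidated: the Gly is dropped and the amide flag set. A segment starting
#' with Gln (or Glu, when enabled) is flagged as N-terminal pyroglutamate;
#' the sequence is unchanged.
#'
#' @param segment basic-trimmed peptide sequence.
#' @param flank the removed trailing basic run (`""` if none).
#' @param pyroglu_from_E also flag N-terminal Glu as pyroglutamate.
#' @return A list of class `mature_peptide` with `sequence`, `amidated`,
#'   `pyroglutamate`, `flank_removed`, and `pre_amidation_length` (the
#'   trimmed length before the amide Gly loss, the length convention used
#'   for reporting).
#' @examples
#' apply_terminal_ptms("YLERIGSGNELVG", "KR")$amidated  # TRUE
#' @export
apply_terminal_ptms <- function(segment, flank, pyroglu_from_E = FALSE) {
  sequence <- segment
  amidated <- FALSE
  if (nzchar(flank) && nchar(segment) > 0 &&
      substr(segment, nchar(segment), nchar(segment)) == "G") {
    sequence <- substr(segment, 1L, nchar(segment) - 1L)
    amidated <- TRUE
  }
  first <- substr(segment, 1L, 1L)
  pyroglu <- first == "Q" || (pyroglu_from_E && first == "E")
  structure(list(sequence = sequence, amidated = amidated,
                 pyroglutamate = pyroglu, flank_removed = flank,
                 pre_amidation_length = nchar(segment)),
            class = "mature_peptide")
}

#' Predict tyrosine sulfation positions
#'
#' A Tyr is flagged when at least one acidic residue (D or E) occurs within
#' two positions on either side (window clipped at the peptide ends). This
#' is a local sequence-context heuristic for sulfotransferase substrates.
#'
#' @param peptide amino-acid string (pre-amidation coordinates are
#'   conventional for reporting).
#' @return Integer vector of 1-based Tyr positions predicted sulfated.
#' @examples
#' predict_tyr_sulfation("EYE")  # 2
#' @export
predict_tyr_sulfation <- function(peptide) {
  if (!nzchar(peptide)) stop("empty peptide")
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  ys <- which(chars == "Y")
  flagged <- integer(0)
  for (y in ys) {
    win <- max(1L, y - 2L):min(length(chars), y + 2L)
    win <- setdiff(win, y)
    if (any(chars[win] %in% c("D", "E"))) flagged <- c(flagged, y)
  }
  flagged
}

#' Count disulfide bridges and propose a pairing
#'
#' The bridge count is `floor(total Cys / 2)` over all chains; an odd total
#' flags one unpaired Cys. The proposed pairing is a nested first-with-last
#' heuristic over the concatenated Cys list and is reported as low-confidence
#' evidence only; the count is the quantity used downstream.
#'
#' @param chains character vector of peptide sequences.
#' @return A list with `bridge_count`, `unpaired` (0 or 1), and `pairing`
#'   (a data frame of chain/position pairs, 1-based within each chain).
#' @export
predict_disulfides <- function(chains) {
  stopifnot(length(chains) >= 1)
  cys <- list()
  for (ci in seq_along(chains)) {
    pos <- which(strsplit(chains[ci], "", fixed = TRUE)[[1]] == "C")
    for (p in pos) cys[[length(cys) + 1L]] <- c(chain = ci, position = p)
  }
  total <- length(cys)
  bridge_count <- total %/% 2L
  unpaired <- total %% 2L
  pairing <- data.frame(chain1 = integer(0), pos1 = integer(0),
                        chain2 = integer(0), pos2 = integer(0))
  lo <- 1L
  hi <- total
  while (lo < hi) {
    pairing <- rbind(pairing, data.frame(
      chain1 = cys[[lo]][["chain"]], pos1 = cys[[lo]][["position"]],
      chain2 = cys[[hi]][["chain"]], pos2 = cys[[hi]][["position"]]))
    lo <- lo + 1L
    hi <- hi - 1L
  }
  list(bridge_count = bridge_count, unpaired = unpaired, pairing = pairing)
}

#' Detect an insulin-like B-C-A chain architecture
#'
#' Present when a precursor yields exactly three peptide segments where the
#' last (A chain) contains a `CC` doublet and at least three Cys, the first
#' (B chain) contains at least two Cys, and the middle (C chain) contains at
#' most one Cys. The disulfide count is computed over the B and A chains plus
#' any Cys-bearing C chain.
#'
#' @param segments character vector of the precursor's processed peptides in
#'   precursor order.
#' @return `NULL` when the architecture is absent, otherwise a list with
#'   `b_chain`, `c_chain`, `a_chain`, and `disulfide_count`.
#' @export
detect_insulin_architecture <- function(segments) {
  if (length(segments) != 3) return(NULL)
  b <- segments[1]; cc <- segments[2]; a <- segments[3]
  if (!grepl("CC", a, fixed = TRUE)) return(NULL)
  if (count_cysteines(a) < 3) return(NULL)
  if (count_cysteines(b) < 2) return(NULL)
  if (count_cysteines(cc) > 1) return(NULL)
  chains <- c(b, a)
  if (count_cysteines(cc) > 0) chains <- c(b, cc, a)
  list(b_chain = b, c_chain = cc, a_chain = a,
       disulfide_count = predict_disulfides(chains)$bridge_count)
}

#' Derive fully processed mature peptides for one precursor
#'
#' Convenience wrapper chaining [excise_peptides()], [apply_terminal_ptms()]
#' and [predict_tyr_sulfation()] over the kept segments.
#'
#' @param protein precursor protein.
#' @param signal a [predict_signal_peptide()] result.
#' @param sites cleavage sites on the mature region.
#' @param rules a [cleavage_rules()].
#' @param pyroglu_from_E passed to [apply_terminal_ptms()].
#' @return A data frame with one row per kept peptide: `peptide`
#'   (post-amidation sequence), `pre_amidation_length`, `flank`, `start`,
#'   `end`, `amidated`, `pyroglutamate`, `sulfo_positions` (comma-separated
#'   1-based Tyr positions, pre-amidation coordinates).
#' @export
derive_mature_peptides <- function(protein, signal, sites,
                                   rules = cleavage_rules(),
                                   pyroglu_from_E = FALSE) {
  segs <- excise_peptides(protein, signal, sites, rules)
  segs <- segs[segs$kept, , drop = FALSE]
  if (nrow(segs) == 0) {
    return(data.frame(peptide = character(0), pre_amidation_length = integer(0),
                      flank = character(0), start = integer(0),
                      end = integer(0), amidated = logical(0),
                      pyroglutamate = logical(0),
                      sulfo_positions = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(segs)), function(k) {
    mp <- apply_terminal_ptms(segs$peptide[k], segs$flank[k],
                              pyroglu_from_E = pyroglu_from_E)
    sulfo <- predict_tyr_sulfation(segs$peptide[k])
    data.frame(peptide = mp$sequence,
               pre_amidation_length = mp$pre_amidation_length,
               flank = segs$flank[k], start = segs$start[k], end = segs$end[k],
               amidated = mp$amidated, pyroglutamate = mp$pyroglutamate,
               sulfo_positions = paste(sulfo, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
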