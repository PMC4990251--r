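# run expr under a fixed RNG seed without touching the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic precursor
#'
#' A precursor spec describes one synthetic preprohormone: a hydrophobic
#' signal peptide followed by repeated peptide units, each flanked by a
#' basic cleavage run, plus untranslated-region lengths for the transcript.
#'
#' @param family family label carried into the truth table.
#' @param units data frame with columns `sequence`, `copies`, `flank`;
#'   flanks must be one of `KR`, `KK`, `RR`, `KKR` (or `""` for a terminal
#'   unit that is not followed by a cleavage site).
#' @param signal_length total signal peptide length in residues (15-30,
#'   Met included).
#' @param utr5,utr3 untranslated-region lengths in bases.
#' @return A list of class `precursor_spec`.
#' @export
precursor_spec <- function(family, units, signal_length = 22L,
                           utr5 = 50L, utr3 = 100L) {
  stopifnot(is.data.frame(units), nrow(units) >= 1,
            all(c("sequence", "copies", "flank") %in% names(units)),
            all(units$copies >= 1),
            signal_length >= 15, signal_length <= 30)
  ok_flank <- units$flank %in% c("KR", "KK", "RR", "KKR", "")
  if (!all(ok_flank)) {
    stop("invalid flank motif(s): ", paste(unique(units$flank[!ok_flank]),
                                           collapse = ", "))
  }
  structure(list(family = family, units = units,
                 signal_length = as.integer(signal_length),
                 utr5 = as.integer(utr5), utr3 = as.integer(utr3)),
            class = "precursor_spec")
}

#' Build a synthetic precursor protein with its expected peptide list
#'
#' The protein is `M` + a hydrophobic signal core (sampled from L/V/F, so
#' the core itself contains no small residues and the cut point carries the
#' only (-3,-1) motif) ending in `ASA` +
#' the concatenated (unit + flank) blocks. Expected mature peptides are
#' derived by the package's own processing rules with the known signal
#' boundary, so the truth list is self-consistent by construction.
#'
#' @param spec a [precursor_spec()].
#' @param rng_seed integer seed; the same seed always yields the same
#'   protein.
#' @return A list with `protein`, `signal_length`, `peptides` (the
#'   [derive_mature_peptides()] table), and `expected_peptides` (character
#'   vector of processed sequences).
#' @export
build_precursor_protein <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "precursor_spec"))
  core_len <- spec$signal_length - 4L   # M + core + "ASA"
  core <- .with_seed(rng_seed, paste(
    sample(c("L", "V", "F"), core_len, replace = TRUE), collapse = ""))
  signal <- paste0("M", core, "ASA")
  blocks <- unlist(lapply(seq_len(nrow(spec$units)), function(k) {
    rep(paste0(spec$units$sequence[k], spec$units$flank[k]),
        spec$units$copies[k])
  }))
  protein <- paste0(signal, paste(blocks, collapse = ""))
  sig <- list(present = TRUE, cleavage_after = spec$signal_length)
  mature <- substr(protein, spec$signal_length + 1L, nchar(protein))
  sites <- find_cleavage_sites(mature)
  peptides <- derive_mature_peptides(protein, sig, sites)
  list(protein = protein, signal_length = spec$signal_length,
       peptides = peptides, expected_peptides = peptides$peptide)
}

#' Back-translate a protein and embed it in a synthetic transcript
#'
#' Codons are sampled uniformly among synonymous codons of the standard
#' genetic code; the coding sequence starts at `ATG` and ends with a `TAA`
#' stop; uniform-random UTRs of the spec's lengths are attached. Translating
#' the CDS recovers the protein exactly.
#'
#' @param protein amino-acid string starting with Met.
#' @param spec a [precursor_spec()] (supplies UTR lengths).
#' @param rng_seed integer seed.
#' @return A list with `sequence`, `cds_start`, `cds_end` (0-based half-open
#'   nucleotide coordinates of the CDS including the stop codon).
#' @export
back_translate_and_embed <- function(protein, spec, rng_seed) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  .with_seed(rng_seed, {
    codons <- vapply(chars, function(aa) {
      opts <- by_aa[[aa]]
      if (is.null(opts)) stop("cannot back-translate residue ", aa)
      opts[sample.int(length(opts), 1L)]
    }, character(1), USE.NAMES = FALSE)
    cds <- paste0(paste(codons, collapse = ""), "TAA")
    utr5 <- paste(sample(c("A", "C", "G", "T"), spec$utr5, replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(c("A", "C", "G", "T"), spec$utr3, replace = TRUE),
                  collapse = "")
    list(sequence = paste0(utr5, cds, utr3),
         cds_start = spec$utr5,
         cds_end = spec$utr5 + nchar(cds))
  })
}

#' Built-in synthetic precursor templates, one per peptide family
#'
#' Unit sequences are taken from the packaged mature-peptide fixture table
#' (trimmed of their printed flanking basics, which become the unit flanks),
#' so synthetic benchmarks exercise the same sequences as the fixture tests.
#'
#' @return A named list of unit data frames (columns `sequence`, `copies`,
#'   `flank`), keyed by profile family name.
#' @export
family_templates <- function() {
  tab <- read_mature_peptide_table()
  unit_of <- function(precursor, name) {
    s <- tab$sequence[tab$precursor == precursor & tab$peptide_name == name]
    flank <- regmatches(s, regexpr("[KR]+$", s))
    flank <- if (length(flank)) flank else ""
    list(sequence = substr(s, 1, nchar(s) - nchar(flank)), flank = flank)
  }
  fdsig <- lapply(paste0("P", 1:4), function(p) unit_of("BnFDSIG-like", p))
  vp <- unit_of("BnVP-like", "Vasopressin-like")
  nph <- unit_of("BnVP-like", "Neurophysin")
  ghb <- unit_of("BnGHB5", "Mature")
  npf <- unit_of("BnNPFL", "Mature")
  ilp <- lapply(c("ChainB", "ChainC", "ChainA"), function(p) unit_of("BnILP-A", p))
  list(
    pedal_orcokinin_FDSIG = data.frame(
      sequence = vapply(fdsig, `[[`, "", "sequence"),
      copies = 2L,
      flank = vapply(fdsig, `[[`, "", "flank"),
      stringsAsFactors = FALSE),
    NPF = data.frame(sequence = npf$sequence, copies = 1L, flank = npf$flank,
                     stringsAsFactors = FALSE),
    vasopressin = data.frame(
      sequence = c(vp$sequence, nph$sequence), copies = 1L,
      flank = c(vp$flank, nph$flank), stringsAsFactors = FALSE),
    GPB5 = data.frame(sequence = ghb$sequence, copies = 1L, flank = ghb$flank,
                      stringsAsFactors = FALSE),
    insulin_like = data.frame(
      sequence = vapply(ilp, `[[`, "", "sequence"),
      copies = 1L,
      flank = vapply(ilp, `[[`, "", "flank"),
      stringsAsFactors = FALSE))
}

#' Family query peptides for the synthetic benchmark
#'
#' One representative mature peptide per family (the sequences also used as
#' synthetic precursor units).
#'
#' @return Named character vector of query peptides.
#' @export
build_family_queries <- function() {
  tpl <- family_templates()
  c(Q_pedal = tpl$pedal_orcokinin_FDSIG$sequence[1],
    Q_NPF = tpl$NPF$sequence[1],
    Q_vasopressin = tpl$vasopressin$sequence[1],
    Q_GPB5 = tpl$GPB5$sequence[1],
    Q_insulin = tpl$insulin_like$sequence[1])
}

# dinucleotide-preserving shuffle: random Eulerian path on the dinucleotide
# multigraph (random arborescence toward the terminal letter, remaining
# edges shuffled). Falls back to a plain letter shuffle if the walk cannot
# be completed; both preserve length and base composition.
.dinucleotide_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) return(sequence)
  letters_here <- unique(chars)
  root <- chars[n]
  edges <- split(chars[-1], chars[-n])      # out-edge multisets
  # Wilson-style loop-erased random walks build an arborescence toward root
  nxt <- list()
  in_tree <- stats::setNames(rep(FALSE, length(letters_here)), letters_here)
  in_tree[root] <- TRUE
  step <- function(u) {
    opts <- edges[[u]]
    opts[sample.int(length(opts), 1L)]
  }
  for (v in setdiff(names(edges), root)) {
    if (in_tree[[v]]) next
    path <- v
    u <- v
    guard <- 0L
    repeat {
      w <- step(u)
      guard <- guard + 1L
      if (guard > 10000L) return(paste(sample(chars), collapse = ""))
      if (in_tree[[w]]) {
        walk <- c(path, w)
        break
      }
      pos <- match(w, path)
      path <- if (!is.na(pos)) path[seq_len(pos)] else c(path, w)
      u <- w
    }
    for (k in seq_len(length(walk) - 1L)) {
      nxt[[walk[k]]] <- walk[k + 1L]
      in_tree[walk[k]] <- TRUE
    }
  }
  # order each vertex's out edges: random order, designated tree edge last
  pools <- list()
  for (v in names(edges)) {
    pool <- edges[[v]]
    if (v != root && !is.null(nxt[[v]])) {
      drop1 <- match(nxt[[v]], pool)
      rest <- pool[-drop1]
      pools[[v]] <- c(rest[sample.int(length(rest))], nxt[[v]])
    } else {
      pools[[v]] <- pool[sample.int(length(pool))]
    }
  }
  used <- stats::setNames(rep(0L, length(pools)), names(pools))
  out <- character(n)
  out[1] <- chars[1]
  u <- chars[1]
  for (k in 2:n) {
    used[u] <- used[u] + 1L
    w <- pools[[u]][used[[u]]]
    out[k] <- w
    u <- w
  }
  paste(out, collapse = "")
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Precursor transcripts are built from the family templates (cycled when
#' `n_precursors` exceeds the template count) with randomized signal cores,
#' codon choices and UTRs. Decoys are an even split of dinucleotide-shuffled
#' copies of the precursor transcripts (hard decoys preserving local
#' composition) and uniform-random sequences matched in length and GC
#' content to a precursor transcript.
#'
#' @param n_precursors,n_decoys transcript counts.
#' @param seed integer seed controlling all randomness.
#' @return A list with `transcripts` (data frame `id`, `sequence`),
#'   `truth` (data frame: `id`, `is_precursor`, `family`, `protein`,
#'   `signal_length`, `expected_peptides` (semicolon-joined), `cds_start`,
#'   `cds_end` 0-based half-open), and `queries` (from
#'   [build_family_queries()]).
#' @export
generate_dataset <- function(n_precursors, n_decoys, seed) {
  tpl <- family_templates()
  fams <- names(tpl)
  tx_id <- function(i) sprintf("tx%04d", i)
  rows <- list()
  truth <- list()
  if (n_precursors > 0) {
    for (i in seq_len(n_precursors)) {
      fam <- fams[((i - 1L) %% length(fams)) + 1L]
      sub_seed <- seed * 1000L + i
      geom <- .with_seed(sub_seed, c(sample(18:28, 1L), sample(30:80, 1L),
                                     sample(60:150, 1L)))
      spec <- precursor_spec(fam, tpl[[fam]], signal_length = geom[1],
                             utr5 = geom[2], utr3 = geom[3])
      built <- build_precursor_protein(spec, rng_seed = sub_seed + 1L)
      tx <- back_translate_and_embed(built$protein, spec,
                                     rng_seed = sub_seed + 2L)
      rows[[i]] <- data.frame(id = tx_id(i), sequence = tx$sequence,
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        id = tx_id(i), is_precursor = TRUE, family = fam,
        protein = built$protein, signal_length = built$signal_length,
        expected_peptides = paste(built$expected_peptides, collapse = ";"),
        cds_start = tx$cds_start, cds_end = tx$cds_end,
        stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0) {
    n_shuffled <- if (n_precursors > 0) n_decoys %/% 2L else 0L
    for (j in seq_len(n_decoys)) {
      idx <- n_precursors + j
      sub_seed <- seed * 1000L + 500L + j
      src <- if (n_precursors > 0) {
        .with_seed(sub_seed, sample.int(n_precursors, 1L))
      } else 0L
      seq_j <- if (j <= n_shuffled) {
        .with_seed(sub_seed + 1L, .dinucleotide_shuffle(rows[[src]]$sequence))
      } else {
        len <- if (src > 0) nchar(rows[[src]]$sequence) else 600L
        gc <- if (src > 0) {
          s <- rows[[src]]$sequence
          (nchar(gsub("[AT]", "", s))) / nchar(s)
        } else 0.45
        p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
        .with_seed(sub_seed + 1L, paste(
          sample(names(p), len, replace = TRUE, prob = p), collapse = ""))
      }
      rows[[idx]] <- data.frame(id = tx_id(idx), sequence = seq_j,
                                stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(
        id = tx_id(idx), is_precursor = FALSE, family = NA_character_,
        protein = NA_character_, signal_length = NA_integer_,
        expected_peptides = NA_character_, cds_start = NA_integer_,
        cds_end = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  transcripts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), sequence = character(0))
  truth_tab <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0), is_precursor = logical(0))
  list(transcripts = transcripts, truth = truth_tab,
       queries = build_family_queries())
}

#' Write a synthetic dataset to FASTA plus a truth TSV
#'
#' @param dataset a [generate_dataset()] result.
#' @param fasta_path,truth_path output paths.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, fasta_path, truth_path) {
  write_fasta(dataset$transcripts$id, dataset$transcripts$sequence, fasta_path)
  utils::write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Score a pipeline report against a dataset's ground truth
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param truth the `truth` data frame of a [generate_dataset()] result.
#' @return A list with `recall` and `precision` at the candidate level,
#'   `signal_boundary_rate` (exact signal-cut agreement among detected true
#'   precursors; compared in transcript nucleotide coordinates when the
#'   report carries ORF spans, so that an ORF extended through an upstream
#'   in-frame AUG still scores as correct), `peptide_set_rate` (exact
#'   multiset equality of processed peptides among detected true
#'   precursors), and the count fields used.
#' @export
evaluate_recovery <- function(report, truth) {
  detected <- report$precursors$transcript_id
  if (length(detected) > 0 && !all(detected %in% truth$id)) {
    stop("report and truth use different transcript id spaces")
  }
  true_ids <- truth$id[truth$is_precursor]
  tp <- intersect(detected, true_ids)
  recall <- if (length(true_ids) == 0) NA_real_ else length(tp) / length(true_ids)
  precision <- if (length(detected) == 0) NA_real_ else length(tp) / length(detected)
  sig_ok <- 0L
  pep_ok <- 0L
  for (id in tp) {
    trow <- truth[truth$id == id, ]
    prow <- report$precursors[report$precursors$transcript_id == id, ][1, ]
    if (!is.na(prow$signal_cleavage_after)) {
      if (!is.null(prow$orf_nt_start) && !is.null(trow$cds_start) &&
          !is.na(trow$cds_start)) {
        # compare cut positions on the transcript, not within the ORF
        cut_nt <- if (prow$orf_frame > 0) {
          prow$orf_nt_start + 3L * prow$signal_cleavage_after
        } else {
          prow$orf_nt_end - 3L * prow$signal_cleavage_after
        }
        truth_cut <- trow$cds_start + 3L * trow$signal_length
        if (cut_nt == truth_cut) sig_ok <- sig_ok + 1L
      } else if (prow$signal_cleavage_after == trow$signal_length) {
        sig_ok <- sig_ok + 1L
      }
    }
    expected <- sort(strsplit(trow$expected_peptides, ";", fixed = TRUE)[[1]])
    got <- sort(report$peptides$peptide[report$peptides$transcript_id == id])
    if (identical(expected, got)) pep_ok <- pep_ok + 1L
  }
  list(recall = recall, precision = precision,
       signal_boundary_rate = if (length(tp)) sig_ok / length(tp) else NA_real_,
       peptide_set_rate = if (length(tp)) pep_ok / length(tp) else NA_real_,
       n_true = length(true_ids), n_detected = length(detected),
       n_true_detected = length(tp))
}
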