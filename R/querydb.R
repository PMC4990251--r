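#' Construct annotation records
#'
#' An annotation record is one curated known-peptide entry: an accession,
#' a free-text description, and an amino-acid sequence. Record sets drive
#' the keyword filtering that builds the local query peptide database.
#'
#' @param accession character vector of unique identifiers.
#' @param description character vector of free-text descriptions.
#' @param sequence character vector of amino-acid sequences (20 canonical
#'   letters plus `X`; lower case is accepted and upper-cased).
#' @param taxon optional character vector of source taxa.
#' @return A data frame of class `annotation_records` with columns
#'   `accession`, `description`, `sequence`, `taxon`.
#' @examples
#' annotation_records("P01(1)", "vasopressin precursor", "CYIQNCPLG")
#' @export
annotation_records <- function(accession, description, sequence, taxon = NA_character_) {
  stopifnot(length(accession) == length(description),
            length(description) == length(sequence))
  sequence <- toupper(sequence)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    stop("sequence contains non-canonical letters (other than X) in record(s): ",
         paste(accession[bad], collapse = ", "))
  }
  out <- data.frame(accession = as.character(accession),
                    description = as.character(description),
                    sequence = sequence,
                    taxon = rep_len(as.character(taxon), length(accession)),
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_records", class(out))
  out
}

# Default include/exclude terms used to screen invertebrate peptide-hormone
# annotation records into the local query database.
DEFAULT_INCLUDE_TERMS <- c("np", "hormone", "neurohormone")
DEFAULT_EXCLUDE_TERMS <- c("receptor", "receptor associated", "hypothetical",
                           "uncharacterized", "signal", "cytochrome",
                           "esterase", "transferase", "binding protein",
                           "hydrolase", "lipase", "inducible protein",
                           "methyltransferase", "transmembrane")

#' Create a keyword filter
#'
#' Filters are applied to record descriptions by case-insensitive matching.
#' Exclusion always takes precedence over inclusion. Short single-word terms
#' (3 characters or fewer, e.g. `"NP"`) are matched as whole words so that
#' a two-letter term does not fire on accidental substrings; longer terms and
#' multi-word terms are matched as plain substrings (so `"hormone"` still
#' matches `"neurohormones"`).
#'
#' @param include_terms character vector of inclusion terms (non-empty).
#' @param exclude_terms character vector of exclusion terms (may be empty).
#' @return An object of class `keyword_filter` with lowercased terms.
#' @examples
#' keyword_filter()  # the default curation filter
#' @export
keyword_filter <- function(include_terms = DEFAULT_INCLUDE_TERMS,
                           exclude_terms = DEFAULT_EXCLUDE_TERMS) {
  include_terms <- tolower(as.character(include_terms))
  exclude_terms <- tolower(as.character(exclude_terms))
  if (length(include_terms) == 0 || all(!nzchar(include_terms))) {
    stop("keyword_filter requires at least one non-empty include term")
  }
  structure(list(include_terms = include_terms, exclude_terms = exclude_terms),
            class = "keyword_filter")
}

#' @export
print.keyword_filter <- function(x, ...) {
  cat("keyword_filter\n")
  cat("  include:", paste(x$include_terms, collapse = ", "), "\n")
  cat("  exclude:", paste(x$exclude_terms, collapse = ", "), "\n")
  invisible(x)
}

# TRUE where any term matches the description (case-insensitive).
.match_terms <- function(descriptions, terms) {
  descriptions <- tolower(descriptions)
  hit <- rep(FALSE, length(descriptions))
  for (term in terms) {
    if (!nzchar(term)) next
    if (!grepl("\\s", term) && nchar(term) <= 3) {
      # short single-word term: whole-word match
      pat <- paste0("\\b", term, "\\b")
      hit <- hit | grepl(pat, descriptions, perl = TRUE)
    } else {
      hit <- hit | grepl(term, descriptions, fixed = TRUE)
    }
  }
  hit
}

#' Filter annotation records into a query set
#'
#' Keeps exactly the records whose description contains at least one include
#' term and no exclude term. Input order is preserved; duplicate accessions
#' collapse to their first occurrence; records with an empty sequence are
#' skipped with a warning and counted in the result's `n_skipped` attribute.
#'
#' @param records an `annotation_records` data frame (or compatible data frame
#'   with the same columns).
#' @param filter a [keyword_filter()].
#' @return A `query_set`: the filtered `annotation_records` with the filter
#'   attached as attribute `provenance` and the skipped-record count as
#'   attribute `n_skipped`.
#' @examples
#' recs <- annotation_records(
#'   c("A1", "A2"),
#'   c("insulin-like peptide hormone precursor", "vasopressin receptor 2"),
#'   c("MKLV", "MKAV"))
#' filter_annotation_records(recs, keyword_filter())
#' @export
filter_annotation_records <- function(records, filter = keyword_filter()) {
  if (!inherits(filter, "keyword_filter")) stop("filter must be a keyword_filter")
  if (nrow(records) == 0) {
    out <- records
    attr(out, "provenance") <- filter
    attr(out, "n_skipped") <- 0L
    class(out) <- unique(c("query_set", class(out)))
    return(out)
  }
  empty <- !nzchar(records$sequence) | is.na(records$sequence)
  n_skipped <- sum(empty)
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) with empty sequence skipped: ",
            paste(records$accession[empty], collapse = ", "))
    records <- records[!empty, , drop = FALSE]
  }
  inc <- .match_terms(records$description, filter$include_terms)
  exc <- .match_terms(records$description, filter$exclude_terms)
  keep <- inc & !exc
  out <- records[keep, , drop = FALSE]
  out <- out[!duplicated(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- filter
  attr(out, "n_skipped") <- n_skipped
  class(out) <- unique(c("query_set", class(out)))
  out
}

#' Read a keyword filter from a YAML or JSON config file
#'
#' The file must contain keys `include_terms` and (optionally)
#' `exclude_terms`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [keyword_filter()].
#' @export
read_keyword_filter <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$include_terms)) stop("config must define include_terms")
  keyword_filter(include_terms = cfg$include_terms,
                 exclude_terms = cfg$exclude_terms %||% character(0))
}

#' Write a query set as protein FASTA
#'
#' Headers are `accession description`; sequence lines wrap at 60 columns.
#'
#' @param qs a `query_set` or `annotation_records` data frame.
#' @param destination output file path.
#' @return Invisibly, the number of records written.
#' @export
write_query_fasta <- function(qs, destination) {
  n <- nrow(qs)
  if (n == 0) {
    # empty query set -> empty file
    ok <- file.create(destination)
    if (!ok) stop("cannot write to ", destination)
    return(invisible(0L))
  }
  seqs <- Biostrings::AAStringSet(qs$sequence)
  desc <- ifelse(is.na(qs$description) | !nzchar(qs$description),
                 qs$accession, paste(qs$accession, qs$description))
  names(seqs) <- desc
  Biostrings::writeXStringSet(seqs, filepath = destination, width = 60L)
  invisible(n)
}

#' Read a protein FASTA file back as annotation records
#'
#' The inverse of [write_query_fasta()]: the header is split at the first
#' whitespace into accession and description.
#'
#' @param path protein FASTA path.
#' @return An `annotation_records` data frame.
#' @export
read_query_fasta <- function(path) {
  fa <- read_fasta(path, alphabet = "AA")
  annotation_records(fa$id, fa$description, fa$sequence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
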