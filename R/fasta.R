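#' Read a FASTA file
#'
#' Tolerant of wrapped lines and CRLF line endings. The header is parsed as
#' `id` plus `description` at the first whitespace. With `alphabet = "DNA"`
#' any letter outside `A,C,G,T,N` is an error naming the offending record.
#' With `alphabet = "AA"` the canonical amino-acid letters plus `X` and `*`
#' are accepted; a file whose every sequence uses only nucleotide letters
#' (`A,C,G,T,N,U`) is rejected as a probable nucleotide file read with the
#' wrong alphabet.
#'
#' @param path FASTA file path.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("cannot parse FASTA file ", path, ": ",
                                          conditionMessage(e)))
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("[\r \t]", "", as.character(ss)))
  if (alphabet == "DNA") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("illegal nucleotide characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
  } else {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", seqs)
    if (any(bad)) {
      stop("illegal amino-acid characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
    if (all(!grepl("[^ACGTNU]", seqs))) {
      stop("file ", path, " looks like nucleotide sequence but was read ",
           "with the protein alphabet")
    }
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param ids character vector of record ids (descriptions may be appended
#'   after whitespace by the caller).
#' @param sequences character vector of sequences.
#' @param path output path.
#' @param width sequence line wrap width.
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(ids, sequences, path, width = 60L) {
  stopifnot(length(ids) == length(sequences))
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(0L))
  }
  ss <- Biostrings::BStringSet(sequences)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(width))
  invisible(length(ids))
}

#' Read a nucleotide FASTA file as transcripts
#'
#' @param path nucleotide FASTA path.
#' @return A data frame with columns `id`, `description`, `sequence` where
#'   every sequence is over `A,C,G,T,N`.
#' @export
read_transcripts <- function(path) {
  read_fasta(path, alphabet = "DNA")
}
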