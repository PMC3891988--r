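# Sequence input/output and the transcript model used by probe design.
# Sequences are plain upper-case DNA strings over {A,C,G,T,N}; coordinates
# throughout the package are 1-based inclusive on the mRNA-sense strand.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(seqs, allow_n = TRUE, what = "sequence") {
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub(sprintf("[%s]", allowed), "",
                                      seqs[bad][1]), "")))
    stop(what, " contains invalid character(s): ",
         paste(ch, collapse = ", "))
  }
  invisible(seqs)
}

#' Read a FASTA file of DNA (or RNA) sequences
#'
#' Sequences are upper-cased and U is mapped to T, so RNA input is accepted
#' transparently; any residue outside `{A,C,G,T,N}` after that mapping is an
#' error. Record order follows the file.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return data.frame with columns `id` (the full header line without `>`)
#'   and `sequence`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- names(set)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  seqs <- chartr("u", "t", tolower(as.character(set)))
  seqs <- toupper(seqs)
  check_dna(seqs, allow_n = TRUE, what = paste0("record in ", path))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' Lines wrap at 60 columns.
#'
#' @param records data.frame with `id` and `sequence` columns (as returned
#'   by [read_fasta()]), or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Build a transcript table
#'
#' The substrate of probe design: one row per mRNA with its gene identifier
#' and subspecies of origin.
#'
#' @param transcript_id,gene_id character vectors (recycled gene_id allowed).
#' @param sequence DNA strings over `{A,C,G,T,N}`, 5'->3' mRNA sense.
#' @param subspecies one of `"japonica"`, `"indica"`, `"other"`.
#' @return data.frame with class `transcript_set`.
#' @export
transcript_set <- function(transcript_id, gene_id = transcript_id,
                           sequence, subspecies = "japonica") {
  subspecies <- match.arg(subspecies, c("japonica", "indica", "other"))
  if (anyDuplicated(transcript_id)) {
    stop("duplicate transcript_id: ",
         transcript_id[duplicated(transcript_id)][1])
  }
  sequence <- toupper(sequence)
  check_dna(sequence)
  if (any(nchar(sequence) < 1L)) stop("empty sequence")
  out <- data.frame(transcript_id = transcript_id, gene_id = gene_id,
                    subspecies = subspecies, sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' 3'-proximal design window of a transcript
#'
#' Labeled aRNA is 3'-biased, so probes are restricted to the final
#' `window` nucleotides of the transcript. Returns the transcript
#' coordinates (1-based, inclusive) of that terminal window, clamped to the
#' transcript start for short transcripts.
#'
#' @param length_or_transcript transcript length in nt, or a one-row
#'   `transcript_set`.
#' @param window window size in nt (default 1200); must be >= 60.
#' @return integer vector `c(start, end)`.
#' @export
three_prime_window <- function(length_or_transcript, window = 1200L) {
  len <- if (is.data.frame(length_or_transcript)) {
    nchar(length_or_transcript$sequence[1])
  } else {
    as.integer(length_or_transcript)
  }
  if (window < 60L) stop("window must be >= 60 nt")
  if (len < 60L) stop("too short for any probe (length ", len, " < 60)")
  c(start = max(1L, len - as.integer(window) + 1L), end = len)
}
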