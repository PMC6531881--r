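#' Write simulated reads to FASTA plus a truth sidecar
#'
#' One FASTA record per read (the read id already encodes sample
#' metadata) and a tab-separated truth file
#' `read_id<TAB>label<TAB>ref_a<TAB>ref_b<TAB>breakpoint<TAB>inherited_errors`.
#'
#' @param reads A `read_set`.
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional truth TSV path (default: FASTA path with
#'   `.truth.tsv` appended).
#' @return Invisibly, the FASTA path.
#' @export
write_reads_fasta <- function(reads, fasta_path, truth_path = NULL) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, fasta_path)
  if (is.null(truth_path))
    truth_path <- paste0(sub("\\.fa(sta)?$", "", fasta_path), ".truth.tsv")
  truth <- data.frame(
    read_id = reads$read_id,
    label = ifelse(reads$origin == "chimera", "chimera", "source"),
    ref_a = reads$ref_a,
    ref_b = ifelse(is.na(reads$ref_b), ".", reads$ref_b),
    breakpoint = ifelse(is.na(reads$breakpoint), ".",
                        as.character(reads$breakpoint)),
    inherited_errors = reads$pcr_errors + reads$seq_errors)
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}

#' Read simulated reads back from FASTA (+ optional truth sidecar)
#'
#' @param fasta_path FASTA of reads.
#' @param truth_path Optional truth TSV written by [write_reads_fasta()].
#' @param sample_id Sample label to assign (default: prefix of read ids
#'   before `_read`).
#' @return A `read_set` data.frame (provenance columns NA when no truth
#'   sidecar is given).
#' @export
read_reads_fasta <- function(fasta_path, truth_path = NULL,
                             sample_id = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (is.null(sample_id)) sample_id <- sub("_read[0-9]+$", "", ids)
  out <- data.frame(
    read_id = ids, sample = sample_id, sequence = as.character(ss),
    origin = NA_character_, ref_a = NA_character_, ref_b = NA_character_,
    breakpoint = NA_integer_, pcr_errors = NA_integer_,
    seq_errors = NA_integer_, polymerase = NA_character_,
    cycles = NA_integer_, replicate = NA_integer_,
    stringsAsFactors = FALSE)
  if (!is.null(truth_path)) {
    tr <- read.table(truth_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    m <- match(out$read_id, tr$read_id)
    out$origin <- ifelse(tr$label[m] == "chimera", "chimera", "source")
    out$ref_a <- tr$ref_a[m]
    out$ref_b <- ifelse(tr$ref_b[m] == ".", NA_character_, tr$ref_b[m])
    out$breakpoint <- suppressWarnings(as.integer(tr$breakpoint[m]))
    out$pcr_errors <- tr$inherited_errors[m]
    out$seq_errors <- 0L
  }
  class(out) <- c("read_set", "data.frame")
  out
}
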