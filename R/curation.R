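#' Screen reads on ambiguity and length
#'
#' Removes reads containing more than `max_ambiguous` non-A/C/G/T
#' characters or whose length falls outside `length_window`, the
#' screening applied to assembled contigs before any downstream curation.
#' Removal counts are attached as the `"screen_log"` attribute and
#' reported with a message.
#'
#' @param reads A `read_set` data.frame (see [sample_reads()]).
#' @param max_ambiguous Maximum ambiguous base calls tolerated (default 0).
#' @param length_window Two-element numeric `c(min, max)` of retained
#'   lengths (inclusive).
#' @return The filtered `read_set` (a warning-level message, not an error,
#'   if nothing survives).
#' @export
screen_reads <- function(reads, max_ambiguous = 0L,
                         length_window = c(0, Inf)) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  if (length(length_window) != 2L || length_window[1] > length_window[2])
    stop("length_window must be c(min, max) with min <= max")
  n_amb <- nchar(gsub("[ACGT]", "", reads$sequence))
  len <- nchar(reads$sequence)
  drop_amb <- n_amb > max_ambiguous
  drop_len <- !drop_amb & (len < length_window[1] | len > length_window[2])
  keep <- !(drop_amb | drop_len)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- c(input = nrow(reads), ambiguous = sum(drop_amb),
           length = sum(drop_len), retained = sum(keep))
  attr(out, "screen_log") <- log
  message("screen_reads: removed ", sum(drop_amb), " ambiguous and ",
          sum(drop_len), " out-of-window reads; ", sum(keep), " retained")
  if (!nrow(out)) warning("screen_reads: no reads survived screening")
  class(out) <- c("read_set", "data.frame")
  out
}

#' Dereplicate reads into a count table
#'
#' Collapses identical sequences within each sample. The count table
#' (sample, sequence, count) is the currency of all downstream curation
#' and truth assessment; per-sample totals always equal the number of
#' reads that went in.
#'
#' @param reads A `read_set` data.frame with `sample` and `sequence`
#'   columns (or a list of read sets, which is bound first).
#' @return A `count_table` data.frame with columns `sample`, `sequence`,
#'   `count`, ordered by sample, then decreasing count, then sequence.
#' @export
dereplicate <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads)) reads <- bind_read_sets(reads)
  stopifnot(all(c("sample", "sequence") %in% names(reads)))
  if (!nrow(reads)) stop("no reads to dereplicate")
  dt <- as.data.table(reads[, c("sample", "sequence")])
  dt <- dt[, list(count = .N), by = c("sample", "sequence")]
  dt <- dt[order(sample, -count, sequence)]
  setDF(dt)
  class(dt) <- c("count_table", "data.frame")
  dt
}

#' Abundance preclustering (denoising)
#'
#' Merges the counts of sequences that are within `max_diffs` alignment
#' operations (substitutions + indels, package aligner) of a more
#' abundant sequence, per sample. Sequences are visited in decreasing
#' abundance (ties broken lexicographically); each sequence merges into
#' the first already-retained sequence within range, or is retained
#' itself. The retained sequence keeps its own string, counts are
#' conserved exactly, and the fully specified visit order makes the
#' result invariant to input row order.
#'
#' @param table A `count_table` from [dereplicate()].
#' @param max_diffs Maximum alignment operations for a merge (default 2,
#'   the 2-nt denoising rule).
#' @return A `count_table` with merged counts.
#' @export
precluster <- function(table, max_diffs = 2L) {
  stopifnot(is.data.frame(table),
            all(c("sample", "sequence", "count") %in% names(table)))
  if (max_diffs < 0L) stop("max_diffs must be >= 0")
  pieces <- lapply(split(table, table$sample), function(tab) {
    ord <- order(-tab$count, tab$sequence)
    tab <- tab[ord, , drop = FALSE]
    if (max_diffs == 0L || nrow(tab) == 1L) return(tab)
    target <- cpp_precluster_assign(tab$sequence, as.integer(max_diffs))
    cnt <- vapply(split(tab$count, target), sum, numeric(1))
    keep <- sort(unique(target))
    data.frame(sample = tab$sample[keep], sequence = tab$sequence[keep],
               count = as.numeric(cnt[as.character(keep)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample, -out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("count_table", "data.frame")
  out
}

#' Read and write count tables
#'
#' Tab-separated `sample<TAB>sequence<TAB>count` files.
#'
#' @param path File path.
#' @return The reader returns a `count_table` data.frame.
#' @export
read_count_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "sequence", "count") %in% names(df)))
  class(df) <- c("count_table", "data.frame")
  df
}

#' @param table A `count_table` to write.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  write.table(table[, c("sample", "sequence", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
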