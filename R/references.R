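#' Construct a mock community
#'
#' A mock community is the ground truth of every analysis in the package:
#' a set of reference amplicon sequences with rrn operon copy numbers and
#' relative template abundances. When abundances are not supplied they are
#' taken proportional to copy number, which is the "equal genomic DNA
#' abundance" model of commercial mock standards: mixing equal masses of
#' genomic DNA makes each organism's template count proportional to its
#' operon copy number.
#'
#' @param sequences Named character vector of DNA sequences (A/C/G/T only),
#'   or a data.frame with columns `id`, `sequence` and optionally
#'   `organism`, `copy_number`.
#' @param copy_numbers Named integer vector of operon copy numbers
#'   (default 1 for every reference).
#' @param abundances Optional named numeric vector of relative template
#'   proportions; normalized to sum to one. Defaults to copy-number
#'   proportional.
#' @param organisms Optional named character vector of organism names.
#' @return An object of class `mock_community`: a list with `refs` (a
#'   data.frame with columns `id`, `organism`, `sequence`, `copy_number`)
#'   and `abundance` (named numeric summing to 1).
#' @examples
#' cm <- mock_community(c(a = "ACGTACGTAC", b = "TGCATGCATG"),
#'                      copy_numbers = c(a = 6, b = 1))
#' cm$abundance  # 6/7, 1/7
#' @export
mock_community <- function(sequences, copy_numbers = NULL,
                           abundances = NULL, organisms = NULL) {
  if (is.data.frame(sequences)) {
    df <- sequences
    if (!all(c("id", "sequence") %in% names(df)))
      stop("data.frame input needs columns `id` and `sequence`")
    ids <- as.character(df$id)
    seqs <- as.character(df$sequence)
    if (is.null(copy_numbers) && "copy_number" %in% names(df))
      copy_numbers <- stats::setNames(df$copy_number, ids)
    if (is.null(organisms) && "organism" %in% names(df))
      organisms <- stats::setNames(as.character(df$organism), ids)
  } else {
    ids <- names(sequences)
    seqs <- unname(as.character(sequences))
  }
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every reference sequence must be named")
  if (anyDuplicated(ids))
    stop("duplicate reference id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) < 2L)
    stop("a mock community needs at least 2 references")
  bad <- grepl("[^ACGT]", seqs) | nchar(seqs) == 0L
  if (any(bad))
    stop("reference sequence(s) ", paste(ids[bad], collapse = ", "),
         " are empty or contain characters outside A/C/G/T")
  if (is.null(copy_numbers))
    copy_numbers <- stats::setNames(rep(1L, length(ids)), ids)
  missing_cn <- setdiff(ids, names(copy_numbers))
  if (length(missing_cn))
    stop("missing copy number for: ", paste(missing_cn, collapse = ", "))
  cn <- as.numeric(copy_numbers[ids])
  if (anyNA(cn) || any(cn < 1) || any(cn != round(cn)))
    stop("copy numbers must be integers >= 1")
  if (is.null(organisms)) organisms <- stats::setNames(ids, ids)
  org <- as.character(organisms[ids])
  org[is.na(org)] <- ids[is.na(org)]
  if (is.null(abundances)) {
    ab <- cn / sum(cn)
  } else {
    missing_ab <- setdiff(ids, names(abundances))
    if (length(missing_ab))
      stop("missing abundance for: ", paste(missing_ab, collapse = ", "))
    ab <- as.numeric(abundances[ids])
    if (anyNA(ab) || any(ab < 0) || sum(ab) <= 0)
      stop("abundances must be non-negative and not all zero")
    ab <- ab / sum(ab)
  }
  out <- list(
    refs = data.frame(id = ids, organism = org, sequence = seqs,
                      copy_number = as.integer(cn),
                      stringsAsFactors = FALSE),
    abundance = stats::setNames(ab, ids)
  )
  class(out) <- "mock_community"
  out
}

#' @export
print.mock_community <- function(x, ...) {
  cat("Mock community: ", nrow(x$refs), " reference sequences, ",
      length(unique(x$refs$organism)), " organisms\n", sep = "")
  cat("  lengths: ", paste(range(nchar(x$refs$sequence)), collapse = "-"),
      " nt; abundances ",
      paste(sprintf("%s=%.3g", names(x$abundance), x$abundance),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load reference sequences from a FASTA file
#'
#' Reads mock-community reference sequences and attaches copy numbers and
#' (optionally) template abundances. Record descriptions of the form
#' `id organism name` set the organism field.
#'
#' @param path FASTA file of reference sequences.
#' @param copy_numbers Named vector, id -> operon copy number. Every FASTA
#'   record must be covered.
#' @param abundances Optional named vector, id -> relative template
#'   proportion (normalized). When omitted, abundances are proportional to
#'   copy numbers.
#' @return A [mock_community].
#' @export
load_references <- function(path, copy_numbers, abundances = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  orgs <- ifelse(grepl("\\s", full),
                 sub("^\\S+\\s+", "", full), ids)
  if (anyDuplicated(ids))
    stop("duplicate record id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mock_community(stats::setNames(as.character(ss), ids),
                 copy_numbers = copy_numbers, abundances = abundances,
                 organisms = stats::setNames(orgs, ids))
}

#' Generate a synthetic reference community
#'
#' Draws `k` random amplicon-length sequences whose pairwise alignment
#' dissimilarities all exceed `min_pairwise_dissimilarity`, standing in
#' for a defined mock standard when real reference sequences are not
#' needed. Each sequence gets its own random base composition (Dirichlet
#' over A/C/G/T), which spreads pairwise dissimilarities well above what
#' uniform-composition random sequences achieve. Deterministic given
#' `seed`.
#'
#' @param k Number of references (>= 2).
#' @param length Sequence length in nt (>= 50).
#' @param min_pairwise_dissimilarity Required minimum pairwise alignment
#'   dissimilarity, in (0, 1).
#' @param seed Integer seed.
#' @param copy_numbers Optional copy numbers (default all 1).
#' @param max_tries Bounded retries per sequence before giving up.
#' @return A [mock_community] with ids `ref_1 ... ref_k`.
#' @export
generate_synthetic_references <- function(k, length, min_pairwise_dissimilarity,
                                          seed, copy_numbers = NULL,
                                          max_tries = 200L) {
  if (k < 2L) stop("k must be >= 2")
  if (length < 50L) stop("length must be >= 50")
  if (min_pairwise_dissimilarity <= 0 || min_pairwise_dissimilarity >= 1)
    stop("min_pairwise_dissimilarity must be in (0, 1)")
  seqs <- withr::with_seed(seed, {
    acc <- character(0)
    for (i in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        freq <- rgamma(4, shape = 1)
        freq <- freq / sum(freq)
        cand <- paste(sample(c("A", "C", "G", "T"), length,
                             replace = TRUE, prob = freq),
                      collapse = "")
        if (all(vapply(acc, function(s)
          seq_dissimilarity(cand, s) >= min_pairwise_dissimilarity,
          logical(1)))) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not generate reference ", i, " at dissimilarity >= ",
             min_pairwise_dissimilarity, " after ", max_tries, " tries")
      acc <- c(acc, cand)
    }
    acc
  })
  mock_community(stats::setNames(seqs, sprintf("ref_%d", seq_len(k))),
                 copy_numbers = copy_numbers)
}

#' Map references to idealized OTU labels
#'
#' Assigns every reference sequence the OTU label it would fall into if
#' reads carried no errors: single-linkage closure over reference pairs
#' with dissimilarity at or below `threshold`. Labels are stable across
#' calls (components are numbered by their lexicographically smallest
#' member id).
#'
#' @param community A [mock_community].
#' @param threshold Dissimilarity threshold in (0, 1); pairs at or below
#'   it share a label. `threshold = 0` keeps every distinct sequence in
#'   its own OTU.
#' @return Named character vector, reference id -> OTU label.
#' @export
reference_otu_map <- function(community, threshold = 0.03) {
  stopifnot(inherits(community, "mock_community"))
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)")
  ids <- community$refs$id
  seqs <- community$refs$sequence
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- if (seqs[i] == seqs[j]) 0 else seq_dissimilarity(seqs[i], seqs[j])
      if (d <= threshold + 1e-12) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # order components by smallest member id (ids sorted lexicographically)
  lead <- vapply(unique(comp), function(cc) min(sort(ids[comp == cc])),
                 character(1))
  labs <- sprintf("ROTU_%d", order(order(lead)))
  stats::setNames(labs[match(comp, unique(comp))], ids)
}

#' GC content of a sequence
#'
#' Fraction of bases that are guanine or cytosine.
#'
#' @param sequence Non-empty DNA string (vectorized).
#' @return Numeric in \[0, 1\].
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence)) || anyNA(sequence))
    stop("sequence must be non-empty")
  gc <- nchar(gsub("[^GCgc]", "", sequence))
  gc / nchar(sequence)
}

#' Packaged example mock community
#'
#' Loads the 8-organism synthetic community bundled with the package: 9
#' reference sequences of 250 nt where one organism carries two
#' intra-genome variants of its amplicon at a 6:1 operon copy ratio,
#' differing by a single T->G substitution. The structure emulates the
#' composition of commercial 8-member mock standards (operon copy numbers
#' between 4 and 10, equal genomic DNA abundance) without reproducing any
#' vendor sequence; all sequences are synthetic.
#'
#' @return A [mock_community] with references `org1 ... org8`, where
#'   organism 3's variants are `org3_v1` (dominant, T allele, 6 copies)
#'   and `org3_v2` (rare, G allele, 1 copy).
#' @export
example_community <- function() {
  fa <- system.file("extdata", "mock_community_synthetic.fasta",
                    package = "ampsim", mustWork = TRUE)
  tsv <- system.file("extdata", "mock_community_synthetic.tsv",
                     package = "ampsim", mustWork = TRUE)
  meta <- read_community_metadata(tsv)
  load_references(fa, copy_numbers = meta$copy_number,
                  abundances = meta$abundance)
}

#' Read and write community metadata sidecars
#'
#' Tab-separated sidecar with columns `id`, `copy_number`, `abundance`.
#'
#' @param path File path.
#' @return For the reader, a list with named vectors `copy_number` and
#'   `abundance`.
#' @export
read_community_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  list(copy_number = stats::setNames(df$copy_number, df$id),
       abundance = stats::setNames(df$abundance, df$id))
}

#' @param community A [mock_community] to write.
#' @rdname read_community_metadata
#' @export
write_community_metadata <- function(community, path) {
  df <- data.frame(id = community$refs$id,
                   copy_number = community$refs$copy_number,
                   abundance = unname(community$abundance[community$refs$id]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write community references to FASTA
#'
#' @param community A [mock_community].
#' @param path Output FASTA path.
#' @export
write_references_fasta <- function(community, path) {
  ss <- Biostrings::DNAStringSet(community$refs$sequence)
  names(ss) <- paste(community$refs$id, community$refs$organism)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
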