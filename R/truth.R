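#' Build the exhaustive bimera library of a mock community
#'
#' Enumerates every possible single-breakpoint chimera (bimera) between
#' ordered pairs of reference sequences: for each ordered pair (a, b) the
#' two parents are globally aligned and, at every interior alignment
#' column, the ungapped prefix of a is joined to the ungapped suffix of
#' b. Duplicate candidate sequences are collapsed (first emission wins)
#' and candidates identical to any reference are dropped. Breakpoints are
#' reported as the 0-based prefix length in parent-a coordinates
#' (half-open), which is well defined for unequal-length parents.
#'
#' @param community A [mock_community] with >= 2 references.
#' @return A data.frame of class `chimera_library` with columns
#'   `sequence`, `parent_a`, `parent_b`, `breakpoint`.
#' @export
build_chimera_library <- function(community) {
  stopifnot(inherits(community, "mock_community"))
  ids <- community$refs$id
  seqs <- stats::setNames(community$refs$sequence, ids)
  pieces <- list()
  for (ia in seq_along(ids)) {
    for (ib in seq_along(ids)) {
      if (ia == ib) next
      a <- seqs[[ia]]; b <- seqs[[ib]]
      al <- cpp_align_full(a, b)
      acols <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
      bcols <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      ca <- cumsum(acols != "-")
      cb <- cumsum(bcols != "-")
      A <- length(acols)
      if (A < 2L) next
      t <- seq_len(A - 1L)
      cand <- paste0(substring(a, 1L, ca[t]),
                     substring(b, cb[t] + 1L, nchar(b)))
      pieces[[length(pieces) + 1L]] <- data.frame(
        sequence = cand, parent_a = ids[ia], parent_b = ids[ib],
        breakpoint = ca[t], stringsAsFactors = FALSE)
    }
  }
  lib <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(sequence = character(0), parent_a = character(0),
               parent_b = character(0), breakpoint = integer(0))
  lib <- lib[!duplicated(lib$sequence), , drop = FALSE]
  lib <- lib[!(lib$sequence %in% unname(seqs)), , drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("chimera_library", "data.frame")
  lib
}

#' Truth classifier for a mock community
#'
#' Precomputes the bimera library and its k-mer index so that many
#' sequences can be classified efficiently. Classification of a query
#' computes its alignment distance to every reference and the minimum
#' distance to any library chimera; the query is called chimeric when it
#' is at least `margin` bases closer to a chimera than to any single
#' reference. The k-mer index supplies the lossless lower bound
#' `distance >= L1(profiles) / (2k)`, so pruned classification is exactly
#' equal to the exhaustive scan.
#'
#' @param community A [mock_community].
#' @param margin Classification margin in bases (default 3).
#' @param library Optional prebuilt [build_chimera_library()] result.
#' @param kmer k-mer size of the pruning index (default 4).
#' @return An environment of class `truth_classifier`.
#' @export
truth_classifier <- function(community, margin = 3L, library = NULL,
                             kmer = 4L) {
  stopifnot(inherits(community, "mock_community"))
  if (is.null(library)) library <- build_chimera_library(community)
  cl <- new.env(parent = emptyenv())
  ord <- order(community$refs$id)
  cl$ref_ids <- community$refs$id[ord]
  cl$ref_seqs <- community$refs$sequence[ord]
  cl$library <- library
  cl$margin <- as.integer(margin)
  cl$kmer <- as.integer(kmer)
  cl$profiles <- if (nrow(library))
    cpp_kmer_profiles(library$sequence, kmer) else NULL
  cl$cache <- new.env(parent = emptyenv())
  class(cl) <- "truth_classifier"
  cl
}

#' @export
print.truth_classifier <- function(x, ...) {
  cat("Truth classifier: ", length(x$ref_ids), " references, ",
      nrow(x$library), " library chimeras, margin ", x$margin, "\n",
      sep = "")
  invisible(x)
}

classify_one <- function(query, cl) {
  hit <- cl$cache[[query]]
  if (!is.null(hit)) return(hit)
  stats <- lapply(cl$ref_seqs, function(r) cpp_align_stats(query, r))
  dists <- vapply(stats, function(s)
    unname(s["subs"] + s["ins"] + s["dels"]), numeric(1))
  best <- which.min(dists)  # ref ids sorted, so ties pick smallest id
  best_ref_distance <- as.integer(dists[best])
  best_chim <- NA_integer_
  chim_parents <- c(NA_character_, NA_character_)
  if (!is.null(cl$profiles) && nrow(cl$library)) {
    qp <- as.vector(cpp_kmer_profiles(query, cl$kmer))
    l1 <- colSums(abs(cl$profiles - qp))
    bound <- l1 / (2 * cl$kmer)
    ord <- order(bound)
    res <- cpp_best_distance(query, cl$library$sequence[ord], bound[ord])
    if (res$index > 0L) {
      best_chim <- as.integer(res$distance)
      li <- ord[res$index]
      chim_parents <- c(cl$library$parent_a[li], cl$library$parent_b[li])
    }
  }
  is_chim <- !is.na(best_chim) &&
    (best_ref_distance - best_chim >= cl$margin)
  s <- stats[[best]]
  out <- list(
    is_chimeric = is_chim,
    best_ref = cl$ref_ids[best],
    best_ref_distance = best_ref_distance,
    best_chimera_distance = best_chim,
    chimera_parent_a = chim_parents[1],
    chimera_parent_b = chim_parents[2],
    substitutions = if (is_chim) NA_integer_ else unname(s["subs"]),
    insertions = if (is_chim) NA_integer_ else unname(s["ins"]),
    deletions = if (is_chim) NA_integer_ else unname(s["dels"])
  )
  assign(query, out, envir = cl$cache)
  out
}

#' Classify a sequence against the mock-community truth
#'
#' @param query DNA string to classify.
#' @param community A [mock_community] (ignored when `classifier` given).
#' @param library Optional prebuilt library.
#' @param margin Bases-closer-to-a-chimera threshold (default 3).
#' @param classifier Optional [truth_classifier()]; building one up front
#'   is much faster when classifying many sequences.
#' @return A list (`truth_label`): `is_chimeric`, `best_ref`,
#'   `best_ref_distance`, `best_chimera_distance` (NA when the library is
#'   empty), `chimera_parent_a/b`, and (non-chimeric only)
#'   `substitutions`, `insertions`, `deletions` relative to the best
#'   reference (ties resolved to the lexicographically smallest id).
#' @export
classify_sequence <- function(query, community = NULL, library = NULL,
                              margin = 3L, classifier = NULL) {
  check_dna(query, "query")
  if (is.null(classifier)) {
    if (is.null(community))
      stop("supply either `community` or a prebuilt `classifier`")
    classifier <- truth_classifier(community, margin = margin,
                                   library = library)
  }
  classify_one(query, classifier)
}

#' Classify every unique sequence of a count table
#'
#' @param table A `count_table` (or character vector of sequences).
#' @param classifier A [truth_classifier()].
#' @return A data.frame with one row per unique sequence: `sequence`,
#'   `is_chimeric`, `best_ref`, `best_ref_distance`,
#'   `best_chimera_distance`, `substitutions`, `insertions`, `deletions`.
#' @export
classify_table <- function(table, classifier) {
  stopifnot(inherits(classifier, "truth_classifier"))
  seqs <- if (is.character(table)) unique(table) else unique(table$sequence)
  rows <- lapply(seqs, classify_one, cl = classifier)
  data.frame(
    sequence = seqs,
    is_chimeric = vapply(rows, `[[`, logical(1), "is_chimeric"),
    best_ref = vapply(rows, `[[`, character(1), "best_ref"),
    best_ref_distance = vapply(rows, `[[`, integer(1), "best_ref_distance"),
    best_chimera_distance = vapply(rows, `[[`, integer(1),
                                   "best_chimera_distance"),
    substitutions = vapply(rows, `[[`, integer(1), "substitutions"),
    insertions = vapply(rows, `[[`, integer(1), "insertions"),
    deletions = vapply(rows, `[[`, integer(1), "deletions"),
    stringsAsFactors = FALSE
  )
}

#' Reference-based error rate, excluding chimeras
#'
#' For each sample, classifies every unique sequence, excludes those
#' called chimeric by the margin screen, and reports the count-weighted
#' error rate: total substitutions + insertions + deletions relative to
#' each sequence's best reference, divided by total bases. This is the
#' mock-community error-rate estimator of amplicon curation pipelines:
#' the measured rate conflates polymerase and sequencer errors, which is
#' also true of the quantity it estimates.
#'
#' @param table A `count_table`.
#' @param community A [mock_community] (ignored when `classifier` given).
#' @param library Optional prebuilt chimera library.
#' @param margin Chimera margin (default 3).
#' @param classifier Optional prebuilt [truth_classifier()].
#' @return A data.frame with one row per sample: `sample`, `n_reads`
#'   (non-chimeric), `n_chimeric_excluded`, `substitutions`, `insertions`,
#'   `deletions`, `total_bases`, `error_rate`. When every sequence of a
#'   sample is chimeric, `total_bases` is 0 and `error_rate` NA, with a
#'   warning.
#' @export
error_rate <- function(table, community = NULL, library = NULL, margin = 3L,
                       classifier = NULL) {
  stopifnot(is.data.frame(table),
            all(c("sample", "sequence", "count") %in% names(table)))
  if (!nrow(table)) stop("empty count table")
  if (is.null(classifier))
    classifier <- truth_classifier(community, margin = margin,
                                   library = library)
  lab <- classify_table(table, classifier)
  m <- match(table$sequence, lab$sequence)
  tab <- cbind(table, lab[m, c("is_chimeric", "substitutions", "insertions",
                               "deletions")])
  tab$bases <- nchar(tab$sequence)
  pieces <- lapply(split(tab, tab$sample), function(d) {
    chim <- d$is_chimeric
    keep <- d[!chim, , drop = FALSE]
    subs <- sum(keep$count * keep$substitutions)
    ins <- sum(keep$count * keep$insertions)
    dels <- sum(keep$count * keep$deletions)
    total <- sum(keep$count * keep$bases)
    data.frame(
      sample = d$sample[1],
      n_reads = sum(keep$count),
      n_chimeric_excluded = sum(d$count[chim]),
      substitutions = subs, insertions = ins, deletions = dels,
      total_bases = total,
      error_rate = if (total > 0) (subs + ins + dels) / total else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (anyNA(out$error_rate))
    warning("all sequences chimeric in sample(s): ",
            paste(out$sample[is.na(out$error_rate)], collapse = ", "))
  out
}

#' Truth chimera rate of a count table
#'
#' Count-weighted fraction of sequences classified chimeric by the
#' margin screen, per sample.
#'
#' @inheritParams error_rate
#' @return A data.frame with columns `sample`, `n_reads`, `n_chimeric`,
#'   `chimera_rate`.
#' @export
truth_chimera_rate <- function(table, community = NULL, library = NULL,
                               margin = 3L, classifier = NULL) {
  if (is.null(classifier))
    classifier <- truth_classifier(community, margin = margin,
                                   library = library)
  lab <- classify_table(table, classifier)
  chim <- lab$is_chimeric[match(table$sequence, lab$sequence)]
  pieces <- lapply(split(data.frame(count = table$count, chim = chim),
                         table$sample), function(d)
    c(n = sum(d$count), nc = sum(d$count[d$chim])))
  out <- do.call(rbind, pieces)
  data.frame(sample = rownames(out), n_reads = out[, "n"],
             n_chimeric = out[, "nc"],
             chimera_rate = out[, "nc"] / out[, "n"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dominant-to-rare variant ratio
#'
#' Ratio of reads whose best reference is the dominant intra-genome
#' variant to reads whose best reference is the rare variant, computed on
#' non-preclustered counts with chimeric sequences excluded. With
#' unbiased amplification of templates mixed 6:1 the expected ratio is
#' near 6.
#'
#' @param table A dereplicated, non-preclustered `count_table` (all
#'   samples pooled).
#' @param dominant,rare Reference ids of the two variants.
#' @param community A [mock_community] containing both.
#' @param classifier Optional prebuilt [truth_classifier()].
#' @return The ratio (finite when the rare variant was observed;
#'   otherwise NA with a warning).
#' @export
variant_ratio <- function(table, dominant, rare, community = NULL,
                          classifier = NULL) {
  if (identical(dominant, rare)) stop("dominant and rare must differ")
  if (is.null(classifier)) {
    stopifnot(all(c(dominant, rare) %in% community$refs$id))
    classifier <- truth_classifier(community)
  }
  lab <- classify_table(table, classifier)
  m <- match(table$sequence, lab$sequence)
  ok <- !lab$is_chimeric[m]
  best <- lab$best_ref[m]
  n_dom <- sum(table$count[ok & best == dominant])
  n_rare <- sum(table$count[ok & best == rare])
  if (n_rare == 0) {
    warning("no reads assigned to rare variant ", rare,
            "; ratio undefined")
    return(NA_real_)
  }
  n_dom / n_rare
}

#' Chimera overlap across conditions
#'
#' Quantifies how reproducible chimera formation is across conditions
#' (e.g. polymerases): the fraction of distinct chimeric sequences shared
#' by all conditions, and per condition, the (optionally
#' abundance-weighted) fraction of its chimeras that belong to the shared
#' intersection.
#'
#' @param flag_sets Named list (condition -> character vector of chimeric
#'   sequences); at least two non-empty sets.
#' @param abundances Optional named list (condition -> named numeric of
#'   per-sequence chimera counts) for abundance weighting.
#' @return A list with `shared_fraction` (|intersection| / |union|) and
#'   `per_condition_fraction` (named numeric).
#' @export
chimera_overlap <- function(flag_sets, abundances = NULL) {
  if (length(flag_sets) < 2L) stop("need >= 2 condition sets")
  sets <- lapply(flag_sets, unique)
  if (any(!lengths(sets))) stop("every condition set must be non-empty")
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  if (!length(uni)) stop("empty union")
  per <- vapply(names(sets), function(cn) {
    s <- sets[[cn]]
    if (!is.null(abundances)) {
      ab <- abundances[[cn]]
      sum(ab[intersect(names(ab), inter)]) / sum(ab)
    } else {
      length(intersect(s, inter)) / length(s)
    }
  }, numeric(1))
  list(shared_fraction = length(inter) / length(uni),
       per_condition_fraction = per)
}

#' Write a truth report TSV
#'
#' `sample<TAB>sequence<TAB>count<TAB>label<TAB>best_ref<TAB>subs<TAB>ins<TAB>dels`
#'
#' @param table A `count_table`.
#' @param classifier A [truth_classifier()].
#' @param path Output path.
#' @export
write_truth_report <- function(table, classifier, path) {
  lab <- classify_table(table, classifier)
  m <- match(table$sequence, lab$sequence)
  out <- data.frame(
    sample = table$sample, sequence = table$sequence, count = table$count,
    label = ifelse(lab$is_chimeric[m], "chimera", "source"),
    best_ref = lab$best_ref[m], subs = lab$substitutions[m],
    ins = lab$insertions[m], dels = lab$deletions[m])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
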