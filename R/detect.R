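#' De novo chimera detection (UCHIME-style)
#'
#' A deterministic, abundance-informed de novo detector modeled on the
#' UCHIME screening step of amplicon pipelines. It is a documented
#' stand-in, not a reimplementation: real-world detectors are treated as
#' black boxes with imperfect sensitivity, and this one exists so that
#' sensitivity and specificity can be measured against truth labels.
#'
#' Per sample, unique sequences are processed in decreasing abundance
#' (ties lexicographic). Candidate parents of a query are the previously
#' accepted (non-flagged) sequences whose abundance is at least
#' `min_parent_fold` times the query's. For every ordered parent pair the
#' best single-breakpoint bimera model is found from the three-sequence
#' alignment (query aligned to each parent, positions compared in query
#' coordinates): the score rewards query positions that match one parent
#' but not the other on each side of the breakpoint and penalizes
#' positions matching neither parent. A query is flagged when the best
#' score reaches `score_threshold` and the chimeric model explains the
#' query with at least 2 fewer differences than the best single parent.
#' Flagged sequences never become parents. Because processing order is
#' fully specified, permuting input rows never changes the output.
#'
#' When many sequences qualify as parents, only the `max_parents`
#' candidates with the most similar k-mer profiles to the query are
#' aligned (a deterministic prescreen in the spirit of UCHIME's k-mer
#' candidate selection); ties break on abundance, then sequence.
#'
#' @param table A dereplicated (optionally preclustered) `count_table`.
#' @param min_parent_fold Minimum parent:query abundance ratio (default 2).
#' @param score_threshold Minimum score to flag (default 2).
#' @param max_parents Candidate parents examined per query (default 20).
#' @return A data.frame of class `chimera_calls`: `sample`, `sequence`,
#'   `count`, `flagged`, `score`, `parent_a`, `parent_b` (parents are NA
#'   unless flagged).
#' @export
detect_chimeras <- function(table, min_parent_fold = 2, score_threshold = 2,
                            max_parents = 20L) {
  stopifnot(is.data.frame(table),
            all(c("sample", "sequence", "count") %in% names(table)))
  pieces <- lapply(split(table, table$sample), function(tab) {
    ord <- order(-tab$count, tab$sequence)
    tab <- tab[ord, , drop = FALSE]
    n <- nrow(tab)
    flagged <- logical(n)
    score <- numeric(n)
    pa <- rep(NA_character_, n)
    pb <- rep(NA_character_, n)
    accepted <- integer(0)
    prof <- cpp_kmer_profiles(tab$sequence, 4L)
    for (i in seq_len(n)) {
      q <- tab$sequence[i]
      parents <- accepted[tab$count[accepted] >= min_parent_fold * tab$count[i]]
      if (length(parents) > max_parents) {
        l1 <- colSums(abs(prof[, parents, drop = FALSE] - prof[, i]))
        parents <- parents[order(l1, -tab$count[parents],
                                 tab$sequence[parents])[seq_len(max_parents)]]
        parents <- sort(parents)
      }
      if (length(parents) >= 2L) {
        L <- nchar(q)
        # m: query positions matched by each candidate parent (L x p)
        m <- vapply(parents, function(p)
          query_match_vector(q, tab$sequence[p]), logical(L))
        C <- apply(m, 2, cumsum)
        cL <- C[L, ]
        best_single_diffs <- L - max(cL)
        # for the (x prefix, y suffix) model with breakpoint t:
        #   score_t = (Cx[t] - Cy[t]) + CyL - bothL - neither
        #   diffs_t = L - CyL - (Cx[t] - Cy[t])
        # so one breakpoint maximizes score and minimizes diffs at once
        bothL <- crossprod(m)          # shared matched positions per pair
        p <- length(parents)
        Ct <- C[seq_len(L - 1L), , drop = FALSE]
        best <- list(score = -Inf, diffs = Inf, a = NA, b = NA)
        for (x in seq_len(p)) {
          gap <- Ct[, x] - Ct
          g <- apply(gap, 2, max)      # best prefix advantage per suffix y
          neither <- L - cL[x] - cL + bothL[x, ]
          sc <- g + cL - bothL[x, ] - neither
          diffs <- L - cL - g
          sc[x] <- -Inf
          cand <- which(sc == max(sc))
          cand <- cand[diffs[cand] == min(diffs[cand])]
          y <- cand[order(tab$sequence[parents[cand]])[1]]
          better <- sc[y] > best$score ||
            (sc[y] == best$score && diffs[y] < best$diffs) ||
            (sc[y] == best$score && diffs[y] == best$diffs &&
               !is.na(best$a) &&
               paste(tab$sequence[parents[x]], tab$sequence[parents[y]]) <
                 paste(best$a, best$b))
          if (better)
            best <- list(score = sc[y], diffs = diffs[y],
                         a = tab$sequence[parents[x]],
                         b = tab$sequence[parents[y]])
        }
        if (is.finite(best$score)) score[i] <- max(best$score, 0)
        if (is.finite(best$score) && best$score >= score_threshold &&
            (best_single_diffs - best$diffs) >= 2) {
          flagged[i] <- TRUE
          pa[i] <- best$a
          pb[i] <- best$b
        }
      }
      if (!flagged[i]) accepted <- c(accepted, i)
    }
    data.frame(sample = tab$sample, sequence = tab$sequence,
               count = tab$count, flagged = flagged, score = score,
               parent_a = pa, parent_b = pb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("chimera_calls", "data.frame")
  out
}

# logical vector over query positions: TRUE where the query base is
# aligned to an identical parent base (indel positions count as mismatch)
query_match_vector <- function(query, parent) {
  as.logical(cpp_query_match(query, parent))
}

#' Evaluate a chimera detector against truth labels
#'
#' Sensitivity is the fraction of true chimeras flagged; specificity the
#' fraction of non-chimeric sequences left unflagged. Confusion counts
#' are over unique sequences, or count-weighted with
#' `weighting = "abundance"`.
#'
#' @param calls `chimera_calls` from [detect_chimeras()].
#' @param truth A data.frame mapping `sequence` to `is_chimeric` (e.g.
#'   from [classify_table()]), or a named logical vector.
#' @param weighting `"unique"` or `"abundance"`.
#' @return A list of class `sens_spec`: `sensitivity`, `specificity`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_detector <- function(calls, truth, weighting = c("unique",
                                                          "abundance")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(truth))
    truth <- stats::setNames(truth$is_chimeric, truth$sequence)
  miss <- setdiff(unique(calls$sequence), names(truth))
  if (length(miss))
    stop("missing truth label for sequence(s): ",
         paste(substr(miss, 1, 30), collapse = ", "))
  is_chim <- as.logical(truth[calls$sequence])
  w <- if (weighting == "abundance") calls$count else rep(1, nrow(calls))
  tp <- sum(w[calls$flagged & is_chim])
  fp <- sum(w[calls$flagged & !is_chim])
  fn <- sum(w[!calls$flagged & is_chim])
  tn <- sum(w[!calls$flagged & !is_chim])
  out <- list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn)
  class(out) <- "sens_spec"
  out
}

#' @export
print.sens_spec <- function(x, ...) {
  cat(sprintf(
    "Detector evaluation: sensitivity %.3f, specificity %.3f (tp %s fp %s tn %s fn %s)\n",
    x$sensitivity, x$specificity, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Write chimera calls TSV
#'
#' `sample<TAB>sequence<TAB>flagged<TAB>score<TAB>parent_a<TAB>parent_b`
#'
#' @param calls `chimera_calls`.
#' @param path Output path.
#' @export
write_chimera_calls <- function(calls, path) {
  write.table(calls[, c("sample", "sequence", "flagged", "score",
                        "parent_a", "parent_b")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
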