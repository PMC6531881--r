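# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive global alignment score: enumerates every alignment of a and
# b as a move sequence (diagonal / gap-in-b / gap-in-a) and scores it
# with match +1, mismatch -1, and gap runs costing 2 + (len - 1).
# Returns the maximum score. Only usable for short sequences.
oracle_best_score <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last_move, gap_open) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) 1 else -1
      rec(i + 1, j + 1, score + s, "M", FALSE)
    }
    if (i <= length(av)) {
      cost <- if (identical(last_move, "X")) 1 else 2
      rec(i + 1, j, score - cost, "X", TRUE)
    }
    if (j <= length(bv)) {
      cost <- if (identical(last_move, "Y")) 1 else 2
      rec(i, j + 1, score - cost, "Y", TRUE)
    }
    invisible()
  }
  rec(1, 1, 0, "", FALSE)
  best
}

# Plain unit-cost Levenshtein distance by full DP (no banding); a lower
# bound on any alignment's operation count.
oracle_lev <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j] + (av[i] != bv[j]),
                           d[i, j + 1] + 1, d[i + 1, j] + 1)
  d[n + 1, m + 1]
}

# Brute-force truth classification: same margin rule, but scanning every
# reference and every library candidate with plain alignments (no k-mer
# index, no pruning, no early stop).
brute_classify <- function(query, community, library, margin = 3) {
  ids <- sort(community$refs$id)
  seqs <- community$refs$sequence[match(ids, community$refs$id)]
  ref_d <- vapply(seqs, function(r) {
    s <- ampsim:::cpp_align_stats(query, r)
    unname(s["subs"] + s["ins"] + s["dels"])
  }, numeric(1))
  best_ref <- which.min(ref_d)
  chim_d <- if (nrow(library)) min(vapply(library$sequence, function(c2) {
    s <- ampsim:::cpp_align_stats(query, c2)
    unname(s["subs"] + s["ins"] + s["dels"])
  }, numeric(1))) else NA_real_
  list(is_chimeric = !is.na(chim_d) && ref_d[best_ref] - chim_d >= margin,
       best_ref = ids[best_ref],
       best_ref_distance = as.integer(ref_d[best_ref]),
       best_chimera_distance = if (is.na(chim_d)) NA_integer_ else
         as.integer(chim_d))
}

# Community of two references identical except a single T -> G change,
# mixed at `ratio`:1 template abundance (dominant:rare).
variant_pair_community <- function(length = 250, ratio = 6, seed = 1) {
  base <- generate_synthetic_references(2, length, 0.05, seed = seed)
  dom <- base$refs$sequence[1]
  tpos <- which(strsplit(dom, "")[[1]] == "T")
  if (!length(tpos)) stop("no T in generated sequence")
  pos <- tpos[ceiling(length(tpos) / 2)]
  rare <- dom
  substr(rare, pos, pos) <- "G"
  mock_community(c(dom = dom, rare = rare),
                 copy_numbers = c(dom = ratio, rare = 1))
}

# Small well-separated community for simulation-heavy tests.
small_community <- function(k = 4, len = 120, seed = 2) {
  generate_synthetic_references(k, len, 0.10, seed = seed)
}

# Perfect single-breakpoint bimera of two sequences of equal length,
# joined at position `p` (prefix from a).
perfect_bimera <- function(a, b, p) {
  paste0(substr(a, 1, p), substr(b, p + 1, nchar(b)))
}
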