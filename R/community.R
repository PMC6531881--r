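#' Cluster sequences into OTUs (abundance-greedy, radius-based)
#'
#' Sequences are visited in decreasing total (across-sample) abundance,
#' ties broken lexicographically. Each sequence joins the first existing
#' OTU whose founding representative is within `threshold` dissimilarity
#' (package aligner; `(mismatches + indel columns) / alignment length`),
#' else founds a new OTU with itself as representative. Counts are
#' conserved exactly. This greedy radius clustering is a fully specified,
#' order-independent substitute for optimizing OTU assignment algorithms;
#' the community-level quantities studied here concern trends across PCR
#' conditions, not clustering internals.
#'
#' @param table A `count_table`.
#' @param threshold Dissimilarity radius (default 0.03, i.e. 3%).
#' @return A list of class `otu_table`: `counts` (integer matrix, samples
#'   x OTUs) and `reps` (named character: OTU label -> representative
#'   sequence). OTU labels are `OTU_0001, ...` in founding order.
#' @export
cluster_otus <- function(table, threshold = 0.03) {
  stopifnot(is.data.frame(table),
            all(c("sample", "sequence", "count") %in% names(table)))
  if (!nrow(table)) stop("empty count table")
  tot <- tapply(table$count, table$sequence, sum)
  seqs <- names(sort(tot, decreasing = TRUE))
  # stable tie-break: decreasing abundance then lexicographic
  seqs <- seqs[order(-tot[seqs], seqs)]
  otu_of <- cpp_cluster_assign(seqs, threshold)
  names(otu_of) <- seqs
  labs <- sprintf("OTU_%04d", seq_len(max(otu_of)))
  samples <- sort(unique(table$sample))
  counts <- matrix(0L, nrow = length(samples), ncol = max(otu_of),
                   dimnames = list(samples, labs))
  oi <- otu_of[table$sequence]
  si <- match(table$sample, samples)
  for (k in seq_len(nrow(table)))
    counts[si[k], oi[k]] <- counts[si[k], oi[k]] + as.integer(table$count[k])
  reps <- stats::setNames(seqs[match(seq_len(max(otu_of)), otu_of)], labs)
  structure(list(counts = counts, reps = reps), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " OTUs; totals ", paste(range(rowSums(x$counts)), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "otu_table")) x$counts else as.matrix(x)
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts to `depth` reads without replacement.
#' Samples below the requested depth are dropped with a warning listing
#' them (a common, documented practice when depths are uneven).
#'
#' @param table An `otu_table` or counts matrix (samples x OTUs).
#' @param depth Target reads per sample (default: smallest sample total).
#' @param seed Integer seed; subsampling is deterministic given it.
#' @return An `otu_table` (or matrix, matching the input) with row sums
#'   equal to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  counts <- as_counts(table)
  tot <- rowSums(counts)
  if (is.null(depth)) depth <- min(tot)
  low <- tot < depth
  if (any(low)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[low], collapse = ", "))
    counts <- counts[!low, , drop = FALSE]
  }
  if (!nrow(counts)) stop("no samples at or above the rarefaction depth")
  rar <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    # advisory heuristic about count magnitudes; irrelevant for
    # simulated integer count matrices
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  if (inherits(table, "otu_table")) {
    keep <- colSums(rar) > 0
    structure(list(counts = rar[, keep, drop = FALSE],
                   reps = table$reps[colnames(rar)[keep]]),
              class = "otu_table")
  } else rar
}

#' Alpha diversity metrics of one sample
#'
#' @param row Non-negative integer count vector with positive sum.
#' @return A list: `sobs` (observed richness), `shannon` (natural-log
#'   Shannon index) and `goods_coverage` (1 - singletons / total reads).
#' @examples
#' alpha_metrics(rep(10, 8))$shannon  # log(8)
#' @export
alpha_metrics <- function(row) {
  row <- as.numeric(row)
  if (any(row < 0) || sum(row) <= 0)
    stop("counts must be non-negative with positive sum")
  p <- row[row > 0] / sum(row)
  list(sobs = sum(row > 0),
       shannon = -sum(p * log(p)),
       goods_coverage = 1 - sum(row == 1) / sum(row))
}

#' Alpha diversity for every sample of an OTU table
#'
#' @param table An `otu_table` or counts matrix.
#' @return A data.frame: `sample`, `sobs`, `shannon`, `goods_coverage`.
#' @export
alpha_diversity <- function(table) {
  counts <- as_counts(table)
  rows <- apply(counts, 1, alpha_metrics)
  data.frame(sample = rownames(counts),
             sobs = vapply(rows, `[[`, numeric(1), "sobs"),
             shannon = vapply(rows, `[[`, numeric(1), "shannon"),
             goods_coverage = vapply(rows, `[[`, numeric(1),
                                     "goods_coverage"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis distance matrix
#'
#' `d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)`; samples should be
#' rarefied to even depth first (a warning is raised when totals differ).
#'
#' @param table An `otu_table` or counts matrix with >= 2 samples.
#' @return A symmetric matrix with zero diagonal and entries in \[0, 1\],
#'   labeled by sample.
#' @export
bray_curtis <- function(table) {
  counts <- as_counts(table)
  if (nrow(counts) < 2L) stop("need >= 2 samples")
  if (any(rowSums(counts) == 0)) stop("zero-sum sample row")
  if (length(unique(rowSums(counts))) > 1L)
    warning("sample totals differ; consider rarefying first")
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Principal coordinates analysis
#'
#' Classical scaling of a distance matrix (double-centered -d^2/2). Axes
#' are ordered by eigenvalue; negative eigenvalues are reported rather
#' than dropped; each axis's sign is fixed so its largest-magnitude
#' loading is positive, making ordinations reproducible.
#'
#' @param dist A symmetric distance matrix.
#' @param k Number of axes to return (default 2; reduced with a warning
#'   when fewer positive axes exist).
#' @return A list: `points` (samples x axes), `eig` (all eigenvalues),
#'   `rel_eig` (eigenvalues / sum of positive eigenvalues).
#' @export
pcoa_ord <- function(dist, k = 2L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  kk <- min(k, n - 1L)
  if (kk < k) warning("only ", kk, " axes available; k reduced")
  sc <- suppressWarnings(cmdscale(stats::as.dist(d), k = kk, eig = TRUE))
  pts <- sc$points
  npos <- ncol(pts)
  if (npos < kk)
    warning("only ", npos, " axes with positive eigenvalues returned")
  for (a in seq_len(ncol(pts))) {
    j <- which.max(abs(pts[, a]))
    if (pts[j, a] < 0) pts[, a] <- -pts[, a]
  }
  colnames(pts) <- sprintf("PCo%d", seq_len(ncol(pts)))
  list(points = pts, eig = sc$eig,
       rel_eig = sc$eig / sum(sc$eig[sc$eig > 0]))
}

#' PERMANOVA (sequential sums of squares on a distance matrix)
#'
#' Permutational multivariate analysis of variance: the Gower-centered
#' inner-product matrix of the distances is partitioned sequentially
#' (Type I) over the factors in the order given, reporting per-factor R2,
#' pseudo-F, and permutation p-values from free permutation of sample
#' labels. `p = (1 + #{permuted F >= observed}) / (1 + permutations)`, so
#' p is never exactly zero. Factor order matters under sequential sums of
#' squares and is chosen by the caller.
#'
#' @param dist Symmetric distance matrix with sample labels.
#' @param factors A data.frame (rows = samples, in `dist` label order or
#'   with matching rownames); each column one factor with >= 2 levels.
#' @param permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A data.frame of class `permanova`: one row per factor plus
#'   `Residual` and `Total`, with columns `term`, `df`, `SS`, `R2`,
#'   `pseudo_F`, `p_value`, and the permutation count as attribute
#'   `"permutations"`. Factor and residual R2 sum to 1.
#' @export
permanova <- function(dist, factors, permutations = 999L, seed = 1L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  factors <- as.data.frame(factors)
  if (!is.null(rownames(d)) && !is.null(rownames(factors)) &&
      all(rownames(d) %in% rownames(factors)))
    factors <- factors[rownames(d), , drop = FALSE]
  if (nrow(factors) != n) stop("factors must have one row per sample")
  for (f in names(factors)) {
    factors[[f]] <- factor(factors[[f]])
    if (nlevels(factors[[f]]) < 2L)
      stop("factor `", f, "` has a single level")
    if (anyNA(factors[[f]])) stop("factor `", f, "` has missing levels")
  }
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ss_total <- sum(diag(G))

  terms <- names(factors)
  X <- matrix(1, n, 1)
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L
  for (ti in seq_along(terms)) {
    X <- cbind(X, stats::model.matrix(~ 0 + factors[[ti]]))
    qq <- qr(X)
    hats[[ti]] <- tcrossprod(qr.Q(qq)[, seq_len(qq$rank), drop = FALSE])
    dfs[ti] <- qq$rank - prev_rank
    prev_rank <- qq$rank
  }
  df_res <- n - prev_rank

  trace_terms <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    ss <- diff(c(0, tr))
    res <- sum(diag(Gm)) - tr[length(tr)]
    list(ss = ss, res = res)
  }
  obs <- trace_terms(G)
  F_obs <- (obs$ss / dfs) / (obs$res / df_res)

  exceed <- numeric(length(terms))
  withr::with_seed(seed, {
    for (b in seq_len(permutations)) {
      p <- sample.int(n)
      Gp <- G[p, p]
      pr <- trace_terms(Gp)
      Fp <- (pr$ss / dfs) / (pr$res / df_res)
      exceed <- exceed + (Fp >= F_obs - 1e-12)
    }
  })
  pval <- (1 + exceed) / (1 + permutations)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(obs$ss, obs$res, ss_total),
    R2 = c(obs$ss, obs$res, ss_total) / ss_total,
    pseudo_F = c(F_obs, NA, NA),
    p_value = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "permutations") <- as.integer(permutations)
  class(out) <- c("permanova", "data.frame")
  out
}

#' Three-stage artifact attribution
#'
#' Attributes community-level distortion to its sources by rebuilding the
#' OTU table at three curation stages: (1) `no_errors_no_chimeras` -
#' chimera-tagged reads are dropped and each remaining read is mapped to
#' the OTU its source reference would fall into with no sequencing
#' errors (via [reference_otu_map()]), isolating pure amplification
#' bias/drift; (2) `residual_errors_complete_removal` - observed
#' sequences are dereplicated, preclustered, truth-screened for chimeras
#' (margin classifier) and clustered de novo, adding residual errors but
#' with perfect chimera removal; (3) `residual_errors_detector_removal` -
#' as stage 2 but chimeras are removed with [detect_chimeras()], the
#' realistic pipeline. Alpha metrics are computed per stage on tables
#' rarefied to a common depth.
#'
#' @param readsets A list of truth-tagged `read_set`s (or one bound
#'   `read_set`).
#' @param community The [mock_community] the simulation used.
#' @param threshold OTU dissimilarity threshold (default 0.03).
#' @param max_diffs Precluster radius (default 2).
#' @param margin Truth chimera margin (default 3).
#' @param min_parent_fold,score_threshold Detector settings.
#' @param depth Rarefaction depth (default: smallest sample total across
#'   stages).
#' @param seed Seed for rarefaction.
#' @return A list: `summary` (data.frame stage/sample/sobs/shannon/
#'   goods_coverage), `tables` (per-stage rarefied `otu_table`s), and
#'   `depth`.
#' @export
attribution_pipeline <- function(readsets, community, threshold = 0.03,
                                 max_diffs = 2L, margin = 3L,
                                 min_parent_fold = 2, score_threshold = 2,
                                 depth = NULL, seed = 1L) {
  reads <- if (is.data.frame(readsets)) readsets else bind_read_sets(readsets)
  if (!all(c("origin", "ref_a") %in% names(reads)) ||
      anyNA(reads$origin))
    stop("readsets lack truth provenance tags; stages 1-2 unavailable")
  rmap <- reference_otu_map(community, threshold)

  # stage 1: drop tagged chimeras, map reads to idealized reference OTUs
  src <- reads[reads$origin != "chimera", , drop = FALSE]
  s1_tab <- table(src$sample, rmap[src$ref_a])
  s1 <- matrix(as.integer(s1_tab), nrow = nrow(s1_tab),
               dimnames = dimnames(s1_tab))

  # stages 2-3 share dereplication + preclustering
  ct <- precluster(dereplicate(reads), max_diffs = max_diffs)
  cl <- truth_classifier(community, margin = margin)
  lab <- classify_table(ct, cl)
  chim <- lab$is_chimeric[match(ct$sequence, lab$sequence)]
  s2 <- cluster_otus(ct[!chim, , drop = FALSE], threshold)

  calls <- detect_chimeras(ct, min_parent_fold = min_parent_fold,
                           score_threshold = score_threshold)
  key <- paste(ct$sample, ct$sequence)
  flag <- calls$flagged[match(key, paste(calls$sample, calls$sequence))]
  s3 <- cluster_otus(ct[!flag, , drop = FALSE], threshold)

  tables <- list(no_errors_no_chimeras = s1,
                 residual_errors_complete_removal = s2,
                 residual_errors_detector_removal = s3)
  if (is.null(depth))
    depth <- min(vapply(tables, function(t) min(rowSums(as_counts(t))),
                        numeric(1)))
  rar <- lapply(seq_along(tables), function(i)
    rarefy(tables[[i]], depth = depth, seed = derive_seed(seed, i)))
  names(rar) <- names(tables)
  summary <- do.call(rbind, lapply(names(rar), function(st) {
    a <- alpha_diversity(rar[[st]])
    cbind(stage = st, a, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, tables = rar, depth = depth)
}

#' Intercycle community distance
#'
#' Mean Bray-Curtis distance between every baseline-cycle replicate and
#' every replicate at each other cycle count, per polymerase: the
#' community-level footprint of additional amplification rounds.
#'
#' @param counts An `otu_table` or counts matrix (rows = samples).
#' @param meta Data.frame with columns `sample`, `polymerase`, `cycles`,
#'   `replicate` (one row per counts row).
#' @param baseline_cycles Reference cycle count (default 25).
#' @return A data.frame: `polymerase`, `cycles`, `mean_distance`.
#'   Conditions with no baseline or target samples are simply absent.
#' @export
intercycle_distance <- function(counts, meta, baseline_cycles = 25L) {
  m <- as_counts(counts)
  stopifnot(nrow(m) == nrow(meta))
  rows <- list()
  for (pol in unique(meta$polymerase)) {
    base <- which(meta$polymerase == pol & meta$cycles == baseline_cycles)
    if (!length(base)) next
    for (cyc in setdiff(sort(unique(meta$cycles[meta$polymerase == pol])),
                        baseline_cycles)) {
      tgt <- which(meta$polymerase == pol & meta$cycles == cyc)
      if (!length(tgt)) next
      d <- bc_pairs(m, base, tgt)
      rows[[length(rows) + 1L]] <- data.frame(
        polymerase = pol, cycles = cyc, mean_distance = mean(d),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

bc_pairs <- function(m, idx_a, idx_b) {
  out <- numeric(0)
  for (i in idx_a) for (j in idx_b) {
    if (i == j) next
    x <- m[i, ]; y <- m[j, ]
    out <- c(out, sum(abs(x - y)) / sum(x + y))
  }
  out
}

#' Replicate drift
#'
#' Mean pairwise Bray-Curtis distance among technical replicates of each
#' (polymerase, cycles) condition: stochastic run-to-run drift of PCR.
#'
#' @inheritParams intercycle_distance
#' @return A data.frame: `polymerase`, `cycles`, `n_replicates`,
#'   `mean_distance`. Conditions with fewer than 2 replicates are skipped
#'   with a warning.
#' @export
replicate_drift <- function(counts, meta) {
  m <- as_counts(counts)
  stopifnot(nrow(m) == nrow(meta))
  conds <- unique(meta[, c("polymerase", "cycles")])
  rows <- list()
  skipped <- character(0)
  for (k in seq_len(nrow(conds))) {
    idx <- which(meta$polymerase == conds$polymerase[k] &
                   meta$cycles == conds$cycles[k])
    if (length(idx) < 2L) {
      skipped <- c(skipped, paste(conds$polymerase[k], conds$cycles[k]))
      next
    }
    pr <- utils::combn(idx, 2)
    d <- vapply(seq_len(ncol(pr)), function(c2) {
      x <- m[pr[1, c2], ]; y <- m[pr[2, c2], ]
      sum(abs(x - y)) / sum(x + y)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      polymerase = conds$polymerase[k], cycles = conds$cycles[k],
      n_replicates = length(idx), mean_distance = mean(d),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("condition(s) with < 2 replicates skipped: ",
            paste(skipped, collapse = "; "))
  do.call(rbind, rows)
}

#' Write a shared-style OTU table / distance matrix
#'
#' The OTU table is written rows = samples, columns = OTU labels; the
#' distance matrix as a square tab-delimited file with header labels.
#'
#' @param table An `otu_table`.
#' @param path Output path.
#' @export
write_otu_table <- function(table, path) {
  counts <- as_counts(table)
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param dist A labeled square distance matrix.
#' @rdname write_otu_table
#' @export
write_distance_matrix <- function(dist, path) {
  d <- as.matrix(dist)
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
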