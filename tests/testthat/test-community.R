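test_that("OTU clustering respects the radius and conserves counts", {
  cm <- generate_synthetic_references(8, 250, 0.10, seed = 1)
  tab <- data.frame(sample = "s1", sequence = cm$refs$sequence,
                    count = 8:1, stringsAsFactors = FALSE)
  ot <- cluster_otus(tab, 0.03)
  expect_equal(ncol(ot$counts), 8)
  expect_equal(sum(ot$counts), sum(tab$count))

  # satellites one substitution away join the abundant founder
  a <- cm$refs$sequence[1]
  sat <- vapply(c(10, 60, 200), function(p) {
    s <- a
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
    s
  }, character(1))
  tab2 <- data.frame(sample = "s1", sequence = c(a, sat),
                     count = c(50, 3, 2, 1))
  ot2 <- cluster_otus(tab2, 0.03)
  expect_equal(ncol(ot2$counts), 1)
  expect_equal(unname(ot2$reps), a)
  expect_equal(sum(ot2$counts), 56)

  # threshold 0: one OTU per unique sequence
  expect_equal(ncol(cluster_otus(tab2, 0)$counts), 4)

  # OTU count is non-increasing in threshold
  n_at <- vapply(c(0, 0.01, 0.05, 0.2, 0.6),
                 function(t) ncol(cluster_otus(tab, t)$counts), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("rarefaction evens depths and drops shallow samples", {
  counts <- rbind(s1 = c(1000, 1000), s2 = c(300, 700), s3 = c(30, 20))
  expect_warning(r <- rarefy(counts, depth = 100, seed = 4), "s3")
  expect_equal(unname(rowSums(r)), c(100, 100))
  expect_identical(r, suppressWarnings(rarefy(counts, depth = 100,
                                              seed = 4)))
  # hypergeometric expectation at 50:50
  draws <- vapply(1:20, function(s)
    rarefy(counts[1, , drop = FALSE], 100, seed = s)[1], numeric(1))
  se <- sqrt(100 * 0.5 * 0.5) / sqrt(20)
  expect_lt(abs(mean(draws) - 50), 3 * se)
  # full-depth rarefaction is the identity
  expect_equal(unname(rarefy(counts[1, , drop = FALSE], 2000, seed = 1)),
               unname(counts[1, , drop = FALSE]))
})

test_that("alpha metrics match closed forms", {
  eq8 <- alpha_metrics(rep(10, 8))
  expect_equal(eq8$sobs, 8)
  expect_equal(eq8$shannon, log(8))
  expect_equal(eq8$goods_coverage, 1)

  single <- alpha_metrics(c(0, 7, 0))
  expect_equal(single$sobs, 1)
  expect_equal(single$shannon, 0)
  expect_equal(single$goods_coverage, 1)

  mix <- alpha_metrics(c(5, 3, 2))
  expect_equal(mix$shannon,
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)))
  expect_equal(alpha_metrics(c(1, 1, 8))$goods_coverage, 0.8)
  expect_error(alpha_metrics(c(0, 0)), "positive sum")
})

test_that("Bray-Curtis matches its closed form", {
  m <- rbind(a = c(1, 1), b = c(0, 2), c = c(1, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  disj <- rbind(x = c(5, 0), y = c(0, 5))
  expect_equal(bray_curtis(disj)["x", "y"], 1)
  expect_error(bray_curtis(rbind(c(1, 1))), "samples")
  expect_error(bray_curtis(rbind(a = c(1, 1), b = c(0, 0))), "zero-sum")
})

test_that("PCoA recovers geometry and reports negative eigenvalues", {
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa_ord(d3, k = 2)
  expect_equal(p3$eig[1], p3$eig[2], tolerance = 1e-9)
  expect_gt(p3$eig[1], 0)

  # points on a line round-trip their pairwise distances on one axis
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pl <- pcoa_ord(dl, k = 2)
  expect_gt(pl$eig[1], 1e-8)
  expect_lt(abs(pl$eig[2]), 1e-8)
  rec <- as.matrix(dist(pl$points[, 1]))
  expect_equal(unname(rec), unname(dl), tolerance = 1e-8)

  # duplicated sample lands on identical coordinates
  dd <- as.matrix(dist(c(0, 0, 2, 5)))
  dimnames(dd) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pd <- pcoa_ord(dd, k = 2)
  expect_lt(max(abs(pd$points[1, ] - pd$points[2, ])), 1e-6)
})

test_that("permanova matches vegan::adonis2 and detects separation", {
  set.seed(7)
  counts <- matrix(rpois(12 * 6, 20), nrow = 12,
                   dimnames = list(sprintf("s%02d", 1:12), NULL))
  counts[1:6, 1] <- counts[1:6, 1] + 60
  meta <- data.frame(grp = rep(c("a", "b"), each = 6),
                     batch = rep(c("x", "y"), 6),
                     row.names = rownames(counts))
  d <- suppressWarnings(bray_curtis(counts))
  pm <- permanova(d, meta, permutations = 299, seed = 3)
  ad <- vegan::adonis2(stats::as.dist(d) ~ grp + batch, data = meta,
                       permutations = 299, by = "terms")
  expect_equal(pm$R2[1:2], ad$R2[1:2], tolerance = 1e-10)
  expect_equal(pm$pseudo_F[1:2], ad$F[1:2], tolerance = 1e-10)
  expect_equal(sum(pm$R2[1:3]), 1)
  expect_lte(pm$p_value[1], 0.02)

  # strongly separated groups: R2 near 1, p at the permutation floor
  sep <- rbind(matrix(rep(c(100, 0, 10), each = 4), nrow = 4),
               matrix(rep(c(0, 100, 10), each = 4), nrow = 4))
  rownames(sep) <- paste0("t", 1:8)
  dsep <- suppressWarnings(bray_curtis(sep + matrix(rpois(24, 2),
                                                    nrow = 8)))
  pm2 <- permanova(dsep, data.frame(g = rep(c("a", "b"), each = 4),
                                    row.names = rownames(sep)),
                   permutations = 199, seed = 5)
  expect_gt(pm2$R2[1], 0.8)
  expect_gte(pm2$p_value[1], 1 / 200)

  # label invariance: permuting sample order leaves R2 unchanged
  perm <- sample(12)
  pm3 <- permanova(d[perm, perm], meta[rownames(d)[perm], , drop = FALSE],
                   permutations = 49, seed = 9)
  expect_equal(pm3$R2[1:2], pm$R2[1:2], tolerance = 1e-10)

  expect_error(permanova(d, data.frame(g = rep("a", 12),
                                       row.names = rownames(d))),
               "single level")
})

test_that("permanova p-values are calibrated under the null", {
  # 200 null data sets: type-I error at alpha = 0.05 within binomial 3 SE
  n <- 12
  rejections <- withr::with_seed(202, {
    vapply(1:200, function(b) {
      counts <- matrix(rpois(n * 8, 15), nrow = n)
      rownames(counts) <- paste0("s", 1:n)
      d <- suppressWarnings(bray_curtis(counts))
      meta <- data.frame(g = rep(c("a", "b"), each = n / 2),
                         row.names = rownames(counts))
      permanova(d, meta, permutations = 99,
                seed = 1000 + b)$p_value[1] <= 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("attribution stages collapse without artifacts and order with them", {
  cm <- small_community(k = 4, len = 120, seed = 2)
  prof0 <- pcr_profile("ideal", 0, 0, 0, efficiency = 1)
  sets <- lapply(1:2, function(r)
    sample_reads(simulate_pcr(cm, prof0, 20, 200, seed = r, pool_cap = 1e5),
                 500, 0, seed = 40 + r, replicate = r))
  out <- attribution_pipeline(sets, cm, seed = 1)
  expect_equal(sort(unique(out$summary$stage)),
               sort(c("no_errors_no_chimeras",
                      "residual_errors_complete_removal",
                      "residual_errors_detector_removal")))
  expect_true(all(out$summary$sobs == 4))

  # single-cycle chimeras (pure bimeras) but no errors: stages 1-2 sit at
  # reference richness, the detector stage can only add OTUs
  profc <- pcr_profile("chim", 0, 0, 0.15, efficiency = 1)
  setsc <- lapply(1:2, function(r)
    sample_reads(simulate_pcr(cm, profc, 1, 2000, seed = 10 + r,
                              pool_cap = 1e5),
                 500, 0, seed = 60 + r, replicate = r))
  outc <- attribution_pipeline(setsc, cm, seed = 1)
  sm <- outc$summary
  s1 <- sm$sobs[sm$stage == "no_errors_no_chimeras"]
  s2 <- sm$sobs[sm$stage == "residual_errors_complete_removal"]
  s3 <- sm$sobs[sm$stage == "residual_errors_detector_removal"]
  expect_true(all(s1 == 4))
  expect_true(all(s2 == 4))
  expect_true(all(s3 >= s2))

  # untagged reads cannot drive stage 1
  bad <- bind_read_sets(sets)
  bad$origin <- NA_character_
  expect_error(attribution_pipeline(bad, cm), "provenance")
})

test_that("intercycle distances and replicate drift behave on known inputs", {
  counts <- rbind(a25_1 = c(50, 50), a25_2 = c(50, 50),
                  a30_1 = c(50, 50), a35_1 = c(50, 50))
  meta <- data.frame(sample = rownames(counts), polymerase = "A",
                     cycles = c(25, 25, 30, 35), replicate = c(1, 2, 1, 1))
  ic <- intercycle_distance(counts, meta, baseline_cycles = 25)
  expect_equal(ic$mean_distance, c(0, 0))

  drift <- replicate_drift(counts[1:2, ], meta[1:2, ])
  expect_equal(drift$mean_distance, 0)
  expect_warning(replicate_drift(counts, meta), "skipped")

  # four replicates: mean over the six pairs
  m4 <- rbind(r1 = c(10, 0), r2 = c(0, 10), r3 = c(10, 0), r4 = c(0, 10))
  meta4 <- data.frame(sample = rownames(m4), polymerase = "A",
                      cycles = 30, replicate = 1:4)
  d4 <- replicate_drift(m4, meta4)
  expect_equal(d4$n_replicates, 4)
  expect_equal(d4$mean_distance, 4 / 6)  # four disjoint pairs of six
})

test_that("OTU table and distance matrix writers round-trip via read.table", {
  cm <- small_community(k = 3, len = 80, seed = 6)
  tab <- data.frame(sample = rep(c("s1", "s2"), each = 3),
                    sequence = rep(cm$refs$sequence, 2),
                    count = c(5, 3, 2, 4, 4, 2))
  ot <- cluster_otus(tab, 0.03)
  f <- tempfile(); write_otu_table(ot, f)
  back <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(unname(as.matrix(back[, -1])), unname(ot$counts))
  f2 <- tempfile(); write_distance_matrix(bray_curtis(ot), f2)
  b2 <- read.table(f2, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(b2$sample, rownames(ot$counts))
})
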