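test_that("bimera library enumeration matches the count formula", {
  # ungapped pair: k(k-1)(L-1) candidates before deduplication
  cm <- small_community(k = 2, len = 60, seed = 6)
  a <- cm$refs$sequence[1]; b <- cm$refs$sequence[2]
  al <- align(a, b)
  lib <- build_chimera_library(cm)
  if (al$insertions + al$deletions == 0) {
    expect_lte(nrow(lib), 2 * 59)
  }
  expect_true(all(lib$parent_a != lib$parent_b))
  expect_false(any(lib$sequence %in% cm$refs$sequence))
  expect_false(any(duplicated(lib$sequence)))

  cm8 <- generate_synthetic_references(8, 250, 0.10, seed = 1)
  lib8 <- build_chimera_library(cm8)
  expect_lte(nrow(lib8), 8 * 7 * 249)
  expect_gt(nrow(lib8), 1000)
})

test_that("one-base-different parents leave only breakpoint-spanning bimeras", {
  # 10-mers differing at position 5: every join switching before/after
  # position 5 equals a parent; only ordered joins across it survive --
  # and those equal the parents too, so the library is empty
  a <- "ACGTACGTAC"
  b <- a; substr(b, 5, 5) <- "G"
  cm <- mock_community(c(a = a, b = b))
  lib <- build_chimera_library(cm)
  # enumerate by hand: prefix(a, p) + suffix(b, p+1) is b for p < 5 and
  # a for p >= 5 (and symmetrically), so nothing survives dedup rules
  hand <- unique(unlist(lapply(1:9, function(p)
    c(perfect_bimera(a, b, p), perfect_bimera(b, a, p)))))
  expect_true(all(hand %in% c(a, b)))
  expect_equal(nrow(lib), 0)
})

test_that("margin classification matches hand-constructed cases", {
  cm <- generate_synthetic_references(2, 100, 0.10, seed = 4)
  a <- cm$refs$sequence[1]; b <- cm$refs$sequence[2]
  cl <- truth_classifier(cm)

  exact <- classify_sequence(a, classifier = cl)
  expect_false(exact$is_chimeric)
  expect_equal(exact$best_ref_distance, 0)
  expect_equal(exact$best_ref, "ref_1")

  lib <- build_chimera_library(cm)
  mid <- lib$sequence[which.min(abs(lib$breakpoint - 50))]
  lab <- classify_sequence(mid, classifier = cl)
  expect_true(lab$is_chimeric)
  expect_equal(lab$best_chimera_distance, 0)
  expect_gte(lab$best_ref_distance, 3)

  one_sub <- a; substr(one_sub, 50, 50) <-
    setdiff(c("A", "C", "G", "T"), substr(a, 50, 50))[1]
  lab2 <- classify_sequence(one_sub, classifier = cl)
  expect_false(lab2$is_chimeric)
  expect_equal(lab2$substitutions, 1)
})

test_that("pruned classification equals the exhaustive brute-force scan", {
  # small references so the exhaustive scan is affordable
  for (seed in c(3, 9)) {
    cm <- generate_synthetic_references(3, 60, 0.10, seed = seed)
    lib <- build_chimera_library(cm)
    cl <- truth_classifier(cm, library = lib)
    set.seed(seed)
    queries <- c(
      cm$refs$sequence,
      perfect_bimera(cm$refs$sequence[1], cm$refs$sequence[2], 30),
      perfect_bimera(cm$refs$sequence[3], cm$refs$sequence[1], 15),
      # mutated references and mutated bimeras
      as.character(ampsim:::cpp_mutate(
        rep(cm$refs$sequence, 2), rep(2L, 6), rep(1L, 6), rep(0L, 6))),
      as.character(ampsim:::cpp_mutate(
        perfect_bimera(cm$refs$sequence[2], cm$refs$sequence[3], 40),
        3L, 0L, 1L)))
    for (q in queries) {
      got <- classify_sequence(q, classifier = cl)
      want <- brute_classify(q, cm, lib, margin = 3)
      expect_equal(got$is_chimeric, want$is_chimeric, info = q)
      expect_equal(got$best_ref_distance, want$best_ref_distance, info = q)
      expect_equal(got$best_chimera_distance, want$best_chimera_distance,
                   info = q)
      expect_equal(got$best_ref, want$best_ref, info = q)
    }
  }
})

test_that("simulated error-free cross-reference bimeras are in the library", {
  cm <- small_community(k = 4, len = 120, seed = 2)
  lib <- build_chimera_library(cm)
  prof <- pcr_profile("chimeric", 0, 0, 0.5, efficiency = 1)
  # one cycle: every chimera joins two pure reference molecules
  pool <- simulate_pcr(cm, prof, cycles = 1, initial_molecules = 2000,
                       seed = 11)
  ch <- pool$molecules[pool$molecules$origin == "chimera", ]
  expect_gt(nrow(ch), 50)
  expect_true(all(ch$sequence %in% c(lib$sequence, cm$refs$sequence)))
})

test_that("well-separated simulated chimeras are classified chimeric", {
  cm <- small_community(k = 4, len = 120, seed = 2)
  cl <- truth_classifier(cm)
  a <- cm$refs$sequence[1]; b <- cm$refs$sequence[2]
  # margin-respecting breakpoints away from the ends
  for (p in c(30, 60, 90)) {
    lab <- classify_sequence(perfect_bimera(a, b, p), classifier = cl)
    expect_true(lab$is_chimeric, info = paste("breakpoint", p))
  }
})

test_that("error rate follows its arithmetic definition and exclusion rules", {
  cm <- generate_synthetic_references(2, 250, 0.10, seed = 4)
  a <- cm$refs$sequence[1]
  two_subs <- a
  for (p in c(10, 20)) substr(two_subs, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  tab <- data.frame(sample = "s1", sequence = c(a, two_subs),
                    count = c(3, 1), stringsAsFactors = FALSE)
  er <- error_rate(tab, community = cm)
  expect_equal(er$error_rate, 2 / 1000)
  expect_equal(er$n_reads, 4)
  expect_equal(er$n_chimeric_excluded, 0)

  # error-free table has rate exactly 0
  tab0 <- data.frame(sample = "s1", sequence = cm$refs$sequence,
                     count = c(5, 5))
  expect_equal(error_rate(tab0, community = cm)$error_rate, 0)

  # chimeric sequences are excluded from both numerator and denominator
  bim <- perfect_bimera(cm$refs$sequence[1], cm$refs$sequence[2], 125)
  tab2 <- rbind(tab, data.frame(sample = "s1", sequence = bim, count = 7))
  er2 <- error_rate(tab2, community = cm)
  expect_equal(er2$n_chimeric_excluded, 7)
  expect_equal(er2$error_rate, 2 / 1000)

  # invariant to duplicating every count by a constant factor
  tab3 <- tab2; tab3$count <- tab3$count * 13
  expect_equal(error_rate(tab3, community = cm)$error_rate, er2$error_rate)
})

test_that("truth-tag expectation recovers the measured error rate", {
  # chimera-free deep sample: alignment-measured errors vs the brute-force
  # average of per-read truth tags (PCR ops + sequencing subs)
  cm <- generate_synthetic_references(4, 150, 0.10, seed = 2)
  cl <- truth_classifier(cm)
  prof <- pcr_profile("measured", 3e-4, 3e-5, 0, efficiency = 0.95)
  pool <- simulate_pcr(cm, prof, cycles = 20, initial_molecules = 500,
                       seed = 77, pool_cap = 1e5)
  rs <- sample_reads(pool, 5000, seq_sub_rate = 2e-4, seed = 78)
  expected <- sum(rs$pcr_errors + rs$seq_errors) / sum(nchar(rs$sequence))
  measured <- error_rate(dereplicate(rs), classifier = cl)$error_rate
  expect_gt(measured, 0)
  expect_lt(abs(measured / expected - 1), 0.2)
})

test_that("variant ratio recovers the template mixing ratio", {
  vp <- variant_pair_community(length = 250, ratio = 6, seed = 1)
  prof <- pcr_profile("clean", 0, 0, 0, efficiency = 1)
  cl <- truth_classifier(vp)
  ratios <- vapply(1:6, function(s) {
    pool <- simulate_pcr(vp, prof, cycles = 10, initial_molecules = 3000,
                         seed = 300 + s, pool_cap = 1e6)
    rs <- sample_reads(pool, 7000, seq_sub_rate = 0, seed = 400 + s)
    variant_ratio(dereplicate(rs), "dom", "rare", classifier = cl)
  }, numeric(1))
  # binomial sampling SE of the ratio at depth 7000, p = 6/7
  p <- 6 / 7
  se_ratio <- sqrt(p * (1 - p) / 7000) / (1 - p)^2 / sqrt(6)
  expect_lt(abs(mean(ratios) - 6), 3 * (se_ratio + 0.25))

  # equal templates give ratio near 1
  eq <- mock_community(
    stats::setNames(vp$refs$sequence, c("dom", "rare")),
    copy_numbers = c(dom = 1, rare = 1))
  pool <- simulate_pcr(eq, prof, cycles = 8, initial_molecules = 3000,
                       seed = 5)
  rs <- sample_reads(pool, 7000, seq_sub_rate = 0, seed = 6)
  r1 <- variant_ratio(dereplicate(rs), "dom", "rare",
                      classifier = truth_classifier(eq))
  expect_lt(abs(r1 - 1), 0.2)

  # rare variant absent: NA with a warning, never an error
  tab <- data.frame(sample = "s", sequence = vp$refs$sequence[1],
                    count = 10)
  expect_warning(r0 <- variant_ratio(tab, "dom", "rare", classifier = cl),
                 "rare")
  expect_true(is.na(r0))
})

test_that("chimera overlap fractions follow set arithmetic", {
  expect_equal(chimera_overlap(list(a = c("x", "y"), b = c("x", "y")))
               $shared_fraction, 1)
  expect_equal(chimera_overlap(list(a = "x", b = "y"))$shared_fraction, 0)
  ov <- chimera_overlap(list(c1 = c("a", "b", "c"), c2 = c("b", "c", "d")))
  expect_equal(ov$shared_fraction, 0.5)
  expect_equal(unname(ov$per_condition_fraction), c(2 / 3, 2 / 3))
  ov2 <- chimera_overlap(
    list(c1 = c("a", "b"), c2 = c("b", "c")),
    abundances = list(c1 = c(a = 9, b = 1), c2 = c(b = 5, c = 5)))
  expect_equal(unname(ov2$per_condition_fraction), c(0.1, 0.5))
  expect_error(chimera_overlap(list(a = "x")), ">= 2")
})
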