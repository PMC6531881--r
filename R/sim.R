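#' Polymerase error/chimera profiles
#'
#' Returns one of five named presets emulating commonly used high-fidelity
#' polymerases. The numeric rates are package calibration choices, not
#' measured values; what they preserve is the relative ordering reported
#' for such enzymes: the ~10x-over-Taq fidelity class (Accuprime,
#' Platinum) has roughly tenfold higher misincorporation rates than the
#' ~100x class (KAPA, Q5, Phusion), KAPA has the lowest substitution rate
#' and the lowest template-switch probability, and Platinum the highest
#' template-switch probability.
#'
#' @param name One of `"Accuprime"`, `"KAPA"`, `"Phusion"`, `"Platinum"`,
#'   `"Q5"` (case-insensitive).
#' @return A `pcr_profile` object; see [pcr_profile()].
#' @examples
#' polymerase_profile("KAPA")$sub_rate
#' @export
polymerase_profile <- function(name) {
  presets <- list(
    Accuprime = list(sub_rate = 1.2e-4, chimera_prob = 0.002),
    KAPA      = list(sub_rate = 1.0e-5, chimera_prob = 0.001),
    Phusion   = list(sub_rate = 1.2e-5, chimera_prob = 0.004),
    Platinum  = list(sub_rate = 1.0e-4, chimera_prob = 0.008),
    Q5        = list(sub_rate = 1.1e-5, chimera_prob = 0.0045)
  )
  hit <- match(tolower(name), tolower(names(presets)))
  if (is.na(hit))
    stop("unknown polymerase profile \"", name, "\"; available presets: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[hit]]
  pcr_profile(names(presets)[hit], sub_rate = p$sub_rate,
              indel_rate = p$sub_rate / 10, chimera_prob = p$chimera_prob,
              efficiency = 0.95)
}

#' Construct a PCR polymerase profile
#'
#' @param name Profile label carried through to sample metadata.
#' @param sub_rate Substitutions per base per duplication (0 to 0.01).
#' @param indel_rate Insertions+deletions per base per duplication
#'   (0 to 0.01).
#' @param chimera_prob Probability that a newly synthesized molecule is a
#'   template-switch chimera, in \[0, 1).
#' @param efficiency Per-cycle duplication probability in (0, 1\]; a single
#'   number (applied to every template) or a named vector over reference
#'   ids (per-template amplification bias).
#' @return A list of class `pcr_profile`.
#' @export
pcr_profile <- function(name, sub_rate, indel_rate, chimera_prob,
                        efficiency = 1) {
  if (sub_rate < 0 || sub_rate > 0.01 || indel_rate < 0 || indel_rate > 0.01)
    stop("sub_rate and indel_rate must be in [0, 0.01]")
  if (chimera_prob < 0 || chimera_prob >= 1)
    stop("chimera_prob must be in [0, 1)")
  if (any(efficiency <= 0) || any(efficiency > 1))
    stop("efficiency values must be in (0, 1]")
  structure(list(name = name, sub_rate = sub_rate, indel_rate = indel_rate,
                 chimera_prob = chimera_prob, efficiency = efficiency),
            class = "pcr_profile")
}

#' @export
print.pcr_profile <- function(x, ...) {
  cat("PCR profile \"", x$name, "\": sub ", x$sub_rate, "/base/dup, indel ",
      x$indel_rate, ", chimera ", x$chimera_prob, ", efficiency ",
      paste(signif(x$efficiency, 3), collapse = ","), "\n", sep = "")
  invisible(x)
}

# For each ordered reference pair (a, b): an integer vector over prefix
# lengths p = 1..len(a) giving the number of b bases aligned to the first
# p bases of a (at the last alignment column consuming the p-th a base).
build_pair_maps <- function(community) {
  ids <- community$refs$id
  seqs <- stats::setNames(community$refs$sequence, ids)
  maps <- new.env(parent = emptyenv())
  for (ia in ids) {
    for (ib in ids) {
      if (ia == ib) next
      al <- cpp_align_full(seqs[[ia]], seqs[[ib]])
      acols <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
      bcols <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      cb <- cumsum(bcols != "-")
      idx <- which(acols != "-")  # column where the p-th a base sits
      la <- length(idx)
      last_col <- c(idx[-1L] - 1L, length(acols))
      assign(paste(ia, ib, sep = "\r"), as.integer(cb[last_col]),
             envir = maps)
    }
  }
  maps
}

resolve_efficiency <- function(profile, community) {
  ids <- community$refs$id
  eff <- profile$efficiency
  if (length(eff) == 1L && is.null(names(eff)))
    return(stats::setNames(rep(as.numeric(eff), length(ids)), ids))
  missing <- setdiff(ids, names(eff))
  if (length(missing))
    stop("profile efficiency missing for reference(s): ",
         paste(missing, collapse = ", "))
  stats::setNames(as.numeric(eff[ids]), ids)
}

#' Simulate PCR amplification of a mock community
#'
#' Count-space simulation of `cycles` rounds of PCR. The initial template
#' pool is drawn multinomially from the community's template abundances.
#' Each cycle, every molecule duplicates with its per-template efficiency;
#' each new copy acquires `Poisson(sub_rate x length)` substitutions and
#' `Poisson(indel_rate x length)` single-base indels at uniform positions,
#' inheriting all errors already present in its template (mutation history
#' is genealogical, which is what makes early-cycle errors abundant). With
#' probability `chimera_prob` the new copy is instead a template-switch
#' chimera: the template's prefix up to a uniform interior breakpoint
#' joined to the corresponding suffix of a partner molecule sampled
#' abundance-proportionally from the start-of-cycle pool. Template
#' switches onto a partner from the same reference lineage are treated as
#' plain duplications (the joined product of two faithful copies of one
#' reference is that reference).
#'
#' Molecules are multiset entries (unique sequence + provenance, with a
#' count), not individual agents, so 35 cycles stay tractable; when the
#' total count would exceed `pool_cap` the pool is downsampled
#' multinomially back to the cap, preserving expected proportions.
#'
#' @param community A [mock_community].
#' @param profile A [pcr_profile].
#' @param cycles Number of amplification rounds (>= 1).
#' @param initial_molecules Starting template count
#'   (>= 10 x number of references).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param pool_cap Per-cycle total-count cap (default 1e6).
#' @return An `amplicon_pool`: a list with `molecules` (data.frame with
#'   columns `sequence`, `count`, `origin` ("source"/"chimera"), `ref_a`,
#'   `ref_b`, `breakpoint` (prefix length of `ref_a`-derived bases, NA for
#'   source molecules), `errors` (accumulated polymerase error
#'   operations)), plus `cycles_run`, `profile_name`, `seed`,
#'   `initial_molecules`.
#' @export
simulate_pcr <- function(community, profile, cycles, initial_molecules = 1000L,
                         seed = 1L, pool_cap = 1e6) {
  stopifnot(inherits(community, "mock_community"),
            inherits(profile, "pcr_profile"))
  if (cycles < 1L) stop("cycles must be >= 1")
  nref <- nrow(community$refs)
  if (initial_molecules < 10L * nref)
    stop("initial_molecules must be >= 10 x number of references")
  if (pool_cap > 2^31 - 1) stop("pool_cap must fit in a 32-bit integer")
  eff <- resolve_efficiency(profile, community)
  sub <- profile$sub_rate
  ind <- profile$indel_rate
  chp <- profile$chimera_prob
  # alignment coordinate maps between reference pairs: for a breakpoint
  # after the p-th base of reference a, the number of reference-b bases
  # aligned up to that point.  Joining at these coordinates makes every
  # error-free template switch an exact member of the bimera library.
  pair_map <- if (chp > 0) build_pair_maps(community) else NULL
  ref_len <- stats::setNames(nchar(community$refs$sequence),
                             community$refs$id)

  pool <- withr::with_seed(seed, {
    init <- as.vector(rmultinom(1L, initial_molecules,
                                community$abundance))
    keep <- init > 0L
    seqs <- community$refs$sequence[keep]
    cnt <- as.numeric(init[keep])
    refa <- community$refs$id[keep]
    refb <- rep(NA_character_, sum(keep))
    brk <- rep(NA_integer_, sum(keep))
    errs <- rep(0L, sum(keep))
    origin <- rep("source", sum(keep))
    len <- nchar(seqs)

    for (cyc in seq_len(cycles)) {
      n <- length(seqs)
      cnt0 <- cnt
      newc <- rbinom(n, cnt, eff[refa])
      nch <- if (chp > 0) rbinom(n, newc, chp) else integer(n)
      lam <- (sub + ind) * len
      p0 <- exp(-lam)
      ncl <- rbinom(n, newc - nch, p0)
      nerr <- newc - nch - ncl
      cnt <- cnt + ncl

      add_seq <- character(0); add_cnt <- numeric(0)
      add_org <- character(0); add_ra <- character(0)
      add_rb <- character(0); add_bk <- integer(0); add_er <- integer(0)

      tot_e <- sum(nerr)
      if (tot_e > 0L) {
        ti <- rep.int(seq_len(n), nerr)
        lam_i <- lam[ti]
        # zero-truncated Poisson: total error ops per erroneous copy
        ktot <- qpois(runif(tot_e, dpois(0, lam_i), 1), lam_i)
        ktot[ktot < 1L] <- 1L
        ks <- rbinom(tot_e, ktot, if (sub + ind > 0) sub / (sub + ind) else 0)
        ki <- ktot - ks
        kins <- rbinom(tot_e, ki, 0.5)
        kdel <- ki - kins
        mut <- as.character(cpp_mutate(seqs[ti], ks, kins, kdel))
        add_seq <- c(add_seq, mut)
        add_cnt <- c(add_cnt, rep(1, tot_e))
        add_org <- c(add_org, origin[ti])
        add_ra <- c(add_ra, refa[ti])
        add_rb <- c(add_rb, refb[ti])
        add_bk <- c(add_bk, brk[ti])
        add_er <- c(add_er, errs[ti] + ktot)
      }

      tot_c <- sum(nch)
      if (tot_c > 0L) {
        ti <- rep.int(seq_len(n), nch)
        pj <- sample.int(n, tot_c, replace = TRUE, prob = cnt0)
        same <- refa[ti] == refa[pj]
        if (any(same)) {
          # same-lineage switch: indistinguishable from a plain duplication
          dup <- tabulate(ti[same], nbins = n)
          cnt <- cnt + dup
        }
        if (any(!same)) {
          ti2 <- ti[!same]; pj2 <- pj[!same]
          lt <- len[ti2]; lp <- len[pj2]
          b <- 1L + as.integer(floor(runif(length(ti2)) * (lt - 1L)))
          b[b > lt - 1L] <- lt[b > lt - 1L] - 1L
          # breakpoint in template-reference coordinates (molecules with
          # indels are mapped proportionally), then across the reference
          # pair alignment, then into partner-molecule coordinates
          la_r <- ref_len[refa[ti2]]; lb_r <- ref_len[refa[pj2]]
          p_ref <- ifelse(lt == la_r, b,
                          pmax(1L, pmin(la_r - 1L,
                                        as.integer(round(b * la_r / lt)))))
          key <- paste(refa[ti2], refa[pj2], sep = "\r")
          bp_ref <- vapply(seq_along(ti2), function(z)
            pair_map[[key[z]]][p_ref[z]], integer(1))
          bp <- ifelse(lp == lb_r, bp_ref,
                       pmax(0L, pmin(lp - 1L,
                                     as.integer(round(bp_ref * lp / lb_r)))))
          cseq <- paste0(substr(seqs[ti2], 1L, b),
                         substr(seqs[pj2], bp + 1L, lp))
          add_seq <- c(add_seq, cseq)
          add_cnt <- c(add_cnt, rep(1, length(ti2)))
          add_org <- c(add_org, rep("chimera", length(ti2)))
          add_ra <- c(add_ra, refa[ti2])
          add_rb <- c(add_rb, refa[pj2])
          add_bk <- c(add_bk, b)
          add_er <- c(add_er, errs[ti2] + errs[pj2])
        }
      }

      if (length(add_seq)) {
        seqs <- c(seqs, add_seq)
        cnt <- c(cnt, add_cnt)
        origin <- c(origin, add_org)
        refa <- c(refa, add_ra)
        refb <- c(refb, add_rb)
        brk <- c(brk, add_bk)
        errs <- c(errs, add_er)
        len <- c(len, nchar(add_seq))
      }

      if (sum(cnt) > pool_cap) {
        cnt <- as.numeric(rmultinom(1L, as.integer(pool_cap), cnt))
        keep <- cnt > 0
        seqs <- seqs[keep]; cnt <- cnt[keep]; origin <- origin[keep]
        refa <- refa[keep]; refb <- refb[keep]; brk <- brk[keep]
        errs <- errs[keep]; len <- len[keep]
      }
    }

    dt <- data.table(sequence = seqs, count = cnt, origin = origin,
                     ref_a = refa, ref_b = refb, breakpoint = brk,
                     errors = errs)
    dt <- dt[, list(count = sum(count)),
             by = c("sequence", "origin", "ref_a", "ref_b", "breakpoint",
                    "errors")]
    setDF(dt)
    dt[, c("sequence", "count", "origin", "ref_a", "ref_b", "breakpoint",
           "errors")]
  })

  structure(list(molecules = pool, cycles_run = as.integer(cycles),
                 profile_name = profile$name, seed = as.integer(seed),
                 initial_molecules = as.integer(initial_molecules)),
            class = "amplicon_pool")
}

#' @export
print.amplicon_pool <- function(x, ...) {
  cat("Amplicon pool after ", x$cycles_run, " cycles (profile ",
      x$profile_name, "): ", nrow(x$molecules), " unique molecules, total ",
      format(sum(x$molecules$count), big.mark = ","), "\n", sep = "")
  cat("  chimeric fraction (by count): ",
      signif(sum(x$molecules$count[x$molecules$origin == "chimera"]) /
               sum(x$molecules$count), 3), "\n", sep = "")
  invisible(x)
}

#' Sample sequenced reads from an amplicon pool
#'
#' Draws `depth` reads multinomially in proportion to molecule counts and
#' adds post-assembly sequencing noise as independent
#' `Poisson(seq_sub_rate x length)` substitutions per read (assembled
#' paired-end contigs leave substitutions as the dominant residual
#' sequencing artifact; indels enter through the polymerase model).
#' Every read carries its molecule's truth provenance.
#'
#' @param pool An `amplicon_pool` from [simulate_pcr()].
#' @param depth Number of reads (>= 1).
#' @param seq_sub_rate Sequencing substitution rate per base.
#' @param seed Integer seed.
#' @param sample_id Sample label stored in the metadata.
#' @param replicate Replicate index stored in the metadata.
#' @return A `read_set` data.frame with columns `read_id`, `sample`,
#'   `sequence`, `origin`, `ref_a`, `ref_b`, `breakpoint`, `pcr_errors`,
#'   `seq_errors`, `polymerase`, `cycles`, `replicate`.
#' @export
sample_reads <- function(pool, depth, seq_sub_rate = 0, seed = 1L,
                         sample_id = NULL, replicate = 0L) {
  stopifnot(inherits(pool, "amplicon_pool"))
  if (depth < 1L) stop("depth must be >= 1")
  mol <- pool$molecules
  if (nrow(mol) == 0L) stop("pool is empty")
  if (is.null(sample_id))
    sample_id <- paste(pool$profile_name, pool$cycles_run, replicate,
                       sep = "_")
  withr::with_seed(seed, {
    draws <- as.vector(rmultinom(1L, as.integer(depth), mol$count))
    idx <- rep.int(seq_len(nrow(mol)), draws)
    seqs <- mol$sequence[idx]
    k <- rpois(length(idx), seq_sub_rate * nchar(seqs))
    if (any(k > 0L)) {
      hot <- which(k > 0L)
      seqs[hot] <- as.character(
        cpp_mutate(seqs[hot], k[hot], integer(length(hot)),
                   integer(length(hot))))
    }
    out <- data.frame(
      read_id = sprintf("%s_read%06d", sample_id, seq_along(idx)),
      sample = sample_id,
      sequence = seqs,
      origin = mol$origin[idx],
      ref_a = mol$ref_a[idx],
      ref_b = mol$ref_b[idx],
      breakpoint = mol$breakpoint[idx],
      pcr_errors = mol$errors[idx],
      seq_errors = as.integer(k),
      polymerase = pool$profile_name,
      cycles = pool$cycles_run,
      replicate = as.integer(replicate),
      stringsAsFactors = FALSE
    )
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Run a polymerase x cycles x replicate experiment grid
#'
#' One simulated sample per combination of profile, cycle count and
#' replicate, with distinct RNG streams derived from a single master seed
#' (so the whole grid is reproducible from one integer). Optional
#' per-replicate lognormal jitter of amplification efficiencies models
#' tube-to-tube stochastic drift.
#'
#' @param community A [mock_community].
#' @param profile_names Character vector of preset names (see
#'   [polymerase_profile()]) or a named list of [pcr_profile] objects.
#' @param cycles_list Integer vector of cycle counts.
#' @param replicates Replicates per condition (>= 1).
#' @param depth Reads per sample.
#' @param seq_sub_rate Sequencing substitution rate per base.
#' @param seed Master integer seed.
#' @param initial_molecules,pool_cap Passed to [simulate_pcr()].
#' @param efficiency_sd Standard deviation of per-replicate lognormal
#'   efficiency jitter (0 disables drift in efficiencies).
#' @return A list of `read_set` data.frames, one per (profile, cycles,
#'   replicate), with complete metadata columns.
#' @export
run_experiment_grid <- function(community, profile_names, cycles_list,
                                replicates = 4L, depth = 5000L,
                                seq_sub_rate = 2e-4, seed = 1L,
                                initial_molecules = 1000L, pool_cap = 1e6,
                                efficiency_sd = 0) {
  if (!length(profile_names) || !length(cycles_list))
    stop("profile_names and cycles_list must be non-empty")
  if (replicates < 1L) stop("replicates must be >= 1")
  profiles <- if (is.list(profile_names)) profile_names else
    stats::setNames(lapply(profile_names, polymerase_profile), profile_names)
  out <- vector("list", length(profiles) * length(cycles_list) * replicates)
  i <- 0L
  for (pn in seq_along(profiles)) {
    prof <- profiles[[pn]]
    base_eff <- resolve_efficiency(prof, community)
    for (cyc in cycles_list) {
      for (rep_i in seq_len(replicates)) {
        i <- i + 1L
        s_jit <- derive_seed(seed, 3L * i)
        s_sim <- derive_seed(seed, 3L * i + 1L)
        s_seq <- derive_seed(seed, 3L * i + 2L)
        prof_r <- prof
        if (efficiency_sd > 0) {
          jit <- withr::with_seed(s_jit,
                                  exp(rnorm(length(base_eff), 0, efficiency_sd)))
          prof_r$efficiency <- pmin(1, base_eff * jit)
        }
        pool <- simulate_pcr(community, prof_r, cycles = cyc,
                             initial_molecules = initial_molecules,
                             seed = s_sim, pool_cap = pool_cap)
        out[[i]] <- sample_reads(pool, depth = depth,
                                 seq_sub_rate = seq_sub_rate, seed = s_seq,
                                 replicate = rep_i - 1L)
      }
    }
  }
  out
}

#' Bind a list of read sets into one data.frame
#'
#' @param readsets List of `read_set` objects.
#' @return A single `read_set` data.frame.
#' @export
bind_read_sets <- function(readsets) {
  out <- as.data.frame(rbindlist(lapply(readsets, as.data.frame)))
  class(out) <- c("read_set", "data.frame")
  out
}
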