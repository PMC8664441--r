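test_that("angle clustering recovers synthetic blob structure", {
  # three tight blobs at the canonical diplotype angles
  sc <- blob_scores(c(2, 45, 88), n_per = 20, seed = 1)
  cs <- cluster_scores(sc)
  expect_equal(cs$k, 3L)
  truth <- rep(1:3, each = 20)
  # labels must match blob membership up to relabeling
  expect_equal(length(unique(paste(truth, cs$labels))), 3L)

  # four blobs (a distinct within-taxon haplotype) give k >= 4
  sc4 <- blob_scores(c(2, 25, 45, 88), n_per = 15, seed = 2)
  expect_gte(cluster_scores(sc4)$k, 4L)

  # identical scores collapse to a single cluster
  sc1 <- data.frame(sample_id = paste0("s", 1:8), v_score = 3, b_score = 3,
                    radius = sqrt(18), angle = 45)
  expect_equal(cluster_scores(sc1)$k, 1L)
})

test_that("all-zero radii flag the locus as having no variants", {
  sc <- data.frame(sample_id = paste0("s", 1:6), v_score = 0, b_score = 0,
                   radius = 0, angle = NA_real_)
  cs <- cluster_scores(sc)
  expect_true(cs$no_variants)
  expect_equal(cs$k, 0L)
})

test_that("low-radius samples are excluded from clusters but keep their ids", {
  sc <- blob_scores(c(5, 85), n_per = 10, radius = 10, seed = 3)
  sc$radius[1] <- 0.1   # 1% of max: below the 5% cut
  sc$v_score[1] <- 0.1 * cos(sc$angle[1] * pi / 180)
  sc$b_score[1] <- 0.1 * sin(sc$angle[1] * pi / 180)
  cs <- cluster_scores(sc)
  expect_true(is.na(cs$labels[sc$sample_id[1]]))
  expect_false(anyNA(cs$labels[sc$sample_id[-1]]))
})

test_that("strict majority consensus requires > 50% and never calls N", {
  m <- cmat(c(A = 90, C = 10),          # clear majority
            c(A = 50, C = 50),          # exact tie: NOCALL
            c(N = 80, A = 20),          # N majority: NOCALL
            c(),                        # zero depth: NOCALL
            c(DEL = 60, A = 30))        # DEL is callable
  hap <- consensus_haplotype(m)
  expect_equal(hap, c(1L, NA, NA, NA, 6L))
  expect_equal(hap_to_char(hap), c("A", "NOCALL", "NOCALL", "NOCALL", "DEL"))
})

test_that("pooled homozygote consensus recovers the true haplotype under noise", {
  set.seed(11)
  hap <- sample.int(4L, 200, replace = TRUE)
  eps <- 0.01
  pooled <- matrix(0L, 6, 200, dimnames = list(DM_STATES, NULL))
  for (i in 1:200) {
    p <- rep(eps / 5, 6)
    p[hap[i]] <- 1 - eps
    pooled[, i] <- rmultinom(1, 1000, p)
  }
  got <- consensus_haplotype(pooled)
  called <- !is.na(got)
  expect_true(all(got[called] == hap[called]))
  expect_gt(mean(called), 0.99)
})

test_that("diplotype log-likelihoods match closed forms", {
  eps <- 0.005
  hap_v <- c(1L, 2L, 3L)
  hap_b <- c(4L, 2L, 1L)
  # HOM with every read matching: lnL = N_tot ln(1 - eps)
  cc <- hom_counts(hap_v, 20)
  r <- diplotype_loglik(cc, hap_v, hap_b, "BvHOM", eps)
  expect_equal(r$lnL, 60 * log(1 - eps), tolerance = 1e-12)

  # symmetric HET: alpha_hat = 0.5 within 1e-3, matches brute-force grid
  het <- het_counts(hap_v, hap_b, 15, 15)
  r <- diplotype_loglik(het, hap_v, hap_b, "HET", eps)
  expect_equal(r$alpha_hat, 0.5, tolerance = 1e-3)
  mask <- rep(TRUE, 3)
  bf <- brute_het_lnl(het, hap_v, hap_b, mask, eps)
  expect_equal(r$lnL, bf$lnL, tolerance = 1e-6)

  # biased HET 70:30 -> alpha_hat ~ 0.7, lnL within 1e-6 of the grid maximum
  het2 <- het_counts(hap_v, hap_b, 70, 30)
  r2 <- diplotype_loglik(het2, hap_v, hap_b, "HET", eps)
  expect_equal(r2$alpha_hat, 0.7, tolerance = 0.01)
  bf2 <- brute_het_lnl(het2, hap_v, hap_b, mask, eps)
  expect_equal(r2$lnL, bf2$lnL, tolerance = 1e-6)
  expect_equal(r2$alpha_hat, bf2$alpha, tolerance = 1e-4)

  # all columns masked -> undefined -> caller flags MISSING
  r3 <- diplotype_loglik(cc, rep(NA_integer_, 3), hap_b, "HET", eps)
  expect_true(is.na(r3$lnL))
  expect_equal(call_diplotype(cc, rep(NA_integer_, 3), hap_b)$state, "MISSING")
})

test_that("coestimation equals exhaustive brute force on small random loci", {
  for (seed in 1:12) {
    loc <- rand_small_locus(seed)
    co <- coestimate_locus(loc$counts, loc$candidates, epsilon = 0.005)
    bf <- brute_force_total(loc$counts, loc$haps, epsilon = 0.005)
    expect_equal(co$total_lnL, bf, tolerance = 1e-4,
                 label = sprintf("total lnL (seed %d)", seed))
  }
})

test_that("identical or single candidates leave the locus unresolvable", {
  hap <- c(1L, 2L, 3L)
  counts <- list(a = hom_counts(hap, 10), b = hom_counts(hap, 10))
  cands <- list(list(states = hap, angle = 5), list(states = hap, angle = 80))
  co <- coestimate_locus(counts, cands)
  expect_true("unresolvable" %in% co$flags)
  expect_true(all(co$calls$state == "MISSING"))
})

test_that("F0/F1 pattern violations are flagged but calls are kept", {
  ped <- toy_pedigree(4, 4)
  hap_v <- rep(1L, 10)
  hap_b <- rep(2L, 10)
  counts <- c(
    setNames(list(hom_counts(hap_b, 30)), "SIRE"),   # wrong way around
    setNames(list(hom_counts(hap_v, 30)), "DAM"),
    setNames(lapply(1:3, function(i) het_counts(hap_v, hap_b, 15, 15)),
             c("F1F", "F1M6", "F1M7")),
    setNames(lapply(1:8, function(i) het_counts(hap_v, hap_b, 15, 15)),
             ped$sample_id[ped$generation == "F2"]))
  cands <- list(list(states = hap_v, angle = 5), list(states = hap_b, angle = 85))
  co <- coestimate_locus(counts, cands, pedigree = ped)
  expect_true("expected_F0F1_pattern_violated" %in% co$flags)
  expect_equal(co$calls$state[co$calls$sample_id == "SIRE"], "BbHOM")
})

test_that("polarized-matrix update keeps or improves cluster separation", {
  cf <- preset_config("clean", seed = 21, n_loci = 2, family_sizes = c(25, 25),
                      coverage = 80)
  truth <- simulate_pedigree_genomes(cf)
  sync <- simulate_reads(truth, cf)
  ped <- truth$pedigree
  lc <- sync$loci[[1]]
  sire <- ped$sample_id[ped$role == "grandsire_Bv"]
  dam <- ped$sample_id[ped$role == "granddam_Bb"]
  mp0 <- polarize(lc$counts[[sire]], lc$counts[[dam]])
  sc0 <- score_samples(lc$counts, mp0)
  cs0 <- cluster_scores(sc0, counts_list = lc$counts)
  expect_gte(cs0$k, 2)
  mp1 <- update_polarized_matrix(cs0)
  sc1 <- score_samples(lc$counts, mp1)
  cs1 <- cluster_scores(sc1, counts_list = lc$counts)
  gap <- function(cs) {
    a <- sort(vapply(cs$clusters, `[[`, numeric(1), "mean_angle"))
    if (length(a) < 2) return(0)
    min(diff(a))
  }
  expect_gte(gap(cs1), gap(cs0) - 1)  # unchanged or improved (1 degree slack)
  expect_equal(mp1$source, "updated_clusters")
})

test_that("two clusters suffice for the polarized-matrix update", {
  sc <- blob_scores(c(3, 87), n_per = 8, seed = 5)
  hap_v <- rep(1L, 4)
  hap_b <- rep(2L, 4)
  counts <- c(lapply(1:8, function(i) hom_counts(hap_v, 20)),
              lapply(1:8, function(i) hom_counts(hap_b, 20)))
  names(counts) <- sc$sample_id
  cs <- cluster_scores(sc, counts_list = counts)
  expect_equal(cs$k, 2L)
  mp <- update_polarized_matrix(cs)
  expect_equal(unname(mp$values[1, 1]), 1, tolerance = 1e-6)
  expect_equal(unname(mp$values[2, 1]), -1, tolerance = 1e-6)
})

test_that("whitelist rescoring matches full-matrix calls on clean data", {
  cf <- preset_config("clean", seed = 31, n_loci = 1, family_sizes = c(20, 20),
                      coverage = 100)
  truth <- simulate_pedigree_genomes(cf)
  sync <- simulate_reads(truth, cf)
  lc <- sync$loci[[1]]
  res <- diplotype_locus(lc, truth$pedigree)
  lo <- truth$loci[[1]]
  var_at <- which(lo$hap_bv != lo$hap_bb)
  expect_gte(length(var_at), 2)
  wl <- data.frame(locus_id = lc$locus_id, pos = var_at,
                   state_bv = DM_STATES[lo$hap_bv[var_at]],
                   state_bb = DM_STATES[lo$hap_bb[var_at]])
  re <- rescore_with_whitelist(lc$counts, wl, lc$n)
  expect_equal(re$state, res$calls$state)

  # reads only off the whitelist columns -> MISSING
  empty <- lc$counts[[1]]
  empty[] <- 0L
  off <- setdiff(seq_len(lc$n), var_at)[1]
  empty[1, off] <- 10L
  re2 <- rescore_with_whitelist(list(x = empty), wl, lc$n)
  expect_equal(re2$state, "MISSING")

  # position beyond locus length is rejected
  expect_error(rescore_with_whitelist(lc$counts, transform(wl, pos = lc$n + 1),
                                      lc$n), "beyond")
})
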