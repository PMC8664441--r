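# shared fixtures: small count matrices, synthetic score blobs, and an
# independent brute-force likelihood oracle for the coestimation machinery

# 6 x n count matrix from a list of (state, count) pairs per column;
# states given as characters from DM_STATES
cmat <- function(...) {
  cols <- list(...)
  m <- matrix(0L, 6L, length(cols), dimnames = list(DM_STATES, NULL))
  for (i in seq_along(cols)) {
    cc <- cols[[i]]
    if (!length(cc)) next
    m[match(names(cc), DM_STATES), i] <- as.integer(cc)
  }
  m
}

# homozygote counts: `depth` reads on hap state at every column
hom_counts <- function(hap, depth) {
  n <- length(hap)
  m <- matrix(0L, 6L, n, dimnames = list(DM_STATES, NULL))
  m[cbind(hap, seq_len(n))] <- as.integer(depth)
  m
}

# heterozygote counts: d1 reads on hap1 states, d2 on hap2 states
het_counts <- function(hap1, hap2, d1, d2) {
  n <- length(hap1)
  m <- matrix(0L, 6L, n, dimnames = list(DM_STATES, NULL))
  m[cbind(hap1, seq_len(n))] <- m[cbind(hap1, seq_len(n))] + as.integer(d1)
  m[cbind(hap2, seq_len(n))] <- m[cbind(hap2, seq_len(n))] + as.integer(d2)
  m
}

# synthetic score table: blobs of `n_per` samples at given angles (degrees)
blob_scores <- function(angles, n_per = 20, radius = 10, jitter = 0.5,
                        seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    ang <- unlist(lapply(angles, function(a)
      pmin(pmax(rnorm(n_per, a, jitter), 0), 90)))
    r <- pmax(rnorm(length(ang), radius, radius / 20), 0.1)
    data.frame(sample_id = sprintf("s%03d", seq_along(ang)),
               v_score = r * cos(ang * pi / 180),
               b_score = r * sin(ang * pi / 180),
               radius = r, angle = ang, stringsAsFactors = FALSE)
  })
}

# minimal pedigree: 2 F0 + 3 F1 + F2 offspring split across two families
toy_pedigree <- function(n6 = 10, n7 = 10, sexes = NULL) {
  f2 <- c(sprintf("F2_6_%02d", seq_len(n6)), sprintf("F2_7_%02d", seq_len(n7)))
  ped <- data.frame(
    sample_id = c("SIRE", "DAM", "F1F", "F1M6", "F1M7", f2),
    generation = c("F0", "F0", "F1", "F1", "F1", rep("F2", length(f2))),
    role = c("grandsire_Bv", "granddam_Bb", "F1_father", "F1_mother",
             "F1_mother", rep("offspring", length(f2))),
    family = c("", "", "", "6", "7", rep(c("6", "7"), c(n6, n7))),
    sex = c("male", "female", "male", "female", "female",
            if (is.null(sexes)) rep("unknown", length(f2)) else sexes),
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

# --- independent brute-force oracle -----------------------------------------
# builds the per-column expected distributions explicitly from the error
# model definition and grid-searches the admixture coefficient; shares no
# code path with diplotype_loglik / coestimate_locus

emission <- function(hap, n, epsilon) {
  E <- matrix(epsilon / 5, 6, n)
  ok <- !is.na(hap)
  E[cbind(hap[ok], which(ok))] <- 1 - epsilon
  E
}

brute_hom_lnl <- function(counts, hap, mask, epsilon) {
  E <- emission(hap, ncol(counts), epsilon)
  sum(counts[, mask, drop = FALSE] * log(E[, mask, drop = FALSE]))
}

brute_het_lnl <- function(counts, hap_bv, hap_bb, mask, epsilon,
                          bounds = c(0.1, 0.9)) {
  Ev <- emission(hap_bv, ncol(counts), epsilon)[, mask, drop = FALSE]
  Eb <- emission(hap_bb, ncol(counts), epsilon)[, mask, drop = FALSE]
  cc <- counts[, mask, drop = FALSE]
  lnl_at <- function(agrid) {
    vapply(agrid, function(a) sum(cc * log(a * Ev + (1 - a) * Eb)), numeric(1))
  }
  coarse <- seq(bounds[1], bounds[2], by = 1e-3)
  v1 <- lnl_at(coarse)
  a0 <- coarse[which.max(v1)]
  fine <- seq(max(bounds[1], a0 - 1e-3), min(bounds[2], a0 + 1e-3), by = 1e-6)
  v2 <- lnl_at(fine)
  list(lnL = max(v2), alpha = fine[which.max(v2)])
}

brute_sample_best <- function(counts, hap_bv, hap_bb, epsilon) {
  mask <- !is.na(hap_bv) & !is.na(hap_bb)
  if (!any(mask) || sum(counts[, mask, drop = FALSE]) == 0) return(0)
  max(brute_hom_lnl(counts, hap_bb, mask, epsilon),
      brute_het_lnl(counts, hap_bv, hap_bb, mask, epsilon)$lnL,
      brute_hom_lnl(counts, hap_bv, mask, epsilon))
}

# exhaustive pairs x states x alpha-grid total; haps = list of integer vectors
brute_force_total <- function(counts_list, haps, epsilon) {
  best <- -Inf
  for (i in seq_along(haps)) {
    for (j in seq_along(haps)) {
      if (i == j) next
      tot <- sum(vapply(counts_list, brute_sample_best, numeric(1),
                        hap_bv = haps[[i]], hap_bb = haps[[j]],
                        epsilon = epsilon))
      best <- max(best, tot)
    }
  }
  best
}

# random small locus for the oracle-equivalence checks
rand_small_locus <- function(seed, n_samples = 8, n_cols = 30, depth = 15) {
  set.seed(seed)
  hap_bv <- sample.int(4L, n_cols, replace = TRUE)
  hap_bb <- hap_bv
  var_at <- sample.int(n_cols, max(3L, rbinom(1, n_cols, 0.3)))
  hap_bb[var_at] <- ((hap_bv[var_at] - 1L +
                      sample.int(3L, length(var_at), TRUE)) %% 4L) + 1L
  # an occasional third candidate and some NOCALLs
  hap_c <- hap_bv
  flip <- sample.int(n_cols, 4L)
  hap_c[flip] <- ((hap_c[flip] - 1L + sample.int(3L, 4L, TRUE)) %% 4L) + 1L
  hap_bv[sample.int(n_cols, 2L)] <- NA
  states <- sample(c("BbHOM", "HET", "BvHOM"), n_samples, replace = TRUE)
  counts <- lapply(states, function(st) {
    d <- rpois(n_cols, depth)
    k <- switch(st, BvHOM = d, BbHOM = rep(0L, n_cols),
                HET = rbinom(n_cols, d, 0.55))
    m <- matrix(0L, 6L, n_cols, dimnames = list(DM_STATES, NULL))
    h1 <- ifelse(is.na(hap_bv), hap_c, hap_bv)  # reads need a real state
    m[cbind(h1, seq_len(n_cols))] <- k
    m[cbind(hap_bb, seq_len(n_cols))] <- m[cbind(hap_bb, seq_len(n_cols))] + (d - k)
    # sprinkle a few error reads
    e_at <- sample.int(n_cols, 3L)
    m[cbind(sample.int(6L, 3L, TRUE), e_at)] <-
      m[cbind(sample.int(6L, 3L, TRUE), e_at)] + 1L
    m
  })
  names(counts) <- sprintf("s%02d", seq_len(n_samples))
  haps <- list(hap_bv, hap_bb)
  if (seed %% 2 == 0) haps <- c(haps, list(hap_c))
  cands <- lapply(seq_along(haps), function(i)
    list(states = haps[[i]], angle = c(5, 85, 45)[i]))
  list(counts = counts, haps = haps, candidates = cands)
}
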