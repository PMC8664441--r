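#' Cluster sample scores per locus
#'
#' Samples are clustered on their angle in the (Bv score, Bb score) plane,
#' weighted by radius, so that the geometry of the three expected diplotype
#' clusters (near 0 degrees = BvHOM, near 45 = HET, near 90 = BbHOM) drives
#' the partition. More than three clusters can form when more than two
#' haplotypes segregate. The number of clusters k is chosen in `1..k_max` by
#' BIC over an exact dynamic-programming weighted 1-D k-means (angles are
#' first aggregated into fine bins, which keeps the DP exact up to the bin
#' width and deterministic). Samples with radius below `r_min_frac` times the
#' locus maximum are excluded from cluster statistics but remain available
#' for likelihood calling; a locus where every radius is zero is flagged
#' `no_variants`.
#'
#' @param scores data.frame from [score_samples()].
#' @param counts_list optional named list of per-sample count matrices; when
#'   given, each cluster stores its pooled counts (needed for consensus
#'   haplotypes and the polarized-matrix update).
#' @param sexes optional named character vector (`male`/`female`, other values
#'   ignored) over F2 samples; enables per-cluster sex tallies.
#' @param r_min_frac radius cut for cluster membership, as a fraction of the
#'   locus maximum radius (default 0.05).
#' @param k_max maximum number of clusters considered (default 6).
#' @param bin_width angle bin width in degrees for the exact DP (default
#'   0.05).
#' @return an object of class `cluster_set`: list with `k`, `labels` (named
#'   integer vector, NA for excluded samples), `clusters` (per cluster:
#'   `members`, `mean_angle`, `n`, `pooled_counts`, `n_male`, `n_female`,
#'   `p_m`), `r_min` and `no_variants`.
#' @export
cluster_scores <- function(scores, counts_list = NULL, sexes = NULL,
                           r_min_frac = 0.05, k_max = 6, bin_width = 0.05) {
  ids <- scores$sample_id
  labels <- setNames(rep(NA_integer_, nrow(scores)), ids)
  if (all(scores$radius == 0)) {
    return(structure(list(k = 0L, labels = labels, clusters = list(),
                          r_min = 0, no_variants = TRUE),
                     class = "cluster_set"))
  }
  r_min <- r_min_frac * max(scores$radius)
  incl <- which(scores$radius >= r_min & scores$radius > 0)
  ang <- scores$angle[incl]
  w <- scores$radius[incl]
  n <- length(incl)

  # aggregate into fine angle bins (weight-preserving), then exact weighted DP
  bin <- round(ang / bin_width)
  ub <- sort(unique(bin))
  bw <- vapply(split(w, factor(bin, levels = ub)), sum, numeric(1))
  bx <- vapply(split(ang * w, factor(bin, levels = ub)), sum, numeric(1)) / bw
  kmx <- min(k_max, length(ub))

  dp <- kmeans1d_dp(bx, bw, kmx)
  # BIC over k: weights normalized so the effective sample size is n
  scale <- n / sum(bw)
  bic <- vapply(seq_len(kmx), function(k) {
    wss <- dp$wss[k] * scale
    n * log(wss / n + 1) + 2 * k * log(n)
  }, numeric(1))
  k <- which.min(bic)
  bounds <- dp$boundaries[[k]]  # bin index ranges per cluster

  cl_of_bin <- integer(length(ub))
  for (j in seq_len(k)) cl_of_bin[bounds[j]:bounds[j + 1]] <- j
  lab <- cl_of_bin[match(bin, ub)]
  labels[incl] <- lab

  clusters <- lapply(seq_len(k), function(j) {
    mem <- ids[incl[lab == j]]
    wj <- w[lab == j]
    aj <- ang[lab == j]
    pooled <- NULL
    if (!is.null(counts_list))
      pooled <- Reduce(`+`, counts_list[mem])
    n_male <- n_female <- NA_integer_
    p_m <- NA_real_
    if (!is.null(sexes)) {
      sx <- sexes[intersect(mem, names(sexes))]
      n_male <- sum(sx == "male")
      n_female <- sum(sx == "female")
      p_m <- if (n_male + n_female > 0) n_male / (n_male + n_female) else NA_real_
    }
    list(id = j, members = mem, mean_angle = sum(aj * wj) / sum(wj),
         n = length(mem), pooled_counts = pooled,
         n_male = n_male, n_female = n_female, p_m = p_m)
  })
  structure(list(k = k, labels = labels, clusters = clusters,
                 r_min = r_min, no_variants = FALSE),
            class = "cluster_set")
}

# exact weighted 1-D k-means by dynamic programming over sorted values.
# returns, for each k, the minimal weighted within-cluster sum of squares and
# the cluster boundaries (as index breaks of length k + 1, boundaries[j] ..
# boundaries[j+1] spanning cluster j's values).
kmeans1d_dp <- function(x, w, k_max) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  n <- length(x)
  W <- cumsum(w)
  WX <- cumsum(w * x)
  WX2 <- cumsum(w * x^2)
  seg_cost <- function(i, j) {
    # cost of segment [i..j], vectorized over i
    sw <- W[j] - ifelse(i > 1, W[i - 1], 0)
    sx <- WX[j] - ifelse(i > 1, WX[i - 1], 0)
    sx2 <- WX2[j] - ifelse(i > 1, WX2[i - 1], 0)
    pmax(sx2 - sx^2 / sw, 0)
  }
  cost <- matrix(Inf, k_max, n)
  from <- matrix(1L, k_max, n)
  cost[1, ] <- seg_cost(rep(1L, n), seq_len(n))
  if (k_max > 1) {
    for (k in 2:k_max) {
      for (j in k:n) {
        i <- k:j
        cand <- cost[k - 1, i - 1] + seg_cost(i, j)
        best <- which.min(cand)
        cost[k, j] <- cand[best]
        from[k, j] <- i[best]
      }
    }
  }
  # boundaries[[k]]: cluster j spans sorted indices b[j] .. b[j+1]-1 (last to n)
  boundaries <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    starts <- integer(k)
    j <- n
    for (kk in k:1) {
      starts[kk] <- from[kk, j]
      j <- starts[kk] - 1L
    }
    boundaries[[k]] <- c(1L, starts[-1], n)
  }
  list(wss = cost[, n], boundaries = boundaries, order = o)
}

#' Update the polarized matrix from the two axis-nearest clusters
#'
#' After initial clustering, the polarized matrix (estimated so far from only
#' the two grandparents) is re-estimated from the pooled raw counts of the
#' cluster nearest 0 degrees (new Bv source) and the cluster nearest 90
#' degrees (new Bb source), i.e. the clusters holding the purest individuals
#' of each taxon. Position weights are recomputed on the pooled counts. Ties
#' in angle are broken toward the cluster with the larger pooled depth.
#'
#' @param cluster_set a `cluster_set` whose clusters carry pooled counts.
#' @return a `polarized_matrix` with source `"updated_clusters"`.
#' @export
update_polarized_matrix <- function(cluster_set) {
  cls <- cluster_set$clusters
  if (length(cls) < 2) stop_fmt("polarized-matrix update needs at least 2 clusters")
  if (is.null(cls[[1]]$pooled_counts))
    stop_fmt("cluster_set lacks pooled counts; rebuild with counts_list")
  angs <- vapply(cls, `[[`, numeric(1), "mean_angle")
  depth <- vapply(cls, function(cl) sum(cl$pooled_counts), numeric(1))
  lo <- which(angs == min(angs))
  if (length(lo) > 1) lo <- lo[which.max(depth[lo])]
  hi <- which(angs == max(angs))
  if (length(hi) > 1) hi <- hi[which.max(depth[hi])]
  polarize(cls[[lo]]$pooled_counts, cls[[hi]]$pooled_counts,
           source = "updated_clusters")
}

#' Strict majority consensus haplotype from pooled counts
#'
#' Per column, calls the state whose count strictly exceeds half the column
#' depth; otherwise NOCALL (NA). N is never called: a column whose majority
#' state is N becomes NOCALL, because N carries no ancestry information.
#'
#' @param pooled 6 x n matrix of pooled read counts.
#' @return integer vector of state indices into [DM_STATES] with NA = NOCALL.
#' @export
consensus_haplotype <- function(pooled) {
  n <- ncol(pooled)
  depth <- colSums(pooled)
  idx <- max.col(t(pooled), ties.method = "first")
  maxv <- pooled[cbind(idx, seq_len(n))]
  hap <- ifelse(depth > 0 & 2 * maxv > depth & idx != 5L, idx, NA_integer_)
  as.integer(hap)
}

#' Convert a consensus haplotype to character states
#' @param hap integer state-index vector (NA = NOCALL).
#' @return character vector over [DM_STATES] with `"NOCALL"` for NA.
#' @export
hap_to_char <- function(hap) {
  out <- DM_STATES[hap]
  out[is.na(hap)] <- "NOCALL"
  out
}

#' Diplotype log-likelihood of a sample given a taxon haplotype pair
#'
#' Columns where either haplotype is NOCALL are masked. Per unmasked column
#' i, the expected read distribution is a mixture over the two carried
#' haplotypes with a symmetric error model: a read matches its source
#' haplotype state with probability `1 - epsilon` and is any one of the other
#' five states with probability `epsilon/5` each. For the homozygous states
#' the mixture is a point mass on one haplotype; for HET it is
#' `alpha * hap_bv + (1 - alpha) * hap_bb`, and the log-likelihood is
#' maximized over the enrichment-bias admixture coefficient `alpha` (a
#' concave 1-D problem, solved with [stats::optimize()] to tolerance 1e-8).
#' The default bounds `[0.1, 0.9]` reflect the modest enrichment bias seen in
#' capture data; wider bounds let the HET model collapse onto a homozygote
#' (alpha near 0 or 1), which destroys the HOM/HET likelihood contrast --
#' see the methods vignette.
#'
#' @param counts 6 x n count matrix for the sample.
#' @param hap_bv,hap_bb integer state-index haplotypes (NA = NOCALL).
#' @param state one of `"BbHOM"`, `"HET"`, `"BvHOM"`.
#' @param epsilon per-read error probability in (0, 0.5).
#' @param alpha_bounds admixture bounds for HET.
#' @return list with `lnL` (NA when every column is masked or the sample has
#'   no reads on unmasked columns) and `alpha_hat` (HET only).
#' @export
diplotype_loglik <- function(counts, hap_bv, hap_bb, state,
                             epsilon = 0.005, alpha_bounds = c(0.1, 0.9)) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  agg <- loglik_terms(counts, hap_bv, hap_bb)
  if (is.null(agg)) return(list(lnL = NA_real_, alpha_hat = NA_real_))
  e <- epsilon / 5
  m <- 1 - epsilon
  if (state == "BvHOM") {
    return(list(lnL = agg$Kv_all * log(m) + (agg$Kt - agg$Kv_all) * log(e),
                alpha_hat = NA_real_))
  }
  if (state == "BbHOM") {
    return(list(lnL = agg$Kb_all * log(m) + (agg$Kt - agg$Kb_all) * log(e),
                alpha_hat = NA_real_))
  }
  if (state != "HET") stop_fmt("unknown diplotype state '%s'", state)
  const <- agg$Km_same * log(m) + (agg$Kt_same - agg$Km_same) * log(e) +
    agg$Ko_diff * log(e)
  if (agg$Kv_diff + agg$Kb_diff == 0)
    return(list(lnL = const, alpha_hat = 0.5))
  f <- function(a) {
    agg$Kv_diff * log(a * m + (1 - a) * e) +
      agg$Kb_diff * log(a * e + (1 - a) * m) + const
  }
  opt <- optimize(f, interval = alpha_bounds, maximum = TRUE, tol = 1e-8)
  list(lnL = opt$objective, alpha_hat = opt$maximum)
}

# sufficient statistics of the per-column mixture likelihood: because the
# error model only distinguishes "matches hap_bv", "matches hap_bb" and
# "other", the log-likelihood depends on the counts only through these totals.
loglik_terms <- function(counts, hap_bv, hap_bb) {
  mask <- !is.na(hap_bv) & !is.na(hap_bb)
  if (!any(mask)) return(NULL)
  cols <- which(mask)
  Kt <- sum(counts[, cols, drop = FALSE])
  if (Kt == 0) return(NULL)
  kv <- counts[cbind(hap_bv[cols], cols)]
  kb <- counts[cbind(hap_bb[cols], cols)]
  same <- hap_bv[cols] == hap_bb[cols]
  ktot <- colSums(counts[, cols, drop = FALSE])
  list(Kt = Kt,
       Kv_all = sum(kv), Kb_all = sum(kb),
       Km_same = sum(kv[same]), Kt_same = sum(ktot[same]),
       Kv_diff = sum(kv[!same]), Kb_diff = sum(kb[!same]),
       Ko_diff = sum(ktot[!same]) - sum(kv[!same]) - sum(kb[!same]))
}

#' Call the ML diplotype of one sample for a fixed haplotype pair
#'
#' @inheritParams diplotype_loglik
#' @return one-row data.frame: `state` (`MISSING` when no usable data),
#'   ln-likelihood triple, `support` (ln-units gap between best and
#'   second-best state) and `alpha_hat`.
#' @export
call_diplotype <- function(counts, hap_bv, hap_bb, epsilon = 0.005) {
  lb <- diplotype_loglik(counts, hap_bv, hap_bb, "BbHOM", epsilon)
  lh <- diplotype_loglik(counts, hap_bv, hap_bb, "HET", epsilon)
  lv <- diplotype_loglik(counts, hap_bv, hap_bb, "BvHOM", epsilon)
  lnl <- c(lb$lnL, lh$lnL, lv$lnL)
  if (anyNA(lnl)) {
    return(data.frame(state = "MISSING", lnL_BbHOM = NA_real_,
                      lnL_HET = NA_real_, lnL_BvHOM = NA_real_,
                      support = NA_real_, alpha_hat = NA_real_,
                      stringsAsFactors = FALSE))
  }
  best <- which.max(lnl)
  data.frame(state = DM_DIPLOTYPES[best],
             lnL_BbHOM = lnl[1], lnL_HET = lnl[2], lnL_BvHOM = lnl[3],
             support = lnl[best] - max(lnl[-best]),
             alpha_hat = lh$alpha_hat, stringsAsFactors = FALSE)
}

#' Extract candidate haplotypes from a cluster set
#'
#' Reduces each cluster's pooled counts to a strict majority consensus,
#' drops empty consensuses and duplicates (keeping the occurrence from the
#' cluster nearest the Bv axis).
#'
#' @param cluster_set a `cluster_set` carrying pooled counts.
#' @return list of candidates, each a list with `states` (integer haplotype),
#'   `angle` and `cluster_id`.
#' @export
candidate_haplotypes <- function(cluster_set) {
  cls <- cluster_set$clusters
  cls <- cls[order(vapply(cls, `[[`, numeric(1), "mean_angle"))]
  out <- list()
  seen <- character()
  for (cl in cls) {
    if (is.null(cl$pooled_counts) || sum(cl$pooled_counts) == 0) next
    hap <- consensus_haplotype(cl$pooled_counts)
    if (all(is.na(hap))) next
    key <- paste(ifelse(is.na(hap), ".", hap), collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- list(states = hap, angle = cl$mean_angle,
                                   cluster_id = cl$id)
  }
  out
}

#' Coestimate the ML taxon haplotype pair and all sample diplotypes
#'
#' For every candidate haplotype pair, the total score is the sum over
#' samples of the best diplotype log-likelihood; the ML pair maximizes this
#' total under the Mendelian three-diplotype model. Orientation follows
#' cluster geometry: the pair member whose source cluster sits nearer the Bv
#' axis (smaller angle) is labelled Bv; angle ties are resolved by evaluating
#' both orientations. After pair selection, the taxon haplotypes are refined
#' once by pooling the raw counts of all samples called BvHOM (resp. BbHOM)
#' and recomputing the strict majority consensus, followed by one re-calling
#' pass. F0/F1 calls are compared with the expected pattern (grandsire BvHOM,
#' granddam BbHOM, all F1 HET) and the locus is flagged -- not dropped --
#' when violated, surfacing the manual rescoring queue.
#'
#' @param counts_list named list of per-sample 6 x n count matrices.
#' @param candidates candidate list from [candidate_haplotypes()] (or built
#'   by hand: each element needs `states` and `angle`).
#' @param pedigree optional pedigree for the F0/F1 pattern check.
#' @param epsilon error-model parameter passed to [diplotype_loglik()].
#' @return list with `hap_bv`, `hap_bb` (refined), `calls` (data.frame with
#'   one row per sample), `pair_support`, `total_lnL` (best pair total before
#'   refinement, comparable to an exhaustive search), `flags` and
#'   `pair_table`.
#' @export
coestimate_locus <- function(counts_list, candidates, pedigree = NULL,
                             epsilon = 0.005) {
  flags <- character()
  keys <- vapply(candidates, function(h)
    paste(ifelse(is.na(h$states), ".", h$states), collapse = ""), character(1))
  candidates <- candidates[!duplicated(keys)]
  if (length(candidates) < 2) {
    flags <- c(flags, "unresolvable")
    calls <- missing_calls(names(counts_list))
    return(list(hap_bv = NULL, hap_bb = NULL, calls = calls,
                pair_support = NA_real_, total_lnL = NA_real_,
                flags = flags, pair_table = NULL))
  }
  angs <- vapply(candidates, `[[`, numeric(1), "angle")

  pairs <- list()
  for (i in seq_along(candidates)) {
    for (j in seq_along(candidates)) {
      if (i >= j) next
      if (angs[i] < angs[j]) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      } else if (angs[i] > angs[j]) {
        pairs[[length(pairs) + 1]] <- c(j, i)
      } else {
        pairs[[length(pairs) + 1]] <- c(i, j)
        pairs[[length(pairs) + 1]] <- c(j, i)
      }
    }
  }
  totals <- numeric(length(pairs))
  call_sets <- vector("list", length(pairs))
  for (p in seq_along(pairs)) {
    bv <- candidates[[pairs[[p]][1]]]$states
    bb <- candidates[[pairs[[p]][2]]]$states
    cs <- lapply(counts_list, call_diplotype, hap_bv = bv, hap_bb = bb,
                 epsilon = epsilon)
    best_lnl <- vapply(cs, function(r)
      if (r$state == "MISSING") 0 else max(r$lnL_BbHOM, r$lnL_HET, r$lnL_BvHOM),
      numeric(1))
    totals[p] <- sum(best_lnl)
    call_sets[[p]] <- cs
  }
  ord <- order(totals, decreasing = TRUE)
  best <- ord[1]
  pair_support <- if (length(totals) > 1) totals[best] - totals[ord[2]] else NA_real_
  hap_bv <- candidates[[pairs[[best]][1]]]$states
  hap_bb <- candidates[[pairs[[best]][2]]]$states

  calls <- do.call(rbind, call_sets[[best]])
  calls <- data.frame(sample_id = names(counts_list), calls,
                      row.names = NULL, stringsAsFactors = FALSE)

  # one refinement pass: pool all homozygote-called samples per taxon
  ref_bv <- refine_hap(counts_list[calls$sample_id[calls$state == "BvHOM"]], hap_bv)
  ref_bb <- refine_hap(counts_list[calls$sample_id[calls$state == "BbHOM"]], hap_bb)
  if (!identical(ref_bv, ref_bb) &&
      (!identical(ref_bv, hap_bv) || !identical(ref_bb, hap_bb))) {
    hap_bv <- ref_bv
    hap_bb <- ref_bb
    cs <- lapply(counts_list, call_diplotype, hap_bv = hap_bv, hap_bb = hap_bb,
                 epsilon = epsilon)
    calls <- data.frame(sample_id = names(counts_list), do.call(rbind, cs),
                        row.names = NULL, stringsAsFactors = FALSE)
  }

  if (!is.null(pedigree) && !check_f0f1_pattern(calls, pedigree))
    flags <- c(flags, "expected_F0F1_pattern_violated")

  list(hap_bv = hap_bv, hap_bb = hap_bb, calls = calls,
       pair_support = pair_support, total_lnL = totals[best], flags = flags,
       pair_table = data.frame(
         bv = vapply(pairs, `[`, numeric(1), 1),
         bb = vapply(pairs, `[`, numeric(1), 2),
         total_lnL = totals))
}

refine_hap <- function(counts_subset, fallback) {
  if (!length(counts_subset)) return(fallback)
  hap <- consensus_haplotype(Reduce(`+`, counts_subset))
  if (all(is.na(hap))) fallback else hap
}

missing_calls <- function(ids) {
  data.frame(sample_id = ids, state = "MISSING", lnL_BbHOM = NA_real_,
             lnL_HET = NA_real_, lnL_BvHOM = NA_real_, support = NA_real_,
             alpha_hat = NA_real_, stringsAsFactors = FALSE)
}

check_f0f1_pattern <- function(calls, pedigree) {
  st <- setNames(calls$state, calls$sample_id)
  sire <- pedigree$sample_id[pedigree$role == "grandsire_Bv"]
  dam <- pedigree$sample_id[pedigree$role == "granddam_Bb"]
  f1 <- pedigree$sample_id[pedigree$generation == "F1"]
  ok <- TRUE
  if (sire %in% names(st)) ok <- ok && identical(unname(st[sire]), "BvHOM")
  if (dam %in% names(st)) ok <- ok && identical(unname(st[dam]), "BbHOM")
  f1 <- intersect(f1, names(st))
  if (length(f1)) ok <- ok && all(st[f1] == "HET")
  ok
}

#' Full per-locus diplotyping pipeline
#'
#' Runs the complete heuristic-plus-likelihood workflow for one locus:
#' initial polarized matrix from the two grandparents, sample scoring,
#' clustering, one high-coverage polarized-matrix update from the two
#' axis-nearest clusters followed by one re-scoring and re-clustering pass,
#' strict-majority candidate haplotypes, and Mendelian ML coestimation of
#' the taxon haplotype pair and all sample diplotypes.
#'
#' @param lc a `locus_counts` object (one element of `sync_data$loci`).
#' @param pedigree pedigree data.frame; identifies the two grandparents and
#'   supplies F2 sexes for cluster tallies.
#' @param epsilon error-model parameter.
#' @param r_min_frac,k_max clustering controls, see [cluster_scores()].
#' @return object of class `locus_diplotypes`: list with `locus_id`, `calls`,
#'   `hap_bv`, `hap_bb`, `clusters`, `scores`, `mp`, `pair_support`,
#'   `total_lnL` and `flags`.
#' @export
diplotype_locus <- function(lc, pedigree, epsilon = 0.005,
                            r_min_frac = 0.05, k_max = 6) {
  sire <- pedigree$sample_id[pedigree$role == "grandsire_Bv"]
  dam <- pedigree$sample_id[pedigree$role == "granddam_Bb"]
  if (!all(c(sire, dam) %in% names(lc$counts)))
    stop_fmt("locus %s: grandparent sample(s) absent from counts", lc$locus_id)
  sexes <- setNames(pedigree$sex, pedigree$sample_id)
  sexes <- sexes[pedigree$generation == "F2" & pedigree$sex %in% c("male", "female")]

  mp <- polarize(lc$counts[[sire]], lc$counts[[dam]], source = "initial_F0")
  scores <- score_samples(lc$counts, mp)
  if (all(scores$radius == 0)) {
    return(structure(list(locus_id = lc$locus_id,
                          calls = missing_calls(names(lc$counts)),
                          hap_bv = NULL, hap_bb = NULL,
                          clusters = NULL, scores = scores, mp = mp,
                          pair_support = NA_real_, total_lnL = NA_real_,
                          flags = "no_variants"),
                     class = "locus_diplotypes"))
  }
  cs <- cluster_scores(scores, counts_list = lc$counts, sexes = sexes,
                       r_min_frac = r_min_frac, k_max = k_max)
  if (cs$k >= 2) {
    mp2 <- update_polarized_matrix(cs)
    scores2 <- score_samples(lc$counts, mp2)
    if (!all(scores2$radius == 0)) {
      mp <- mp2
      scores <- scores2
      cs <- cluster_scores(scores, counts_list = lc$counts, sexes = sexes,
                           r_min_frac = r_min_frac, k_max = k_max)
    }
  }
  cand <- candidate_haplotypes(cs)
  co <- coestimate_locus(lc$counts, cand, pedigree = pedigree, epsilon = epsilon)
  structure(list(locus_id = lc$locus_id, calls = co$calls,
                 hap_bv = co$hap_bv, hap_bb = co$hap_bb,
                 clusters = cs, scores = scores, mp = mp,
                 pair_support = co$pair_support, total_lnL = co$total_lnL,
                 flags = co$flags),
            class = "locus_diplotypes")
}

#' Diplotype every locus of a sync data set
#'
#' @param sync a `sync_data` object.
#' @param pedigree pedigree data.frame.
#' @param ... passed to [diplotype_locus()].
#' @return list with `loci` (per-locus `locus_diplotypes` results) and
#'   `calls`, the combined long-format call data.frame.
#' @export
diplotype_all <- function(sync, pedigree, ...) {
  res <- lapply(sync$loci, diplotype_locus, pedigree = pedigree, ...)
  calls <- do.call(rbind, lapply(res, function(r)
    data.frame(locus_id = r$locus_id, r$calls, row.names = NULL,
               stringsAsFactors = FALSE)))
  rownames(calls) <- NULL
  list(loci = res, calls = calls)
}

#' Rescore samples at a locus from an annotated variant whitelist
#'
#' The manual-curation path: taxon haplotypes are defined only at the
#' whitelisted positions (all other columns masked) and every sample is
#' re-called with the identical likelihood machinery. Samples with zero depth
#' at every whitelist column come back MISSING.
#'
#' @param counts_list named list of per-sample 6 x n count matrices.
#' @param whitelist data.frame rows for this locus from
#'   [read_variant_whitelist()].
#' @param n locus length (number of reference positions).
#' @param epsilon error-model parameter.
#' @return call data.frame, one row per sample.
#' @export
rescore_with_whitelist <- function(counts_list, whitelist, n, epsilon = 0.005) {
  if (!nrow(whitelist)) stop_fmt("whitelist for locus has no entries")
  if (any(whitelist$pos > n))
    stop_fmt("whitelist position %d beyond locus length %d",
             whitelist$pos[whitelist$pos > n][1], n)
  hap_bv <- rep(NA_integer_, n)
  hap_bb <- rep(NA_integer_, n)
  hap_bv[whitelist$pos] <- state_index(whitelist$state_bv)
  hap_bb[whitelist$pos] <- state_index(whitelist$state_bb)
  cs <- lapply(counts_list, call_diplotype, hap_bv = hap_bv, hap_bb = hap_bb,
               epsilon = epsilon)
  data.frame(sample_id = names(counts_list), do.call(rbind, cs),
             row.names = NULL, stringsAsFactors = FALSE)
}
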