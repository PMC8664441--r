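#' Per-locus, per-family segregation-distortion chi-square
#'
#' Tests the F2 diplotype counts of each family against the Mendelian 1:2:1
#' expectation (expected N/4, N/2, N/4 of the N non-missing calls;
#' `chi2 = sum (obs - exp)^2 / exp`, df = 2). MISSING calls are excluded;
#' families with no informative calls get NA statistics.
#'
#' @param calls long-format call data.frame (`locus_id`, `sample_id`,
#'   `state`).
#' @param pedigree pedigree data.frame; only F2 samples are used and the
#'   family labels come from it.
#' @return data.frame with one row per locus x family: counts `n_BbHOM`,
#'   `n_HET`, `n_BvHOM`, `chi2`, `p_value`.
#' @export
segregation_chisq <- function(calls, pedigree) {
  f2 <- pedigree[pedigree$generation == "F2", , drop = FALSE]
  fam <- setNames(f2$family, f2$sample_id)
  sub <- calls[calls$sample_id %in% f2$sample_id, , drop = FALSE]
  sub$family <- fam[sub$sample_id]
  out <- do.call(rbind, lapply(split(sub, list(sub$locus_id, sub$family), drop = TRUE),
    function(d) {
      st <- d$state[d$state %in% DM_DIPLOTYPES]
      n <- length(st)
      obs <- c(sum(st == "BbHOM"), sum(st == "HET"), sum(st == "BvHOM"))
      if (n == 0) {
        chi2 <- p <- NA_real_
      } else {
        expd <- n * c(0.25, 0.5, 0.25)
        chi2 <- sum((obs - expd)^2 / expd)
        p <- pchisq(chi2, df = 2, lower.tail = FALSE)
      }
      data.frame(locus_id = d$locus_id[1], family = d$family[1],
                 n_BbHOM = obs[1], n_HET = obs[2], n_BvHOM = obs[3],
                 n = n, chi2 = chi2, p_value = p, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$locus_id, out$family), , drop = FALSE]
}

#' Flag segregation records against dual significance thresholds
#'
#' Lower threshold: Bonferroni correction dividing `alpha` by the number of
#' chromosome arms (`chi2 > qchisq(1 - alpha/n_arms, 2)`, equivalently
#' `-2 ln(alpha/n_arms)` for df 2). Upper threshold: Benjamini-Hochberg
#' step-up across all locus x family p-values at experiment-wise `alpha`.
#'
#' @param records output of [segregation_chisq()].
#' @param n_arms number of chromosome arms used for the Bonferroni
#'   denominator (default 24).
#' @param alpha experiment-wise significance level (default 0.05).
#' @return `records` with logical columns `exceeds_bonferroni` and
#'   `exceeds_bh` added; the Bonferroni chi-square critical value is attached
#'   as attribute `chi2_bonferroni`.
#' @export
significance_thresholds <- function(records, n_arms = 24, alpha = 0.05) {
  crit <- qchisq(1 - alpha / n_arms, df = 2)
  records$exceeds_bonferroni <- !is.na(records$chi2) & records$chi2 > crit
  adj <- p.adjust(records$p_value, method = "BH")
  records$exceeds_bh <- !is.na(adj) & adj <= alpha
  attr(records, "chi2_bonferroni") <- crit
  records
}

#' Reduce linkage-map bins to one locus per map position
#'
#' For every bin (set of loci sharing a cM position within a linkage group)
#' with two or more loci, counts pairwise diplotype differences across F2
#' individuals (pairs with a MISSING call in either member are skipped).
#' While the maximum pairwise difference exceeds `max_diff` (default 3), the
#' locus with the largest summed differences is removed; one survivor is then
#' picked uniformly at random under `seed`. Loci exceeding the lower
#' (Bonferroni) segregation threshold are removed before binning when
#' `records` are supplied. Singleton bins pass through.
#'
#' @param map map data.frame (`locus_id`, `linkage_group`, `position_cM`).
#' @param calls long-format call data.frame restricted to (or containing) F2
#'   samples.
#' @param pedigree pedigree used to restrict calls to F2 individuals.
#' @param records optional flagged records from [significance_thresholds()];
#'   loci with `exceeds_bonferroni` in any family are dropped first.
#' @param seed integer seed for the random survivor pick.
#' @param max_diff tolerated maximum pairwise difference (default 3).
#' @return list with `bins` (per multi-locus bin: `linkage_group`,
#'   `position_cM`, `members`, `removed`, `selected`, `max_diff_before`,
#'   `max_diff_after`) and `reduced_loci`, the one-locus-per-position vector.
#' @export
reduce_bins <- function(map, calls, pedigree, records = NULL, seed = 1,
                        max_diff = 3) {
  f2 <- pedigree$sample_id[pedigree$generation == "F2"]
  keep <- map$locus_id
  if (!is.null(records)) {
    distorted <- unique(records$locus_id[records$exceeds_bonferroni])
    keep <- setdiff(keep, distorted)
  }
  sub <- calls[calls$sample_id %in% f2 & calls$locus_id %in% keep, , drop = FALSE]
  st <- matrix(NA_character_, length(keep), length(f2),
               dimnames = list(keep, f2))
  st[cbind(match(sub$locus_id, keep), match(sub$sample_id, f2))] <-
    ifelse(sub$state %in% DM_DIPLOTYPES, sub$state, NA_character_)

  m <- map[map$locus_id %in% keep, , drop = FALSE]
  key <- paste(m$linkage_group, m$position_cM, sep = "@")
  groups <- split(m$locus_id, key)

  bins <- list()
  reduced <- character()
  with_seed(seed, {
    for (k in sort(names(groups))) {
      loci <- sort(groups[[k]])
      if (length(loci) == 1L) {
        reduced <- c(reduced, loci)
        next
      }
      D <- pairwise_diff_matrix(st[loci, , drop = FALSE])
      before <- max(D)
      removed <- character()
      while (max(D) > max_diff && nrow(D) > 1L) {
        worst <- which.max(rowSums(D))
        removed <- c(removed, rownames(D)[worst])
        D <- D[-worst, -worst, drop = FALSE]
      }
      survivors <- rownames(D)
      if (!length(survivors)) {
        warning(sprintf("bin %s empty after outlier removal; dropped", k))
        next
      }
      selected <- survivors[sample.int(length(survivors), 1L)]
      reduced <- c(reduced, selected)
      lg <- m$linkage_group[match(loci[1], m$locus_id)]
      cm <- m$position_cM[match(loci[1], m$locus_id)]
      bins[[length(bins) + 1]] <- list(
        linkage_group = lg, position_cM = cm, members = loci,
        removed = removed, selected = selected,
        max_diff_before = before, max_diff_after = max(D))
    }
  })
  list(bins = bins, reduced_loci = reduced)
}

# counts, per locus pair, the F2 individuals with unequal non-missing calls
pairwise_diff_matrix <- function(st) {
  L <- nrow(st)
  D <- matrix(0, L, L, dimnames = list(rownames(st), rownames(st)))
  for (a in seq_len(L - 1)) {
    for (b in (a + 1):L) {
      ok <- !is.na(st[a, ]) & !is.na(st[b, ])
      D[a, b] <- D[b, a] <- sum(st[a, ok] != st[b, ok])
    }
  }
  D
}
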