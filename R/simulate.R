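#' Inverse Kosambi map function: cM distance to recombination fraction
#'
#' `r = 0.5 * tanh(2 d)` with `d` in Morgans; bounded below 0.5, consistent
#' with a map built under the Kosambi function. No crossover interference is
#' modelled beyond what Kosambi implies between adjacent intervals.
#'
#' @param cM map distance in centimorgans.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
kosambi_r <- function(cM) 0.5 * tanh(2 * cM / 100)

#' Simulation configuration for a three-generation cross
#'
#' The defaults emulate the targeted-capture study conditions: mean locus
#' length 673 bp, between-taxon divergence d_xy lognormal with mean 0.0202
#' and mode 0.013, two F2 families of 80 and 82, mean coverage 147x with a
#' center-peaked profile (plateau over the central 250 bp bait span, linear
#' decay to 10% at the termini), sequencing error 0.005, overmerging
#' contamination on 20% of loci, and capture bias 0.55 toward the Bv taxon in
#' heterozygotes (baits designed from the Bv assembly).
#'
#' @param n_loci number of loci.
#' @param locus_length list with `mean`, `sd`, `min` (bp).
#' @param d_xy list with either `meanlog`/`sdlog` (lognormal) or `const`.
#'   Defaults solve mean 0.0202 / mode 0.013.
#' @param n_lg number of linkage groups.
#' @param lg_length_cM linkage-group length in cM.
#' @param family_sizes F2 offspring per family.
#' @param coverage mean read depth at the profile peak.
#' @param coverage_profile list with `plateau` (bp at full coverage, centred)
#'   and `edge_frac` (relative depth at the termini).
#' @param epsilon_seq per-read sequencing error probability.
#' @param overmerge list with `frac_loci` (fraction of loci receiving
#'   contamination), `pos_frac` (fraction of positions in the contaminated
#'   terminal block) and `depth_frac` (contaminant depth relative to peak
#'   coverage). Off-target reads pile up over a contiguous block at a
#'   randomly chosen locus end, in every sample, creating consistently
#'   heterozygous-looking sites.
#' @param capture_bias expected Bv read fraction in true heterozygotes.
#' @param sd_locus `NULL`, or list with `lg` and `cM` placing the
#'   sex-determining locus.
#' @param sex_hap `NULL`, or list with `offset_cM` and `divergence`: adds a
#'   locus near the SD locus where the heterogametic F0 carries a diverged
#'   sex-linked haplotype (in phase with Y under XY, with W under ZW).
#' @param system `"XY"` or `"ZW"`.
#' @param seed integer seed; fully determines the simulation.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 24,
                       locus_length = list(mean = 673, sd = 80, min = 300),
                       d_xy = list(meanlog = -4.0487, sdlog = 0.5419),
                       n_lg = 12,
                       lg_length_cM = 130,
                       family_sizes = c(80, 82),
                       coverage = 147,
                       coverage_profile = list(plateau = 250, edge_frac = 0.1),
                       epsilon_seq = 0.005,
                       overmerge = list(frac_loci = 0.2, pos_frac = 0.1,
                                        depth_frac = 0.5),
                       capture_bias = 0.55,
                       sd_locus = NULL,
                       sex_hap = NULL,
                       system = c("XY", "ZW"),
                       seed = 1) {
  system <- match.arg(system)
  probs <- c(epsilon_seq, overmerge$frac_loci, overmerge$pos_frac,
             capture_bias, coverage_profile$edge_frac)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must lie in [0, 1]")
  if (!is.null(sex_hap) && is.null(sd_locus))
    stop_fmt("sex_hap requires sd_locus")
  if (!is.null(sex_hap)) {
    sex_hap$offset_cM <- sex_hap$offset_cM %||% 5
    sex_hap$divergence <- sex_hap$divergence %||% 0.04
  }
  structure(list(n_loci = n_loci, locus_length = locus_length, d_xy = d_xy,
                 n_lg = n_lg, lg_length_cM = lg_length_cM,
                 family_sizes = family_sizes, coverage = coverage,
                 coverage_profile = coverage_profile,
                 epsilon_seq = epsilon_seq, overmerge = overmerge,
                 capture_bias = capture_bias, sd_locus = sd_locus,
                 sex_hap = sex_hap, system = system,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Named simulation presets
#'
#' * `"clean"`: no sequencing error, no overmerging, no capture bias.
#' * `"paper"`: the study-like noise regime (147x, error 0.005, 20%
#'   overmerged loci, capture bias 0.55).
#' * `"novariant"`: d_xy = 0 with error-free reads, so no locus carries any
#'   variation at all (the degenerate no-signal input).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
preset_config <- function(preset = c("paper", "clean", "novariant"),
                          seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    paper = list(),
    clean = list(epsilon_seq = 0,
                 overmerge = list(frac_loci = 0, pos_frac = 0, depth_frac = 0),
                 capture_bias = 0.5),
    novariant = list(d_xy = list(const = 0), epsilon_seq = 0,
                     overmerge = list(frac_loci = 0, pos_frac = 0,
                                      depth_frac = 0)))
  do.call(sim_config, c(args, list(seed = seed), list(...)))
}

taxon_of_code <- c(bv = "Bv", y = "Bv", bb = "Bb", w = "Bb")

#' Simulate the pedigree, haplotypes and true diplotypes of a cross
#'
#' The two F0 founders are fixed for their taxon haplotypes, which differ at
#' Binomial(length, d_xy) positions per locus. All F1 are heterozygous
#' everywhere. F2 gametes recombine between adjacent loci of a linkage group
#' with the inverse-Kosambi fraction of their cM gap. With an SD locus, sex
#' follows the transmission of the heterogametic F1 parent's sex chromosome
#' (XY: the F1 father's Bv-labelled Y makes sons), so at the SD locus no male
#' is BbHOM and no female is BvHOM; without one, sex is assigned 1:1 at
#' random. An optional sex-linked diverged haplotype rides the heterogametic
#' F0's sex chromosome at a locus near the SD position.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_truth`: `config`, `map`, `pedigree`, `loci`
#'   (haplotypes and metadata), `hapcodes` (per locus, 2 x samples character
#'   matrix over codes bv/bb/y/w), `diplotypes` (loci x samples character
#'   matrix of true states), `sd_locus_id`, `sex_hap_locus_id`.
#' @export
simulate_pedigree_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, sim_genomes_impl(config))
}

sim_genomes_impl <- function(cf) {
  n_loci <- cf$n_loci
  lg <- rep_len(seq_len(cf$n_lg), n_loci)
  cm <- runif(n_loci, 0, cf$lg_length_cM)
  ids <- sprintf("L%04d", seq_len(n_loci))
  sd_id <- hap_id <- NULL
  if (!is.null(cf$sd_locus)) {
    cand <- which(lg == cf$sd_locus$lg)
    if (!length(cand)) {
      lg[1] <- cf$sd_locus$lg
      cand <- 1L
    }
    sd_i <- cand[1]
    cm[sd_i] <- cf$sd_locus$cM
    sd_id <- ids[sd_i]
    if (!is.null(cf$sex_hap)) {
      hc <- setdiff(which(lg == cf$sd_locus$lg), sd_i)
      if (!length(hc)) {
        hc <- if (n_loci >= 2) 2L else stop_fmt("sex_hap needs at least 2 loci")
        lg[hc] <- cf$sd_locus$lg
      }
      hap_i <- hc[1]
      cm[hap_i] <- min(cf$sd_locus$cM + cf$sex_hap$offset_cM, cf$lg_length_cM)
      hap_id <- ids[hap_i]
    }
  }
  len <- pmax(round(rnorm(n_loci, cf$locus_length$mean, cf$locus_length$sd)),
              cf$locus_length$min)
  dxy <- if (!is.null(cf$d_xy$const)) rep(cf$d_xy$const, n_loci)
         else rlnorm(n_loci, cf$d_xy$meanlog, cf$d_xy$sdlog)

  loci <- vector("list", n_loci)
  names(loci) <- ids
  for (i in seq_len(n_loci)) {
    n <- len[i]
    bv <- sample.int(4L, n, replace = TRUE)
    bb <- bv
    nv <- rbinom(1, n, min(dxy[i], 1))
    if (nv > 0) {
      at <- sample.int(n, nv)
      bb[at] <- ((bv[at] - 1L + sample.int(3L, nv, replace = TRUE)) %% 4L) + 1L
    }
    y <- NULL
    if (!is.null(hap_id) && ids[i] == hap_id) {
      y <- bv
      ne <- rbinom(1, n, cf$sex_hap$divergence)
      if (ne > 0) {
        at <- sample.int(n, ne)
        # a third state, different from both taxon haplotypes
        for (p in at) y[p] <- setdiff(1:4, c(bv[p], bb[p]))[1]
      }
    }
    loci[[i]] <- list(locus_id = ids[i], linkage_group = lg[i],
                      position_cM = cm[i], n = n, d_xy = dxy[i],
                      hap_bv = bv, hap_bb = bb, hap_sex = y)
  }
  map <- validate_map(data.frame(locus_id = ids, linkage_group = lg,
                                 position_cM = cm, stringsAsFactors = FALSE))

  # pedigree
  fam_labels <- as.character(seq(6, length.out = length(cf$family_sizes)))
  f2_ids <- unlist(lapply(seq_along(cf$family_sizes), function(f)
    sprintf("F2_%s_%03d", fam_labels[f], seq_len(cf$family_sizes[f]))))
  f2_fam <- rep(fam_labels, cf$family_sizes)
  mothers <- paste0("F1_MOTHER_", fam_labels)
  ped <- data.frame(
    sample_id = c("BV_F0", "BB_F0", "F1_FATHER", mothers, f2_ids),
    generation = c("F0", "F0", rep("F1", 1 + length(mothers)),
                   rep("F2", length(f2_ids))),
    role = c("grandsire_Bv", "granddam_Bb", "F1_father",
             rep("F1_mother", length(mothers)), rep("offspring", length(f2_ids))),
    family = c("", "", "", fam_labels, f2_fam),
    sex = c("male", "female", "male", rep("female", length(mothers)),
            rep("unknown", length(f2_ids))),
    stringsAsFactors = FALSE)

  # sex-linked copy codes for the F1 parents: code_v = grandsire-derived copy,
  # code_b = granddam-derived copy, per locus
  parents <- c("F1_FATHER", mothers)
  code_v <- matrix("bv", n_loci, length(parents), dimnames = list(ids, parents))
  code_b <- matrix("bb", n_loci, length(parents), dimnames = list(ids, parents))
  if (!is.null(hap_id)) {
    r_link <- kosambi_r(abs(cm[match(hap_id, ids)] - cm[match(sd_id, ids)]))
    if (cf$system == "XY") {
      # diverged haplotype is in phase with the grandsire's Y
      code_v[hap_id, "F1_FATHER"] <-
        if (runif(1) > r_link) "y" else "bv"        # father inherited the Y
      for (mo in mothers)                            # mothers inherited the X
        code_v[hap_id, mo] <- if (runif(1) > r_link) "bv" else "y"
    } else {
      # diverged haplotype in phase with the granddam's W; F1 females carry W
      for (mo in mothers)
        code_b[hap_id, mo] <- if (runif(1) > r_link) "w" else "bb"
      code_b[hap_id, "F1_FATHER"] <- if (runif(1) > r_link) "bb" else "w"
    }
  }

  # F2 gametes: per parent, per linkage group, a Markov chain of taxon labels
  n_f2 <- length(f2_ids)
  pat_lab <- mat_lab <- matrix(NA, n_f2, n_loci, dimnames = list(f2_ids, ids))
  for (g in seq_len(cf$n_lg)) {
    on_g <- which(lg == g)
    on_g <- on_g[order(cm[on_g])]
    if (!length(on_g)) next
    r <- kosambi_r(diff(cm[on_g]))
    for (side in c("pat", "mat")) {
      labs <- matrix(FALSE, n_f2, length(on_g))  # TRUE = Bv label
      labs[, 1] <- runif(n_f2) < 0.5
      if (length(on_g) > 1) {
        for (l in 2:length(on_g)) {
          flip <- runif(n_f2) < r[l - 1]
          labs[, l] <- xor(labs[, l - 1], flip)
        }
      }
      if (side == "pat") pat_lab[, on_g] <- labs else mat_lab[, on_g] <- labs
    }
  }

  # sex assignment
  if (!is.null(sd_id)) {
    sd_i <- match(sd_id, ids)
    if (cf$system == "XY") {
      sex_f2 <- ifelse(pat_lab[, sd_i], "male", "female")
    } else {
      sex_f2 <- ifelse(mat_lab[, sd_i], "male", "female")
    }
  } else {
    sex_f2 <- ifelse(runif(n_f2) < 0.5, "male", "female")
  }
  ped$sex[match(f2_ids, ped$sample_id)] <- sex_f2

  # per-locus haplotype-code matrix for every sample
  all_ids <- ped$sample_id
  mother_of <- setNames(mothers, fam_labels)
  hapcodes <- vector("list", n_loci)
  names(hapcodes) <- ids
  diplo <- matrix(NA_character_, n_loci, length(all_ids),
                  dimnames = list(ids, all_ids))
  for (i in seq_len(n_loci)) {
    hc <- matrix("bb", 2, length(all_ids), dimnames = list(NULL, all_ids))
    is_hap <- !is.null(hap_id) && ids[i] == hap_id
    hc[, "BV_F0"] <- if (is_hap && cf$system == "XY") c("bv", "y") else "bv"
    hc[, "BB_F0"] <- if (is_hap && cf$system == "ZW") c("bb", "w") else "bb"
    for (pr in parents) hc[, pr] <- c(code_v[i, pr], code_b[i, pr])
    pv <- ifelse(pat_lab[, i], code_v[i, "F1_FATHER"], code_b[i, "F1_FATHER"])
    mo <- mother_of[f2_fam]
    mv <- ifelse(mat_lab[, i],
                 code_v[cbind(i, match(mo, parents))],
                 code_b[cbind(i, match(mo, parents))])
    hc[1, f2_ids] <- pv
    hc[2, f2_ids] <- mv
    hapcodes[[i]] <- hc
    tx <- matrix(taxon_of_code[hc], 2)
    diplo[i, ] <- ifelse(tx[1, ] == "Bv" & tx[2, ] == "Bv", "BvHOM",
                  ifelse(tx[1, ] == "Bb" & tx[2, ] == "Bb", "BbHOM", "HET"))
  }

  structure(list(config = cf, map = map, pedigree = validate_pedigree(ped),
                 loci = loci, hapcodes = hapcodes, diplotypes = diplo,
                 sd_locus_id = sd_id, sex_hap_locus_id = hap_id),
            class = "sim_truth")
}

coverage_profile_vec <- function(n, plateau, edge_frac) {
  if (n <= plateau) return(rep(1, n))
  half <- (n - plateau) / 2
  pos <- seq_len(n)
  lo <- ceiling(half)
  hi <- n - lo + 1
  p <- rep(1, n)
  left <- pos < lo
  right <- pos > n - lo
  p[left] <- edge_frac + (1 - edge_frac) * (pos[left] - 1) / half
  p[right] <- edge_frac + (1 - edge_frac) * (n - pos[right]) / half
  p
}

#' Simulate read-count matrices for a cross
#'
#' Per position, depth is Poisson around `coverage x profile(position)`.
#' Reads are drawn from the individual's two haplotypes, with Bv-probability
#' `capture_bias` when the two carried haplotypes belong to different taxa
#' (enrichment bias; 0.5 within a taxon). Sequencing errors flip a read to a
#' uniformly chosen other state with probability `epsilon_seq`. Overmerged
#' loci receive additive contaminant reads carrying a locus-unrelated paralog
#' haplotype, piling up over a terminal block of positions in ALL samples,
#' which is what creates consistently heterozygous-looking sites.
#'
#' @param truth a `sim_truth` from [simulate_pedigree_genomes()].
#' @param config the same `sim_config`.
#' @param path optional path; when given the sync file is written there.
#' @return a `sync_data` object (invisibly written to `path` if requested).
#' @export
simulate_reads <- function(truth, config, path = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  sync <- with_seed(config$seed + 1000003L, sim_reads_impl(truth, config))
  if (!is.null(path)) write_sync(sync, path)
  sync
}

sim_reads_impl <- function(truth, cf) {
  ids <- truth$pedigree$sample_id
  loci_out <- vector("list", length(truth$loci))
  names(loci_out) <- names(truth$loci)
  for (lid in names(truth$loci)) {
    lo <- truth$loci[[lid]]
    n <- lo$n
    prof <- coverage_profile_vec(n, cf$coverage_profile$plateau,
                                 cf$coverage_profile$edge_frac)
    lambda <- cf$coverage * prof
    hapset <- list(bv = lo$hap_bv, bb = lo$hap_bb, y = lo$hap_sex, w = lo$hap_sex)
    # overmerging contamination shared by all samples at this locus:
    # off-target reads pile up over a terminal block at one end
    contam <- NULL
    if (cf$overmerge$frac_loci > 0 && runif(1) < cf$overmerge$frac_loci) {
      npos <- max(1L, round(cf$overmerge$pos_frac * n))
      cpos <- if (runif(1) < 0.5) seq_len(npos) else seq(n - npos + 1L, n)
      contam <- list(pos = cpos,
                     hap = sample.int(4L, npos, replace = TRUE),
                     lambda = rep(cf$overmerge$depth_frac * cf$coverage, npos))
    }
    hc <- truth$hapcodes[[lid]]
    counts <- vector("list", length(ids))
    names(counts) <- ids
    for (s in ids) {
      h1 <- hapset[[hc[1, s]]]
      h2 <- hapset[[hc[2, s]]]
      t1 <- taxon_of_code[hc[1, s]]
      t2 <- taxon_of_code[hc[2, s]]
      p1 <- if (t1 != t2) (if (t1 == "Bv") cf$capture_bias else 1 - cf$capture_bias)
            else 0.5
      d <- rpois(n, lambda)
      k <- rbinom(n, d, p1)
      tmp <- numeric(6L * n)
      off <- 6L * (seq_len(n) - 1L)
      idx1 <- h1 + off
      idx2 <- h2 + off
      tmp[idx1] <- tmp[idx1] + k
      tmp[idx2] <- tmp[idx2] + (d - k)
      if (cf$epsilon_seq > 0) {
        for (src in list(list(idx = idx1, hap = h1, kk = k),
                         list(idx = idx2, hap = h2, kk = d - k))) {
          e <- rbinom(n, src$kk, cf$epsilon_seq)
          if (any(e > 0)) {
            tmp[src$idx] <- tmp[src$idx] - e
            ppos <- rep(seq_len(n), e)
            psrc <- rep(src$hap, e)
            o <- sample.int(5L, length(ppos), replace = TRUE)
            tgt <- o + (o >= psrc)
            tmp <- tmp + tabulate(tgt + 6L * (ppos - 1L), nbins = 6L * n)
          }
        }
      }
      if (!is.null(contam)) {
        cc <- rpois(length(contam$pos), contam$lambda)
        cidx <- contam$hap + 6L * (contam$pos - 1L)
        tmp[cidx] <- tmp[cidx] + cc
      }
      counts[[s]] <- matrix(as.integer(tmp), 6L, n,
                            dimnames = list(DM_STATES, NULL))
    }
    loci_out[[lid]] <- structure(
      list(locus_id = lid, n = n, ref = DM_STATES[lo$hap_bv], counts = counts),
      class = "locus_counts")
  }
  structure(list(samples = ids, loci = loci_out), class = "sync_data")
}

#' Run a complete simulated scenario end to end
#'
#' Simulates genomes and reads, diplotypes every locus, compares calls to the
#' simulated truth, and computes the downstream statistics (segregation
#' chi-square with thresholds, b profile, cluster-sex statistics, and -- when
#' an SD locus is configured -- the SD-region scan and heterogamety verdict).
#'
#' @param config a `sim_config`.
#' @param out_dir optional output directory; when given, writes the sync
#'   file, pedigree/map/truth TSVs, the diplotype matrix, profiles and a JSON
#'   report.
#' @param epsilon error-model parameter used for calling (not the simulated
#'   sequencing error).
#' @return list with `truth`, `sync`, `diplo`, `accuracy`, `confusion`,
#'   `support_gt10`, `missing_rate`, `flagged_loci`, `seg`, `scan`,
#'   `heterogamety` and `report`.
#' @export
run_scenario <- function(config, out_dir = NULL, epsilon = 0.005) {
  truth <- simulate_pedigree_genomes(config)
  sync <- simulate_reads(truth, config)
  diplo <- diplotype_all(sync, truth$pedigree, epsilon = epsilon)

  ped <- truth$pedigree
  f2 <- ped$sample_id[ped$generation == "F2"]
  flags <- lapply(diplo$loci, `[[`, "flags")
  flagged <- names(flags)[lengths(flags) > 0]
  usable <- setdiff(names(diplo$loci), flagged[
    vapply(flags[flagged], function(f)
      any(f %in% c("no_variants", "unresolvable")), logical(1))])

  calls <- diplo$calls
  cm <- matrix(NA_character_, length(truth$loci), length(f2),
               dimnames = list(names(truth$loci), f2))
  sub <- calls[calls$sample_id %in% f2, , drop = FALSE]
  cm[cbind(match(sub$locus_id, rownames(cm)), match(sub$sample_id, f2))] <- sub$state
  tm <- truth$diplotypes[rownames(cm), f2, drop = FALSE]

  use <- rownames(cm) %in% usable
  confusion <- table(truth = tm[use, ], call = cm[use, ])
  accuracy <- if (any(use)) mean(cm[use, ] == tm[use, ]) else NA_real_
  missing_rate <- if (any(use)) mean(cm[use, ] == "MISSING") else NA_real_
  supp <- sub$support[sub$locus_id %in% usable & sub$state != "MISSING"]
  support_gt10 <- if (length(supp)) mean(supp > 10) else NA_real_

  seg <- significance_thresholds(segregation_chisq(calls, ped))
  cluster_sets <- lapply(diplo$loci, `[[`, "clusters")
  sire <- ped$sample_id[ped$role == "grandsire_Bv"]
  dam <- ped$sample_id[ped$role == "granddam_Bb"]
  f0_scores <- do.call(rbind, lapply(diplo$loci, function(r)
    data.frame(locus_id = r$locus_id,
               angle_sire = r$scores$angle[r$scores$sample_id == sire],
               angle_dam = r$scores$angle[r$scores$sample_id == dam])))
  scan <- sex_scan(calls, truth$map, ped, cluster_sets = cluster_sets,
                   f0_scores = f0_scores)
  het <- NULL
  if (!is.null(config$sd_locus) && any(!is.na(scan$b)))
    het <- infer_heterogamety(scan)

  report <- list(
    n_loci = length(truth$loci), n_samples = length(ped$sample_id),
    n_f2 = length(f2), accuracy = accuracy, missing_rate = missing_rate,
    support_gt10 = support_gt10, flagged_loci = flags[lengths(flags) > 0],
    verdict = if (!is.null(het)) het$verdict else NA_character_,
    seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sync(sync, file.path(out_dir, "reads.sync"))
    write_pedigree(ped, file.path(out_dir, "pedigree.tsv"))
    write_map(truth$map, file.path(out_dir, "map.tsv"))
    write_diplotype_matrix(calls, file.path(out_dir, "diplotypes.tsv"))
    tdf <- data.frame(locus_id = rep(rownames(truth$diplotypes),
                                     ncol(truth$diplotypes)),
                      sample_id = rep(colnames(truth$diplotypes),
                                      each = nrow(truth$diplotypes)),
                      truth = as.vector(truth$diplotypes))
    write.table(tdf, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(seg, file.path(out_dir, "chi2_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(scan, file.path(out_dir, "b_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }

  list(truth = truth, sync = sync, diplo = diplo, accuracy = accuracy,
       confusion = confusion, support_gt10 = support_gt10,
       missing_rate = missing_rate, flagged_loci = flags[lengths(flags) > 0],
       seg = seg, scan = scan, heterogamety = het, report = report)
}
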