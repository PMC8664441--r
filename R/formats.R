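#' Parse a PoPoolation2-style sync file into per-sample count matrices
#'
#' The sync dialect is tab-separated: locus id, 1-based position, reference
#' base, then one column per sample of colon-separated read counts in
#' `A:T:C:G:N:del` order. Counts are remapped into the canonical internal row
#' order `A, C, G, T, N, DEL` (see [DM_STATES]). Positions absent from the
#' file are zero-filled so that every locus covers contiguous positions
#' `1..n`; insertions are not representable (the matrix covers reference
#' positions only).
#'
#' @param path path to a sync text file.
#' @param sample_ids character vector naming the per-sample columns, in file
#'   order. Defaults to `S1..Sk`.
#' @return an object of class `sync_data`: a list with elements `samples`
#'   (character) and `loci`, a named list of `locus_counts` objects, each a
#'   list with `locus_id`, `n`, `ref` (reference base per position) and
#'   `counts`, a named list of 6 x n integer matrices (rows = [DM_STATES]).
#' @seealso [write_sync()]
#' @export
parse_sync <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_fmt("sync file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop_fmt("sync parse error at line %d: expected %d fields, found %d",
             which(nf != nf[1])[1], nf[1], nf[nf != nf[1]][1])
  if (nf[1] < 4) stop_fmt("sync file must have at least one sample column")
  n_samp <- nf[1] - 3L
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_samp))
  if (length(sample_ids) != n_samp)
    stop_fmt("%d sample ids supplied but file has %d sample columns",
             length(sample_ids), n_samp)

  tab <- do.call(rbind, fields)
  locus <- tab[, 1]
  pos <- suppressWarnings(as.integer(tab[, 2]))
  if (anyNA(pos) || any(pos < 1L))
    stop_fmt("sync parse error at line %d: bad position field '%s'",
             which(is.na(pos) | pos < 1L)[1], tab[which(is.na(pos) | pos < 1L)[1], 2])
  ref <- tab[, 3]

  count_ok <- grepl("^[0-9]+:[0-9]+:[0-9]+:[0-9]+:[0-9]+:[0-9]+$",
                    tab[, 4:nf[1], drop = FALSE])
  if (!all(count_ok)) {
    bad <- which(!matrix(count_ok, nrow = nrow(tab)), arr.ind = TRUE)[1, 1]
    stop_fmt("sync parse error at line %d: malformed count field", bad)
  }

  loci <- list()
  for (lid in unique(locus)) {
    rows <- which(locus == lid)
    p <- pos[rows]
    if (anyDuplicated(p))
      stop_fmt("sync structural error: duplicate position %d in locus %s",
               p[anyDuplicated(p)], lid)
    n <- max(p)
    ref_vec <- rep("N", n)
    ref_vec[p] <- ref[rows]
    counts <- vector("list", n_samp)
    names(counts) <- sample_ids
    for (s in seq_len(n_samp)) {
      m <- matrix(0L, nrow = 6L, ncol = n, dimnames = list(DM_STATES, NULL))
      vals <- strsplit(tab[rows, 3L + s], ":", fixed = TRUE)
      v <- matrix(as.integer(unlist(vals)), nrow = 6L)
      m[SYNC_TO_INTERNAL, p] <- v
      counts[[s]] <- m
    }
    loci[[lid]] <- structure(
      list(locus_id = lid, n = n, ref = ref_vec, counts = counts),
      class = "locus_counts")
  }
  structure(list(samples = sample_ids, loci = loci), class = "sync_data")
}

#' Write count matrices back to sync format
#'
#' Inverse of [parse_sync()]: the internal `A, C, G, T, N, DEL` rows are
#' emitted in the sync `A:T:C:G:N:del` column order. A file produced by this
#' writer parses back to an identical object, and re-writing reproduces the
#' file byte for byte.
#'
#' @param x a `sync_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync_data"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (lc in x$loci) {
    samp <- vapply(lc$counts, function(m) {
      apply(m[SYNC_TO_INTERNAL, , drop = FALSE], 2, paste, collapse = ":")
    }, character(lc$n))
    if (lc$n == 1L) samp <- matrix(samp, nrow = 1L)
    lines <- paste(lc$locus_id, seq_len(lc$n), lc$ref,
                   apply(samp, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read and validate a pedigree table
#'
#' Expects a TSV with header columns `sample_id`, `generation` (F0/F1/F2),
#' `role` (`grandsire_Bv`, `granddam_Bb`, `F1_father`, `F1_mother`,
#' `offspring`), `family` and optionally `sex` (`male`, `female`,
#' `uncertain`, `unknown`). Exactly one grandsire, one granddam and one F1
#' father are required; every F2 row needs a family label. If the sex column
#' is absent, all F2 get sex `unknown` with a warning.
#'
#' @param path path to the pedigree TSV.
#' @return a validated `data.frame` with class `c("pedigree", "data.frame")`.
#' @export
parse_pedigree <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "generation", "role", "family")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("pedigree missing column(s): %s", paste(miss, collapse = ", "))
  if (!"sex" %in% names(df)) {
    warning("pedigree has no sex column; all F2 sex set to 'unknown'")
    df$sex <- ifelse(df$generation == "F2", "unknown", "")
  }
  validate_pedigree(df)
}

#' Validate an in-memory pedigree data.frame
#' @param df data.frame with the [parse_pedigree()] columns.
#' @return the validated pedigree.
#' @export
validate_pedigree <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop_fmt("duplicate sample id(s): %s",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (sum(df$role == "grandsire_Bv") != 1L)
    stop_fmt("pedigree must contain exactly one grandsire_Bv (found %d)",
             sum(df$role == "grandsire_Bv"))
  if (sum(df$role == "granddam_Bb") != 1L)
    stop_fmt("pedigree must contain exactly one granddam_Bb (found %d)",
             sum(df$role == "granddam_Bb"))
  if (sum(df$role == "F1_father") != 1L)
    stop_fmt("pedigree must contain exactly one F1_father (found %d)",
             sum(df$role == "F1_father"))
  f2 <- df$generation == "F2"
  if (any(f2 & (is.na(df$family) | df$family == "")))
    stop_fmt("every F2 sample needs a family label")
  bad_sex <- f2 & !df$sex %in% c("male", "female", "uncertain", "unknown")
  if (any(bad_sex))
    stop_fmt("invalid F2 sex label(s): %s",
             paste(unique(df$sex[bad_sex]), collapse = ", "))
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Write a pedigree table as TSV
#' @param ped pedigree data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a linkage-map table
#'
#' TSV with columns `locus_id`, `linkage_group`, `position_cM`. Rows are
#' sorted by linkage group and position; loci sharing a position within a
#' linkage group form a bin.
#'
#' @param path path to the map TSV.
#' @return a sorted `data.frame` with class `c("map_table", "data.frame")`.
#' @export
parse_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "linkage_group", "position_cM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("map missing column(s): %s", paste(miss, collapse = ", "))
  validate_map(df)
}

#' Validate and sort an in-memory map data.frame
#' @param df data.frame with the [parse_map()] columns.
#' @return the validated, sorted map.
#' @export
validate_map <- function(df) {
  if (anyDuplicated(df$locus_id))
    stop_fmt("duplicate locus id(s) in map: %s",
             paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  if (any(df$position_cM < 0)) stop_fmt("negative cM position in map")
  df <- df[order(df$linkage_group, df$position_cM, df$locus_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("map_table", "data.frame")
  df
}

#' Write a map table as TSV
#' @param map map data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

lepmap_slots <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

#' Write Lep-MAP3 posterior and pedigree input files
#'
#' Recodes diplotypes BbHOM, HET, BvHOM as genotypes AA, AC, CC. Each locus
#' becomes one line: locus id, position, then per individual ten
#' space-separated relative likelihoods in canonical Lep-MAP3 genotype order
#' (AA AC AG AT CC CG CT GG GT TT). The most likely diplotype is coded 1 and
#' the other two carry `exp(lnL - lnL_best)`; the remaining seven slots are
#' zero. MISSING calls are written as a uniform all-ones vector (Lep-MAP3's
#' no-information convention). A companion pedigree file in the Lep-MAP3
#' six-row layout is written alongside.
#'
#' @param calls long-format call data.frame with columns `locus_id`,
#'   `sample_id`, `state` and `lnL_BbHOM`, `lnL_HET`, `lnL_BvHOM`.
#' @param pedigree pedigree data.frame (defines individual order and the
#'   six-row pedigree file).
#' @param path output path for the posterior file.
#' @param pedigree_path output path for the pedigree file; default
#'   `paste0(path, ".ped")`.
#' @param positions optional named numeric vector of per-locus positions;
#'   defaults to the locus rank order.
#' @return invisibly, a list with both paths.
#' @export
write_lepmap_posterior <- function(calls, pedigree, path,
                                   pedigree_path = paste0(path, ".ped"),
                                   positions = NULL) {
  ids <- pedigree$sample_id
  loci <- unique(calls$locus_id)
  if (is.null(positions)) positions <- setNames(seq_along(loci), loci)
  con <- file(path, open = "wb")
  for (lid in loci) {
    sub <- calls[calls$locus_id == lid, , drop = FALSE]
    idx <- match(ids, sub$sample_id)
    if (anyNA(idx)) {
      close(con)
      stop_fmt("locus %s: no call for pedigree member(s) %s", lid,
               paste(ids[is.na(idx)], collapse = ", "))
    }
    sub <- sub[idx, , drop = FALSE]
    cells <- vapply(seq_len(nrow(sub)), function(i) {
      v <- rep(0, 10)
      if (is.na(sub$state[i]) || sub$state[i] == "MISSING") {
        v[] <- 1
      } else {
        lnl <- c(sub$lnL_BbHOM[i], sub$lnL_HET[i], sub$lnL_BvHOM[i])
        rel <- exp(lnl - max(lnl))
        v[c(1L, 2L, 5L)] <- rel  # AA, AC, CC
      }
      paste(fmt_num(v), collapse = " ")
    }, character(1))
    writeLines(paste(c(lid, fmt_num(positions[[lid]]), cells), collapse = "\t"),
               con, sep = "\n")
  }
  close(con)
  write_lepmap_pedigree(pedigree, pedigree_path)
  invisible(list(posterior = path, pedigree = pedigree_path))
}

# Lep-MAP3 six-row pedigree layout: family, id, father, mother, sex, phenotype
write_lepmap_pedigree <- function(pedigree, path) {
  ids <- pedigree$sample_id
  sire <- ids[pedigree$role == "grandsire_Bv"]
  dam <- ids[pedigree$role == "granddam_Bb"]
  f1f <- ids[pedigree$role == "F1_father"]
  mothers <- pedigree[pedigree$role == "F1_mother", , drop = FALSE]
  father <- ifelse(pedigree$generation == "F1", sire,
                   ifelse(pedigree$generation == "F2", f1f, "0"))
  mother_of_family <- setNames(mothers$sample_id, mothers$family)
  mother <- rep("0", nrow(pedigree))
  mother[pedigree$generation == "F1"] <- dam
  f2 <- pedigree$generation == "F2"
  if (any(f2)) {
    if (nrow(mothers) == 1L) {
      mother[f2] <- mothers$sample_id
    } else {
      m <- mother_of_family[pedigree$family[f2]]
      if (anyNA(m)) stop_fmt("no F1_mother for family %s",
                             paste(unique(pedigree$family[f2][is.na(m)]), collapse = ", "))
      mother[f2] <- m
    }
  }
  sex_code <- ifelse(pedigree$role %in% c("grandsire_Bv", "F1_father"), "1",
              ifelse(pedigree$role %in% c("granddam_Bb", "F1_mother"), "2",
              ifelse(pedigree$sex == "male", "1",
              ifelse(pedigree$sex == "female", "2", "0"))))
  rows <- list(
    c("CHR", "POS", rep("1", length(ids))),
    c("CHR", "POS", ids),
    c("CHR", "POS", father),
    c("CHR", "POS", mother),
    c("CHR", "POS", sex_code),
    c("CHR", "POS", rep("0", length(ids))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in rows) writeLines(paste(r, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a Lep-MAP3 posterior file written by [write_lepmap_posterior()]
#'
#' @param path posterior file path.
#' @return a list with `loci`, `positions`, and `lik`, a list (per locus) of
#'   individuals x 10 numeric matrices.
#' @export
read_lepmap_posterior <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  loci <- vapply(fields, `[[`, character(1), 1L)
  positions <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  lik <- lapply(fields, function(f) {
    vals <- strsplit(f[-(1:2)], " ", fixed = TRUE)
    if (any(lengths(vals) != 10L))
      stop_fmt("posterior line for locus %s: expected 10 likelihoods per individual", f[1])
    matrix(as.numeric(unlist(vals)), ncol = 10L, byrow = TRUE,
           dimnames = list(NULL, lepmap_slots))
  })
  list(loci = loci, positions = setNames(positions, loci), lik = setNames(lik, loci))
}

# re-emit a parsed posterior object; used for round-trip checks
write_lepmap_posterior_raw <- function(obj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(obj$loci)) {
    cells <- apply(obj$lik[[i]], 1, function(v) paste(fmt_num(v), collapse = " "))
    writeLines(paste(c(obj$loci[i], fmt_num(obj$positions[i]), cells),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Write the full diplotype matrix as TSV
#'
#' One row per locus; per sample, a diplotype column (`BbHOM`/`HET`/`BvHOM`
#' or `NA` for missing) and a `<sample>.support` column with the ln-likelihood
#' support of the call.
#'
#' @param calls long-format call data.frame (`locus_id`, `sample_id`, `state`,
#'   `support`).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_diplotype_matrix()]
#' @export
write_diplotype_matrix <- function(calls, path) {
  samples <- unique(calls$sample_id)
  loci <- unique(calls$locus_id)
  st <- matrix(NA_character_, length(loci), length(samples),
               dimnames = list(loci, samples))
  sup <- st
  idx <- cbind(match(calls$locus_id, loci), match(calls$sample_id, samples))
  state <- ifelse(calls$state == "MISSING", NA_character_, calls$state)
  st[idx] <- state
  sup[idx] <- ifelse(is.na(calls$support), NA_character_, fmt_num(calls$support))
  out <- data.frame(locus_id = loci, stringsAsFactors = FALSE)
  for (s in samples) {
    out[[s]] <- st[, s]
    out[[paste0(s, ".support")]] <- sup[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a diplotype matrix written by [write_diplotype_matrix()]
#'
#' @param path TSV path.
#' @return long-format call data.frame with `locus_id`, `sample_id`, `state`
#'   (`MISSING` for NA entries) and `support`.
#' @export
read_diplotype_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samp <- names(df)[!grepl("\\.support$", names(df)) & names(df) != "locus_id"]
  out <- do.call(rbind, lapply(samp, function(s) {
    data.frame(locus_id = df$locus_id, sample_id = s,
               state = ifelse(is.na(df[[s]]), "MISSING", df[[s]]),
               support = as.numeric(df[[paste0(s, ".support")]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a variant whitelist for the manual rescoring path
#'
#' TSV with columns `locus_id`, `pos`, `state_bv`, `state_bb`. States must be
#' in the canonical alphabet and the two states must differ (equal states
#' carry no ancestry information and are rejected).
#'
#' @param path whitelist TSV path.
#' @param locus_lengths optional named integer vector; when given, positions
#'   exceeding the locus length raise an error at parse time.
#' @return a validated data.frame.
#' @export
read_variant_whitelist <- function(path, locus_lengths = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "pos", "state_bv", "state_bb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("whitelist missing column(s): %s", paste(miss, collapse = ", "))
  bad <- !df$state_bv %in% DM_STATES | !df$state_bb %in% DM_STATES
  if (any(bad))
    stop_fmt("whitelist state outside alphabet at row %d", which(bad)[1])
  if (any(df$state_bv == df$state_bb))
    stop_fmt("whitelist row %d is uninformative: state_bv equals state_bb",
             which(df$state_bv == df$state_bb)[1])
  if (any(df$pos < 1L | df$pos != round(df$pos)))
    stop_fmt("whitelist positions must be positive integers")
  if (!is.null(locus_lengths)) {
    n <- locus_lengths[df$locus_id]
    if (any(!is.na(n) & df$pos > n))
      stop_fmt("whitelist position beyond locus length at row %d",
               which(!is.na(n) & df$pos > n)[1])
  }
  df
}
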