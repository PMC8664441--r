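test_that("sync parsing remaps A:T:C:G:N:del into canonical state order", {
  f <- withr::local_tempfile()
  writeLines(c("L1\t1\tA\t10:0:2:0:0:0\t0:0:0:0:0:0",
               "L1\t2\tC\t0:5:0:3:1:2\t1:1:1:1:1:1"), f)
  sx <- parse_sync(f, sample_ids = c("a", "b"))
  m <- sx$loci$L1$counts$a
  expect_equal(unname(m["A", 1]), 10L)
  expect_equal(unname(m["C", 1]), 2L)   # sync slot 3 is C
  expect_equal(sum(m[c("G", "T", "N", "DEL"), 1]), 0L)
  expect_equal(unname(m["T", 2]), 5L)   # sync slot 2 is T
  expect_equal(unname(m["G", 2]), 3L)
  expect_equal(unname(m["DEL", 2]), 2L)
  # empty sample field is a legal zero column
  expect_equal(sum(sx$loci$L1$counts$b[, 1]), 0L)
  expect_equal(colSums(sx$loci$L1$counts$b)[2], 6, ignore_attr = TRUE)
})

test_that("sync positions are zero-filled to contiguous 1..n and errors name lines", {
  f <- withr::local_tempfile()
  writeLines(c("L1\t1\tA\t1:0:0:0:0:0",
               "L1\t3\tG\t0:0:0:2:0:0"), f)
  sx <- parse_sync(f)
  expect_equal(sx$loci$L1$n, 3L)
  expect_equal(sum(sx$loci$L1$counts$S1[, 2]), 0L)

  bad <- withr::local_tempfile()
  writeLines("L1\t1\tA\t1:0:0", bad)
  expect_error(parse_sync(bad), "line 1")
  dup <- withr::local_tempfile()
  writeLines(c("L1\t2\tA\t1:0:0:0:0:0", "L1\t2\tA\t1:0:0:0:0:0"), dup)
  expect_error(parse_sync(dup), "duplicate position")
})

test_that("sync write -> parse -> write is byte-identical", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeLines(c("L1\t1\tA\t10:0:2:0:0:0\t3:1:0:0:0:1",
               "L1\t2\tC\t0:5:0:3:1:2\t0:0:0:0:0:0",
               "L2\t1\tG\t7:7:7:7:7:7\t1:2:3:4:5:6",
               "L3\t1\tT\t0:9:0:0:0:0\t0:0:0:0:0:0"), f1)
  sx <- parse_sync(f1)
  write_sync(sx, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
})

test_that("pedigree parsing validates structure and defaults missing sex", {
  ped <- toy_pedigree(80, 82)
  expect_s3_class(ped, "pedigree")
  expect_equal(sum(ped$generation == "F2"), 162)

  f <- withr::local_tempfile()
  bad <- ped
  bad$role[2] <- "grandsire_Bv"  # two grandsires
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_pedigree(f), "grandsire_Bv")

  nosex <- ped[, setdiff(names(ped), "sex")]
  write.table(nosex, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(p2 <- parse_pedigree(f), "sex")
  expect_true(all(p2$sex[p2$generation == "F2"] == "unknown"))
})

test_that("map parsing sorts, derives bins, rejects duplicates and negatives", {
  f <- withr::local_tempfile()
  writeLines(c("locus_id\tlinkage_group\tposition_cM",
               "B\t1\t5.5", "A\t1\t0.0", "C\t1\t5.5"), f)
  m <- parse_map(f)
  expect_equal(m$locus_id, c("A", "B", "C"))
  bins <- split(m$locus_id, paste(m$linkage_group, m$position_cM))
  expect_equal(sort(lengths(bins), decreasing = TRUE)[[1]], 2L)

  writeLines(c("locus_id\tlinkage_group\tposition_cM", "A\t1\t1", "A\t1\t2"), f)
  expect_error(parse_map(f), "duplicate")
  writeLines(c("locus_id\tlinkage_group\tposition_cM", "A\t1\t-1"), f)
  expect_error(parse_map(f), "negative")
})

test_that("Lep-MAP3 posterior encodes relative likelihoods in AA/AC/CC slots", {
  ped <- toy_pedigree(1, 1)
  ids <- ped$sample_id
  calls <- data.frame(locus_id = "L1", sample_id = ids, state = "HET",
                      lnL_BbHOM = -5, lnL_HET = -1, lnL_BvHOM = -9,
                      stringsAsFactors = FALSE)
  calls$state[ids == "SIRE"] <- "BvHOM"
  calls$lnL_BbHOM[ids == "SIRE"] <- -30
  calls$lnL_HET[ids == "SIRE"] <- -10
  calls$lnL_BvHOM[ids == "SIRE"] <- 0
  calls$state[ids == "DAM"] <- "MISSING"
  calls[ids == "DAM", c("lnL_BbHOM", "lnL_HET", "lnL_BvHOM")] <- NA
  f <- withr::local_tempfile()
  write_lepmap_posterior(calls, ped, f)
  post <- read_lepmap_posterior(f)
  lik <- post$lik$L1
  het_row <- lik[match("F1F", ids), ]
  expect_equal(unname(het_row[c("AA", "AC", "CC")]),
               c(exp(-4), 1, exp(-8)), tolerance = 1e-5)
  expect_equal(sum(het_row[-c(1, 2, 5)]), 0)
  # best BvHOM with support 10: CC = 1, AC = e^-10
  sire_row <- lik[match("SIRE", ids), ]
  expect_equal(unname(sire_row["CC"]), 1)
  expect_equal(unname(sire_row["AC"]), exp(-10), tolerance = 1e-6)
  expect_lte(unname(sire_row["AC"]), 4.6e-5)
  # MISSING -> ten equal entries
  expect_true(all(lik[match("DAM", ids), ] == 1))
  # row maxima are exactly 1, entries in (0, 1], <= 3 nonzero for called rows
  expect_true(all(apply(lik, 1, max) == 1))
  expect_true(all(lik >= 0 & lik <= 1))
  called <- setdiff(seq_along(ids), match("DAM", ids))
  expect_true(all(rowSums(lik[called, ] > 0) <= 3))

  # missing pedigree member errors
  expect_error(write_lepmap_posterior(calls[-1, ], ped, f), "no call")
})

test_that("Lep-MAP3 posterior write -> read -> write is byte-identical", {
  ped <- toy_pedigree(2, 2)
  calls <- do.call(rbind, lapply(c("L1", "L2"), function(l)
    data.frame(locus_id = l, sample_id = ped$sample_id,
               state = rep(c("BbHOM", "HET", "BvHOM"),
                           length.out = nrow(ped)),
               lnL_BbHOM = -runif(nrow(ped), 0, 20),
               lnL_HET = -runif(nrow(ped), 0, 20),
               lnL_BvHOM = -runif(nrow(ped), 0, 20),
               stringsAsFactors = FALSE)))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_lepmap_posterior(calls, ped, f1)
  obj <- read_lepmap_posterior(f1)
  diplomap:::write_lepmap_posterior_raw(obj, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  # the six-row pedigree companion exists and has the layout
  ped_lines <- readLines(paste0(f1, ".ped"))
  expect_length(ped_lines, 6)
  expect_true(all(lengths(strsplit(ped_lines, "\t")) == nrow(ped) + 2))
})

test_that("diplotype matrix round-trips including NA encoding", {
  calls <- data.frame(
    locus_id = rep(c("L1", "L2"), each = 3),
    sample_id = rep(c("a", "b", "c"), 2),
    state = c("BbHOM", "HET", "MISSING", "BvHOM", "MISSING", "HET"),
    support = c(12.5, 3.25, NA, 100, NA, 0.5),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_diplotype_matrix(calls, f)
  back <- read_diplotype_matrix(f)
  back <- back[order(back$locus_id, back$sample_id), ]
  calls <- calls[order(calls$locus_id, calls$sample_id), ]
  expect_equal(back$state, calls$state)
  expect_equal(back$support, calls$support, tolerance = 1e-6)
})

test_that("variant whitelist validation rejects bad states and positions", {
  f <- withr::local_tempfile()
  writeLines(c("locus_id\tpos\tstate_bv\tstate_bb",
               "L1\t3\tA\tC", "L1\t7\tG\tDEL"), f)
  wl <- read_variant_whitelist(f)
  expect_equal(nrow(wl), 2)

  writeLines(c("locus_id\tpos\tstate_bv\tstate_bb", "L1\t3\tA\tA"), f)
  expect_error(read_variant_whitelist(f), "uninformative")
  writeLines(c("locus_id\tpos\tstate_bv\tstate_bb", "L1\t3\tX\tC"), f)
  expect_error(read_variant_whitelist(f), "alphabet")
  writeLines(c("locus_id\tpos\tstate_bv\tstate_bb", "L1\t99\tA\tC"), f)
  expect_error(read_variant_whitelist(f, locus_lengths = c(L1 = 50)), "beyond")
})
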