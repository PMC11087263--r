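test_that("unique exact substrings are placed end-to-end", {
  g <- dss("ACGTTTAAGCCA")
  out <- align_reads(data.frame(read_id = "r", sequence = "TTAAGC",
                                stringsAsFactors = FALSE), g)
  a <- out$alignments
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 4L)
  expect_equal(a$end, 10L)
  expect_identical(a$strand, "+")
  expect_true(a$unique)
})

test_that("strand involution: the reverse complement maps to the same interval", {
  g <- generate_genome(1, 20000, seed = 21)
  seq30 <- ref_seq(g, "contig_1", 5000, 5030)
  out <- align_reads(data.frame(read_id = c("f", "r"),
                                sequence = c(seq30, revcomp(seq30)),
                                stringsAsFactors = FALSE), g)
  a <- out$alignments
  expect_equal(a$start, c(5000L, 5000L))
  expect_equal(a$end, c(5030L, 5030L))
  expect_setequal(a$strand[a$read_id == "f"], "+")
  expect_setequal(a$strand[a$read_id == "r"], "-")
})

test_that("the seeded aligner equals a brute-force Hamming scan", {
  g <- generate_genome(1, 50000, seed = 23)
  set.seed(23)
  reads <- lapply(1:60, function(i) {
    len <- sample(c(24L, 40L, 70L), 1)  # includes the short-read fallback path
    pos <- sample(50000L - len, 1) - 1L
    s <- ref_seq(g, "contig_1", pos, pos + len)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      for (j in sample(len, nmut)) {
        substr(s, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, j, j)), 1)
      }
    }
    if (i %% 3 == 0) s <- revcomp(s)
    s
  })
  out <- align_reads(data.frame(read_id = sprintf("r%02d", 1:60),
                                sequence = unlist(reads),
                                stringsAsFactors = FALSE), g)
  a <- out$alignments
  for (i in 1:60) {
    bf <- brute_force_hits(reads[[i]], g, max_mismatch = 2L)
    row <- a[a$read_id == sprintf("r%02d", i), ]
    if (is.null(bf)) {
      expect_equal(nrow(row), 0L)
    } else {
      best <- bf[bf$n_mismatches == min(bf$n_mismatches), , drop = FALSE]
      expect_equal(nrow(row), 1L)
      expect_identical(row$unique, nrow(best) == 1L)
      if (nrow(best) == 1L) {
        expect_equal(row$start, best$start)
        expect_equal(row$end, best$end)
        expect_identical(row$strand, best$strand)
        expect_equal(row$n_mismatches, best$n_mismatches)
      }
    }
  }
})

test_that("multimappers are flagged and unmapped reads counted", {
  seg <- filler(3000)
  set.seed(31)
  uniqpart <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  g <- dss(paste0(seg, uniqpart, seg))  # duplicated 3 kb flanks
  dup_read <- substr(seg, 101, 160)
  out <- align_reads(data.frame(
    read_id = c("dup", "none"),
    sequence = c(dup_read, strrep("TGCATTGCAA", 6)),
    stringsAsFactors = FALSE), g)
  expect_equal(out$stats[["multimapped"]], 1L)
  a <- out$alignments
  expect_false(any(a$unique[a$read_id == "dup"]))
  expect_equal(out$stats[["unmapped"]], 1L)
  expect_equal(out$stats[["reads_in"]],
               out$stats[["aligned_unique"]] + out$stats[["multimapped"]] +
                 out$stats[["unmapped"]])
})

test_that("empty inputs are rejected", {
  g <- generate_genome(1, 1000, seed = 1)
  expect_error(align_reads(data.frame(read_id = character(0),
                                      sequence = character(0)), g),
               "empty read set")
  expect_error(align_reads(data.frame(read_id = "r", sequence = "ACGT"),
                           Biostrings::DNAStringSet()), "empty genome")
})

test_that("SAM export/import round-trips the built-in alignments", {
  w <- run_small_world(seed = 3, n_insertions = 5, len = 1e5,
                       junction_depth = 3)
  a <- w$aligned$alignments
  a <- a[seq_len(min(50L, nrow(a))), ]
  sam <- withr::local_tempfile(fileext = ".sam")
  export_sam(a, w$genome, sam, reads = w$trimmed$reads)
  side_map <- w$trimmed$reads[w$trimmed$reads$mate == 1L,
                              c("read_id", "side")]
  imp <- import_alignments(sam, w$genome, side_map = side_map)
  b <- imp$alignments
  cols <- c("read_id", "mate", "contig", "start", "end", "strand", "side",
            "n_mismatches", "unique")
  ord <- function(d) {
    d <- d[do.call(order, d[c("contig", "start", "read_id", "mate")]), cols]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(b), ord(a))
  # flank tags also survive the round trip without an explicit side map
  imp2 <- import_alignments(sam, w$genome)
  expect_identical(ord(imp2$alignments), ord(a))
})

test_that("clipped or gapped SAM records are excluded from import", {
  g <- dss(planted_ttaa_contig(1200, 500))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:contig_1\tLN:1200",
    sprintf("ok\t0\tcontig_1\t101\t60\t30M\t*\t0\t0\t%s\t*", ref_seq(g, "contig_1", 100, 130)),
    sprintf("clip\t0\tcontig_1\t201\t60\t5S25M\t*\t0\t0\t%s\t*", ref_seq(g, "contig_1", 195, 225)),
    sprintf("gap\t0\tcontig_1\t301\t60\t10M5D20M\t*\t0\t0\t%s\t*", ref_seq(g, "contig_1", 300, 330))
  ), sam)
  imp <- import_alignments(sam, g)
  expect_equal(nrow(imp$alignments), 1L)
  expect_identical(imp$alignments$read_id, "ok")
  expect_equal(imp$alignments$start, 100L)
  expect_equal(imp$alignments$end, 130L)
  expect_equal(imp$stats[["excluded_clipped_or_gapped"]], 2L)
  # unknown contig is a hard error
  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrX\tLN:1200",
               "r\t0\tchrX\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"), bad)
  expect_error(import_alignments(bad, g), "absent from the reference")
})
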