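# Genome with TTAA planted at 100 and (for internal-TTAA cases) a second
# motif inside the read footprint.
g_plain <- dss(planted_ttaa_contig(1200, c(100, 400)))

test_that("terminal TTAA detection is strand- and side-aware", {
  # + strand read starting at the TTAA (right flank)
  a <- aln_row("contig_1", 100, 160, strand = "+", side = "right")
  jn <- detect_junctions(a, g_plain)$junctions
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$ttaa_start, 100L)
  expect_identical(jn$junction_end, "5p")
  expect_false(jn$internal_ttaa)
  # - strand read ending at the TTAA (left flank, reverse-complemented)
  a <- aln_row("contig_1", 44, 104, strand = "-", side = "left")
  jn <- detect_junctions(a, g_plain)$junctions
  expect_equal(jn$ttaa_start, 100L)
  expect_identical(jn$junction_end, "3p")
  # read not touching a TTAA at its genome-facing terminus is dropped
  a <- aln_row("contig_1", 200, 260, strand = "+", side = "right")
  out <- detect_junctions(a, g_plain)
  expect_equal(nrow(out$junctions), 0L)
  expect_equal(out$stats[["dropped_no_terminal_ttaa"]], 1L)
})

test_that("internal TTAA flags match a brute-force 4-mer scan", {
  # read spanning both planted TTAAs: junction at 100, internal at 400
  a <- aln_row("contig_1", 100, 404, strand = "+", side = "right")
  jn <- detect_junctions(a, g_plain)$junctions
  expect_true(jn$internal_ttaa)
  # property: random windows anchored at the TTAA, flag equals brute scan
  g <- generate_genome(1, 50000, seed = 29)
  sites <- ttaa_sites(g, "contig_1")
  sites <- sites[sites > 200 & sites < 49000]
  set.seed(29)
  for (t0 in sample(sites, 25)) {
    len <- sample(40:120, 1)
    a <- aln_row("contig_1", t0, t0 + len, strand = "+", side = "right")
    out <- detect_junctions(a, g)
    seg <- ref_seq(g, "contig_1", t0, t0 + len)
    occ <- which(substring(seg, 1:(len - 3), 4:len) == "TTAA") - 1L
    expect_equal(nrow(out$junctions), 1L)  # terminal TTAA by construction
    expect_identical(out$junctions$internal_ttaa, any(occ != 0L))
  }
})

test_that("junction reads without a side or uniqueness never pass", {
  a <- rbind(aln_row("contig_1", 100, 160, side = "none"),
             aln_row("contig_1", 100, 160, side = "left", unique = FALSE))
  out <- detect_junctions(a, g_plain)
  expect_equal(nrow(out$junctions), 0L)
  expect_equal(out$stats[["dropped_no_side"]], 1L)
  expect_equal(out$stats[["dropped_nonunique"]], 1L)
  expect_error(detect_junctions(aln_row("contig_1", 1100, 1300, side = "left"),
                                g_plain), "outside contig")
})

test_that("candidates group junction reads by their shared genomic TTAA", {
  jn <- rbind(
    aln_row("contig_1", 44, 104, strand = "-", side = "left", read_id = "L1"),
    aln_row("contig_1", 100, 160, strand = "+", side = "right", read_id = "R1"),
    aln_row("contig_1", 400, 450, strand = "+", side = "right", read_id = "R2"))
  out <- detect_junctions(jn, g_plain)
  cand <- build_candidates(out$junctions)
  expect_equal(nrow(cand), 2L)
  c1 <- cand[cand$ttaa_start == 100L, ]
  expect_equal(c1$left_support, 1L)
  expect_equal(c1$right_support, 1L)
  c2 <- cand[cand$ttaa_start == 400L, ]
  expect_equal(c2$left_support, 0L)
  expect_equal(c2$right_support, 1L)
})

test_that("PCR duplicates collapse to one unit of support", {
  dup <- do.call(rbind, lapply(1:10, function(i)
    aln_row("contig_1", 100, 160, strand = "+", side = "right",
            read_id = sprintf("d%02d", i))))
  jn <- detect_junctions(dup, g_plain)$junctions
  cand <- build_candidates(jn)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$right_support, 1L)
  # distinct fragment ends are distinct support
  two <- rbind(dup[1, , drop = FALSE],
               {x <- aln_row("contig_1", 100, 170, strand = "+",
                             side = "right", read_id = "other"); x})
  jn2 <- detect_junctions(two, g_plain)$junctions
  expect_equal(build_candidates(jn2)$right_support, 2L)
})

test_that("validation enforces both flanks and the internal-TTAA rule", {
  # single flank
  a <- aln_row("contig_1", 100, 160, strand = "+", side = "right")
  cand <- build_candidates(detect_junctions(a, g_plain)$junctions)
  call <- validate_sites(cand, g_plain)
  expect_identical(call$status, "rejected")
  expect_identical(call$rejection_reason, "single_flank")
  # both flanks, clean reads: validated
  both <- rbind(
    aln_row("contig_1", 44, 104, strand = "-", side = "left", read_id = "L"),
    aln_row("contig_1", 100, 160, strand = "+", side = "right", read_id = "R"))
  call <- validate_sites(build_candidates(detect_junctions(both, g_plain)$junctions),
                         g_plain)
  expect_identical(call$status, "validated")
  expect_identical(call$rejection_reason, "none")
})

test_that("internal-TTAA-only candidates depend on the mode switch", {
  # both flanks supported at TTAA@400, but every read also spans TTAA@100
  g <- dss(planted_ttaa_contig(1200, c(100, 400)))
  both <- rbind(
    aln_row("contig_1", 90, 404, strand = "-", side = "left", read_id = "L"),
    aln_row("contig_1", 400, 720, strand = "+", side = "right", read_id = "R"))
  both$side <- c("left", "right")
  jn <- detect_junctions(both, g)$junctions
  jn <- jn[jn$ttaa_start == 400L, , drop = FALSE]
  expect_true(all(jn$internal_ttaa | jn$side == "right"))
  cand <- build_candidates(jn)
  per_read <- validate_sites(cand, g, internal_ttaa_mode = "per-read")
  all_reads <- validate_sites(cand, g, internal_ttaa_mode = "all-reads")
  between <- validate_sites(cand, g, internal_ttaa_mode = "between-reads")
  # the left flank's only read spans the other TTAA -> no clean left read
  expect_equal(cand$left_clean, 0L)
  expect_identical(per_read$status, "rejected")
  expect_identical(per_read$rejection_reason, "internal_ttaa")
  expect_identical(all_reads$status, "rejected")
  # inter-read span is just the shared TTAA, hence clean: accepted
  expect_identical(between$status, "validated")
})

test_that("the call set is invariant to read order", {
  w <- run_small_world(seed = 5, n_insertions = 6, len = 1.5e5,
                       error_rate = 0.01, background_fraction = 0.2)
  usable <- w$aligned$alignments[w$aligned$alignments$unique, , drop = FALSE]
  set.seed(99)
  shuf <- usable[sample(nrow(usable)), , drop = FALSE]
  calls2 <- validate_sites(
    build_candidates(detect_junctions(shuf, w$genome)$junctions), w$genome)
  expect_identical(
    w$calls[order(w$calls$contig, w$calls$ttaa_start),
            c("contig", "ttaa_start", "left_support", "right_support",
              "status")],
    calls2[order(calls2$contig, calls2$ttaa_start),
           c("contig", "ttaa_start", "left_support", "right_support",
             "status")])
})

test_that("truth recovery on a small synthetic world is exact", {
  w <- run_small_world(seed = 8, n_insertions = 10, len = 2e5,
                       error_rate = 0, background_fraction = 0.2,
                       junction_depth = 5)
  v <- w$calls[w$calls$status == "validated", ]
  expect_setequal(site_key(v), site_key(w$truth))
  # subset monotonicity: calls are candidates; candidates come from junctions
  expect_true(all(site_key(w$calls) %in% site_key(w$candidates)))
  expect_true(all(site_key(w$candidates) %in%
                    paste(w$junctions$junctions$contig,
                          w$junctions$junctions$ttaa_start)))
})
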