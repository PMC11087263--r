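# Fixtures are built in code: no stored data files.

# A DNAStringSet from literal strings (bypasses generate_genome's minimum
# length when a tiny hand-crafted contig is needed).
dss <- function(...) {
  x <- Biostrings::DNAStringSet(c(...))
  if (is.null(names(x))) names(x) <- paste0("contig_", seq_along(x))
  x
}

# A TTAA-free filler of a given length (period-3 repeat, contains no TTAA).
filler <- function(n) substr(strrep("ACG", ceiling(n / 3) + 1L), 1L, n)

# Contig with TTAA planted at the given 0-based offsets, no other TTAA.
planted_ttaa_contig <- function(len, offsets) {
  s <- filler(len)
  for (o in offsets) {
    stopifnot(o + 4L <= len)
    substr(s, o + 1L, o + 4L) <- "TTAA"
  }
  s
}

# Hand-rolled alignment record rows for calling-stage tests.
aln_row <- function(contig, start, end, strand = "+", side = "left",
                    read_id = "r1", mate = 1L, n_mismatches = 0L,
                    unique = TRUE) {
  data.frame(read_id = read_id, mate = mate, contig = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, side = side,
             n_mismatches = as.integer(n_mismatches), unique = unique,
             stringsAsFactors = FALSE)
}

# Independent naive primer scan: leftmost anchor with Hamming distance
# <= ceil(frac * primer length); character-by-character, no shared code
# with match_primer.
naive_primer_scan <- function(read, primer, frac) {
  pl <- nchar(primer)
  pv <- strsplit(primer, "")[[1]]
  rv <- strsplit(read, "")[[1]]
  lim <- ceiling(frac * pl)
  for (pos in 0:(nchar(read) - pl)) {
    if (sum(rv[(pos + 1):(pos + pl)] != pv) <= lim) return(pos)
  }
  NA_integer_
}

# Independent brute-force end-to-end scan via Biostrings matchPattern on
# both strands: every placement within the mismatch budget.
brute_force_hits <- function(seq, genome, max_mismatch = 2L) {
  out <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (ctg in names(genome)) {
      m <- Biostrings::matchPattern(s, genome[[ctg]],
                                    max.mismatch = max_mismatch)
      st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
      ok <- st >= 1L & en <= length(genome[[ctg]])
      if (!any(ok)) next
      mm <- vapply(which(ok), function(i) {
        sum(strsplit(as.character(m[[i]]), "")[[1]] !=
              strsplit(s, "")[[1]])
      }, integer(1))
      out <- rbind(out, data.frame(
        contig = ctg, start = st[ok] - 1L, end = en[ok], strand = strand,
        n_mismatches = mm, stringsAsFactors = FALSE))
    }
  }
  out
}

# Small simulated dataset run through trim+align+call; returns all pieces.
run_small_world <- function(seed = 1L, n_insertions = 8L, len = 2e5,
                            error_rate = 0, background_fraction = 0,
                            junction_depth = 5L,
                            internal_ttaa_mode = "per-read") {
  g <- generate_genome(1, len, seed = seed)
  sp <- sim_params(n_insertions = n_insertions, error_rate = error_rate,
                   background_fraction = background_fraction,
                   junction_depth = junction_depth, seed = seed)
  truth <- place_insertions(g, sp)
  sim <- simulate_reads(g, truth, sp, primer_set(),
                        withr::local_tempdir(.local_envir = parent.frame()))
  trm <- trim_and_tag(read_fastq(sim$reads_1), read_fastq(sim$reads_2))
  al <- align_reads(trm$reads, g)
  jn <- detect_junctions(al$alignments[al$alignments$unique, , drop = FALSE],
                         g)
  cand <- build_candidates(jn$junctions)
  calls <- validate_sites(cand, g, internal_ttaa_mode = internal_ttaa_mode)
  list(genome = g, params = sp, truth = truth, sim = sim, trimmed = trm,
       aligned = al, junctions = jn, candidates = cand, calls = calls)
}

site_key <- function(df) paste(df$contig, df$ttaa_start)
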