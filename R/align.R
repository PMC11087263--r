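#' Build a k-mer seed index over a genome
#'
#' Encodes every k-mer of each contig as a 2-bit integer (k <= 15 so codes
#' fit in a 32-bit signed integer) and stores them sorted for binary-search
#' lookup. Used by the built-in end-to-end aligner.
#'
#' @param genome A `DNAStringSet`.
#' @param k Seed length (default 15).
#' @return A `genome_index` list.
#' @export
genome_index <- function(genome, k = 15L) {
  stopifnot(k >= 4L, k <= 15L)
  contigs <- lapply(names(genome), function(ctg) {
    s <- as.character(genome[[ctg]])
    codes <- encode_kmers(s, k)
    ord <- order(codes)
    # sorted_codes stored as double: findInterval would otherwise coerce
    # the whole vector on every lookup
    list(name = ctg, seq = s, dna = genome[[ctg]], len = nchar(s),
         sorted_codes = as.double(codes[ord]), positions = ord)
  })
  names(contigs) <- names(genome)
  structure(list(contigs = contigs, k = as.integer(k)), class = "genome_index")
}

# 2-bit rolling encoding of all k-mers; returns integer vector of length
# L - k + 1 (position i = k-mer starting at base i, 1-based).
#' @keywords internal
encode_kmers <- function(seq_char, k) {
  b <- utf8ToInt(seq_char)
  # A=65 C=67 G=71 T=84 -> 0 1 2 3
  map <- integer(85)
  map[c(65L, 67L, 71L, 84L)] <- 0:3
  b <- map[b]
  L <- length(b)
  n <- L - k + 1L
  if (n < 1L) return(integer(0))
  code <- integer(n)
  for (j in 0:(k - 1L)) {
    code <- code * 4L + b[(1L + j):(n + j)]
  }
  code
}

#' @keywords internal
kmer_code <- function(seq_char, k) encode_kmers(seq_char, k)

# positions (1-based) of k-mer code x in an indexed contig; binary search
# (findInterval re-validates the whole sorted vector on every call)
#' @keywords internal
lookup_code <- function(contig_index, x) {
  sc <- contig_index$sorted_codes
  n <- length(sc)
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {  # first index with sc[i] >= x
    mid <- (lo + hi) %/% 2L
    if (sc[mid] < x) lo <- mid + 1L else hi <- mid
  }
  i <- lo
  while (i <= n && sc[i] == x) i <- i + 1L
  if (i == lo) return(integer(0))
  contig_index$positions[lo:(i - 1L)]
}

#' @keywords internal
hamming_raw <- function(a, b) sum(a != b)

#' Align trimmed reads end-to-end on a reference genome
#'
#' Ungapped end-to-end placement: a read aligns at a position when its full
#' length matches the reference with at most `max_mismatch` substitutions
#' (no indels, no clipping). Both strands are searched. Candidate positions
#' come from `max_mismatch + 1` disjoint seeds (pigeonhole: at least one
#' seed is exact for any alignment within the mismatch budget); reads
#' shorter than `k * (max_mismatch + 1)` fall back to an exhaustive scan so
#' the guarantee holds at every length. Reads with more than one equally
#' best location are marked `unique = FALSE` and excluded downstream;
#' unmapped reads are dropped and counted.
#'
#' @param reads data.frame with columns `read_id`, `mate`, `sequence`,
#'   `side` (from [trim_and_tag()]; `side` defaults to `"none"` if absent).
#' @param genome A `DNAStringSet`, or a prebuilt [genome_index()].
#' @param max_mismatch Mismatch budget (default 2).
#' @param k Seed length if an index must be built.
#' @return A list with `alignments` (data.frame: `read_id`, `mate`,
#'   `contig`, `start`, `end` 0-based half-open, `strand`, `side`,
#'   `n_mismatches`, `unique`), ordered by (contig, start, read_id), and
#'   `stats` (`reads_in`, `aligned_unique`, `multimapped`, `unmapped`).
#' @export
align_reads <- function(reads, genome, max_mismatch = 2L, k = 15L) {
  if (inherits(genome, "genome_index")) {
    idx <- genome
  } else {
    if (length(genome) == 0L) stop("empty genome")
    idx <- genome_index(genome, k)
  }
  if (nrow(reads) == 0L) stop("empty read set")
  if (is.null(reads$side)) reads$side <- "none"
  if (is.null(reads$mate)) reads$mate <- 1L
  k <- idx$k

  fwd <- reads$sequence
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))

  n <- nrow(reads)
  o_contig <- character(n); o_start <- integer(n); o_end <- integer(n)
  o_strand <- character(n); o_mm <- integer(n); o_uniq <- logical(n)
  mapped <- logical(n)
  n_multi <- 0L; n_unmapped <- 0L
  for (i in seq_len(n)) {
    hits <- align_one(fwd[i], rev[i], idx, max_mismatch, k)
    if (is.null(hits)) { n_unmapped <- n_unmapped + 1L; next }
    best <- which(hits$mm == min(hits$mm))
    uniq <- length(best) == 1L
    if (!uniq) {
      n_multi <- n_multi + 1L
      best <- best[order(hits$contig[best], hits$start[best],
                         hits$strand[best])]
    }
    b <- best[1L]
    mapped[i] <- TRUE
    o_contig[i] <- hits$contig[b]; o_start[i] <- hits$start[b]
    o_end[i] <- hits$end[b]; o_strand[i] <- hits$strand[b]
    o_mm[i] <- hits$mm[b]; o_uniq[i] <- uniq
  }
  aln <- data.frame(
    read_id = reads$read_id[mapped], mate = reads$mate[mapped],
    contig = o_contig[mapped], start = o_start[mapped],
    end = o_end[mapped], strand = o_strand[mapped],
    side = reads$side[mapped], n_mismatches = o_mm[mapped],
    unique = o_uniq[mapped], stringsAsFactors = FALSE)
  aln <- aln[order(aln$contig, aln$start, aln$read_id, aln$mate), ,
             drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln,
       stats = c(reads_in = nrow(reads),
                 aligned_unique = sum(aln$unique),
                 multimapped = n_multi, unmapped = n_unmapped))
}

# All end-to-end hits of one read (both strands) within the mismatch budget,
# as parallel vectors. Returns NULL when none.
#' @keywords internal
align_one <- function(fwd, rev, idx, max_mismatch, k) {
  len <- nchar(fwd)
  h_contig <- character(0); h_start <- integer(0)
  h_strand <- character(0); h_mm <- integer(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else rev
    sr <- charToRaw(s)
    for (ci in idx$contigs) {
      if (len > ci$len) next
      if (len >= k * (max_mismatch + 1L)) {
        offs <- unique(c((0:max_mismatch) * k, len - k))
        cand <- integer(0)
        for (off in offs) {
          code <- encode_kmers(substr(s, off + 1L, off + k), k)
          cand <- c(cand, lookup_code(ci, code) - off)
        }
        cand <- unique(cand[cand >= 1L & cand + len - 1L <= ci$len])
      } else {
        # short reads: exhaustive scan (seeded pigeonhole guarantee fails)
        m <- Biostrings::matchPattern(s, ci$dna, max.mismatch = max_mismatch)
        cand <- BiocGenerics::start(m)
      }
      for (p in cand) {
        mm <- hamming_raw(charToRaw(substr(ci$seq, p, p + len - 1L)), sr)
        if (mm <= max_mismatch) {
          h_contig <- c(h_contig, ci$name); h_start <- c(h_start, p - 1L)
          h_strand <- c(h_strand, strand); h_mm <- c(h_mm, mm)
        }
      }
    }
  }
  if (!length(h_start)) return(NULL)
  list(contig = h_contig, start = h_start, end = h_start + len,
       strand = h_strand, mm = h_mm)
}
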