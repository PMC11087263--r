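#' Find a primer in a read by anchored Hamming scan
#'
#' Slides the primer over every anchor position of the read and reports the
#' leftmost position at which the Hamming distance is at most
#' `ceil(max_mismatch_frac * primer length)`. No indels are considered:
#' nested-PCR products carry the primer verbatim at a fixed offset, and an
#' indel-free search keeps downstream coordinates exact.
#'
#' @param read_sequence DNA string.
#' @param primer DNA string, length >= 10.
#' @param max_mismatch_frac Allowed mismatch fraction of the primer length
#'   (default 0.1).
#' @return 0-based match position, or `NA_integer_` if no match.
#' @examples
#' match_primer(paste0(primer_set()$nested_5TR, "TTAAGCGT"),
#'              primer_set()$nested_5TR)  # 0
#' @export
match_primer <- function(read_sequence, primer, max_mismatch_frac = 0.1) {
  plen <- nchar(primer)
  if (plen < 10L) stop("primer must be at least 10 nt (got ", plen, ")")
  n <- nchar(read_sequence)
  if (n < plen) return(NA_integer_)
  max_mm <- ceiling(max_mismatch_frac * plen)
  pr <- charToRaw(primer)
  rr <- charToRaw(read_sequence)
  for (pos in 0:(n - plen)) {
    if (sum(rr[(pos + 1L):(pos + plen)] != pr) <= max_mm) return(pos)
  }
  NA_integer_
}

#' Trim spPCR primers and tag reads with their transposon side
#'
#' For each pair, read 1 is searched for the two nested primers: a hit for
#' the 5'TR nested primer tags the pair `left`, the 3'TR nested primer tags
#' it `right`; the matched primer and any bases preceding it are removed.
#' Primary primers and splinkerette adapter sequence are trimmed wherever
#' seen (on either mate) but never used for tagging. Reads shorter than
#' `min_length` after trimming are discarded; a read 1 matching both nested
#' primers is ambiguous and the pair is discarded.
#'
#' @param reads_1,reads_2 data.frames with columns `read_id`, `sequence`
#'   (as from the internal FASTQ reader), row-matched mates.
#' @param primers A [primer_set()].
#' @param max_mismatch_frac Mismatch tolerance for primer matching.
#' @param min_length Minimum read length after trimming (default 20).
#' @return A list with `reads` (data.frame: `read_id`, `mate`, `sequence`,
#'   `side` in `left`/`right`/`none`, `trimmed_bases`) and `stats`
#'   (named counts: `pairs_in`, `pairs_out`, `discard_short`,
#'   `discard_ambiguous`, `tagged_left`, `tagged_right`, `untagged`).
#' @export
trim_and_tag <- function(reads_1, reads_2, primers = primer_set(),
                         max_mismatch_frac = 0.1, min_length = 20L) {
  stopifnot(inherits(primers, "primer_set"),
            nrow(reads_1) == nrow(reads_2))
  n <- nrow(reads_1)
  side <- rep("none", n)
  seq1 <- reads_1$sequence
  seq2 <- reads_2$sequence
  trim2 <- integer(n)

  m5 <- leftmost_matches(seq1, primers$nested_5TR, max_mismatch_frac)
  m3 <- leftmost_matches(seq1, primers$nested_3TR, max_mismatch_frac)
  ambiguous <- !is.na(m5) & !is.na(m3)
  side[!ambiguous & !is.na(m5)] <- "left"
  side[!ambiguous & is.na(m5) & !is.na(m3)] <- "right"
  # matched primer plus any bases preceding it removed
  cut <- ifelse(side == "left", m5 + nchar(primers$nested_5TR),
                ifelse(side == "right", m3 + nchar(primers$nested_3TR), 0L))
  trim1 <- as.integer(cut)
  seq1 <- substr(seq1, cut + 1L, nchar(seq1))

  # primary primers trimmed when at the (new) read start, never for tagging
  for (pp in c(primers$primary_5TR, primers$primary_3TR)) {
    mp <- leftmost_matches(seq1, pp, max_mismatch_frac)
    hit <- !ambiguous & !is.na(mp) & mp == 0L
    trim1[hit] <- trim1[hit] + nchar(pp)
    seq1[hit] <- substr(seq1[hit], nchar(pp) + 1L, nchar(seq1[hit]))
  }

  # splinkerette read-through on the mate 3' end
  ad <- revcomp(primers$splinkerette_top)
  ad <- substr(ad, 1L, min(nchar(ad), 20L))
  ma <- leftmost_matches(seq2, ad, max_mismatch_frac)
  hit <- !is.na(ma)
  trim2[hit] <- nchar(seq2[hit]) - ma[hit]
  seq2[hit] <- substr(seq2[hit], 1L, ma[hit])

  short <- !ambiguous & (nchar(seq1) < min_length | nchar(seq2) < min_length)
  keep <- !ambiguous & !short

  reads <- data.frame(
    read_id = c(reads_1$read_id[keep], reads_2$read_id[keep]),
    mate = rep(c(1L, 2L), each = sum(keep)),
    sequence = c(seq1[keep], seq2[keep]),
    side = c(side[keep], rep("none", sum(keep))),
    trimmed_bases = c(trim1[keep], trim2[keep]),
    stringsAsFactors = FALSE
  )
  stats <- c(pairs_in = n, pairs_out = sum(keep),
             discard_short = sum(short), discard_ambiguous = sum(ambiguous),
             tagged_left = sum(side[keep] == "left"),
             tagged_right = sum(side[keep] == "right"),
             untagged = sum(side[keep] == "none"))
  list(reads = reads, stats = stats)
}

# Batched [match_primer()]: leftmost anchored Hamming occurrence of one
# primer in each of many reads (vmatchPattern does the scan at C speed;
# substitutions only, same contract as match_primer).
#' @keywords internal
leftmost_matches <- function(seqs, primer, max_mismatch_frac = 0.1) {
  max_mm <- ceiling(max_mismatch_frac * nchar(primer))
  m <- Biostrings::vmatchPattern(primer, Biostrings::DNAStringSet(seqs),
                                 max.mismatch = max_mm)
  st <- Biostrings::startIndex(m)
  plen <- nchar(primer)
  mapply(function(v, w) {
    # vmatchPattern reports out-of-limits fuzzy hits; keep fully inside ones
    v <- v[v >= 1L & v + plen - 1L <= w]
    if (length(v)) min(v) - 1L else NA_integer_
  }, st, nchar(seqs), USE.NAMES = FALSE)
}
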