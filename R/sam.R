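#' Export alignment records as SAM
#'
#' Writes plain ungapped records (`<len>M` CIGAR) with `NM` (mismatches) and
#' `NH` (1 for unique, 2 for multimapped) tags; MAPQ is 60 for unique
#' placements and 0 otherwise. `SEQ` is taken from `reads` when supplied
#' (matched by `read_id` and `mate`), otherwise filled from the reference.
#'
#' @param alignments Alignment data.frame from [align_reads()].
#' @param genome A `DNAStringSet` (for the `@SQ` header and fallback SEQ).
#' @param path Output SAM path.
#' @param reads Optional trimmed-reads data.frame with `read_id`, `mate`,
#'   `sequence`.
#' @return `path`, invisibly.
#' @export
export_sam <- function(alignments, genome, path, reads = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  a <- alignments
  seqs <- character(nrow(a))
  if (!is.null(reads)) {
    key <- paste(reads$read_id, reads$mate)
    seqs <- reads$sequence[match(paste(a$read_id, a$mate), key)]
  }
  recs <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    s <- seqs[i]
    if (is.na(s) || !nzchar(s)) {
      s <- ref_seq(genome, a$contig[i], a$start[i], a$end[i])
    } else if (a$strand[i] == "-") {
      s <- revcomp(s)  # SAM stores SEQ in reference orientation
    }
    flag <- 1L + (if (a$mate[i] == 1L) 64L else 128L) +
      (if (a$strand[i] == "-") 16L else 0L)
    recs[i] <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d%s",
      a$read_id[i], flag, a$contig[i], a$start[i] + 1L,
      if (a$unique[i]) 60L else 0L, a$end[i] - a$start[i], s,
      a$n_mismatches[i], if (a$unique[i]) 1L else 2L,
      # transposon flank tag survives the round trip
      if (!is.null(a$side) && a$side[i] %in% c("left", "right"))
        paste0("\tZS:Z:", a$side[i]) else "")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Import external end-to-end alignments from SAM
#'
#' Normalizes an externally produced SAM file to the package's alignment
#' record model. Records violating the end-to-end contract — soft/hard
#' clipping, insertions, deletions or splices in the CIGAR — are excluded
#' and counted. Multimappers (NH tag > 1, or MAPQ below `mapq_min`) are
#' marked `unique = FALSE`. The transposon side tag is re-attached to
#' mate-1 records by `read_id`.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @param genome A `DNAStringSet`; records on contigs absent from it are an
#'   error.
#' @param side_map Optional data.frame with `read_id`, `side` for mate-1
#'   side re-attachment.
#' @param mapq_min MAPQ at or above which a record without an NH tag counts
#'   as unique (default 10).
#' @return A list with `alignments` (same shape as [align_reads()], plus a
#'   `paired` flag cleared when the mate is missing) and `stats`
#'   (`records_in`, `excluded_clipped_or_gapped`, `unmapped`,
#'   `multimapped`).
#' @export
import_alignments <- function(sam_path, genome, side_map = NULL,
                              mapq_min = 10L) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("NM", "NH", "ZS"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_in <- length(x$qname)
  if (n_in == 0L) {
    return(list(alignments = empty_alignments(), stats = c(
      records_in = 0L, excluded_clipped_or_gapped = 0L, unmapped = 0L,
      multimapped = 0L)))
  }
  rname <- as.character(x$rname)
  mapped <- !is.na(x$pos)
  if (any(!rname[mapped] %in% names(genome))) {
    stop("SAM refers to contigs absent from the reference: ",
         paste(unique(setdiff(rname[mapped], names(genome))), collapse = ", "))
  }
  endtoend <- mapped & grepl("^[0-9]+M$", x$cigar)
  mlen <- suppressWarnings(as.integer(sub("M$", "", x$cigar)))

  flag <- x$flag
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n_in)
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(0L, n_in)
  uniq <- ifelse(!is.na(nh), nh == 1L, x$mapq >= mapq_min)

  keep <- which(endtoend)
  aln <- data.frame(
    read_id = x$qname[keep], mate = mate[keep], contig = rname[keep],
    start = x$pos[keep] - 1L, end = x$pos[keep] - 1L + mlen[keep],
    strand = strand[keep], side = "none",
    n_mismatches = ifelse(is.na(nm[keep]), 0L, nm[keep]),
    unique = uniq[keep], stringsAsFactors = FALSE)
  zs <- x$tag$ZS
  if (!is.null(zs)) {
    zk <- zs[keep]
    aln$side[!is.na(zk)] <- zk[!is.na(zk)]
  }
  if (!is.null(side_map)) {
    m <- match(aln$read_id, side_map$read_id)
    hit <- !is.na(m) & aln$mate == 1L
    aln$side[hit] <- side_map$side[m[hit]]
  }
  # pairing flag: cleared when the mate record is missing
  mates_seen <- tapply(aln$mate, aln$read_id, function(v) length(unique(v)))
  aln$paired <- mates_seen[aln$read_id] == 2L
  aln <- aln[order(aln$contig, aln$start, aln$read_id, aln$mate), ,
             drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln,
       stats = c(records_in = n_in,
                 excluded_clipped_or_gapped = sum(mapped & !endtoend),
                 unmapped = sum(!mapped),
                 multimapped = sum(!uniq[keep])))
}

#' @keywords internal
empty_alignments <- function() {
  data.frame(read_id = character(0), mate = integer(0),
             contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), side = character(0),
             n_mismatches = integer(0), unique = logical(0),
             stringsAsFactors = FALSE)
}
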