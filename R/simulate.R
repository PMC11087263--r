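#' Simulate splinkerette-PCR junction read pairs
#'
#' Emits, for every insertion event and each of its two flanks,
#' `junction_depth` read pairs with the structure the spPCR chemistry
#' produces after nested amplification:
#'
#' * read 1 = nested primer + the duplicated TTAA + genomic flank. Left-flank
#'   (5'TR-side) reads run leftward from the TTAA, i.e. they are the reverse
#'   complement of the reference segment ending at the TTAA; right-flank
#'   (3'TR-side) reads run rightward on the forward strand. Because TTAA is
#'   its own reverse complement, the genome-derived portion of read 1 always
#'   begins with TTAA.
#' * read 2 = a purely genomic mate further into the same flank, read back
#'   toward the junction (FR orientation, fixed `insert_size`).
#'
#' Substitution errors are applied at `error_rate` per base; by default they
#' are never placed inside the terminal TTAA of read 1
#' (`params$protect_junction`). A `background_fraction` of all pairs are
#' plain genomic fragments from random positions with no primer and no
#' junction, modelling genomic carry-over.
#'
#' @param genome A `DNAStringSet`.
#' @param truth An `insertion_truth` data.frame from [place_insertions()].
#' @param params A [sim_params()] object.
#' @param primers A [primer_set()].
#' @param out_dir Directory to write into (created if needed).
#' @return Invisibly, a list with paths `reads_1`, `reads_2` (FASTQ,
#'   Phred+33, constant Q37), `truth_bed`, `truth_tsv`, plus the counts
#'   `n_junction_pairs` and `n_background_pairs`.
#' @export
simulate_reads <- function(genome, truth, params, primers = primer_set(),
                           out_dir) {
  stopifnot(inherits(params, "sim_params"), inherits(primers, "primer_set"))
  rl <- params$read_length
  p5 <- primers$nested_5TR
  p3 <- primers$nested_3TR
  if (rl <= max(nchar(p5), nchar(p3)) + 4L) {
    stop("read_length must exceed nested primer length + 4")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ids <- character(0); s1 <- character(0); s2 <- character(0)
  n_junction <- 0L

  for (i in seq_len(nrow(truth))) {
    ctg <- truth$contig[i]; t0 <- truth$ttaa_start[i]
    for (flank in c("left", "right")) {
      primer <- if (flank == "left") p5 else p3
      glen <- rl - nchar(primer)
      if (flank == "left") {
        # genomic portion ends at the TTAA; read runs leftward (revcomp)
        gseq <- revcomp(ref_seq(genome, ctg, t0 + 4L - glen, t0 + 4L))
        mate <- ref_seq(genome, ctg, t0 + 4L - params$insert_size,
                        t0 + 4L - params$insert_size + rl)
      } else {
        gseq <- ref_seq(genome, ctg, t0, t0 + glen)
        mate <- revcomp(ref_seq(genome, ctg,
                                t0 + params$insert_size - rl,
                                t0 + params$insert_size))
      }
      for (d in seq_len(params$junction_depth)) {
        ids <- c(ids, sprintf("%s:%s:%d", truth$event_id[i], flank, d))
        s1 <- c(s1, paste0(primer, gseq))
        s2 <- c(s2, mate)
        n_junction <- n_junction + 1L
      }
    }
  }

  bf <- params$background_fraction
  n_bg <- if (bf > 0) as.integer(round(n_junction * bf / (1 - bf))) else 0L

  withr::with_seed(params$seed + 7919L, {
    if (n_bg > 0L) {
      ctgs <- sample(names(genome), n_bg, replace = TRUE)
      for (j in seq_len(n_bg)) {
        L <- length(genome[[ctgs[j]]])
        pos <- sample.int(L - params$insert_size, 1L) - 1L
        ids <- c(ids, sprintf("bg:%d", j))
        s1 <- c(s1, ref_seq(genome, ctgs[j], pos, pos + rl))
        s2 <- c(s2, revcomp(ref_seq(genome, ctgs[j],
                                    pos + params$insert_size - rl,
                                    pos + params$insert_size)))
      }
    }
    if (params$error_rate > 0) {
      plen1 <- nchar(s1)  # protect terminal TTAA of junction read 1
      prot <- ifelse(grepl("^bg:", ids), -1L,
                     nchar(ifelse(grepl(":left:", ids), p5, p3)))
      pf <- if (params$protect_junction) prot + 1L else rep(-1L, length(prot))
      s1 <- mapply(add_substitutions, s1, protect_from = pf,
                   MoreArgs = list(rate = params$error_rate, protect_len = 4L),
                   USE.NAMES = FALSE)
      s2 <- vapply(s2, add_substitutions, character(1),
                   rate = params$error_rate, USE.NAMES = FALSE)
      stopifnot(identical(nchar(s1), plen1))
    }
  })

  q <- strrep("F", rl)  # constant Q37, Phred+33
  f1 <- file.path(out_dir, "reads_1.fastq")
  f2 <- file.path(out_dir, "reads_2.fastq")
  write_fastq(ids, s1, q, f1)
  write_fastq(ids, s2, q, f2)

  bed <- file.path(out_dir, "truth.bed")
  tsv <- file.path(out_dir, "truth.tsv")
  write_truth(truth, bed, tsv)

  invisible(list(reads_1 = f1, reads_2 = f2, truth_bed = bed,
                 truth_tsv = tsv, n_junction_pairs = n_junction,
                 n_background_pairs = n_bg))
}

#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Apply i.i.d. substitutions; positions [protect_from, protect_from+protect_len)
# (1-based) are exempt when protect_from > 0.
#' @keywords internal
add_substitutions <- function(seq, rate, protect_from = -1L, protect_len = 0L) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (protect_from > 0L) {
    hit <- hit[hit < protect_from | hit >= protect_from + protect_len]
  }
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' @keywords internal
write_fastq <- function(ids, seqs, qual_char, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep(substr(qual_char, 1, 1),
                                              nchar(seqs))))
  invisible(path)
}

#' Write a ground-truth table as BED and TSV
#'
#' BED intervals are the 0-based half-open TTAA tetranucleotides
#' `[ttaa_start, ttaa_start + 4)`.
#' @keywords internal
write_truth <- function(truth, bed_path, tsv_path) {
  bed <- data.frame(truth$contig, truth$ttaa_start, truth$ttaa_start + 4L,
                    truth$event_id)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bed_path)
}

#' Read FASTQ into a data.frame of id/sequence
#' @keywords internal
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}
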