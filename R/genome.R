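#' Generate a toy genome
#'
#' Draws contigs of i.i.d. uniform A/C/G/T. A random sequence contains the
#' piggyBac target tetranucleotide TTAA about once every 256 bp, so even a
#' short contig carries many candidate integration sites.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (minimum 1000).
#' @param seed Integer seed; the genome is a deterministic function of
#'   `(n_contigs, contig_length, seed)`.
#' @return A [Biostrings::DNAStringSet] with unique contig names
#'   (`contig_1`, ...); the seed is recorded in `metadata()`.
#' @examples
#' g <- generate_genome(2, 5000, seed = 7)
#' width(g)
#' @export
generate_genome <- function(n_contigs, contig_length, seed) {
  stopifnot(n_contigs >= 1)
  if (contig_length < 1000) {
    stop("contig_length must be >= 1000 (got ", contig_length, ")")
  }
  seqs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("contig_", seq_len(n_contigs))
  S4Vectors::metadata(g)$seed <- as.integer(seed)
  g
}

#' Locate TTAA sites on a contig
#'
#' @param genome A `DNAStringSet`.
#' @param contig Contig name.
#' @return Integer vector of 0-based start coordinates of every TTAA
#'   occurrence on the forward strand (TTAA is its own reverse complement,
#'   so the strands agree).
#' @export
ttaa_sites <- function(genome, contig) {
  m <- Biostrings::matchPattern("TTAA", genome[[contig]])
  BiocGenerics::start(m) - 1L
}

#' Extract reference sequence as a character string
#'
#' @param genome A `DNAStringSet`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase DNA string.
#' @keywords internal
ref_seq <- function(genome, contig, start, end) {
  as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
}

#' Simulation parameters for splinkerette read generation
#'
#' @param n_insertions Number of ground-truth integration events.
#' @param read_length Read length in bp (both mates). Default 100 (2x100 bp
#'   paired-end layout).
#' @param junction_depth Junction read pairs emitted per insertion flank.
#' @param error_rate Per-base substitution rate (in `[0, 0.1)`). Default
#'   0.01, a typical short-read error level; set 0 for exact-recovery
#'   experiments.
#' @param background_fraction Fraction of all read pairs that are plain
#'   genomic background (no primer, no junction), in `[0, 1)`. Default 0.2,
#'   modelling substantial genomic carry-over.
#' @param insert_size Outer distance from the junction to the far end of the
#'   mate, bp.
#' @param protect_junction If `TRUE` (default) substitution errors are never
#'   placed inside the terminal TTAA of a junction read, so exact-recovery
#'   tests are deterministic; set `FALSE` to stress the caller.
#' @param hard_mode If `TRUE`, [place_insertions()] drops its minimum-spacing
#'   requirement between events (collision handling stress test).
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_insertions = 30L, read_length = 100L,
                       junction_depth = 50L, error_rate = 0.01,
                       background_fraction = 0.2, insert_size = 300L,
                       protect_junction = TRUE, hard_mode = FALSE,
                       seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.1,
            background_fraction >= 0, background_fraction < 1,
            junction_depth >= 1, n_insertions >= 0)
  structure(list(
    n_insertions = as.integer(n_insertions),
    read_length = as.integer(read_length),
    junction_depth = as.integer(junction_depth),
    error_rate = error_rate,
    background_fraction = background_fraction,
    insert_size = as.integer(insert_size),
    protect_junction = isTRUE(protect_junction),
    hard_mode = isTRUE(hard_mode),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Place ground-truth piggyBac insertions at TTAA sites
#'
#' piggyBac integrates exclusively at TTAA tetranucleotides and duplicates
#' the target site, so each simulated event is anchored to a genomic TTAA.
#' By default an eligible site must be at least `2 * read_length` away from
#' every other TTAA occurrence in the genome (and `insert_size +
#' read_length` from contig ends), so each truth site is unambiguously
#' recoverable and its junction reads carry no internal TTAA: caller
#' correctness is tested separately from collision handling. `hard_mode`
#' relaxes the spacing, admitting any TTAA clear of the end margins.
#'
#' @param genome A `DNAStringSet` from [generate_genome()] (or any genome).
#' @param params A [sim_params()] object.
#' @return A data.frame of class `insertion_truth` with columns
#'   `event_id`, `contig`, `ttaa_start` (0-based coordinate of the
#'   duplicated TTAA).
#' @export
place_insertions <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_insertions
  empty <- data.frame(event_id = character(0), contig = character(0),
                      ttaa_start = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("insertion_truth", "data.frame")
  if (n == 0L) return(empty)

  margin <- params$insert_size + params$read_length
  spacing <- if (params$hard_mode) 1L else 2L * params$read_length

  sites <- do.call(rbind, lapply(names(genome), function(ctg) {
    s <- ttaa_sites(genome, ctg)
    inside <- s >= margin & s + 4L + margin <= length(genome[[ctg]])
    # isolation from every other TTAA occurrence (spacing = 1 in hard mode)
    gap_prev <- c(Inf, diff(s))
    gap_next <- c(diff(s), Inf)
    ok <- inside & gap_prev >= spacing & gap_next >= spacing
    if (!any(ok)) return(NULL)
    data.frame(contig = ctg, ttaa_start = s[ok], stringsAsFactors = FALSE)
  }))
  if (is.null(sites) || nrow(sites) < n) {
    stop(sprintf(
      "insufficient eligible TTAA sites: requested %d, only %d available at spacing %d",
      n, if (is.null(sites)) 0L else nrow(sites), spacing))
  }

  chosen <- withr::with_seed(params$seed, sample.int(nrow(sites), n))
  out <- sites[chosen, , drop = FALSE]
  out <- out[order(out$contig, out$ttaa_start), , drop = FALSE]
  out <- data.frame(event_id = sprintf("ins%03d", seq_len(n)),
                    contig = out$contig, ttaa_start = out$ttaa_start,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # TTAA invariant holds by construction; assert anyway (cheap, load-bearing)
  stopifnot(all(vapply(seq_len(n), function(i) {
    ref_seq(genome, out$contig[i], out$ttaa_start[i], out$ttaa_start[i] + 4L)
  }, character(1)) == "TTAA"))
  class(out) <- c("insertion_truth", "data.frame")
  out
}
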