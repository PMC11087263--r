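#' Splinkerette / piggyBac primer sets
#'
#' A primer set bundles the six oligonucleotides used by the splinkerette-PCR
#' (spPCR) protocol: the splinkerette adapter top strand and hairpin lower
#' strand, the primary PCR primers anchored in the piggyBac 5'TR and 3'TR
#' inverted terminal repeats, and the secondary (nested) PCR primers for the
#' same two ends. The nested primers dominate the sequenced material, so they
#' are the ones used to tag a read with its transposon side; the others are
#' trimmed when seen.
#'
#' Defaults are the standard published spPCR oligo set for piggyBac
#' (HMSpAa/HMSpBb splinkerette adapter, PB-L/R-Sp1 primary, PB-L/R-Sp2
#' nested).
#'
#' @param splinkerette_top,splinkerette_hairpin Splinkerette adapter strands.
#' @param primary_5TR,primary_3TR Primary PCR primers (piggyBac 5'TR / 3'TR).
#' @param nested_5TR,nested_3TR Secondary nested PCR primers; these assign
#'   the `left` (5'TR) and `right` (3'TR) side tags during trimming.
#' @return An object of class `primer_set`: a named list of uppercase
#'   DNA strings.
#' @examples
#' p <- primer_set()
#' nchar(p$nested_5TR)
#' @export
primer_set <- function(splinkerette_top = "CGAAGAGTAACCGTTGCTAGGAGAGACCGTGGCTGAATGAGACTGGTGTCGACACTAGTGG",
                       splinkerette_hairpin = "GATCCCACTAGTGTCGACACCAGTCTCTAATTTTTTTTTTCAAAAAAA",
                       primary_5TR = "GCGTGCTTGTCAATGCGGTAAGTGTCACTG",
                       primary_3TR = "CCTCGATATACAGACCGATAAAACACATGC",
                       nested_5TR = "ACGCATGCATTCTTGAAATATTGCTCTCTC",
                       nested_3TR = "ACGCATGATTATCTTTAACGTACGTCACAA") {
  p <- list(
    splinkerette_top = splinkerette_top,
    splinkerette_hairpin = splinkerette_hairpin,
    primary_5TR = primary_5TR,
    primary_3TR = primary_3TR,
    nested_5TR = nested_5TR,
    nested_3TR = nested_3TR
  )
  p <- lapply(p, function(s) {
    s <- toupper(gsub("[[:space:]]", "", s))
    if (!grepl("^[ACGT]+$", s)) {
      stop("primer sequences must contain only A/C/G/T after normalization")
    }
    s
  })
  if (nchar(p$nested_5TR) == 0L || nchar(p$nested_3TR) == 0L) {
    stop("nested primers must be non-empty")
  }
  structure(p, class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat("spPCR primer set:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s (%d nt)\n", nm, x[[nm]], nchar(x[[nm]])))
  }
  invisible(x)
}

#' Read a primer set from a YAML config file
#'
#' Keys are the six primer names accepted by [primer_set()]; missing keys
#' fall back to the built-in defaults.
#'
#' @param path Path to a YAML file.
#' @return A `primer_set`.
#' @export
read_primer_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(primer_set)))
  do.call(primer_set, cfg[keep])
}
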