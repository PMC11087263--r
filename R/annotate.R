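#' Load transcript models from a GFF3 annotation
#'
#' Builds per-transcript models (exons, CDS, UTRs) from `gene`/`mRNA`/
#' `exon`/`CDS` features. `five_prime_UTR`/`three_prime_UTR` features are
#' used when present; otherwise UTRs are derived as the exonic regions
#' outside the CDS span, split into 5' and 3' by strand. Records with
#' malformed coordinates or an unknown strand are rejected and counted,
#' with their line numbers reported.
#'
#' @param gff_path Path to a GFF3 file.
#' @return A list of class `gene_models`: per transcript, a list with
#'   `transcript_id`, `gene`, `contig`, `strand`, and [IRanges::IRanges]
#'   `exons`, `cds`, `utr5`, `utr3` (1-based closed, as in GFF3). The
#'   number of rejected records is in `attr(, "n_rejected")`.
#' @export
load_annotation <- function(gff_path) {
  lines <- readLines(gff_path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  bad <- integer(0)
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))) ||
        !f[7] %in% c("+", "-", ".")) {
      bad <- c(bad, i)
    }
  }
  if (length(bad)) {
    warning(sprintf("rejected %d malformed GFF3 record(s) at line(s) %s",
                    length(bad), paste(bad, collapse = ", ")))
    tmp <- tempfile(fileext = ".gff3")
    writeLines(lines[-bad], tmp)
    gff_path <- tmp
  }
  if (length(setdiff(body, bad)) == 0L) {
    warning("empty GFF3: no gene models loaded")
    return(structure(list(), class = "gene_models", n_rejected = length(bad)))
  }
  g <- rtracklayer::import(gff_path, format = "gff3")
  typ <- as.character(g$type)
  parent <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else
    NA_character_, character(1))

  tx_idx <- which(typ %in% c("mRNA", "transcript"))
  genes <- g[typ == "gene"]
  gene_name <- function(gid) {
    gi <- match(gid, genes$ID)
    if (is.na(gi)) return(gid)
    nm <- genes$Name[gi]
    if (is.null(nm) || is.na(nm)) gid else nm
  }

  models <- lapply(tx_idx, function(ti) {
    tid <- g$ID[ti]
    kids <- which(parent == tid)
    pick <- function(what) {
      r <- IRanges::IRanges(BiocGenerics::start(g)[kids][typ[kids] == what],
                            BiocGenerics::end(g)[kids][typ[kids] == what])
      IRanges::reduce(r)  # reduce() output is sorted and non-overlapping
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    utr5 <- pick("five_prime_UTR")
    utr3 <- pick("three_prime_UTR")
    strand <- as.character(BiocGenerics::strand(g)[ti])
    if (length(utr5) == 0L && length(utr3) == 0L && length(cds) > 0L) {
      utr <- IRanges::setdiff(exons, cds)
      if (strand == "-") {
        utr5 <- utr[BiocGenerics::start(utr) > max(BiocGenerics::end(cds))]
        utr3 <- utr[BiocGenerics::end(utr) < min(BiocGenerics::start(cds))]
      } else {
        utr5 <- utr[BiocGenerics::end(utr) < min(BiocGenerics::start(cds))]
        utr3 <- utr[BiocGenerics::start(utr) > max(BiocGenerics::end(cds))]
      }
    }
    list(transcript_id = tid, gene = gene_name(parent[ti]),
         contig = as.character(GenomicRanges::seqnames(g)[ti]),
         strand = strand, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
  })
  structure(models, class = "gene_models", n_rejected = length(bad))
}

# category precedence; smaller wins
.cat_rank <- c(exon = 1L, "5'UTR" = 2L, "3'UTR" = 3L, intron = 4L,
               intergenic = 5L)

#' Classify insertion sites against gene models
#'
#' Each validated site's TTAA interval (`[ttaa_start, ttaa_start + 4)`) is
#' tested for >= 1 bp of overlap with every transcript's features, with
#' precedence CDS-exon > 5'UTR > 3'UTR > intron > intergenic across all
#' overlapping transcripts ("exon" means CDS-exon; UTR hits are a separate
#' category). Ties at equal precedence resolve to the lexicographically
#' smallest gene name, so the result is invariant to GFF3 record order.
#'
#' @param calls An `insertion_calls` data.frame (only rows with
#'   `status == "validated"` are classified).
#' @param models A `gene_models` list from [load_annotation()].
#' @return A data.frame of class `site_annotations`: `site_id`, `contig`,
#'   `ttaa_start`, `category` (exon, 5'UTR, 3'UTR, intron, intergenic),
#'   `gene` (NA iff intergenic).
#' @export
classify_sites <- function(calls, models) {
  v <- calls[calls$status == "validated", , drop = FALSE]
  cat_out <- character(nrow(v))
  gene_out <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(v))) {
    site <- IRanges::IRanges(v$ttaa_start[i] + 1L, v$ttaa_start[i] + 4L)
    best_rank <- .cat_rank[["intergenic"]]
    best_gene <- NA_character_
    for (m in models) {
      if (m$contig != v$contig[i]) next
      rank <- NA_integer_
      if (n_overlap(site, m$cds)) rank <- .cat_rank[["exon"]]
      else if (n_overlap(site, m$utr5)) rank <- .cat_rank[["5'UTR"]]
      else if (n_overlap(site, m$utr3)) rank <- .cat_rank[["3'UTR"]]
      else if (length(m$exons) &&
               n_overlap(site, range(m$exons))) rank <- .cat_rank[["intron"]]
      if (is.na(rank)) next
      if (rank < best_rank ||
          (rank == best_rank && !is.na(best_gene) && m$gene < best_gene)) {
        best_rank <- rank
        best_gene <- m$gene
      }
    }
    cat_out[i] <- names(.cat_rank)[best_rank]
    gene_out[i] <- if (best_rank == .cat_rank[["intergenic"]])
      NA_character_ else best_gene
  }
  out <- data.frame(site_id = v$site_id, contig = v$contig,
                    ttaa_start = v$ttaa_start, category = cat_out,
                    gene = gene_out, stringsAsFactors = FALSE)
  class(out) <- c("site_annotations", "data.frame")
  out
}

#' @keywords internal
n_overlap <- function(a, b) {
  length(b) > 0L && IRanges::countOverlaps(a, b, minoverlap = 1L) > 0L
}

#' Tabulate insertion-site categories
#'
#' @param annotations A `site_annotations` data.frame.
#' @return Named integer vector over the five categories (exon, 5'UTR,
#'   3'UTR, intron, intergenic); the counts always sum to the number of
#'   classified sites.
#' @export
summarize_categories <- function(annotations) {
  lv <- names(.cat_rank)
  out <- table(factor(annotations$category, levels = lv))
  stopifnot(sum(out) == nrow(annotations))
  setNames(as.integer(out), lv)
}
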