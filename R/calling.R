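#' Detect TTAA junction reads
#'
#' piggyBac duplicates its TTAA target site, so after primer trimming the
#' genome-facing terminus of a junction read is the duplicated TTAA. A
#' side-tagged, uniquely aligned read becomes a junction read when the
#' reference sequence under its 5'-terminus tetranucleotide is `TTAA`
#' (strand-aware: for a `+` alignment the read's 5' end sits at the interval
#' start; for a `-` alignment at the interval end). Reads whose aligned
#' sequence carries a TTAA at any other position are flagged
#' `internal_ttaa`. Non-unique alignments are never considered; side-less
#' and terminal-TTAA-less reads are dropped and counted.
#'
#' @param alignments Alignment data.frame ([align_reads()] or
#'   [import_alignments()]).
#' @param genome A `DNAStringSet`.
#' @return A list with `junctions` (alignment columns plus `junction_end`
#'   in `5p`/`3p` — which end of the genomic interval carries the TTAA —
#'   `ttaa_start` and `internal_ttaa`) and `stats` (`alignments_in`,
#'   `dropped_nonunique`, `dropped_no_side`, `dropped_no_terminal_ttaa`,
#'   `junctions_out`).
#' @export
detect_junctions <- function(alignments, genome) {
  a <- alignments
  n_in <- nrow(a)
  n_nonuniq <- sum(!a$unique)
  a <- a[a$unique, , drop = FALSE]
  n_noside <- sum(!a$side %in% c("left", "right"))
  a <- a[a$side %in% c("left", "right"), , drop = FALSE]

  if (nrow(a) > 0L) {
    bad <- a$start < 0L | a$end > Biostrings::width(genome)[
      match(a$contig, names(genome))]
    if (any(bad | is.na(bad))) stop("alignment interval outside contig")
  }

  keep <- logical(nrow(a))
  junction_end <- character(nrow(a))
  ttaa_start <- integer(nrow(a))
  internal <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    refseg <- ref_seq(genome, a$contig[i], a$start[i], a$end[i])
    L <- nchar(refseg)
    if (a$strand[i] == "+") {
      term_off <- 0L; junction_end[i] <- "5p"
      ttaa_start[i] <- a$start[i]
    } else {
      term_off <- L - 4L; junction_end[i] <- "3p"
      ttaa_start[i] <- a$end[i] - 4L
    }
    if (substr(refseg, term_off + 1L, term_off + 4L) != "TTAA") next
    keep[i] <- TRUE
    occ <- find_ttaa(refseg)
    internal[i] <- any(occ != term_off)
  }
  jn <- a[keep, , drop = FALSE]
  jn$junction_end <- junction_end[keep]
  jn$ttaa_start <- ttaa_start[keep]
  jn$internal_ttaa <- internal[keep]
  rownames(jn) <- NULL
  list(junctions = jn,
       stats = c(alignments_in = n_in, dropped_nonunique = n_nonuniq,
                 dropped_no_side = n_noside,
                 dropped_no_terminal_ttaa = sum(!keep),
                 junctions_out = nrow(jn)))
}

# 0-based offsets of all TTAA occurrences in a string (overlap-safe; TTAA
# cannot overlap itself)
#' @keywords internal
find_ttaa <- function(s) {
  m <- gregexpr("TTAA", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Assemble TTAA-anchored candidate insertion sites
#'
#' Junction reads from the two flanks of one insertion share the duplicated
#' genomic TTAA, so reads are grouped by `(contig, ttaa_start)` — a 4-bp
#' alignment overlap at exactly that tetranucleotide. Within a site,
#' placements identical in `(start, end, strand)` are collapsed as PCR
#' duplicates before support counting; a collapsed group counts as "clean"
#' (no internal TTAA) when any member read is clean, since duplicates
#' represent one molecule and an internal TTAA created by a sequencing
#' error is a read-level artifact.
#'
#' @param junctions Junction data.frame from [detect_junctions()].
#' @return A data.frame of class `candidate_sites`, one row per distinct
#'   genomic TTAA, ordered by (contig, ttaa_start): `site_id`, `contig`,
#'   `ttaa_start`, `left_support`, `right_support` (deduplicated counts),
#'   `left_clean`, `right_clean`, `has_internal_ttaa_support_only`, and the
#'   innermost flanking-read termini `left_max_end`, `right_min_start`
#'   (NA when that flank is unsupported).
#' @export
build_candidates <- function(junctions) {
  jn <- junctions
  cols <- c("site_id", "contig", "ttaa_start", "left_support",
            "right_support", "left_clean", "right_clean",
            "has_internal_ttaa_support_only", "left_max_end",
            "right_min_start")
  if (nrow(jn) == 0L) {
    out <- as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols))
    out$site_id <- character(0); out$contig <- character(0)
    class(out) <- c("candidate_sites", "data.frame")
    return(out)
  }
  # collapse PCR duplicates: identical fragment placement
  dup_key <- paste(jn$contig, jn$ttaa_start, jn$side, jn$start, jn$end,
                   jn$strand, sep = "\r")
  clean_by_dup <- tapply(!jn$internal_ttaa, dup_key, any)
  first <- !duplicated(dup_key)
  dd <- jn[first, , drop = FALSE]
  dd$clean <- as.logical(clean_by_dup[dup_key[first]])

  site_key <- paste(dd$contig, dd$ttaa_start, sep = "\r")
  agg <- function(v, f) as.vector(tapply(v, site_key, f))
  ord_sites <- !duplicated(site_key)
  out <- data.frame(
    contig = dd$contig[ord_sites], ttaa_start = dd$ttaa_start[ord_sites],
    stringsAsFactors = FALSE)
  sk <- site_key[ord_sites]
  stat <- function(f, v) as.vector(tapply(v, site_key, f)[sk])
  out$left_support <- stat(sum, dd$side == "left")
  out$right_support <- stat(sum, dd$side == "right")
  out$left_clean <- stat(sum, dd$clean & dd$side == "left")
  out$right_clean <- stat(sum, dd$clean & dd$side == "right")
  out$has_internal_ttaa_support_only <- out$left_clean + out$right_clean == 0L
  out$left_max_end <- stat(function(v) if (all(is.na(v))) NA_integer_ else
    max(v, na.rm = TRUE), ifelse(dd$side == "left", dd$end, NA_integer_))
  out$right_min_start <- stat(function(v) if (all(is.na(v))) NA_integer_ else
    min(v, na.rm = TRUE), ifelse(dd$side == "right", dd$start, NA_integer_))
  out <- out[order(out$contig, out$ttaa_start), , drop = FALSE]
  out <- cbind(site_id = sprintf("site%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' Validate candidate sites into insertion calls
#'
#' The two-stage filter: a candidate is validated when (a) deduplicated
#' junction support is present on both flanks of the TTAA
#' (`>= min_support` each), and (b) the internal-TTAA rule holds under the
#' chosen interpretation of "no TTAA in the middle of the read":
#'
#' * `per-read` (default): at least one supporting read per flank has no
#'   internal TTAA. TTAA recurs roughly every 256 bp in random sequence, so
#'   demanding that every read be clean would discard true sites.
#' * `all-reads`: every supporting read on both flanks is clean.
#' * `between-reads`: the genomic span between the flanks' innermost read
#'   termini contains no TTAA besides the site's own. Junction reads abut
#'   the duplicated TTAA, so this span is normally the site itself and the
#'   rule reduces to (a).
#'
#' Candidates failing (a) get `rejection_reason = "single_flank"`; failing
#' only (b), `"internal_ttaa"`.
#'
#' @param candidates A `candidate_sites` data.frame.
#' @param genome A `DNAStringSet` (used by `between-reads` mode and for the
#'   output TTAA assertion).
#' @param internal_ttaa_mode One of `"per-read"`, `"all-reads"`,
#'   `"between-reads"`.
#' @param min_support Minimum deduplicated junction reads per flank
#'   (default 1).
#' @return A data.frame of class `insertion_calls`: candidate columns plus
#'   `status` (`validated`/`rejected`) and `rejection_reason`
#'   (`single_flank`/`internal_ttaa`/`none`).
#' @export
validate_sites <- function(candidates, genome,
                           internal_ttaa_mode = c("per-read", "all-reads",
                                                  "between-reads"),
                           min_support = 1L) {
  mode <- match.arg(internal_ttaa_mode)
  cd <- candidates
  # every reported coordinate must sit on a genomic TTAA
  for (i in seq_len(nrow(cd))) {
    stopifnot(ref_seq(genome, cd$contig[i], cd$ttaa_start[i],
                      cd$ttaa_start[i] + 4L) == "TTAA")
  }
  rule_a <- cd$left_support >= min_support & cd$right_support >= min_support
  rule_b <- switch(mode,
    "per-read" = cd$left_clean >= 1L & cd$right_clean >= 1L,
    "all-reads" = cd$left_clean == cd$left_support &
                  cd$right_clean == cd$right_support,
    "between-reads" = vapply(seq_len(nrow(cd)), function(i) {
      if (!rule_a[i]) return(FALSE)
      span <- sort(c(cd$right_min_start[i], cd$left_max_end[i]))
      seg <- ref_seq(genome, cd$contig[i], span[1], span[2])
      all(find_ttaa(seg) + span[1] == cd$ttaa_start[i])
    }, logical(1)))
  status <- ifelse(rule_a & rule_b, "validated", "rejected")
  reason <- ifelse(!rule_a, "single_flank",
                   ifelse(!rule_b, "internal_ttaa", "none"))
  out <- cbind(cd, status = status, rejection_reason = reason,
               stringsAsFactors = FALSE)
  class(out) <- c("insertion_calls", "data.frame")
  out
}

#' @export
print.insertion_calls <- function(x, ...) {
  cat(sprintf("Insertion calls: %d candidate site(s), %d validated\n",
              nrow(x), sum(x$status == "validated")))
  NextMethod()
}

#' Write validated calls as BED and the full call table as TSV
#'
#' BED intervals are `[ttaa_start, ttaa_start + 4)`, name = site id,
#' score = min(left, right) deduplicated support.
#'
#' @param calls An `insertion_calls` data.frame.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the validated subset.
#' @export
write_calls <- function(calls, bed_path = NULL, tsv_path = NULL) {
  v <- calls[calls$status == "validated", , drop = FALSE]
  if (!is.null(bed_path)) {
    bed <- data.frame(v$contig, v$ttaa_start, v$ttaa_start + 4L, v$site_id,
                      pmin(v$left_support, v$right_support))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(v)
}

#' Per-site junction support barplot
#'
#' @param x An `insertion_calls` data.frame.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.insertion_calls <- function(x, ...) {
  v <- x[x$status == "validated", , drop = FALSE]
  if (nrow(v) == 0L) {
    warning("no validated calls to plot")
    return(invisible(NULL))
  }
  h <- rbind(left = v$left_support, right = v$right_support)
  graphics::barplot(h, beside = TRUE, names.arg = v$site_id, las = 2,
                    legend.text = c("left flank", "right flank"),
                    ylab = "deduplicated junction reads", ...)
  invisible(NULL)
}
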