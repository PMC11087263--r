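#' Run the full insertion-site pipeline
#'
#' Executes, in order: (optional) read simulation, primer trimming and side
#' tagging, end-to-end alignment (built-in aligner, or SAM import when
#' `config$sam` is given), TTAA junction detection, candidate assembly,
#' two-stage validation, and (optional, when `config$gff` is given)
#' annotation. Intermediate and final files are persisted under
#' `config$out_dir`; identical config and seeds give byte-identical output.
#'
#' @param config A named list, or path to a YAML file with the same keys:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{reference}{FASTA path; omit when `simulate` is given.}
#'     \item{reads_1, reads_2}{paired FASTQ paths; omit when simulating.}
#'     \item{simulate}{list of [sim_params()] arguments plus `n_contigs`,
#'       `contig_length`; the simulator generates reference + reads.}
#'     \item{sam}{optional pre-aligned SAM to import instead of aligning.}
#'     \item{primers}{optional YAML primer file (defaults built in).}
#'     \item{gff}{optional GFF3 annotation for site classification.}
#'     \item{max_mismatch, k, min_length, max_mismatch_frac,
#'       internal_ttaa_mode, min_support}{stage parameters (all optional).}
#'     \item{seed}{integer seed (default 1).}
#'   }
#' @return A `run_summary` list: per-stage counters, candidate and
#'   validated counts, optional category table, config snapshot, seed and
#'   package version. Also written as `summary.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  primers <- if (is.null(config$primers)) primer_set() else
    read_primer_set(config$primers)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  summary <- list(tool = "spinmap",
                  version = as.character(utils::packageVersion("spinmap")),
                  seed = seed, config = config, stages = list())

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    genome <- stage("simulate", {
      g <- generate_genome(
        n_contigs = sim_cfg$n_contigs %||% 1L,
        contig_length = sim_cfg$contig_length %||% 1e6,
        seed = seed)
      Biostrings::writeXStringSet(g, file.path(out_dir, "reference.fa"))
      g
    })
    sp <- do.call(sim_params, c(
      sim_cfg[intersect(names(sim_cfg), names(formals(sim_params)))],
      if (!"seed" %in% names(sim_cfg)) list(seed = seed)))
    truth <- stage("simulate", place_insertions(genome, sp))
    sim <- stage("simulate",
                 simulate_reads(genome, truth, sp, primers, out_dir))
    config$reads_1 <- sim$reads_1
    config$reads_2 <- sim$reads_2
    summary$stages$simulate <- c(
      n_insertions = nrow(truth),
      junction_pairs = sim$n_junction_pairs,
      background_pairs = sim$n_background_pairs)
    summary$truth_bed <- sim$truth_bed
  } else {
    genome <- stage("load_reference",
                    Biostrings::readDNAStringSet(config$reference))
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  r1 <- stage("read_fastq", read_fastq(config$reads_1))
  r2 <- stage("read_fastq", read_fastq(config$reads_2))
  trimmed <- stage("trim", trim_and_tag(
    r1, r2, primers,
    max_mismatch_frac = config$max_mismatch_frac %||% 0.1,
    min_length = config$min_length %||% 20L))
  summary$stages$trim <- trimmed$stats

  if (!is.null(config$sam)) {
    side_map <- trimmed$reads[trimmed$reads$mate == 1L,
                              c("read_id", "side")]
    al <- stage("import_alignments",
                import_alignments(config$sam, genome, side_map))
  } else {
    al <- stage("align", align_reads(
      trimmed$reads, genome,
      max_mismatch = config$max_mismatch %||% 2L,
      k = config$k %||% 15L))
    stage("align", export_sam(al$alignments, genome,
                              file.path(out_dir, "alignments.sam"),
                              reads = trimmed$reads))
  }
  summary$stages$align <- al$stats
  usable <- al$alignments[al$alignments$unique, , drop = FALSE]

  jn <- stage("detect_junctions", detect_junctions(usable, genome))
  summary$stages$junctions <- jn$stats
  cand <- stage("build_candidates", build_candidates(jn$junctions))
  calls <- stage("validate_sites", validate_sites(
    cand, genome,
    internal_ttaa_mode = config$internal_ttaa_mode %||% "per-read",
    min_support = config$min_support %||% 1L))
  write_calls(calls, bed_path = file.path(out_dir, "calls.bed"),
              tsv_path = file.path(out_dir, "calls.tsv"))
  utils::write.table(calls[calls$status == "rejected", , drop = FALSE],
                     file.path(out_dir, "rejected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$candidates <- nrow(cand)
  summary$validated <- sum(calls$status == "validated")
  summary$stages$validate <- c(
    candidates = nrow(cand),
    validated = summary$validated,
    rejected = sum(calls$status == "rejected"))

  if (!is.null(config$gff)) {
    models <- stage("annotate", load_annotation(config$gff))
    ann <- stage("annotate", classify_sites(calls, models))
    utils::write.table(ann, file.path(out_dir, "annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$categories <- as.list(summarize_categories(ann))
  } else {
    warning("no GFF3 supplied: site classification skipped")
  }

  class(summary) <- "run_summary"
  js <- unclass(summary)
  js$stages <- lapply(js$stages, as.list)  # keep counter names in JSON
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  summary
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("spinmap run (seed %d): %d candidate site(s), %d validated\n",
              x$seed, x$candidates, x$validated))
  if (!is.null(x$categories)) {
    cat("categories:",
        paste(names(x$categories), unlist(x$categories), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check per-stage read conservation in a run summary
#'
#' Every stage must account for all of its input: reads in = reads out +
#' discarded, per category.
#'
#' @param summary A `run_summary`.
#' @return `TRUE` when every stage balances, otherwise `FALSE` (with a
#'   warning naming the stage).
#' @export
check_conservation <- function(summary) {
  s <- summary$stages
  ok <- TRUE
  chk <- function(name, total, parts) {
    if (isTRUE(all.equal(total, sum(parts)))) return(TRUE)
    warning(sprintf("stage '%s' does not conserve reads: %d != %d",
                    name, total, sum(parts)))
    FALSE
  }
  if (!is.null(s$trim)) {
    ok <- chk("trim", s$trim[["pairs_in"]],
              s$trim[c("pairs_out", "discard_short", "discard_ambiguous")]) && ok
  }
  if (!is.null(s$align) && "reads_in" %in% names(s$align)) {
    ok <- chk("align", s$align[["reads_in"]],
              s$align[c("aligned_unique", "multimapped", "unmapped")]) && ok
  }
  if (!is.null(s$junctions)) {
    ok <- chk("junctions", s$junctions[["alignments_in"]],
              s$junctions[c("dropped_nonunique", "dropped_no_side",
                            "dropped_no_terminal_ttaa", "junctions_out")]) && ok
  }
  if (!is.null(s$validate)) {
    ok <- chk("validate", s$validate[["candidates"]],
              s$validate[c("validated", "rejected")]) && ok
  }
  ok
}

#' Ellipsoid volume from caliper measurements
#'
#' The standard caliper approximation for tumour/teratoma volume,
#' `V = L * W * H * pi / 6` (mm^3 for mm inputs): the volume of an
#' ellipsoid with the three measured lengths as its axes.
#'
#' @param L,W,H Non-negative caliper lengths (mm).
#' @return Volume in mm^3. Vectorized; symmetric in its arguments and
#'   homogeneous of degree 3.
#' @examples
#' ellipsoid_volume(12, 10, 8)  # ~502.65 mm^3
#' @export
ellipsoid_volume <- function(L, W, H) {
  if (any(c(L, W, H) < 0)) stop("caliper lengths must be non-negative")
  L * W * H * pi / 6
}
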