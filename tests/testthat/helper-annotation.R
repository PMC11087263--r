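# A synthetic GFF3 with coding genes laid out on a 100 kb contig. Each gene:
# two exons with the CDS covering the middle, leaving UTR space at both ends.
make_gff <- function(path, n_genes = 10, contig = "contig_1", shuffle = FALSE) {
  lines <- c("##gff-version 3")
  recs <- character(0)
  for (i in seq_len(n_genes)) {
    base <- 2000 + (i - 1) * 9000        # 1-based gene start
    strand <- if (i %% 2 == 0) "-" else "+"
    gid <- sprintf("gene%02d", i)
    tid <- sprintf("tx%02d", i)
    e1 <- c(base, base + 999)            # exon 1
    e2 <- c(base + 3000, base + 3999)    # exon 2
    cds <- c(base + 500, base + 3499)    # CDS spans into both exons
    feats <- c(
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=Gene%02d",
              contig, e1[1], e2[2], strand, gid, i),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              contig, e1[1], e2[2], strand, tid, gid),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s",
              contig, e1[1], e1[2], strand, tid, tid),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e2;Parent=%s",
              contig, e2[1], e2[2], strand, tid, tid),
      sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c1;Parent=%s",
              contig, cds[1], e1[2], strand, tid, tid),
      sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c2;Parent=%s",
              contig, e2[1], cds[2], strand, tid, tid))
    recs <- c(recs, feats)
  }
  if (shuffle) recs <- recs[sample(length(recs))]
  writeLines(c(lines, recs), path)
  path
}

# Independent per-base category map over [1, len] (1-based), applying the
# documented precedence base by base.
brute_category_map <- function(models, len) {
  rank <- rep(5L, len)  # intergenic
  gene <- rep(NA_character_, len)
  lv <- c("exon", "5'UTR", "3'UTR", "intron", "intergenic")
  for (m in models) {
    span <- range(c(BiocGenerics::start(m$exons), BiocGenerics::end(m$exons)))
    for (pos in span[1]:span[2]) {
      r <- 4L
      inr <- function(ir) length(ir) > 0L &&
        any(pos >= BiocGenerics::start(ir) & pos <= BiocGenerics::end(ir))
      if (inr(m$cds)) r <- 1L
      else if (inr(m$utr5)) r <- 2L
      else if (inr(m$utr3)) r <- 3L
      if (r < rank[pos] ||
          (r == rank[pos] && !is.na(gene[pos]) && m$gene < gene[pos])) {
        rank[pos] <- r
        gene[pos] <- m$gene
      }
    }
  }
  list(category = lv[rank], gene = ifelse(rank == 5L, NA, gene))
}

fake_call <- function(ttaa_start, contig = "contig_1") {
  structure(data.frame(site_id = sprintf("s%d", seq_along(ttaa_start)),
                       contig = contig, ttaa_start = as.integer(ttaa_start),
                       status = "validated", stringsAsFactors = FALSE),
            class = c("insertion_calls", "data.frame"))
}

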