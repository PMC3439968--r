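# Fixtures built in code: tiny genomes, hand-made annotations, and a
# direct constructor for crosslink-site maps.

tiny_genome <- function(seqs = c(c1 = strrep("ACGT", 250))) {
  toupper(seqs)
}

# Hand-made annotation from an exon table given as a list of rows:
# list(tx, gene, contig, strand, start, end, biotype)
make_ann <- function(rows, cds = NULL, contigs = NULL) {
  ex <- do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript_id = r[[1]], gene_id = r[[2]], contig = r[[3]],
               strand = r[[4]], start = as.integer(r[[5]]),
               end = as.integer(r[[6]]),
               biotype = if (length(r) >= 7) r[[7]] else "protein_coding",
               stringsAsFactors = FALSE)
  }))
  cds_df <- if (!is.null(cds)) {
    do.call(rbind, lapply(cds, function(r) {
      data.frame(transcript_id = r[[1]], start = as.integer(r[[2]]),
                 end = as.integer(r[[3]]), stringsAsFactors = FALSE)
    }))
  } else NULL
  iclipr:::build_annotation(ex, cds_df, contigs = contigs)
}

make_map <- function(contig, strand, pos, count = 1L) {
  n <- max(length(contig), length(strand), length(pos), length(count))
  out <- data.frame(contig = rep_len(contig, n),
                    strand = rep_len(strand, n),
                    pos = as.integer(rep_len(pos, n)),
                    count = as.integer(rep_len(count, n)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xlink_map", "data.frame")
  out
}

make_tags <- function(contig, start, end, barcode, strand,
                      unique_mapping = TRUE) {
  n <- max(length(contig), length(start), length(end), length(barcode),
           length(strand))
  data.frame(contig = rep_len(contig, n), start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)),
             barcode = rep_len(barcode, n), strand = rep_len(strand, n),
             unique_mapping = rep_len(unique_mapping, n),
             stringsAsFactors = FALSE)
}

# One-region data frame usable by call_sites/cluster_fdr.
make_regions <- function(contig = "c1", strand = "+", start = 0L,
                         end = 10000L) {
  n <- max(length(contig), length(strand), length(start), length(end))
  data.frame(region_id = sprintf("region_%04d", seq_len(n)),
             contig = rep_len(contig, n), strand = rep_len(strand, n),
             start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)), stringsAsFactors = FALSE)
}

# Brute-force oracle: scan all window substrings with per-site set
# semantics, on the transcript-oriented sequence.
oracle_weights <- function(sites, genome, windows = list(c(-30, -10),
                                                         c(10, 30))) {
  rc <- function(x) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  w <- stats::setNames(numeric(1024), all_pentamers())
  for (i in seq_len(nrow(sites))) {
    seq <- genome[[sites$contig[i]]]
    L <- nchar(seq)
    found <- character(0)
    for (win in windows) {
      for (o in seq(win[1], win[2] - 4)) {
        if (sites$strand[i] == "+") {
          a <- sites$pos[i] + o
          if (a < 0 || a + 5 > L) next
          p <- substr(seq, a + 1, a + 5)
        } else {
          a <- sites$pos[i] - o - 4
          if (a < 0 || a + 5 > L) next
          p <- rc(substr(seq, a + 1, a + 5))
        }
        if (!grepl("N", p)) found <- c(found, chartr("T", "U", p))
      }
    }
    for (p in unique(found)) w[p] <- w[p] + 1
  }
  w
}

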