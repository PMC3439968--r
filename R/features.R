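# RNA-class classification of crosslink events, density enrichment,
# target-set comparison between proteins, and density-vs-expression
# correlation.
#
# Every event is assigned to exactly one class, strand-matched, by a
# fixed priority: scaRNA > snoRNA > lincRNA > other-ncRNA > CDS-exon >
# 5'UTR > 3'UTR > intron > intergenic. Nucleotide lengths per class are
# computed on the same priority-partitioned, merged intervals, so no
# base is counted twice.

.CLASS_ORDER <- c("scaRNA", "snoRNA", "lincRNA", "other-ncRNA", "CDS-exon",
                  "5'UTR", "3'UTR", "intron", "intergenic")

# Strand-aware GRanges of raw (pre-priority) intervals per class.
class_ranges <- function(annotation) {
  g <- annotation$genes
  ex <- annotation$exons
  cds <- annotation$cds
  # single seqlevels universe so set operations never mix Seqinfo objects
  sl <- sort(unique(c(g$contig, ex$contig)))
  empty <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(sl))
  mk <- function(df) {
    if (nrow(df) == 0L) return(empty)
    GenomicRanges::GRanges(factor(df$contig, levels = sl),
                           IRanges::IRanges(df$start + 1L, df$end),
                           strand = df$strand)
  }
  nc_map <- c(lincRNA = "lincRNA", snoRNA = "snoRNA", scaRNA = "scaRNA",
              snRNA = "other-ncRNA", rRNA = "other-ncRNA",
              tRNA = "other-ncRNA", other_ncRNA = "other-ncRNA")
  out <- list()
  for (cl in c("scaRNA", "snoRNA", "lincRNA", "other-ncRNA")) {
    sel <- g$biotype %in% names(nc_map)[nc_map == cl]
    out[[cl]] <- GenomicRanges::reduce(mk(g[sel, , drop = FALSE]))
  }
  pc_genes <- g$gene_id[g$biotype == "protein_coding"]
  pc_ex <- ex[ex$gene_id %in% pc_genes, , drop = FALSE]
  cds_m <- cds[cds$transcript_id %in% pc_ex$transcript_id, , drop = FALSE]
  cds_exon <- empty
  utr5 <- empty
  utr3 <- empty
  if (nrow(cds_m)) {
    for (i in seq_len(nrow(cds_m))) {
      e <- pc_ex[pc_ex$transcript_id == cds_m$transcript_id[i], ,
                 drop = FALSE]
      er <- IRanges::IRanges(e$start + 1L, e$end)
      cr <- IRanges::IRanges(cds_m$start[i] + 1L, cds_m$end[i])
      inter <- IRanges::intersect(er, cr)
      left <- if (cds_m$start[i] >= 1L) {
        IRanges::intersect(er, IRanges::IRanges(1L, cds_m$start[i]))
      } else IRanges::IRanges()
      right <- if (cds_m$end[i] < max(e$end)) {
        IRanges::intersect(er, IRanges::IRanges(cds_m$end[i] + 1L,
                                                max(e$end)))
      } else IRanges::IRanges()
      plus <- e$strand[1L] == "+"
      gr_of <- function(ir) {
        if (length(ir) == 0L) return(empty)
        GenomicRanges::GRanges(factor(e$contig[1L], levels = sl), ir,
                               strand = e$strand[1L])
      }
      cds_exon <- c(cds_exon, gr_of(inter))
      utr5 <- c(utr5, gr_of(if (plus) left else right))
      utr3 <- c(utr3, gr_of(if (plus) right else left))
    }
  }
  # exons of protein-coding transcripts without CDS count as CDS-exon
  no_cds <- setdiff(unique(pc_ex$transcript_id), cds_m$transcript_id)
  if (length(no_cds)) {
    cds_exon <- c(cds_exon, mk(pc_ex[pc_ex$transcript_id %in% no_cds, ,
                                     drop = FALSE]))
  }
  out[["CDS-exon"]] <- GenomicRanges::reduce(cds_exon)
  out[["5'UTR"]] <- GenomicRanges::reduce(utr5)
  out[["3'UTR"]] <- GenomicRanges::reduce(utr3)
  out[["intron"]] <- GenomicRanges::reduce(mk(annotation$introns))
  out
}

# Partition raw class ranges by priority (earlier classes win).
partition_classes <- function(annotation) {
  raw <- class_ranges(annotation)
  taken <- raw[[1L]][0]
  out <- list()
  for (cl in setdiff(.CLASS_ORDER, "intergenic")) {
    r <- raw[[cl]]
    if (length(taken)) {
      r <- GenomicRanges::setdiff(r, taken, ignore.strand = FALSE)
    }
    out[[cl]] <- r
    taken <- GenomicRanges::reduce(c(taken, r))
  }
  out
}

#' Classify crosslink events by RNA class
#'
#' @param map A `xlink_map` (one row per crosslink position; counts give
#'   the event weights).
#' @param annotation A `clip_annotation`.
#' @param genome_length Total genome length used for the intergenic class
#'   length; default is twice the summed contig lengths (both strands),
#'   matching the strand-aware class lengths.
#' @return Object of class `class_table`: data frame with per-class
#'   `count` (events), `length` (merged nt), `proportion` and
#'   `fold_enrichment`.
#' @export
classify <- function(map, annotation, genome_length = NULL) {
  parts <- partition_classes(annotation)
  if (is.null(genome_length)) {
    if (is.null(annotation$contig_lengths)) {
      stop("annotation lacks contig lengths; supply genome_length")
    }
    genome_length <- 2 * sum(as.numeric(annotation$contig_lengths))
  }
  ev <- GenomicRanges::GRanges(map$contig,
                               IRanges::IRanges(map$pos + 1L, width = 1L),
                               strand = map$strand)
  cls <- rep("intergenic", nrow(map))
  assigned <- logical(nrow(map))
  lens <- numeric(0L)
  for (cl in setdiff(.CLASS_ORDER, "intergenic")) {
    lens[cl] <- sum(as.numeric(IRanges::width(parts[[cl]])))
    if (length(parts[[cl]]) == 0L) next
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(ev, parts[[cl]], ignore.strand = FALSE)))
    hit <- hit[!assigned[hit]]
    cls[hit] <- cl
    assigned[hit] <- TRUE
  }
  lens["intergenic"] <- genome_length - sum(lens)
  counts <- vapply(.CLASS_ORDER,
                   function(cl) sum(map$count[cls == cl]), numeric(1L))
  out <- data.frame(class = .CLASS_ORDER, count = counts,
                    length = lens[.CLASS_ORDER],
                    proportion = if (sum(counts) > 0) counts / sum(counts)
                    else rep(0, length(counts)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- density_enrichment(out, genome_length)
  attr(out, "event_class") <- cls
  class(out) <- c("class_table", "data.frame")
  out
}

#' Fold enrichment of CLIP-tag density per RNA class
#'
#' Fold = (class count / class length) / (total count / genome length):
#' the CLIP-tag density of each class relative to the average density
#' over the genome.
#'
#' @param class_table Data frame with `count` and `length` columns.
#' @param genome_length Genome length in nucleotides for the average
#'   density.
#' @return `class_table` with a `fold_enrichment` column.
#' @export
density_enrichment <- function(class_table, genome_length) {
  bad <- class_table$length == 0 & class_table$count > 0
  if (any(bad)) {
    stop("class with zero length but nonzero count: ",
         paste(class_table$class[bad], collapse = ", "))
  }
  total <- sum(class_table$count)
  avg <- total / genome_length
  class_table$fold_enrichment <- ifelse(
    class_table$length > 0,
    (class_table$count / class_table$length) / avg, NA_real_)
  class_table
}

#' Overlap of two gene target sets
#' @param genesA,genesB Character vectors of gene ids.
#' @return Named integer vector `c(onlyA, shared, onlyB)`.
#' @export
gene_overlap <- function(genesA, genesB) {
  a <- unique(genesA)
  b <- unique(genesB)
  c(onlyA = length(setdiff(a, b)), shared = length(intersect(a, b)),
    onlyB = length(setdiff(b, a)))
}

#' Overlap of two cluster sets
#'
#' A cluster is shared when a same-strand cluster of the other set
#' overlaps it by at least `min_overlap` nucleotides.
#'
#' @param clustersA,clustersB Cluster data frames (contig, strand, start,
#'   end).
#' @param min_overlap Minimum overlap in nucleotides (default 15).
#' @return Named integer vector `c(onlyA, shared, onlyB)` where `shared`
#'   is reported for each set separately in attributes `sharedA`,
#'   `sharedB`; the `shared` element is `sharedA + sharedB`.
#' @export
cluster_overlap <- function(clustersA, clustersB, min_overlap = 15L) {
  as_gr <- function(cl) {
    if (nrow(cl) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(cl$contig,
                           IRanges::IRanges(cl$start + 1L, cl$end),
                           strand = cl$strand)
  }
  ga <- as_gr(clustersA)
  gb <- as_gr(clustersB)
  shared_a <- if (length(ga) && length(gb)) {
    length(unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      ga, gb, minoverlap = min_overlap, ignore.strand = FALSE))))
  } else 0L
  shared_b <- if (length(ga) && length(gb)) {
    length(unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      gb, ga, minoverlap = min_overlap, ignore.strand = FALSE))))
  } else 0L
  out <- c(onlyA = length(ga) - shared_a, shared = shared_a + shared_b,
           onlyB = length(gb) - shared_b)
  attr(out, "sharedA") <- shared_a
  attr(out, "sharedB") <- shared_b
  out
}

#' Correlation of CLIP-tag density with gene expression
#'
#' Per-gene tag density (strand-matched event count divided by gene
#' length) is rank-correlated (Spearman) with an expression value table.
#'
#' @param map A `xlink_map`.
#' @param annotation A `clip_annotation`.
#' @param expression Data frame with columns `gene_id` and `value`.
#' @param n_bins Number of expression bins for the summary (default 10).
#' @return List with `rho` (Spearman correlation), `n` genes, and
#'   `binned` (mean density per expression bin).
#' @export
density_expression_correlation <- function(map, annotation, expression,
                                           n_bins = 10L) {
  g <- annotation$genes[annotation$genes$gene_id %in% expression$gene_id, ,
                        drop = FALSE]
  if (nrow(g) < 10L) stop("expression values for fewer than 10 genes")
  ggr <- GenomicRanges::GRanges(g$contig,
                                IRanges::IRanges(g$start + 1L, g$end),
                                strand = g$strand)
  ev <- GenomicRanges::GRanges(map$contig,
                               IRanges::IRanges(map$pos + 1L, width = 1L),
                               strand = map$strand)
  ov <- GenomicRanges::findOverlaps(ev, ggr, ignore.strand = FALSE)
  counts <- numeric(nrow(g))
  if (length(ov)) {
    tt <- tapply(map$count[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), sum)
    counts[as.integer(names(tt))] <- tt
  }
  dens <- counts / (g$end - g$start)
  expr <- expression$value[match(g$gene_id, expression$gene_id)]
  rho <- stats::cor(dens, expr, method = "spearman")
  br <- stats::quantile(expr, probs = seq(0, 1, length.out = n_bins + 1L))
  bin <- cut(expr, breaks = unique(br), include.lowest = TRUE)
  binned <- data.frame(bin = levels(bin),
                       mean_density = as.numeric(
                         tapply(dens, bin, mean)[levels(bin)]),
                       n = as.integer(table(bin)[levels(bin)]),
                       stringsAsFactors = FALSE)
  list(rho = rho, n = nrow(g), binned = binned)
}
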