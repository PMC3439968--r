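# Genome, annotation and track I/O.
#
# All internal coordinates are 0-based half-open. GTF (1-based inclusive)
# is converted on read; BED and bedGraph are native 0-based half-open.

#' Load a genome from a FASTA file
#'
#' Reads a multi-record FASTA file and returns the contig sequences as a
#' named character vector, upper-cased. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences over `{A,C,G,T,N}`.
#' @export
load_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate record names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Contig lengths of a genome
#' @param genome Named character vector of contig sequences.
#' @return Named integer vector of lengths in nucleotides.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

.BIOTYPES <- c("protein_coding", "lincRNA", "snoRNA", "scaRNA", "snRNA",
               "rRNA", "tRNA", "other_ncRNA")

#' Load a gene annotation from a GTF file
#'
#' Parses exon and CDS features (GTF 2.2 attributes `gene_id`,
#' `transcript_id`, optional `gene_biotype`) into an internal annotation
#' model with 0-based half-open coordinates, derived introns, and
#' transcript-level CDS spans. Minus-strand transcripts keep
#' genomically sorted exon lists; transcript-oriented iteration is
#' derived where needed.
#'
#' @param path Path to a GTF file.
#' @param contigs Optional named vector of contig lengths (or a genome as
#'   returned by [load_genome()]) used for bounds checking.
#' @return An object of class `clip_annotation`: a list with data frames
#'   `genes` (gene_id, contig, strand, start, end, biotype),
#'   `transcripts` (transcript_id, gene_id), `exons`, `introns`
#'   (transcript_id, gene_id, contig, strand, start, end) and `cds`
#'   (transcript_id, start, end), plus `contig_lengths`.
#' @export
load_annotation <- function(path, contigs = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS features in GTF: ", path)
  if (is.null(df$gene_biotype)) df$gene_biotype <- NA_character_
  df$gene_biotype[is.na(df$gene_biotype)] <- "protein_coding"
  # 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  build_annotation(
    exons = df[df$type == "exon",
               c("transcript_id", "gene_id", "seqnames", "strand",
                 "start0", "end0", "gene_biotype")],
    cds = df[df$type == "CDS",
             c("transcript_id", "start0", "end0")],
    contigs = contigs
  )
}

# Assemble the annotation model from 0-based exon/CDS tables.
build_annotation <- function(exons, cds = NULL, contigs = NULL) {
  names(exons) <- c("transcript_id", "gene_id", "contig", "strand",
                    "start", "end", "biotype")
  stopifnot(all(exons$strand %in% c("+", "-")))
  if (!is.null(contigs)) {
    len <- if (is.character(contigs)) contig_lengths(contigs) else contigs
    bad <- !(exons$contig %in% names(len)) |
      exons$start < 0L | exons$end > len[exons$contig]
    if (any(bad)) {
      stop("exon outside contig bounds: ",
           paste(utils::head(exons$transcript_id[bad], 3), collapse = ", "))
    }
  } else {
    len <- NULL
  }
  o <- order(exons$contig, exons$transcript_id, exons$start)
  exons <- exons[o, , drop = FALSE]

  intron_list <- list()
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    if (nrow(ex) > 1L) {
      if (any(ex$start[-1L] < ex$end[-nrow(ex)])) {
        stop("transcript with overlapping exons: ", tx)
      }
      intron_list[[tx]] <- data.frame(
        transcript_id = tx, gene_id = ex$gene_id[1L],
        contig = ex$contig[1L], strand = ex$strand[1L],
        start = ex$end[-nrow(ex)], end = ex$start[-1L],
        stringsAsFactors = FALSE
      )
    }
  }
  introns <- if (length(intron_list)) {
    do.call(rbind, intron_list)
  } else {
    data.frame(transcript_id = character(), gene_id = character(),
               contig = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  rownames(introns) <- NULL

  agg <- split(exons, exons$gene_id)
  genes <- do.call(rbind, lapply(agg, function(g) {
    bt <- g$biotype[1L]
    if (!bt %in% .BIOTYPES) bt <- "other_ncRNA"
    data.frame(gene_id = g$gene_id[1L], contig = g$contig[1L],
               strand = g$strand[1L], start = min(g$start),
               end = max(g$end), biotype = bt, stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  transcripts <- unique(exons[, c("transcript_id", "gene_id")])
  rownames(transcripts) <- NULL

  cds_tab <- data.frame(transcript_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  if (!is.null(cds) && nrow(cds)) {
    names(cds) <- c("transcript_id", "start", "end")
    cds_tab <- do.call(rbind, lapply(split(cds, cds$transcript_id),
      function(cc) data.frame(transcript_id = cc$transcript_id[1L],
                              start = min(cc$start), end = max(cc$end),
                              stringsAsFactors = FALSE)))
    rownames(cds_tab) <- NULL
  }

  ann <- list(genes = genes, transcripts = transcripts,
              exons = exons[, c("transcript_id", "gene_id", "contig",
                                "strand", "start", "end")],
              introns = introns, cds = cds_tab, contig_lengths = len)
  class(ann) <- "clip_annotation"
  ann
}

#' @export
print.clip_annotation <- function(x, ...) {
  cat("clip_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons,",
      nrow(x$introns), "introns\n")
  invisible(x)
}

#' Derive co-transcribed regions
#'
#' Strand-specific unions of overlapping annotated gene spans, merged
#' into maximal intervals. These are the domains within which crosslink
#' positions are shuffled to form the permutation null.
#'
#' @param annotation A `clip_annotation`.
#' @return Data frame with columns `region_id`, `contig`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @export
derive_cotranscribed_regions <- function(annotation) {
  g <- annotation$genes
  out <- list()
  for (key in unique(paste(g$contig, g$strand))) {
    sel <- paste(g$contig, g$strand) == key
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start[sel] + 1L,
                                           end = g$end[sel]))
    out[[key]] <- data.frame(
      contig = g$contig[sel][1L], strand = g$strand[sel][1L],
      start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res$region_id <- sprintf("region_%04d", seq_len(nrow(res)))
  res[, c("region_id", "contig", "strand", "start", "end")]
}

#' Read aligned CLIP-tags from a BED-like file
#'
#' Columns: contig, start, end, random barcode, score (ignored), strand.
#' Coordinates are 0-based half-open. Tags flagged as non-uniquely mapped
#' are not representable in this format; all rows are taken as unique
#' mappings.
#'
#' @param path Path to the tag file.
#' @return Data frame with columns `contig`, `start`, `end`, `barcode`,
#'   `strand`, `unique_mapping`.
#' @export
read_tags <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), barcode = character(),
                      strand = character(), unique_mapping = logical(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed tag line ", which(nf < 6L)[1L], " in ", path,
         " (expected 6 tab-separated columns)")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed tag line ", which(is.na(start) | is.na(end))[1L],
         " in ", path, " (non-integer coordinates)")
  }
  if (any(start >= end)) {
    stop("malformed tag line ", which(start >= end)[1L], " in ", path,
         " (start >= end)")
  }
  if (!all(m[, 6L] %in% c("+", "-"))) {
    stop("malformed tag line ", which(!m[, 6L] %in% c("+", "-"))[1L],
         " in ", path, " (strand must be + or -)")
  }
  data.frame(contig = m[, 1L], start = start, end = end,
             barcode = m[, 4L], strand = m[, 6L],
             unique_mapping = TRUE, stringsAsFactors = FALSE)
}

#' Write aligned tags to a BED-like file
#' @param tags Tag data frame as from [read_tags()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(
    data.frame(tags$contig, tags$start, tags$end, tags$barcode, 0L,
               tags$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a crosslink-site map as strand-split bedGraph files
#'
#' Emits `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph` with rows
#' (contig, pos, pos + 1, count).
#'
#' @param map A `xlink_map` (see [pileup()]).
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_sites <- function(map, prefix) {
  paths <- c(`+` = paste0(prefix, ".plus.bedgraph"),
             `-` = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    sel <- map$strand == s
    utils::write.table(
      data.frame(map$contig[sel], map$pos[sel], map$pos[sel] + 1L,
                 map$count[sel]),
      paths[[s]], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE
    )
  }
  invisible(unname(paths))
}

#' Read strand-split bedGraph crosslink-site files
#' @param prefix Path prefix used by [write_sites()].
#' @return A `xlink_map` data frame (contig, strand, pos, count).
#' @export
read_sites <- function(prefix) {
  parts <- list()
  for (s in c("+", "-")) {
    p <- paste0(prefix, if (s == "+") ".plus.bedgraph" else ".minus.bedgraph")
    if (file.exists(p) && file.size(p) > 0L) {
      d <- utils::read.table(p, sep = "\t", stringsAsFactors = FALSE)
      parts[[s]] <- data.frame(contig = d[[1L]], strand = s, pos = d[[2L]],
                               count = d[[4L]], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(parts)) do.call(rbind, parts) else {
    data.frame(contig = character(), strand = character(), pos = integer(),
               count = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xlink_map", "data.frame")
  out
}

#' Write CLIP-tag clusters to a BED file
#'
#' Rows are 0-based half-open; the name field carries the total tag count
#' (`tags=<n>`), the score field the FDR scaled by 1000 and capped at
#' 1000.
#'
#' @param clusters Cluster data frame (see [call_clusters()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  score <- pmin(1000L, as.integer(round(clusters$fdr * 1000)))
  utils::write.table(
    data.frame(clusters$contig, clusters$start, clusters$end,
               sprintf("tags=%d", clusters$total_count), score,
               clusters$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a cluster BED file written by [write_clusters()]
#' @param path Path to the BED file.
#' @return Cluster data frame (contig, strand, start, end, total_count,
#'   fdr).
#' @export
read_clusters <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      total_count = integer(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(contig = d[[1L]], strand = d[[6L]], start = d[[2L]],
             end = d[[3L]],
             total_count = as.integer(sub("tags=", "", d[[4L]], fixed = TRUE)),
             fdr = d[[5L]] / 1000, stringsAsFactors = FALSE)
}
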