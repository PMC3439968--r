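# From aligned CLIP-tags to a deduplicated crosslink-site count map.
#
# iCLIP reverse transcription truncates at the crosslinked nucleotide,
# so the inferred protein contact is the nucleotide immediately 5' of
# the read start (in read orientation): genomic start - 1 on '+',
# genomic end (half-open) on '-'.

#' Split a raw read into experiment barcode, random barcode and insert
#'
#' The layout mask is read 5' to 3': `N` marks a random-barcode (UMI)
#' position, `X` an experiment-barcode position. Both barcodes are
#' removed; the remainder of the read is the insert.
#'
#' @param read_sequence Read sequence (character scalar).
#' @param layout Barcode mask over `{N, X}`, default `"NNNXXXXNN"`.
#' @return List with `experiment_barcode`, `random_barcode`,
#'   `insert_sequence`.
#' @export
parse_barcode <- function(read_sequence, layout = "NNNXXXXNN") {
  mask <- strsplit(layout, "")[[1L]]
  if (length(mask) == 0L || !any(mask == "N") ||
      !all(mask %in% c("N", "X"))) {
    stop("barcode layout must be a nonempty string over {N, X} with >= 1 N")
  }
  bases <- strsplit(read_sequence, "")[[1L]]
  if (length(bases) <= length(mask)) {
    stop("read shorter than barcode mask (", length(bases), " <= ",
         length(mask), ")")
  }
  head_bases <- bases[seq_along(mask)]
  list(
    experiment_barcode = paste(head_bases[mask == "X"], collapse = ""),
    random_barcode = paste(head_bases[mask == "N"], collapse = ""),
    insert_sequence = paste(bases[-seq_along(mask)], collapse = "")
  )
}

#' Assign crosslink positions to aligned tags
#'
#' The crosslink site is the first nucleotide upstream of the tag start
#' in read orientation: `start - 1` on the '+' strand, `end` (half-open)
#' on the '-' strand. Tags whose crosslink would fall outside the contig
#' get `NA` and are dropped by downstream steps.
#'
#' @param tags Tag data frame (contig, start, end, barcode, strand,
#'   unique_mapping).
#' @param contig_len Named vector of contig lengths (or a genome).
#' @return `tags` with an added integer column `xlink_pos` (`NA` where
#'   the position falls off the contig) and non-unique mappings removed.
#' @export
assign_crosslink <- function(tags, contig_len) {
  if (is.character(contig_len)) contig_len <- contig_lengths(contig_len)
  n_nonunique <- sum(!tags$unique_mapping)
  if (n_nonunique > 0L) {
    message("dropping ", n_nonunique, " non-uniquely mapped tags")
    tags <- tags[tags$unique_mapping, , drop = FALSE]
  }
  pos <- ifelse(tags$strand == "+", tags$start - 1L, tags$end)
  len <- contig_len[tags$contig]
  pos[pos < 0L | pos >= len] <- NA_integer_
  tags$xlink_pos <- as.integer(pos)
  tags
}

#' Collapse PCR duplicates by random barcode
#'
#' One unique event is kept per distinct (contig, strand, crosslink
#' position, random barcode) combination; truncation-length variants of
#' the same molecule therefore collapse. Barcodes containing `N` only
#' match themselves. Tags without an assigned crosslink position are
#' dropped.
#'
#' @param tags Tag data frame with `xlink_pos` from [assign_crosslink()].
#' @return Data frame of unique events (contig, strand, pos, barcode);
#'   attribute `n_duplicates` records the number discarded.
#' @export
deduplicate <- function(tags) {
  tags <- tags[!is.na(tags$xlink_pos), , drop = FALSE]
  key <- paste(tags$contig, tags$strand, tags$xlink_pos, tags$barcode,
               sep = "\r")
  keep <- !duplicated(key)
  ev <- data.frame(contig = tags$contig[keep], strand = tags$strand[keep],
                   pos = tags$xlink_pos[keep], barcode = tags$barcode[keep],
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$contig, ev$strand, ev$pos, ev$barcode), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "n_duplicates") <- sum(!keep)
  ev
}

#' Pile up unique events into a crosslink-site count map
#'
#' @param events Deduplicated events from [deduplicate()].
#' @return An object of class `xlink_map`: a data frame (contig, strand,
#'   pos, count) with one row per occupied position; `sum(count)` equals
#'   the number of events.
#' @export
pileup <- function(events) {
  if (nrow(events) == 0L) {
    out <- data.frame(contig = character(), strand = character(),
                      pos = integer(), count = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("xlink_map", "data.frame")
    return(out)
  }
  key <- paste(events$contig, events$strand, events$pos, sep = "\r")
  tab <- table(key)
  first <- !duplicated(key)
  out <- data.frame(contig = events$contig[first],
                    strand = events$strand[first],
                    pos = events$pos[first],
                    count = as.integer(tab[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("xlink_map", "data.frame")
  out
}

#' Run the tag-to-sites stage in one call
#'
#' Convenience wrapper: assign crosslinks, deduplicate, pile up.
#'
#' @inheritParams assign_crosslink
#' @return A `xlink_map`.
#' @export
tags_to_sites <- function(tags, contig_len) {
  pileup(deduplicate(assign_crosslink(tags, contig_len)))
}
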