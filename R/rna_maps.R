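# Positional metaprofiles (RNA maps) of crosslink sites around splice
# sites, branch points and transcript anchors.
#
# Offsets are in transcript orientation (negative = upstream of the
# anchor/boundary). Only the feature half adjacent to each boundary
# contributes, and per-offset densities are normalized by the number of
# feature halves spanning that offset ("crosslinks per 10^3 nt"), which
# corrects for the genome-wide length distribution of exons and introns.

# Accumulate +1 over [lo, hi] (0-based offsets in -W..W) into a
# length-(2W+1) array, vectorized over junctions via a difference array.
add_ranges <- function(acc, lo, hi, W) {
  lo <- pmax(lo, -W)
  hi <- pmin(hi, W)
  ok <- lo <= hi
  if (!any(ok)) return(acc)
  d <- numeric(2L * W + 2L)
  li <- tabulate(lo[ok] + W + 1L, nbins = 2L * W + 2L)
  hi_t <- tabulate(hi[ok] + W + 2L, nbins = 2L * W + 2L)
  acc + cumsum(li - hi_t)[seq_len(2L * W + 1L)]
}

# Unique introns pooled over transcripts within each gene, with the
# flanking exon lengths needed for junction geometry.
pooled_junction_parts <- function(annotation) {
  ex <- annotation$exons
  parts <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    if (nrow(e) < 2L) next
    n <- nrow(e)
    parts[[tx]] <- data.frame(
      gene_id = e$gene_id[1L], contig = e$contig[1L], strand = e$strand[1L],
      intron_start = e$end[-n], intron_end = e$start[-1L],
      exon_left_len = e$end[-n] - e$start[-n],
      exon_right_len = e$end[-1L] - e$start[-1L],
      stringsAsFactors = FALSE
    )
  }
  if (!length(parts)) {
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), intron_start = integer(),
                      intron_end = integer(), exon_left_len = integer(),
                      exon_right_len = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Build splice-site junctions and per-offset normalizers
#'
#' Derives exon-intron (5'ss) and intron-exon (3'ss) junctions from the
#' pooled introns of an annotation. Only the feature half adjacent to the
#' boundary is used (`floor(length/2)` nucleotides). Junctions whose exon
#' is shorter than `min_exon` or whose intron is shorter than
#' `min_intron` are excluded.
#'
#' @param annotation A `clip_annotation`.
#' @param window Half-width of the offset window around each boundary
#'   (default 300; offsets run `-window..window`).
#' @param min_exon Minimum exon length (default 60).
#' @param min_intron Minimum intron length (default 200).
#' @return Object of class `junction_set`: list with `junctions` (one row
#'   per retained junction: kind, contig, strand, boundary, exon_half,
#'   intron_half), `normalizer` (per kind, counts of spanning halves per
#'   offset), `window`, and `n_excluded`.
#' @export
build_junctions <- function(annotation, window = 300L, min_exon = 60L,
                            min_intron = 200L) {
  p <- pooled_junction_parts(annotation)
  intron_len <- p$intron_end - p$intron_start
  plus <- p$strand == "+"
  # exon on the transcript-upstream side of the intron
  exon_up <- ifelse(plus, p$exon_left_len, p$exon_right_len)
  exon_down <- ifelse(plus, p$exon_right_len, p$exon_left_len)
  # genomic position of the offset-0 base at each boundary
  b5 <- ifelse(plus, p$intron_start, p$intron_end - 1L)
  b3 <- ifelse(plus, p$intron_end, p$intron_start - 1L)
  j <- rbind(
    data.frame(kind = "5ss", contig = p$contig, strand = p$strand,
               boundary = b5, exon_len = exon_up, intron_len = intron_len,
               stringsAsFactors = FALSE),
    data.frame(kind = "3ss", contig = p$contig, strand = p$strand,
               boundary = b3, exon_len = exon_down, intron_len = intron_len,
               stringsAsFactors = FALSE)
  )
  # collapse duplicates across transcripts (same boundary), keeping the
  # longest flanking features
  o <- order(j$kind, j$contig, j$strand, j$boundary,
             -j$exon_len, -j$intron_len)
  j <- j[o, , drop = FALSE]
  j <- j[!duplicated(j[, c("kind", "contig", "strand", "boundary")]), ,
         drop = FALSE]
  keep <- j$exon_len >= min_exon & j$intron_len >= min_intron
  n_excluded <- sum(!keep)
  j <- j[keep, , drop = FALSE]
  j$exon_half <- j$exon_len %/% 2L
  j$intron_half <- j$intron_len %/% 2L
  rownames(j) <- NULL

  W <- as.integer(window)
  norm <- list()
  for (kind in c("5ss", "3ss")) {
    sel <- j$kind == kind
    acc <- numeric(2L * W + 1L)
    if (any(sel)) {
      if (kind == "5ss") {
        acc <- add_ranges(acc, -j$exon_half[sel], rep(-1L, sum(sel)), W)
        acc <- add_ranges(acc, rep(0L, sum(sel)), j$intron_half[sel] - 1L, W)
      } else {
        acc <- add_ranges(acc, -j$intron_half[sel], rep(-1L, sum(sel)), W)
        acc <- add_ranges(acc, rep(0L, sum(sel)), j$exon_half[sel] - 1L, W)
      }
    }
    norm[[kind]] <- stats::setNames(acc, as.character(seq.int(-W, W)))
  }
  structure(list(junctions = j, normalizer = norm, window = W,
                 min_exon = min_exon, min_intron = min_intron,
                 n_excluded = n_excluded),
            class = "junction_set")
}

# Footprint rows (genomic position, offset) for a set of anchors with
# per-anchor covered offset ranges [lo1,hi1] (and optionally [lo2,hi2]).
expand_footprint <- function(contig, strand, anchor, lo, hi, id, W) {
  lo <- pmax(lo, -W)
  hi <- pmin(hi, W)
  ok <- lo <= hi
  if (!any(ok)) {
    return(data.frame(contig = character(), strand = character(),
                      g = integer(), off = integer(), id = integer(),
                      stringsAsFactors = FALSE))
  }
  n <- hi[ok] - lo[ok] + 1L
  off <- unlist(lapply(which(ok), function(i) seq.int(lo[i], hi[i])))
  ct <- rep(contig[ok], n)
  st <- rep(strand[ok], n)
  an <- rep(anchor[ok], n)
  g <- ifelse(st == "+", an + off, an - off)
  data.frame(contig = ct, strand = st, g = as.integer(g), off = off,
             id = rep(id[ok], n), stringsAsFactors = FALSE)
}

# Assign each site position to its closest covering anchor row; ties go
# to the downstream boundary in transcript orientation (negative offset).
assign_to_footprint <- function(map, fp) {
  if (nrow(fp) == 0L || nrow(map) == 0L) {
    return(data.frame(site = integer(), off = integer(), id = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  skey <- paste(map$contig, map$strand, map$pos, sep = "\r")
  fkey <- paste(fp$contig, fp$strand, fp$g, sep = "\r")
  m <- match(fkey, skey)
  hit <- !is.na(m)
  if (!any(hit)) {
    return(data.frame(site = integer(), off = integer(), id = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  cand <- data.frame(site = m[hit], off = fp$off[hit], id = fp$id[hit],
                     kind = if (!is.null(fp$kind)) fp$kind[hit] else
                       NA_character_, stringsAsFactors = FALSE)
  o <- order(cand$site, abs(cand$off), cand$off, cand$id)
  cand <- cand[o, , drop = FALSE]
  cand[!duplicated(cand$site), , drop = FALSE]
}

make_meta_profile <- function(raw, norm, W, half_width, sigma) {
  density <- ifelse(norm > 0, 1000 * raw / norm, NA_real_)
  smoothed <- smooth_profile(density, half_width = half_width,
                             sigma = sigma)
  out <- data.frame(offset = seq.int(-W, W), raw = raw, normalizer = norm,
                    density = density, smoothed = smoothed)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Metaprofiles of crosslink sites around splice-site junctions
#'
#' Each unique crosslink position lying in a retained feature half is
#' assigned to its closest retained boundary (ties to the downstream
#' boundary in transcript orientation), contributes 1.0 at its offset,
#' and densities are reported per 10^3 nt of spanning feature halves.
#'
#' @param map A `xlink_map` (unique crosslink positions; counts are not
#'   used as weights).
#' @param junctions A `junction_set` from [build_junctions()].
#' @param half_width Gaussian smoothing half-width (default 5).
#' @param sigma Gaussian sigma (default `half_width / 2`).
#' @return Named list of two `meta_profile` data frames (`5ss`, `3ss`)
#'   with attributes `n_assigned` and `n_unassigned`.
#' @export
junction_profile <- function(map, junctions, half_width = 5L,
                             sigma = half_width / 2) {
  j <- junctions$junctions
  W <- junctions$window
  fp <- list()
  for (kind in c("5ss", "3ss")) {
    sel <- which(j$kind == kind)
    if (!length(sel)) next
    if (kind == "5ss") {
      lo1 <- -j$exon_half[sel]; hi1 <- rep(-1L, length(sel))
      lo2 <- rep(0L, length(sel)); hi2 <- j$intron_half[sel] - 1L
    } else {
      lo1 <- -j$intron_half[sel]; hi1 <- rep(-1L, length(sel))
      lo2 <- rep(0L, length(sel)); hi2 <- j$exon_half[sel] - 1L
    }
    f1 <- expand_footprint(j$contig[sel], j$strand[sel], j$boundary[sel],
                           lo1, hi1, sel, W)
    f2 <- expand_footprint(j$contig[sel], j$strand[sel], j$boundary[sel],
                           lo2, hi2, sel, W)
    f <- rbind(f1, f2)
    if (nrow(f)) f$kind <- kind
    fp[[kind]] <- f
  }
  fp <- do.call(rbind, fp)
  asg <- assign_to_footprint(map, fp)
  out <- list()
  for (kind in c("5ss", "3ss")) {
    raw <- numeric(2L * W + 1L)
    ksel <- asg$kind == kind
    if (any(ksel)) {
      raw <- tabulate(asg$off[ksel] + W + 1L, nbins = 2L * W + 1L)
    }
    out[[kind]] <- make_meta_profile(raw, junctions$normalizer[[kind]], W,
                                     half_width, sigma)
  }
  attr(out, "n_assigned") <- nrow(asg)
  attr(out, "n_unassigned") <- nrow(map) - nrow(asg)
  out
}

#' Gaussian smoothing of a metaprofile density
#'
#' Discrete Gaussian kernel with support `-half_width..half_width` and
#' standard deviation `sigma` (default `half_width / 2`), normalized to
#' sum 1. At profile edges and across undefined offsets (`NA`, e.g.
#' normalizer 0) the kernel is renormalized over the defined neighbors,
#' so total mass is conserved wherever no truncation occurs.
#'
#' @param x Numeric vector of densities over contiguous offsets (`NA`
#'   where undefined).
#' @param half_width Kernel support half-width (>= 1).
#' @param sigma Kernel standard deviation; set `sigma = half_width` to
#'   treat the stated half-width as sigma instead of support.
#' @return Numeric vector like `x` (`NA` preserved).
#' @export
smooth_profile <- function(x, half_width = 5L, sigma = half_width / 2) {
  if (half_width < 1L) stop("half_width must be >= 1")
  ii <- seq.int(-half_width, half_width)
  w <- exp(-ii^2 / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(x)
  def <- !is.na(x)
  num <- numeric(n)
  den <- numeric(n)
  for (k in seq_along(ii)) {
    sh <- ii[k]
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    okd <- ok
    okd[ok] <- def[src[ok]]
    num[okd] <- num[okd] + w[k] * x[src[okd]]
    den[okd] <- den[okd] + w[k]
  }
  out <- rep(NA_real_, n)
  out[def] <- num[def] / den[def]
  out
}

#' Select one branch point per intron from a candidate table
#'
#' Filters, in order: introns shorter than `min_intron` are dropped;
#' candidates with negative SVM score or outside the last half of the
#' intron are dropped; the highest-scoring remaining candidate is chosen,
#' ties going to the candidate closest to the intron-exon junction; the
#' selection is discarded if it lies closer than `min_dist` nucleotides
#' to that junction.
#'
#' @param annotation A `clip_annotation` (supplies intron coordinates).
#' @param candidates Data frame with columns `intron_id`, `contig`,
#'   `position` (0-based genomic), `strand`, `score`. `intron_id` must be
#'   `"<contig>:<strand>:<start>-<end>"` for a pooled intron.
#' @param min_intron Minimum intron length (default 240).
#' @param min_dist Minimum distance of the branch point to the 3' splice
#'   site (default 20).
#' @return Data frame with one row per unique intron: intron coordinates,
#'   `bp_pos`, `score`, `selected`, and `reason` for exclusions.
#' @export
select_branch_points <- function(annotation, candidates, min_intron = 240L,
                                 min_dist = 20L) {
  intr <- unique(annotation$introns[, c("contig", "strand", "start", "end")])
  intr$intron_id <- intron_id(intr$contig, intr$strand, intr$start, intr$end)
  rownames(intr) <- NULL
  intr$len <- intr$end - intr$start
  out <- intr
  out$bp_pos <- NA_integer_
  out$score <- NA_real_
  out$selected <- FALSE
  out$reason <- NA_character_
  for (i in seq_len(nrow(intr))) {
    cc <- candidates[candidates$intron_id == intr$intron_id[i], ,
                     drop = FALSE]
    if (intr$len[i] < min_intron) {
      out$reason[i] <- "intron_too_short"
      next
    }
    if (nrow(cc) == 0L) {
      out$reason[i] <- "no_candidates"
      next
    }
    if (any(cc$position < intr$start[i] | cc$position >= intr$end[i])) {
      stop("branch-point candidate outside its intron: ", intr$intron_id[i])
    }
    half <- intr$len[i] %/% 2L
    # distance to the 3' splice site: 0 = last intron nucleotide
    d3 <- if (intr$strand[i] == "+") intr$end[i] - 1L - cc$position else
      cc$position - intr$start[i]
    in_last_half <- d3 < half
    ok <- cc$score >= 0 & in_last_half
    if (!any(ok)) {
      out$reason[i] <- "no_valid_candidate"
      next
    }
    cc <- cc[ok, , drop = FALSE]
    d3 <- d3[ok]
    pick <- order(-cc$score, d3)[1L]
    if (d3[pick] < min_dist) {
      out$reason[i] <- "too_close_to_3ss"
      next
    }
    out$bp_pos[i] <- cc$position[pick]
    out$score[i] <- cc$score[pick]
    out$selected[i] <- TRUE
  }
  out
}

#' Canonical intron identifier
#' @param contig,strand,start,end Intron coordinates (0-based half-open).
#' @return Character vector of ids `"<contig>:<strand>:<start>-<end>"`.
#' @export
intron_id <- function(contig, strand, start, end) {
  sprintf("%s:%s:%d-%d", contig, strand, start, end)
}

#' Metaprofile of crosslink sites around branch points
#'
#' Offsets are relative to the branch-point nucleotide (offset 0) in
#' transcript orientation; only the last half of each intron contributes,
#' and the normalizer counts introns whose last-half footprint spans each
#' offset.
#'
#' @param map A `xlink_map`.
#' @param selections Output of [select_branch_points()] (only selected
#'   rows are used).
#' @param window Offset half-window (default 300).
#' @inheritParams junction_profile
#' @return A `meta_profile` data frame.
#' @export
branchpoint_profile <- function(map, selections, window = 300L,
                                half_width = 5L, sigma = half_width / 2) {
  sel <- selections[selections$selected, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no selected branch points")
  W <- as.integer(window)
  half <- sel$len %/% 2L
  # offset range of the last-half footprint relative to the branch point
  lo <- ifelse(sel$strand == "+", sel$end - half - sel$bp_pos,
               sel$bp_pos - (sel$start + half - 1L))
  hi <- ifelse(sel$strand == "+", sel$end - 1L - sel$bp_pos,
               sel$bp_pos - sel$start)
  norm <- add_ranges(numeric(2L * W + 1L), lo, hi, W)
  fp <- expand_footprint(sel$contig, sel$strand, sel$bp_pos, lo, hi,
                         seq_len(nrow(sel)), W)
  asg <- assign_to_footprint(map, fp)
  raw <- if (nrow(asg)) tabulate(asg$off + W + 1L, nbins = 2L * W + 1L) else
    numeric(2L * W + 1L)
  out <- make_meta_profile(raw, stats::setNames(norm,
                                                as.character(seq.int(-W, W))),
                           W, half_width, sigma)
  attr(out, "n_assigned") <- nrow(asg)
  attr(out, "n_unassigned") <- nrow(map) - nrow(asg)
  out
}

#' Anchors at transcript 3' ends or ORF ends
#'
#' @param annotation A `clip_annotation`.
#' @param type `"tx3p"` for the transcript 3'-terminal nucleotide,
#'   `"cds_end"` for the last coding nucleotide (ORF-3'UTR boundary);
#'   the latter keeps only transcripts with a CDS.
#' @param biotype Optional biotype filter on the owning gene.
#' @return Data frame (transcript_id, contig, strand, anchor, span_start,
#'   span_end) suitable for [anchored_profile()].
#' @export
transcript_anchors <- function(annotation, type = c("tx3p", "cds_end"),
                               biotype = NULL) {
  type <- match.arg(type)
  ex <- annotation$exons
  sp <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(e) {
    data.frame(transcript_id = e$transcript_id[1L], gene_id = e$gene_id[1L],
               contig = e$contig[1L], strand = e$strand[1L],
               span_start = min(e$start), span_end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  if (!is.null(biotype)) {
    bt <- annotation$genes$biotype[match(sp$gene_id, annotation$genes$gene_id)]
    sp <- sp[bt %in% biotype, , drop = FALSE]
  }
  if (type == "tx3p") {
    sp$anchor <- ifelse(sp$strand == "+", sp$span_end - 1L, sp$span_start)
  } else {
    m <- match(sp$transcript_id, annotation$cds$transcript_id)
    sp <- sp[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
    sp$anchor <- ifelse(sp$strand == "+", annotation$cds$end[m] - 1L,
                        annotation$cds$start[m])
  }
  sp
}

#' Metaprofile of items relative to transcript anchors
#'
#' Items (crosslink sites or cluster midpoints) are assigned to the
#' closest anchor whose transcript span contains them; offsets are in
#' transcript orientation. The normalizer counts transcripts whose span
#' covers each offset.
#'
#' @param items Data frame with columns `contig`, `strand`, `pos`
#'   (cluster midpoints can be computed with [cluster_midpoints()]).
#' @param anchors Data frame from [transcript_anchors()].
#' @param window Offset half-window (default 300).
#' @inheritParams junction_profile
#' @return A `meta_profile` data frame.
#' @export
anchored_profile <- function(items, anchors, window = 300L,
                             half_width = 5L, sigma = half_width / 2) {
  if (nrow(anchors) == 0L) stop("no anchors supplied")
  W <- as.integer(window)
  lo <- ifelse(anchors$strand == "+", anchors$span_start - anchors$anchor,
               anchors$anchor - (anchors$span_end - 1L))
  hi <- ifelse(anchors$strand == "+", anchors$span_end - 1L - anchors$anchor,
               anchors$anchor - anchors$span_start)
  norm <- add_ranges(numeric(2L * W + 1L), lo, hi, W)
  fp <- expand_footprint(anchors$contig, anchors$strand, anchors$anchor,
                         lo, hi, seq_len(nrow(anchors)), W)
  asg <- assign_to_footprint(items, fp)
  raw <- if (nrow(asg)) tabulate(asg$off + W + 1L, nbins = 2L * W + 1L) else
    numeric(2L * W + 1L)
  out <- make_meta_profile(raw, stats::setNames(norm,
                                                as.character(seq.int(-W, W))),
                           W, half_width, sigma)
  attr(out, "n_assigned") <- nrow(asg)
  attr(out, "n_unassigned") <- nrow(items) - nrow(asg)
  out
}

#' Cluster midpoints as profile items
#' @param clusters Cluster data frame.
#' @return Data frame (contig, strand, pos) of interval midpoints.
#' @export
cluster_midpoints <- function(clusters) {
  data.frame(contig = clusters$contig, strand = clusters$strand,
             pos = as.integer((clusters$start + clusters$end - 1L) %/% 2L),
             stringsAsFactors = FALSE)
}
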