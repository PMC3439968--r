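# Permutation FDR for crosslink sites and CLIP-tag clusters.
#
# The null model re-places every event in a co-transcribed region
# independently and uniformly within that region. For each count height
# k, FDR(k) = (mean number of null positions with count >= k) /
# (number of observed positions with count >= k), clipped to [0, 1] and
# made non-increasing in k. Significance uses strict inequality
# (fdr < threshold).

#' Randomize event positions uniformly within a region
#'
#' @param event_count Number of events to place (>= 0).
#' @param region_length Region length in nucleotides (>= 1).
#' @return Integer vector of length `region_length` with per-position
#'   counts; `sum` equals `event_count`.
#' @export
randomize_within_region <- function(event_count, region_length) {
  stopifnot(region_length >= 1L, event_count >= 0L)
  if (event_count == 0L) return(integer(region_length))
  tabulate(sample.int(region_length, event_count, replace = TRUE),
           nbins = region_length)
}

# Map each site row to the index of its containing region (NA if none).
assign_region <- function(map, regions) {
  idx <- rep(NA_integer_, nrow(map))
  mk <- paste(map$contig, map$strand)
  rk <- paste(regions$contig, regions$strand)
  for (key in unique(rk)) {
    rsel <- which(rk == key)
    msel <- which(mk == key)
    if (!length(msel)) next
    o <- order(regions$start[rsel])
    rs <- regions$start[rsel][o]
    re <- regions$end[rsel][o]
    j <- findInterval(map$pos[msel], rs)
    hit <- j >= 1L & map$pos[msel] < re[pmax(j, 1L)]
    idx[msel[hit]] <- rsel[o][j[hit]]
  }
  idx
}

# Null distribution summary for one region: for each height in `ks`,
# the mean number of randomized positions with count >= that height.
null_ge_heights <- function(n_events, region_length, ks, n_perm) {
  acc <- numeric(length(ks))
  for (p in seq_len(n_perm)) {
    h <- rle(sort.int(sample.int(region_length, n_events,
                                 replace = TRUE)))$lengths
    acc <- acc + vapply(ks, function(k) sum(h >= k), numeric(1L))
  }
  acc / n_perm
}

# Clip to [0,1] and enforce monotone non-increase in count height
# (heights ascending): a taller pile is never less significant.
monotone_fdr <- function(fdr_raw) {
  fdr <- pmin(1, pmax(0, fdr_raw))
  rev(cummax(rev(fdr)))
}

#' Call statistically significant crosslink sites
#'
#' Per co-transcribed region, compares observed per-position unique-tag
#' counts against `n_perm` uniform re-placements of all of the region's
#' events; a site's FDR is the height-level FDR of its count. Events
#' outside every region are reported with `fdr = NA` (unscored).
#'
#' @param map A `xlink_map`.
#' @param regions Co-transcribed regions from
#'   [derive_cotranscribed_regions()].
#' @param n_perm Number of permutations (default 100).
#' @param threshold FDR significance threshold (default 0.05, strict).
#' @param seed Optional integer seed for the permutation RNG.
#' @return Data frame of site calls (contig, strand, pos, count, fdr,
#'   region_id, significant).
#' @export
call_sites <- function(map, regions, n_perm = 100L, threshold = 0.05,
                       seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ridx <- assign_region(map, regions)
  fdr <- rep(NA_real_, nrow(map))
  for (r in unique(ridx[!is.na(ridx)])) {
    sel <- which(!is.na(ridx) & ridx == r)
    counts <- map$count[sel]
    n_events <- sum(counts)
    L <- regions$end[r] - regions$start[r]
    ks <- sort(unique(counts))
    obs_ge <- vapply(ks, function(k) sum(counts >= k), numeric(1L))
    null_ge <- null_ge_heights(n_events, L, ks, n_perm)
    fdr_k <- monotone_fdr(null_ge / obs_ge)
    fdr[sel] <- fdr_k[match(counts, ks)]
  }
  out <- data.frame(contig = map$contig, strand = map$strand, pos = map$pos,
                    count = map$count, fdr = fdr,
                    region_id = ifelse(is.na(ridx), NA_character_,
                                       regions$region_id[ridx]),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$fdr) & out$fdr < threshold
  out
}

#' Merge significant sites into CLIP-tag clusters
#'
#' Maximal runs of positions (per contig and strand) with inter-position
#' gaps of at most `max_gap` nucleotides; the cluster interval spans the
#' first to one past the last member position.
#'
#' @param sites Site-call data frame (typically the significant subset of
#'   [call_sites()] output).
#' @param max_gap Maximum spacing between consecutive member positions
#'   (default 15).
#' @return Data frame of clusters (contig, strand, start, end, n_sites,
#'   total_count, region_id).
#' @export
call_clusters <- function(sites, max_gap = 15L) {
  if (nrow(sites) == 0L) {
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), total_count = integer(),
                      region_id = character(), stringsAsFactors = FALSE))
  }
  sites <- sites[order(sites$contig, sites$strand, sites$pos), , drop = FALSE]
  key <- paste(sites$contig, sites$strand)
  newrun <- c(TRUE, key[-1L] != key[-length(key)] |
                diff(sites$pos) > max_gap)
  grp <- cumsum(newrun)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sites)), grp), function(i) {
    data.frame(contig = sites$contig[i[1L]], strand = sites$strand[i[1L]],
               start = min(sites$pos[i]), end = max(sites$pos[i]) + 1L,
               n_sites = length(i), total_count = sum(sites$count[i]),
               region_id = if (!is.null(sites$region_id))
                 sites$region_id[i[1L]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Permutation FDR for CLIP-tag clusters
#'
#' Per region and permutation, all of the region's events are re-placed
#' uniformly, positions reaching the region's minimal significant count
#' height are taken as null significant sites, and those are merged into
#' null clusters with the same `max_gap`. For a total-count level t,
#' FDR(t) = (mean number of null clusters with total >= t) / (number of
#' observed clusters with total >= t).
#'
#' @param clusters Clusters from [call_clusters()] on significant sites.
#' @param sites Full site-call table from [call_sites()] (supplies the
#'   per-region event totals and significance heights).
#' @param regions Co-transcribed regions.
#' @param n_perm Number of permutations (default 100).
#' @param threshold FDR threshold for retention (default 0.05, strict).
#' @param max_gap Cluster merge gap (default 15).
#' @param seed Optional integer seed.
#' @return `clusters` with columns `fdr` and `significant` added.
#' @export
cluster_fdr <- function(clusters, sites, regions, n_perm = 100L,
                        threshold = 0.05, max_gap = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clusters$fdr <- NA_real_
  if (nrow(clusters) == 0L) {
    clusters$significant <- logical(0L)
    return(clusters)
  }
  ridx_sites <- match(sites$region_id, regions$region_id)
  for (rid in unique(clusters$region_id)) {
    csel <- which(clusters$region_id == rid)
    r <- match(rid, regions$region_id)
    ssel <- which(!is.na(ridx_sites) & ridx_sites == r)
    n_events <- sum(sites$count[ssel])
    kstar <- min(sites$count[ssel][sites$significant[ssel]])
    L <- regions$end[r] - regions$start[r]
    ts <- sort(unique(clusters$total_count[csel]))
    obs_ge <- vapply(ts, function(t) sum(clusters$total_count[csel] >= t),
                     numeric(1L))
    acc <- numeric(length(ts))
    for (p in seq_len(n_perm)) {
      pos <- sort.int(sample.int(L, n_events, replace = TRUE))
      rl <- rle(pos)
      sig <- rl$lengths >= kstar
      if (!any(sig)) next
      sp <- rl$values[sig]
      sc <- rl$lengths[sig]
      grp <- cumsum(c(TRUE, diff(sp) > max_gap))
      totals <- vapply(split(sc, grp), sum, numeric(1L))
      acc <- acc + vapply(ts, function(t) sum(totals >= t), numeric(1L))
    }
    fdr_t <- monotone_fdr((acc / n_perm) / obs_ge)
    clusters$fdr[csel] <- fdr_t[match(clusters$total_count[csel], ts)]
  }
  clusters$significant <- !is.na(clusters$fdr) & clusters$fdr < threshold
  clusters
}
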