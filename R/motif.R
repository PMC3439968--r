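# In vivo binding motifs: pentamer Z-scores around crosslink sites
# against within-gene shuffled nulls, and a consensus matrix from the
# top-ranked pentamers.
#
# The crosslink-adjacent offsets (-9..+9) are excluded by construction:
# pentamers are counted only inside the windows [-30,-10] and [+10,+30]
# (offsets in transcript orientation), avoiding the U-rich crosslinking
# bias at the site itself. Motifs are reported in the RNA alphabet.

.RNA_BASES <- c("A", "C", "G", "U")

#' All 1,024 pentamers in canonical order (RNA alphabet)
#' @return Character vector of length 1024.
#' @export
all_pentamers <- function() {
  i <- 0:1023
  paste0(.RNA_BASES[i %/% 256L + 1L],
         .RNA_BASES[(i %/% 64L) %% 4L + 1L],
         .RNA_BASES[(i %/% 16L) %% 4L + 1L],
         .RNA_BASES[(i %/% 4L) %% 4L + 1L],
         .RNA_BASES[i %% 4L + 1L])
}

# Integer pentamer index per contig: `plus[i]` is the 1..1024 id of the
# pentamer whose leftmost (genomic) base is 0-based position i-1 read on
# the '+' strand; `minus[i]` the id of its reverse complement (the
# pentamer read 5'->3' on the '-' strand). NA where any base is N.
pentamer_index <- function(genome) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lapply(genome, function(seq) {
    v <- lut[utf8ToInt(seq)]
    L <- length(v)
    if (L < 5L) return(list(plus = integer(0), minus = integer(0), len = L))
    i <- seq_len(L - 4L)
    plus <- v[i] * 256L + v[i + 1L] * 64L + v[i + 2L] * 16L +
      v[i + 3L] * 4L + v[i + 4L] + 1L
    w <- 3L - v
    minus <- w[i + 4L] * 256L + w[i + 3L] * 64L + w[i + 2L] * 16L +
      w[i + 1L] * 4L + w[i] + 1L
    list(plus = plus, minus = minus, len = L)
  })
}

# Pentamer start offsets (transcript orientation, offset of the
# pentamer's first base) implied by the evaluation windows.
window_offsets <- function(windows, span = c("full", "start")) {
  span <- match.arg(span)
  unlist(lapply(windows, function(w) {
    if (span == "full") seq.int(w[1L], w[2L] - 4L) else seq.int(w[1L], w[2L])
  }))
}

# Per-pentamer weights for a set of sites given a prebuilt index.
# Each site contributes 1.0 to every *distinct* pentamer found in its
# windows (once per site even if present in both windows); windows
# running off the contig contribute from their in-bounds part.
pentamer_weights_idx <- function(contig, strand, pos, index, offs) {
  n <- length(pos)
  site <- rep(seq_len(n), each = length(offs))
  off <- rep(offs, times = n)
  p <- rep(pos, each = length(offs))
  s <- rep(strand, each = length(offs))
  # 1-based index of the pentamer's leftmost genomic base + 1
  ai <- ifelse(s == "+", p + off + 1L, p - off - 3L)
  ids <- rep(NA_integer_, length(ai))
  for (ct in unique(contig)) {
    csel <- rep(contig == ct, each = length(offs))
    idx <- index[[ct]]
    ok <- csel & ai >= 1L & ai <= (idx$len - 4L)
    okp <- ok & s == "+"
    okm <- ok & s == "-"
    ids[okp] <- idx$plus[ai[okp]]
    ids[okm] <- idx$minus[ai[okm]]
  }
  keep <- !is.na(ids)
  key <- (site[keep] - 1) * 1024 + ids[keep]
  ids_u <- ids[keep][!duplicated(key)]
  tabulate(ids_u, nbins = 1024L)
}

#' Pentamer weights around crosslink sites
#'
#' For each site, the set of distinct pentamers whose full 5-nt span lies
#' within the offset windows (default `[-30,-10]` and `[+10,+30]`,
#' transcript orientation, inclusive) contributes 1.0 per pentamer.
#' Weighting is per unique crosslink position, not per tag count.
#'
#' @param sites Data frame with columns `contig`, `strand`, `pos`.
#' @param genome Named character vector of contig sequences.
#' @param windows List of two-element offset vectors (inclusive bounds).
#' @param span `"full"` requires the whole pentamer inside a window;
#'   `"start"` only its first base.
#' @return Named numeric vector of length 1024 (names from
#'   [all_pentamers()]).
#' @export
pentamer_weights <- function(sites, genome,
                             windows = list(c(-30L, -10L), c(10L, 30L)),
                             span = "full") {
  if (nrow(sites) == 0L) stop("no sites supplied")
  index <- pentamer_index(genome)
  offs <- window_offsets(windows, span)
  w <- pentamer_weights_idx(sites$contig, sites$strand, sites$pos,
                            index, offs)
  stats::setNames(as.numeric(w), all_pentamers())
}

# Longest containing same-strand gene per site (tie broken by gene_id).
site_genes <- function(sites, annotation) {
  g <- annotation$genes
  glen <- g$end - g$start
  gi <- rep(NA_integer_, nrow(sites))
  sk <- paste(sites$contig, sites$strand)
  gk <- paste(g$contig, g$strand)
  for (key in unique(gk)) {
    gsel <- which(gk == key)
    ssel <- which(sk == key)
    if (!length(ssel)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[ssel] + 1L, width = 1L),
      IRanges::IRanges(g$start[gsel] + 1L, g$end[gsel])
    )
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- gsel[S4Vectors::subjectHits(ov)]
    o <- order(qh, -glen[sh], g$gene_id[sh])
    first <- !duplicated(qh[o])
    gi[ssel[qh[o][first]]] <- sh[o][first]
  }
  gi
}

#' Pentamer Z-scores against within-gene shuffled nulls
#'
#' Observed pentamer weights are standardized against `n_shuffles`
#' re-placements of every site uniformly within its containing gene
#' (longest same-strand gene; ties broken by gene id). Sites outside any
#' gene are dropped with a message.
#'
#' @inheritParams pentamer_weights
#' @param annotation A `clip_annotation` (supplies the gene spans used as
#'   the shuffling domain).
#' @param n_shuffles Number of shuffles (default 100, minimum 2).
#' @param seed Optional integer seed.
#' @return Object of class `pentamer_ztable`: data frame with columns
#'   `pentamer`, `observed_weight`, `null_mean`, `null_sd`, `z`, sorted
#'   by decreasing `z`. Pentamers with `null_sd == 0` get `z = 0` when
#'   the observation matches the null mean and `+/-Inf` otherwise.
#' @export
pentamer_zscores <- function(sites, genome, annotation, n_shuffles = 100L,
                             windows = list(c(-30L, -10L), c(10L, 30L)),
                             span = "full", seed = NULL) {
  if (n_shuffles < 2L) stop("n_shuffles must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  gi <- site_genes(sites, annotation)
  if (anyNA(gi)) {
    message("dropping ", sum(is.na(gi)), " sites outside annotated genes")
    sites <- sites[!is.na(gi), , drop = FALSE]
    gi <- gi[!is.na(gi)]
  }
  if (nrow(sites) == 0L) stop("no sites inside annotated genes")
  index <- pentamer_index(genome)
  offs <- window_offsets(windows, span)
  obs <- pentamer_weights_idx(sites$contig, sites$strand, sites$pos,
                              index, offs)
  gstart <- annotation$genes$start[gi]
  glen <- annotation$genes$end[gi] - gstart
  null <- matrix(0, nrow = n_shuffles, ncol = 1024L)
  for (s in seq_len(n_shuffles)) {
    rpos <- gstart + as.integer(floor(stats::runif(length(gi)) * glen))
    null[s, ] <- pentamer_weights_idx(sites$contig, sites$strand, rpos,
                                      index, offs)
  }
  mu <- colMeans(null)
  sd <- sqrt(colSums(sweep(null, 2L, mu)^2) / (n_shuffles - 1L))
  z <- ifelse(sd > 0, (obs - mu) / sd,
              ifelse(obs == mu, 0, sign(obs - mu) * Inf))
  out <- data.frame(pentamer = all_pentamers(), observed_weight = obs,
                    null_mean = mu, null_sd = sd, z = z,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$pentamer), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites") <- nrow(sites)
  class(out) <- c("pentamer_ztable", "data.frame")
  out
}

.IUPAC_RNA <- c(A = "A", C = "C", G = "G", U = "U",
                AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y", GU = "K",
                ACG = "V", ACU = "H", AGU = "D", CGU = "B", ACGU = "N")

#' Consensus matrix from top-ranked pentamers
#'
#' Stacks the top `k` pentamers (unweighted) into a 4 x 5 base-frequency
#' matrix and derives a per-position IUPAC string from the bases with
#' nonzero frequency.
#'
#' @param top_pentamers Character vector of pentamers, or a
#'   `pentamer_ztable` (its top rows by Z are used).
#' @param k Number of pentamers to stack (default 5).
#' @return List with `matrix` (rows A, C, G, U; columns sum to 1) and
#'   `iupac` (length-5 consensus string).
#' @export
consensus_from_top <- function(top_pentamers, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  if (inherits(top_pentamers, "pentamer_ztable") ||
      is.data.frame(top_pentamers)) {
    top_pentamers <- top_pentamers$pentamer
  }
  pents <- toupper(chartr("T", "U", utils::head(top_pentamers, k)))
  if (any(nchar(pents) != 5L)) stop("pentamers must all have length 5")
  mat <- matrix(0, nrow = 4L, ncol = 5L,
                dimnames = list(.RNA_BASES, paste0("pos", 1:5)))
  for (p in pents) {
    b <- strsplit(p, "")[[1L]]
    for (j in 1:5) mat[b[j], j] <- mat[b[j], j] + 1
  }
  mat <- sweep(mat, 2L, colSums(mat), "/")
  iupac <- vapply(1:5, function(j) {
    present <- .RNA_BASES[mat[, j] > 0]
    .IUPAC_RNA[[paste(sort(present), collapse = "")]]
  }, character(1L))
  list(matrix = mat, iupac = paste(iupac, collapse = ""))
}
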