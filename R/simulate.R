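# Synthetic genomes, annotations, branch-point candidates and simulated
# CLIP-tags with known ground truth.
#
# The generator encodes the iCLIP truncation assumption in reverse: each
# simulated binding event spawns tags whose start is one nucleotide
# downstream of the crosslink on the event strand, so the crosslink
# caller inverts the generator exactly. Binding motifs are planted by
# local sequence rewriting (not rejection sampling), which makes the
# planted fraction exact and every rewrite traceable in the truth set.
#
# Independent RNG streams per stage: the genome, the events and the tag
# emission each reseed from the config seed plus a fixed stage offset,
# so changing one stage's parameters does not perturb the draws of the
# others.

#' Simulation configuration
#'
#' @param seed Master integer seed; each stage derives its own stream.
#' @param n_contigs,contig_length Genome shape (default 2 x 1 Mb).
#' @param gc GC content of the background sequence.
#' @param n_genes Number of genes to place (non-overlapping).
#' @param frac_intronless Fraction of protein-coding genes that are
#'   intronless, histone-like (single exon, CDS, short 3'UTR).
#' @param frac_ncRNA Fraction of ncRNA genes; `ncRNA_weights` splits it
#'   over subclasses.
#' @param ncRNA_weights Named weights for lincRNA/snoRNA/scaRNA/other.
#' @param exon_count_lambda Poisson rate for extra exons beyond two.
#' @param exon_len_meanlog,exon_len_sdlog Log-normal exon lengths.
#' @param intron_len_meanlog,intron_len_sdlog Log-normal intron lengths.
#' @param nc_len_meanlog,nc_len_sdlog Log-normal ncRNA gene lengths.
#' @param histone_utr5,histone_cds_meanlog,histone_cds_sdlog,histone_utr3
#'   Histone-like gene geometry.
#' @param n_sites Number of true binding positions.
#' @param multiplicity_mean Mean of the geometric per-site event
#'   multiplicity (>= 1).
#' @param motif Planted pentamer (RNA alphabet).
#' @param plant_frac Fraction of sites with the motif planted at a
#'   sampled offset such that its 5-nt span lies within `[+10,+30]` of
#'   the crosslink.
#' @param plant_offsets Candidate start offsets of the planted pentamer.
#' @param plant_flank Number of bases written on each side of the planted
#'   pentamer, drawn from the pentamer's own base composition; emulates
#'   the degenerate, composition-biased stretches SR-type proteins bind
#'   rather than isolated exact pentamers (0 disables).
#' @param enrich_5ss_frac Fraction of sites placed uniformly inside
#'   `enrich_5ss_window` (offsets relative to 5' splice sites).
#' @param enrich_5ss_window Two-element offset window.
#' @param enrich_bp_frac,enrich_bp_window Same, relative to selected
#'   branch points.
#' @param histone_frac Fraction of sites placed 14-50 nt downstream of
#'   the ORF end of histone-like genes.
#' @param expression_sdlog Log-normal sd of per-gene expression weights.
#' @param pcr_duplication_rate Probability that a molecule gains a PCR
#'   duplicate (shared position and barcode).
#' @param barcode_layout Barcode mask over `{N, X}`.
#' @param tag_len_min,tag_len_max Uniform tag (insert) length bounds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L, contig_length = 1e6L, gc = 0.5,
                       n_genes = 150L,
                       frac_intronless = 0.1, frac_ncRNA = 0.12,
                       ncRNA_weights = c(lincRNA = 0.4, snoRNA = 0.25,
                                         scaRNA = 0.2, other_ncRNA = 0.15),
                       exon_count_lambda = 3,
                       exon_len_meanlog = log(300), exon_len_sdlog = 0.4,
                       intron_len_meanlog = log(1000), intron_len_sdlog = 0.5,
                       nc_len_meanlog = log(300), nc_len_sdlog = 0.4,
                       histone_utr5 = 30L, histone_cds_meanlog = log(400),
                       histone_cds_sdlog = 0.3, histone_utr3 = 60L,
                       n_sites = 13000L, multiplicity_mean = 1.5,
                       motif = "UCCUC", plant_frac = 0,
                       plant_offsets = 10:26, plant_flank = 2L,
                       enrich_5ss_frac = 0, enrich_5ss_window = c(-75L, -65L),
                       enrich_bp_frac = 0, enrich_bp_window = c(0L, 5L),
                       histone_frac = 0,
                       expression_sdlog = 1,
                       pcr_duplication_rate = 0.2,
                       barcode_layout = "NNNXXXXNN",
                       tag_len_min = 40L, tag_len_max = 100L) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_intronless, cfg$frac_ncRNA, cfg$plant_frac,
          cfg$enrich_5ss_frac, cfg$enrich_bp_frac, cfg$histone_frac,
          cfg$pcr_duplication_rate)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$multiplicity_mean >= 1,
            cfg$n_sites >= 1, cfg$gc > 0, cfg$gc < 1)
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = ""), character(1L)))
}

# Draw one gene structure (relative coordinates from 0).
draw_gene_structure <- function(cfg) {
  u <- stats::runif(1L)
  if (u < cfg$frac_ncRNA) {
    bt <- sample(names(cfg$ncRNA_weights), 1L, prob = cfg$ncRNA_weights)
    bt <- if (bt == "other_ncRNA") "snRNA" else bt
    len <- max(80L, as.integer(round(stats::rlnorm(1L, cfg$nc_len_meanlog,
                                                   cfg$nc_len_sdlog))))
    list(biotype = bt, type = "ncRNA", exon_len = len, intron_len = integer(0),
         cds = NULL, len = len)
  } else if (u < cfg$frac_ncRNA + cfg$frac_intronless) {
    cds <- max(90L, as.integer(round(stats::rlnorm(1L, cfg$histone_cds_meanlog,
                                                   cfg$histone_cds_sdlog))))
    len <- cfg$histone_utr5 + cds + cfg$histone_utr3
    list(biotype = "protein_coding", type = "histone",
         exon_len = len, intron_len = integer(0),
         cds = c(cfg$histone_utr5, cfg$histone_utr5 + cds), len = len)
  } else {
    n_ex <- 2L + stats::rpois(1L, cfg$exon_count_lambda)
    ex <- pmax(60L, as.integer(round(stats::rlnorm(
      n_ex, cfg$exon_len_meanlog, cfg$exon_len_sdlog))))
    intr <- pmax(100L, as.integer(round(stats::rlnorm(
      n_ex - 1L, cfg$intron_len_meanlog, cfg$intron_len_sdlog))))
    list(biotype = "protein_coding", type = "coding",
         exon_len = ex, intron_len = intr, cds = NULL,
         len = sum(ex) + sum(intr))
  }
}

#' Simulate a genome, annotation and branch-point candidates
#'
#' Places non-overlapping genes on i.i.d. background sequence. Multi-exon
#' protein-coding genes get a CDS from the midpoint of their first exon
#' to the midpoint of their last exon; each intron of at least 100 nt
#' gets 1-3 fabricated branch-point candidates with Normal(1, 1) scores
#' placed in its last half. Per-gene expression weights are log-normal.
#'
#' @param config A `sim_config`.
#' @return Object of class `clip_sim`: list with `config`, `genome`,
#'   `annotation`, `branchpoints` and `genes` (gene_id, type, weight).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  genome <- stats::setNames(
    vapply(seq_len(config$n_contigs),
           function(i) rand_seq(config$contig_length, config$gc),
           character(1L)),
    sprintf("chr%d", seq_len(config$n_contigs)))

  structs <- lapply(seq_len(config$n_genes), function(i)
    draw_gene_structure(config))
  ctg <- sort(sample.int(config$n_contigs, config$n_genes, replace = TRUE))
  exon_rows <- list()
  cds_rows <- list()
  gene_type <- character(config$n_genes)
  for (ci in seq_len(config$n_contigs)) {
    idx <- which(ctg == ci)
    if (!length(idx)) next
    lens <- vapply(structs[idx], `[[`, numeric(1L), "len")
    free <- config$contig_length - sum(lens) - 2L * length(idx)
    if (free < 0) stop("infeasible packing: total gene length exceeds contig")
    cuts <- diff(c(0, sort(stats::runif(length(idx))), 1))
    gaps <- as.integer(floor(free * cuts[seq_along(idx)])) + 1L
    start <- 0L
    for (k in seq_along(idx)) {
      i <- idx[k]
      st <- structs[[i]]
      gstart <- start + gaps[k]
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene_%03d", i)
      tid <- sprintf("tx_%03d", i)
      gene_type[i] <- st$type
      # exon coordinates (genomic, 0-based half-open)
      es <- gstart + cumsum(c(0L, st$exon_len[-length(st$exon_len)] +
                                st$intron_len))
      ee <- es + st$exon_len
      exon_rows[[i]] <- data.frame(
        transcript_id = tid, gene_id = gid, contig = names(genome)[ci],
        strand = strand, start = es, end = ee, biotype = st$biotype,
        stringsAsFactors = FALSE)
      if (st$type == "coding") {
        # CDS from midpoint of the genomically first exon to midpoint of
        # the last (valid on both strands; UTR halves at both ends)
        cds_rows[[i]] <- data.frame(
          transcript_id = tid,
          start = es[1L] + st$exon_len[1L] %/% 2L,
          end = ee[length(ee)] - st$exon_len[length(ee)] %/% 2L,
          stringsAsFactors = FALSE)
      } else if (st$type == "histone") {
        cds_rows[[i]] <- data.frame(
          transcript_id = tid,
          start = if (strand == "+") gstart + st$cds[1L] else
            gstart + st$len - st$cds[2L],
          end = if (strand == "+") gstart + st$cds[2L] else
            gstart + st$len - st$cds[1L],
          stringsAsFactors = FALSE)
      }
      start <- gstart + st$len
    }
  }
  exons <- do.call(rbind, exon_rows)
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else NULL
  ann <- build_annotation(exons, cds, contigs = contig_lengths(genome))

  intr <- unique(ann$introns[, c("contig", "strand", "start", "end")])
  bp_rows <- list()
  if (nrow(intr)) {
    for (i in seq_len(nrow(intr))) {
      len <- intr$end[i] - intr$start[i]
      if (len < 100L) next
      n_bp <- sample.int(3L, 1L)
      half <- len %/% 2L
      # last half (adjacent to the 3' splice site) in genomic coordinates
      if (intr$strand[i] == "+") {
        pos <- intr$end[i] - 1L - sample.int(half, n_bp, replace = TRUE) + 1L
      } else {
        pos <- intr$start[i] + sample.int(half, n_bp, replace = TRUE) - 1L
      }
      bp_rows[[i]] <- data.frame(
        intron_id = intron_id(intr$contig[i], intr$strand[i],
                              intr$start[i], intr$end[i]),
        contig = intr$contig[i], position = pos, strand = intr$strand[i],
        score = stats::rnorm(n_bp, 1, 1), stringsAsFactors = FALSE)
    }
  }
  branchpoints <- if (length(bp_rows)) do.call(rbind, bp_rows) else
    data.frame(intron_id = character(), contig = character(),
               position = integer(), strand = character(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(branchpoints) <- NULL

  genes <- data.frame(
    gene_id = ann$genes$gene_id,
    type = gene_type[as.integer(sub("gene_", "", ann$genes$gene_id))],
    weight = stats::rlnorm(nrow(ann$genes), 0, config$expression_sdlog),
    stringsAsFactors = FALSE)

  structure(list(config = config, genome = genome, annotation = ann,
                 branchpoints = branchpoints, genes = genes),
            class = "clip_sim")
}

# Write a motif (DNA alphabet) into a contig sequence at 0-based pos.
rewrite_seq <- function(seq, pos, motif_dna) {
  substr(seq, pos + 1L, pos + nchar(motif_dna)) <- motif_dna
  seq
}

#' Simulate binding events (the truth set)
#'
#' Places `n_sites` true binding positions: a `plant_frac` fraction gets
#' the configured pentamer written into the sequence at a sampled offset
#' within `[+10,+30]` of the crosslink (transcript orientation); optional
#' fractions are concentrated at 5'-splice-site offsets, branch-point
#' offsets, or histone ORF ends; the remainder is uniform within
#' expression-weighted gene spans. Per-site event multiplicities are
#' geometric with the configured mean.
#'
#' @param sim A `clip_sim` from [simulate_genome()].
#' @return `sim` with `genome` updated (motif rewrites) and `truth`
#'   added: data frame (contig, strand, pos, n_events, kind, gene_id)
#'   with one row per unique crosslink position, plus `motif_instances`.
#' @export
simulate_events <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  ann <- sim$annotation
  g <- ann$genes
  glen <- g$end - g$start
  w <- sim$genes$weight[match(g$gene_id, sim$genes$gene_id)] * glen
  clen <- contig_lengths(sim$genome)
  motif_dna <- chartr("U", "T", cfg$motif)

  kinds <- sample(c("planted", "ss5", "bp", "histone", "background"),
                  cfg$n_sites, replace = TRUE,
                  prob = c(cfg$plant_frac, cfg$enrich_5ss_frac,
                           cfg$enrich_bp_frac, cfg$histone_frac,
                           max(0, 1 - cfg$plant_frac - cfg$enrich_5ss_frac -
                                 cfg$enrich_bp_frac - cfg$histone_frac)))

  draw_in_gene <- function(n, margin = 0L) {
    gi <- sample.int(nrow(g), n, replace = TRUE, prob = w)
    lo <- g$start[gi] + margin
    hi <- g$end[gi] - margin
    swap <- hi <= lo
    lo[swap] <- g$start[gi][swap]
    hi[swap] <- g$end[gi][swap]
    pos <- lo + as.integer(floor(stats::runif(n) * (hi - lo)))
    pos <- pmax(1L, pmin(pos, clen[g$contig[gi]] - 2L))
    data.frame(contig = g$contig[gi], strand = g$strand[gi],
               pos = as.integer(pos), gene_id = g$gene_id[gi],
               stringsAsFactors = FALSE)
  }

  rows <- list()
  motif_inst <- list()

  n_bg <- sum(kinds == "background")
  if (n_bg) {
    d <- draw_in_gene(n_bg)
    d$kind <- "background"
    rows$background <- d
  }

  n_pl <- sum(kinds == "planted")
  if (n_pl) {
    fl <- cfg$plant_flank
    alphabet <- unique(strsplit(motif_dna, "")[[1L]])
    # rewrites must not overlap each other (or run off the contig), or a
    # later planting would corrupt an earlier motif; placements are
    # resampled with bounded retries
    occupied <- lapply(clen, function(L) logical(L))
    d_list <- vector("list", n_pl)
    for (i in seq_len(n_pl)) {
      placed <- FALSE
      for (try in 1:50) {
        d1 <- draw_in_gene(1L, margin = 38L + fl)
        off <- if (length(cfg$plant_offsets) > 1L)
          sample(cfg$plant_offsets, 1L) else cfg$plant_offsets
        left <- if (d1$strand == "+") d1$pos + off else d1$pos - off - 4L
        span <- seq.int(left - fl, left + 4L + fl)
        if (span[1L] < 0L || span[length(span)] >= clen[d1$contig] ||
            any(occupied[[d1$contig]][span + 1L])) next
        flank <- function(n) paste(sample(alphabet, n, replace = TRUE),
                                   collapse = "")
        mseq <- paste0(flank(fl), motif_dna, flank(fl))
        if (d1$strand == "-") mseq <- revcomp(mseq)
        sim$genome[[d1$contig]] <- rewrite_seq(sim$genome[[d1$contig]],
                                               left - fl, mseq)
        occupied[[d1$contig]][span + 1L] <- TRUE
        d1$kind <- "planted"
        motif_inst[[length(motif_inst) + 1L]] <- data.frame(
          contig = d1$contig, strand = d1$strand, left = left,
          offset = off, site_pos = d1$pos, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        d1 <- draw_in_gene(1L)
        d1$kind <- "background"
      }
      d_list[[i]] <- d1
    }
    rows$planted <- do.call(rbind, d_list)
  }

  n_ss <- sum(kinds == "ss5")
  if (n_ss) {
    jn <- build_junctions(ann, window = max(abs(cfg$enrich_5ss_window)),
                          min_exon = 2L * max(abs(cfg$enrich_5ss_window)),
                          min_intron = 2L)$junctions
    jn <- jn[jn$kind == "5ss", , drop = FALSE]
    if (nrow(jn) == 0L) stop("no 5'ss junctions eligible for enrichment")
    ji <- sample.int(nrow(jn), n_ss, replace = TRUE)
    offs <- sample(seq.int(cfg$enrich_5ss_window[1L],
                           cfg$enrich_5ss_window[2L]), n_ss, replace = TRUE)
    pos <- ifelse(jn$strand[ji] == "+", jn$boundary[ji] + offs,
                  jn$boundary[ji] - offs)
    rows$ss5 <- data.frame(contig = jn$contig[ji], strand = jn$strand[ji],
                           pos = as.integer(pos), gene_id = NA_character_,
                           kind = "ss5", stringsAsFactors = FALSE)
  }

  n_bp <- sum(kinds == "bp")
  if (n_bp) {
    selbp <- select_branch_points(ann, sim$branchpoints)
    selbp <- selbp[selbp$selected, , drop = FALSE]
    if (nrow(selbp) == 0L) stop("no selected branch points for enrichment")
    bi <- sample.int(nrow(selbp), n_bp, replace = TRUE)
    offs <- sample(seq.int(cfg$enrich_bp_window[1L],
                           cfg$enrich_bp_window[2L]), n_bp, replace = TRUE)
    pos <- ifelse(selbp$strand[bi] == "+", selbp$bp_pos[bi] + offs,
                  selbp$bp_pos[bi] - offs)
    rows$bp <- data.frame(contig = selbp$contig[bi],
                          strand = selbp$strand[bi], pos = as.integer(pos),
                          gene_id = NA_character_, kind = "bp",
                          stringsAsFactors = FALSE)
  }

  n_hist <- sum(kinds == "histone")
  if (n_hist) {
    anch <- transcript_anchors(ann, type = "cds_end")
    hg <- sim$genes$gene_id[sim$genes$type == "histone"]
    anch <- anch[anch$gene_id %in% hg, , drop = FALSE]
    if (nrow(anch) == 0L) stop("no histone-like genes for enrichment")
    ai <- sample.int(nrow(anch), n_hist, replace = TRUE)
    offs <- sample(14:50, n_hist, replace = TRUE)
    pos <- ifelse(anch$strand[ai] == "+", anch$anchor[ai] + offs,
                  anch$anchor[ai] - offs)
    rows$histone <- data.frame(contig = anch$contig[ai],
                               strand = anch$strand[ai],
                               pos = as.integer(pos),
                               gene_id = anch$gene_id[ai], kind = "histone",
                               stringsAsFactors = FALSE)
  }

  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev$pos <- pmax(1L, pmin(ev$pos, clen[ev$contig] - 2L))
  # per-site event multiplicity, geometric with mean multiplicity_mean
  ev$n_events <- 1L + stats::rgeom(nrow(ev), prob = 1 / cfg$multiplicity_mean)
  # collapse coincident positions, summing multiplicities
  key <- paste(ev$contig, ev$strand, ev$pos, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(ev$n_events, key, sum)
    first <- !duplicated(key)
    ev <- ev[first, , drop = FALSE]
    ev$n_events <- as.integer(agg[key[first]])
  }
  ev <- ev[order(ev$contig, ev$strand, ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  sim$truth <- ev
  sim$motif_instances <- if (length(motif_inst))
    do.call(rbind, motif_inst) else NULL
  sim
}

#' Emit simulated CLIP-tags from the truth set
#'
#' Each event spawns one unique molecule: the tag start is one nucleotide
#' downstream of the crosslink on the event strand, the insert length is
#' uniform in `[tag_len_min, tag_len_max]` clipped to the contig, and
#' the random barcode is drawn without replacement among the molecules
#' of a position (so deduplication inverts the generator exactly). PCR
#' duplicates — extra copies sharing crosslink position and barcode but
#' re-drawn length — are appended with probability
#' `pcr_duplication_rate` per molecule, and rows are shuffled.
#'
#' @param sim A `clip_sim` with `truth` from [simulate_events()].
#' @return `sim` with `tags` added (contig, start, end, barcode, strand,
#'   unique_mapping) and `n_pcr_duplicates` recorded.
#' @export
emit_tags <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 2L)
  tr <- sim$truth
  clen <- contig_lengths(sim$genome)
  nb <- sum(strsplit(cfg$barcode_layout, "")[[1L]] == "N")
  n_codes <- 4L^nb
  if (any(tr$n_events > n_codes)) {
    stop("per-site multiplicity exceeds the random-barcode space")
  }
  idx <- rep(seq_len(nrow(tr)), tr$n_events)
  barcode_int <- unlist(lapply(tr$n_events, function(k)
    sample.int(n_codes, k)))
  bases <- c("A", "C", "G", "T")
  int_to_bc <- function(x) {
    x <- x - 1L
    out <- character(length(x))
    for (j in seq_len(nb)) {
      out <- paste0(bases[x %% 4L + 1L], out)
      x <- x %/% 4L
    }
    out
  }
  mol <- data.frame(contig = tr$contig[idx], strand = tr$strand[idx],
                    pos = tr$pos[idx], barcode = int_to_bc(barcode_int),
                    stringsAsFactors = FALSE)
  make_span <- function(m) {
    L <- sample.int(cfg$tag_len_max - cfg$tag_len_min + 1L, nrow(m),
                    replace = TRUE) + cfg$tag_len_min - 1L
    cl <- clen[m$contig]
    start <- ifelse(m$strand == "+", m$pos + 1L, pmax(0L, m$pos - L))
    end <- ifelse(m$strand == "+", pmin(cl, m$pos + 1L + L), m$pos)
    data.frame(contig = m$contig, start = as.integer(start),
               end = as.integer(end), barcode = m$barcode,
               strand = m$strand, unique_mapping = TRUE,
               stringsAsFactors = FALSE)
  }
  tags <- make_span(mol)
  dup <- stats::runif(nrow(mol)) < cfg$pcr_duplication_rate
  n_dup <- sum(dup)
  if (n_dup) tags <- rbind(tags, make_span(mol[dup, , drop = FALSE]))
  tags <- tags[sample.int(nrow(tags)), , drop = FALSE]
  rownames(tags) <- NULL
  sim$tags <- tags
  sim$n_pcr_duplicates <- n_dup
  sim
}

#' Write all simulation outputs to a directory
#'
#' Emits `genome.fa`, `annotation.gtf`, `branchpoints.tsv`, `tags.bed`,
#' `expression.tsv` and `truth_sites.tsv`.
#'
#' @param sim A `clip_sim` after [emit_tags()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  utils::write.table(sim$branchpoints, file.path(dir, "branchpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tags(sim$tags, file.path(dir, "tags.bed"))
  utils::write.table(
    data.frame(gene_id = sim$genes$gene_id, value = sim$genes$weight),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an annotation as GTF (1-based inclusive)
#' @param annotation A `clip_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ex <- annotation$exons
  bt <- annotation$genes$biotype[match(ex$gene_id, annotation$genes$gene_id)]
  attr_str <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$gene_id, ex$transcript_id, bt)
  lines <- sprintf("%s\ticlipr\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$contig, ex$start + 1L, ex$end, ex$strand, attr_str)
  cds <- annotation$cds
  if (nrow(cds)) {
    m <- match(cds$transcript_id, ex$transcript_id)
    attr_c <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      ex$gene_id[m], cds$transcript_id, bt[m])
    lines <- c(lines, sprintf("%s\ticlipr\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                              ex$contig[m], cds$start + 1L, cds$end,
                              ex$strand[m], attr_c))
  }
  writeLines(lines, path)
  invisible(path)
}
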