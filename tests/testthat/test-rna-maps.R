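# Junction/branch-point/anchored metaprofiles, normalization, smoothing.

test_that("junction normalizer counts spanning feature halves", {
  # one '+' gene: exon [0,100), intron [100,500), exon [500,600)
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 500, 600)
  ))
  jn <- build_junctions(ann, window = 300L)
  n5 <- jn$normalizer[["5ss"]]
  # exon half covers offsets -50..-1; intron half 0..199
  expect_equal(unname(n5[as.character(c(-10, -60, 150, 250))]),
               c(1, 0, 1, 0))
  expect_equal(unname(n5["-50"]), 1)
  expect_equal(unname(n5["-51"]), 0)
  expect_equal(unname(n5["199"]), 1)
  expect_equal(unname(n5["200"]), 0)
})

test_that("short exons or introns exclude the junction", {
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 59),     # exon 59 nt
    list("t1", "g1", "c1", "+", 500, 700)
  ))
  jn <- build_junctions(ann)
  expect_false(any(jn$junctions$kind == "5ss"))
  expect_equal(jn$n_excluded, 1L)

  ann2 <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 299, 500)   # intron 199 nt
  ))
  expect_equal(nrow(build_junctions(ann2)$junctions), 0L)
})

test_that("normalizer equals a per-offset brute-force count", {
  set.seed(17)
  for (rep in 1:5) {
    sim <- simulate_genome(sim_config(seed = 400L + rep, n_contigs = 1L,
                                      contig_length = 150000L,
                                      n_genes = 15L))
    W <- 120L
    jn <- build_junctions(sim$annotation, window = W)
    for (kind in c("5ss", "3ss")) {
      j <- jn$junctions[jn$junctions$kind == kind, ]
      oracle <- numeric(2 * W + 1)
      for (d in seq(-W, W)) {
        if (kind == "5ss") {
          cov <- (d < 0 & -d <= j$exon_half) | (d >= 0 & d < j$intron_half)
        } else {
          cov <- (d < 0 & -d <= j$intron_half) | (d >= 0 & d < j$exon_half)
        }
        oracle[d + W + 1] <- sum(cov)
      }
      expect_equal(unname(jn$normalizer[[kind]]), oracle)
    }
  }
})

test_that("junction density is per 10^3 nt of spanning halves", {
  # four '+' genes, identical geometry, so normalizer[-70] = 4
  rows <- list()
  for (i in 1:4) {
    off <- (i - 1) * 2000
    rows <- c(rows, list(
      list(paste0("t", i), paste0("g", i), "c1", "+", off, off + 200),
      list(paste0("t", i), paste0("g", i), "c1", "+", off + 600, off + 800)
    ))
  }
  ann <- make_ann(rows)
  jn <- build_junctions(ann)
  expect_equal(unname(jn$normalizer[["5ss"]]["-70"]), 4)
  # one event at offset -70 from the first 5'ss (boundary at 200)
  map <- make_map("c1", "+", 130L, 1L)
  pr <- junction_profile(map, jn)
  expect_equal(pr[["5ss"]]$density[pr[["5ss"]]$offset == -70], 250)
  expect_equal(attr(pr, "n_assigned"), 1L)
})

test_that("Gaussian smoothing conserves mass and matches direct convolution", {
  h <- 5L
  ii <- seq(-h, h)
  w <- exp(-ii^2 / (2 * (h / 2)^2))
  w <- w / sum(w)

  x <- numeric(101)
  x[51] <- 7
  sm <- smooth_profile(x, half_width = h)
  expect_equal(sm[51 + ii], 7 * w)
  expect_lt(abs(sum(sm) - sum(x)) / sum(x), 1e-9)

  xc <- rep(3.3, 60)
  expect_equal(smooth_profile(xc, h), xc, tolerance = 1e-9)

  set.seed(23)
  for (rep in 1:5) {
    x <- stats::runif(80)
    x[sample.int(80, 10)] <- NA
    got <- smooth_profile(x, half_width = h)
    oracle <- rep(NA_real_, 80)
    for (d in which(!is.na(x))) {
      nb <- d + ii
      ok <- nb >= 1 & nb <= 80
      ok[ok] <- !is.na(x[nb[ok]])
      oracle[d] <- sum(w[ok] * x[nb[ok]]) / sum(w[ok])
    }
    expect_equal(got, oracle)
  }
  expect_error(smooth_profile(1:10, half_width = 0), "half_width")
})

test_that("branch-point selection applies all filters in order", {
  # introns on both strands, lengths 239/240/400
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 339, 439),    # intron [100,339) len 239
    list("t2", "g2", "c1", "+", 1000, 1100),
    list("t2", "g2", "c1", "+", 1340, 1440),  # intron [1100,1340) len 240
    list("t3", "g3", "c1", "-", 2000, 2100),
    list("t3", "g3", "c1", "-", 2500, 2600)   # intron [2100,2500) len 400
  ))
  i1 <- intron_id("c1", "+", 100L, 339L)
  i2 <- intron_id("c1", "+", 1100L, 1340L)
  i3 <- intron_id("c1", "-", 2100L, 2500L)
  cand <- data.frame(
    intron_id = c(i1, i2, i2, i3, i3, i3),
    contig = "c1",
    position = c(300L,                 # perfect but intron too short
                 1340L - 1L - 19L,     # 19 nt from 3'ss
                 1340L - 1L - 60L,     # negative score
                 2100L + 30L,          # score 2, 30 nt from 3'ss ('-')
                 2100L + 50L,          # score 2, 50 nt -> tie, farther
                 2100L + 25L),         # higher position? score negative
    strand = c("+", "+", "+", "-", "-", "-"),
    score = c(3, 3, -1, 2, 2, -0.5), stringsAsFactors = FALSE)
  sel <- select_branch_points(ann, cand)
  expect_equal(sel$reason[sel$intron_id == i1], "intron_too_short")
  # best valid candidate in i2 is 19 nt from the junction -> dropped
  expect_equal(sel$reason[sel$intron_id == i2], "too_close_to_3ss")
  # tie on score 2: the one closest to the 3'ss wins (30 nt)
  expect_true(sel$selected[sel$intron_id == i3])
  expect_equal(sel$bp_pos[sel$intron_id == i3], 2130L)

  bad <- data.frame(intron_id = i3, contig = "c1", position = 50L,
                    strand = "-", score = 1, stringsAsFactors = FALSE)
  expect_error(select_branch_points(ann, bad), "outside its intron")
})

test_that("branch-point profile is a delta at 0 for events at the BP", {
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 500, 600)  # intron [100,500) len 400
  ))
  bp <- data.frame(intron_id = intron_id("c1", "+", 100L, 500L),
                   contig = "c1", position = 450L, strand = "+",
                   score = 2, stringsAsFactors = FALSE)
  sel <- select_branch_points(ann, bp)
  expect_true(sel$selected)
  map <- make_map("c1", "+", 450L, 3L)
  pr <- branchpoint_profile(map, sel, window = 100L)
  expect_equal(pr$raw[pr$offset == 0], 1)
  expect_equal(sum(pr$raw), 1)
  # normalizer spans the last half of the intron around the BP
  expect_gt(pr$normalizer[pr$offset == 0], 0)
})

test_that("anchored profiles use transcript orientation", {
  ann <- make_ann(list(list("t1", "g1", "c1", "+", 0, 500),
                       list("t2", "g2", "c1", "-", 1000, 1500)))
  anch <- transcript_anchors(ann, type = "tx3p")
  # '+' transcript: anchor at 499; '-' transcript: anchor at 1000
  expect_equal(anch$anchor[anch$strand == "+"], 499L)
  expect_equal(anch$anchor[anch$strand == "-"], 1000L)

  items <- data.frame(contig = "c1", strand = c("+", "-"),
                      pos = c(499L, 990L), stringsAsFactors = FALSE)
  # the '-' item is 10 nt genomically left of its anchor -> offset +10,
  # but 990 lies outside the transcript span, so only offset 0 is assigned
  pr <- anchored_profile(items[1, ], anch, window = 50L)
  expect_equal(pr$raw[pr$offset == 0], 1)

  items2 <- data.frame(contig = "c1", strand = "-", pos = 1010L,
                       stringsAsFactors = FALSE)
  pr2 <- anchored_profile(items2, anch, window = 50L)
  expect_equal(pr2$raw[pr2$offset == -10], 1)

  items3 <- data.frame(contig = "c1", strand = "-", pos = 1000L + 10L,
                       stringsAsFactors = FALSE)
  expect_equal(sum(pr2$raw), 1)
})

test_that("profiles are invariant under strand reversal of the genome", {
  cfg <- sim_config(seed = 19L, n_contigs = 1L, contig_length = 120000L,
                    n_genes = 15L, n_sites = 3000L)
  sim <- simulate_events(simulate_genome(cfg))
  map <- make_map(sim$truth$contig, sim$truth$strand, sim$truth$pos,
                  sim$truth$n_events)
  jn <- build_junctions(sim$annotation, window = 150L)
  pr <- junction_profile(map, jn)

  # mirror everything: coordinates x -> L-1-x, strands flipped
  L <- contig_lengths(sim$genome)[["chr1"]]
  ex <- sim$annotation$exons
  flip_rows <- lapply(seq_len(nrow(ex)), function(i) list(
    ex$transcript_id[i], ex$gene_id[i], ex$contig[i],
    if (ex$strand[i] == "+") "-" else "+",
    L - ex$end[i], L - ex$start[i]))
  ann_f <- make_ann(flip_rows)
  map_f <- make_map(sim$truth$contig,
                    ifelse(sim$truth$strand == "+", "-", "+"),
                    L - 1L - sim$truth$pos, sim$truth$n_events)
  jn_f <- build_junctions(ann_f, window = 150L)
  pr_f <- junction_profile(map_f, jn_f)
  for (kind in c("5ss", "3ss")) {
    expect_equal(pr_f[[kind]]$raw, pr[[kind]]$raw)
    expect_equal(pr_f[[kind]]$normalizer, pr[[kind]]$normalizer)
  }
})

test_that("cluster midpoints land at the anchor offset 0", {
  cl <- data.frame(contig = "c1", strand = "+", start = 480L, end = 520L,
                   stringsAsFactors = FALSE)
  mid <- cluster_midpoints(cl)
  expect_equal(mid$pos, 499L)
})
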