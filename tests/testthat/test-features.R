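# RNA-class classification, density enrichment, overlaps, expression.

test_that("classification follows the class priority and strand matching", {
  # snoRNA nested inside the host gene's intron
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 500, 600),
    list("t2", "g2", "c1", "+", 200, 300, "snoRNA")
  ), cds = list(list("t1", 50, 550)))
  map <- make_map("c1", c("+", "+", "+", "-"),
                  c(250L, 400L, 5000L, 250L), 1L)
  ct <- classify(map, ann, genome_length = 20000L)
  cls <- attr(ct, "event_class")
  expect_equal(cls[map$pos == 250 & map$strand == "+"], "snoRNA")
  expect_equal(cls[map$pos == 400], "intron")
  expect_equal(cls[map$pos == 5000], "intergenic")
  # antisense event falls through to intergenic
  expect_equal(cls[map$strand == "-"], "intergenic")
  expect_equal(sum(ct$proportion), 1)
})

test_that("UTRs and CDS exons split protein-coding exons", {
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 500, 600)
  ), cds = list(list("t1", 50, 550)))
  map <- make_map("c1", "+", c(10L, 60L, 520L, 580L), 1L)
  cls <- attr(classify(map, ann, genome_length = 2000L), "event_class")
  expect_equal(cls, c("5'UTR", "CDS-exon", "CDS-exon", "3'UTR"))
})

test_that("proportions sum to 1 on random simulations", {
  for (seed in 1:3) {
    sim <- simulate_events(simulate_genome(
      sim_config(seed = 500L + seed, n_contigs = 1L,
                 contig_length = 120000L, n_genes = 20L, n_sites = 1500L,
                 frac_ncRNA = 0.2, frac_intronless = 0.15)))
    map <- make_map(sim$truth$contig, sim$truth$strand, sim$truth$pos,
                    sim$truth$n_events)
    ct <- classify(map, sim$annotation)
    expect_equal(sum(ct$proportion), 1)
    expect_equal(sum(ct$count), sum(map$count))
  }
})

test_that("density enrichment follows its definition and scale invariance", {
  tab <- data.frame(class = c("exon", "rest"), count = c(100, 0),
                    length = c(1e4, 1e6 - 1e4), stringsAsFactors = FALSE)
  out <- density_enrichment(tab, genome_length = 1e6)
  expect_equal(out$fold_enrichment[1], 100)

  tab10 <- tab
  tab10$count <- tab$count * 10
  out10 <- density_enrichment(tab10, genome_length = 1e6)
  expect_equal(out10$fold_enrichment, out$fold_enrichment)

  bad <- data.frame(class = "x", count = 5, length = 0,
                    stringsAsFactors = FALSE)
  expect_error(density_enrichment(bad, 100), "zero length")
})

test_that("uniform tags give fold enrichment near 1 in every class", {
  sim <- simulate_genome(sim_config(seed = 61L, n_contigs = 1L,
                                    contig_length = 200000L, n_genes = 30L,
                                    frac_ncRNA = 0.2, frac_intronless = 0.1))
  set.seed(62)
  n <- 1e5L
  ev <- data.frame(contig = "chr1", strand = sample(c("+", "-"), n, TRUE),
                   pos = sample.int(200000L, n, TRUE) - 1L,
                   barcode = as.character(seq_len(n)),
                   stringsAsFactors = FALSE)
  ct <- classify(pileup(ev), sim$annotation)
  big <- ct[ct$length >= 5000, ]
  expect_true(all(abs(big$fold_enrichment - 1) < 0.1))
})

test_that("gene overlap is a set partition", {
  expect_equal(unname(gene_overlap(c("g1", "g2"), c("g2", "g3"))),
               c(1L, 1L, 1L))
  expect_equal(unname(gene_overlap(c("a", "b"), c("a", "b"))), c(0L, 2L, 0L))
  expect_equal(unname(gene_overlap(c("a"), c("b"))), c(1L, 0L, 1L))
})

test_that("cluster overlap requires >= min_overlap same-strand nucleotides", {
  a <- data.frame(contig = "c1", strand = "+", start = 100L, end = 130L,
                  stringsAsFactors = FALSE)
  b14 <- data.frame(contig = "c1", strand = "+", start = 116L, end = 150L,
                    stringsAsFactors = FALSE)
  b15 <- data.frame(contig = "c1", strand = "+", start = 115L, end = 150L,
                    stringsAsFactors = FALSE)
  expect_equal(unname(cluster_overlap(a, b14)), c(1L, 0L, 1L),
               ignore_attr = TRUE)
  expect_equal(unname(cluster_overlap(a, b15)), c(0L, 2L, 0L),
               ignore_attr = TRUE)
  # opposite strand never shared
  b_rc <- transform(b15, strand = "-")
  expect_equal(unname(cluster_overlap(a, b_rc))[[2]], 0L,
               ignore_attr = TRUE)
})

test_that("cluster overlap matches a brute-force all-pairs oracle", {
  set.seed(71)
  for (rep in 1:8) {
    mk <- function(n) {
      st <- sample.int(3000L, n)
      data.frame(contig = "c1", strand = sample(c("+", "-"), n, TRUE),
                 start = st, end = st + sample(5:60, n, TRUE),
                 stringsAsFactors = FALSE)
    }
    a <- mk(sample(3:15, 1))
    b <- mk(sample(3:15, 1))
    got <- cluster_overlap(a, b, min_overlap = 15L)
    ov <- function(x, y) {
      vapply(seq_len(nrow(x)), function(i) any(
        y$strand == x$strand[i] &
          pmin(y$end, x$end[i]) - pmax(y$start, x$start[i]) >= 15L),
        logical(1))
    }
    sa <- sum(ov(a, b))
    sb <- sum(ov(b, a))
    expect_equal(unname(got), c(nrow(a) - sa, sa + sb, nrow(b) - sb),
                 ignore_attr = TRUE)
  }
})

test_that("density-expression correlation behaves on monotone/null/planted", {
  sim <- simulate_genome(sim_config(seed = 81L, n_contigs = 2L,
                                    contig_length = 700000L, n_genes = 200L))
  g <- sim$annotation$genes
  # density exactly proportional to expression
  set.seed(82)
  expr <- data.frame(gene_id = g$gene_id, value = stats::runif(nrow(g)))
  k <- pmax(1L, round(expr$value * 50))
  ev <- data.frame(
    contig = rep(g$contig, k), strand = rep(g$strand, k),
    pos = unlist(lapply(seq_len(nrow(g)), function(i)
      g$start[i] + seq_len(k[i]))),
    barcode = "A", stringsAsFactors = FALSE)
  # equalize gene length effect: scale counts by length via value
  expr$value <- k / (g$end - g$start)
  r <- density_expression_correlation(pileup(ev), sim$annotation, expr)
  expect_equal(r$rho, 1)

  # permuted expression: no correlation
  nulls <- vapply(1:10, function(s) {
    set.seed(s)
    e2 <- expr
    e2$value <- sample(e2$value)
    density_expression_correlation(pileup(ev), sim$annotation, e2)$rho
  }, numeric(1))
  expect_true(mean(abs(nulls) < 0.2) >= 0.9)

  # expression-weighted placement: positive correlation
  hits <- 0L
  for (s in 1:10) {
    sim2 <- simulate_events(simulate_genome(
      sim_config(seed = 900L + s, n_contigs = 1L, contig_length = 400000L,
                 n_genes = 60L, n_sites = 3000L)))
    expr2 <- data.frame(gene_id = sim2$genes$gene_id,
                        value = sim2$genes$weight)
    map2 <- make_map(sim2$truth$contig, sim2$truth$strand, sim2$truth$pos,
                     sim2$truth$n_events)
    if (density_expression_correlation(map2, sim2$annotation,
                                       expr2)$rho > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  expect_error(density_expression_correlation(
    make_map("c1", "+", 1L, 1L), sim$annotation,
    expr[1:5, ]), "fewer than 10")
})
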