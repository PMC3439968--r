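# Genome/annotation/track I/O and the internal coordinate model.

test_that("load_genome parses records, upper-cases and rejects bad files", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c2", "NN"), fa)
  g <- load_genome(fa)
  expect_equal(g, c(c1 = "ACGT", c2 = "NN"))
  expect_equal(unname(contig_lengths(g)), c(4L, 2L))

  writeLines(c(">c1", "acgt"), fa)
  expect_equal(unname(load_genome(fa)), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "GG"), fa)
  expect_error(load_genome(fa), "duplicate")

  writeLines(character(0), fa)
  expect_error(load_genome(fa))
})

test_that("GTF coordinates convert to 0-based half-open with derived introns", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("c1\tsrc\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("c1\tsrc\texon\t201\t300\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')
  ), gtf)
  ann <- load_annotation(gtf)
  expect_equal(ann$exons$start, c(0L, 200L))
  expect_equal(ann$exons$end, c(100L, 300L))
  expect_equal(ann$introns$start, 100L)
  expect_equal(ann$introns$end, 200L)
  expect_equal(ann$genes$biotype, "protein_coding")
})

test_that("minus-strand transcripts keep genomic order; orientation derivable", {
  ann <- make_ann(list(
    list("t1", "g1", "c1", "-", 0, 100),
    list("t1", "g1", "c1", "-", 200, 300)
  ))
  # genomically sorted storage
  expect_equal(ann$exons$start, c(0L, 200L))
  # transcript-oriented first exon of a '-' transcript is the genomically
  # last one
  ex <- ann$exons[ann$exons$transcript_id == "t1", ]
  first_tx_oriented <- ex[order(-ex$start), ][1, ]
  expect_equal(c(first_tx_oriented$start, first_tx_oriented$end),
               c(200L, 300L))
})

test_that("annotation loading validates bounds and exon overlap", {
  ann_rows <- list(list("t1", "g1", "c1", "+", 0, 100))
  expect_error(make_ann(ann_rows, contigs = c(c1 = 50L)), "bounds")
  expect_error(make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t1", "g1", "c1", "+", 50, 150)
  )), "overlapping")
})

test_that("GTF round-trips through write_annotation_gtf and load_annotation", {
  set.seed(42)
  for (rep in 1:3) {
    sim <- simulate_genome(sim_config(seed = 100L + rep, n_contigs = 1L,
                                      contig_length = 100000L,
                                      n_genes = 12L))
    gtf <- withr::local_tempfile(fileext = ".gtf")
    write_annotation_gtf(sim$annotation, gtf)
    back <- load_annotation(gtf, sim$genome)
    for (tab in c("exons", "introns", "genes")) {
      a <- sim$annotation[[tab]]
      b <- back[[tab]]
      o_a <- do.call(order, a)
      o_b <- do.call(order, b)
      expect_equal(a[o_a, , drop = FALSE], b[o_b, , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("co-transcribed regions merge same-strand overlaps only", {
  ann <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t2", "g2", "c1", "+", 50, 150)
  ))
  r <- derive_cotranscribed_regions(ann)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0L, 150L))

  ann2 <- make_ann(list(
    list("t1", "g1", "c1", "+", 0, 100),
    list("t2", "g2", "c1", "-", 50, 150)
  ))
  expect_equal(nrow(derive_cotranscribed_regions(ann2)), 2L)
})

test_that("co-transcribed regions match a per-base brute-force oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    starts <- sort(sample.int(900, n))
    ends <- pmin(1000L, starts + sample(10:120, n, replace = TRUE))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    rows <- lapply(seq_len(n), function(i)
      list(paste0("t", i), paste0("g", i), "c1", strands[i],
           starts[i], ends[i]))
    ann <- make_ann(rows)
    got <- derive_cotranscribed_regions(ann)
    for (s in c("+", "-")) {
      covered <- logical(1000)
      for (i in which(strands == s)) {
        covered[(starts[i] + 1):ends[i]] <- TRUE
      }
      runs <- rle(covered)
      stops <- cumsum(runs$lengths)
      begin <- stops - runs$lengths + 1L
      oracle <- data.frame(start = begin[runs$values] - 1L,
                           end = stops[runs$values])
      gs <- got[got$strand == s, c("start", "end")]
      rownames(gs) <- NULL
      expect_equal(gs, oracle, ignore_attr = TRUE)
      # every gene is contained in exactly one region of its strand
      for (i in which(strands == s)) {
        hit <- gs$start <= starts[i] & ends[i] <= gs$end
        expect_equal(sum(hit), 1L)
      }
    }
  }
})

test_that("tag files parse, validate and round-trip", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t100\t130\tACG\t.\t+", bed)
  tg <- read_tags(bed)
  expect_equal(tg$contig, "c1")
  expect_equal(c(tg$start, tg$end), c(100L, 130L))
  expect_equal(tg$barcode, "ACG")
  expect_equal(tg$strand, "+")

  writeLines(c("c1\t100\t130\tACG\t.\t+", "c1\t50\tXX\tACG\t.\t+"), bed)
  expect_error(read_tags(bed), "line 2")

  set.seed(11)
  tags <- make_tags("c1", s <- sample.int(1000, 20),
                    s + sample(30:60, 20, TRUE),
                    replicate(20, paste(sample(c("A", "C", "G", "T"), 5,
                                               TRUE), collapse = "")),
                    sample(c("+", "-"), 20, TRUE))
  write_tags(tags, bed)
  expect_equal(read_tags(bed), tags, ignore_attr = TRUE)
})

test_that("site maps and clusters round-trip through bedGraph/BED", {
  map <- make_map("c1", c("+", "+", "-"), c(99L, 150L, 42L), c(3L, 1L, 2L))
  prefix <- withr::local_tempfile()
  write_sites(map, prefix)
  plus <- readLines(paste0(prefix, ".plus.bedgraph"))
  expect_equal(plus[1], "c1\t99\t100\t3")
  expect_equal(read_sites(prefix), map, ignore_attr = TRUE)

  set.seed(3)
  for (rep in 1:5) {
    n <- sample(1:20, 1)
    st <- sort(sample.int(5000, n))
    cl <- data.frame(contig = "c1", strand = sample(c("+", "-"), n, TRUE),
                     start = st, end = st + sample(1:200, n, TRUE),
                     total_count = sample.int(500, n),
                     fdr = sample(0:50, n, TRUE) / 1000,
                     stringsAsFactors = FALSE)
    bed <- withr::local_tempfile(fileext = ".bed")
    write_clusters(cl, bed)
    expect_equal(read_clusters(bed), cl, ignore_attr = TRUE)
  }
})
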