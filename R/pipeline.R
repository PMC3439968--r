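# End-to-end pipeline wiring and run configuration.

#' Default analysis parameters
#'
#' The published defaults of the analysis: site/cluster FDR threshold
#' 0.05 (strict), cluster merge gap 15 nt, 100 permutations and 100
#' motif shuffles, pentamer windows `[-30,-10]` and `[+10,+30]` (with
#' the crosslink extended by 30 nt in both directions), junction window
#' +/-300 nt, minimum exon 60 nt, minimum intron 200 nt, branch-point
#' minimum intron 240 nt and minimum distance to the 3' splice site
#' 20 nt, Gaussian smoothing half-width 5, cluster-overlap threshold
#' 15 nt, top 5 pentamers for the consensus.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    n_perm = 100L,
    fdr = 0.05,
    max_gap = 15L,
    window = 300L,
    half_width = 5L,
    min_exon = 60L,
    min_intron = 200L,
    min_intron_bp = 240L,
    bp_min_dist = 20L,
    shuffles = 100L,
    min_overlap = 15L,
    motif_extension = 30L,
    motif_windows = list(c(-30L, -10L), c(10L, 30L)),
    top_pentamers = 5L
  )
}

#' Run the full pipeline on simulated data
#'
#' Simulates a dataset, writes its files, reads them back through the
#' package's own readers, and runs crosslink assignment, site and
#' cluster calling, motif analysis, RNA maps and RNA-class
#' classification. All stages are seeded; two runs with the same seed
#' produce identical outputs.
#'
#' @param out_dir Output directory.
#' @param config A `sim_config` (its `seed` is overridden by `seed`).
#' @param params Analysis parameters, see [default_params()].
#' @param seed Master integer seed.
#' @return Invisibly, a list with the main result objects (`sites`,
#'   `clusters`, `ztable`, `consensus`, `profiles`, `class_table`).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         params = default_params(), seed = 1L) {
  config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- emit_tags(simulate_events(simulate_genome(config)))
  write_sim(sim, file.path(out_dir, "sim"))

  genome <- load_genome(file.path(out_dir, "sim", "genome.fa"))
  ann <- load_annotation(file.path(out_dir, "sim", "annotation.gtf"), genome)
  tags <- read_tags(file.path(out_dir, "sim", "tags.bed"))

  map <- tags_to_sites(tags, genome)
  write_sites(map, file.path(out_dir, "sites"))

  regions <- derive_cotranscribed_regions(ann)
  sites <- call_sites(map, regions, n_perm = params$n_perm,
                      threshold = params$fdr, seed = seed + 11L)
  sig <- sites[sites$significant, , drop = FALSE]
  clusters <- call_clusters(sig, max_gap = params$max_gap)
  clusters <- cluster_fdr(clusters, sites, regions, n_perm = params$n_perm,
                          threshold = params$fdr, max_gap = params$max_gap,
                          seed = seed + 12L)
  write_clusters(clusters[clusters$significant, , drop = FALSE],
                 file.path(out_dir, "clusters.bed"))
  utils::write.table(sites, file.path(out_dir, "site_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ztable <- pentamer_zscores(sig, genome, ann,
                             n_shuffles = params$shuffles,
                             windows = params$motif_windows,
                             seed = seed + 13L)
  consensus <- consensus_from_top(ztable, k = params$top_pentamers)
  utils::write.table(ztable, file.path(out_dir, "pentamer_zscores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jn <- build_junctions(ann, window = params$window,
                        min_exon = params$min_exon,
                        min_intron = params$min_intron)
  profiles <- junction_profile(map, jn, half_width = params$half_width)
  bp_sel <- select_branch_points(ann, sim$branchpoints,
                                 min_intron = params$min_intron_bp,
                                 min_dist = params$bp_min_dist)
  profiles$bp <- if (any(bp_sel$selected)) {
    branchpoint_profile(map, bp_sel, window = params$window,
                        half_width = params$half_width)
  } else NULL
  for (nm in names(profiles)) {
    if (!is.null(profiles[[nm]])) {
      utils::write.table(profiles[[nm]],
                         file.path(out_dir, sprintf("profile_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  class_table <- classify(map, ann)
  utils::write.table(class_table, file.path(out_dir, "class_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_provenance(file.path(out_dir, "provenance.json"), params, seed,
                   c(genome = file.path(out_dir, "sim", "genome.fa"),
                     tags = file.path(out_dir, "sim", "tags.bed")))
  invisible(list(sim = sim, map = map, sites = sites, clusters = clusters,
                 ztable = ztable, consensus = consensus,
                 profiles = profiles, class_table = class_table))
}

# Machine-readable run record: parameters, seed, input checksums.
write_provenance <- function(path, params, seed, inputs) {
  sums <- vapply(inputs, function(p)
    as.character(tools::md5sum(p)), character(1L))
  rec <- list(seed = seed, parameters = params,
              input_md5 = as.list(sums),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), path)
  } else {
    dput(rec, file = path)
  }
  invisible(path)
}
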