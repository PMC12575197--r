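# Shared, memoised desk-scale replicate runs. The planted-sweep and neutral
# replicate sets are used by both the module property tests and the
# acceptance suite; computing each set once keeps the whole run inside the
# time budget. Seeds are fixed and recorded here.

SWEEP_SEEDS <- 1:20
NEUTRAL_SEEDS <- 1001:1020
SWEEP_POS <- 1e6
SEQ_LEN <- 2e6

.replicate_cache <- new.env(parent = emptyenv())

test_xpclr_config <- function() {
  xpclr_config(grid_spacing = 5000, max_snps_per_window = 100,
               genetic_map_rate = 2e-7)
}

test_genes <- function() tile_genes(SEQ_LEN, 20000, 20000)

# gene containing the sweep site and a fixed off-sweep control gene
sweep_gene_id <- function() {
  g <- test_genes()
  g$gene_id[g$start <= SWEEP_POS & g$end > SWEEP_POS]
}
control_gene_id <- function() {
  g <- test_genes()
  g$gene_id[g$start <= 250000 & g$end > 250000]
}

# One full analysis chain on a simulated cohort (QC -> three scans ->
# consensus), at the test preset.
analyse_replicate <- function(seed, sweep) {
  specs <- if (sweep) list(list(pos = SWEEP_POS, s = 0.1)) else list()
  sim <- simulate_two_pop(sim_config(sweep_specs = specs, seed = seed))
  gm <- suppressWarnings(filter_snp_qc(filter_variant_quality(
    sim$genotypes[["1"]])))
  pm <- sim$popmap
  lens <- c("1" = SEQ_LEN)

  win <- fstpi_scan(gm, pm, "fat", "thin", chrom_lengths = lens)
  outl <- call_joint_outliers(win)
  xp <- xpclr_scan(gm, pm, "fat", "thin", test_xpclr_config(),
                   chrom_lengths = lens)
  segs <- suppressWarnings(roh_scan(gm, pm, "fat", roh_params("test")))
  track <- occurrence_track(segs, gm, pm$sample[pm$group == "fat"])
  islands <- call_islands(track, 20)

  genes <- test_genes()
  g_fst <- regions_to_genes(outl$regions, genes)
  g_xp <- regions_to_genes(xp$regions, genes)
  g_roh <- regions_to_genes(
    data.frame(chrom = islands$chrom, start = islands$start - 1L,
               end = islands$end, stringsAsFactors = FALSE), genes)
  list(
    win = win, outlier_regions = outl$regions,
    xp_points = xp$points, xp_regions = xp$regions, omega = xp$omega,
    roh_segments = segs, roh_track = track, roh_islands = islands,
    consensus = consensus_genes(g_fst, g_xp, g_roh),
    gm = gm, pm = pm
  )
}

sweep_replicates <- function(seeds = SWEEP_SEEDS) {
  lapply(seeds, function(s) {
    key <- paste0("sweep_", s)
    if (is.null(.replicate_cache[[key]])) {
      .replicate_cache[[key]] <- analyse_replicate(s, sweep = TRUE)
    }
    .replicate_cache[[key]]
  })
}

neutral_replicates <- function(seeds = NEUTRAL_SEEDS) {
  lapply(seeds, function(s) {
    key <- paste0("neutral_", s)
    if (is.null(.replicate_cache[[key]])) {
      .replicate_cache[[key]] <- analyse_replicate(s, sweep = FALSE)
    }
    .replicate_cache[[key]]
  })
}

# does any region (0-based half-open) cover `pos` (0-based bp)?
covers <- function(regions, pos, chrom = "1", slop = 0) {
  any(regions$chrom == chrom & regions$start <= pos + slop &
        regions$end > pos - slop)
}
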