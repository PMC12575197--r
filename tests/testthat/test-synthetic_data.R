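small_cfg <- function(seed, gens = 50L, sweeps = list(), n_e = 100L) {
  sim_config(n_diploids_per_pop = 20, n_e_per_pop = n_e,
             sequence_length = 5e5, n_sites = 300,
             split_generations = gens, sweep_specs = sweeps, seed = seed)
}

test_that("identical seed and config give byte-identical VCF output", {
  f1 <- tempfile(fileext = ".vcf.gz"); f2 <- tempfile(fileext = ".vcf.gz")
  write_vcf(simulate_two_pop(small_cfg(123))$genotypes, f1)
  write_vcf(simulate_two_pop(small_cfg(123))$genotypes, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  # and a different seed differs
  f3 <- tempfile(fileext = ".vcf.gz")
  write_vcf(simulate_two_pop(small_cfg(124))$genotypes, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1) + 10),
                         readBin(f3, "raw", file.size(f3) + 10)))
})

test_that("planted sweeps are fixed in the object population at sampling", {
  sim <- simulate_two_pop(small_cfg(5, gens = 200L,
                                    sweeps = list(list(pos = 2.5e5, s = 0.2))))
  gm <- sim$genotypes[["1"]]
  expect_equal(nrow(sim$truth), 1L)
  expect_true(sim$truth$fixed)
  site <- match(sim$truth$pos, gm$pos)
  fat <- sim$popmap$sample[sim$popmap$group == "fat"]
  thin <- sim$popmap$sample[sim$popmap$group == "thin"]
  expect_true(all(gm$geno[fat, site] == 2L))
  expect_true(all(gm$geno[thin, site] == 0L))
})

test_that("an unfixable sweep hits the generation cap with a clear error", {
  cfg <- sim_config(n_diploids_per_pop = 10, n_e_per_pop = 50,
                    sequence_length = 1e5, n_sites = 50,
                    split_generations = 5, generation_cap_factor = 3,
                    sweep_specs = list(list(pos = 5e4, s = 0.01)), seed = 2)
  expect_error(simulate_two_pop(cfg), "larger s")
})

test_that("config validation enforces the stated invariants", {
  expect_error(sim_config(n_diploids_per_pop = 1), "n_diploids_per_pop")
  expect_error(sim_config(sweep_specs = list(list(pos = 1e5, s = 0))),
               "selection coefficient")
  expect_error(sim_config(sweep_specs = list(list(pos = 2e6, s = 0.1))),
               "sweep position")
  expect_error(sim_config(n_diploids_per_pop = 50, n_e_per_pop = 20))
})

test_that("neutral allele frequencies drift without directional bias", {
  # martingale check: the two populations drift from the same split state,
  # so the mean (object - reference) frequency difference over many
  # replicates is 0 within 3 standard errors
  diffs <- vapply(1:200, function(i) {
    sim <- simulate_two_pop(sim_config(
      n_diploids_per_pop = 10, n_e_per_pop = 10, sequence_length = 1e5,
      n_sites = 60, split_generations = 5, seed = 40000L + i))
    gm <- sim$genotypes[["1"]]
    fat <- sim$popmap$sample[sim$popmap$group == "fat"]
    thin <- sim$popmap$sample[sim$popmap$group == "thin"]
    mean(colMeans(gm$geno[fat, ]) - colMeans(gm$geno[thin, ])) / 2
  }, 0)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("genome-wide FST increases with divergence time", {
  fst_at <- function(gens) {
    vapply(1:10, function(i) {
      sim <- simulate_two_pop(small_cfg(50000L + 17L * i + gens, gens = gens))
      wc_fst_window(sim$genotypes[["1"]], sim$popmap,
                    obj = "fat", ref = "thin")$fst
    }, 0)
  }
  expect_gt(mean(fst_at(500L)), mean(fst_at(50L)))
})

test_that("pi near a fixed sweep is depressed below the genome-wide median", {
  reps <- sweep_replicates(SWEEP_SEEDS)
  depressed <- vapply(reps, function(r) {
    win <- r$win
    near <- win$start >= SWEEP_POS - 50000 & win$end <= SWEEP_POS + 50000
    mean(win$pi_obj[near]) < median(win$pi_obj)
  }, TRUE)
  expect_gte(mean(depressed), 0.8)
})

test_that("simulator output passes read_vcf and both QC filters", {
  sim <- simulate_two_pop(small_cfg(9))
  f <- tempfile(fileext = ".vcf.gz")
  write_vcf(sim$genotypes, f)
  gms <- read_vcf(f)
  expect_equal(attr(gms, "skipped"), c(multiallelic = 0L, indel = 0L))
  out <- filter_snp_qc(filter_variant_quality(gms))
  expect_true(all(vapply(out, function(g) length(g$pos), 0L) > 0))
  expect_equal(gms[["1"]]$geno, sim$genotypes[["1"]]$geno)
})

test_that("two-chromosome output splits the sequence and the truth table", {
  cfg <- sim_config(n_diploids_per_pop = 10, n_e_per_pop = 50,
                    sequence_length = 4e5, n_sites = 200,
                    split_generations = 60, n_chromosomes = 2,
                    sweep_specs = list(list(pos = 3e5, s = 0.3)), seed = 3)
  sim <- simulate_two_pop(cfg)
  expect_named(sim$genotypes, c("1", "2"))
  expect_true(all(sim$genotypes[["2"]]$pos <= 2e5))
  expect_equal(sim$truth$chrom, "2")
  expect_equal(sim$truth$pos, 3e5 + 1 - 2e5)
})

test_that("tile_genes tiles deterministically and round-trips through BED", {
  g <- tile_genes(1e5, 10000, 10000)
  expect_equal(nrow(g), 5L)
  expect_equal(g$gene_id[1], "GENE0001")
  expect_equal(g$start, seq(0L, 80000L, by = 20000L))
  bed <- tempfile(fileext = ".bed")
  g2 <- tile_genes(1e5, 10000, 10000, bed_path = bed)
  back <- read_gene_annotation(bed)
  expect_equal(back$gene_id, g2$gene_id)
  expect_equal(back$start, g2$start)
  expect_equal(back$end, g2$end)
  # any interior position lies within gene_size + gap of some gene
  for (p in c(0, 15000, 55000, 99999)) {
    expect_lte(min(pmax(g$start - p, 0, p - g$end + 1)), 20000)
  }
})

test_that("fixtures are deterministic and well-formed", {
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- make_fixture_vcf("tiny_fst", d1)
  f2 <- make_fixture_vcf("tiny_fst", d2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  gm <- read_vcf(f1[1])[["1"]]
  expect_equal(dim(gm$geno), c(8L, 12L))
  roh <- make_fixture_vcf("roh_toy", d1)
  expect_equal(length(read_vcf(roh[1])[["1"]]$pos), 200L)
  expect_error(make_fixture_vcf("nope", d1))
})
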