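test_that("read_vcf decodes GT, skips non-SNP records, and counts them", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    "1\t100\t.\tA\tG\t.\t.\tQD=5;MQ=50;FS=2\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tA\tA,T\t.\t.\t.\tGT\t0/0\t0/1\t1/1",       # multi-allelic
    "1\t300\t.\tAT\tA\t.\t.\t.\tGT\t0/0\t0/1\t1/1",        # indel
    "1\t400\t.\tC\tT\t.\t.\t.\tGT\t./.\t0|1\t1/1"          # missing + phased
  ), vcf)
  gms <- read_vcf(vcf)
  expect_named(gms, "1")
  gm <- gms[["1"]]
  expect_equal(gm$pos, c(100L, 400L))
  expect_equal(unname(gm$geno[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gm$geno[, 2]), c(NA_integer_, 1L, 2L))
  expect_equal(attr(gms, "skipped"),
               c(multiallelic = 1L, indel = 1L))
  expect_equal(gm$info$qd, c(5, NA))
  expect_equal(gm$info$mq, c(50, NA))
})

test_that("read_vcf errors name the offending record", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "1\t500\t.\tA\tG\t.\t.\t.\tGT\t0/1",
    "1\t400\t.\tA\tG\t.\t.\t.\tGT\t0/1"
  ), vcf)
  expect_error(read_vcf(vcf), "1:400")

  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "1\t500\t.\tA\tG\t.\t.\t.\tDP\t12"
  ), vcf2)
  expect_error(read_vcf(vcf2), "GT")
})

test_that("VCF round trip preserves chrom, positions, genotypes and info", {
  set.seed(42)
  g <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 5)
  gm <- genotype_matrix("7", sort(sample.int(1e5, 12)), sprintf("S%d", 1:5),
                        g, info = data.frame(qd = runif(12, 2, 30),
                                             mq = rep(60, 12),
                                             fs = rep(1.5, 12),
                                             dp = rep(10, 12)))
  for (ext in c(".vcf", ".vcf.gz")) {
    path <- tempfile(fileext = ext)
    write_vcf(gm, path)
    back <- read_vcf(path)[["7"]]
    expect_equal(back$pos, gm$pos)
    expect_equal(back$geno, gm$geno)
    expect_equal(back$info$dp, gm$info$dp)
    expect_equal(back$info$qd, gm$info$qd, tolerance = 1e-6)
  }
})

test_that("variant-quality filter applies strict thresholds with boundaries", {
  info <- data.frame(qd = c(1.5, 2.0, 5, 5), mq = c(60, 20, 19, 60),
                     fs = c(1, 60.0, 1, 60.1), dp = rep(10, 4))
  gm <- genotype_matrix("1", c(10L, 20L, 30L, 40L), c("a", "b"),
                        matrix(1L, 2, 4), info)
  out <- filter_variant_quality(gm)
  # site 1 fails QD<2, site 3 fails MQ<20, site 4 fails FS>60; site 2 is
  # boundary-valued on all three and survives
  expect_equal(out$pos, 20L)
  expect_equal(attr(out, "filter_log")[["removed_qd"]], 1)
  expect_equal(attr(out, "filter_log")[["removed_mq"]], 1)
  expect_equal(attr(out, "filter_log")[["removed_fs"]], 1)
  # absent INFO passes the sub-filter
  gm2 <- genotype_matrix("1", c(10L, 20L), c("a", "b"), matrix(1L, 2, 2))
  expect_equal(length(filter_variant_quality(gm2)$pos), 2L)
})

test_that("SNP QC filter applies non-strict call-rate and MAF boundaries", {
  # 10 samples: site 1 has exactly 1 missing (call rate 0.9 -> removed),
  # site 2 has MAF exactly 0.05, site 3 passes, sites 4/5 fail depth
  g <- matrix(1L, 10, 5)
  g[1, 1] <- NA
  g[, 2] <- 0L; g[1, 2] <- 1L                     # MAF = 1/20 = 0.05
  info <- data.frame(qd = NA, mq = NA, fs = NA,
                     dp = c(10, 10, 10, 2.9, 30.5))
  gm <- genotype_matrix("1", (1:5) * 10L, sprintf("S%02d", 1:10), g, info)
  out <- filter_snp_qc(gm)
  expect_equal(out$pos, 30L)
  tl <- attr(out, "filter_log")
  expect_equal(tl[["removed_callrate"]], 1)
  expect_equal(tl[["removed_maf"]], 1)
  expect_equal(tl[["removed_depth"]], 2)
  # depth absent -> depth sub-filter skipped with a warning
  gm2 <- genotype_matrix("1", (1:5) * 10L, sprintf("S%02d", 1:10), g)
  expect_warning(out2 <- filter_snp_qc(gm2), "depth")
  expect_equal(out2$pos, c(30L, 40L, 50L))
})

test_that("filter_toy fixture yields the constructed retained count", {
  dir <- tempfile(); files <- make_fixture_vcf("filter_toy", dir)
  gms <- read_vcf(files[1])
  out <- filter_snp_qc(filter_variant_quality(gms))
  expect_equal(sum(vapply(out, function(g) length(g$pos), 0L)), 6L)
})

test_that("filtering is idempotent and order-commutative", {
  set.seed(7)
  for (rep in 1:5) {
    g <- matrix(sample(c(0:2, NA), 12 * 30, replace = TRUE,
                       prob = c(.4, .2, .3, .1)), 12, 30)
    info <- data.frame(qd = runif(30, 0, 10), mq = runif(30, 10, 70),
                       fs = runif(30, 0, 90), dp = runif(30, 1, 40))
    gm <- genotype_matrix("1", sort(sample.int(1e6, 30)),
                          sprintf("S%02d", 1:12), g, info)
    f1 <- function(x) filter_variant_quality(x)
    f2 <- function(x) filter_snp_qc(x)
    a <- f2(f1(gm)); b <- f1(f2(gm)); aa <- f2(f1(f2(f1(gm))))
    expect_equal(a$pos, b$pos)
    expect_equal(a$geno, b$geno)
    expect_equal(aa$pos, a$pos)
  }
})

test_that("gene annotation reads BED and GFF3 with coordinate conventions", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tGENE1", "chr1\t300\t400\tGENE2"), bed)
  gb <- read_gene_annotation(bed)
  expect_equal(gb$gene_id, c("GENE1", "GENE2"))
  expect_equal(gb$start[1], 100L)
  expect_equal(gb$end[1], 200L)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=GENE1",
    "chr1\tsrc\tmRNA\t101\t150\t.\t+\t.\tID=RNA1;Parent=GENE1",
    "chr1\tsrc\tgene\t301\t400\t.\t-\t.\tID=GENE2",
    "chr1\tsrc\tgene\t301\t400\t.\t-\t.\tID=GENE2"   # duplicate row
  ), gff)
  gg <- read_gene_annotation(gff, "gff3")
  expect_equal(nrow(gg), 2L)                         # mRNA ignored, dedup
  expect_equal(gg$start[gg$gene_id == "GENE1"], 100L)  # 1-based -> 0-based
  expect_equal(gg$end[gg$gene_id == "GENE1"], 200L)

  expect_error(read_gene_annotation(tempfile(fileext = ".xyz")), "format")
})

test_that("region BED and TSV writers round-trip with their conventions", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(regions, bed)
  expect_equal(readLines(bed), "chr1\t0\t50000")
  expect_equal(read_regions_bed(bed), regions)

  tsv <- tempfile(fileext = ".tsv")
  write_table_tsv(regions, tsv)
  line <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(line$start, 1L)                       # 1-based inclusive out
  expect_equal(line$end, 50000L)
  expect_equal(read_table_tsv(tsv), regions)

  # empty inputs: header-only TSV, empty BED
  empty <- regions[0, ]
  write_regions_bed(empty, bed); write_table_tsv(empty, tsv)
  expect_equal(length(readLines(bed)), 0L)
  expect_equal(length(readLines(tsv)), 1L)
})

test_that("population map rejects duplicate assignments", {
  expect_error(population_map(c("a", "a"), c("x", "y")), "more than one")
  pm <- population_map(c("a", "b"), c("x", "y"))
  f <- tempfile(); writeLines(c("a\tx", "b\ty"), f)
  expect_equal(read_popmap(f), pm)
})
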