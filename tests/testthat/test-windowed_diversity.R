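make_gm <- function(obj, ref, pos = NULL, chrom = "1") {
  g <- rbind(obj, ref)
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 1000L
  genotype_matrix(chrom, pos,
                  c(sprintf("O%d", seq_len(nrow(obj))),
                    sprintf("R%d", seq_len(nrow(ref)))), g)
}
make_pm <- function(n_obj, n_ref) {
  population_map(c(sprintf("O%d", seq_len(n_obj)),
                   sprintf("R%d", seq_len(n_ref))),
                 rep(c("obj", "ref"), c(n_obj, n_ref)))
}

test_that("sliding_windows tiles with truncated trailing windows", {
  w <- sliding_windows(100000, 50000, 25000)
  expect_equal(w$start, c(0L, 25000L, 50000L, 75000L))
  expect_equal(w$end, c(50000L, 75000L, 100000L, 100000L))
  w2 <- sliding_windows(50000, 50000, 25000)
  expect_equal(nrow(w2), 2L)          # full window + 25 kb partial
  expect_equal(w2$end[2], 50000L)
  w3 <- sliding_windows(100000, 50000, 50000)   # step = size tiles exactly
  expect_equal(w3$start, c(0L, 50000L))
  expect_error(sliding_windows(1e5, 0, 10), "positive")
  expect_error(sliding_windows(1e5, 10, 20), "exceed")
})

test_that("wc_fst_window matches fixation, monomorphic and contract cases", {
  gm <- make_gm(matrix(0L, 4, 1), matrix(2L, 4, 1))
  r <- wc_fst_window(gm, make_pm(4, 4), obj = "obj", ref = "ref")
  expect_equal(r$fst, 1.0)
  expect_equal(r$n_snps, 1L)

  gm2 <- make_gm(matrix(2L, 4, 3), matrix(2L, 4, 3))
  r2 <- wc_fst_window(gm2, make_pm(4, 4), obj = "obj", ref = "ref")
  expect_true(is.nan(r2$fst))
  expect_equal(r2$n_snps, 0L)

  pm3 <- population_map(c("O1", "O2", "R1", "R2", "X1"),
                        c("a", "a", "b", "b", "c"))
  gm3 <- genotype_matrix("1", 1000L, c("O1", "O2", "R1", "R2", "X1"),
                         matrix(c(0L, 1L, 2L, 1L, 0L), 5, 1))
  expect_error(wc_fst_window(gm3, pm3), "two groups")
})

test_that("tiny_fst fixture FST equals the brute-force oracle to 1e-12", {
  dir <- tempfile(); files <- make_fixture_vcf("tiny_fst", dir)
  gm <- read_vcf(files[1])[["1"]]
  pm <- read_popmap(files[2])
  got <- wc_fst_window(gm, pm, obj = "popA", ref = "popB")
  want <- oracle_wc_fst(gm$geno[1:4, , drop = FALSE],
                        gm$geno[5:8, , drop = FALSE])
  expect_equal(got$fst, want, tolerance = 1e-12)
})

test_that("windowed FST and pi equal brute-force oracles on 100 random instances", {
  set.seed(20240901)
  for (i in 1:100) {
    d <- random_two_pop(n_site = 20, n_samp = 6, miss = 0.1)
    gm <- make_gm(d$obj, d$ref)
    pm <- make_pm(6, 6)
    win <- c(0L, 21000L)
    got <- wc_fst_window(gm, pm, win, obj = "obj", ref = "ref")$fst
    want <- oracle_wc_fst(d$obj, d$ref)
    if (is.nan(want)) expect_true(is.nan(got))
    else expect_equal(got, want, tolerance = 1e-12)
    got_pi <- pi_window(gm, sprintf("O%d", 1:6), win)
    expect_equal(got_pi, oracle_pi(d$obj, 21000), tolerance = 1e-12)
  }
})

test_that("pi_window closed forms and invariances hold", {
  # one site, alleles (0,0,1,1) in a 50 kb window
  gm <- make_gm(matrix(c(0L, 2L), 2, 1), matrix(0L, 2, 1))
  expect_equal(pi_window(gm, c("O1", "O2"), c(0L, 50000L)),
               (2 * 0.5 * 0.5 * 4 / 3) / 50000, tolerance = 1e-12)
  # zero segregating sites
  gm0 <- make_gm(matrix(0L, 2, 3), matrix(0L, 2, 3))
  expect_equal(pi_window(gm0, c("O1", "O2"), c(0L, 50000L)), 0)
  # sample reordering and REF/ALT swap invariance
  set.seed(5)
  d <- random_two_pop(n_site = 30, n_samp = 8)
  gm1 <- make_gm(d$obj, d$ref)
  perm <- sample(sprintf("O%d", 1:8))
  expect_equal(pi_window(gm1, perm, c(0L, 31000L)),
               pi_window(gm1, sprintf("O%d", 1:8), c(0L, 31000L)))
  gm2 <- make_gm(2L - d$obj, d$ref)
  expect_equal(pi_window(gm2, sprintf("O%d", 1:8), c(0L, 31000L)),
               pi_window(gm1, sprintf("O%d", 1:8), c(0L, 31000L)),
               tolerance = 1e-14)
})

test_that("transform_stats fills z and log2 ratio as documented", {
  rec <- data.frame(chrom = "1", start = c(0, 25e3, 50e3),
                    end = c(50e3, 75e3, 100e3), n_snps = 5,
                    fst = c(0.1, 0.2, 0.3),
                    pi_obj = c(1e-4, 1e-4, 2e-4),
                    pi_ref = c(1e-4, 2e-4, 2e-4))
  tr <- transform_stats(rec)
  expect_equal(tr$z_fst, c(-1, 0, 1))
  expect_equal(tr$log2_pi_ratio, c(0, 1, 0))
  # pi of zero -> undefined ratio
  rec$pi_obj[2] <- 0
  expect_true(is.na(transform_stats(rec)$log2_pi_ratio[2]))
  rec$fst <- 0.2
  expect_error(transform_stats(rec), "identical")
})

test_that("z_fst has mean 0 and sample sd 1 to 1e-9 on scan output", {
  rep1 <- sweep_replicates(SWEEP_SEEDS[1])[[1]]
  z <- rep1$win$z_fst[is.finite(rep1$win$z_fst)]
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
})

test_that("joint outlier calling flags, merges, and is monotone in q", {
  set.seed(11)
  n <- 100
  rec <- data.frame(chrom = "1", start = (0:(n - 1)) * 25000L,
                    end = (0:(n - 1)) * 25000L + 50000L, n_snps = 10,
                    fst = runif(n, 0, 0.2),
                    pi_obj = runif(n, 1e-5, 1e-4),
                    pi_ref = runif(n, 1e-5, 1e-4))
  # plant exactly 3 windows extreme in both metrics, far apart
  hot <- c(10, 40, 70)
  rec$fst[hot] <- 0.9
  rec$pi_obj[hot] <- 1e-6
  tr <- transform_stats(rec)
  out <- call_joint_outliers(tr, mode = "absolute", z_cut = 1.58,
                             ratio_cut = 2, ratio_direction = ">")
  expect_equal(nrow(out$windows), 3L)
  expect_equal(nrow(out$regions), 3L)

  # overlapping flagged windows merge into one maximal region
  m <- merge_intervals(data.frame(chrom = "1", start = c(0L, 25000L),
                                  end = c(50000L, 75000L)))
  expect_equal(m, data.frame(chrom = "1", start = 0L, end = 75000L))

  # quantile mode monotone in q (flagged windows nest)
  f1 <- call_joint_outliers(tr, q = 0.02)$windows$start
  f2 <- call_joint_outliers(tr, q = 0.10)$windows$start
  expect_true(all(f1 %in% f2))
})

test_that("windowed scan matches per-window recomputation across chromosomes", {
  set.seed(99)
  d1 <- random_two_pop(n_site = 40, n_samp = 5)
  d2 <- random_two_pop(n_site = 25, n_samp = 5)
  gms <- list("1" = make_gm(d1$obj, d1$ref,
                            pos = sort(sample.int(9e4, 40)), chrom = "1"),
              "2" = make_gm(d2$obj, d2$ref,
                            pos = sort(sample.int(9e4, 25)), chrom = "2"))
  pm <- make_pm(5, 5)
  win <- fstpi_scan(gms, pm, "obj", "ref", size = 30000, step = 15000,
                    chrom_lengths = c("1" = 9e4, "2" = 9e4))
  for (i in seq_len(nrow(win))) {
    gm <- gms[[win$chrom[i]]]
    w <- c(win$start[i], win$end[i])
    ref <- wc_fst_window(gm, pm, w, obj = "obj", ref = "ref")
    expect_equal(win$fst[i], ref$fst)
    expect_equal(win$n_snps[i], ref$n_snps)
    expect_equal(win$pi_obj[i], pi_window(gm, sprintf("O%d", 1:5), w))
  }
})
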