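#' Sliding windows along a chromosome
#'
#' 0-based half-open windows of `size` bp every `step` bp starting at 0. The
#' trailing windows are truncated at the chromosome end and kept whenever
#' they contain at least one bp.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp (default 50 kb).
#' @param step window step in bp (default 25 kb).
#' @return data.frame with columns `start`, `end`.
#' @export
sliding_windows <- function(chrom_length, size = 50000L, step = 25000L) {
  if (size <= 0 || step <= 0) stop("window size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  starts <- seq(0L, max(0L, as.integer(chrom_length) - 1L), by = as.integer(step))
  data.frame(start = starts,
             end = pmin(starts + as.integer(size), as.integer(chrom_length)))
}

# Per-site Weir & Cockerham (1984) variance components for two populations.
# geno_obj / geno_ref: samples x sites genotype matrices. Returns list of
# vectors a, b, c and `usable` (polymorphic across the pooled sample with
# both groups genotyped).
wc_site_components <- function(geno_obj, geno_ref) {
  comp_pop <- function(g) {
    n <- colSums(!is.na(g))                       # genotyped individuals
    alt <- colSums(g, na.rm = TRUE)
    het <- colSums(g == 1L, na.rm = TRUE)
    p <- ifelse(n > 0L, alt / (2 * n), NA_real_)
    h <- ifelse(n > 0L, het / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  o <- comp_pop(geno_obj); rf <- comp_pop(geno_ref)
  r <- 2
  nbar <- (o$n + rf$n) / r
  usable <- o$n > 0L & rf$n > 0L & nbar > 1
  nc <- (r * nbar - (o$n^2 + rf$n^2) / (r * nbar)) / (r - 1)
  pbar <- (o$n * o$p + rf$n * rf$p) / (r * nbar)
  s2 <- (o$n * (o$p - pbar)^2 + rf$n * (rf$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (o$n * o$h + rf$n * rf$h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1
  usable <- usable & poly
  a[!usable] <- 0; b[!usable] <- 0; cc[!usable] <- 0
  list(a = a, b = b, c = cc, usable = usable)
}

#' Weir-Cockerham FST for one window
#'
#' Two-population Weir & Cockerham (1984) estimator, combining sites by ratio
#' of sums of the per-site variance components: `sum(a) / sum(a + b + c)`.
#' Sites monomorphic across the pooled sample contribute nothing; missing
#' genotypes are excluded per site. Returns `NaN` when the denominator is 0.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] with exactly the two contrast groups.
#' @param window `c(start, end)` 0-based half-open, or NULL for all sites.
#' @param obj,ref group labels (defaults: the two groups in `pm`, object
#'   first).
#' @return list(fst =, n_snps = number of usable SNPs).
#' @export
wc_fst_window <- function(gm, pm, window = NULL, obj = NULL, ref = NULL) {
  grp <- unique(pm$group)
  if (length(grp) != 2L) stop("exactly two groups required, got ", length(grp))
  if (is.null(obj)) obj <- grp[1L]
  if (is.null(ref)) ref <- grp[2L]
  ct <- pm_contrast(pm, gm, obj, ref)
  idx <- if (is.null(window)) seq_along(gm$pos) else
    which(gm$pos > window[1L] & gm$pos <= window[2L])
  go <- gm$geno[ct$obj, idx, drop = FALSE]
  gr <- gm$geno[ct$ref, idx, drop = FALSE]
  comp <- wc_site_components(go, gr)
  den <- sum(comp$a + comp$b + comp$c)
  list(fst = if (den == 0) NaN else sum(comp$a) / den,
       n_snps = sum(comp$usable))
}

# per-site unbiased heterozygosity terms 2*p*(1-p)*n/(n-1) for one group
pi_site_terms <- function(geno) {
  n <- 2L * colSums(!is.na(geno))               # non-missing alleles
  alt <- colSums(geno, na.rm = TRUE)
  p <- ifelse(n > 0L, alt / n, 0)
  term <- ifelse(n > 1L, 2 * p * (1 - p) * n / (n - 1), 0)
  term
}

#' Windowed nucleotide diversity
#'
#' `pi = sum over sites of 2 p (1 - p) n / (n - 1)` divided by the full
#' window span in bp, where `p` is the within-group non-missing alternate
#' allele frequency and `n` the non-missing allele count at the site.
#' Positions without a genotyped SNP count as invariant sequence.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids of the group.
#' @param window `c(start, end)` 0-based half-open.
#' @return nucleotide diversity per bp (0 if the window has no SNPs).
#' @export
pi_window <- function(gm, samples, window) {
  idx <- which(gm$pos > window[1L] & gm$pos <= window[2L])
  span <- window[2L] - window[1L]
  if (!length(idx)) return(0)
  sum(pi_site_terms(gm$geno[samples, idx, drop = FALSE])) / span
}

#' Genome-wide sliding-window FST / diversity scan
#'
#' Computes, for every sliding window on every chromosome, the
#' Weir-Cockerham FST between the object and reference groups and the
#' per-group nucleotide diversity, then fills the genome-wide transforms via
#' [transform_stats()].
#'
#' @param gms a [genotype_matrix()] or named list of them.
#' @param pm a [population_map()].
#' @param obj,ref object and reference group labels.
#' @param size,step window size and step in bp.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @return data.frame of window records: `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `fst`, `pi_obj`, `pi_ref`, `log2_pi_ratio`,
#'   `z_fst`.
#' @export
fstpi_scan <- function(gms, pm, obj, ref, size = 50000L, step = 25000L,
                       chrom_lengths = NULL) {
  gms <- gm_as_list(gms)
  recs <- lapply(gms, function(gm) {
    ct <- pm_contrast(pm, gm, obj, ref)
    len <- if (!is.null(chrom_lengths) && gm$chrom %in% names(chrom_lengths))
      chrom_lengths[[gm$chrom]] else max(gm$pos)
    w <- sliding_windows(len, size, step)
    go <- gm$geno[ct$obj, , drop = FALSE]
    gr <- gm$geno[ct$ref, , drop = FALSE]
    comp <- wc_site_components(go, gr)
    t_obj <- pi_site_terms(go)
    t_ref <- pi_site_terms(gr)
    num <- cumsum(c(0, comp$a))
    den <- cumsum(c(0, comp$a + comp$b + comp$c))
    usa <- cumsum(c(0L, comp$usable))
    po <- cumsum(c(0, t_obj)); pr <- cumsum(c(0, t_ref))
    lo <- findInterval(w$start, gm$pos)         # sites with pos <= start
    hi <- findInterval(w$end, gm$pos)           # sites with pos <= end
    dsum <- den[hi + 1L] - den[lo + 1L]
    data.frame(
      chrom = gm$chrom, start = w$start, end = w$end,
      n_snps = usa[hi + 1L] - usa[lo + 1L],
      fst = ifelse(dsum == 0, NaN, (num[hi + 1L] - num[lo + 1L]) / dsum),
      pi_obj = (po[hi + 1L] - po[lo + 1L]) / (w$end - w$start),
      pi_ref = (pr[hi + 1L] - pr[lo + 1L]) / (w$end - w$start),
      stringsAsFactors = FALSE
    )
  })
  transform_stats(do.call(rbind, c(recs, make.row.names = FALSE)))
}

#' Fill z(FST) and log2 diversity-ratio transforms
#'
#' `z_fst` standardises FST over all windows with a defined estimate
#' (genome-wide mean and sample standard deviation, ddof 1).
#' `log2_pi_ratio = log2(pi_ref / pi_obj)`, so positive values flag
#' diversity loss in the object group; the ratio is undefined (`NA`) when
#' either diversity is 0, and such windows are excluded from outlier calling.
#'
#' @param records window records from [fstpi_scan()].
#' @return `records` with `z_fst` and `log2_pi_ratio` columns filled.
#' @export
transform_stats <- function(records) {
  ok <- is.finite(records$fst)
  if (sum(ok) < 2L) stop("need >= 2 windows with defined FST")
  s <- stats::sd(records$fst[ok])
  if (s == 0) stop("all FST values identical; z-transform undefined")
  records$z_fst <- (records$fst - mean(records$fst[ok])) / s
  records$z_fst[!ok] <- NA_real_
  records$log2_pi_ratio <- ifelse(
    records$pi_obj > 0 & records$pi_ref > 0,
    log2(records$pi_ref / records$pi_obj), NA_real_
  )
  records
}

#' Call joint FST / diversity-ratio outlier windows
#'
#' In `quantile` mode (default), a window is flagged when its `z_fst` is in
#' the top `q` fraction AND its `log2_pi_ratio` is in the top `q` fraction of
#' defined values (ties at the cutoff included). In `absolute` mode the
#' printed thresholds are used directly: `z_fst > z_cut` and `log2_pi_ratio`
#' beyond `ratio_cut` in the direction `ratio_direction`. Flagged windows
#' that overlap or touch are merged into maximal regions.
#'
#' @param records transformed window records.
#' @param mode `"quantile"` or `"absolute"`.
#' @param q top fraction per metric in quantile mode.
#' @param z_cut,ratio_cut absolute-mode thresholds (the published values are
#'   1.58 and 0.24).
#' @param ratio_direction `">"` (diversity loss in the object group, the
#'   default under this package's ratio orientation) or `"<"`.
#' @return list with `windows` (flagged window records) and `regions`
#'   (merged data.frame `chrom`, `start`, `end`, 0-based half-open).
#' @export
call_joint_outliers <- function(records, mode = c("quantile", "absolute"),
                                q = 0.05, z_cut = 1.58, ratio_cut = 0.24,
                                ratio_direction = c(">", "<")) {
  mode <- match.arg(mode)
  ratio_direction <- match.arg(ratio_direction)
  ok <- is.finite(records$z_fst) & is.finite(records$log2_pi_ratio)
  flag <- rep(FALSE, nrow(records))
  if (mode == "quantile") {
    z <- records$z_fst[ok]
    rat <- if (ratio_direction == ">") records$log2_pi_ratio[ok]
           else -records$log2_pi_ratio[ok]
    k <- max(1L, ceiling(q * sum(ok)))
    z_cutoff <- sort(z, decreasing = TRUE)[min(k, length(z))]
    r_cutoff <- sort(rat, decreasing = TRUE)[min(k, length(rat))]
    flag[ok] <- z >= z_cutoff & rat >= r_cutoff
  } else {
    rat_ok <- if (ratio_direction == ">") records$log2_pi_ratio > ratio_cut
              else records$log2_pi_ratio < ratio_cut
    flag[ok] <- records$z_fst[ok] > z_cut & rat_ok[ok]
  }
  flagged <- records[flag, , drop = FALSE]
  list(windows = flagged,
       regions = merge_intervals(flagged[, c("chrom", "start", "end")]))
}

#' Merge overlapping or touching intervals
#'
#' @param df data.frame `chrom`, `start`, `end` (0-based half-open).
#' @return merged intervals sorted by chromosome and start.
#' @export
merge_intervals <- function(df) {
  if (!nrow(df)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- df[1L, ]
  for (i in seq_len(nrow(df))[-1L]) {
    row <- df[i, ]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}
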