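#' Variant-quality filter (QD / MQ / FS)
#'
#' Removes sites with Quality-by-Depth below `qd_min`, mapping quality below
#' `mq_min`, or Fisher-strand above `fs_max`. Thresholds are strict in the
#' removal direction, so boundary values (QD = 2.0, MQ = 20, FS = 60.0) are
#' retained. A site lacking one of the INFO statistics passes that sub-filter;
#' the number of such sites is recorded in the returned tallies.
#'
#' @param gm a [genotype_matrix()] or list of them.
#' @param qd_min,mq_min,fs_max filter thresholds.
#' @return filtered object of the same shape, with attribute `filter_log`
#'   (named counts: removed_qd, removed_mq, removed_fs, missing_info).
#' @export
filter_variant_quality <- function(gm, qd_min = 2.0, mq_min = 20,
                                   fs_max = 60.0) {
  if (!inherits(gm, "genotype_matrix")) {
    out <- lapply(gm, filter_variant_quality, qd_min = qd_min,
                  mq_min = mq_min, fs_max = fs_max)
    logs <- lapply(out, attr, "filter_log")
    attr(out, "filter_log") <- Reduce(`+`, logs)
    return(out)
  }
  n <- length(gm$pos)
  get <- function(col) {
    if (is.null(gm$info) || is.null(gm$info[[col]])) rep(NA_real_, n)
    else gm$info[[col]]
  }
  qd <- get("qd"); mq <- get("mq"); fs <- get("fs")
  bad_qd <- !is.na(qd) & qd < qd_min
  bad_mq <- !is.na(mq) & mq < mq_min
  bad_fs <- !is.na(fs) & fs > fs_max
  keep <- !(bad_qd | bad_mq | bad_fs)
  out <- gm_subset_sites(gm, keep)
  attr(out, "filter_log") <- c(
    removed_qd = sum(bad_qd), removed_mq = sum(bad_mq),
    removed_fs = sum(bad_fs),
    missing_info = sum(is.na(qd) | is.na(mq) | is.na(fs))
  )
  out
}

#' SNP-level QC filter (call rate / MAF / mean depth)
#'
#' A site is removed iff its call rate is `<= call_rate_min`, its minor
#' allele frequency is `<= maf_min` (computed from non-missing alleles only),
#' or its per-site mean depth lies outside `[depth_min, depth_max]`. Note the
#' non-strict boundaries on call rate and MAF: a call rate of exactly 90% or
#' a MAF of exactly 0.05 is removed. If depth is absent from the input the
#' depth sub-filter is skipped with a warning.
#'
#' @param gm a [genotype_matrix()] or list of them.
#' @param call_rate_min,maf_min,depth_min,depth_max thresholds.
#' @return filtered object with attribute `filter_log` (named counts:
#'   removed_callrate, removed_maf, removed_depth).
#' @export
filter_snp_qc <- function(gm, call_rate_min = 0.9, maf_min = 0.05,
                          depth_min = 3, depth_max = 30) {
  if (!inherits(gm, "genotype_matrix")) {
    out <- lapply(gm, filter_snp_qc, call_rate_min = call_rate_min,
                  maf_min = maf_min, depth_min = depth_min,
                  depth_max = depth_max)
    logs <- lapply(out, attr, "filter_log")
    attr(out, "filter_log") <- Reduce(`+`, logs)
    return(out)
  }
  g <- gm$geno
  n_samp <- nrow(g)
  n_called <- n_samp - colSums(is.na(g))
  call_rate <- if (n_samp) n_called / n_samp else rep(0, ncol(g))
  alt <- colSums(g, na.rm = TRUE)
  tot <- 2L * n_called
  p <- ifelse(tot > 0L, alt / tot, 0)
  maf <- pmin(p, 1 - p)

  bad_cr <- call_rate <= call_rate_min
  bad_maf <- maf <= maf_min
  dp <- if (!is.null(gm$info) && !is.null(gm$info$dp)) gm$info$dp else NULL
  if (is.null(dp) || all(is.na(dp))) {
    warning("mean depth absent; depth sub-filter skipped for chromosome ",
            gm$chrom, call. = FALSE)
    bad_dp <- rep(FALSE, ncol(g))
  } else {
    bad_dp <- !is.na(dp) & (dp < depth_min | dp > depth_max)
  }
  keep <- !(bad_cr | bad_maf | bad_dp)
  out <- gm_subset_sites(gm, keep)
  attr(out, "filter_log") <- c(
    removed_callrate = sum(bad_cr), removed_maf = sum(bad_maf),
    removed_depth = sum(bad_dp)
  )
  out
}
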