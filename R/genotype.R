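#' Genotype matrix for one chromosome
#'
#' The central container of the package: biallelic diploid genotypes for one
#' chromosome, coded as counts of the alternate allele (0, 1, 2) with `NA`
#' for missing calls. Rows are samples, columns are sites. Physical
#' positions are 1-based (VCF convention) and strictly increasing.
#'
#' @param chrom chromosome identifier (length-1 character).
#' @param pos integer vector of 1-based positions, strictly increasing.
#' @param samples character vector of unique sample identifiers.
#' @param geno integer matrix, `length(samples)` rows by `length(pos)`
#'   columns, values in `{0, 1, 2, NA}`.
#' @param info optional `data.frame` of per-site INFO statistics with any of
#'   the columns `qd`, `mq`, `fs`, `dp` (per-site mean depth); one row per
#'   site. Missing statistics are `NA`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, samples, geno, info = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  pos <- as.integer(pos)
  if (is.unsorted(pos, strictly = TRUE)) {
    bad <- which(diff(pos) <= 0L)[1L] + 1L
    stop("positions not strictly increasing at ", chrom, ":", pos[bad])
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != length(pos)) {
    stop("geno must be length(samples) x length(pos)")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L)) {
    stop("genotype codes must be in {0, 1, 2, NA}")
  }
  if (!is.null(info)) {
    info <- as.data.frame(info)
    if (nrow(info) != length(pos)) stop("info must have one row per site")
  }
  dimnames(geno) <- list(samples, NULL)
  structure(
    list(chrom = chrom, pos = pos, samples = samples, geno = geno, info = info),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: chrom %s, %d samples x %d sites [%s..%s]\n",
    x$chrom, length(x$samples), length(x$pos),
    if (length(x$pos)) format(x$pos[1]) else "-",
    if (length(x$pos)) format(x$pos[length(x$pos)]) else "-"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by site index
#'
#' @param gm a `genotype_matrix`.
#' @param idx logical or integer index over sites (columns).
#' @return a `genotype_matrix` with the selected sites, INFO rows included.
#' @export
gm_subset_sites <- function(gm, idx) {
  genotype_matrix(
    gm$chrom, gm$pos[idx], gm$samples,
    gm$geno[, idx, drop = FALSE],
    if (is.null(gm$info)) NULL else gm$info[idx, , drop = FALSE]
  )
}

#' Subset a genotype matrix by sample id
#'
#' @param gm a `genotype_matrix`.
#' @param samples character vector of sample ids to keep (order preserved).
#' @return a `genotype_matrix` restricted to those samples.
#' @export
gm_subset_samples <- function(gm, samples) {
  miss <- setdiff(samples, gm$samples)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  genotype_matrix(gm$chrom, gm$pos, samples,
                  gm$geno[samples, , drop = FALSE], gm$info)
}

# Apply a per-chromosome function over a genotype_matrix or a list of them.
gm_apply <- function(x, f, ...) {
  if (inherits(x, "genotype_matrix")) return(f(x, ...))
  stopifnot(is.list(x))
  lapply(x, f, ...)
}

# Normalise gm-or-list-of-gms to a list.
gm_as_list <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    stats::setNames(list(x), x$chrom)
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "genotype_matrix")))
    stats::setNames(x, vapply(x, function(g) g$chrom, ""))
  }
}

#' Population map: sample-to-group assignment
#'
#' @param sample character vector of sample ids.
#' @param group character vector of group labels, parallel to `sample`.
#' @return a `population_map` (a data.frame with columns `sample`, `group`).
#' @export
population_map <- function(sample, group) {
  stopifnot(length(sample) == length(group))
  sample <- as.character(sample); group <- as.character(group)
  if (anyDuplicated(sample)) {
    stop("sample assigned to more than one group: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  structure(data.frame(sample = sample, group = group,
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

#' Read a population map TSV ("sample<TAB>group", no header)
#'
#' @param path path to a two-column tab-separated file.
#' @return a [population_map()].
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "group"))
  population_map(df$sample, df$group)
}

# Samples of one group, checked non-empty.
pm_samples <- function(pm, group) {
  s <- pm$sample[pm$group == group]
  if (!length(s)) stop("group '", group, "' is empty in the population map")
  s
}

# Validate a two-group contrast and return list(obj=, ref=) sample vectors,
# restricted to samples present in gm.
pm_contrast <- function(pm, gm, obj, ref) {
  if (identical(obj, ref)) stop("object and reference group must differ")
  keep <- intersect(gm$samples, pm$sample)
  pm <- pm[pm$sample %in% keep, , drop = FALSE]
  list(obj = pm_samples(pm, obj), ref = pm_samples(pm, ref))
}
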