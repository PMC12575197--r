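#' Map outlier regions to genes
#'
#' A gene is reported iff its interval, extended by `flank` bp on both sides,
#' intersects at least one region by >= 1 bp (half-open convention: touching
#' intervals do not overlap). Each reported gene carries its supporting
#' regions.
#'
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param genes a `gene_models` data.frame (see [read_gene_annotation()]).
#' @param flank bp added to each side of every gene before intersection.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `regions`
#'   (semicolon-joined supporting intervals); zero rows when nothing
#'   overlaps.
#' @export
regions_to_genes <- function(regions, genes, flank = 0L) {
  if (nrow(regions) && nrow(genes) &&
      !any(unique(regions$chrom) %in% unique(genes$chrom))) {
    warning("no shared chromosome names between regions (",
            paste(unique(regions$chrom), collapse = ","), ") and genes (",
            paste(unique(genes$chrom), collapse = ","), ")", call. = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    gs <- genes$start[i] - flank
    ge <- genes$end[i] + flank
    ov <- regions$chrom == genes$chrom[i] & regions$start < ge &
      regions$end > gs
    if (any(ov)) {
      sup <- paste(sprintf("%s:%d-%d", regions$chrom[ov], regions$start[ov],
                           regions$end[ov]), collapse = ";")
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], chrom = genes$chrom[i],
        start = genes$start[i], end = genes$end[i], regions = sup,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      regions = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(hits, make.row.names = FALSE))
}

#' Three-method gene consensus
#'
#' Computes all seven Venn cells for the gene sets found by the
#' FST/diversity scan, the composite-likelihood scan and the ROH-island
#' scan. The candidate list is the triple intersection, sorted.
#'
#' @param fstpi,xpclr,roh character vectors of gene ids (or data.frames with
#'   a `gene_id` column).
#' @return a `consensus_report` list: `sets` (the three inputs as sorted
#'   sets), `venn` (named list of the 7 exclusive cells), `counts` (named
#'   integer vector over cells), `union`, and `consensus` (triple
#'   intersection, sorted).
#' @export
consensus_genes <- function(fstpi, xpclr, roh) {
  as_set <- function(x) {
    if (is.data.frame(x)) x <- x$gene_id
    sort(unique(as.character(x)))
  }
  A <- as_set(fstpi); B <- as_set(xpclr); C <- as_set(roh)
  venn <- list(
    fstpi_only = setdiff(A, union(B, C)),
    xpclr_only = setdiff(B, union(A, C)),
    roh_only = setdiff(C, union(A, B)),
    fstpi_xpclr = setdiff(intersect(A, B), C),
    fstpi_roh = setdiff(intersect(A, C), B),
    xpclr_roh = setdiff(intersect(B, C), A),
    all_three = intersect(intersect(A, B), C)
  )
  structure(list(
    sets = list(fstpi = A, xpclr = B, roh = C),
    venn = venn,
    counts = vapply(venn, length, 0L),
    union = sort(unique(c(A, B, C))),
    consensus = sort(venn$all_three)
  ), class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus_report\n")
  cat(sprintf("  genes: fstpi %d | xpclr %d | roh %d | union %d\n",
              length(x$sets$fstpi), length(x$sets$xpclr),
              length(x$sets$roh), length(x$union)))
  cat(sprintf("  consensus (all three methods): %d\n", length(x$consensus)))
  if (length(x$consensus)) {
    cat("  ", paste(x$consensus, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
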