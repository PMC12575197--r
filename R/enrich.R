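#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name` (no
#'   header).
#' @return data.frame with those columns.
#' @export
read_term_annotation <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    stringsAsFactors = FALSE,
                    col.names = c("gene_id", "term_id", "term_name"))
}

#' Hypergeometric term over-representation test
#'
#' For each annotated term, tests whether the candidate gene list contains
#' more term members than expected from random draws out of the background
#' (all genes present in the annotation, or a supplied universe). The
#' p-value is the exact hypergeometric upper tail `P[X >= k]` for `k`
#' candidate genes among `K` term genes, `n` candidates in the background of
#' `N` genes, with Benjamini-Hochberg adjustment across terms. This is a
#' transparent, reproducible stand-in for service-based GO tools (whose
#' modified scores and backgrounds are not reproducible offline); the raw
#' `p < alpha` rule mirrors the usual reporting convention.
#'
#' @param candidates character vector of candidate gene ids. Genes absent
#'   from the background are dropped with a message.
#' @param annotation data.frame `gene_id`, `term_id`, `term_name` (see
#'   [read_term_annotation()]).
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05, raw p).
#' @param background optional character vector overriding the default
#'   background (all annotated genes).
#' @return data.frame sorted by p: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `gene_ratio`, `p_value`, `log10_p`, `p_adjusted`, `significant`,
#'   `genes` (pipe-joined members). Terms with fewer than 2 background genes
#'   are skipped.
#' @export
enrich <- function(candidates, annotation, alpha = 0.05, background = NULL) {
  candidates <- unique(as.character(candidates))
  ann <- unique(annotation[, c("gene_id", "term_id", "term_name")])
  if (is.null(background)) {
    background <- unique(ann$gene_id)
  } else {
    background <- unique(as.character(background))
    ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  }
  dropped <- setdiff(candidates, background)
  if (length(dropped)) {
    message(length(dropped), " candidate gene(s) absent from background; dropped")
  }
  cand <- intersect(candidates, background)
  if (!length(cand)) stop("no candidate gene overlaps the background")
  N <- length(background)
  n <- length(cand)

  res <- lapply(split(ann, ann$term_id), function(tt) {
    members <- unique(tt$gene_id)
    K <- length(members)
    if (K < 2L) return(NULL)
    in_term <- intersect(cand, members)
    k <- length(in_term)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tt$term_id[1L], term_name = tt$term_name[1L],
               k = k, K = K, n = n, N = N, gene_ratio = k / n,
               p_value = p,
               genes = paste(sort(in_term), collapse = "|"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(res[!vapply(res, is.null, TRUE)],
                          make.row.names = FALSE))
  if (is.null(res)) stop("no testable terms (all terms have K < 2)")
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$log10_p <- -log10(res$p_value)
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "k", "K", "n", "N", "gene_ratio",
          "p_value", "log10_p", "p_adjusted", "significant", "genes")]
}
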