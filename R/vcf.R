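#' Read a multi-sample VCF into genotype matrices
#'
#' Reads VCF 4.x (plain text or gzip) and returns one [genotype_matrix()] per
#' chromosome. Only biallelic SNP records are kept; multi-allelic records and
#' indels are skipped and counted. Diploid GT values are decoded to alternate
#' allele counts (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, anything with a
#' missing allele -> `NA`); phased separators (`|`) are accepted. Per-site
#' INFO statistics QD, MQ, FS and mean depth (INFO DP divided by the sample
#' count, else the mean FORMAT DP) are captured when present.
#'
#' @param path VCF file, optionally gzip-compressed.
#' @param region optional chromosome name; other chromosomes are ignored.
#' @return a named list of `genotype_matrix`, one per chromosome in file
#'   order, with attribute `skipped` = c(multiallelic =, indel =).
#' @export
read_vcf <- function(path, region = NULL) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body <- lines[!startsWith(lines, "##")]
  hdr_i <- which(startsWith(body, "#CHROM"))
  if (length(hdr_i) != 1L) stop("not a VCF: missing #CHROM header line")
  hdr <- strsplit(body[hdr_i], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 10L) stop("VCF has no sample columns (GT field required)")
  samples <- hdr[-(1:9)]
  recs <- body[-seq_len(hdr_i)]
  recs <- recs[nzchar(recs)]
  skipped <- c(multiallelic = 0L, indel = 0L)
  if (!length(recs)) {
    out <- list()
    attr(out, "skipped") <- skipped
    return(out)
  }

  fields <- strsplit(recs, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(hdr))) {
    stop("malformed VCF record at line ", which(nf != length(hdr))[1L])
  }
  m <- matrix(unlist(fields), ncol = length(hdr), byrow = TRUE)
  if (!is.null(region)) m <- m[m[, 1L] == region, , drop = FALSE]
  if (!nrow(m)) {
    out <- list()
    attr(out, "skipped") <- skipped
    return(out)
  }

  ref <- m[, 4L]; alt <- m[, 5L]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & ref != "." & alt != "." & !multi
  skipped["multiallelic"] <- sum(multi)
  skipped["indel"] <- sum(!snp & !multi)
  m <- m[snp, , drop = FALSE]
  if (!nrow(m)) {
    out <- list()
    attr(out, "skipped") <- skipped
    return(out)
  }

  fmt <- strsplit(m[, 9L], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), 0L)
  if (anyNA(gt_idx)) {
    stop("FORMAT field without GT at record ", which(is.na(gt_idx))[1L])
  }
  dp_idx <- vapply(fmt, function(f) match("DP", f, nomatch = 0L), 0L)

  n_samp <- length(samples)
  sm <- m[, -(1:9), drop = FALSE]              # sites x samples
  gt <- sm
  gt[] <- sub(":.*$", "", sm)                  # GT when it is field 1
  if (any(gt_idx != 1L)) {
    for (i in which(gt_idx != 1L)) {
      parts <- strsplit(sm[i, ], ":", fixed = TRUE)
      gt[i, ] <- vapply(parts, `[`, "", gt_idx[i])
    }
  }
  code <- decode_gt(gt)                        # sites x samples matrix

  # per-site mean depth: INFO DP / n_samp, else mean FORMAT DP
  info_str <- m[, 8L]
  dp <- extract_info_num(info_str, "DP") / n_samp
  if (anyNA(dp) && any(dp_idx > 0L)) {
    for (i in which(is.na(dp) & dp_idx > 0L)) {
      parts <- strsplit(sm[i, ], ":", fixed = TRUE)
      v <- suppressWarnings(as.numeric(vapply(parts, function(p)
        if (length(p) >= dp_idx[i]) p[dp_idx[i]] else NA_character_, "")))
      dp[i] <- mean(v, na.rm = TRUE)
    }
  }
  info <- data.frame(
    qd = extract_info_num(info_str, "QD"),
    mq = extract_info_num(info_str, "MQ"),
    fs = extract_info_num(info_str, "FS"),
    dp = dp
  )

  chroms <- m[, 1L]
  pos <- as.integer(m[, 2L])
  out <- list()
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    p <- pos[sel]
    if (is.unsorted(p, strictly = TRUE)) {
      bad <- which(diff(p) <= 0L)[1L] + 1L
      stop("unsorted or duplicated position at ", ch, ":", p[bad])
    }
    out[[ch]] <- genotype_matrix(
      ch, p, samples,
      t(code[sel, , drop = FALSE]),
      info[sel, , drop = FALSE]
    )
  }
  attr(out, "skipped") <- skipped
  out
}

# "0/1", "1|0", "./.", "0/." -> alt allele count or NA (sites x samples in,
# same shape out).
decode_gt <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  code <- suppressWarnings(as.integer(a1) + as.integer(a2))
  code[a1 == "." | a2 == "."] <- NA_integer_
  dim(code) <- dim(gt)
  code
}

extract_info_num <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  mm <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_real_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- suppressWarnings(as.numeric(sub(pat, "\\1",
    regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)))
  out
}

#' Write genotype matrices as a VCF
#'
#' Emits a minimal VCF 4.2 with synthetic REF/ALT alleles (`A`/`G`), unphased
#' GT, and any captured INFO statistics. A `.gz` extension triggers gzip
#' compression. `write_vcf(read_vcf(x))` preserves chromosome, position and
#' genotype codes.
#'
#' @param gms a `genotype_matrix` or list of them (one per chromosome).
#' @param path output path; gzip if it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gms, path) {
  gms <- gm_as_list(gms)
  samples <- if (length(gms)) gms[[1L]]$samples else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  # write through a text layer with fixed LF endings for determinism
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  for (gm in gms) {
    if (!identical(gm$samples, samples)) {
      stop("all chromosomes must share the same sample set")
    }
    n_samp <- length(samples)
    info <- rep(".", length(gm$pos))
    if (!is.null(gm$info)) {
      parts <- mapply(function(qd, mq, fs, dp) {
        p <- character()
        if (!is.na(dp)) p <- c(p, paste0("DP=", as.integer(round(dp * n_samp))))
        if (!is.na(qd)) p <- c(p, paste0("QD=", format(qd)))
        if (!is.na(mq)) p <- c(p, paste0("MQ=", format(mq)))
        if (!is.na(fs)) p <- c(p, paste0("FS=", format(fs)))
        if (length(p)) paste(p, collapse = ";") else "."
      },
      qd = if (is.null(gm$info$qd)) rep(NA_real_, length(gm$pos)) else gm$info$qd,
      mq = if (is.null(gm$info$mq)) rep(NA_real_, length(gm$pos)) else gm$info$mq,
      fs = if (is.null(gm$info$fs)) rep(NA_real_, length(gm$pos)) else gm$info$fs,
      dp = if (is.null(gm$info$dp)) rep(NA_real_, length(gm$pos)) else gm$info$dp)
      info <- unlist(parts)
    }
    g <- gm$geno + 1L                          # samples x sites, 1..3 or NA
    gs <- matrix("./.", nrow(g), ncol(g))
    gs[!is.na(g)] <- gt_str[g[!is.na(g)]]
    site_gt <- apply(gs, 2L, paste, collapse = "\t")
    lines <- c(lines, paste(gm$chrom, gm$pos, ".", "A", "G", ".", "PASS",
                            info, "GT", site_gt, sep = "\t"))
  }
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (>= 4 columns: chrom, start, end, name) is taken as 0-based
#' half-open. GFF3 input keeps only `gene` features (e.g. mRNA rows are
#' ignored), requires an `ID` or `gene_id` attribute, and is converted from
#' 1-based inclusive to 0-based half-open coordinates. Duplicate gene ids on
#' the same interval are deduplicated; the same id on different intervals is
#' an error.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (class `gene_models`), 0-based half-open.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer annotation format from '", path,
                          "'; pass format='bed' or 'gff3'"))
  }
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 4L) stop("BED gene annotation needs >= 4 columns")
    out <- data.frame(gene_id = as.character(df[[4L]]),
                      chrom = as.character(df[[1L]]),
                      start = as.integer(df[[2L]]),
                      end = as.integer(df[[3L]]),
                      strand = if (ncol(df) >= 6L) as.character(df[[6L]])
                               else "unknown",
                      stringsAsFactors = FALSE)
  } else {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
      gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene", ,
               drop = FALSE]
      ids <- as.character(gr$ID)
      if (!is.null(gr$gene_id)) {
        gid <- as.character(gr$gene_id)
        ids[is.na(ids)] <- gid[is.na(ids)]
      }
      if (anyNA(ids)) stop("GFF3 gene feature without ID or gene_id")
      out <- data.frame(gene_id = ids,
                        chrom = as.character(gr$seqnames),
                        start = as.integer(gr$start) - 1L,
                        end = as.integer(gr$end),
                        strand = as.character(gr$strand),
                        stringsAsFactors = FALSE)
    } else {
      out <- read_gff3_genes(path)
    }
    out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  }
  out <- unique(out)
  if (anyDuplicated(out$gene_id)) {
    stop("gene id on conflicting intervals: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  bad <- out$start >= out$end
  if (any(bad)) stop("gene with start >= end: ", out$gene_id[bad][1L])
  class(out) <- c("gene_models", "data.frame")
  out
}

# Fallback GFF3 gene reader used when rtracklayer is unavailable.
read_gff3_genes <- function(path) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 9L]
  f <- f[vapply(f, `[`, "", 3L) == "gene"]
  if (!length(f)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), a,
                               perl = TRUE))
    if (length(m)) sub(paste0("^.*", key, "="), "", m) else NA_character_
  }
  ids <- vapply(f, function(x) {
    id <- attr_get(x[9L], "ID")
    if (is.na(id)) id <- attr_get(x[9L], "gene_id")
    id
  }, "")
  if (anyNA(ids)) stop("GFF3 gene feature without ID or gene_id")
  data.frame(gene_id = ids,
             chrom = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
             end = as.integer(vapply(f, `[`, "", 5L)),
             strand = vapply(f, `[`, "", 7L),
             stringsAsFactors = FALSE)
}

#' Write genomic regions as BED (0-based half-open)
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(regions)))
  lines <- if (nrow(regions) == 0L) character() else {
    base <- paste(regions$chrom, format(regions$start, scientific = FALSE,
                                        trim = TRUE),
                  format(regions$end, scientific = FALSE, trim = TRUE),
                  sep = "\t")
    if (!is.null(regions$name)) paste(base, regions$name, sep = "\t") else base
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a 3+ column BED file of regions
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open) and `name`
#'   if a fourth column is present.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  out
}

#' Write a table as TSV with 1-based inclusive coordinates
#'
#' Any `start`/`end` columns are converted from the internal 0-based
#' half-open convention to 1-based inclusive on output; [read_table_tsv()]
#' reverses the conversion, so a round trip is the identity.
#'
#' @param df a data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  df <- as.data.frame(df)
  if ("start" %in% names(df)) df$start <- df$start + 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#'
#' @param path TSV file with a header.
#' @return data.frame with `start` converted back to 0-based half-open.
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  if ("start" %in% names(df)) df$start <- df$start - 1L
  df
}
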