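#' Minimal TOML-subset reader
#'
#' Parses the subset of TOML used by run configs: `[section]` headers,
#' `key = value` scalars (strings, numbers, booleans) and flat arrays of
#' scalars, with `#` comments. This in-package reader exists because no TOML
#' parser is available in the supported dependency set; it intentionally
#' rejects nested tables and multi-line values.
#'
#' @param path TOML file.
#' @return nested named list (one list per section).
#' @export
read_toml_lite <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (tok %in% c("true", "false")) return(tok == "true")
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    stop("cannot parse TOML value: ", tok)
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (grepl("\\.", section)) stop("nested TOML tables unsupported: ", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1L]]
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      parsed <- if (grepl("^\\[.*\\]$", val)) {
        toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1L]]
        toks <- toks[nzchar(trimws(toks))]
        if (!length(toks)) list() else {
          v <- lapply(toks, parse_scalar)
          unlist(v)
        }
      } else parse_scalar(val)
      if (is.null(section)) out[[key]] <- parsed
      else out[[section]][[key]] <- parsed
    } else {
      stop("cannot parse TOML line: ", ln)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recognised config keys with defaults (NULL = no default, optional).
config_schema <- function() {
  list(
    run = list(out_dir = "sweepscan_run", seed = 1, obj = "fat",
               ref = "thin", preset = "test"),
    input = list(vcf = NULL, popmap = NULL, genes = NULL, terms = NULL),
    simulate = list(enabled = FALSE, n_diploids_per_pop = 50,
                    n_e_per_pop = 1000, sequence_length = 2e6, n_sites = 2000,
                    split_generations = 300, recombination_rate = 2e-7,
                    sweep_pos = numeric(), sweep_s = numeric(),
                    n_chromosomes = 1, gene_size = 20000, gene_gap = 20000),
    filter = list(enabled = TRUE, qd_min = 2.0, mq_min = 20, fs_max = 60.0,
                  call_rate_min = 0.9, maf_min = 0.05, depth_min = 3,
                  depth_max = 30),
    fstpi = list(window = 50000, step = 25000, mode = "quantile", q = 0.05,
                 z_cut = 1.58, ratio_cut = 0.24, ratio_direction = ">"),
    xpclr = list(grid_spacing = 2000, window_genetic_span = 0.005,
                 max_snps_per_window = 200, corr_threshold = 0.95,
                 genetic_map_rate = 1e-8, top_fraction = 0.01,
                 n_quad = 512),
    roh = list(preset = "plink", island_threshold = 20),
    consensus = list(flank = 0),
    enrich = list(enabled = TRUE, alpha = 0.05, n_terms = 10)
  )
}

#' Validate and normalise a run configuration
#'
#' Accepts a TOML file path or a nested list, checks every key against the
#' schema (unknown keys are rejected), type/range-checks the values, fills
#' defaults, and applies the named preset. All problems are reported at
#' once. The `"test"` preset scales the scan to 2 Mb desk-scale simulations
#' (5 kb scan grid, 100 SNPs/window, test ROH parameters); the `"published"`
#' preset keeps the published full-scale settings.
#'
#' @param config path to a TOML file, or a nested list.
#' @return normalised `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_toml_lite(config)
  stopifnot(is.list(config))
  schema <- config_schema()
  errors <- character()
  unknown_sec <- setdiff(names(config), names(schema))
  if (length(unknown_sec)) {
    errors <- c(errors, paste0("unknown section(s): ",
                               paste(unknown_sec, collapse = ", ")))
  }
  out <- schema
  for (sec in intersect(names(config), names(schema))) {
    unknown <- setdiff(names(config[[sec]]), names(schema[[sec]]))
    if (length(unknown)) {
      errors <- c(errors, paste0("[", sec, "] unknown key(s): ",
                                 paste(unknown, collapse = ", ")))
    }
    for (key in intersect(names(config[[sec]]), names(schema[[sec]]))) {
      out[[sec]][[key]] <- config[[sec]][[key]]
    }
  }

  # preset application before range checks
  preset <- out$run$preset
  if (!preset %in% c("test", "published")) {
    errors <- c(errors, "[run] preset must be 'test' or 'published'")
  } else if (preset == "test") {
    if (is.null(config$xpclr$grid_spacing)) out$xpclr$grid_spacing <- 5000
    if (is.null(config$xpclr$max_snps_per_window)) {
      out$xpclr$max_snps_per_window <- 100
    }
    if (is.null(config$xpclr$genetic_map_rate)) {
      # match the desk-scale simulator map so genetic distances are true
      out$xpclr$genetic_map_rate <- out$simulate$recombination_rate
    }
    if (is.null(config$roh$preset)) out$roh$preset <- "test"
  }

  check <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  check(!identical(out$run$obj, out$run$ref),
        "[run] obj and ref labels must differ")
  check(out$fstpi$window > 0 && out$fstpi$step > 0 &&
          out$fstpi$step <= out$fstpi$window,
        "[fstpi] need 0 < step <= window")
  check(out$fstpi$mode %in% c("quantile", "absolute"),
        "[fstpi] mode must be 'quantile' or 'absolute'")
  check(out$fstpi$q > 0 && out$fstpi$q < 1, "[fstpi] q must be in (0,1)")
  check(out$xpclr$grid_spacing > 0, "[xpclr] grid_spacing must be positive")
  check(out$xpclr$top_fraction > 0 && out$xpclr$top_fraction < 1,
        "[xpclr] top_fraction must be in (0,1)")
  check(out$roh$preset %in% c("plink", "test"),
        "[roh] preset must be 'plink' or 'test'")
  check(out$roh$island_threshold >= 0 && out$roh$island_threshold < 100,
        "[roh] island_threshold must be in [0,100)")
  check(out$enrich$alpha > 0 && out$enrich$alpha < 1,
        "[enrich] alpha must be in (0,1)")
  if (!isTRUE(out$simulate$enabled)) {
    for (key in c("vcf", "popmap", "genes")) {
      if (is.null(out$input[[key]])) {
        errors <- c(errors, paste0("[input] missing required key: ", key))
      } else if (!file.exists(out$input[[key]])) {
        errors <- c(errors, paste0("[input] file not found: ",
                                   out$input[[key]]))
      }
    }
  } else {
    check(out$simulate$n_diploids_per_pop >= 2,
          "[simulate] n_diploids_per_pop must be >= 2")
    check(length(out$simulate$sweep_pos) == length(out$simulate$sweep_s),
          "[simulate] sweep_pos and sweep_s must have equal length")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  structure(out, class = "run_config")
}

#' Bundled demo configuration
#'
#' A small simulated run (25 diploids per population, 1 Mb, 1,000 sites, one
#' planted sweep) that exercises every pipeline stage in well under a minute.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @return a validated `run_config`.
#' @export
demo_config <- function(out_dir = file.path(tempdir(), "sweepscan_demo"),
                        seed = 1) {
  validate_config(list(
    run = list(out_dir = out_dir, seed = seed, preset = "test"),
    simulate = list(enabled = TRUE, n_diploids_per_pop = 25,
                    sequence_length = 1e6, n_sites = 1000,
                    split_generations = 200, sweep_pos = 5e5, sweep_s = 0.15),
    fstpi = list(window = 50000, step = 25000)
  ))
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> QC filters -> FST/diversity scan ->
#' composite-likelihood scan -> ROH islands -> three-method gene consensus
#' -> term enrichment, writing the stage outputs under the configured run
#' directory together with a JSON manifest. Completed stages (their output
#' files already present) are skipped when `resume = TRUE`, so deleting one
#' stage's outputs recomputes only that stage and the ones after it have
#' their inputs re-read from disk.
#'
#' @param config a `run_config` (see [validate_config()]), or anything it
#'   accepts.
#' @param resume skip stages whose outputs already exist (default TRUE).
#' @return invisibly, a list with the run directory, the consensus report
#'   and the enrichment table (NULL when not computed).
#' @export
run_all <- function(config, resume = TRUE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir <- config$run$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(dir, "run.log")
  log <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    message(line)
  }
  log("sweepscan run; seed = ", config$run$seed,
      "; preset = ", config$run$preset)
  pth <- function(...) file.path(dir, ...)
  counts <- list()
  done <- function(...) resume && all(file.exists(c(...)))

  ## stage: simulate or load -------------------------------------------------
  vcf_path <- pth("data", "input.vcf.gz")
  popmap_path <- pth("data", "popmap.tsv")
  genes_path <- pth("data", "genes.bed")
  dir.create(pth("data"), showWarnings = FALSE)
  if (isTRUE(config$simulate$enabled)) {
    if (!done(vcf_path, popmap_path, genes_path)) {
      sc <- config$simulate
      sweeps <- if (length(sc$sweep_pos)) {
        lapply(seq_along(sc$sweep_pos), function(i)
          list(pos = sc$sweep_pos[i], s = sc$sweep_s[i]))
      } else list()
      sim <- simulate_two_pop(sim_config(
        n_diploids_per_pop = sc$n_diploids_per_pop,
        n_e_per_pop = sc$n_e_per_pop,
        sequence_length = sc$sequence_length, n_sites = sc$n_sites,
        split_generations = sc$split_generations,
        recombination_rate = sc$recombination_rate, sweep_specs = sweeps,
        n_chromosomes = sc$n_chromosomes, seed = config$run$seed))
      write_vcf(sim$genotypes, vcf_path)
      utils::write.table(sim$popmap, popmap_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      genes <- tile_genes(sc$sequence_length, sc$gene_size, sc$gene_gap)
      write_regions_bed(data.frame(chrom = genes$chrom, start = genes$start,
                                   end = genes$end, name = genes$gene_id),
                        genes_path)
      write_table_tsv(sim$truth, pth("data", "truth.tsv"))
      log("simulate: ", length(sim$genotypes), " chromosome(s), ",
          sum(vapply(sim$genotypes, function(g) length(g$pos), 0L)), " sites")
    } else log("simulate: outputs present, skipped")
  } else {
    vcf_path <- config$input$vcf
    popmap_path <- config$input$popmap
    genes_path <- config$input$genes
  }

  gms <- read_vcf(vcf_path)
  pm <- read_popmap(popmap_path)
  genes <- read_gene_annotation(genes_path)
  obj <- config$run$obj; ref <- config$run$ref

  ## stage: filters ----------------------------------------------------------
  if (isTRUE(config$filter$enabled)) {
    fc <- config$filter
    gms <- filter_variant_quality(gms, fc$qd_min, fc$mq_min, fc$fs_max)
    n1 <- sum(vapply(gms, function(g) length(g$pos), 0L))
    gms <- suppressWarnings(filter_snp_qc(gms, fc$call_rate_min, fc$maf_min,
                                          fc$depth_min, fc$depth_max))
    counts$snps_after_qc <- sum(vapply(gms, function(g) length(g$pos), 0L))
    log("filter: ", n1, " after variant-quality, ", counts$snps_after_qc,
        " after SNP QC")
  }
  chrom_lengths <- NULL
  if (isTRUE(config$simulate$enabled)) {
    len <- config$simulate$sequence_length
    chrom_lengths <- if (config$simulate$n_chromosomes == 2)
      c("1" = len %/% 2, "2" = len - len %/% 2) else c("1" = len)
  }

  ## stage: fstpi ------------------------------------------------------------
  fst_windows_path <- pth("fstpi_windows.tsv")
  fst_regions_path <- pth("fstpi_regions.bed")
  if (!done(fst_windows_path, fst_regions_path)) {
    fp <- config$fstpi
    win <- fstpi_scan(gms, pm, obj, ref, fp$window, fp$step, chrom_lengths)
    out <- call_joint_outliers(win, fp$mode, q = fp$q, z_cut = fp$z_cut,
                               ratio_cut = fp$ratio_cut,
                               ratio_direction = fp$ratio_direction)
    write_table_tsv(win, fst_windows_path)
    write_regions_bed(out$regions, fst_regions_path)
    log("fstpi: ", nrow(win), " windows, ", nrow(out$regions),
        " outlier region(s)")
  } else log("fstpi: outputs present, skipped")
  fst_regions <- read_regions_bed(fst_regions_path)

  ## stage: xpclr ------------------------------------------------------------
  xp_points_path <- pth("xpclr_points.tsv")
  xp_regions_path <- pth("xpclr_regions.bed")
  if (!done(xp_points_path, xp_regions_path)) {
    xc <- config$xpclr
    xcfg <- xpclr_config(grid_spacing = xc$grid_spacing,
                         window_genetic_span = xc$window_genetic_span,
                         max_snps_per_window = xc$max_snps_per_window,
                         corr_threshold = xc$corr_threshold,
                         genetic_map_rate = xc$genetic_map_rate,
                         n_quad = xc$n_quad,
                         top_fraction = xc$top_fraction)
    xp <- xpclr_scan(gms, pm, obj, ref, xcfg, chrom_lengths = chrom_lengths)
    write_table_tsv(xp$points, xp_points_path)
    write_regions_bed(xp$regions, xp_regions_path)
    log("xpclr: ", nrow(xp$points), " grid points (omega = ",
        signif(xp$omega, 4), "), ", nrow(xp$regions), " top region(s)")
  } else log("xpclr: outputs present, skipped")
  xp_regions <- read_regions_bed(xp_regions_path)

  ## stage: roh --------------------------------------------------------------
  roh_seg_path <- pth("roh_segments.tsv")
  roh_track_path <- pth("roh_track.tsv")
  roh_islands_path <- pth("roh_islands.bed")
  if (!done(roh_seg_path, roh_track_path, roh_islands_path)) {
    rp <- roh_params(config$roh$preset)
    segs <- suppressWarnings(roh_scan(gms, pm, obj, rp))
    track <- occurrence_track(segs, gms, pm_samples(pm, obj))
    islands <- call_islands(track, config$roh$island_threshold)
    write_table_tsv(segs, roh_seg_path)
    utils::write.table(track, roh_track_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    # islands are stored 1-based inclusive; convert to BED half-open
    write_regions_bed(data.frame(chrom = islands$chrom,
                                 start = islands$start - 1L,
                                 end = islands$end,
                                 stringsAsFactors = FALSE),
                      roh_islands_path)
    log("roh: ", nrow(segs), " segments, ", nrow(islands), " island(s)")
  } else log("roh: outputs present, skipped")
  roh_regions <- read_regions_bed(roh_islands_path)

  ## stage: consensus --------------------------------------------------------
  consensus_path <- pth("consensus_genes.tsv")
  venn_path <- pth("venn_counts.tsv")
  g_fst <- regions_to_genes(fst_regions, genes, config$consensus$flank)
  g_xp <- regions_to_genes(xp_regions, genes, config$consensus$flank)
  g_roh <- regions_to_genes(roh_regions, genes, config$consensus$flank)
  report <- consensus_genes(g_fst, g_xp, g_roh)
  utils::write.table(
    data.frame(cell = names(report$counts), n = report$counts,
               genes = vapply(report$venn, paste, "", collapse = "|")),
    venn_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$consensus, consensus_path)
  log("consensus: ", length(report$consensus), " gene(s) shared by all ",
      "three methods")

  ## stage: enrich -----------------------------------------------------------
  enrich_path <- pth("enrichment.tsv")
  enr <- NULL
  if (isTRUE(config$enrich$enabled)) {
    if (!done(enrich_path)) {
      ann <- if (!is.null(config$input$terms)) {
        read_term_annotation(config$input$terms)
      } else {
        # synthetic round-robin annotation over the gene models
        data.frame(gene_id = genes$gene_id,
                   term_id = sprintf("TERM%02d",
                                     (seq_len(nrow(genes)) - 1L) %%
                                       config$enrich$n_terms + 1L),
                   term_name = sprintf("synthetic term %02d",
                                       (seq_len(nrow(genes)) - 1L) %%
                                         config$enrich$n_terms + 1L),
                   stringsAsFactors = FALSE)
      }
      if (length(report$consensus)) {
        enr <- enrich(report$consensus, ann, config$enrich$alpha)
        write_table_tsv(enr, enrich_path)
        log("enrich: ", nrow(enr), " terms tested, ",
            sum(enr$significant), " significant at alpha = ",
            config$enrich$alpha)
      } else {
        writeLines(paste("term_id", "term_name", "k", "K", "n", "N",
                         "gene_ratio", "p_value", "log10_p", "p_adjusted",
                         "significant", "genes", sep = "\t"), enrich_path)
        log("enrich: no consensus genes; header-only output")
      }
    } else {
      log("enrich: outputs present, skipped")
      enr <- read_table_tsv(enrich_path)
    }
  }

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = config$run$seed,
    preset = config$run$preset,
    config = unclass(config),
    counts = c(counts, list(consensus_genes = length(report$consensus)))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(dir = dir, consensus = report, enrichment = enr))
}
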