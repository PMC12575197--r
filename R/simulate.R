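#' Simulation configuration for the two-population generator
#'
#' Describes a clean-split demography: an ancestral diploid population is
#' seeded with segregating sites drawn from the neutral site-frequency
#' spectrum (derived-allele count i with probability proportional to 1/i),
#' duplicated into an object ("fat") and a reference ("thin") population, and
#' each population then drifts independently for `split_generations`
#' Wright-Fisher generations with Poisson-recombination gametes. Hard sweeps
#' are planted in the object population and conditioned on fixation by
#' restarting lost sweeps.
#'
#' No new mutations arise after seeding, so both populations segregate the
#' same site panel, as in a joint-called VCF.
#'
#' The desk-scale geometry deserves a note: the defaults make the 2 Mb toy
#' sequence stand in for a whole chromosome, not for 2 Mb of a real genome.
#' The map rate of 2e-7 Morgans/bp gives it a ~0.4 Morgan genetic length, so
#' an s = 0.1 sweep's hitchhiking footprint (roughly
#' `s / (ln(2 Ne s) * rate)` bp, ~90 kb here) is interior to the sequence
#' and can be localised; and the simulated population of `n_e_per_pop` =
#' 1,000 diploids per group keeps drift over 300 generations at ~0.15
#' coalescent units (genome-wide FST ~0.15-0.2, the regime of real
#' between-breed contrasts), strong enough to need the contrast statistics
#' but far from fixing the genome. With a real-scale 1 cM/Mb map and a
#' population equal to the 50-diploid sample, a planted sweep drags the
#' entire sequence to fixation and neutral drift alone removes ~95% of
#' diversity, leaving no signal geometry to detect.
#'
#' @param n_diploids_per_pop diploid sample size per group (the individuals
#'   written to the output).
#' @param n_e_per_pop simulated diploid population size per group
#'   (default 1000); must be at least `n_diploids_per_pop`.
#' @param sequence_length simulated sequence length in bp.
#' @param n_sites number of seeded segregating sites.
#' @param split_generations generations of independent drift after the split.
#' @param recombination_rate per-bp per-generation crossover rate
#'   (Morgans/bp); default 2e-7 (a ~0.4 Morgan map over the default 2 Mb).
#' @param sweep_specs list of sweeps, each `list(pos =, s =)` with `pos` in
#'   `[0, sequence_length)` and selection coefficient `0 < s <= 1`; fitness at
#'   the sweep site is 1, 1+s, 1+2s by derived-allele count. Sweeps are
#'   planted in the object population.
#' @param n_chromosomes 1 or 2; with 2 the sequence is split at the midpoint
#'   into chromosomes "1" and "2" so per-chromosome code paths are exercised.
#' @param generation_cap_factor restart budget: simulation aborts if total
#'   simulated generations exceed `generation_cap_factor * split_generations`.
#' @param seed integer RNG seed; every run is fully reproducible from it.
#' @return a `sim_config` list with validated fields.
#' @export
sim_config <- function(n_diploids_per_pop = 50,
                       n_e_per_pop = 1000,
                       sequence_length = 2e6,
                       n_sites = 2000,
                       split_generations = 300,
                       recombination_rate = 2e-7,
                       sweep_specs = list(),
                       n_chromosomes = 1,
                       generation_cap_factor = 100,
                       seed = 1L) {
  stopifnot(n_diploids_per_pop >= 2, sequence_length > 0, n_sites >= 1,
            split_generations >= 1, recombination_rate >= 0,
            n_chromosomes %in% c(1L, 2L),
            n_e_per_pop >= n_diploids_per_pop)
  for (sw in sweep_specs) {
    stopifnot(is.list(sw), !is.null(sw$pos), !is.null(sw$s))
    if (sw$s <= 0 || sw$s > 1) stop("selection coefficient must be in (0, 1]")
    if (sw$pos < 0 || sw$pos >= sequence_length) {
      stop("sweep position outside [0, sequence_length)")
    }
  }
  structure(list(
    n_diploids_per_pop = as.integer(n_diploids_per_pop),
    n_e_per_pop = as.integer(n_e_per_pop),
    sequence_length = as.integer(sequence_length),
    n_sites = as.integer(n_sites),
    split_generations = as.integer(split_generations),
    recombination_rate = recombination_rate,
    sweep_specs = sweep_specs,
    n_chromosomes = as.integer(n_chromosomes),
    generation_cap_factor = generation_cap_factor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-population cohort with optional planted sweeps
#'
#' Forward Wright-Fisher simulation over haplotypes (see [sim_config()] for
#' the model). Each generation, every offspring is formed by the random union
#' of two gametes; parents are drawn with replacement, proportionally to
#' fitness while a sweep segregates. A gamete inherits one parental haplotype
#' with `Poisson(recombination_rate * sequence_length)` crossovers at uniform
#' positions. Sweeps start from a single copy in the object population
#' immediately after the split and are conditioned on fixation by restarting
#' the object population from the split state whenever the beneficial allele
#' is lost.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (named list of [genotype_matrix()], one per
#'   chromosome; a constant mean depth of 15 is attached so QC filters can
#'   run), `popmap` (a [population_map()]: groups `"fat"` = object and
#'   `"thin"` = reference), and `truth` (data.frame: chrom, pos, s, fixed).
#' @export
simulate_two_pop <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  N <- config$n_e_per_pop
  n_hap <- 2L * N
  L <- config$sequence_length
  R <- config$recombination_rate * L

  # site panel: unique sorted positions; sweep sites forced into the panel
  pos <- sort(sample.int(L, config$n_sites, replace = FALSE))
  sweep_pos <- vapply(config$sweep_specs, function(sw) as.integer(sw$pos) + 1L,
                      0L)  # 1-based site coordinate
  pos <- sort(union(pos, sweep_pos))
  S <- length(pos)
  sweep_idx <- match(sweep_pos, pos)

  # neutral SFS seeding: derived count i w.p. 1/i over 1..n_hap-1.
  # H is sites x haplotypes so haplotype copies are contiguous in memory.
  counts <- 1:(n_hap - 1L)
  cnt <- sample(counts, S, replace = TRUE, prob = 1 / counts)
  H <- matrix(0L, S, n_hap)
  for (j in seq_len(S)) H[j, sample.int(n_hap, cnt[j])] <- 1L
  H[sweep_idx, ] <- 0L  # sweep alleles are new mutations, absent pre-split

  H_fat <- H
  H_thin <- H

  # reference population: pure drift
  for (g in seq_len(config$split_generations)) {
    H_thin <- wf_generation(H_thin, pos, R, L)
  }

  # object population: drift + conditioned sweeps
  s_vec <- vapply(config$sweep_specs, function(sw) sw$s, 0)
  cap <- config$generation_cap_factor * config$split_generations
  total_gens <- 0L
  repeat {
    Hc <- H_fat
    if (length(sweep_idx)) {
      for (k in seq_along(sweep_idx)) {
        Hc[sweep_idx[k], sample.int(n_hap, 1L)] <- 1L
      }
    }
    lost <- FALSE
    odd <- seq(1L, n_hap, 2L); even <- seq(2L, n_hap, 2L)
    for (g in seq_len(config$split_generations)) {
      fit <- NULL
      if (length(sweep_idx)) {
        fit <- rep(1, N)
        for (k in seq_along(sweep_idx)) {
          gcnt <- Hc[sweep_idx[k], odd] + Hc[sweep_idx[k], even]
          fit <- fit * (1 + s_vec[k] * gcnt)
        }
      }
      Hc <- wf_generation(Hc, pos, R, L, fitness = fit)
      total_gens <- total_gens + 1L
      if (length(sweep_idx)) {
        ac <- rowSums(Hc[sweep_idx, , drop = FALSE])
        if (any(ac == 0L)) { lost <- TRUE; break }
      }
    }
    if (!lost && length(sweep_idx)) {
      lost <- any(rowSums(Hc[sweep_idx, , drop = FALSE]) < n_hap)
    }
    if (!lost) { H_fat <- Hc; break }
    if (total_gens > cap) {
      stop("sweep failed to fix within the generation cap; ",
           "consider a larger selection coefficient s")
    }
  }

  n_samp <- config$n_diploids_per_pop
  fat_ids <- sprintf("FAT%03d", seq_len(n_samp))
  thin_ids <- sprintf("THN%03d", seq_len(n_samp))
  take <- seq_len(n_samp)                       # individuals are exchangeable
  geno <- rbind(hap_to_geno(H_fat)[take, , drop = FALSE],
                hap_to_geno(H_thin)[take, , drop = FALSE])
  rownames(geno) <- c(fat_ids, thin_ids)

  info <- data.frame(qd = NA_real_, mq = NA_real_, fs = NA_real_, dp = 15)
  gms <- list()
  if (config$n_chromosomes == 1L) {
    gms[["1"]] <- genotype_matrix("1", pos, rownames(geno), geno,
                                  info[rep(1L, S), ])
    truth_chrom <- rep("1", length(sweep_pos))
    truth_pos <- sweep_pos
  } else {
    half <- L %/% 2L
    left <- pos <= half
    gms[["1"]] <- genotype_matrix("1", pos[left], rownames(geno),
                                  geno[, left, drop = FALSE],
                                  info[rep(1L, sum(left)), ])
    gms[["2"]] <- genotype_matrix("2", pos[!left] - half, rownames(geno),
                                  geno[, !left, drop = FALSE],
                                  info[rep(1L, sum(!left)), ])
    truth_chrom <- ifelse(sweep_pos <= half, "1", "2")
    truth_pos <- ifelse(sweep_pos <= half, sweep_pos, sweep_pos - half)
  }

  list(
    genotypes = gms,
    popmap = population_map(c(fat_ids, thin_ids),
                            rep(c("fat", "thin"), each = n_samp)),
    truth = data.frame(chrom = truth_chrom, pos = truth_pos,
                       s = if (length(s_vec)) s_vec else numeric(),
                       fixed = rep(TRUE, length(sweep_pos)),
                       stringsAsFactors = FALSE)
  )
}

# One Wright-Fisher generation. H: haplotype matrix (2N x S, 0/1); pos:
# 1-based site positions; R: expected crossovers per gamete; fitness:
# per-individual relative fitness (parents drawn proportionally). RNG stays
# in R; the matrix assembly is compiled.
wf_generation <- function(H, pos, R, L, fitness = NULL) {
  n_hap <- ncol(H)                 # H is sites x haplotypes
  N <- n_hap %/% 2L
  prob <- if (is.null(fitness)) NULL else fitness / sum(fitness)
  # each of the 2N gametes comes from an independent parent
  parent <- sample.int(N, n_hap, replace = TRUE, prob = prob)
  n_x <- stats::rpois(n_hap, R)
  first <- sample.int(2L, n_hap, replace = TRUE)        # starting haplotype
  bp <- stats::runif(sum(n_x), 0, L)
  bp_off <- c(0L, cumsum(n_x))
  .wf_next_gen(H, pos, parent, first, bp, bp_off)
}

# haplotypes (S x 2N) -> diploid genotypes (N x S)
hap_to_geno <- function(H) {
  n_hap <- ncol(H)
  t(H[, seq(1L, n_hap, 2L), drop = FALSE] +
      H[, seq(2L, n_hap, 2L), drop = FALSE])
}

#' Tile synthetic genes along a sequence
#'
#' Genes `GENE0001`, `GENE0002`, ... are laid left to right with a fixed gap,
#' so any interior position is within `gene_size + gap` of a gene.
#'
#' @param sequence_length total sequence length (bp).
#' @param gene_size gene length (bp).
#' @param gap gap between consecutive genes (bp).
#' @param chrom chromosome name for the models.
#' @param bed_path optional path; when given, the models are also written as
#'   a BED file.
#' @return a `gene_models` data.frame (0-based half-open).
#' @export
tile_genes <- function(sequence_length, gene_size, gap, chrom = "1",
                       bed_path = NULL) {
  stopifnot(gene_size > 0, gap > 0)
  starts <- seq(0L, sequence_length - 1L, by = gene_size + gap)
  ends <- pmin(starts + gene_size, sequence_length)
  keep <- ends > starts
  out <- data.frame(
    gene_id = sprintf("GENE%04d", seq_len(sum(keep))),
    chrom = chrom, start = as.integer(starts[keep]),
    end = as.integer(ends[keep]), strand = "+", stringsAsFactors = FALSE
  )
  class(out) <- c("gene_models", "data.frame")
  if (!is.null(bed_path)) {
    write_regions_bed(data.frame(chrom = out$chrom, start = out$start,
                                 end = out$end, name = out$gene_id), bed_path)
  }
  out
}

#' Write a small deterministic test fixture
#'
#' Hand-constructed datasets used by the unit tests:
#' \describe{
#'   \item{tiny_fst}{2 populations x 4 diploids x 12 sites with known allele
#'     counts, as `tiny_fst.vcf` + `tiny_fst.popmap.tsv`.}
#'   \item{roh_toy}{one individual homozygous over a ~1 Mb central block
#'     flanked by heterozygous sites, plus an all-heterozygous individual.}
#'   \item{filter_toy}{10 sites of which exactly 4 violate the QC rules:
#'     one QD < 2.0, one MQ < 20, one FS > 60, one MAF <= 0.05; the other 6
#'     pass every sub-filter.}
#'   \item{enrich_toy}{a gene-to-term annotation (`enrich_toy.terms.tsv`) of
#'     50 background genes and a 10-gene candidate list
#'     (`enrich_toy.candidates.txt`) with one strongly enriched term.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory (created if needed).
#' @return character vector of the file paths written.
#' @export
make_fixture_vcf <- function(name = c("tiny_fst", "roh_toy", "filter_toy",
                                      "enrich_toy"),
                             dir = tempdir()) {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, paste0(name, ...))
  switch(name,
    tiny_fst = {
      # 8 samples (popA 4, popB 4); genotype codes chosen to span
      # fixed-difference, shared-polymorphism and missing-data cases
      ga <- matrix(c(
        0,0,0,0,  2,2,2,2,  1,1,1,1,  0,0,1,1,  2,2,2,2,  0,1,2,0,
        0,0,0,0,  1,0,0,0,  2,2,1,1,  0,0,0,NA, 1,2,1,0,  0,0,0,0
      ), nrow = 4)
      gb <- matrix(c(
        2,2,2,2,  0,0,0,0,  1,1,1,1,  1,1,2,2,  2,2,2,2,  2,1,0,2,
        0,0,0,1,  1,1,1,1,  0,0,1,1,  2,NA,2,2, 0,1,0,1,  0,0,0,0
      ), nrow = 4)
      gm <- genotype_matrix("1", seq(1000L, by = 1000L, length.out = 12L),
                            c(sprintf("A%d", 1:4), sprintf("B%d", 1:4)),
                            rbind(ga, gb))
      write_vcf(gm, pth(".vcf"))
      writeLines(paste(c(sprintf("A%d", 1:4), sprintf("B%d", 1:4)),
                       rep(c("popA", "popB"), each = 4), sep = "\t"),
                 pth(".popmap.tsv"))
      c(pth(".vcf"), pth(".popmap.tsv"))
    },
    roh_toy = {
      pos <- seq(10000L, by = 10000L, length.out = 200L)  # 2 Mb, 10 kb apart
      hom_block <- pos >= 500000L & pos < 1500000L        # ~1 Mb central run
      g1 <- ifelse(hom_block, 2L, 1L)                     # ROH carrier
      g2 <- rep(1L, length(pos))                          # all-het control
      gm <- genotype_matrix("1", pos, c("S1", "S2"), rbind(g1, g2))
      write_vcf(gm, pth(".vcf"))
      writeLines(c("S1\tfat", "S2\tfat"), pth(".popmap.tsv"))
      c(pth(".vcf"), pth(".popmap.tsv"))
    },
    filter_toy = {
      pos <- seq(100L, by = 100L, length.out = 10L)
      # 6 samples; site 4 has MAF = 1/12 <= ... make exactly MAF 0: all hom-ref
      g <- matrix(1L, 6, 10)
      g[, 4L] <- 0L                                        # MAF 0 -> removed
      info <- data.frame(
        qd = c(5, 1.5, 5, 5, 5, 5, 5, 5, 5, 5),            # site 2 fails QD
        mq = c(60, 60, 10, 60, 60, 60, 60, 60, 60, 60),    # site 3 fails MQ
        fs = c(1, 1, 1, 1, 80, 1, 1, 1, 1, 1),             # site 5 fails FS
        dp = rep(15, 10)
      )
      gm <- genotype_matrix("1", pos, sprintf("S%d", 1:6), g, info)
      write_vcf(gm, pth(".vcf"))
      c(pth(".vcf"))
    },
    enrich_toy = {
      genes <- sprintf("G%03d", 1:50)
      # TERM_A holds genes 1..10; candidates are genes 1..8 plus 46,47
      ann <- rbind(
        data.frame(gene_id = genes[1:10], term_id = "TERM_A",
                   term_name = "lipid storage"),
        data.frame(gene_id = genes[11:30], term_id = "TERM_B",
                   term_name = "cilium assembly"),
        data.frame(gene_id = genes[c(31:50)], term_id = "TERM_C",
                   term_name = "ion transport")
      )
      utils::write.table(ann, pth(".terms.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      writeLines(genes[c(1:8, 46, 47)], pth(".candidates.txt"))
      c(pth(".terms.tsv"), pth(".candidates.txt"))
    }
  )
}
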