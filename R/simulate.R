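#' Configuration for the synthetic genotype-panel generator
#'
#' Defaults emulate a small germplasm-verification study on a highly inbred,
#' structured crop panel: two diverged populations of 20 accessions each
#' (cultivated-vs-wild scale divergence 0.3 on the F-model scale), two
#' chromosomes with distance-decaying LD from a narrow founder base, six
#' selfing generations (residual heterozygosity about 1.6%), an array-style
#' subset covering half the sites with 0.5% genotyping error, and planted
#' identity errors: four mislabelled accessions (two cross-population swaps)
#' plus two duplicated array entries.
#'
#' @param n_pops number of populations.
#' @param n_per_pop accessions per population.
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp chromosome length in bp.
#' @param n_sites_per_chrom biallelic SNPs per chromosome.
#' @param divergence per-site allele-frequency divergence between populations
#'   (F-model parameter in `[0, 1)`; 0 = exchangeable populations).
#' @param rho_per_bp per-bp donor switch rate of the haplotype-copying
#'   process; smaller values give longer-range LD. One value, or one per
#'   chromosome.
#' @param selfing_generations generations of selfing applied to each
#'   individual (heterozygosity halves per generation in expectation).
#' @param founder_haplotypes_per_pop founder haplotypes each population's
#'   chromosomes are mosaics of; few founders = strong LD, as in crop panels
#'   with a narrow genetic base.
#' @param array_fraction fraction of sites on the simulated array.
#' @param geno_error_rate array genotyping error (flips 0 <-> 2).
#' @param missing_rate per-cell missing rate (sequencing panel; applied again
#'   to the array subset).
#' @param n_mislabels number of mislabelled accessions (even; planted as
#'   cross-population pair swaps of array genotypes).
#' @param n_duplicates number of cloned array entries under new IDs.
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_pops = 2, n_per_pop = 20, n_chrom = 2,
                       chrom_len_bp = 1e6, n_sites_per_chrom = 400,
                       divergence = 0.3, rho_per_bp = 1e-5,
                       selfing_generations = 6,
                       founder_haplotypes_per_pop = 4,
                       array_fraction = 0.5, geno_error_rate = 0.005,
                       missing_rate = 0.01, n_mislabels = 4,
                       n_duplicates = 2, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires an explicit seed")
  cfg <- list(n_pops = n_pops, n_per_pop = n_per_pop, n_chrom = n_chrom,
              chrom_len_bp = chrom_len_bp,
              n_sites_per_chrom = n_sites_per_chrom, divergence = divergence,
              rho_per_bp = rho_per_bp,
              selfing_generations = selfing_generations,
              founder_haplotypes_per_pop = founder_haplotypes_per_pop,
              array_fraction = array_fraction,
              geno_error_rate = geno_error_rate, missing_rate = missing_rate,
              n_mislabels = n_mislabels, n_duplicates = n_duplicates,
              seed = as.integer(seed))
  rates <- c("divergence", "array_fraction", "geno_error_rate", "missing_rate")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  }
  if (cfg$divergence >= 1) stop("divergence must be < 1")
  if (cfg$array_fraction <= 0) stop("array_fraction must be in (0, 1]")
  if (cfg$n_mislabels %% 2 != 0) {
    stop("n_mislabels must be even (mislabels are planted as pair swaps)")
  }
  if (cfg$n_mislabels + cfg$n_duplicates > cfg$n_pops * cfg$n_per_pop) {
    stop("n_mislabels + n_duplicates exceeds the sample count")
  }
  if (cfg$founder_haplotypes_per_pop < 2) stop("need >= 2 founder haplotypes")
  if (cfg$n_sites_per_chrom > cfg$chrom_len_bp) {
    stop("more sites than base pairs on a chromosome")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured inbred genotype panel
#'
#' Generative model, per chromosome: (1) site positions are drawn uniformly
#' and sorted; ancestral allele frequencies p ~ U(0.05, 0.95); (2) population
#' frequencies follow the F-model, p_k ~ Beta(p(1-d)/d, (1-p)(1-d)/d) with
#' d the divergence parameter; (3) each population gets a small set of
#' founder haplotypes drawn site-wise from p_k, and every sampled chromosome
#' is a mosaic of founders, switching donor between adjacent sites with
#' probability 1 - exp(-rho * gap) (geometric segment lengths -> LD that
#' decays with distance); (4) individuals pair two such chromosomes and are
#' then selfed by single-seed descent: each site is still segregating
#' (heterozygous where the parental chromosomes differ) with probability
#' 0.5^g, while fixed sites double one parental haplotype, chosen along the
#' chromosome by a recombining two-state mosaic so that inbreeding preserves
#' haplotype-scale LD; (5) cells are set missing at
#' `missing_rate`. Seeds the RNG once from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [genotype_panel()]) and `truth` (class
#'   `"sim_truth"`: per-sample population, expected-counterpart map, per
#'   chromosome the rho used and the ancestral/population frequencies;
#'   mislabel and duplicate ledgers are filled by [plant_mislabels()]).
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  ns <- config$n_pops * config$n_per_pop
  samples <- sprintf("S%03d", seq_len(ns))
  pop <- rep(seq_len(config$n_pops), each = config$n_per_pop)
  rho <- rep(config$rho_per_bp, length.out = config$n_chrom)
  geno_chunks <- vector("list", config$n_chrom)
  site_chunks <- vector("list", config$n_chrom)
  freqs <- vector("list", config$n_chrom)
  for (ch in seq_len(config$n_chrom)) {
    m <- config$n_sites_per_chrom
    pos <- sort(sample.int(config$chrom_len_bp, m))
    p <- stats::runif(m, 0.05, 0.95)
    d <- config$divergence
    G <- matrix(0L, nrow = ns, ncol = m)
    pk_all <- matrix(NA_real_, nrow = config$n_pops, ncol = m)
    nf <- config$founder_haplotypes_per_pop
    # divergence 0 means no structure at all: populations share one founder
    # pool and are exchangeable by construction
    founders_common <- if (d == 0) {
      matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nrow = nf)
    } else NULL
    for (k in seq_len(config$n_pops)) {
      pk <- if (d > 0) {
        stats::rbeta(m, p * (1 - d) / d, (1 - p) * (1 - d) / d)
      } else p
      pk_all[k, ] <- pk
      founders <- if (d == 0) founders_common else {
        matrix(stats::rbinom(nf * m, 1L, rep(pk, each = nf)), nrow = nf)
      }
      rows <- which(pop == k)
      for (i in rows) {
        h1 <- copy_haplotype(founders, pos, rho[ch])
        h2 <- copy_haplotype(founders, pos, rho[ch])
        G[i, ] <- self_genotypes(h1, h2, pos, rho[ch],
                                 config$selfing_generations)
      }
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(G)) < config$missing_rate
      G[drop] <- -1L
    }
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    site_chunks[[ch]] <- data.frame(
      chrom = sprintf("chr%02d", ch), pos = pos, id = ".",
      ref = ref, alt = unname(alt), vtype = "SNP",
      qd = NA_real_, fs = NA_real_, mq = NA_real_,
      stringsAsFactors = FALSE)
    geno_chunks[[ch]] <- G
    freqs[[ch]] <- list(ancestral = p, population = pk_all, pos = pos)
  }
  panel <- genotype_panel(samples, do.call(rbind, site_chunks),
                          do.call(cbind, geno_chunks))
  panel <- assign_snp_ids(panel)
  truth <- structure(list(
    samples = data.frame(sample_id = samples, population = pop,
                         stringsAsFactors = FALSE),
    expected = stats::setNames(samples, samples),
    rho_per_bp = stats::setNames(rho, sprintf("chr%02d", seq_len(config$n_chrom))),
    freqs = freqs,
    mislabels = data.frame(sample_id = character(), actual = character(),
                           stringsAsFactors = FALSE),
    duplicates = data.frame(dup_id = character(), source = character(),
                            stringsAsFactors = FALSE),
    config = config), class = "sim_truth")
  list(panel = panel, truth = truth)
}

# one chromosome as a founder mosaic with geometric segment lengths
copy_haplotype <- function(founders, pos, rho) {
  m <- length(pos)
  nf <- nrow(founders)
  switch_p <- 1 - exp(-rho * diff(pos))
  seg <- cumsum(c(1L, (stats::runif(m - 1) < switch_p) * 1L))
  donors <- sample.int(nf, max(seg), replace = TRUE)
  founders[cbind(donors[seg], seq_len(m))]
}

# selfing by single-seed descent: each site is still segregating with
# probability 0.5^g; fixed sites double one parental haplotype, chosen by a
# recombining two-state mosaic so haplotype-scale LD survives inbreeding
self_genotypes <- function(h1, h2, pos, rho, generations) {
  if (generations <= 0) return(h1 + h2)
  hz <- copy_haplotype(rbind(h1, h2), pos, rho)
  residual <- stats::runif(length(pos)) < 0.5^generations
  g <- 2L * hz
  g[residual] <- h1[residual] + h2[residual]
  g
}

#' Array-style subset of a simulated panel
#'
#' Draws a random fraction of sites (emulating fixed-content array design),
#' applies genotyping error (each homozygous cell flips 0 <-> 2 with
#' probability `geno_error_rate`) and additional missingness. Sample IDs are
#' preserved. Uses the current RNG stream; call within a seeded run (see
#' [simulate_study()]).
#'
#' @param panel the sequencing-scale [genotype_panel()].
#' @param config the [sim_config()] used to generate it.
#' @return a [genotype_panel()] with attribute `site_index` (indices of the
#'   retained sites in `panel`).
#' @export
array_subset <- function(panel, config) {
  m <- n_sites(panel)
  keep <- sort(sample.int(m, max(2, round(config$array_fraction * m))))
  out <- subset_sites(panel, keep)
  if (config$geno_error_rate > 0) {
    hom <- which(out$geno == 0L | out$geno == 2L)
    flip <- hom[stats::runif(length(hom)) < config$geno_error_rate]
    out$geno[flip] <- 2L - out$geno[flip]
  }
  if (config$missing_rate > 0) {
    drop <- which(stats::runif(length(out$geno)) < config$missing_rate)
    out$geno[drop] <- -1L
  }
  attr(out, "site_index") <- keep
  out
}

#' Plant mislabels and duplicates in the array panel
#'
#' Mislabels are planted as pair swaps of array genotype rows between
#' populations (the seed envelopes were exchanged, so each sample's array
#' entry carries the other's genotypes); both members of a swap are
#' mislabelled. Duplicates clone a sample's array genotypes under a fresh
#' `DUPn` ID. All events are recorded in the truth ledger, which is
#' sufficient to score every verification verdict.
#'
#' @param array_panel the [array_subset()] panel.
#' @param truth the `sim_truth` from [simulate_panel()].
#' @param n_mislabels,n_duplicates event counts (defaults from the config in
#'   `truth`).
#' @return list with `array_panel` and updated `truth`.
#' @export
plant_mislabels <- function(array_panel, truth,
                            n_mislabels = truth$config$n_mislabels,
                            n_duplicates = truth$config$n_duplicates) {
  if (n_mislabels %% 2 != 0) stop("n_mislabels must be even")
  samples <- array_panel$samples
  pop <- truth$samples$population[match(samples, truth$samples$sample_id)]
  if (n_mislabels > 0) {
    n_swaps <- n_mislabels / 2
    pops <- sort(unique(pop))
    from_pop <- if (length(pops) > 1) pops[1] else pops
    to_pop <- if (length(pops) > 1) pops[2] else pops
    a_ids <- sample(samples[pop == from_pop], n_swaps)
    b_ids <- sample(setdiff(samples[pop == to_pop], a_ids), n_swaps)
    for (s in seq_len(n_swaps)) {
      ia <- match(a_ids[s], samples); ib <- match(b_ids[s], samples)
      tmp <- array_panel$geno[ia, ]
      array_panel$geno[ia, ] <- array_panel$geno[ib, ]
      array_panel$geno[ib, ] <- tmp
    }
    truth$mislabels <- data.frame(sample_id = c(a_ids, b_ids),
                                  actual = c(b_ids, a_ids),
                                  stringsAsFactors = FALSE)
  }
  if (n_duplicates > 0) {
    pool <- setdiff(samples, truth$mislabels$sample_id)
    src <- sample(pool, n_duplicates)
    dup_ids <- sprintf("DUP%d", seq_len(n_duplicates))
    geno <- rbind(array_panel$geno,
                  array_panel$geno[match(src, samples), , drop = FALSE])
    array_panel <- genotype_panel(c(samples, dup_ids), array_panel$sites, geno)
    truth$duplicates <- data.frame(dup_id = dup_ids, source = src,
                                   stringsAsFactors = FALSE)
  }
  list(array_panel = array_panel, truth = truth)
}

#' Simulate a full two-platform study
#'
#' One seeded run of [simulate_panel()], [array_subset()] and
#' [plant_mislabels()] under a single RNG stream: a dense sequencing-style
#' panel, a sparse array-style panel with planted identity errors, and the
#' ground-truth ledger. Identical seed and config give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `seq_panel`, `array_panel`, `truth`, and `metadata`
#'   (data frame `sample_id`, `species`, `country` — species tags the
#'   population, countries are assigned round-robin for labelling).
#' @export
simulate_study <- function(config) {
  sim <- simulate_panel(config)
  arr <- array_subset(sim$panel, config)
  planted <- plant_mislabels(arr, sim$truth)
  countries <- c("China", "Korea", "Japan", "United States", "Russia")
  meta <- data.frame(
    sample_id = sim$panel$samples,
    species = paste0("pop", sim$truth$samples$population),
    country = countries[(seq_along(sim$panel$samples) - 1) %%
                          length(countries) + 1],
    stringsAsFactors = FALSE)
  list(seq_panel = sim$panel, array_panel = planted$array_panel,
       truth = planted$truth, metadata = meta)
}
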