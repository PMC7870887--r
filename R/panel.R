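#' Genotype panel: samples x biallelic sites
#'
#' The central container every analysis stage consumes. Genotypes are coded
#' per (sample, site) cell as an integer dosage of the alternate allele:
#' `0` homozygous reference, `1` heterozygous, `2` homozygous alternate,
#' `-1` missing. Sites carry chromosome, 1-based position, alleles, a variant
#' type (`"SNP"` or `"INDEL"`) and the INFO scalars used by hard filtering
#' (QD, FS, MQ; `NA` when absent from the source VCF).
#'
#' @param samples character vector of unique sample IDs.
#' @param sites data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `vtype`, `qd`, `fs`, `mq`. Missing optional columns are filled with `NA`.
#' @param geno integer matrix, `length(samples)` rows by `nrow(sites)`
#'   columns, entries in `{0, 1, 2, -1}`.
#'
#' @return An object of class `"genotype_panel"`: a list with elements
#'   `samples`, `sites` and `geno` (rows named by sample).
#' @export
genotype_panel <- function(samples, sites, geno) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "id", "ref", "alt", "vtype", "qd", "fs", "mq")
  for (col in setdiff(needed, names(sites))) {
    sites[[col]] <- rep(if (col == "vtype") NA_character_ else NA_real_,
                        nrow(sites))
  }
  sites <- sites[needed]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$id <- as.character(sites$id)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (is.null(dim(geno))) geno <- matrix(as.integer(geno), nrow = length(samples))
  geno <- matrix(as.integer(geno), nrow = nrow(geno), ncol = ncol(geno))
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(sites)) {
    stop(sprintf("geno is %d x %d but panel has %d samples and %d sites",
                 nrow(geno), ncol(geno), length(samples), nrow(sites)))
  }
  bad <- !(geno %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) stop("genotype codes must be in {0, 1, 2, -1}")
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    key <- paste(sites$chrom, sites$pos)
    if (anyDuplicated(key)) stop("duplicate (chrom, pos) pairs")
    ord <- order(sites$chrom, sites$pos)
    if (!identical(ord, seq_len(nrow(sites)))) {
      sites <- sites[ord, , drop = FALSE]
      geno <- geno[, ord, drop = FALSE]
    }
    rownames(sites) <- NULL
  }
  rownames(geno) <- samples
  structure(list(samples = samples, sites = sites, geno = geno),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d sites on %d chromosome(s)\n",
              length(x$samples), nrow(x$sites),
              length(unique(x$sites$chrom))))
  if (nrow(x$sites) > 0) {
    st <- missing_het_stats(x)
    cat(sprintf("  missing %.2f%%, heterozygous %.2f%%\n",
                100 * st$missing_fraction, 100 * st$het_fraction))
  }
  invisible(x)
}

#' @export
summary.genotype_panel <- function(object, ...) {
  tab <- table(factor(object$geno, levels = c(-1, 0, 1, 2)))
  names(tab) <- c("missing", "hom_ref", "het", "hom_alt")
  list(n_samples = length(object$samples),
       n_sites = nrow(object$sites),
       chromosomes = table(object$sites$chrom),
       code_counts = tab)
}

#' Number of samples / sites in a panel
#' @param panel a [genotype_panel()].
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel by site index or by sample ID
#'
#' @param panel a [genotype_panel()].
#' @param idx integer vector of site indices (in current site order).
#' @return a new `genotype_panel`.
#' @export
subset_sites <- function(panel, idx) {
  genotype_panel(panel$samples, panel$sites[idx, , drop = FALSE],
                 panel$geno[, idx, drop = FALSE])
}

#' @rdname subset_sites
#' @param ids character vector of sample IDs to keep (order respected).
#' @export
subset_samples <- function(panel, ids) {
  miss <- setdiff(ids, panel$samples)
  if (length(miss)) stop("samples not in panel: ", paste(miss, collapse = ", "))
  keep <- match(ids, panel$samples)
  genotype_panel(panel$samples[keep], panel$sites,
                 panel$geno[keep, , drop = FALSE])
}

#' Per-cell missing and heterozygous fractions
#'
#' Fractions are over all (sample, site) cells of the panel; together with the
#' homozygous fraction (codes 0 and 2) they sum to one.
#'
#' @param panel a non-empty [genotype_panel()].
#' @return list with `missing_fraction` and `het_fraction`, both in `[0, 1]`.
#' @export
missing_het_stats <- function(panel) {
  ncell <- length(panel$geno)
  if (ncell == 0) stop("empty panel")
  list(missing_fraction = sum(panel$geno == -1L) / ncell,
       het_fraction = sum(panel$geno == 1L) / ncell)
}
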