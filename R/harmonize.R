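#' Match sites of two panels on (chrom, pos) and classify allele orientation
#'
#' Array- and sequencing-derived panels frequently disagree on which allele is
#' REF and on reported strand, so matching is positional and the allele pair
#' decides the orientation: `identical` (same ref/alt), `swapped` (ref/alt
#' reversed), `flipped` (reverse-complement strand), `flipped_swapped` (both),
#' `ambiguous` (A/T or C/G pairs, where flip and swap cannot be told apart)
#' or `incompatible` (allele sets differ).
#'
#' @param a,b [genotype_panel()] objects (sites sorted, the panel invariant).
#' @return data frame with columns `idx_a`, `idx_b` (site indices into each
#'   panel) and `class`.
#' @export
intersect_sites <- function(a, b) {
  key_a <- paste(a$sites$chrom, a$sites$pos)
  key_b <- paste(b$sites$chrom, b$sites$pos)
  idx_b <- match(key_a, key_b)
  idx_a <- which(!is.na(idx_b))
  idx_b <- idx_b[idx_a]
  ra <- a$sites$ref[idx_a]; aa <- a$sites$alt[idx_a]
  rb <- b$sites$ref[idx_b]; ab <- b$sites$alt[idx_b]
  cls <- classify_alleles(ra, aa, rb, ab)
  data.frame(idx_a = idx_a, idx_b = idx_b, class = cls,
             ref_a = ra, alt_a = aa, ref_b = rb, alt_b = ab,
             stringsAsFactors = FALSE)
}

revcomp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

classify_alleles <- function(ra, aa, rb, ab) {
  amb <- nchar(ra) == 1 & nchar(aa) == 1 &
    revcomp_base(ra) == aa  # A/T or C/G pair: strand unresolvable
  cls <- rep("incompatible", length(ra))
  cls[ra == rb & aa == ab] <- "identical"
  cls[ra == ab & aa == rb] <- "swapped"
  snp <- nchar(ra) == 1 & nchar(aa) == 1 & nchar(rb) == 1 & nchar(ab) == 1
  fl <- snp & cls == "incompatible" &
    ra == revcomp_base(rb) & aa == revcomp_base(ab)
  fs <- snp & cls == "incompatible" &
    ra == revcomp_base(ab) & aa == revcomp_base(rb)
  cls[fl] <- "flipped"
  cls[fs] <- "flipped_swapped"
  cls[amb & cls != "incompatible"] <- "ambiguous"
  cls
}

#' Orient the second panel's genotype columns onto the first panel's alleles
#'
#' `identical` and `flipped` sites keep their codes (complementing both
#' alleles does not change dosage); `swapped` and `flipped_swapped` sites have
#' codes 0 and 2 exchanged; `ambiguous` and `incompatible` sites are dropped
#' and tallied. With `keep_ambiguous = TRUE`, A/T and C/G sites are retained
#' and oriented at face value by their reported alleles.
#'
#' @param pairs output of [intersect_sites()].
#' @param b the second [genotype_panel()].
#' @param keep_ambiguous keep strand-ambiguous sites (default drop).
#' @return list with `geno` (b-sample rows over kept sites), `kept` (row
#'   indices into `pairs`), `n_swapped`, `n_dropped_ambiguous`,
#'   `n_dropped_incompatible`.
#' @export
harmonize_genotypes <- function(pairs, b, keep_ambiguous = FALSE) {
  cls <- pairs$class
  keep_cls <- c("identical", "swapped", "flipped", "flipped_swapped")
  if (keep_ambiguous) keep_cls <- c(keep_cls, "ambiguous")
  kept <- which(cls %in% keep_cls)
  g <- b$geno[, pairs$idx_b[kept], drop = FALSE]
  flip <- cls[kept] %in% c("swapped", "flipped_swapped")
  if (keep_ambiguous) {
    # A/T and C/G sites oriented at face value by the reported alleles
    amb <- cls[kept] == "ambiguous"
    flip[amb] <- pairs$ref_a[kept][amb] == pairs$alt_b[kept][amb]
  }
  if (any(flip)) {
    cols <- g[, flip, drop = FALSE]
    swapped <- cols
    swapped[cols == 0L] <- 2L
    swapped[cols == 2L] <- 0L
    g[, flip] <- swapped
  }
  list(geno = g, kept = kept,
       n_swapped = sum(cls[kept] %in% c("swapped", "flipped_swapped")),
       n_dropped_ambiguous = sum(cls == "ambiguous") * (!keep_ambiguous),
       n_dropped_incompatible = sum(cls == "incompatible"))
}

#' Mask heterozygous calls as missing
#'
#' Recodes every heterozygous call (1) as missing (-1); all other codes are
#' unchanged. Idempotent. This is the standard pre-processing before
#' identity-by-state comparison of inbred material, where residual
#' heterozygosity is mostly genotyping noise.
#'
#' @param panel a [genotype_panel()].
#' @return the masked panel.
#' @export
mask_hets <- function(panel) {
  panel$geno[panel$geno == 1L] <- -1L
  panel
}

#' Merge two genotype panels on common positions
#'
#' Intersects sites on (chrom, pos), orients the second panel's genotypes onto
#' the first panel's alleles ([harmonize_genotypes()]), and column-binds the
#' two sample sets over the retained sites. Sample IDs present in both inputs
#' keep the first panel's column; the second panel's copy is suffixed `"_b"`
#' and retained (so self-merges act as positive controls downstream). The
#' combined missing-plus-heterozygous cell fraction is reported before any
#' masking.
#'
#' @param a,b [genotype_panel()] objects sharing a coordinate system.
#' @param mask_hets also mask heterozygous calls in the merged panel.
#' @param keep_ambiguous retain strand-ambiguous (A/T, C/G) sites.
#' @return an object of class `"merge_result"`: list with `panel`,
#'   `n_common_sites` (positional intersection size), `n_allele_swapped`,
#'   `n_dropped_strand_ambiguous`, `n_dropped_incompatible`,
#'   `missing_het_fraction`, `rename_map` (named character vector, new name
#'   per colliding input ID of `b`).
#' @export
merge_panels <- function(a, b, mask_hets = FALSE, keep_ambiguous = FALSE) {
  pairs <- intersect_sites(a, b)
  if (nrow(pairs) == 0) {
    stop("no common (chrom, pos) sites between the two panels; ",
         "check that both use the same assembly and chromosome names")
  }
  h <- harmonize_genotypes(pairs, b, keep_ambiguous = keep_ambiguous)
  idx_a <- pairs$idx_a[h$kept]
  samples_b <- b$samples
  collide <- samples_b %in% a$samples
  rename_map <- stats::setNames(paste0(samples_b[collide], "_b"),
                                samples_b[collide])
  samples_b[collide] <- rename_map
  geno <- rbind(a$geno[, idx_a, drop = FALSE], h$geno)
  panel <- genotype_panel(c(a$samples, samples_b),
                          a$sites[idx_a, , drop = FALSE], geno)
  mh <- sum(panel$geno == -1L | panel$geno == 1L) / length(panel$geno)
  if (mask_hets) panel <- mask_hets(panel)
  structure(list(panel = panel,
                 n_common_sites = nrow(pairs),
                 n_allele_swapped = h$n_swapped,
                 n_dropped_strand_ambiguous = h$n_dropped_ambiguous,
                 n_dropped_incompatible = h$n_dropped_incompatible,
                 missing_het_fraction = mh,
                 rename_map = rename_map),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf(paste0("merge_result: %d common sites (%d retained); ",
                     "%d allele-swapped, %d strand-ambiguous dropped, ",
                     "%d incompatible dropped\n"),
              x$n_common_sites, n_sites(x$panel), x$n_allele_swapped,
              x$n_dropped_strand_ambiguous, x$n_dropped_incompatible))
  cat(sprintf("  missing + het fraction before masking: %.3f%%\n",
              100 * x$missing_het_fraction))
  invisible(x)
}
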