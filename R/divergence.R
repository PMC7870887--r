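#' Binned SNP-difference profiles against a reference accession
#'
#' For each query sample and each fixed-width genomic bin, counts the sites
#' where both the query and the reference carry a homozygous call
#' (`n_compared`) and, of those, the sites where the calls differ (`n_diff`)
#' — the computation behind reference-versus-collection heatmaps. Bins are
#' 0-based half-open multiples of `bin_size` from position 0 and tile each
#' chromosome (empty bins are emitted with zeros), so `n_diff` summed over
#' bins equals the genome-wide pairwise difference count.
#'
#' @param panel a [genotype_panel()].
#' @param ref_id reference sample ID.
#' @param query_ids query sample IDs (default: all other samples).
#' @param bin_size bin width in bp (default 500000).
#' @param include_hets count heterozygous calls as present (and differing
#'   when codes differ); default FALSE, i.e. hets are excluded like missing.
#' @param chrom_sizes optional data frame (`chrom`, `size_bp`) fixing how far
#'   bins tile; defaults to the last site position per chromosome.
#' @return data frame of class `"divergence_profile"` with columns `chrom`,
#'   `start`, `end`, `query`, `n_compared`, `n_diff`; attribute `ref_id`.
#' @export
binned_differences <- function(panel, ref_id, query_ids = NULL,
                               bin_size = 500000, include_hets = FALSE,
                               chrom_sizes = NULL) {
  if (!ref_id %in% panel$samples) stop("reference sample not in panel: ", ref_id)
  if (is.null(query_ids)) query_ids <- setdiff(panel$samples, ref_id)
  miss <- setdiff(query_ids, panel$samples)
  if (length(miss)) stop("query samples not in panel: ",
                         paste(miss, collapse = ", "))
  s <- panel$sites
  chroms <- unique(s$chrom)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- data.frame(
      chrom = chroms,
      size_bp = vapply(chroms, function(ch) max(s$pos[s$chrom == ch]),
                       numeric(1)))
  }
  gref <- panel$geno[match(ref_id, panel$samples), ]
  present <- function(g) if (include_hets) g != -1L else g == 0L | g == 2L
  out <- vector("list", length(query_ids) * length(chroms))
  k <- 0
  for (q in query_ids) {
    gq <- panel$geno[match(q, panel$samples), ]
    both <- present(gref) & present(gq)
    diffc <- both & gref != gq
    for (ch in chroms) {
      size <- chrom_sizes$size_bp[match(ch, chrom_sizes$chrom)]
      nb <- max(1, ceiling(size / bin_size))
      on_ch <- s$chrom == ch
      bin_idx <- s$pos[on_ch] %/% bin_size + 1  # 0-based half-open bins
      n_comp <- tabulate(bin_idx[both[on_ch]], nbins = nb)
      n_diff <- tabulate(bin_idx[diffc[on_ch]], nbins = nb)
      k <- k + 1
      out[[k]] <- data.frame(
        chrom = ch, start = (seq_len(nb) - 1) * bin_size,
        end = seq_len(nb) * bin_size, query = q,
        n_compared = n_comp, n_diff = n_diff, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("divergence_profile", "data.frame")
  attr(res, "ref_id") <- ref_id
  attr(res, "bin_size") <- bin_size
  res
}

#' Write divergence profiles as BED-like TSV
#'
#' Columns: chrom, start (0-based), end (half-open), query, n_compared,
#' n_diff.
#'
#' @param profiles a [binned_differences()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_divergence_bed <- function(profiles, path) {
  out <- as.data.frame(profiles)
  out$start <- sprintf("%.0f", out$start)  # never scientific notation
  out$end <- sprintf("%.0f", out$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
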