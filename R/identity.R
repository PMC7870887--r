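#' Identity-by-state similarity matrix
#'
#' For each sample pair, similarity is the mean over co-called sites of
#' `1 - |g_i - g_j| / 2` with dosage codes g in {0, 1, 2}; with heterozygotes
#' masked this reduces to the simple matching fraction of homozygous calls.
#' Pairs sharing fewer than `min_shared` co-called sites are flagged invalid
#' (`NA` similarity) rather than reported from vacuously small overlap.
#'
#' @param panel a [genotype_panel()] (typically after [mask_hets()]).
#' @param min_shared minimum co-called sites for a valid pairwise value.
#' @return an object of class `"ibs_matrix"`: list with `samples`, `sim`
#'   (symmetric matrix in `[0, 1]`, `NA` where invalid) and `n_shared`
#'   (co-called site counts).
#' @export
ibs_similarity <- function(panel, min_shared = 100) {
  G <- panel$geno
  # indicator crossproducts give, per pair, shared-call counts and the summed
  # |g_i - g_j| without a sample-pair loop
  X0 <- (G == 0L) * 1
  X1 <- (G == 1L) * 1
  X2 <- (G == 2L) * 1
  M <- X0 + X1 + X2
  n_shared <- M %*% t(M)
  d01 <- X0 %*% t(X1); d12 <- X1 %*% t(X2); d02 <- X0 %*% t(X2)
  absdiff <- (d01 + t(d01)) + (d12 + t(d12)) + 2 * (d02 + t(d02))
  sim <- 1 - absdiff / (2 * n_shared)
  sim[n_shared < min_shared] <- NA_real_
  dimnames(sim) <- list(panel$samples, panel$samples)
  dimnames(n_shared) <- dimnames(sim)
  structure(list(samples = panel$samples, sim = sim,
                 n_shared = n_shared, min_shared = min_shared),
            class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  off <- x$sim[upper.tri(x$sim)]
  cat(sprintf("ibs_matrix: %d samples; off-diagonal similarity %.3f-%.3f (median %.3f)\n",
              length(x$samples), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE), stats::median(off, na.rm = TRUE)))
  if (anyNA(off)) {
    cat(sprintf("  %d pair(s) below min_shared = %d flagged NA\n",
                sum(is.na(off)), x$min_shared))
  }
  invisible(x)
}

#' Top similarity matches for each query
#'
#' For each query sample, ranks reference samples (the query itself excluded)
#' by descending similarity; exact ties are broken by lexicographic reference
#' ID. Invalid (NA) pairs rank last.
#'
#' @param sim an [ibs_similarity()] result.
#' @param queries,references character vectors of sample IDs (defaults: all).
#' @param k number of matches per query.
#' @return named list: per query either a data frame (`match`, `sim`,
#'   `n_shared`) or an error message string for queries absent from the
#'   matrix.
#' @export
top_matches <- function(sim, queries = sim$samples, references = sim$samples,
                        k = 1) {
  refs <- setdiff(intersect(references, sim$samples), character(0))
  out <- lapply(queries, function(q) {
    if (!q %in% sim$samples) return(sprintf("query '%s' not in matrix", q))
    r <- setdiff(refs, q)
    s <- sim$sim[q, r]
    ord <- order(-s, r, na.last = TRUE)
    take <- utils::head(ord, k)
    data.frame(match = r[take], sim = unname(s[take]),
               n_shared = unname(sim$n_shared[q, r[take]]),
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, queries)
}

#' Classify accessions against their expected counterparts
#'
#' Implements the germplasm verification rules used to screen a resequenced
#' collection against its array-genotyped counterparts. With
#' `top` the best-matching reference and `gap = top_sim - expected_sim`:
#'
#' * `CONFIRMED` — top match is the expected counterpart, similarity >= `confirm`;
#' * `DRIFTED` — top match is the expected counterpart with similarity
#'   below `confirm` (seed-lot divergence after independent propagation), or
#'   a sub-`floor` counterpart within `gap_max` of the best match;
#' * `REDUNDANT_CONSISTENT` — another reference matches best, but the
#'   expected counterpart is >= `floor` and within `gap_max` of it
#'   (duplicated genotypes in the collection);
#' * `MIS_ASSIGNED` — the best match beats the expected counterpart by more
#'   than `gap_max` (identity/tracking error);
#' * `UNIQUE` — no expected counterpart and no reference >= `floor`;
#' * `NO_EXPECTED` — no expected counterpart, yet some reference >= `floor`.
#'
#' @param sim an [ibs_similarity()] result.
#' @param expected named character vector mapping query ID to expected
#'   counterpart ID; queries absent from it are treated as having no
#'   counterpart.
#' @param queries query IDs (default: names of `expected` if non-NULL, else
#'   all samples).
#' @param references reference IDs searched for matches (default: all samples
#'   other than the query).
#' @param thresholds list with `confirm` (default 0.99), `floor` (0.90) and
#'   `gap_max` (0.03), all similarity fractions.
#' @return an object of class `"match_report"`: data frame with columns
#'   `query`, `expected`, `expected_sim`, `top_match`, `top_sim`, `gap`,
#'   `n_shared`, `verdict`.
#' @export
classify_accessions <- function(sim, expected,
                                queries = NULL, references = sim$samples,
                                thresholds = list(confirm = 0.99,
                                                  floor = 0.90,
                                                  gap_max = 0.03)) {
  if (is.null(queries)) {
    queries <- if (!is.null(names(expected))) names(expected) else sim$samples
  }
  tm <- top_matches(sim, queries, references, k = 1)
  rows <- lapply(queries, function(q) {
    t1 <- tm[[q]]
    if (is.character(t1)) {
      return(data.frame(query = q, expected = NA_character_,
                        expected_sim = NA_real_, top_match = NA_character_,
                        top_sim = NA_real_, gap = NA_real_,
                        n_shared = NA_real_, verdict = "ERROR",
                        stringsAsFactors = FALSE))
    }
    exp_id <- if (q %in% names(expected)) unname(expected[q]) else NA_character_
    exp_sim <- if (!is.na(exp_id) && exp_id %in% sim$samples) {
      sim$sim[q, exp_id]
    } else NA_real_
    top_id <- t1$match[1]
    top_sim <- t1$sim[1]
    gap <- if (!is.na(exp_sim)) top_sim - exp_sim else NA_real_
    verdict <- verdict_rule(exp_id, exp_sim, top_id, top_sim, gap, thresholds)
    data.frame(query = q, expected = exp_id, expected_sim = exp_sim,
               top_match = top_id, top_sim = top_sim, gap = gap,
               n_shared = t1$n_shared[1], verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("match_report", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

verdict_rule <- function(exp_id, exp_sim, top_id, top_sim, gap, th) {
  if (is.na(exp_id) || is.na(exp_sim)) {
    if (!is.na(top_sim) && top_sim >= th$floor) return("NO_EXPECTED")
    return("UNIQUE")
  }
  # strict comparison, with a guard so a gap of exactly gap_max computed in
  # floating point is not pushed over the boundary
  if (!is.na(gap) && gap > th$gap_max + 1e-9) return("MIS_ASSIGNED")
  if (identical(top_id, exp_id)) {
    if (exp_sim >= th$confirm) return("CONFIRMED")
    return("DRIFTED")
  }
  if (exp_sim >= th$floor) return("REDUNDANT_CONSISTENT")
  "DRIFTED"
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: %d accessions\n", nrow(x)))
  print(table(x$verdict))
  invisible(x)
}

#' Write a verification report as TSV
#' @param report a [classify_accessions()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path) {
  out <- as.data.frame(report)
  for (col in c("expected_sim", "top_sim", "gap")) {
    out[[paste0(col, "_pct")]] <- round(100 * out[[col]], 2)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
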