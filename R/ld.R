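#' Pairwise r-squared between SNPs on one chromosome
#'
#' Computes, for every SNP pair within `max_dist` bp, the squared Pearson
#' correlation of genotype dosage codes across samples, using
#' pairwise-complete observations (cells missing in either sample are
#' dropped for that pair). Pairs where either site is monomorphic among the
#' shared calls have undefined correlation; they are skipped and tallied.
#' r2 is invariant to exchanging ref/alt coding (0 <-> 2) at either site.
#'
#' @param panel a [genotype_panel()].
#' @param chrom chromosome to analyse; may be omitted for a
#'   single-chromosome panel.
#' @param max_dist_bp maximum inter-site distance in bp (default 1e6, the
#'   span over which decay is typically resolved in inbred crop panels).
#' @return data frame of class `"ld_pairs"` with columns `chrom`, `dist`,
#'   `r2`; attributes `n_skipped` (undefined-correlation pairs) and
#'   `n_samples`.
#' @export
pairwise_r2 <- function(panel, chrom = NULL, max_dist_bp = 1e6) {
  s <- panel$sites
  keep <- is.na(s$vtype) | s$vtype != "INDEL"
  if (!is.null(chrom)) {
    keep <- keep & s$chrom == chrom
  } else {
    chroms <- unique(s$chrom[keep])
    if (length(chroms) > 1) stop("multi-chromosome panel: give `chrom`")
    chrom <- chroms
  }
  idx <- which(keep)
  empty <- data.frame(chrom = character(), dist = numeric(), r2 = numeric())
  if (length(idx) < 2) {
    return(structure(empty, class = c("ld_pairs", "data.frame"),
                     n_skipped = 0L, n_samples = length(panel$samples)))
  }
  G <- panel$geno[, idx, drop = FALSE]
  pos <- s$pos[idx]
  M <- (G != -1L) * 1
  A <- G * M          # missing cells contribute 0 to the sums below
  n <- crossprod(M)
  Sxy <- crossprod(A)
  Sx <- crossprod(A, M)       # sum of x over cells shared with y
  Sxx <- crossprod(A * G, M)  # A*G = G^2 on observed cells
  num <- n * Sxy - Sx * t(Sx)
  den <- (n * Sxx - Sx^2) * t(n * Sxx - Sx^2)
  r2 <- ifelse(den > 0, num^2 / den, NA_real_)

  D <- outer(pos, pos, function(a, b) b - a)
  sel <- upper.tri(D) & D > 0 & D <= max_dist_bp
  dist <- D[sel]
  r2v <- r2[sel]
  n_skipped <- sum(is.na(r2v))
  ok <- !is.na(r2v)
  out <- data.frame(chrom = rep(chrom, sum(ok)), dist = dist[ok], r2 = r2v[ok])
  structure(out, class = c("ld_pairs", "data.frame"),
            n_skipped = n_skipped, n_samples = length(panel$samples))
}

#' Hill-Weir expected r-squared
#'
#' Closed-form expectation of r2 under drift-recombination equilibrium for a
#' sample of `n` individuals, as a function of the population-scaled
#' recombination parameter `C` (the product of the per-bp scale and physical
#' distance):
#' \deqn{E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
#'   \left[1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right]}
#' The expectation decreases in both `C` and `n`; the second factor tends to
#' 1 as `n` grows (the `1/n` term is the finite-sample inflation of r2).
#'
#' @param C non-negative population-scaled recombination (vectorised).
#' @param n sample size (>= 2).
#' @return expected r2 values in `(0, 1)`.
#' @export
hill_weir_r2 <- function(C, n) {
  if (any(C < 0)) stop("C must be >= 0")
  if (n < 2) stop("n must be >= 2")
  lead <- (10 + C) / ((2 + C) * (11 + C))
  lead * (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay curve to observed LD
#'
#' Estimates the per-bp scale `rho` such that expected r2 at distance `d` is
#' `hill_weir_r2(rho * d, n)`, by least squares against the observations. By
#' default the fit is on log-spaced distance-bin means (robust to the very
#' uneven pair density along a chromosome); set `use_bins = FALSE` to fit raw
#' pairs. The single free parameter is profiled on a log10 grid and refined
#' by golden-section search, which converges for any input. The decay
#' distance is then the root of the fitted monotone curve against `baseline`,
#' solved by bisection; if the curve never crosses the baseline over the
#' observed distance range extended tenfold, the fit is flagged not reached.
#'
#' @param pairs an [pairwise_r2()] result (or data frame with `dist`, `r2`).
#' @param n number of samples the r2 values were computed from.
#' @param baseline r2 level defining the decay distance (default 0.2).
#' @param n_bins number of log-spaced distance bins (default 100).
#' @param use_bins fit binned means (default) or raw pairs.
#' @return an object of class `"ld_fit"`: list with `rho_per_bp`, `n`,
#'   `baseline`, `decay_distance` (bp; `NA` if not reached), `reached`,
#'   `bins` (data frame `dist`, `r2`, `count`), `n_pairs`, `sse`.
#' @export
fit_ld_decay <- function(pairs, n, baseline = 0.2, n_bins = 100,
                         use_bins = TRUE) {
  pairs <- pairs[!is.na(pairs$r2) & pairs$dist > 0, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no usable (dist, r2) pairs")
  if (nrow(pairs) < 50 || diff(range(log10(pairs$dist))) < 2) {
    warning("few pairs or narrow distance range; fit may be unstable")
  }
  brk <- exp(seq(log(min(pairs$dist)), log(max(pairs$dist)),
                 length.out = n_bins + 1))
  brk[1] <- brk[1] - 1e-9
  bin <- cut(pairs$dist, brk, labels = FALSE, include.lowest = TRUE)
  bins <- data.frame(
    dist = as.numeric(tapply(pairs$dist, bin, mean)),
    r2 = as.numeric(tapply(pairs$r2, bin, mean)),
    count = as.numeric(tapply(pairs$r2, bin, length))
  )
  bins <- bins[!is.na(bins$dist), , drop = FALSE]
  fit_d <- if (use_bins) bins$dist else pairs$dist
  fit_r <- if (use_bins) bins$r2 else pairs$r2
  sse <- function(log10_rho) {
    sum((fit_r - hill_weir_r2(10^log10_rho * fit_d, n))^2)
  }
  grid <- seq(-12, 0, by = 0.05)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  rho <- 10^opt$minimum

  dmax <- max(pairs$dist) * 10
  f <- function(d) hill_weir_r2(rho * d, n) - baseline
  reached <- f(1e-9) > 0 && f(dmax) < 0
  decay <- if (reached) {
    stats::uniroot(f, c(1e-9, dmax), tol = 1e-4)$root
  } else NA_real_
  structure(list(rho_per_bp = rho, n = n, baseline = baseline,
                 decay_distance = decay, reached = reached, bins = bins,
                 n_pairs = nrow(pairs), sse = opt$objective,
                 use_bins = use_bins),
            class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  cat(sprintf("ld_fit: Hill-Weir decay, n = %d samples, %d pairs\n",
              x$n, x$n_pairs))
  cat(sprintf("  rho = %.4g per bp\n", x$rho_per_bp))
  if (x$reached) {
    cat(sprintf("  decay distance at r2 = %.2f: %.1f kb\n",
                x$baseline, x$decay_distance / 1e3))
  } else {
    cat(sprintf("  baseline r2 = %.2f not reached over the fitted range\n",
                x$baseline))
  }
  invisible(x)
}

#' @export
summary.ld_fit <- function(object, ...) {
  res <- object$bins$r2 - predict(object, object$bins$dist)
  out <- c(object[c("rho_per_bp", "n", "baseline", "decay_distance",
                    "reached", "n_pairs", "sse")],
           list(residual_sd = stats::sd(res)))
  class(out) <- "summary.ld_fit"
  out
}

#' @export
print.summary.ld_fit <- function(x, ...) {
  cat(sprintf("Hill-Weir LD decay fit\n  rho_per_bp   %.6g\n  n            %d\n",
              x$rho_per_bp, x$n))
  cat(sprintf("  decay (bp)   %s  (baseline r2 = %.2f)\n",
              if (x$reached) format(round(x$decay_distance)) else "not reached",
              x$baseline))
  cat(sprintf("  pairs        %d\n  residual sd  %.4f\n", x$n_pairs,
              x$residual_sd))
  invisible(x)
}

#' @export
coef.ld_fit <- function(object, ...) c(rho_per_bp = object$rho_per_bp)

#' @export
predict.ld_fit <- function(object, dist = object$bins$dist, ...) {
  hill_weir_r2(object$rho_per_bp * dist, object$n)
}

#' @export
residuals.ld_fit <- function(object, ...) {
  object$bins$r2 - predict(object, object$bins$dist)
}

#' @export
plot.ld_fit <- function(x, ...) {
  plot(x$bins$dist / 1e3, x$bins$r2, log = "x", pch = 16, cex = 0.6,
       col = "grey40", xlab = "distance (kb)", ylab = expression(r^2), ...)
  d <- exp(seq(log(min(x$bins$dist)), log(max(x$bins$dist)), length.out = 200))
  graphics::lines(d / 1e3, predict(x, d), col = "firebrick", lwd = 2)
  graphics::abline(h = x$baseline, lty = 3)
  if (x$reached) graphics::abline(v = x$decay_distance / 1e3, lty = 3)
  invisible(x)
}

#' Per-chromosome LD decay summary
#'
#' Fits the Hill-Weir curve on each chromosome and tabulates chromosome size,
#' decay distance at the baseline, their unweighted mean, and the squared
#' Pearson correlation between size and decay distance. Chromosomes whose fit
#' fails or never reaches the baseline are reported `NA` and excluded from
#' the mean and correlation.
#'
#' @param panel a multi-chromosome [genotype_panel()].
#' @param chrom_sizes optional data frame (`chrom`, `size_bp`); defaults to
#'   the maximum site position per chromosome.
#' @param baseline r2 level for the decay distance.
#' @param max_dist_bp pair-distance cap passed to [pairwise_r2()].
#' @return data frame (`chromosome`, `chromosome_size_mb`,
#'   `decay_distance_mb`) with attributes `mean_decay_mb` and
#'   `size_decay_r2`.
#' @export
ld_chromosome_summary <- function(panel, chrom_sizes = NULL, baseline = 0.2,
                                  max_dist_bp = 1e6) {
  chroms <- unique(panel$sites$chrom)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- data.frame(
      chrom = chroms,
      size_bp = vapply(chroms, function(ch)
        max(panel$sites$pos[panel$sites$chrom == ch]), numeric(1)))
  }
  decay <- vapply(chroms, function(ch) {
    fit <- tryCatch({
      pr <- pairwise_r2(panel, chrom = ch, max_dist_bp = max_dist_bp)
      suppressWarnings(fit_ld_decay(pr, n = length(panel$samples),
                                    baseline = baseline))
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$reached) NA_real_ else fit$decay_distance
  }, numeric(1))
  size <- chrom_sizes$size_bp[match(chroms, chrom_sizes$chrom)]
  out <- data.frame(chromosome = chroms,
                    chromosome_size_mb = size / 1e6,
                    decay_distance_mb = decay / 1e6)
  rownames(out) <- NULL
  ok <- !is.na(out$decay_distance_mb)
  attr(out, "mean_decay_mb") <- if (any(ok)) mean(out$decay_distance_mb[ok]) else NA_real_
  attr(out, "size_decay_r2") <- if (sum(ok) >= 2 &&
                                    stats::sd(out$chromosome_size_mb[ok]) > 0 &&
                                    stats::sd(out$decay_distance_mb[ok]) > 0) {
    stats::cor(out$chromosome_size_mb[ok], out$decay_distance_mb[ok])^2
  } else NA_real_
  out
}
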