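# shared fixtures and independent brute-force oracles

make_panel <- function(geno, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                       samples = NULL, vtype = "SNP") {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(geno)))
  if (is.null(chrom)) chrom <- rep("chr01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  genotype_panel(samples,
                 data.frame(chrom = chrom, pos = pos, id = rep(".", m),
                            ref = ref, alt = alt,
                            vtype = rep(vtype, length.out = m),
                            stringsAsFactors = FALSE),
                 geno)
}

random_panel <- function(n, m, missing_rate = 0.1, het_rate = 0.1) {
  codes <- sample(c(0L, 2L), n * m, replace = TRUE)
  flip <- runif(n * m)
  codes[flip < het_rate] <- 1L
  codes[flip > 1 - missing_rate] <- -1L
  make_panel(matrix(codes, nrow = n),
             pos = sort(sample.int(1e6, m)))
}

write_tiny_vcf <- function(path, records, samples = "S01",
                           gts = NULL) {
  # records: data.frame chrom, pos, ref, alt, info; gts: matrix records x samples
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  if (is.null(gts)) gts <- matrix("0/0", nrow(records), length(samples))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", ".",
            if (is.null(records$info)) "." else records$info[i],
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# site-by-site double-loop IBS oracle
ibs_oracle <- function(panel) {
  G <- panel$geno
  n <- nrow(G)
  sim <- matrix(NA_real_, n, n)
  shared <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0; tot <- 0
    for (k in seq_len(ncol(G))) {
      gi <- G[i, k]; gj <- G[j, k]
      if (gi != -1L && gj != -1L) {
        tot <- tot + 1
        s <- s + (1 - abs(gi - gj) / 2)
      }
    }
    shared[i, j] <- tot
    sim[i, j] <- if (tot > 0) s / tot else NA_real_
  }
  list(sim = sim, n_shared = shared)
}

# per-pair Pearson correlation oracle with pairwise-complete observations
r2_oracle <- function(panel, max_dist_bp = 1e6) {
  G <- panel$geno
  pos <- panel$sites$pos
  out <- NULL
  for (i in seq_len(ncol(G) - 1)) for (j in (i + 1):ncol(G)) {
    d <- pos[j] - pos[i]
    if (d <= 0 || d > max_dist_bp) next
    x <- G[, i]; y <- G[, j]
    ok <- x != -1L & y != -1L
    r <- suppressWarnings(cor(x[ok], y[ok]))
    if (!is.na(r)) out <- rbind(out, data.frame(dist = d, r2 = r^2))
  }
  out
}

# column-loop p-distance oracle
pdist_oracle <- function(aln) {
  S <- aln$seqs
  n <- nrow(S)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    comp <- 0; mism <- 0
    for (k in seq_len(ncol(S))) {
      a <- S[i, k]; b <- S[j, k]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        comp <- comp + 1
        if (a != b) mism <- mism + 1
      }
    }
    if (comp > 0) d[i, j] <- mism / comp
  }
  d
}
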