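#' Read a VCF file into a genotype panel
#'
#' Imports biallelic records from a VCF 4.x file (plain or bgzip/gzip
#' compressed) into a [genotype_panel()]. GT values are coded as alternate
#' allele dosage; phased and unphased separators are treated identically and
#' any GT containing `.` codes as missing (`-1`). Records with multiple ALT
#' alleles, symbolic alleles (`<...>`), missing ALT, or a (chrom, pos) already
#' seen are skipped and counted in the `n_skipped` attribute of the result.
#' The INFO scalars QD, FS and MQ are parsed per site when present.
#'
#' @param path path to the VCF file.
#' @param region optional region string `"chrom"` or `"chrom:start-end"`
#'   (1-based, inclusive on both ends).
#' @return a [genotype_panel()] with attribute `n_skipped` (count of skipped
#'   records).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) {
    return(structure(genotype_panel(character(), empty_sites(), matrix(integer(), 0, 0)),
                     n_skipped = 0L))
  }
  fmt <- if (ncol(vcf@gt) >= 1) vcf@gt[, 1] else character()
  if (ncol(vcf@gt) < 2 || !all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF has no GT genotype field")
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  info <- fix[, "INFO"]

  biallelic <- !is.na(alt) & alt != "." & !grepl(",", alt, fixed = TRUE) &
    !grepl("[<>*]", alt) & !grepl("[<>*]", ref) & !is.na(ref) & ref != alt
  dup <- duplicated(paste(chrom, pos))
  keep <- biallelic & !dup
  n_skipped <- sum(!keep)

  if (!is.null(region)) {
    reg <- parse_region(region)
    inreg <- chrom == reg$chrom
    if (!is.na(reg$start)) inreg <- inreg & pos >= reg$start & pos <= reg$end
    keep <- keep & inreg
  }

  gt <- vcf@gt[, -1, drop = FALSE]
  samples <- colnames(gt)
  idx <- which(keep)
  gt <- gt[idx, , drop = FALSE]
  # first colon-separated field is GT (FORMAT validated above)
  gtf <- sub(":.*$", "", gt)
  gtf <- gsub("|", "/", gtf, fixed = TRUE)
  codes <- matrix(-1L, nrow = length(idx), ncol = length(samples))
  codes[gtf == "0/0" | gtf == "0"] <- 0L
  codes[gtf == "0/1" | gtf == "1/0"] <- 1L
  codes[gtf == "1/1" | gtf == "1"] <- 2L

  sites <- data.frame(
    chrom = chrom[idx], pos = pos[idx],
    id = ifelse(is.na(fix[idx, "ID"]), ".", fix[idx, "ID"]),
    ref = ref[idx], alt = alt[idx],
    vtype = ifelse(nchar(ref[idx]) == 1 & nchar(alt[idx]) == 1, "SNP", "INDEL"),
    qd = info_scalar(info[idx], "QD"),
    fs = info_scalar(info[idx], "FS"),
    mq = info_scalar(info[idx], "MQ"),
    stringsAsFactors = FALSE
  )
  panel <- genotype_panel(samples, sites, t(codes))
  attr(panel, "n_skipped") <- n_skipped
  panel
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), vtype = character(),
             qd = numeric(), fs = numeric(), mq = numeric(),
             stringsAsFactors = FALSE)
}

parse_region <- function(region) {
  if (grepl(":", region, fixed = TRUE)) {
    chrom <- sub(":.*$", "", region)
    span <- sub("^[^:]*:", "", region)
    parts <- strsplit(span, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed region: ", region)
    list(chrom = chrom, start = as.integer(parts[1]), end = as.integer(parts[2]))
  } else {
    list(chrom = region, start = NA_integer_, end = NA_integer_)
  }
}

info_scalar <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_real_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- suppressWarnings(as.numeric(sub(pat, "\\1",
    regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)))
  out
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a GT-only VCF preserving sample order, site order and genotype codes,
#' so that [read_vcf()] round-trips exactly. QD/FS/MQ values present in the
#' site table are written back into INFO. Output is gzip-compressed (vcfR
#' writer); name files `*.vcf.gz`.
#'
#' @param panel a [genotype_panel()].
#' @param path output path (`.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  s <- panel$sites
  info <- rep("", nrow(s))
  for (key in c("qd", "fs", "mq")) {
    val <- s[[key]]
    tag <- toupper(key)
    has <- !is.na(val)
    info[has] <- paste0(info[has], ifelse(nzchar(info[has]), ";", ""),
                        tag, "=", format(val[has], trim = TRUE))
  }
  info[!nzchar(info)] <- "."
  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos),
               ID = ifelse(is.na(s$id) | s$id == "", ".", s$id),
               REF = s$ref, ALT = s$alt, QUAL = ".", FILTER = ".", INFO = info)
  gt_str <- matrix("./.", nrow = nrow(s), ncol = length(panel$samples))
  g <- t(panel$geno)
  gt_str[g == 0L] <- "0/0"
  gt_str[g == 1L] <- "0/1"
  gt_str[g == 2L] <- "1/1"
  colnames(gt_str) <- panel$samples
  gt <- cbind(FORMAT = rep("GT", nrow(s)), gt_str)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
            "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
            "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  out <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Hard-filter variant sites on QD, FS and MQ
#'
#' Applies the standard hard-filter expressions
#' `QD < 26.0 || FS > 60.0 || MQ < 40.0` for SNPs and
#' `QD < 26.0 || FS > 200.0 || MQ < 40.0` for indels: a site FAILs if any
#' clause of its type's expression is true. All comparisons are strict, so
#' boundary values (QD = 26.0, FS = 60.0, MQ = 40.0) PASS. A clause whose
#' annotation is missing is treated as false (a site is never failed by an
#' unobserved annotation); sites with at least one missing annotation are
#' tallied in the `n_missing_info` attribute. Note the QD lower bound of 26
#' is unusually aggressive compared to common practice (QD < 2); it is
#' applied exactly as stated.
#'
#' @param sites site data frame (as in `panel$sites`) with columns `vtype`,
#'   `qd`, `fs`, `mq`.
#' @return character vector of `"PASS"`/`"FAIL"`, aligned with `sites` rows,
#'   with attribute `n_missing_info`.
#' @export
hard_filter <- function(sites) {
  if (is.list(sites) && inherits(sites, "genotype_panel")) sites <- sites$sites
  lt <- function(x, thr) !is.na(x) & x < thr
  gt <- function(x, thr) !is.na(x) & x > thr
  fs_thr <- ifelse(sites$vtype == "INDEL", 200, 60)
  fail <- lt(sites$qd, 26) | gt(sites$fs, fs_thr) | lt(sites$mq, 40)
  flags <- ifelse(fail, "FAIL", "PASS")
  attr(flags, "n_missing_info") <-
    sum(is.na(sites$qd) | is.na(sites$fs) | is.na(sites$mq))
  flags
}

#' Assign deterministic SNP identifiers
#'
#' Sets every site id to `"<chrom>_<pos>_<ref>_<alt>"`. The scheme is
#' deterministic, unique within a panel (no duplicate (chrom, pos) pairs by
#' invariant) and idempotent.
#'
#' @param panel a [genotype_panel()].
#' @return the panel with ids assigned.
#' @export
assign_snp_ids <- function(panel) {
  s <- panel$sites
  panel$sites$id <- paste(s$chrom, s$pos, s$ref, s$alt, sep = "_")
  panel
}
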