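#' Thin sites at a fixed step
#'
#' Keeps every `step`-th site in genomic order starting from `offset`
#' (0-based), the standard way to cut a dense common-SNP set down to an
#' alignment size that tree builders handle comfortably.
#'
#' @param panel a [genotype_panel()].
#' @param step keep one site in `step` (default 5).
#' @param offset 0-based index of the first kept site.
#' @param drop_invariant also drop sites with no genotype variation among
#'   non-missing calls (default FALSE).
#' @return the thinned [genotype_panel()].
#' @export
thin_sites <- function(panel, step = 5, offset = 0, drop_invariant = FALSE) {
  stopifnot(step >= 1, offset >= 0)
  m <- n_sites(panel)
  idx <- seq.int(offset + 1L, m, by = step)
  out <- subset_sites(panel, idx)
  if (drop_invariant) {
    varying <- apply(out$geno, 2, function(g) {
      g <- g[g != -1L]
      length(unique(g)) > 1
    })
    out <- subset_sites(out, which(varying))
  }
  out
}

IUPAC_HET <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", GT = "K", TG = "K",
               AC = "M", CA = "M", AT = "W", TA = "W", CG = "S", GC = "S")

#' Build a concatenated SNP alignment from a panel
#'
#' One alignment column per site: code 0 becomes the ref base, 2 the alt
#' base, -1 becomes `N`, and heterozygotes become the IUPAC ambiguity code of
#' the two alleles (`het_policy = "iupac"`) or `N` (`"missing"`).
#'
#' @param panel a [genotype_panel()] whose sites have single-base ref/alt.
#' @param het_policy `"iupac"` or `"missing"`.
#' @return an object of class `"snp_alignment"`: list with `labels`, `seqs`
#'   (character matrix, samples x columns) and `length`.
#' @export
panel_to_alignment <- function(panel, het_policy = c("iupac", "missing")) {
  het_policy <- match.arg(het_policy)
  s <- panel$sites
  if (any(nchar(s$ref) != 1 | nchar(s$alt) != 1)) {
    stop("alignment requires single-base ref/alt at every site")
  }
  nsamp <- length(panel$samples)
  refm <- matrix(rep(s$ref, each = nsamp), nrow = nsamp)
  altm <- matrix(rep(s$alt, each = nsamp), nrow = nsamp)
  hetc <- IUPAC_HET[paste0(s$ref, s$alt)]
  hetm <- matrix(rep(unname(hetc), each = nsamp), nrow = nsamp)
  seqs <- refm
  seqs[panel$geno == 2L] <- altm[panel$geno == 2L]
  seqs[panel$geno == -1L] <- "N"
  seqs[panel$geno == 1L] <-
    if (het_policy == "iupac") hetm[panel$geno == 1L] else "N"
  rownames(seqs) <- panel$samples
  structure(list(labels = panel$samples, seqs = seqs, length = ncol(seqs)),
            class = "snp_alignment")
}

#' @export
print.snp_alignment <- function(x, ...) {
  cat(sprintf("snp_alignment: %d sequences x %d characters\n",
              length(x$labels), x$length))
  invisible(x)
}

#' Write / read a SNP alignment as FASTA
#' @param aln an [panel_to_alignment()] result.
#' @param path FASTA file path.
#' @return `path` invisibly; `read_alignment_fasta` returns a
#'   `snp_alignment`.
#' @export
write_alignment_fasta <- function(aln, path) {
  m <- tolower(aln$seqs)
  rownames(m) <- aln$labels
  ape::write.FASTA(ape::as.DNAbin(m), path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(bin)))
  structure(list(labels = rownames(m), seqs = m, length = ncol(m)),
            class = "snp_alignment")
}

#' Uncorrected p-distance matrix from a SNP alignment
#'
#' Pairwise mismatch fraction over columns where both sequences carry an
#' unambiguous base (A, C, G or T); columns with `N` or an IUPAC ambiguity
#' code in either sequence are excluded from both numerator and denominator.
#' Pairs with zero comparable columns get `NA` and are flagged.
#'
#' @param aln an [panel_to_alignment()] result (>= 3 sequences).
#' @return symmetric numeric matrix with attribute `n_incomparable_pairs`.
#' @export
p_distance_matrix <- function(aln) {
  if (length(aln$labels) < 3) stop("need >= 3 sequences")
  S <- toupper(aln$seqs)
  V <- (S %in% c("A", "C", "G", "T")) * 1
  dim(V) <- dim(S)
  n_comp <- V %*% t(V)
  matches <- matrix(0, nrow(S), nrow(S))
  for (b in c("A", "C", "G", "T")) {
    X <- (S == b) * 1
    dim(X) <- dim(S)
    matches <- matches + X %*% t(X)
  }
  d <- ifelse(n_comp > 0, (n_comp - matches) / n_comp, NA_real_)
  dimnames(d) <- list(aln$labels, aln$labels)
  attr(d, "n_incomparable_pairs") <- sum(is.na(d[upper.tri(d)]))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; negative branch lengths arising from noisy
#' distances are clamped to zero and tallied in the `n_clamped` attribute.
#' On an additive distance matrix the generating topology and branch lengths
#' are recovered exactly.
#'
#' @param d symmetric non-negative distance matrix (no `NA`).
#' @return a rooted-unrooted `phylo` tree (class from \pkg{ape}) with
#'   attribute `n_clamped`.
#' @export
nj_tree <- function(d) {
  if (anyNA(d)) stop("distance matrix contains NA (incomparable pairs)")
  tree <- ape::nj(stats::as.dist(d))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Root a tree on the branch separating two groups
#'
#' Scans every branch of the unrooted tree for the bipartition that best
#' separates the two groups (e.g. wild vs cultivated species), i.e. the
#' branch minimising the number of leaves on the "wrong" side; ties are
#' broken by the longest branch. The tree is rooted on that branch and the
#' residual mixing count (0 when the groups are cleanly separable) is
#' attached.
#'
#' @param tree a `phylo` tree.
#' @param group_map named character vector: group label per leaf; exactly two
#'   distinct labels, both non-empty on the tree.
#' @return rooted `phylo` with attributes `mixing_count` and `root_groups`.
#' @export
root_between_groups <- function(tree, group_map) {
  tips <- tree$tip.label
  g <- unname(group_map[tips])
  if (anyNA(g)) stop("group_map missing for: ",
                     paste(tips[is.na(g)], collapse = ", "))
  lev <- unique(g)
  if (length(lev) != 2) stop("need exactly two non-empty groups, got ",
                             length(lev))
  ntip <- length(tips)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; ch <- po$edge[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  in1 <- g == lev[1]
  n1 <- sum(in1); n2 <- ntip - n1
  mix <- numeric(nrow(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {
    clade <- desc[[tree$edge[r, 2]]]
    a <- sum(in1[clade]); b <- length(clade) - a
    # wrong-side count if clade is group 1 vs if clade is group 2
    mix[r] <- min((n1 - a) + b, a + (n2 - b))
  }
  best <- which(mix == min(mix))
  if (length(best) > 1) best <- best[which.max(tree$edge.length[best])]
  clade_tips <- tips[desc[[tree$edge[best, 2]]]]
  if (length(clade_tips) == ntip) stop("separating branch is the root edge")
  rooted <- ape::root(tree, outgroup = clade_tips, resolve.root = TRUE)
  attr(rooted, "mixing_count") <- min(mix)
  attr(rooted, "root_groups") <- lev
  rooted
}

#' Tag labels with country of origin
#'
#' Appends `"|<country>"` to every sample label of an alignment or tree,
#' looking countries up in a metadata table; samples without a metadata row
#' get `"|NA"`. The original labels are stored so [unlabel_origin()] can
#' restore them.
#'
#' @param x a `snp_alignment` or `phylo` object.
#' @param metadata data frame with columns `sample_id` and `country`.
#' @return the relabelled object, with attribute `label_map` (named vector
#'   old -> new).
#' @export
label_with_origin <- function(x, metadata) {
  labels <- if (inherits(x, "phylo")) x$tip.label else x$labels
  country <- metadata$country[match(labels, metadata$sample_id)]
  country[is.na(country)] <- "NA"
  new <- paste0(labels, "|", country)
  map <- stats::setNames(new, labels)
  if (inherits(x, "phylo")) {
    x$tip.label <- new
  } else {
    x$labels <- new
    rownames(x$seqs) <- new
  }
  attr(x, "label_map") <- map
  x
}

#' @rdname label_with_origin
#' @export
unlabel_origin <- function(x) {
  map <- attr(x, "label_map")
  if (is.null(map)) return(x)
  restore <- stats::setNames(names(map), unname(map))
  if (inherits(x, "phylo")) {
    x$tip.label <- unname(restore[x$tip.label])
  } else {
    x$labels <- unname(restore[x$labels])
    rownames(x$seqs) <- x$labels
  }
  attr(x, "label_map") <- NULL
  x
}
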