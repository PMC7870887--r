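test_that("site thinning keeps every step-th site from the offset", {
  p <- make_panel(matrix(0L, 1, 10))
  expect_equal(n_sites(thin_sites(p, step = 5, offset = 0)), 2)
  expect_equal(thin_sites(p, step = 5, offset = 4)$sites$pos,
               p$sites$pos[c(5, 10)])
  expect_identical(thin_sites(p, step = 1)$sites, p$sites)
  # a common-set-sized panel thins with ceiling arithmetic
  big <- make_panel(matrix(0L, 1, 25496), pos = seq_len(25496))
  expect_equal(n_sites(thin_sites(big, step = 5)), 5100)
})

test_that("alignment encodes dosage as bases with IUPAC or N hets", {
  p <- make_panel(matrix(c(0L, 2L, 1L, -1L), ncol = 1),
                  ref = "A", alt = "G")
  aln <- panel_to_alignment(p, het_policy = "iupac")
  expect_equal(unname(aln$seqs[, 1]), c("A", "G", "R", "N"))
  aln2 <- panel_to_alignment(p, het_policy = "missing")
  expect_equal(unname(aln2$seqs[, 1]), c("A", "G", "N", "N"))
  # all-missing sample is all N; length equals site count
  q <- make_panel(rbind(c(-1L, -1L, -1L), c(0L, 1L, 2L)),
                  ref = c("A", "C", "T"), alt = c("G", "T", "C"))
  alnq <- panel_to_alignment(q)
  expect_equal(unname(alnq$seqs[1, ]), c("N", "N", "N"))
  expect_equal(alnq$length, 3)
  expect_equal(unname(alnq$seqs[2, ]), c("A", "Y", "C"))
})

test_that("alignment round-trips through FASTA", {
  set.seed(37)
  p <- random_panel(5, 40)
  aln <- panel_to_alignment(p)
  path <- withr::local_tempfile(fileext = ".fna")
  write_alignment_fasta(aln, path)
  back <- read_alignment_fasta(path)
  expect_equal(back$labels, aln$labels)
  expect_equal(unname(back$seqs), unname(aln$seqs))
})

test_that("p-distance matches hand counts and excludes N columns", {
  aln <- structure(list(labels = c("a", "b", "c"),
                        seqs = rbind(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "A"),
                                     c("A", "N", "G", "T")),
                        length = 4), class = "snp_alignment")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)     # 3 comparable columns, all equal
  expect_equal(d["b", "c"], 1 / 3)
  expect_equal(d, t(d))
})

test_that("p-distance equals the column-loop oracle", {
  set.seed(41)
  p <- random_panel(10, 100)
  aln <- panel_to_alignment(p)
  expect_equal(unname(p_distance_matrix(aln)), pdist_oracle(aln),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NJ recovers additive trees exactly", {
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- cophenetic(ref)
  tree <- nj_tree(d)
  expect_equal(attr(tree, "n_clamped"), 0)
  expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  # branch lengths reproduce the generating distances
  expect_equal(cophenetic(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # random 5-taxon trees with positive branch lengths
  set.seed(43)
  for (rep in 1:10) {
    t5 <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    d5 <- cophenetic(t5)
    got <- nj_tree(d5)
    expect_equal(ape::dist.topo(ape::unroot(t5), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
    expect_equal(cophenetic(got)[rownames(d5), colnames(d5)], d5,
                 tolerance = 1e-10)
  }
})

test_that("NJ is invariant to taxon input order", {
  set.seed(47)
  t6 <- ape::rtree(6, br = function(n) runif(n, 0.5, 2))
  d <- cophenetic(t6)
  perm <- sample(rownames(d))
  a <- nj_tree(d)
  b <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(a), ape::unroot(b)), 0,
               ignore_attr = TRUE)
})

test_that("rooting between groups finds the separating branch", {
  tree <- ape::read.tree(
    text = "(((m1:1,m2:1):1,m3:2):3,((s1:1,s2:1):1,s3:2):3);")
  groups <- c(m1 = "max", m2 = "max", m3 = "max",
              s1 = "soja", s2 = "soja", s3 = "soja")
  rooted <- root_between_groups(ape::unroot(tree), groups)
  expect_equal(attr(rooted, "mixing_count"), 0)
  expect_true(ape::is.rooted(rooted))
  # each species side is monophyletic in the rooted tree
  expect_true(ape::is.monophyletic(rooted, c("m1", "m2", "m3")))
  expect_true(ape::is.monophyletic(rooted, c("s1", "s2", "s3")))
  # a leaf nested inside the other group's clade forces a mixing count of 1
  groups2 <- groups; groups2["m1"] <- "soja"
  rooted2 <- root_between_groups(ape::unroot(tree), groups2)
  expect_equal(attr(rooted2, "mixing_count"), 1)
  # single-group input is an error
  expect_error(root_between_groups(ape::unroot(tree),
                                   setNames(rep("max", 6), names(groups))),
               "two")
})

test_that("origin tags append and strip reversibly", {
  meta <- data.frame(sample_id = c("PI483463", "S02"),
                     country = c("China", "Korea"),
                     stringsAsFactors = FALSE)
  p <- make_panel(matrix(0L, 3, 2),
                  samples = c("PI483463", "S02", "PI999999"))
  aln <- panel_to_alignment(p)
  tagged <- label_with_origin(aln, meta)
  expect_equal(tagged$labels,
               c("PI483463|China", "S02|Korea", "PI999999|NA"))
  expect_equal(unlabel_origin(tagged)$labels, aln$labels)
  tree <- nj_tree(p_distance_matrix(panel_to_alignment(random_panel(4, 30))))
  tree$tip.label <- c("PI483463", "S02", "PI999999", "X")
  tagged_tree <- label_with_origin(tree, meta)
  expect_equal(sort(tagged_tree$tip.label),
               sort(c("PI483463|China", "S02|Korea", "PI999999|NA", "X|NA")))
  expect_equal(sort(unlabel_origin(tagged_tree)$tip.label),
               sort(tree$tip.label))
})
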