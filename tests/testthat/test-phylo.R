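test_that("p-distance counts mismatches over comparable sites", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "ACGT", b = "TGCA"))["a", "b"], 1)
  # 8 comparable sites, 2 mismatches
  d <- p_distance(c(a = "AAAAAAAA", b = "AATTAAAA"))
  expect_equal(d["a", "b"], 0.25)
  # gaps excluded pairwise
  d <- p_distance(c(a = "A-GT", b = "ACGA"))
  expect_equal(d["a", "b"], 1 / 3)
  expect_error(p_distance(c(a = "--AA", b = "GG--")),
               "no comparable sites")
})

test_that("p-distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    aln <- setNames(replicate(n, paste(sample(c("A", "C", "G", "T"), 30,
                                              TRUE), collapse = "")),
                    paste0("s", seq_len(n)))
    d <- p_distance(aln)
    expect_equal(unname(d), unname(t(d)))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("neighbor joining solves the three- and four-taxon cases", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  # branch to A = (dAB + dAC - dBC)/2 = 1
  expect_equal(tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")], 1)
  expect_equal(tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "B")], 2)
  expect_equal(tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "C")], 3)

  # additive matrix from ((A:1,B:2):1,(C:3,D:4))
  ids <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
               dimnames = list(ids, ids))
  tr4 <- neighbor_joining(d4)
  expect_equal(max(abs(ape::cophenetic.phylo(tr4)[ids, ids] - d4)), 0,
               tolerance = 1e-9)
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(gen), tr4), 0,
               ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(42)
  for (i in 1:12) {
    case <- random_additive_case(sample(4:12, 1))
    tr <- neighbor_joining(case$d)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), tr), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(case$d),
                                                colnames(case$d)] -
                        case$d)), 1e-8)
    # independent cross-check against ape's implementation
    expect_equal(ape::dist.topo(tr, ape::unroot(ape::nj(case$d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are reproducible and saturate on clean clades", {
  aln <- c(A = "AAAAAAGG", B = "AAAAAAGC", C = "CCCCCCAA",
           D = "CCCCCCAT", E = "GTGTGTGT")
  b1 <- bootstrap_support(aln, n_reps = 30, seed = 9)
  b2 <- bootstrap_support(aln, n_reps = 30, seed = 9)
  expect_identical(b1$node.label, b2$node.label)
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  # a single replicate can only give 0 or 100
  b3 <- bootstrap_support(aln, n_reps = 1, seed = 1)
  s3 <- suppressWarnings(as.numeric(b3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("paralog pairs are supported cherries, each leaf used once", {
  tr <- ape::read.tree(text = "((A:1,B:1)95:1,(C:1,D:1)40:1,(E:1,F:2)77:1);")
  pp <- extract_paralog_pairs(tr, min_support = 50)
  expect_equal(nrow(pp), 2L)
  expect_true(all(pp$gene_a == c("A", "E") | pp$gene_a == c("E", "A")))
  expect_equal(sort(c(pp$gene_a, pp$gene_b)), c("A", "B", "E", "F"))
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(nrow(extract_paralog_pairs(star)), 0L)
})

test_that("paralog pairs recover planted recent duplications", {
  cfg <- sim_config(seed = 8, n_codons = 200,
                    duplication_mya = c(40, 40, 1))
  fam <- simulate_family(cfg)
  aln <- setNames(fam$cds, names(fam$cds)) # equal-length, ungapped
  tree <- bootstrap_support(aln, n_reps = 20, seed = 8)
  pp <- extract_paralog_pairs(tree, min_support = 50)
  recent <- fam$truth[which.min(fam$truth$split_mya), ]
  hit <- any(pp$gene_a == min(recent$gene_a, recent$gene_b) &
               pp$gene_b == max(recent$gene_a, recent$gene_b))
  expect_true(hit)
})

test_that("percent identity uses pairwise deletion", {
  expect_equal(percent_identity(c(a = "MKV", b = "MKV"), c("a", "b")), 100)
  expect_equal(percent_identity(c(a = "MKVA", b = "MKVT"), c("a", "b")), 75)
  expect_error(percent_identity(c(a = "M--", b = "-KV"), c("a", "b")),
               "no comparable sites")
})

test_that("subgroup assignment cuts the deepest edges first", {
  tr <- ape::read.tree(
    text = "((A:0.1,B:0.1):5,(C:0.1,D:0.1):5,(E:0.1,F:0.1):5);")
  expect_equal(length(unique(assign_subgroups(tr, 1))), 1L)
  sg3 <- assign_subgroups(tr, 3)
  expect_true(same_partition(sg3, c(A = 1, B = 1, C = 2, D = 2,
                                    E = 3, F = 3)[names(sg3)]))
  sg6 <- assign_subgroups(tr, 6)
  expect_equal(length(unique(sg6)), 6L)
  expect_error(assign_subgroups(tr, 7), "between 1 and")
})

test_that("newick round-trip preserves topology, lengths and supports", {
  aln <- c(A = "AAAAAAGG", B = "AAAAAAGC", C = "CCCCCCAA",
           D = "CCCCCCAT", E = "GTGTGTGT")
  tr <- bootstrap_support(aln, n_reps = 10, seed = 2)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
  expect_setequal(back$node.label, tr$node.label)
})
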