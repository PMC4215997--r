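toy_matrix <- function() {
  m <- rbind(g1 = c(10, 1, 1, 2),
             g2 = c(9, 2, 1, 1),
             g3 = c(1, 10, 9, 1),
             g4 = c(2, 8, 10, 2))
  colnames(m) <- paste0("t", 1:4)
  expression_matrix(m, state = "rpkm")
}

# members of the k-th merged cluster, as tip index lists
cut_members <- function(hc, k) {
  grab <- function(x) {
    if (x < 0) return(-x)
    c(grab(hc$merge[x, 1]), grab(hc$merge[x, 2]))
  }
  list(grab(k))
}

test_that("RPKM normalization is direct arithmetic", {
  m <- expression_matrix(matrix(c(10, 0), 1, 2,
                                dimnames = list("g", c("a", "b"))),
                         state = "raw_counts")
  out <- rpkm_normalize(m, c(g = 2000), 1e6)
  expect_equal(unname(unclass(out)["g", ]), c(5, 0))
  expect_equal(attr(out, "state"), "rpkm")
  expect_error(rpkm_normalize(m, c(g = 0), 1e6), "lengths must be > 0")
  expect_error(rpkm_normalize(m, c(other = 2000), 1e6), "missing gene length")
})

test_that("RPKM commutes with reordering and scales with library size", {
  set.seed(5)
  counts <- matrix(rpois(20, 50), 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  m <- expression_matrix(counts, "raw_counts")
  len <- setNames(runif(5, 500, 3000), rownames(counts))
  lib <- setNames(runif(4, 1e6, 5e6), colnames(counts))
  r1 <- rpkm_normalize(m, len, lib)
  perm <- c(3, 1, 5, 2, 4)
  m2 <- expression_matrix(counts[perm, ], "raw_counts")
  r2 <- rpkm_normalize(m2, len, lib)
  expect_equal(unclass(r2), unclass(r1)[perm, ], ignore_attr = TRUE)
  r3 <- rpkm_normalize(m, len, 2 * lib)
  expect_equal(unclass(r3), unclass(r1) / 2, ignore_attr = TRUE)
})

test_that("expressed filter keeps genes with any signal", {
  z <- expression_matrix(matrix(0, 2, 2,
                                dimnames = list(c("a", "b"), c("x", "y"))),
                         "rpkm")
  expect_equal(expressed_filter(z), character(0))
  m <- unclass(z)
  m["b", "y"] <- 3
  expect_equal(expressed_filter(expression_matrix(m, "rpkm")), "b")
})

test_that("average-linkage clustering matches a brute-force agglomeration", {
  m <- toy_matrix()
  dend <- hierarchical_cluster(m, "pearson", "average")
  # brute force: start from singletons, repeatedly merge the closest
  # pair under average linkage over the original 1 - cor distances
  d0 <- as.matrix(1 - cor(t(unclass(m))))
  clusters <- as.list(rownames(m))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d0[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]],
                                           clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(dend$hclust$height, heights, tolerance = 1e-12)
  # same member sets at each merge step
  got <- lapply(seq_len(nrow(dend$hclust$merge)), function(k)
    sort(dend$ids[unlist(cut_members(dend$hclust, k))]))
  expect_equal(got, merges)
})

test_that("pearson dendrograms ignore positive row scaling", {
  m <- toy_matrix()
  d1 <- hierarchical_cluster(m, "pearson", "average")
  m2 <- unclass(m)
  m2["g1", ] <- m2["g1", ] * 7.5
  d2 <- hierarchical_cluster(expression_matrix(m2, "rpkm"),
                             "pearson", "average")
  expect_equal(d1$hclust$height, d2$hclust$height, tolerance = 1e-12)
  expect_equal(d1$hclust$merge, d2$hclust$merge)
})

test_that("clustering is invariant to condition order and flags constants", {
  m <- toy_matrix()
  d1 <- hierarchical_cluster(m, "pearson", "average")
  m2 <- expression_matrix(unclass(m)[, c(3, 1, 4, 2)], "rpkm")
  d2 <- hierarchical_cluster(m2, "pearson", "average")
  expect_equal(d1$hclust$height, d2$hclust$height, tolerance = 1e-12)
  bad <- unclass(m)
  bad["g2", ] <- 4
  expect_error(hierarchical_cluster(expression_matrix(bad, "rpkm")),
               "constant row.*g2")
})

test_that("dendrogram heights are monotone for average and complete linkage", {
  set.seed(19)
  for (link in c("average", "complete")) {
    m <- expression_matrix(
      matrix(runif(60, 0, 50), 10, 6,
             dimnames = list(paste0("g", 1:10), paste0("c", 1:6))), "rpkm")
    dend <- hierarchical_cluster(m, "euclidean", link)
    expect_true(all(diff(dend$hclust$height) >= -1e-12))
  }
})

test_that("identical rows merge at height zero and cuts relabel in order", {
  raw <- rbind(a = c(1, 5, 2), b = c(1, 5, 2), c = c(9, 1, 4))
  colnames(raw) <- paste0("t", 1:3)
  m <- expression_matrix(raw, "rpkm")
  dend <- hierarchical_cluster(m, "pearson", "average")
  expect_equal(min(dend$hclust$height), 0)
  expect_equal(unname(cut_clusters(dend, 1)), c(1L, 1L, 1L))
  expect_equal(unname(cut_clusters(dend, 3)), c(1L, 2L, 3L))
  cl2 <- cut_clusters(dend, 2)
  expect_equal(unname(cl2), c(1L, 1L, 2L)) # labels by first appearance
  expect_error(cut_clusters(dend, 4), "between 1")
})
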