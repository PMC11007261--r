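test_that("rarefaction subsamples without replacement to exact depth", {
  ft <- random_table(5, 12, depth = 300, seed = 4)
  r <- rarefy(ft, 300, seed = 1)
  expect_identical(r + 0, ft + 0)  # full-depth rarefaction is the identity

  one <- matrix(c(10L, 0L), 1, 2, dimnames = list("S1", c("A", "B")))
  expect_equal(unname(rarefy(one, 5, seed = 1)[1, ]), c(5, 0))

  # hypergeometric oracle: depth 2 from [1,1,1] keeps each pair w.p. 1/3
  m <- matrix(c(1L, 1L, 1L), 1, 3, dimnames = list("S1", c("A", "B", "C")))
  pairs <- vapply(1:1000, function(s) {
    r <- rarefy(m, 2, seed = s)
    paste(colnames(m)[r[1, ] > 0], collapse = "")
  }, character(1))
  freq <- table(factor(pairs, levels = c("AB", "AC", "BC"))) / 1000
  expect_true(all(abs(freq - 1 / 3) < 0.05))

  mixed <- rbind(ft, low = c(5L, rep(0L, 11)))
  rownames(mixed)[6] <- "low"
  expect_message(r2 <- rarefy(mixed, 300, seed = 1), "dropping")
  expect_false("low" %in% rownames(r2))
  expect_error(rarefy(ft, 0), class = "config_error")
  expect_error(rarefy(ft, 1e6), class = "empty_table_error")
})

test_that("alpha metrics match their closed forms", {
  x <- c(5, 1, 1, 2, 3)  # S=5, F1=2, F2=1
  expect_equal(alpha(x, "chao1"), 7.0)
  expect_equal(alpha(x, "chao1", chao1_variant = "bias_corrected"),
               5 + 2 * 1 / (2 * 2))
  expect_equal(alpha(rep(25, 4), "shannon"), 2.0)
  expect_equal(alpha(rep(25, 4), "shannon", base = exp(1)), log(4))
  expect_equal(alpha(c(97, 1, 1, 1), "goods_coverage"), 0.97)
  expect_equal(alpha(c(50, 50), "simpson"), 0.5)
  expect_equal(alpha(x, "observed"), 5)
  # F2 = 0 falls back to the bias-corrected form
  expect_equal(alpha(c(5, 1, 1), "chao1"), 3 + 2 * 1 / 2)
  expect_error(alpha(c(0, 0), "shannon"), class = "undefined_metric_error")

  # invariants over random samples
  for (s in 1:20) {
    v <- random_table(1, 30, depth = 200, seed = s)[1, ]
    expect_gte(alpha(v, "chao1"), alpha(v, "observed"))
    expect_true(alpha(v, "simpson") >= 0 && alpha(v, "simpson") <= 1)
    expect_true(alpha(v, "goods_coverage") >= 0 &&
                  alpha(v, "goods_coverage") <= 1)
    expect_gte(alpha(v, "shannon"), 0)
  }
})

test_that("taxonomy-based beta metrics match set/abundance formulas", {
  ft <- rbind(S1 = c(A = 2L, B = 3L, C = 0L), S2 = c(A = 0L, B = 1L, C = 4L))
  j <- beta(ft, "jaccard")
  expect_equal(j["S1", "S2"], 2 / 3)
  bc <- beta(ft, "bray_curtis")
  expect_equal(bc["S1", "S2"], (2 + 2 + 4) / (2 + 4 + 4))
  same <- rbind(S1 = c(A = 1L, B = 2L), S2 = c(A = 1L, B = 2L))
  expect_true(all(beta(same, "jaccard") == 0))
  expect_true(all(beta(same, "bray_curtis") == 0))
})

test_that("UniFrac on a unit star tree matches hand computation", {
  star <- read_newick(text = "(A:1,B:1,C:1);")
  ft <- rbind(S1 = c(A = 10L, B = 0L, C = 0L),
              S2 = c(A = 0L, B = 10L, C = 0L))
  expect_equal(beta(ft, "unweighted_unifrac", tree = star)["S1", "S2"], 1.0)
  expect_equal(beta(ft, "weighted_unifrac", tree = star)["S1", "S2"], 2.0)
  expect_error(beta(ft, "unweighted_unifrac"), class = "config_error")
  ft2 <- cbind(ft, D = c(1L, 1L))
  expect_error(beta(ft2, "unweighted_unifrac", tree = star),
               class = "mapping_error")
})

test_that("UniFrac equals the edge-enumeration oracle on random trees", {
  set.seed(99)
  for (case in 1:60) {
    tree <- ape::rtree(8)
    tree$tip.label <- sprintf("T%03d", 1:8)
    ft <- random_table(3, 8, depth = 60, seed = case)
    colnames(ft) <- tree$tip.label
    uf <- beta(ft, "unweighted_unifrac", tree = tree)
    wf <- beta(ft, "weighted_unifrac", tree = tree)
    ra <- relative_abundance(ft)
    for (i in 1:2) for (j in (i + 1):3) {
      pa <- colnames(ft)[ft[i, ] > 0]
      pb <- colnames(ft)[ft[j, ] > 0]
      expect_equal(uf[i, j], oracle_unifrac(tree, pa, pb), tolerance = 1e-10)
      expect_equal(wf[i, j],
                   oracle_unifrac(tree, weighted = TRUE,
                                  ra_a = ra[i, ], ra_b = ra[j, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("PCoA reproduces Euclidean-embeddable geometry", {
  tri <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(tri) <- 0
  res <- pcoa(tri)
  ev <- res$eigenvalues[res$eigenvalues > 1e-9]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(unname(rec), unname(tri), tolerance = 1e-9)

  line <- as.matrix(dist(c(a = 0, b = 1, c = 2)))
  res2 <- pcoa(line)
  expect_equal(res2$proportion_explained[1], 1, tolerance = 1e-9)

  dup <- random_dm(4, seed = 7)
  dup["L02", ] <- dup["L01", ]; dup[, "L02"] <- dup[, "L01"]
  dup["L01", "L02"] <- dup["L02", "L01"] <- 0
  res3 <- pcoa(dup)
  expect_equal(res3$coordinates["L01", ], res3$coordinates["L02", ],
               tolerance = 1e-9)
})

test_that("beta metrics obey symmetry, zero diagonal, and range invariants", {
  tree <- simulate_microbial_tree(12, seed = 3)
  ft <- random_table(6, 12, depth = 400, seed = 8)
  colnames(ft) <- tree$tip.label
  for (m in c("jaccard", "bray_curtis", "unweighted_unifrac",
              "weighted_unifrac")) {
    d <- beta(ft, m, tree = tree)
    expect_true(all(abs(d - t(d)) < 1e-12))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    if (m != "weighted_unifrac") expect_true(all(d <= 1 + 1e-12))
  }
  # PCoA round-trip on a non-negative-definite-safe matrix
  d <- beta(ft, "jaccard")
  res <- pcoa(d)
  if (all(res$eigenvalues >= -1e-9)) {
    rec <- as.matrix(dist(res$coordinates))
    expect_equal(unname(rec), unname(d), tolerance = 1e-6)
  }
})
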