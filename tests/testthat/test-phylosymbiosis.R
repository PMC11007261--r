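test_that("population representatives average or pick relative abundances", {
  ft <- rbind(a1 = c(X = 1L, Y = 0L), a2 = c(X = 0L, Y = 1L),
              b1 = c(X = 4L, Y = 4L))
  mapping <- c(a1 = "A", a2 = "A", b1 = "B")
  reps <- population_representatives(ft, mapping)
  expect_equal(unname(reps["A", ]), c(0.5, 0.5))
  expect_equal(unname(reps["B", ]), c(0.5, 0.5))
  # single-sample population: either mode returns that sample's profile
  pick <- population_representatives(ft, mapping, "random_pick", seed = 3)
  expect_equal(unname(pick["B", ]), c(0.5, 0.5))
  expect_true(all(pick["A", ] %in% c(0, 1)))
  # two identical samples: mean equals either
  ft2 <- rbind(a1 = c(X = 2L, Y = 2L), a2 = c(X = 3L, Y = 3L))
  expect_equal(unname(population_representatives(
    ft2, c(a1 = "A", a2 = "A"))["A", ]), c(0.5, 0.5))
})

test_that("UPGMA agglomerates at half average-linkage height", {
  dm <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(dm)
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)
  expect_equal(coph["B", "C"], 6)
  # ultrametric: equal root-to-tip depths
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)

  # equal distances: all internal heights equal, deterministic topology
  eq <- matrix(4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  t1 <- upgma(eq); t2 <- upgma(eq)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(unname(ape::cophenetic.phylo(t1)[lower.tri(eq)]),
               rep(4, 6), tolerance = 1e-9)

  # ultrametric input round-trips through cophenetic distances
  set.seed(5)
  ut <- ape::rcoal(7)
  cd <- ape::cophenetic.phylo(ut)
  rec <- upgma(cd)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(cd), colnames(cd)], cd,
               tolerance = 1e-8)
  # idempotence: UPGMA -> cophenetic -> UPGMA
  rec2 <- upgma(ape::cophenetic.phylo(rec))
  expect_equal(ape::cophenetic.phylo(rec2)[rownames(cd), colnames(cd)], cd,
               tolerance = 1e-8)
})

test_that("UPGMA agrees with average-linkage hclust on generic input", {
  dm <- random_dm(8, seed = 6)
  tr <- upgma(dm)
  hc <- hclust(as.dist(dm), method = "average")
  expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)],
               as.matrix(cophenetic(hc))[rownames(dm), rownames(dm)],
               tolerance = 1e-9)
})

test_that("normalized RF matches known splits and the phangorn oracle", {
  t1 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds_normalized(t1, t1), 0)
  expect_equal(robinson_foulds_normalized(t1, t2), 1)

  set.seed(7)
  for (case in 1:30) {
    a <- ape::rtree(8); b <- ape::rtree(8)
    b$tip.label <- sample(a$tip.label)
    got <- robinson_foulds_normalized(a, b)
    expected <- phangorn::RF.dist(ape::unroot(a), ape::unroot(b)) /
      (2 * (8 - 3))
    expect_equal(got, expected)
  }
  t5 <- read_newick(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(robinson_foulds_normalized(t1, t5), class = "alignment_error")
})

test_that("random topologies are seeded, binary, and uniform at n = 4", {
  labs <- sprintf("P%02d", 1:6)
  tr <- random_topology(labs, seed = 2)
  expect_setequal(tr$tip.label, labs)
  expect_true(ape::is.binary(tr))
  expect_identical(ape::write.tree(random_topology(labs, seed = 9)),
                   ape::write.tree(random_topology(labs, seed = 9)))

  # the 3 unrooted 4-leaf topologies each appear ~1/3 of the time
  four <- c("A", "B", "C", "D")
  t_ab <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t_ac <- read_newick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  t_ad <- read_newick(text = "((A:1,D:1):1,(B:1,C:1):1);")
  refs <- list(t_ab, t_ac, t_ad)
  hits <- integer(3)
  for (k in 1:10000) {
    tr <- random_topology(four, seed = k)
    m <- which(vapply(refs, function(r)
      robinson_foulds_normalized(tr, r) == 0, logical(1)))
    hits[m] <- hits[m] + 1
  }
  expect_true(all(abs(hits / 10000 - 1 / 3) < 0.02))
})

test_that("phylosymbiosis test recovers a host-shaped dendrogram", {
  host <- simulate_host_tree(10, seed = 8)
  coph <- ape::cophenetic.phylo(host)
  res <- phylosymbiosis_test(host, beta_dm = coph, n_random = 500, seed = 1)
  expect_equal(res$rf_observed, 0)
  expect_equal(res$p, 1 / 501)

  # relabeling invariance
  relab <- setNames(sprintf("Q%02d", 1:10), host$tip.label)
  host2 <- host; host2$tip.label <- unname(relab[host$tip.label])
  coph2 <- coph; dimnames(coph2) <- list(relab[rownames(coph)],
                                         relab[colnames(coph)])
  res2 <- phylosymbiosis_test(host2, beta_dm = coph2, n_random = 500,
                              seed = 1)
  expect_equal(res2$rf_observed, res$rf_observed)
  expect_equal(res2$p, res$p)

  # 4-leaf support is {0, 0.5, 1}
  host4 <- simulate_host_tree(4, seed = 3)
  dm4 <- random_dm(4, seed = 4, labels = host4$tip.label)
  r4 <- phylosymbiosis_test(host4, beta_dm = dm4, n_random = 200, seed = 2)
  expect_true(r4$rf_observed %in% c(0, 0.5, 1))

  # random-pick mode reports the mean RF over replicate dendrograms
  ds <- simulate_communities(null_config(seed = 19))
  mapping <- setNames(ds$metadata$population, ds$metadata$sample_id)
  rp <- phylosymbiosis_test(ds$host_tree, table = ds$table,
                            mapping = mapping, metric = "bray_curtis",
                            mode = "random_pick", n_picks = 10,
                            n_random = 200, seed = 6)
  expect_length(rp$rf_replicates, 10)
  expect_equal(rp$rf_observed, mean(rp$rf_replicates))
})

test_that("RF between random resolved trees concentrates near 1 for n = 16", {
  set.seed(11)
  vals <- replicate(100, {
    a <- random_topology(sprintf("L%02d", 1:16), seed = sample.int(1e6, 1))
    b <- random_topology(sprintf("L%02d", 1:16), seed = sample.int(1e6, 1))
    robinson_foulds_normalized(a, b)
  })
  expect_gt(mean(vals), 0.9)
})
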