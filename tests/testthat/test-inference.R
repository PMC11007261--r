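test_that("Mantel statistic and p behave on monotone and null inputs", {
  A <- random_dm(8, seed = 1)
  res <- mantel(A, 2 * A, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)

  # agreement with vegan on the statistic
  B <- random_dm(8, seed = 2)
  expect_equal(mantel(A, B, method = "pearson", n_perm = 99, seed = 1)$r,
               unname(vegan::mantel(A, B, method = "pearson",
                                    permutations = 99)$statistic))
  expect_equal(mantel(A, B, method = "spearman", n_perm = 99, seed = 1)$r,
               unname(vegan::mantel(A, B, method = "spearman",
                                    permutations = 99)$statistic))

  cst <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(cst) <- 0
  expect_error(mantel(cst, cst), class = "degenerate_statistic_error")
  expect_error(mantel(A, random_dm(8, seed = 3,
                                   labels = paste0("X", 1:8))),
               class = "alignment_error")
})

test_that("exhaustive Mantel p equals the enumeration oracle at n = 4 and 5", {
  for (n in 4:5) {
    A <- random_dm(n, seed = n)
    B <- random_dm(n, seed = n + 10)
    for (meth in c("spearman", "pearson")) {
      got <- mantel(A, B, method = meth, exact = TRUE)
      expect_equal(got$p, oracle_mantel_exact(A, B, method = meth),
                   tolerance = 1e-12)
    }
  }
})

test_that("partial Mantel reduces to simple Mantel under a vacuous control", {
  A <- random_dm(7, seed = 4)
  B <- random_dm(7, seed = 5)
  cst <- matrix(0.4, 7, 7, dimnames = dimnames(A)); diag(cst) <- 0
  simple <- mantel(A, B, n_perm = 199, seed = 9)
  part <- suppressWarnings(
    partial_mantel(A, B, list(c1 = cst), n_perm = 199, seed = 9))
  expect_equal(part$r, simple$r, tolerance = 1e-12)
  expect_equal(part$p, simple$p)

  # full partialling annihilates the statistic
  self <- NULL
  expect_warning(
    self <- partial_mantel(A, A, list(c1 = A), n_perm = 199, seed = 1),
    "constant")
  expect_equal(self$r, 0)
  expect_equal(self$p, 1)
})

test_that("MRM matches OLS normal equations and its R2 identities", {
  resp <- random_dm(5, seed = 6)
  p1 <- random_dm(5, seed = 7)
  p2 <- random_dm(5, seed = 8)
  fit <- mrm(resp, list(a = p1, b = p2), n_perm = 99, seed = 1)
  unf <- function(m) m[lower.tri(m)]
  X <- cbind(1, unf(p1), unf(p2))
  y <- unf(resp)
  cf <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), drop(cf), tolerance = 1e-10)
  r2 <- 1 - sum((y - X %*% cf)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)

  # identity fit
  self <- mrm(resp, list(x = resp), n_perm = 99, seed = 1)
  expect_equal(self$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(self$coefficients["x"]), 1, tolerance = 1e-10)

  # single predictor: R2 = squared Pearson correlation of unfolded vectors
  single <- mrm(resp, list(a = p1), n_perm = 99, seed = 1)
  expect_equal(single$r_squared, cor(unf(resp), unf(p1))^2,
               tolerance = 1e-12)

  expect_error(mrm(resp, list(a = p1, b = 2 * p1)), class = "rank_error")
})

test_that("PERMANOVA matches vegan and the exhaustive oracle", {
  dm <- random_dm(10, seed = 9)
  grp <- rep(c("g1", "g2"), each = 5)
  got <- permanova(dm, setNames(grp, rownames(dm)), n_perm = 199, seed = 1)
  ad <- vegan::adonis2(as.dist(dm) ~ g, data = data.frame(g = grp),
                       permutations = 99)
  expect_equal(got$pseudo_F, ad$F[1], tolerance = 1e-10)

  dm6 <- random_dm(6, seed = 10)
  g6 <- setNames(rep(c("a", "b"), each = 3), rownames(dm6))
  ex <- permanova(dm6, g6, exact = TRUE)
  orc <- oracle_permanova_exact(dm6, unname(g6))
  expect_equal(ex$pseudo_F, orc$F, tolerance = 1e-12)
  expect_equal(ex$p, orc$p, tolerance = 1e-12)

  # perfectly separated groups: within 0, between 1
  sep <- matrix(1, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  sep[1:3, 1:3] <- 0; sep[4:6, 4:6] <- 0
  res <- permanova(sep, setNames(rep(c("a", "b"), each = 3),
                                 rownames(sep)), exact = TRUE)
  expect_true(is.infinite(res$pseudo_F) || res$pseudo_F > 1e10)
  expect_equal(res$p, oracle_permanova_exact(sep, rep(c("a", "b"),
                                                      each = 3))$p)
  expect_error(permanova(dm, setNames(c(rep("a", 9), "b"), rownames(dm))),
               class = "design_error")
})

test_that("pairwise PERMANOVA applies BH and keeps p_adj >= p", {
  ds <- simulate_communities(null_config(seed = 17, n_populations = 6))
  dm <- beta(ds$table, "bray_curtis")
  grp <- setNames(ds$metadata$population, ds$metadata$sample_id)
  pw <- pairwise_permanova(dm, grp, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), choose(6, 2))
  expect_true(all(pw$p_adj >= pw$p - 1e-12))
})

test_that("group tests match hand-computed ranks and handle edge cases", {
  vals <- c(1, 3, 5, 2, 9, 8, 7, 10, 12, 11)
  grp <- rep(c("a", "b", "c"), c(3, 3, 4))
  got <- group_tests(vals, grp)
  expect_equal(got$kruskal$H,
               unname(kruskal.test(vals, factor(grp))$statistic),
               tolerance = 1e-12)
  # Dunn z for groups a vs c with no ties: direct rank computation
  r <- rank(vals); N <- 10
  z_ac <- (mean(r[grp == "a"]) - mean(r[grp == "c"])) /
    sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 4))
  expect_equal(got$dunn$z[got$dunn$group1 == "a" & got$dunn$group2 == "c"],
               z_ac, tolerance = 1e-12)
  expect_true(all(got$dunn$p_adj >= got$dunn$p - 1e-12))

  # completely separated two-group Wilcoxon attains the minimal p for n
  sep <- group_tests(c(1, 2, 3, 10, 11, 12), rep(c("lo", "hi"), each = 3))
  expect_equal(sep$wilcoxon, 2 / choose(6, 3), tolerance = 1e-12)

  tied <- NULL
  expect_warning(tied <- group_tests(rep(5, 6), rep(c("a", "b"), 3)),
                 "tied")
  expect_equal(tied$kruskal$p, 1)
  expect_error(group_tests(1:3, c("a", "a", "b")), class = "design_error")
})

test_that("step regression enumerates subsets with monotone R2", {
  resp <- random_dm(7, seed = 11)
  preds <- list(a = random_dm(7, seed = 12), b = random_dm(7, seed = 13),
                c = random_dm(7, seed = 14), d = random_dm(7, seed = 15))
  tab <- step_regression(resp, preds, n_perm = 99, seed = 1)
  expect_equal(nrow(tab), 15)
  full <- tab$r_squared[tab$model == "a+b+c+d"]
  expect_true(all(full >= tab$r_squared - 1e-12))
  # nested chain monotonicity
  chain <- c("a", "a+b", "a+b+c", "a+b+c+d")
  r2s <- tab$r_squared[match(chain, tab$model)]
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("subsample sensitivity is seeded and degenerate at full quota", {
  ds <- simulate_communities(null_config(seed = 23))
  cov <- covariate_set(ds$metadata, host_tree = ds$host_tree)
  s1 <- subsample_sensitivity(ds$table, ds$metadata, cov,
                              test = "partial_mantel", n_subsamples = 5,
                              per_population = 3, n_perm = 99, seed = 5)
  s2 <- subsample_sensitivity(ds$table, ds$metadata, cov,
                              test = "partial_mantel", n_subsamples = 5,
                              per_population = 3, n_perm = 99, seed = 5)
  expect_identical(s1$statistic, s2$statistic)
  expect_identical(s1$p, s2$p)
  expect_length(s1$statistic, 5)

  # quota = all samples -> every subsample is the full data set
  full <- subsample_sensitivity(ds$table, ds$metadata, cov, test = "mrm",
                                n_subsamples = 3, per_population = 3,
                                n_perm = 99, seed = 2)
  expect_equal(length(unique(round(full$statistic, 12))), 1)
  dmfull <- beta(ds$table, "bray_curtis")
  ref <- mrm(dmfull, cov, n_perm = 99, seed = 1)
  expect_equal(full$statistic[1], ref$r_squared, tolerance = 1e-10)

  expect_error(
    subsample_sensitivity(ds$table, ds$metadata, cov,
                          test = "mrm", per_population = 10, seed = 1),
    class = "design_error")
})
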