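# Permutation statistics on distance matrices. All sampled-permutation
# p-values use the add-one convention p = (#{perm stat >= observed} + 1) /
# (n_perm + 1); exhaustive enumeration reports the exact proportion over
# all n! relabelings (identity included).

# Pair-index matrix: M[i, j] = position of pair {i, j} in the column-major
# strict lower triangle. Permuting matrix rows/columns by `p` then
# unfolding equals indexing the unfolded vector by (M[p, p])[lower.tri].
pair_index <- function(n) {
  M <- matrix(0L, n, n)
  M[lower.tri(M)] <- seq_len(n * (n - 1) / 2)
  M + t(M)
}

permuted_unfold_idx <- function(M, p) (M[p, p])[lower.tri(M)]

# All permutations of 1..n (n <= 7), for exhaustive enumeration oracles.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(ifelse(sub >= k, sub + 1L, sub), nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

align_pair <- function(A, B) {
  if (!setequal(rownames(A), rownames(B)))
    ps_stop("distance matrices have different label sets", "alignment_error")
  B[rownames(A), rownames(A)]
}

#' Mantel test
#'
#' Correlation between the unfolded lower triangles of two distance
#' matrices, with significance by simultaneous row/column permutation of
#' `A`. Spearman uses average-rank ties.
#'
#' @param A,B Labelled distance matrices over the same labels.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (>= 99), ignored when `exact`.
#' @param seed RNG seed.
#' @param alternative `"greater"` (one-sided, the ecology convention) or
#'   `"two.sided"`.
#' @param exact Enumerate all n! permutations (n <= 7) instead of sampling.
#' @return A `mantel_result` list: `r`, `p`, `n_perm`, `method`,
#'   `alternative`, `controlled` (empty for the simple test).
#' @export
mantel <- function(A, B, method = c("spearman", "pearson"), n_perm = 999,
                   seed = 1L, alternative = c("greater", "two.sided"),
                   exact = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!exact && n_perm < 99) ps_stop("n_perm must be >= 99", "config_error")
  B <- align_pair(A, B)
  x <- lower_triangle(A)
  y <- lower_triangle(B)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ps_stop("constant distance matrix: Mantel statistic undefined",
            "degenerate_statistic_error")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r_obs <- stats::cor(x, y)
  n <- nrow(A)
  M <- pair_index(n)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  if (exact) {
    if (n > 7) ps_stop("exact enumeration limited to n <= 7", "config_error")
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(p)
      stats::cor(x[permuted_unfold_idx(M, p)], y))
    p <- mean(stat(r_perm) >= stat(r_obs) - 1e-12)
    n_perm <- nrow(perms)
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      stats::cor(x[permuted_unfold_idx(M, p)], y)
    }, numeric(1)))
    p <- (sum(stat(r_perm) >= stat(r_obs) - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, method = method,
                 alternative = alternative, controlled = character(0)),
            class = "mantel_result")
}

#' Partial Mantel test (residual method)
#'
#' The unfolded (rank-transformed, if Spearman) `A` and `B` vectors are
#' each regressed on the unfolded control matrices; the Mantel statistic
#' is the correlation of the two residual vectors, and the null is built
#' by row/column shuffling of `A`'s residual matrix.
#'
#' @inheritParams mantel
#' @param controls A labelled distance matrix or list of up to 3.
#' @return A `mantel_result` with `controlled` naming the controls.
#' @export
partial_mantel <- function(A, B, controls, method = c("spearman", "pearson"),
                           n_perm = 999, seed = 1L,
                           alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (is.matrix(controls)) controls <- list(control = controls)
  if (length(controls) > 3)
    ps_stop("at most 3 control matrices supported", "config_error")
  B <- align_pair(A, B)
  controls <- align_matrices(controls, rownames(A))
  x <- lower_triangle(A)
  y <- lower_triangle(B)
  Z <- vapply(controls, lower_triangle, numeric(length(x)))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); Z <- apply(Z, 2, rank)
  }
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    ps_warn("collinear control matrices; partialling is ill-conditioned")
  res_x <- stats::resid(stats::lm.fit(X, x))
  res_y <- stats::resid(stats::lm.fit(X, y))
  if (stats::sd(res_x) < 1e-12 || stats::sd(res_y) < 1e-12) {
    # controls absorb a matrix completely: nothing left to correlate
    ps_warn("residuals constant after partialling; returning r = 0, p = 1")
    return(structure(list(r = 0, p = 1, n_perm = n_perm, method = method,
                          alternative = alternative,
                          controlled = names(controls)),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(res_x, res_y)
  n <- nrow(A)
  M <- pair_index(n)
  # residual vector folded back into symmetric-matrix positions, so a
  # label permutation permutes residual pairs coherently
  stat <- function(r) if (alternative == "greater") r else abs(r)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    stats::cor(res_x[permuted_unfold_idx(M, p)], res_y)
  }, numeric(1)))
  p <- (sum(stat(r_perm) >= stat(r_obs) - 1e-12) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = n_perm, method = method,
                 alternative = alternative,
                 controlled = names(controls)), class = "mantel_result")
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the response matrix's unfolded lower triangle on the predictors';
#' R-squared and coefficient p-values come from simultaneous row/column
#' permutation of the response matrix.
#'
#' @param response Labelled distance matrix.
#' @param predictors Named list of labelled distance matrices.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return An `mrm_result`: `coefficients` (incl. intercept), `r_squared`,
#'   `p_r_squared`, `p_coefficients`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = 1L) {
  if (is.matrix(predictors)) predictors <- list(predictor = predictors)
  predictors <- align_matrices(predictors, rownames(response))
  y <- lower_triangle(response)
  Z <- vapply(predictors, lower_triangle, numeric(length(y)))
  X <- cbind(`(Intercept)` = 1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[-seq_len(qx$rank)]
    ps_stop(sprintf("singular design; collinear predictor(s): %s",
                    paste(drop, collapse = ", ")), "rank_error")
  }
  dXtXinv <- pmax(diag(chol2inv(qr.R(qx))), 0)
  df_res <- length(y) - ncol(X)
  fit_stats <- function(yv) {
    cf <- qr.coef(qx, yv)
    res <- yv - X %*% cf
    ss_res <- sum(res^2)
    ss_tot <- sum((yv - mean(yv))^2)
    r2 <- 1 - ss_res / ss_tot
    se <- sqrt(dXtXinv * ss_res / df_res)
    tval <- ifelse(se > 0, cf / se, 0)
    list(cf = cf, r2 = r2, t = tval)
  }
  obs <- fit_stats(y)
  n <- nrow(response)
  M <- pair_index(n)
  perm <- with_seed(seed, lapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    fit_stats(y[permuted_unfold_idx(M, p)])
  }))
  r2_perm <- vapply(perm, `[[`, numeric(1), "r2")
  t_perm <- vapply(perm, function(f) abs(f$t), numeric(ncol(X)))
  p_r2 <- (sum(r2_perm >= obs$r2 - 1e-12) + 1) / (n_perm + 1)
  p_cf <- (rowSums(t_perm >= abs(obs$t) - 1e-12) + 1) / (n_perm + 1)
  structure(list(coefficients = stats::setNames(drop(obs$cf), colnames(X)),
                 r_squared = obs$r2, p_r_squared = p_r2,
                 p_coefficients = stats::setNames(p_cf, colnames(X)),
                 n_perm = n_perm), class = "mrm_result")
}

#' MRM step regressions over every predictor subset
#'
#' One [mrm()] fit per non-empty subset of the predictors (<= 6, i.e.
#' at most 63 models).
#'
#' @inheritParams mrm
#' @return data.frame with `model` (predictor names joined by `+`),
#'   `n_predictors`, `r_squared`, `p_r_squared`.
#' @export
step_regression <- function(response, predictors, n_perm = 999, seed = 1L) {
  k <- length(predictors)
  if (k > 6) ps_stop("at most 6 predictors for step regression",
                     "config_error")
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(predictors), m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    fit <- mrm(response, predictors[s], n_perm = n_perm,
               seed = derive_seed(seed, paste(s, collapse = "+")))
    data.frame(model = paste(s, collapse = "+"), n_predictors = length(s),
               r_squared = fit$r_squared, p_r_squared = fit$p_r_squared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Huygens sums of squares for a squared-distance matrix and grouping.
permanova_f <- function(D2, groups) {
  n <- length(groups)
  ss_total <- sum(D2[lower.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx][lower.tri(D2[idx, idx])]) /
      length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA
#'
#' One-way permutational multivariate ANOVA: pseudo-F from the Huygens
#' decomposition of squared distances, significance by label permutation.
#'
#' @param dm Labelled distance matrix.
#' @param groups Group label per matrix label (named, or in matrix order);
#'   >= 2 groups of >= 2 members.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param exact Enumerate all label permutations (n <= 7).
#' @return A `permanova_result`: `pseudo_F`, `p`, `n_perm`, `groups`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1L, exact = FALSE) {
  validate_distance_matrix(dm)
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) ps_stop("need >= 2 groups", "design_error")
  if (any(tab < 2))
    ps_stop(sprintf("group(s) of size 1: %s",
                    paste(names(tab)[tab < 2], collapse = ", ")),
            "design_error")
  D2 <- dm^2
  f_obs <- permanova_f(D2, groups)
  n <- length(groups)
  if (exact) {
    if (n > 7) ps_stop("exact enumeration limited to n <= 7", "config_error")
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(p) permanova_f(D2, groups[p]))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      permanova_f(D2, groups[sample.int(n)]), numeric(1)))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(pseudo_F = f_obs, p = p, n_perm = n_perm,
                 groups = sort(unique(groups))), class = "permanova_result")
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `pseudo_F`, `p`, `p_adj` (BH).
#' @export
pairwise_permanova <- function(dm, groups, n_perm = 999, seed = 1L) {
  if (!is.null(names(groups))) groups <- groups[rownames(dm)]
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    idx <- groups %in% pr
    sub <- dm[idx, idx]
    res <- permanova(sub, groups[idx], n_perm = n_perm,
                     seed = derive_seed(seed, paste(pr, collapse = "|")))
    data.frame(group1 = pr[1], group2 = pr[2], pseudo_F = res$pseudo_F,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Kruskal-Wallis, Dunn post hoc, and Wilcoxon group tests
#'
#' Kruskal-Wallis H (tie-corrected, chi-square p) across >= 2 groups;
#' Dunn pairwise z statistics with Benjamini-Hochberg adjustment; for
#' exactly two groups the Wilcoxon rank-sum p is reported alongside.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups of >= 2).
#' @return List: `kruskal` (`H`, `df`, `p`), `dunn` (data.frame of pairwise
#'   z, p, p_adj), `wilcoxon` (two-group p or NA).
#' @export
group_tests <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    ps_stop("need >= 2 groups with >= 2 members each", "design_error")
  if (length(unique(values)) == 1) {
    ps_warn("all values tied; tests degenerate with p = 1")
    return(list(kruskal = list(H = 0, df = length(tab) - 1, p = 1),
                dunn = NULL, wilcoxon = if (length(tab) == 2) 1 else NA))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  dunn <- do.call(rbind, lapply(pairs, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  dunn$p_adj <- stats::p.adjust(dunn$p, method = "BH")
  wx <- if (length(gl) == 2)
    suppressWarnings(stats::wilcox.test(values[groups == gl[1]],
                                        values[groups == gl[2]]))$p.value
  else NA
  list(kruskal = list(H = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       dunn = dunn, wilcoxon = wx)
}

#' Subsample sensitivity analysis
#'
#' Repeats a matrix test over many random subsamples of the feature table
#' (a fixed number of samples per population, with per-population
#' overrides), recomputing the beta-diversity matrix each time --
#' mirroring designs where host genetic data cover fewer individuals than
#' the microbiome survey.
#'
#' @param table Feature table.
#' @param metadata Sample metadata with `sample_id` and `population`.
#' @param covariates Named list of sample-level distance matrices; the
#'   first is the focal predictor, the rest are controls (partial Mantel)
#'   or co-predictors (MRM).
#' @param test `"partial_mantel"` or `"mrm"`.
#' @param beta_metric Beta metric for the recomputed response matrix.
#' @param tree Microbial tree (UniFrac metrics).
#' @param n_subsamples Number of subsamples.
#' @param per_population Samples drawn per population.
#' @param overrides Named integer vector of per-population quota overrides.
#' @param alpha Significance level for the summary fraction.
#' @param seed RNG seed; each subsample uses an independent derived stream.
#' @return A `sensitivity_distribution` list: `statistic`, `p`,
#'   `significant_fraction`, `alpha`, `test`.
#' @export
subsample_sensitivity <- function(table, metadata, covariates,
                                  test = c("partial_mantel", "mrm"),
                                  beta_metric = "bray_curtis", tree = NULL,
                                  n_subsamples = 100, per_population = 3,
                                  overrides = NULL, alpha = 0.05,
                                  n_perm = 999, seed = 1L) {
  test <- match.arg(test)
  pops <- split(metadata$sample_id, metadata$population)
  quota <- stats::setNames(rep(per_population, length(pops)), names(pops))
  if (!is.null(overrides)) quota[names(overrides)] <- overrides
  short <- names(pops)[lengths(pops) < quota[names(pops)]]
  if (length(short))
    ps_stop(sprintf("population(s) below quota: %s",
                    paste(short, collapse = ", ")), "design_error")
  one <- function(b) {
    ids <- with_seed(derive_seed(seed, sprintf("subsample%04d", b)),
                     unlist(lapply(names(pops), function(p)
                       sample(pops[[p]], quota[p]))))
    sub <- table[ids, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    bm <- beta(sub, metric = beta_metric, tree = tree)
    cv <- align_matrices(covariates, ids)
    if (test == "partial_mantel") {
      res <- partial_mantel(cv[[1]], bm, cv[-1], n_perm = n_perm,
                            seed = derive_seed(seed, sprintf("test%04d", b)))
      c(stat = res$r, p = res$p)
    } else {
      res <- mrm(bm, cv, n_perm = n_perm,
                 seed = derive_seed(seed, sprintf("test%04d", b)))
      c(stat = res$r_squared, p = res$p_r_squared)
    }
  }
  out <- vapply(seq_len(n_subsamples), one, numeric(2))
  structure(list(statistic = unname(out["stat", ]), p = unname(out["p", ]),
                 significant_fraction = mean(out["p", ] < alpha),
                 alpha = alpha, test = test),
            class = "sensitivity_distribution")
}
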