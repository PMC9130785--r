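test_that("unfold_dyads counts and orders dyads deterministically", {
  m3 <- random_dyad_matrix(3, seed = 1)
  expect_length(unfold_dyads(m3), 3)
  m30 <- random_dyad_matrix(30, seed = 2)
  expect_length(unfold_dyads(m30), 435)
  rect <- matrix(seq_len(900), 30, 30,
                 dimnames = list(paste0("m", 1:30), paste0("f", 1:30)))
  expect_length(unfold_dyads(rect), 900)
  # ordering matches the tidy view dyad-for-dyad
  tb <- dyads_to_tibble(m30)
  expect_equal(tb$distance, unfold_dyads(m30))
  expect_equal(tb$distance,
               m30[cbind(match(tb$id1, rownames(m30)),
                         match(tb$id2, colnames(m30)))])
})

test_that("partial_pearson equals the residualize-then-correlate oracle", {
  withr::with_seed(31, {
    x <- rnorm(6)
    y <- rnorm(6)
    z <- rnorm(6)
    z2 <- rnorm(6)
  })
  oracle <- stats::cor(stats::resid(stats::lm(x ~ z)),
                       stats::resid(stats::lm(y ~ z)))
  expect_equal(partial_pearson(x, y, z), oracle, tolerance = 1e-10)
  # textbook single-covariate formula
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(partial_pearson(x, y, z),
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-10)
  # multiple covariates via the same oracle
  oracle2 <- stats::cor(stats::resid(stats::lm(x ~ z + z2)),
                        stats::resid(stats::lm(y ~ z + z2)))
  expect_equal(partial_pearson(x, y, cbind(z, z2)), oracle2,
               tolerance = 1e-10)
  # y = x with an unrelated covariate -> 1
  expect_equal(partial_pearson(x, x, z), 1)
  # y fully explained by the covariate -> undefined
  expect_warning(r <- partial_pearson(x, z, z), "undefined")
  expect_true(is.na(r))
})

test_that("partial Mantel detects self-association and respects the
          p-value floor", {
  a <- random_dyad_matrix(12, seed = 41)
  c1 <- random_dyad_matrix(12, seed = 42)
  res <- partial_mantel(a, a, covariates = c1, n_perm = 199, seed = 5)
  expect_s3_class(res, "dyadic_test")
  expect_equal(res$observed, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 200)
  expect_equal(res$n_dyads, 66)
  expect_true(all(abs(res$perms) <= 1 + 1e-12))
  # p-values can never be zero
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
})

test_that("observed Mantel statistics agree with vegan", {
  skip_if_not_installed("vegan")
  a <- random_dyad_matrix(15, seed = 51)
  b <- random_dyad_matrix(15, seed = 52)
  c1 <- random_dyad_matrix(15, seed = 53)
  simple <- partial_mantel(a, b, n_perm = 9, seed = 1)
  vg <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                      permutations = 9)
  expect_equal(simple$observed, unname(vg$statistic), tolerance = 1e-10)
  part <- partial_mantel(a, b, covariates = c1, n_perm = 9, seed = 1)
  vgp <- vegan::mantel.partial(stats::as.dist(a), stats::as.dist(b),
                               stats::as.dist(c1), permutations = 9)
  expect_equal(part$observed, unname(vgp$statistic), tolerance = 1e-10)
})

test_that("sampled permutation p matches the exhaustive oracle on 5
          labels", {
  n <- 5
  a <- random_dyad_matrix(n, seed = 61)
  b <- random_dyad_matrix(n, seed = 62)
  cv <- random_dyad_matrix(n, seed = 63)
  perms <- all_perms(n)
  # independent oracle: enumerate all 120 relabelings, recompute the
  # Freedman-Lane statistic by explicit lm residualization each time
  unf <- function(m) m[lower.tri(m)]
  z <- unf(cv)
  ry <- stats::resid(stats::lm(unf(b) ~ z))
  rx <- stats::resid(stats::lm(unf(a) ~ z))
  rmat <- matrix(0, n, n)
  rmat[lower.tri(rmat)] <- rx
  rmat <- rmat + t(rmat)
  stat <- function(p) {
    xp <- unf(rmat[p, p])
    stats::cor(stats::resid(stats::lm(xp ~ z)), ry)
  }
  stats_all <- apply(perms, 1, stat)
  obs <- stat(seq_len(n))
  p_exact <- mean(abs(stats_all) >= abs(obs) - 1e-12)
  res <- partial_mantel(a, b, covariates = cv, n_perm = 10000, seed = 7)
  expect_equal(res$observed,
               partial_pearson(unf(a), unf(b), z), tolerance = 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se + 1e-4)
  # raw-permutation variant against its own exhaustive oracle
  stat_raw <- function(p) {
    xp <- unf(a[p, p])
    stats::cor(stats::resid(stats::lm(xp ~ z)), ry)
  }
  stats_raw <- apply(perms, 1, stat_raw)
  p_raw <- mean(abs(stats_raw) >= abs(stat_raw(1:n)) - 1e-12)
  res_raw <- partial_mantel(a, b, covariates = cv, n_perm = 10000,
                            seed = 8, permute = "raw")
  mc_se_raw <- sqrt(p_raw * (1 - p_raw) / 10000)
  expect_lt(abs(res_raw$p_value - p_raw), 3 * mc_se_raw + 1e-4)
})

test_that("Mantel statistic is symmetric and relabeling-invariant", {
  a <- random_dyad_matrix(10, seed = 71)
  b <- random_dyad_matrix(10, seed = 72)
  cv <- random_dyad_matrix(10, seed = 73)
  r_ab <- partial_mantel(a, b, covariates = cv, n_perm = 19, seed = 1)
  r_ba <- partial_mantel(b, a, covariates = cv, n_perm = 19, seed = 1)
  expect_equal(r_ab$observed, r_ba$observed, tolerance = 1e-12)
  # common relabeling of all matrices leaves the statistic unchanged
  p <- c(3, 1, 4, 2, 10, 9, 5, 6, 8, 7)
  r_perm <- partial_mantel(a[p, p], b[p, p], covariates = cv[p, p],
                           n_perm = 19, seed = 1)
  expect_equal(r_perm$observed, r_ab$observed, tolerance = 1e-12)
  # constant covariate reduces the partial statistic to plain Mantel r
  const <- a * 0
  x <- unfold_dyads(a)
  y <- unfold_dyads(b)
  r_const <- partial_mantel(a, b, covariates = const, n_perm = 19,
                            seed = 1)
  expect_equal(r_const$observed, stats::cor(x, y), tolerance = 1e-10)
  # label mismatch is an error
  b_bad <- b
  rownames(b_bad)[1] <- "zz"
  expect_error(partial_mantel(a, b_bad), "labels")
  # constant matrix is an error
  expect_error(partial_mantel(const, b), "constant")
})

test_that("rectangular partial Spearman handles ranks, ties and its
          exhaustive oracle", {
  withr::with_seed(81, {
    a <- matrix(runif(20), 4, 5,
                dimnames = list(paste0("m", 1:4), paste0("f", 1:5)))
    cv <- matrix(runif(20), 4, 5, dimnames = dimnames(a))
  })
  # strictly increasing transform of a has rho exactly 1
  b <- exp(2 * a)
  dimnames(b) <- dimnames(a)
  res <- partial_spearman_rect(a, b, n_perm = 99, seed = 3)
  expect_equal(res$observed, 1, tolerance = 1e-12)
  expect_equal(res$statistic, "Spearman rho")
  expect_equal(res$n_dyads, 20)
  # all-equal chemical matrix is degenerate
  expect_error(partial_spearman_rect(a * 0 + 1, b), "constant")
  # tied entries use average ranks (statistic equals cor of ranks)
  a_tied <- a
  a_tied[1, 1] <- a_tied[2, 2]
  r_tied <- partial_spearman_rect(a_tied, b, n_perm = 9, seed = 1)
  expect_equal(r_tied$observed,
               stats::cor(rank(as.vector(a_tied)), rank(as.vector(b))),
               tolerance = 1e-12)
  # 2 x 2 exhaustive entry-permutation oracle (24 permutations)
  withr::with_seed(82, {
    a2 <- matrix(runif(4), 2, 2,
                 dimnames = list(c("m1", "m2"), c("f1", "f2")))
    b2 <- matrix(runif(4), 2, 2, dimnames = dimnames(a2))
  })
  xr <- rank(as.vector(a2))
  yr <- rank(as.vector(b2))
  perms <- all_perms(4)
  stats_all <- apply(perms, 1, function(p) stats::cor(xr[p], yr))
  obs <- stats::cor(xr, yr)
  p_exact <- mean(abs(stats_all) >= abs(obs) - 1e-12)
  res2 <- partial_spearman_rect(a2, b2, n_perm = 10000, seed = 9)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res2$p_value - p_exact), 3 * mc_se + 1e-4)
  # restricted row-permutation mode runs and reports its scheme
  res_rows <- partial_spearman_rect(a, b, covariates = cv, n_perm = 49,
                                    seed = 2, null = "rows")
  expect_match(res_rows$note, "rows")
  expect_gte(res_rows$p_value, 1 / 50)
})

test_that("bonferroni_alpha reproduces the published thresholds", {
  expect_equal(round(bonferroni_alpha(0.05, 6), 3), 0.008)
  expect_equal(round(bonferroni_alpha(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0, 3), "alpha")
  expect_error(bonferroni_alpha(0.05, 0), "n_tests")
})

test_that("tidy() returns the full test record", {
  a <- random_dyad_matrix(8, seed = 91)
  b <- random_dyad_matrix(8, seed = 92)
  res <- partial_mantel(a, b, n_perm = 49, seed = 17,
                        adjusted_alpha = 0.0056)
  td <- tidy(res)
  expect_equal(td$statistic, "Mantel r")
  expect_equal(td$n_perm, 49)
  expect_equal(td$seed, 17)
  expect_equal(td$n_dyads, 28)
  expect_equal(td$adjusted_alpha, 0.0056)
})
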