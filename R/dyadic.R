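is_square_symmetric <- function(m) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    isTRUE(all.equal(unname(m), unname(t(m)))) &&
    all(abs(diag(m)) < 1e-12)
}

check_same_labels <- function(mats) {
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(dim(m), dim(ref)) ||
        !identical(rownames(m), rownames(ref)) ||
        !identical(colnames(m), colnames(ref))) {
      stop("distance matrices must share identical row/column labels",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Unfold a dyad matrix into a vector
#'
#' Square symmetric matrices unfold to their strict lower triangle in
#' column-major order (n(n-1)/2 entries); rectangular matrices unfold to all
#' entries in column-major order. The ordering is deterministic, so vectors
#' from matrices with identical labels are aligned dyad-for-dyad.
#'
#' @param m Dyad matrix with dimnames.
#' @return Numeric vector of dyad distances.
#' @export
unfold_dyads <- function(m) {
  if (!is.matrix(m)) stop("`m` must be a matrix", call. = FALSE)
  if (is_square_symmetric(m)) m[lower.tri(m)] else as.vector(m)
}

#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' covariate(s) `z` from both (residualize-then-correlate; for a single
#' covariate this equals the textbook formula
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`).
#'
#' @param x,y Numeric vectors, length >= 4, finite.
#' @param z Covariate: numeric vector, matrix (one column per covariate) or
#'   list of vectors; `NULL` for the plain correlation.
#' @return A single correlation; `NA` with a warning when a covariate
#'   explains `x` or `y` exactly (partial correlation undefined).
#' @export
partial_pearson <- function(x, y, z = NULL) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ",
                                   call. = FALSE)
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (is.null(z)) return(stats::cor(x, y))
  zm <- covariate_matrix(z, length(x))
  q <- qr(cbind(1, zm))
  rx <- qr.resid(q, x)
  ry <- qr.resid(q, y)
  if (stats::sd(rx) < 1e-12 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-12 * max(stats::sd(y), 1)) {
    warning("a covariate explains x or y exactly; partial correlation ",
            "undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

covariate_matrix <- function(z, n) {
  if (is.list(z) && !is.data.frame(z)) z <- do.call(cbind, z)
  zm <- as.matrix(z)
  if (nrow(zm) != n) stop("covariate length mismatch", call. = FALSE)
  zm
}

new_dyadic_test <- function(statistic, observed, p_value, n_perm, tail, seed,
                            n_dyads, adjusted_alpha, perms = NULL,
                            note = NULL) {
  structure(
    list(statistic = statistic, observed = observed, p_value = p_value,
         n_perm = n_perm, tail = tail, seed = seed, n_dyads = n_dyads,
         adjusted_alpha = adjusted_alpha, perms = perms, note = note),
    class = "dyadic_test"
  )
}

#' @export
print.dyadic_test <- function(x, ...) {
  cat(x$statistic, "=", formatC(x$observed, digits = 4, format = "f"),
      " p =", format.pval(x$p_value, digits = 3),
      paste0("(", x$tail, ", ", x$n_perm, " permutations, ",
             x$n_dyads, " dyads)"), "\n")
  if (!is.null(x$adjusted_alpha)) {
    cat("Adjusted significance threshold:",
        formatC(x$adjusted_alpha, digits = 4, format = "g"), "\n")
  }
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

perm_p_value <- function(obs, perms, tail) {
  if (tail == "two-sided") {
    (sum(abs(perms) >= abs(obs) - 1e-12) + 1) / (length(perms) + 1)
  } else {
    (sum(perms >= obs - 1e-12) + 1) / (length(perms) + 1)
  }
}

#' Mantel and partial Mantel permutation test
#'
#' Tests the association between two square dyadic distance matrices,
#' optionally controlling for covariate matrices. The observed statistic is
#' the (partial) Pearson correlation of the unfolded strict lower triangles.
#' The null relabels individuals by simultaneous random row-and-column
#' permutation of the chemical matrix `a`, recomputing the statistic each
#' draw; with covariates the default permutes `a`'s covariate-residualized
#' matrix and re-residualizes each draw (`permute = "residuals"`, the
#' Freedman-Lane scheme), which keeps the type-I error at its nominal level
#' even when `a` is strongly correlated with a covariate — permuting the
#' raw matrix (`permute = "raw"`, the convention of several distance-matrix
#' packages) is anticonservative in that case. The p-value uses the add-one
#' estimator, so it can never be 0 and its minimum is `1/(n_perm + 1)`.
#'
#' @param a,b Square symmetric dyad matrices with identical labels
#'   (conventionally `a` = chemical distance, `b` = genetic distance).
#' @param covariates Optional square dyad matrix or list of matrices (e.g.
#'   breeding-status difference, the other chemical component).
#' @param n_perm Number of random permutations (default 10000).
#' @param tail `"two-sided"` (default) or `"greater"` (positive covariance
#'   hypothesis).
#' @param seed Integer seed for the permutation stream, recorded in the
#'   result.
#' @param permute `"residuals"` (default) or `"raw"`; ignored without
#'   covariates.
#' @param adjusted_alpha Optional Bonferroni-adjusted threshold to carry in
#'   the result (see [bonferroni_alpha()]).
#' @param keep_perms Keep the permutation statistics (for plotting).
#' @return A `dyadic_test` object; see [tidy.dyadic_test()].
#' @export
partial_mantel <- function(a, b, covariates = NULL, n_perm = 10000,
                           tail = c("two-sided", "greater"), seed = 1,
                           permute = c("residuals", "raw"),
                           adjusted_alpha = NULL, keep_perms = TRUE) {
  tail <- match.arg(tail)
  permute <- match.arg(permute)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  mats <- c(list(a, b), if (is.null(covariates)) NULL else
    if (is.list(covariates)) covariates else list(covariates))
  check_same_labels(mats)
  if (!is_square_symmetric(a) || !is_square_symmetric(b)) {
    stop("`a` and `b` must be square symmetric dyad matrices", call. = FALSE)
  }
  x <- unfold_dyads(a)
  y <- unfold_dyads(b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant distance matrix: statistic undefined", call. = FALSE)
  }
  zs <- if (is.null(covariates)) NULL else {
    cl <- if (is.list(covariates)) covariates else list(covariates)
    do.call(cbind, lapply(cl, unfold_dyads))
  }
  obs <- partial_pearson(x, y, zs)
  stat_name <- if (is.null(zs)) "Mantel r" else "partial Mantel r"
  n <- nrow(a)
  # residualize y (and the permuted x draws) on the fixed covariates once
  q <- if (is.null(zs)) NULL else qr(cbind(1, zs))
  ry <- if (is.null(q)) y else qr.resid(q, y)
  # matrix whose rows/columns the null permutes: raw a, or a's residuals
  # folded back into dyadic form (Freedman-Lane)
  pm <- if (is.null(q) || permute == "raw") a else {
    fold_dyads(qr.resid(q, x), n, rownames(a))
  }
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      xp <- unfold_dyads(pm[p, p])
      if (is.null(q)) stats::cor(xp, ry) else stats::cor(qr.resid(q, xp), ry)
    }, numeric(1))
  })
  new_dyadic_test(stat_name, obs, perm_p_value(obs, perms, tail), n_perm,
                  tail, seed, length(x), adjusted_alpha,
                  perms = if (keep_perms) perms else NULL,
                  note = if (!is.null(q)) paste0("permute = ", permute))
}

# inverse of unfold_dyads for the square-symmetric case
fold_dyads <- function(v, n, ids) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Rectangular partial Spearman permutation test
#'
#' Association test for rectangular mixed-sex dyad matrices, where a Mantel
#' test is not applicable. All matrices are unfolded and average-ranked; the
#' statistic is the partial Pearson correlation of the ranks (partial
#' Spearman rho). The default null permutes the entries of `a`'s unfolded
#' dyad vector (`null = "entries"`, mirroring the permutation scheme of
#' standard partial rank-correlation permutation tests); `null = "rows"`
#' instead permutes `a`'s row labels, a restricted scheme that respects the
#' dyadic non-independence of rows. With covariates, what is permuted is by
#' default the covariate-residualized rank vector, re-residualized each
#' draw (`permute = "residuals"`, as in [partial_mantel()]).
#'
#' @param a,b Rectangular dyad matrices with identical row/column labels.
#' @param covariates Optional rectangular matrix or list of matrices.
#' @param null Permutation scheme, `"entries"` (default) or `"rows"`.
#' @inheritParams partial_mantel
#' @return A `dyadic_test` object.
#' @export
partial_spearman_rect <- function(a, b, covariates = NULL, n_perm = 10000,
                                  tail = c("two-sided", "greater"), seed = 1,
                                  null = c("entries", "rows"),
                                  permute = c("residuals", "raw"),
                                  adjusted_alpha = NULL, keep_perms = TRUE) {
  tail <- match.arg(tail)
  null <- match.arg(null)
  permute <- match.arg(permute)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  mats <- c(list(a, b), if (is.null(covariates)) NULL else
    if (is.list(covariates)) covariates else list(covariates))
  check_same_labels(mats)
  x <- rank(as.vector(a))
  y <- rank(as.vector(b))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant distance matrix: statistic undefined", call. = FALSE)
  }
  zs <- if (is.null(covariates)) NULL else {
    cl <- if (is.list(covariates)) covariates else list(covariates)
    do.call(cbind, lapply(cl, function(m) rank(as.vector(m))))
  }
  obs <- partial_pearson(x, y, zs)
  q <- if (is.null(zs)) NULL else qr(cbind(1, zs))
  ry <- if (is.null(q)) y else qr.resid(q, y)
  xperm <- if (is.null(q) || permute == "raw") x else qr.resid(q, x)
  xm <- matrix(xperm, nrow(a), ncol(a)) # arranged as the matrix
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      xp <- if (null == "entries") {
        xperm[sample.int(length(xperm))]
      } else {
        as.vector(xm[sample.int(nrow(xm)), ])
      }
      if (is.null(q)) stats::cor(xp, ry) else stats::cor(qr.resid(q, xp), ry)
    }, numeric(1))
  })
  stat_name <- if (is.null(zs)) "Spearman rho" else "partial Spearman rho"
  new_dyadic_test(stat_name, obs, perm_p_value(obs, perms, tail), n_perm,
                  tail, seed, length(x), adjusted_alpha,
                  perms = if (keep_perms) perms else NULL,
                  note = paste0("null = ", null, " permutation",
                                if (!is.null(q)) paste0(", permute = ",
                                                        permute)))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1].
#' @param n_tests Number of tests in the family, >= 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 6) # 0.00833...
#' bonferroni_alpha(0.05, 9) # 0.00556...
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]",
                                    call. = FALSE)
  if (n_tests < 1) stop("`n_tests` must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dyadic permutation test
#'
#' @param x A `dyadic_test` object.
#' @param ... Unused.
#' @return One-row tibble: statistic name, estimate, p-value, permutation
#'   count, tail, seed, dyad count and adjusted alpha.
#' @export
tidy.dyadic_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    estimate = x$observed,
    p_value = x$p_value,
    n_perm = x$n_perm,
    tail = x$tail,
    seed = x$seed,
    n_dyads = x$n_dyads,
    adjusted_alpha = if (is.null(x$adjusted_alpha)) NA_real_ else
      x$adjusted_alpha
  )
}
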