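#' BIO-ENV compound-subset selection
#'
#' Exhaustive search for the subset of at most `k_max` compounds whose
#' between-individual Euclidean distance matrix maximizes the Mantel
#' correlation with a fixed target (genetic) distance matrix. Every subset
#' of size 1..`k_max` is evaluated; ties break to the lexicographically
#' smallest subset (and, across sizes, the smallest size). Because the
#' winning correlation is the maximum over many subsets it is selection
#' biased and carries no significance value.
#'
#' @param profiles Profile tibble (`individual` + compound columns),
#'   restricted to the dyad group of interest (e.g. females only).
#' @param target Square symmetric distance matrix whose labels equal the
#'   profile individuals (order free).
#' @param k_max Largest subset size, 1 <= `k_max` <= number of compounds.
#' @param correlation `"mantel_pearson"` (default, plain Mantel r) or
#'   `"mantel_spearman"` (rank correlation).
#' @param scale Unit-variance standardize compound columns before computing
#'   subset distances (the classic procedure's optional normalization step;
#'   off by default, profiles are already log-scaled).
#' @param covariate Optional square dyad matrix; when given, the search
#'   maximizes the partial Mantel correlation controlling for it and the
#'   result is flagged accordingly.
#' @param method `"exhaustive"` (default) or `"greedy"` forward selection —
#'   a clearly non-exhaustive fallback for large compound sets.
#' @return A `bioenv_result`: per-size best subsets (`by_k`), the overall
#'   best subset and correlation, and the number of subsets evaluated.
#' @export
bioenv_search <- function(profiles, target, k_max = 6,
                          correlation = c("mantel_pearson",
                                          "mantel_spearman"),
                          scale = FALSE, covariate = NULL,
                          method = c("exhaustive", "greedy")) {
  correlation <- match.arg(correlation)
  method <- match.arg(method)
  cmp <- setdiff(names(profiles), "individual")
  p <- length(cmp)
  if (k_max < 1 || k_max > p) {
    stop("`k_max` must be between 1 and the number of compounds (", p, ")",
         call. = FALSE)
  }
  ids <- profiles$individual
  if (!setequal(ids, rownames(target))) {
    stop("profile individuals and target labels differ", call. = FALSE)
  }
  x <- as.matrix(profiles[cmp])
  rownames(x) <- ids
  if (scale) x <- base::scale(x)
  tgt <- target[ids, ids]
  y <- unfold_dyads(tgt)
  if (stats::sd(y) == 0) {
    stop("constant target matrix: correlations undefined", call. = FALSE)
  }
  # per-compound squared-difference dyad vectors: m dyads x p compounds
  n <- length(ids)
  li <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  d2 <- (x[li[, 1], , drop = FALSE] - x[li[, 2], , drop = FALSE])^2
  if (correlation == "mantel_spearman") y <- rank(y)
  zq <- NULL
  if (!is.null(covariate)) {
    zv <- unfold_dyads(covariate[ids, ids])
    if (correlation == "mantel_spearman") zv <- rank(zv)
    zq <- qr(cbind(1, zv))
    y <- qr.resid(zq, y)
  }
  score_subsets <- function(sets) {
    # sets: k x n_sets index matrix; returns correlation per subset
    dm <- sqrt(crossprod_subsets(d2, sets))
    if (correlation == "mantel_spearman") {
      dm <- apply(dm, 2, rank)
    }
    if (!is.null(zq)) dm <- qr.resid(zq, dm)
    suppressWarnings(as.vector(stats::cor(dm, y)))
  }
  if (method == "greedy") {
    return(bioenv_greedy(d2, y, cmp, k_max, score_subsets, correlation,
                         scale, covariate))
  }
  by_k <- vector("list", k_max)
  n_eval <- 0
  for (k in seq_len(k_max)) {
    sets <- utils::combn(p, k)
    n_eval <- n_eval + ncol(sets)
    cors <- score_subsets(sets)
    best <- which.max(cors) # first max = lexicographically smallest
    by_k[[k]] <- tibble::tibble(
      k = k,
      compounds = list(cmp[sets[, best]]),
      correlation = cors[best]
    )
  }
  finish_bioenv(dplyr::bind_rows(by_k), n_eval, correlation, scale,
                covariate, exhaustive = TRUE)
}

# column sums of d2 over each index subset, vectorized as a matrix product
crossprod_subsets <- function(d2, sets) {
  p <- ncol(d2)
  ind <- matrix(0, p, ncol(sets))
  ind[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = nrow(sets)))] <- 1
  d2 %*% ind
}

bioenv_greedy <- function(d2, y, cmp, k_max, score_subsets, correlation,
                          scale, covariate) {
  p <- length(cmp)
  chosen <- integer(0)
  by_k <- vector("list", k_max)
  n_eval <- 0
  for (k in seq_len(k_max)) {
    cand <- setdiff(seq_len(p), chosen)
    sets <- rbind(matrix(chosen, nrow = k - 1, ncol = length(cand)), cand)
    n_eval <- n_eval + length(cand)
    cors <- score_subsets(sets)
    chosen <- sort(c(chosen, cand[which.max(cors)]))
    by_k[[k]] <- tibble::tibble(k = k, compounds = list(cmp[chosen]),
                                correlation = max(cors))
  }
  finish_bioenv(dplyr::bind_rows(by_k), n_eval, correlation, scale,
                covariate, exhaustive = FALSE)
}

finish_bioenv <- function(by_k, n_eval, correlation, scale, covariate,
                          exhaustive) {
  best <- which.max(by_k$correlation) # smallest k wins ties
  structure(
    list(
      by_k = by_k,
      best_k = by_k$k[best],
      best_compounds = by_k$compounds[[best]],
      best_correlation = by_k$correlation[best],
      n_evaluated = n_eval,
      correlation = correlation,
      scale = scale,
      partial = !is.null(covariate),
      exhaustive = exhaustive
    ),
    class = "bioenv_result"
  )
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(if (x$exhaustive) "Exhaustive" else "Greedy (non-exhaustive)",
      "BIO-ENV search,", x$n_evaluated, "subsets evaluated\n")
  cat("Correlation:", x$correlation,
      if (x$partial) "(partial, covariate-controlled)" else "", "\n")
  cat(sprintf("Best subset (k = %d, r = %.3f): %s\n", x$best_k,
              x$best_correlation, paste(x$best_compounds, collapse = ", ")))
  invisible(x)
}

#' Tidy a BIO-ENV result
#'
#' @param x A `bioenv_result` object.
#' @param ... Unused.
#' @return Tibble with one row per subset size: `k`, `compounds` (comma
#'   separated), `correlation`, and a `best` flag for the overall winner.
#' @export
tidy.bioenv_result <- function(x, ...) {
  dplyr::mutate(
    x$by_k,
    compounds = vapply(.data$compounds, paste, character(1), collapse = ", "),
    best = .data$k == x$best_k
  )
}

#' @export
glance.bioenv_result <- function(x, ...) {
  tibble::tibble(
    best_k = x$best_k,
    best_correlation = x$best_correlation,
    n_evaluated = x$n_evaluated,
    correlation = x$correlation,
    partial = x$partial,
    exhaustive = x$exhaustive
  )
}
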