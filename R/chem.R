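#' Standardize one replicate's peak areas
#'
#' Divides raw compound peak areas by the product of the replicate's internal
#' standard peak area and its sample mass, removing run-to-run instrument
#' sensitivity drift and sample-size differences. Resulting units are
#' area / (area * g) = g^-1.
#'
#' @param areas Numeric vector of nonnegative compound peak areas.
#' @param is_area Internal standard peak area (> 0).
#' @param mass Sample mass in grams (> 0).
#' @param replicate Optional label used in error messages.
#' @return Numeric vector, same length as `areas`.
#' @examples
#' standardize_replicate(c(200, 0), is_area = 100, mass = 0.004)
#' @export
standardize_replicate <- function(areas, is_area, mass, replicate = NULL) {
  lab <- if (is.null(replicate)) "" else paste0(" in replicate ", replicate)
  if (!is.finite(is_area) || is_area <= 0) {
    stop("internal standard area must be positive", lab, call. = FALSE)
  }
  if (!is.finite(mass) || mass <= 0) {
    stop("sample mass must be positive", lab, call. = FALSE)
  }
  areas / (is_area * mass)
}

compound_cols <- function(peak_table) {
  setdiff(names(peak_table),
          c("individual", "replicate", "sample_mass", "is_area"))
}

check_peak_table <- function(peak_table) {
  need <- c("individual", "replicate", "sample_mass", "is_area")
  missing_cols <- setdiff(need, names(peak_table))
  if (length(missing_cols) > 0) {
    stop("peak table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cmp <- compound_cols(peak_table)
  if (length(cmp) == 0) stop("peak table has no compound columns",
                             call. = FALSE)
  if (any(as.matrix(peak_table[cmp]) < 0, na.rm = TRUE)) {
    stop("negative compound peak areas", call. = FALSE)
  }
  invisible(cmp)
}

#' Standardize a replicate-level peak table
#'
#' Applies [standardize_replicate()] row-wise to a wide peak table (one row
#' per individual x replicate, one column per compound).
#'
#' @param peak_table Tibble with columns `individual`, `replicate`,
#'   `sample_mass`, `is_area` and one numeric column per compound.
#' @return Tibble of the same shape with standardized compound columns
#'   (`sample_mass` and `is_area` dropped).
#' @export
standardize_peaks <- function(peak_table) {
  cmp <- check_peak_table(peak_table)
  bad <- which(peak_table$is_area <= 0 | peak_table$sample_mass <= 0 |
                 !is.finite(peak_table$is_area) |
                 !is.finite(peak_table$sample_mass))
  if (length(bad) > 0) {
    stop("nonpositive internal standard area or sample mass in replicate(s) ",
         paste(peak_table$individual[bad], peak_table$replicate[bad],
               sep = "/", collapse = ", "),
         call. = FALSE)
  }
  denom <- peak_table$is_area * peak_table$sample_mass
  out <- peak_table[c("individual", "replicate")]
  out[cmp] <- peak_table[cmp] / denom
  tibble::as_tibble(out)
}

#' Aggregate replicates into per-bird chemical profiles
#'
#' Fixed order of operations: standardize each replicate by internal
#' standard and mass, average the replicate vectors within each individual,
#' then apply `log(x + 1)` entrywise so that a few highly abundant compounds
#' do not dominate downstream analyses.
#'
#' @inheritParams standardize_peaks
#' @return Tibble with one row per individual (`individual` + one column per
#'   compound of log-transformed standardized abundances, all >= 0).
#' @export
aggregate_profiles <- function(peak_table) {
  std <- standardize_peaks(peak_table)
  cmp <- compound_cols(std)
  out <- std |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cmp), mean),
                     .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cmp), log1p))
  out
}

#' Principal components analysis of chemical profiles
#'
#' Centred (and by default unit-variance scaled) PCA of the per-bird profile
#' matrix. When scaling, zero-variance compounds are dropped with a warning.
#' Component signs follow a deterministic convention: each component is
#' flipped so its largest-magnitude loading is positive, making reports
#' reproducible across platforms.
#'
#' @param profiles Tibble from [aggregate_profiles()] (`individual` + one
#'   numeric column per compound); >= 3 individuals, >= 2 compounds, no
#'   missing values.
#' @param scale Logical; unit-variance scale columns (correlation PCA,
#'   default) or centre only (covariance PCA).
#' @param cor_threshold Absolute compound-component correlation at or above
#'   which a compound is flagged as strongly associated with a component.
#' @return An object of class `chem_pca`: `scores` (tibble `individual`,
#'   `PC1`, ...), `var_explained`, `eigenvalues`, `loadings`,
#'   `correlations` (compound-component Pearson r), `strong` (flagged
#'   compounds per component), plus the data dimensions.
#' @export
chem_pca <- function(profiles, scale = TRUE, cor_threshold = 0.7) {
  cmp <- setdiff(names(profiles), "individual")
  x <- as.matrix(profiles[cmp])
  rownames(x) <- profiles$individual
  if (anyNA(x)) stop("missing values in chemical profiles", call. = FALSE)
  if (nrow(x) < 3) stop("PCA needs at least 3 individuals", call. = FALSE)
  if (ncol(x) < 2) stop("PCA needs at least 2 compounds", call. = FALSE)
  dropped <- character(0)
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    dropped <- colnames(x)[sds == 0]
    if (length(dropped) > 0) {
      warning("dropping zero-variance compound(s) before scaling: ",
              paste(dropped, collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  # sign convention: largest-magnitude loading of each component positive
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  ev <- p$sdev^2
  correlations <- suppressWarnings(stats::cor(x, p$x))
  strong <- lapply(seq_len(ncol(correlations)), function(k) {
    r <- correlations[, k]
    names(r)[!is.na(r) & abs(r) >= cor_threshold]
  })
  names(strong) <- colnames(p$x)
  structure(
    list(
      scores = tibble::as_tibble(p$x, rownames = "individual"),
      var_explained = ev / sum(ev),
      eigenvalues = ev,
      loadings = p$rotation,
      correlations = correlations,
      strong = strong,
      cor_threshold = cor_threshold,
      scale = scale,
      dropped = dropped,
      n = nrow(x),
      p = ncol(x)
    ),
    class = "chem_pca"
  )
}

#' @export
print.chem_pca <- function(x, ...) {
  cat("Chemical profile PCA:", x$n, "individuals x", x$p, "compounds",
      if (x$scale) "(correlation)" else "(covariance)", "\n")
  k <- min(5, length(x$var_explained))
  cat("Variance explained:",
      paste0(colnames(x$loadings)[1:k], " ",
             sprintf("%.1f%%", 100 * x$var_explained[1:k]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Choose how many principal components to retain
#'
#' Compares three standard retention rules and returns their median
#' recommendation (unless `override` is given): Kaiser-Guttman (eigenvalues
#' above the mean eigenvalue), the broken-stick model
#' (b_k = (1/p) * sum_{i=k..p} 1/i of total variance), and Horn's parallel
#' analysis (components whose eigenvalues exceed the chosen quantile of
#' eigenvalues from `n_sim` simulated independent-normal datasets of the same
#' size). Broken-stick and parallel analysis count the leading run of
#' components passing their threshold.
#'
#' @param x A `chem_pca` object, or a nonnegative non-increasing eigenvalue
#'   vector.
#' @param n_obs Number of observations (rows); required for parallel
#'   analysis when `x` is a plain eigenvalue vector.
#' @param override If supplied, returned as-is (reproduces an analysis that
#'   fixed the component count a priori).
#' @param n_sim,quantile,seed Parallel-analysis simulation controls.
#' @param scale Whether parallel-analysis reference data are scaled
#'   (correlation PCA); taken from the `chem_pca` object when available.
#' @return Integer count of components, with attribute `"criteria"` holding
#'   the three per-rule recommendations.
#' @export
retain_components <- function(x, n_obs = NULL, override = NULL, n_sim = 199,
                              quantile = 0.95, seed = 1, scale = TRUE) {
  if (inherits(x, "chem_pca")) {
    n_obs <- x$n
    scale <- x$scale
    ev <- x$eigenvalues
  } else {
    ev <- x
  }
  if (length(ev) == 0) stop("empty eigenvalue vector", call. = FALSE)
  if (any(ev < 0) || is.unsorted(rev(ev))) {
    stop("eigenvalues must be nonnegative and non-increasing", call. = FALSE)
  }
  if (!is.null(override)) {
    return(structure(as.integer(override), criteria = NULL))
  }
  p <- length(ev)
  kaiser <- sum(ev > mean(ev))
  bs <- broken_stick(p)
  prop <- ev / sum(ev)
  bs_keep <- prop > bs
  broken <- if (bs_keep[1]) which.min(c(bs_keep, FALSE)) - 1L else 0L
  if (is.null(n_obs)) {
    stop("`n_obs` is required for parallel analysis on a plain eigenvalue ",
         "vector", call. = FALSE)
  }
  qs <- parallel_eigen_quantiles(n_obs, p, n_sim, quantile, seed, scale)
  pa_keep <- ev > qs
  horn <- if (pa_keep[1]) which.min(c(pa_keep, FALSE)) - 1L else 0L
  crit <- c(kaiser = as.integer(kaiser), broken_stick = as.integer(broken),
            parallel = as.integer(horn))
  structure(as.integer(stats::median(crit)), criteria = crit)
}

# Broken-stick expected proportions b_k = (1/p) * sum_{i=k}^{p} 1/i.
broken_stick <- function(p) {
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

parallel_eigen_quantiles <- function(n, p, n_sim, quantile, seed, scale) {
  sims <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      z <- matrix(stats::rnorm(n * p), n, p)
      stats::prcomp(z, center = TRUE, scale. = scale)$sdev^2
    }, numeric(min(n - 1, p)))
  })
  q <- apply(sims, 1, stats::quantile, probs = quantile, names = FALSE)
  # pad in the degenerate n-1 < p case so comparison lengths match
  c(q, rep(Inf, max(0, p - length(q))))
}

#' Dyadic chemical distance matrices for one component
#'
#' Absolute pairwise differences in one principal component's scores, split
#' into the female-female, male-male (square symmetric, zero diagonal) and
#' male-female (rectangular, rows = males, columns = females) dyad groups.
#'
#' @param scores A `chem_pca` object or its `scores` tibble.
#' @param sex Tibble with columns `individual`, `sex` ("F"/"M"), or a named
#'   character vector keyed by individual.
#' @param component Component index (1 = PC1).
#' @return Named list of matrices `FF`, `MM`, `MF`.
#' @export
pc_distance_matrices <- function(scores, sex, component = 1) {
  if (inherits(scores, "chem_pca")) scores <- scores$scores
  col <- paste0("PC", component)
  if (!col %in% names(scores)) {
    stop("no component ", component, " in scores", call. = FALSE)
  }
  v <- stats::setNames(scores[[col]], scores$individual)
  value_distance_matrices(v, sex)
}

#' Dyadic absolute-difference matrices for any per-individual value
#'
#' @param values Named numeric vector keyed by individual id.
#' @param sex As in [pc_distance_matrices()].
#' @return Named list of matrices `FF`, `MM`, `MF`.
#' @export
value_distance_matrices <- function(values, sex) {
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$individual)
  sex <- sex[names(values)]
  check_sex(sex)
  full <- abs(outer(values, values, `-`))
  dimnames(full) <- list(names(values), names(values))
  split_dyad_groups(full, sex)
}

#' Euclidean compound-profile distance matrices by dyad group
#'
#' Euclidean distances between individuals over a chosen set of compound
#' columns of a profile table (optionally unit-variance standardized first),
#' split into the FF / MM / MF dyad groups. Used for signal-compound and
#' BIO-ENV style analyses.
#'
#' @inheritParams chem_pca
#' @inheritParams pc_distance_matrices
#' @param compounds Character vector of compound columns (default all).
#' @param scale Standardize columns before computing distances.
#' @return Named list of matrices `FF`, `MM`, `MF`.
#' @export
profile_distance_matrices <- function(profiles, sex, compounds = NULL,
                                      scale = FALSE) {
  cmp <- setdiff(names(profiles), "individual")
  if (!is.null(compounds)) {
    missing_cols <- setdiff(compounds, cmp)
    if (length(missing_cols) > 0) {
      stop("unknown compound column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    cmp <- compounds
  }
  x <- as.matrix(profiles[cmp])
  rownames(x) <- profiles$individual
  if (scale) x <- base::scale(x)
  full <- as.matrix(stats::dist(x))
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$individual)
  check_sex(sex[rownames(full)])
  split_dyad_groups(full, sex)
}

#' Convert a dyad matrix to a tidy tibble
#'
#' @param m Square symmetric (lower triangle taken) or rectangular dyad
#'   matrix with dimnames.
#' @return Tibble `id1`, `id2`, `distance`, ordered as [unfold_dyads()].
#' @export
dyads_to_tibble <- function(m) {
  if (is_square_symmetric(m)) {
    idx <- which(lower.tri(m), arr.ind = TRUE)
  } else {
    idx <- cbind(rep(seq_len(nrow(m)), times = ncol(m)),
                 rep(seq_len(ncol(m)), each = nrow(m)))
  }
  tibble::tibble(
    id1 = rownames(m)[idx[, 1]],
    id2 = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}
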