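#' Configuration for the full analysis pipeline
#'
#' One object collects every analysis choice, each defaulting to the
#' convention used throughout the package: correlation PCA, two retained
#' components fixed a priori, maximum-rule dyadic MHC distance, two-sided
#' permutation tests with 10 000 draws, and Bonferroni families of 6 linear
#' models and 9 dyadic tests.
#'
#' @param sim A [sim_config()] to simulate inputs, or `NULL` when `paths`
#'   is given.
#' @param paths Optional named list with `peak_table`, `genotype_table`,
#'   `alleles` (TSV/TSV/FASTA) to ingest real data instead of simulating.
#' @param pca_scale Correlation (TRUE) vs covariance PCA.
#' @param retain_override Retained component count fixed a priori (default
#'   2); `NULL` lets the three retention criteria decide.
#' @param locus_modes MHC distance/diversity measures to run.
#' @param dyad_rule `"max"` or `"mean"` cross-pair rule for dyadic MHC
#'   distance.
#' @param n_perm Permutations per dyadic test.
#' @param tail Test tail.
#' @param alpha Family-wise error rate before Bonferroni adjustment.
#' @param bioenv_groups Dyad groups to run BIO-ENV on (subset of
#'   `"FF"`, `"MM"`).
#' @param bioenv_loci Genetic targets for BIO-ENV.
#' @param bioenv_k_max Largest subset size.
#' @param bioenv_n_compounds Pre-filter: exhaustive search runs on the
#'   compounds most correlated (absolute Pearson r) with the tested
#'   component, keeping the search at desk scale; `NULL` uses all compounds.
#' @param seed Master seed; per-test seeds derive from it deterministically.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            pca_scale = TRUE, retain_override = 2,
                            locus_modes = c("DAB1", "DAB2", "both"),
                            dyad_rule = "max", n_perm = 10000,
                            tail = "two-sided", alpha = 0.05,
                            bioenv_groups = "FF",
                            bioenv_loci = c("DAB2", "both"),
                            bioenv_k_max = 6, bioenv_n_compounds = 15,
                            seed = 1) {
  structure(
    list(sim = sim, paths = paths, pca_scale = pca_scale,
         retain_override = retain_override, locus_modes = locus_modes,
         dyad_rule = dyad_rule, n_perm = n_perm, tail = tail, alpha = alpha,
         bioenv_groups = bioenv_groups, bioenv_loci = bioenv_loci,
         bioenv_k_max = bioenv_k_max,
         bioenv_n_compounds = bioenv_n_compounds, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full odour-gene covariance analysis
#'
#' Simulates (or ingests) a cohort, builds per-bird chemical profiles and
#' PC scores, computes MHC diversity and dyadic distance matrices, then
#' produces three reports: per-model coefficient tables with Type III tests
#' (`models`), the 3 dyad groups x locus modes table of partial Mantel /
#' rectangular partial Spearman tests with PC1 and PC2 columns (`dyadic`),
#' and BIO-ENV best subsets (`bioenv`). Each dyadic test controls for the
#' other retained component and the breeding-status difference matrix.
#' Identical config (including seeds) gives identical outputs; when
#' `out_dir` is given the reports are also written as TSV plus a JSON run
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `models`, `dyadic`, `bioenv`, `pca`,
#'   `retained`, `diversity`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- load_study(config)
  profiles <- aggregate_profiles(study$peak_table)
  gt <- study$genotype_table[match(profiles$individual,
                                   study$genotype_table$individual), ]
  if (anyNA(gt$individual)) {
    stop("stage genotypes: peak-table individual missing from genotype ",
         "table", call. = FALSE)
  }
  pca <- chem_pca(profiles, scale = config$pca_scale)
  retained <- retain_components(pca, override = config$retain_override,
                                seed = config$seed)
  k <- max(2L, as.integer(retained)) # dyadic layout needs two components
  sex <- stats::setNames(gt$sex, gt$individual)

  diversity <- purrr::map_dfr(config$locus_modes, function(l) {
    d <- genotype_diversity(gt, study$alleles, locus = l)
    d$locus <- l
    d
  })

  # --- per-individual interaction models (Table-1-like) -------------------
  model_data <- dplyr::left_join(
    pca$scores[c("individual", paste0("PC", seq_len(min(k, pca$p))))],
    gt[c("individual", "sex", "breeding_status")],
    by = "individual"
  )
  models <- purrr::map_dfr(c("PC1", "PC2"), function(resp) {
    purrr::map_dfr(config$locus_modes, function(l) {
      dd <- dplyr::left_join(
        model_data,
        diversity[diversity$locus == l, c("individual", "diversity")],
        by = "individual"
      )
      fit <- fit_interaction_model(dd, response = resp,
                                   diversity = "diversity")
      out <- tidy(fit)
      out$response <- resp
      out$locus <- l
      g <- glance(fit)
      out$adj_r_squared <- g$adj_r_squared
      out$model_p <- g$p_value
      out
    })
  })
  models$adjusted_alpha <- bonferroni_alpha(config$alpha,
                                            2 * length(config$locus_modes))

  # --- dyadic permutation tests (Table-2-like) ----------------------------
  pc_mats <- lapply(1:2, function(cc) pc_distance_matrices(pca, sex, cc))
  status_mats <- value_distance_matrices(
    stats::setNames(gt$breeding_status, gt$individual), sex
  )
  n_family <- 3 * length(config$locus_modes)
  adj <- bonferroni_alpha(config$alpha, n_family)
  test_seed <- seed_stream(config$seed)
  dyadic <- purrr::map_dfr(config$locus_modes, function(l) {
    mhc <- mhc_distance_matrices(gt, study$alleles, locus = l,
                                 rule = config$dyad_rule)
    purrr::map_dfr(c("FF", "MM", "MF"), function(grp) {
      res <- purrr::map(1:2, function(cc) {
        covs <- list(pc_mats[[3 - cc]][[grp]], status_mats[[grp]])
        if (grp == "MF") {
          partial_spearman_rect(pc_mats[[cc]][[grp]], mhc[[grp]],
                                covariates = covs, n_perm = config$n_perm,
                                tail = config$tail, seed = test_seed(),
                                adjusted_alpha = adj, keep_perms = FALSE)
        } else {
          partial_mantel(pc_mats[[cc]][[grp]], mhc[[grp]],
                         covariates = covs, n_perm = config$n_perm,
                         tail = config$tail, seed = test_seed(),
                         adjusted_alpha = adj, keep_perms = FALSE)
        }
      })
      tibble::tibble(
        dyad_group = grp, locus = l,
        n_dyads = res[[1]]$n_dyads,
        test = res[[1]]$statistic,
        r_pc1 = res[[1]]$observed, p_pc1 = res[[1]]$p_value,
        r_pc2 = res[[2]]$observed, p_pc2 = res[[2]]$p_value,
        n_perm = config$n_perm, adjusted_alpha = adj
      )
    })
  })

  # --- BIO-ENV (Table-3-like) ---------------------------------------------
  bioenv <- purrr::map_dfr(config$bioenv_groups, function(grp) {
    keep <- names(sex)[sex == if (grp == "FF") "F" else "M"]
    prof_g <- profiles[profiles$individual %in% keep, ]
    purrr::map_dfr(config$bioenv_loci, function(l) {
      mhc <- mhc_distance_matrices(gt, study$alleles, locus = l,
                                   rule = config$dyad_rule)[[grp]]
      cmp <- setdiff(names(prof_g), "individual")
      if (!is.null(config$bioenv_n_compounds) &&
          config$bioenv_n_compounds < length(cmp)) {
        # pre-filter to the compounds most correlated with PC2 (the
        # component the dyadic female analyses concern), keeping the
        # exhaustive search at desk scale; flagged in the report
        r2 <- abs(pca$correlations[, "PC2"])
        cmp <- names(sort(r2, decreasing = TRUE))[
          seq_len(config$bioenv_n_compounds)]
        prof_g <- prof_g[c("individual", sort(cmp))]
      }
      res <- bioenv_search(prof_g, mhc, k_max = config$bioenv_k_max)
      tibble::tibble(
        dyad_group = grp, locus = l,
        mantel_r = res$best_correlation,
        n_compounds = res$best_k,
        compounds = paste(res$best_compounds, collapse = ", "),
        n_evaluated = res$n_evaluated,
        prefiltered = length(cmp) < pca$p
      )
    })
  })

  manifest <- list(
    package = "scentmhc",
    version = as.character(utils::packageVersion("scentmhc")),
    seed = config$seed,
    config = config_as_list(config),
    retained_components = as.integer(retained),
    n_individuals = nrow(profiles),
    n_compounds = pca$p,
    var_explained_pc1_pc2 = sum(pca$var_explained[1:2]),
    n_dyadic_tests = nrow(dyadic),
    decisions = list(
      pca = if (config$pca_scale) "correlation" else "covariance",
      dyad_rule = config$dyad_rule,
      rectangular_null = "entries",
      bioenv_correlation = "mantel_pearson"
    )
  )
  out <- list(models = models, dyadic = dyadic, bioenv = bioenv, pca = pca,
              retained = retained, diversity = diversity,
              manifest = manifest)
  if (!is.null(out_dir)) write_reports(out, out_dir)
  invisible(out)
}

seed_stream <- function(seed) {
  counter <- 0L
  function() {
    counter <<- counter + 1L
    (seed * 1000L + counter) %% .Machine$integer.max
  }
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
  cfg
}

load_study <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    list(
      peak_table = read_peak_table(p$peak_table),
      genotype_table = read_genotype_table(p$genotype_table),
      alleles = {
        seqs <- read_allele_fasta(p$alleles)
        tibble::tibble(id = names(seqs), locus = NA_character_,
                       sequence = unname(seqs))
      }
    )
  } else if (!is.null(config$sim)) {
    generate_cohort(config$sim)
  } else {
    stop("stage input: config needs either `sim` or `paths`", call. = FALSE)
  }
}

write_reports <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out$models, file.path(out_dir, "models.tsv"))
  readr::write_tsv(out$dyadic, file.path(out_dir, "dyadic_tests.tsv"))
  readr::write_tsv(out$bioenv, file.path(out_dir, "bioenv.tsv"))
  readr::write_tsv(out$diversity, file.path(out_dir, "diversity.tsv"))
  readr::write_tsv(out$pca$scores, file.path(out_dir, "pc_scores.tsv"))
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
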