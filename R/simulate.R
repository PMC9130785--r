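#' Configuration for a synthetic cohort
#'
#' Defaults emulate the study design the analysis assumes: 40 birds per sex
#' sampled while incubating, 80 volatile compounds quantified in triplicate
#' against an internal standard, two MHC class IIB loci (DAB1, DAB2) with
#' two allele copies each drawn from a per-locus pool, and breeding status
#' spanning an approximately 45-day incubation window. A tunable subset of
#' "signal" compounds depends on MHC composition through (i) a linear term
#' in functional genotype diversity and (ii) an additive per-allele
#' contribution that makes chemically similar what is genotypically similar
#' — the dyadic structure the permutation tests look for.
#'
#' @param n_per_sex Individuals per sex.
#' @param n_compounds Compounds in the peak table.
#' @param n_signal_compounds Compounds carrying the MHC signal
#'   (<= `n_compounds`).
#' @param alleles_per_locus Size of the allele pool at each locus.
#' @param seq_length Allele length in amino acids (~100 for a 300 bp exon-2
#'   fragment).
#' @param effect_size Strength of the MHC signal on the log-abundance scale:
#'   both the slope on genotype diversity and the s.d. of per-allele
#'   additive contributions. 0 switches the signal off entirely.
#' @param noise_sd Replicate-level log-scale measurement noise s.d.
#' @param sex_effect,breeding_effect Log-scale main effects of sex (applied
#'   as +/- `sex_effect`/2) and of breeding status (per day).
#' @param incubation_span_days Width of the breeding-status window.
#' @param n_replicates Replicates per bird.
#' @param allele_freqs Optional list with elements `DAB1`, `DAB2`: sampling
#'   probabilities over each pool (default uniform).
#' @param indiv_sd Per-compound individual-identity log-scale s.d. (odour
#'   individuality unrelated to sex, breeding stage or MHC; shared by all
#'   replicates of a bird).
#' @param variable_fraction Fraction of positions that are hypervariable in
#'   each locus pool (alleles at a locus share a founder sequence and differ
#'   only at these sites, emulating allelic descent at exon 2).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_sex = 40, n_compounds = 80,
                       n_signal_compounds = 9, alleles_per_locus = 6,
                       seq_length = 100, effect_size = 1, noise_sd = 0.3,
                       sex_effect = 0.5, breeding_effect = 0.02,
                       indiv_sd = 0.3, incubation_span_days = 45,
                       n_replicates = 3, allele_freqs = NULL,
                       variable_fraction = 0.3, seed = 1) {
  cfg <- list(
    n_per_sex = n_per_sex, n_compounds = n_compounds,
    n_signal_compounds = n_signal_compounds,
    alleles_per_locus = alleles_per_locus, seq_length = seq_length,
    effect_size = effect_size, noise_sd = noise_sd, sex_effect = sex_effect,
    breeding_effect = breeding_effect, indiv_sd = indiv_sd,
    incubation_span_days = incubation_span_days,
    n_replicates = n_replicates, allele_freqs = allele_freqs,
    variable_fraction = variable_fraction, seed = seed
  )
  counts <- c("n_per_sex", "n_compounds", "n_signal_compounds",
              "alleles_per_locus", "seq_length", "incubation_span_days",
              "n_replicates")
  for (nm in counts) {
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]])) {
      stop("`", nm, "` must be a positive integer", call. = FALSE)
    }
  }
  if (n_signal_compounds > n_compounds) {
    stop("`n_signal_compounds` must be <= `n_compounds`", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (indiv_sd < 0) stop("`indiv_sd` must be >= 0", call. = FALSE)
  if (variable_fraction <= 0 || variable_fraction > 1) {
    stop("`variable_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(allele_freqs)) {
    for (l in c("DAB1", "DAB2")) {
      f <- allele_freqs[[l]]
      if (is.null(f) || length(f) != alleles_per_locus || any(f < 0) ||
          sum(f) <= 0) {
        stop("`allele_freqs$", l, "` must be ", alleles_per_locus,
             " nonnegative weights", call. = FALSE)
      }
    }
  }
  structure(cfg, class = "sim_config")
}

#' Generate a pool of distinct alleles
#'
#' Random amino-acid sequences of common length over the 20 standard
#' residues; all sequences in the pool are pairwise distinct and draws are
#' deterministic for a fixed seed.
#'
#' @param n_alleles Pool size, >= 1.
#' @param seq_length Sequence length in residues, >= 1.
#' @param seed Integer seed.
#' @param prefix Id prefix, e.g. `"DAB1"`.
#' @return Named character vector of `n_alleles` distinct sequences.
#' @export
generate_allele_pool <- function(n_alleles, seq_length, seed = 1,
                                 prefix = "allele") {
  if (n_alleles < 1 || seq_length < 1) {
    stop("`n_alleles` and `seq_length` must be >= 1", call. = FALSE)
  }
  if (log(n_alleles) > seq_length * log(20)) {
    stop("cannot draw ", n_alleles, " distinct sequences of length ",
         seq_length, " over 20 residues", call. = FALSE)
  }
  aas <- rownames(.z_scales)
  withr::with_seed(seed, {
    pool <- character(0)
    while (length(pool) < n_alleles) {
      need <- n_alleles - length(pool)
      new <- vapply(seq_len(need), function(i) {
        paste(sample(aas, seq_length, replace = TRUE), collapse = "")
      }, character(1))
      pool <- unique(c(pool, new))
    }
    stats::setNames(pool[seq_len(n_alleles)],
                    sprintf("%s_%02d", prefix, seq_len(n_alleles)))
  })
}

#' Generate a pool of alleles related by descent
#'
#' MHC alleles at a locus are not independent random sequences: they descend
#' from common ancestors and differ mainly at hypervariable sites. This
#' generator draws a founder sequence and a shared substitution path over a
#' fraction of positions, then derives each allele by applying the first
#' `m` substitutions of the path, with `m` evenly spaced from 0 (the
#' founder itself) to the full path. The pool is therefore an allelic
#' series of graded functional divergence: because the substitution sets
#' are nested, the functional distance between any two alleles equals the
#' difference of their divergences from the founder, giving the pool a
#' one-dimensional functional geometry with strongly heterogeneous pairwise
#' distances — the structure dyadic genotype distances rely on.
#'
#' @inheritParams generate_allele_pool
#' @param variable_fraction Fraction of positions on the substitution path.
#' @return Named character vector of `n_alleles` distinct sequences, in
#'   order of increasing divergence from the founder (the first entry).
#' @export
generate_related_pool <- function(n_alleles, seq_length,
                                  variable_fraction = 0.3, seed = 1,
                                  prefix = "allele") {
  if (n_alleles < 1 || seq_length < 1) {
    stop("`n_alleles` and `seq_length` must be >= 1", call. = FALSE)
  }
  aas <- rownames(.z_scales)
  n_var <- max(1, round(variable_fraction * seq_length))
  if (n_alleles > n_var + 1) {
    stop("at most ", n_var + 1, " distinct alleles on a path of ", n_var,
         " variable sites; increase `variable_fraction` or `seq_length`",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    founder <- sample(aas, seq_length, replace = TRUE)
    path <- sample.int(seq_length, n_var)
    # derived residue differs from the founder's at every path site
    subs <- vapply(path, function(pos) {
      sample(setdiff(aas, founder[pos]), 1)
    }, character(1))
    depth <- round(seq(0, n_var, length.out = n_alleles))
    pool <- vapply(depth, function(m) {
      s <- founder
      if (m > 0) s[path[seq_len(m)]] <- subs[seq_len(m)]
      paste(s, collapse = "")
    }, character(1))
    stats::setNames(pool, sprintf("%s_%02d", prefix, seq_len(n_alleles)))
  })
}

#' Generate a synthetic cohort
#'
#' Builds a complete simulated study from a [sim_config()]: per-locus
#' descent-structured allele pools ([generate_related_pool()]),
#' balanced-sex genotypes (two copies per locus, homozygosity allowed),
#' breeding status uniform over the incubation window (stored as sample
#' date minus hatch date, so values are negative during incubation and
#' larger means later), and a replicate-level peak table. Per-compound log
#' standardized abundance is
#' `baseline + sex term + breeding term + individual-identity effect +
#' [signal compounds only: effect_size * diversity + mean per-allele
#' contribution] + replicate noise`. Each pool allele's fixed contribution
#' to a signal compound is the compound's loading times the allele's
#' functional divergence from its locus founder (computed with
#' [allele_distance()] and centered within the pool), so functionally
#' similar alleles contribute similar chemistry, the signal compounds form
#' one correlated MHC-driven block, and chemical similarity tracks
#' functional genotype similarity — the covariance the dyadic tests are
#' built to detect. Raw peak areas are recovered by multiplying by each
#' replicate's internal-standard area and sample mass (both log-normal), so
#' all areas are strictly positive and standardization inverts exactly.
#'
#' @param config A [sim_config()].
#' @return A `simulated_study` list: `peak_table`, `genotype_table`,
#'   `alleles` (tibble `id`, `locus`, `sequence`), `truth` (signal compound
#'   names, per-allele contribution matrix, diversity vector, effect sizes)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    pools <- list(
      DAB1 = generate_related_pool(cfg$alleles_per_locus, cfg$seq_length,
                                   cfg$variable_fraction,
                                   seed = sample.int(2^30, 1),
                                   prefix = "DAB1"),
      DAB2 = generate_related_pool(cfg$alleles_per_locus, cfg$seq_length,
                                   cfg$variable_fraction,
                                   seed = sample.int(2^30, 1),
                                   prefix = "DAB2")
    )
    n <- 2 * cfg$n_per_sex
    ids <- sprintf("bird_%03d", seq_len(n))
    sex <- rep(c("F", "M"), each = cfg$n_per_sex)
    draw <- function(locus) {
      f <- cfg$allele_freqs[[locus]]
      sample(names(pools[[locus]]), n, replace = TRUE, prob = f)
    }
    genotype_table <- tibble::tibble(
      individual = ids, sex = sex,
      breeding_status = -sample.int(cfg$incubation_span_days, n,
                                    replace = TRUE) + 1L,
      dab1_1 = draw("DAB1"), dab1_2 = draw("DAB1"),
      dab2_1 = draw("DAB2"), dab2_2 = draw("DAB2")
    )
    alleles <- tibble::tibble(
      id = c(names(pools$DAB1), names(pools$DAB2)),
      locus = rep(c("DAB1", "DAB2"), each = cfg$alleles_per_locus),
      sequence = c(unname(pools$DAB1), unname(pools$DAB2))
    )
    diversity <- genotype_diversity(genotype_table, alleles,
                                    locus = "both")$diversity
    compounds <- sprintf("compound_%03d", seq_len(cfg$n_compounds))
    signal <- compounds[seq_len(cfg$n_signal_compounds)]
    # each allele shifts a latent MHC odour axis in proportion to its
    # functional divergence from the locus founder (centered per locus);
    # signal compounds load on this shared axis with compound-specific
    # loadings, forming the correlated compound block an empirical "MHC
    # component" would pick up
    phi <- unlist(lapply(pools, function(pool) {
      d <- vapply(pool, allele_distance, numeric(1), b = pool[[1]])
      d - mean(d)
    }), use.names = FALSE)
    names(phi) <- alleles$id
    loadings <- stats::setNames(
      sample(c(-1, 1), cfg$n_signal_compounds, replace = TRUE) *
        stats::runif(cfg$n_signal_compounds, 0.75, 1.25),
      signal
    )
    contrib <- cfg$effect_size * outer(phi, loadings)
    dimnames(contrib) <- list(alleles$id, signal)
    copies <- as.matrix(genotype_table[c("dab1_1", "dab1_2",
                                         "dab2_1", "dab2_2")])
    indiv_contrib <- (contrib[copies[, 1], , drop = FALSE] +
                      contrib[copies[, 2], , drop = FALSE] +
                      contrib[copies[, 3], , drop = FALSE] +
                      contrib[copies[, 4], , drop = FALSE]) / 4
    baseline <- stats::rnorm(cfg$n_compounds, mean = 1, sd = 0.5)
    sex_code <- ifelse(sex == "F", 0.5, -0.5)
    mu <- matrix(baseline, n, cfg$n_compounds, byrow = TRUE,
                 dimnames = list(ids, compounds))
    mu <- mu + cfg$sex_effect * sex_code +
      cfg$breeding_effect * genotype_table$breeding_status +
      matrix(stats::rnorm(n * cfg$n_compounds, sd = cfg$indiv_sd),
             n, cfg$n_compounds)
    mu[, signal] <- mu[, signal] + cfg$effect_size * diversity +
      indiv_contrib
    nrep <- cfg$n_replicates
    rep_rows <- rep(seq_len(n), each = nrep)
    noise <- matrix(stats::rnorm(n * nrep * cfg$n_compounds,
                                 sd = cfg$noise_sd),
                    n * nrep, cfg$n_compounds)
    std_abund <- exp(mu[rep_rows, , drop = FALSE] + noise)
    mass <- stats::rlnorm(n * nrep, meanlog = log(0.004), sdlog = 0.15)
    is_area <- stats::rlnorm(n * nrep, meanlog = log(1e5), sdlog = 0.2)
    peak_table <- tibble::tibble(
      individual = ids[rep_rows],
      replicate = rep(seq_len(nrep), times = n),
      sample_mass = mass,
      is_area = is_area
    )
    peak_table[compounds] <- std_abund * (is_area * mass)
    structure(
      list(
        peak_table = peak_table,
        genotype_table = genotype_table,
        alleles = alleles,
        truth = list(
          signal_compounds = signal,
          contributions = contrib,
          loadings = loadings,
          allele_divergence = phi,
          diversity = stats::setNames(diversity, ids),
          effect_size = cfg$effect_size,
          sex_effect = cfg$sex_effect,
          breeding_effect = cfg$breeding_effect,
          baseline = stats::setNames(baseline, compounds)
        ),
        config = cfg
      ),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat("Simulated cohort:", 2 * cfg$n_per_sex, "birds (",
      cfg$n_per_sex, "per sex ),", cfg$n_compounds, "compounds x",
      cfg$n_replicates, "replicates\n")
  cat("Signal compounds:", cfg$n_signal_compounds,
      "| effect size:", cfg$effect_size, "| seed:", cfg$seed, "\n")
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Peak and genotype tables as TSV, the allele pool as amino-acid FASTA, and
#' the truth record as JSON.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peak_table = file.path(dir, "peak_table.tsv"),
    genotype_table = file.path(dir, "genotype_table.tsv"),
    alleles = file.path(dir, "alleles.fasta"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(study$peak_table, paths["peak_table"])
  readr::write_tsv(study$genotype_table, paths["genotype_table"])
  write_allele_fasta(study$alleles, paths["alleles"])
  truth <- study$truth
  truth$contributions <- as.data.frame(truth$contributions)
  jsonlite::write_json(truth, paths["truth"], digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a peak table or genotype table written by [write_study()]
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_peak_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_peak_table
#' @export
read_genotype_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
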