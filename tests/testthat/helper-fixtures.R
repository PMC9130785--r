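# Small deterministic fixtures shared across test files.

# tiny cohort for structural tests
tiny_cohort <- function(seed = 42, n_per_sex = 10, n_compounds = 12,
                        ...) {
  generate_cohort(sim_config(n_per_sex = n_per_sex,
                             n_compounds = n_compounds,
                             n_signal_compounds = 3, seq_length = 40,
                             seed = seed, ...))
}

# labelled absolute-difference matrix from a named value vector
abs_diff_matrix <- function(v) {
  m <- abs(outer(v, v, `-`))
  dimnames(m) <- list(names(v), names(v))
  m
}

# random square symmetric dyad matrix with zero diagonal
random_dyad_matrix <- function(n, seed, prefix = "i") {
  withr::with_seed(seed, {
    v <- stats::setNames(rnorm(n), sprintf("%s%02d", prefix, seq_len(n)))
    abs_diff_matrix(v)
  })
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# small genotype table + allele set over two ladder pools
toy_genotypes <- function() {
  p1 <- generate_related_pool(3, 12, seed = 5, prefix = "DAB1")
  p2 <- generate_related_pool(3, 12, seed = 6, prefix = "DAB2")
  alleles <- tibble::tibble(
    id = c(names(p1), names(p2)),
    locus = rep(c("DAB1", "DAB2"), each = 3),
    sequence = c(unname(p1), unname(p2))
  )
  genotypes <- tibble::tibble(
    individual = c("f1", "f2", "m1"),
    sex = c("F", "F", "M"),
    breeding_status = c(-10, -20, -30),
    dab1_1 = c("DAB1_01", "DAB1_02", "DAB1_01"),
    dab1_2 = c("DAB1_01", "DAB1_03", "DAB1_02"),
    dab2_1 = c("DAB2_01", "DAB2_01", "DAB2_03"),
    dab2_2 = c("DAB2_02", "DAB2_01", "DAB2_03")
  )
  list(genotypes = genotypes, alleles = alleles)
}
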