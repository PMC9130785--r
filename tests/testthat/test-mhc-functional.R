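test_that("aa_distance matches a brute-force five-term Euclidean oracle", {
  zt <- z_descriptors()
  zm <- as.matrix(zt[, -1])
  rownames(zm) <- zt$aa
  withr::with_seed(11, {
    pairs <- cbind(sample(zt$aa, 50, replace = TRUE),
                   sample(zt$aa, 50, replace = TRUE))
  })
  oracle <- apply(pairs, 1, function(p) {
    s <- 0
    for (k in 1:5) s <- s + (zm[p[1], k] - zm[p[2], k])^2
    sqrt(s)
  })
  expect_equal(aa_distance(pairs[, 1], pairs[, 2]), oracle,
               tolerance = 1e-12)
})

test_that("aa_distance is a metric on the 20 residues", {
  aa <- z_descriptors()$aa
  d <- outer(aa, aa, aa_distance)
  expect_true(all(d >= 0))
  expect_equal(diag(d), rep(0, 20))
  expect_equal(d, t(d)) # symmetry over all 400 ordered pairs
  # off-diagonal strictly positive (identity of indiscernibles)
  expect_true(all(d[upper.tri(d)] > 0))
  # triangle inequality over all 20^3 triples
  viol <- 0L
  for (k in 1:20) {
    viol <- viol + sum(d > outer(d[, k], d[k, ], `+`) + 1e-12)
  }
  expect_identical(viol, 0L)
})

test_that("aa_distance rejects unknown symbols", {
  expect_error(aa_distance("A", "X"), "X")
  expect_error(aa_distance("-", "A"), "-")
})

test_that("distances scale homogeneously with the descriptor table", {
  zt <- z_descriptors()
  zt_scaled <- zt
  zt_scaled[, -1] <- zt_scaled[, -1] * -2.5
  expect_equal(aa_distance("W", "G", table = zt_scaled),
               2.5 * aa_distance("W", "G"))
  expect_equal(allele_distance("ACDY", "AWDG", table = zt_scaled),
               2.5 * allele_distance("ACDY", "AWDG"))
})

test_that("allele_distance averages positionwise residue distances", {
  expect_equal(allele_distance("ACDEF", "ACDEF"), 0)
  # single differing position out of L
  expect_equal(allele_distance("ACDEF", "ACDEY"),
               aa_distance("F", "Y") / 5)
  # random length-30 pair against a positionwise loop oracle
  withr::with_seed(21, {
    a <- paste(sample(z_descriptors()$aa, 30, replace = TRUE),
               collapse = "")
    b <- paste(sample(z_descriptors()$aa, 30, replace = TRUE),
               collapse = "")
  })
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  oracle <- mean(vapply(1:30, function(i) aa_distance(ca[i], cb[i]),
                        numeric(1)))
  expect_equal(allele_distance(a, b), oracle, tolerance = 1e-12)
  expect_equal(allele_distance(a, b), allele_distance(b, a))
  expect_error(allele_distance("ACD", "AC"), "length")
})

test_that("position masks restrict the averaged positions", {
  a <- "ACDEF"
  b <- "WCDEY"
  expect_equal(allele_distance(a, b, positions = 2:4), 0)
  expect_equal(allele_distance(a, b, positions = c(1, 5)),
               mean(aa_distance(c("A", "F"), c("W", "Y"))))
  expect_error(allele_distance(a, b, positions = c(1, 9)), "range")
})

test_that("genotype_diversity handles per-locus and both-loci modes", {
  toy <- toy_genotypes()
  seqs <- stats::setNames(toy$alleles$sequence, toy$alleles$id)
  # homozygote at a locus -> 0
  d1 <- genotype_diversity(toy$genotypes, toy$alleles, locus = "DAB1")
  expect_equal(d1$diversity[1], 0) # f1 is DAB1_01/DAB1_01
  # heterozygote -> allele distance of its two copies
  d2 <- genotype_diversity(toy$genotypes, toy$alleles, locus = "DAB2")
  expect_equal(d2$diversity[1],
               allele_distance(seqs["DAB2_01"], seqs["DAB2_02"]))
  # both-loci mean over all 6 unordered copy pairs, exhaustive oracle
  g <- toy$genotypes[3, ] # m1: {DAB1_01, DAB1_02, DAB2_03, DAB2_03}
  copies <- c("DAB1_01", "DAB1_02", "DAB2_03", "DAB2_03")
  pairs <- utils::combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(p) {
    allele_distance(seqs[copies[p[1]]], seqs[copies[p[2]]])
  }))
  dboth <- genotype_diversity(toy$genotypes, toy$alleles, locus = "both")
  expect_equal(dboth$diversity[3], oracle)
  # {a,a,b,b} pattern: mean of 6 pairwise distances = 4 d(a,b) / 6
  gt_ab <- toy$genotypes[1, ]
  gt_ab[c("dab1_1", "dab1_2")] <- "DAB1_02"
  gt_ab[c("dab2_1", "dab2_2")] <- "DAB1_03" # same-locus alleles as b
  dab <- allele_distance(seqs["DAB1_02"], seqs["DAB1_03"])
  expect_equal(
    genotype_diversity(gt_ab, toy$alleles, locus = "both")$diversity,
    4 * dab / 6
  )
  # max rule
  dmax <- genotype_diversity(toy$genotypes, toy$alleles, locus = "both",
                             combine = "max")
  oracle_max <- max(apply(pairs, 2, function(p) {
    allele_distance(seqs[copies[p[1]]], seqs[copies[p[2]]])
  }))
  expect_equal(dmax$diversity[3], oracle_max)
})

test_that("diversity is zero iff all copies at the loci are identical", {
  toy <- toy_genotypes()
  hom <- toy$genotypes[1, ]
  hom[c("dab1_1", "dab1_2")] <- "DAB1_01"
  hom[c("dab2_1", "dab2_2")] <- "DAB2_01"
  for (l in c("DAB1", "DAB2")) {
    expect_equal(genotype_diversity(hom, toy$alleles, locus = l)$diversity,
                 0)
  }
  # "both" mode includes cross-locus copy pairs, so even a double
  # homozygote has positive diversity when its two loci carry different
  # sequences
  expect_gt(genotype_diversity(hom, toy$alleles, locus = "both")$diversity,
            0)
})

test_that("dyad_mhc_distance enumerates within-locus cross pairs", {
  toy <- toy_genotypes()
  seqs <- stats::setNames(toy$alleles$sequence, toy$alleles$id)
  gi <- toy$genotypes[2, ] # f2: DAB1_02/DAB1_03, DAB2_01/DAB2_01
  gj <- toy$genotypes[3, ] # m1: DAB1_01/DAB1_02, DAB2_03/DAB2_03
  cross <- c(
    apply(expand.grid(c("DAB1_02", "DAB1_03"),
                      c("DAB1_01", "DAB1_02")), 1,
          function(p) allele_distance(seqs[p[1]], seqs[p[2]])),
    apply(expand.grid(c("DAB2_01", "DAB2_01"),
                      c("DAB2_03", "DAB2_03")), 1,
          function(p) allele_distance(seqs[p[1]], seqs[p[2]]))
  )
  expect_equal(dyad_mhc_distance(gi, gj, toy$alleles, locus = "both"),
               max(cross))
  expect_equal(dyad_mhc_distance(gi, gj, toy$alleles, locus = "both",
                                 rule = "mean"),
               mean(cross))
  # symmetry
  expect_equal(dyad_mhc_distance(gj, gi, toy$alleles, locus = "both"),
               dyad_mhc_distance(gi, gj, toy$alleles, locus = "both"))
  # identical homozygous genotypes -> 0 at their locus
  hom <- gi
  hom[c("dab1_1", "dab1_2")] <- "DAB1_01"
  expect_equal(dyad_mhc_distance(hom, hom, toy$alleles, locus = "DAB1"), 0)
  # single-locus {a,a} vs {b,b}: only one distinct cross pair
  gi1 <- gi
  gi1[c("dab1_1", "dab1_2")] <- "DAB1_01"
  gj1 <- gj
  gj1[c("dab1_1", "dab1_2")] <- "DAB1_03"
  expect_equal(dyad_mhc_distance(gi1, gj1, toy$alleles, locus = "DAB1"),
               allele_distance(seqs["DAB1_01"], seqs["DAB1_03"]))
})

test_that("mhc_distance_matrices partitions dyads and matches the
          pairwise oracle", {
  toy <- toy_genotypes()
  m <- mhc_distance_matrices(toy$genotypes, toy$alleles, locus = "both")
  expect_equal(dim(m$FF), c(2, 2))
  expect_equal(dim(m$MM), c(1, 1))
  expect_equal(dim(m$MF), c(1, 2))
  expect_equal(rownames(m$MF), "m1")
  expect_equal(
    m$FF["f1", "f2"],
    dyad_mhc_distance(toy$genotypes[1, ], toy$genotypes[2, ], toy$alleles)
  )
  expect_equal(
    m$MF["m1", "f2"],
    dyad_mhc_distance(toy$genotypes[3, ], toy$genotypes[2, ], toy$alleles)
  )
  # a cohort of clones gives all-zero matrices
  clones <- toy$genotypes
  clones$dab1_1 <- clones$dab1_2 <- "DAB1_01"
  clones$dab2_1 <- clones$dab2_2 <- "DAB2_01"
  mz <- mhc_distance_matrices(clones, toy$alleles, locus = "both")
  expect_true(all(unlist(mz) == 0))
  # unknown sex label
  bad <- toy$genotypes
  bad$sex[1] <- "U"
  expect_error(mhc_distance_matrices(bad, toy$alleles), "sex")
})

test_that("heterozygosity utilities behave as documented", {
  toy <- toy_genotypes()
  het <- mhc_heterozygosity(toy$genotypes, locus = "DAB1")
  expect_equal(het$mhc_het, c(0, 1, 1)) # f1 hom, f2 het, m1 het
  hb <- mhc_heterozygosity(toy$genotypes, locus = "both")
  expect_equal(hb$mhc_het, c(0.5, 0.5, 0.5))
  # Pearson r against the covariance-formula oracle on fixed 5-point data
  x <- c(0, 1, 1, 0, 1)
  y <- c(0.21, 0.34, 0.29, 0.25, 0.31)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(heterozygosity_correlation(x, y), r_oracle)
  expect_equal(heterozygosity_correlation(y, y), 1)
  expect_warning(r0 <- heterozygosity_correlation(rep(1, 5), y), "variance")
  expect_true(is.na(r0))
  expect_error(heterozygosity_correlation(x, y[1:3]), "paired")
})

test_that("nucleotide alleles translate with frame and stop handling", {
  expect_equal(unname(translate_alleles(c(a = "ATGGCTTGG"))), "MAW")
  # frame 2 skips the first base
  expect_equal(unname(translate_alleles(c(a = "CATGGCTTGG"), frame = 2)),
               "MAW")
  # trailing stop is trimmed, premature stop errors
  expect_equal(unname(translate_alleles(c(a = "ATGGCTTGA"))), "MA")
  expect_error(translate_alleles(c(bad = "ATGTGAGCT")), "bad")
})

test_that("allele FASTA round-trips through Biostrings", {
  toy <- toy_genotypes()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(toy$alleles, path)
  back <- read_allele_fasta(path)
  expect_equal(back, stats::setNames(toy$alleles$sequence, toy$alleles$id))
})
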