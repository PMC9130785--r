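#' Physico-chemical distance between two amino acids
#'
#' Euclidean distance in the five-dimensional z-descriptor space
#' (hydrophobicity, steric bulk, polarity, two electronic effects):
#' `sqrt(sum_k (z_k(a) - z_k(b))^2)`. Vectorised over pairs of residues.
#'
#' @param a,b Character vectors of single-letter residue codes (recycled to a
#'   common length).
#' @param table Descriptor table as returned by [z_descriptors()]; a
#'   user-supplied tibble (`aa`, descriptor columns) or matrix with residue
#'   rownames is accepted.
#' @return Numeric vector of nonnegative distances.
#' @examples
#' aa_distance("A", "V")
#' aa_distance("W", "W") # 0
#' @export
aa_distance <- function(a, b, table = z_descriptors()) {
  zm <- as_z_matrix(table)
  check_residues(c(a, b), zm)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  d2 <- rowSums((zm[a, , drop = FALSE] - zm[b, , drop = FALSE])^2)
  unname(sqrt(d2))
}

check_residues <- function(res, zm) {
  bad <- setdiff(unique(res), rownames(zm))
  if (length(bad) > 0) {
    stop(
      "residue symbol(s) not in descriptor table: ",
      paste(shQuote(bad), collapse = ", "),
      " (gaps and ambiguity codes are not supported)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Functional distance between two alleles
#'
#' Mean over aligned positions of the per-residue z-descriptor distance
#' ([aa_distance()]). Sequences must be pre-aligned and of equal length; an
#' optional position mask restricts the average to selected positions (e.g. a
#' peptide-binding-region annotation).
#'
#' @param a,b Amino-acid sequences (single strings over the 20 standard
#'   one-letter codes).
#' @param positions Optional integer vector of 1-based positions to average
#'   over; default all positions.
#' @inheritParams aa_distance
#' @return A single nonnegative number; 0 iff the (masked) sequences are
#'   identical.
#' @examples
#' allele_distance("ACDEF", "ACDEY")
#' @export
allele_distance <- function(a, b, table = z_descriptors(), positions = NULL) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) {
    stop("allele sequences differ in length (", length(ca), " vs ",
         length(cb), "); align them first", call. = FALSE)
  }
  if (!is.null(positions)) {
    if (any(positions < 1 | positions > length(ca))) {
      stop("position mask outside sequence range", call. = FALSE)
    }
    ca <- ca[positions]
    cb <- cb[positions]
  }
  mean(aa_distance(ca, cb, table = table))
}

#' All pairwise functional distances within an allele set
#'
#' @param sequences Named character vector of aligned amino-acid sequences
#'   (names are allele ids), or a tibble with columns `id` and `sequence`.
#' @inheritParams allele_distance
#' @return Square symmetric matrix with zero diagonal, dimnames = allele ids.
#' @export
allele_distance_matrix <- function(sequences, table = z_descriptors(),
                                   positions = NULL) {
  if (is.data.frame(sequences)) {
    seqs <- stats::setNames(sequences$sequence, sequences$id)
  } else {
    seqs <- sequences
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("allele sequences must carry unique ids", call. = FALSE)
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        allele_distance(seqs[[i]], seqs[[j]], table = table,
                        positions = positions)
    }
  }
  d
}

# Resolve the allele-copy id columns for the requested loci and return, per
# individual, the character matrix of copy ids (2 or 4 columns).
locus_copy_cols <- function(locus) {
  locus <- match.arg(locus, c("DAB1", "DAB2", "both"))
  switch(locus,
    DAB1 = c("dab1_1", "dab1_2"),
    DAB2 = c("dab2_1", "dab2_2"),
    both = c("dab1_1", "dab1_2", "dab2_1", "dab2_2")
  )
}

copy_matrix <- function(genotypes, locus) {
  cols <- locus_copy_cols(locus)
  missing_cols <- setdiff(cols, names(genotypes))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks allele columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(genotypes[cols])
  if (anyNA(m)) stop("missing allele copies in genotype table", call. = FALSE)
  rownames(m) <- genotypes$individual
  m
}

#' Functional MHC diversity of each genotype
#'
#' Per-locus diversity is the functional distance between the two allele
#' copies an individual carries at that locus (0 for homozygotes). With
#' `locus = "both"` the four copies across the two loci are reduced by
#' `combine` over all 6 unordered copy pairs (default mean; max available as
#' a sensitivity rule). Higher values reflect functionally more diverse
#' genotypes.
#'
#' @param genotypes Tibble with columns `individual` and allele-copy columns
#'   `dab1_1`, `dab1_2`, `dab2_1`, `dab2_2` holding allele ids.
#' @param alleles Allele sequences: named character vector or tibble
#'   (`id`, `sequence`) covering every id in `genotypes`.
#' @param locus `"DAB1"`, `"DAB2"` or `"both"`.
#' @param combine Reduction over copy pairs in `"both"` mode.
#' @inheritParams allele_distance
#' @return Tibble `individual`, `diversity` (one row per input row).
#' @export
genotype_diversity <- function(genotypes, alleles, locus = "both",
                               combine = c("mean", "max"),
                               table = z_descriptors(), positions = NULL) {
  combine <- match.arg(combine)
  cm <- copy_matrix(genotypes, locus)
  ad <- allele_set_distances(alleles, unique(as.vector(cm)), table, positions)
  f <- if (combine == "mean") mean else max
  div <- apply(cm, 1, function(copies) {
    pairs <- utils::combn(length(copies), 2)
    f(ad[cbind(copies[pairs[1, ]], copies[pairs[2, ]])])
  })
  tibble::tibble(individual = genotypes$individual, diversity = unname(div))
}

# Distance lookup over the allele ids actually used.
allele_set_distances <- function(alleles, ids, table, positions) {
  if (is.data.frame(alleles)) {
    seqs <- stats::setNames(alleles$sequence, alleles$id)
  } else {
    seqs <- alleles
  }
  missing_ids <- setdiff(ids, names(seqs))
  if (length(missing_ids) > 0) {
    stop("allele ids without sequences: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  allele_distance_matrix(seqs[ids], table = table, positions = positions)
}

#' Pairwise MHC distance between two genotypes
#'
#' Dyadic genotype distance: by default the maximum functional allele
#' distance over the cross-individual pairs of allele copies at the
#' requested loci, so that 0 means the two individuals could not be told
#' apart by any copy comparison and low values mark functionally similar
#' genotypes. `rule = "mean"` averages over the cross pairs instead; under
#' additive allele effects on chemistry the mean rule is the
#' better-matched statistic (see the package vignette), so both are
#' reported in sensitivity analyses. With `locus = "both"`, copies are
#' compared within locus only (DAB1 against DAB1, DAB2 against DAB2, 8
#' cross pairs): the two loci are different genes, so cross-locus residue
#' comparisons do not measure genotype similarity.
#'
#' @param gi,gj One-row genotype tibbles (see [genotype_diversity()]).
#' @inheritParams genotype_diversity
#' @param rule `"max"` (default) or `"mean"` over cross-individual copy pairs.
#' @return A single nonnegative number.
#' @export
dyad_mhc_distance <- function(gi, gj, alleles, locus = "both",
                              rule = c("max", "mean"),
                              table = z_descriptors(), positions = NULL) {
  rule <- match.arg(rule)
  loci <- if (locus == "both") c("DAB1", "DAB2") else locus
  ids <- unique(unlist(lapply(loci, function(l) {
    c(copy_matrix(gi, l)[1, ], copy_matrix(gj, l)[1, ])
  })))
  ad <- allele_set_distances(alleles, ids, table, positions)
  f <- if (rule == "max") max else mean
  f(unlist(lapply(loci, function(l) {
    ad[as.character(copy_matrix(gi, l)[1, ]),
       as.character(copy_matrix(gj, l)[1, ])]
  })))
}

#' Dyadic MHC distance matrices by sex pairing
#'
#' Builds the three dyad groups used throughout the analysis: square
#' symmetric female-female (`FF`) and male-male (`MM`) matrices and the
#' rectangular male-female matrix (`MF`, rows = males, columns = females),
#' with entries from [dyad_mhc_distance()].
#'
#' @inheritParams genotype_diversity
#' @inheritParams dyad_mhc_distance
#' @return Named list of matrices `FF`, `MM`, `MF` with individual-id
#'   dimnames.
#' @export
mhc_distance_matrices <- function(genotypes, alleles, locus = "both",
                                  rule = c("max", "mean"),
                                  table = z_descriptors(), positions = NULL) {
  rule <- match.arg(rule)
  check_sex(genotypes$sex)
  loci <- if (locus == "both") c("DAB1", "DAB2") else locus
  cms <- lapply(loci, function(l) copy_matrix(genotypes, l))
  ad <- allele_set_distances(alleles, unique(unlist(lapply(cms, as.vector))),
                             table, positions)
  n <- nrow(cms[[1]])
  f <- if (rule == "max") max else mean
  full <- matrix(0, n, n,
                 dimnames = list(rownames(cms[[1]]), rownames(cms[[1]])))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      cross <- unlist(lapply(cms, function(cm) ad[cm[i, ], cm[j, ]]))
      full[i, j] <- full[j, i] <- f(cross)
    }
  }
  split_dyad_groups(full, stats::setNames(genotypes$sex, genotypes$individual))
}

check_sex <- function(sex) {
  bad <- setdiff(unique(as.character(sex)), c("F", "M"))
  if (length(bad) > 0) {
    stop("unknown sex label(s): ", paste(shQuote(bad), collapse = ", "),
         " (expected \"F\" or \"M\")", call. = FALSE)
  }
  invisible(TRUE)
}

# Partition a full square distance matrix into FF / MM square blocks and the
# rectangular MF block (rows = males, columns = females).
split_dyad_groups <- function(full, sex_by_id) {
  ids <- rownames(full)
  sex <- as.character(sex_by_id[ids])
  fem <- ids[sex == "F"]
  mal <- ids[sex == "M"]
  list(
    FF = full[fem, fem, drop = FALSE],
    MM = full[mal, mal, drop = FALSE],
    MF = full[mal, fem, drop = FALSE]
  )
}

#' Per-individual MHC heterozygosity
#'
#' Default `mode = "indicator"` scores each locus 0 (homozygous) / 1
#' (heterozygous) and averages over the requested loci; `mode = "functional"`
#' uses the z-descriptor diversity score instead ([genotype_diversity()]).
#'
#' @inheritParams genotype_diversity
#' @param mode `"indicator"` or `"functional"`.
#' @return Tibble `individual`, `mhc_het`.
#' @export
mhc_heterozygosity <- function(genotypes, alleles = NULL, locus = "both",
                               mode = c("indicator", "functional"),
                               table = z_descriptors()) {
  mode <- match.arg(mode)
  if (mode == "functional") {
    if (is.null(alleles)) stop("functional mode needs allele sequences",
                               call. = FALSE)
    d <- genotype_diversity(genotypes, alleles, locus = locus, table = table)
    return(tibble::tibble(individual = d$individual, mhc_het = d$diversity))
  }
  loci <- if (locus == "both") c("DAB1", "DAB2") else locus
  het <- rowMeans(vapply(loci, function(l) {
    cm <- copy_matrix(genotypes, l)
    as.numeric(cm[, 1] != cm[, 2])
  }, numeric(nrow(genotypes))))
  tibble::tibble(individual = genotypes$individual, mhc_het = unname(het))
}

#' Correlation between MHC and genome-wide heterozygosity
#'
#' Pearson correlation between per-individual MHC heterozygosity and
#' genome-wide heterozygosity values (the latter consumed as given, e.g.
#' from RAD-seq). Used to check whether MHC variation merely tracks
#' background genetic diversity.
#'
#' @param mhc_het,genome_het Equal-length paired numeric vectors, n >= 3.
#' @return A single correlation; `NA` with a warning when either vector has
#'   zero variance (correlation undefined).
#' @export
heterozygosity_correlation <- function(mhc_het, genome_het) {
  if (length(mhc_het) != length(genome_het)) {
    stop("heterozygosity vectors must be paired (equal length)", call. = FALSE)
  }
  if (length(mhc_het) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (stats::sd(mhc_het) == 0 || stats::sd(genome_het) == 0) {
    warning("zero variance: correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(mhc_het, genome_het)
}

#' Translate nucleotide allele sequences to amino acids
#'
#' Standard genetic code; the reading frame must be supplied. A stop codon
#' anywhere before the final position is an error (premature stop); a
#' trailing stop is trimmed.
#'
#' @param sequences Named character vector of nucleotide sequences, or tibble
#'   (`id`, `sequence`).
#' @param frame Reading frame offset, 1, 2 or 3.
#' @return Named character vector of amino-acid sequences.
#' @export
translate_alleles <- function(sequences, frame = 1) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  }
  if (!frame %in% 1:3) stop("`frame` must be 1, 2 or 3", call. = FALSE)
  vapply(names(sequences), function(id) {
    nt <- sequences[[id]]
    nt <- substr(nt, frame, frame + 3 * ((nchar(nt) - frame + 1) %/% 3) - 1)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), no.init.codon = TRUE
    ))
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    if (stops[1] != -1) {
      if (any(stops < nchar(aa))) {
        stop("premature stop codon in allele ", shQuote(id), call. = FALSE)
      }
      aa <- substr(aa, 1, nchar(aa) - 1)
    }
    aa
  }, character(1))
}

#' Read allele sequences from FASTA
#'
#' @param path FASTA file of amino-acid (default) or nucleotide sequences.
#' @param type `"aa"` or `"dna"`; nucleotide input is translated with
#'   [translate_alleles()].
#' @param frame Reading frame for `type = "dna"`.
#' @return Named character vector of amino-acid sequences.
#' @export
read_allele_fasta <- function(path, type = c("aa", "dna"), frame = 1) {
  type <- match.arg(type)
  if (type == "aa") {
    seqs <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(seqs), names(seqs))
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    translate_alleles(stats::setNames(as.character(seqs), names(seqs)),
                      frame = frame)
  }
}

#' Write allele sequences to FASTA
#'
#' @param sequences Named character vector of amino-acid sequences or tibble
#'   (`id`, `sequence`).
#' @param path Output file.
#' @export
write_allele_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
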