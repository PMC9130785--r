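# Five principal-property scales (z-scales) for the 20 proteinogenic amino
# acids, from Sandberg et al. (1998) J Med Chem 41:2481-2491.
# z1 ~ hydrophobicity, z2 ~ steric bulk / polarizability, z3 ~ polarity,
# z4 and z5 ~ electronic effects. Unitless.
.z_scales <- matrix(
  c(
    #   z1     z2     z3     z4     z5
     0.24, -2.32,  0.60, -0.14,  1.30, # A
     3.52,  2.50, -3.50,  1.99, -0.17, # R
     3.05,  1.62,  1.04, -1.15,  1.61, # N
     3.98,  0.93,  1.93, -2.46,  0.75, # D
     0.84, -1.67,  3.71,  0.18, -2.65, # C
     1.75,  0.50, -1.44, -1.34,  0.66, # Q
     3.11,  0.26, -0.11, -3.04, -0.25, # E
     2.05, -4.06,  0.36, -0.82, -0.38, # G
     2.47,  1.95,  0.26,  3.90,  0.09, # H
    -3.89, -1.73, -1.71, -0.84,  0.26, # I
    -4.28, -1.30, -1.49, -0.72,  0.84, # L
     2.29,  0.89, -2.49,  1.49,  0.31, # K
    -2.85, -0.22,  0.47,  1.94, -0.98, # M
    -4.22,  1.94,  1.06,  0.54, -0.62, # F
    -1.66,  0.27,  1.84,  0.70,  2.00, # P
     2.39, -1.07,  1.15, -1.39,  0.67, # S
     0.75, -2.18, -1.12, -1.46, -0.40, # T
    -4.36,  3.94,  0.59,  3.44, -1.59, # W
    -2.54,  2.44,  0.43,  0.04, -1.47, # Y
    -2.59, -2.64, -1.54, -0.85, -0.02  # V
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    paste0("z", 1:5)
  )
)

#' Amino-acid z-descriptor table
#'
#' The five-factor physico-chemical description of the 20 standard amino
#' acids used to compute functional distances between MHC alleles:
#' hydrophobicity (`z1`), steric bulk (`z2`), polarity (`z3`) and two
#' electronic-effect scores (`z4`, `z5`), from the extended principal-property
#' scales of Sandberg et al. (1998).
#'
#' @return A tibble with 20 rows and columns `aa`, `z1`...`z5`.
#' @examples
#' z_descriptors()
#' @export
z_descriptors <- function() {
  tibble::as_tibble(.z_scales, rownames = "aa")
}

# Coerce a user-supplied descriptor table (tibble with `aa` column, or a
# residue x descriptor matrix) to the internal matrix form.
as_z_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(rownames(table))) {
      stop("descriptor matrix must have residue rownames", call. = FALSE)
    }
    return(table)
  }
  if (is.data.frame(table)) {
    if (!"aa" %in% names(table)) {
      stop("descriptor table must contain an `aa` column", call. = FALSE)
    }
    m <- as.matrix(table[setdiff(names(table), "aa")])
    rownames(m) <- table$aa
    if (any(!is.finite(m))) {
      stop("descriptor table contains non-finite values", call. = FALSE)
    }
    return(m)
  }
  stop("`table` must be a data frame or a matrix of descriptors", call. = FALSE)
}
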