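## Grantham physicochemical distance between amino acids, computed from the
## composition / polarity / volume property formula and normalised so the
## mean over all unordered pairs is 100.

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.grantham_props <- list(
  c = c(A = 0,    R = 0.65, N = 1.33, D = 1.38, C = 2.75, Q = 0.89, E = 0.92,
        G = 0.74, H = 0.58, I = 0,    L = 0,    K = 0.33, M = 0,    F = 0,
        P = 0.39, S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0),
  p = c(A = 8.1,  R = 10.5, N = 11.6, D = 13.0, C = 5.5,  Q = 10.5, E = 12.3,
        G = 9.0,  H = 10.4, I = 5.2,  L = 4.9,  K = 11.3, M = 5.7,  F = 5.2,
        P = 8.0,  S = 9.2,  T = 8.6,  W = 5.4,  Y = 6.2,  V = 5.9),
  v = c(A = 31,   R = 124,  N = 56,   D = 54,   C = 55,   Q = 85,   E = 83,
        G = 3,    H = 96,   I = 111,  L = 111,  K = 119,  M = 105,  F = 132,
        P = 32.5, S = 32,   T = 61,   W = 170,  Y = 136,  V = 84)
)

.build_grantham <- function() {
  cp <- .grantham_props
  raw <- outer(.aa20, .aa20, function(i, j) {
    sqrt(1.833 * (cp$c[i] - cp$c[j])^2 +
         0.1018 * (cp$p[i] - cp$p[j])^2 +
         0.000399 * (cp$v[i] - cp$v[j])^2)
  })
  m <- round(100 / mean(raw[upper.tri(raw)]) * raw)
  dimnames(m) <- list(.aa20, .aa20)
  m
}

.grantham_mat <- .build_grantham()

#' Grantham distance matrix
#'
#' Physicochemical dissimilarity between the 20 standard amino acids,
#' combining side-chain composition, polarity and molecular volume.  Used to
#' decide whether two conserved residues "differ radically" (type II
#' rate shift) — the conventional cutoff is a distance of 60 or more.
#'
#' @return A symmetric 20 x 20 integer matrix with amino-acid one-letter
#'   codes as dimnames; diagonal zero.
#' @examples
#' grantham_matrix()["D", "R"]
#' @export
grantham_matrix <- function() .grantham_mat

#' Grantham distance between two residues
#'
#' @param a,b One-letter amino-acid codes.
#' @return Numeric distance; `NA` if either residue is not one of the 20
#'   standard amino acids (e.g. 'X' or a gap).
#' @examples
#' grantham("L", "I")  # 5, conservative
#' grantham("W", "C")  # 215, radical
#' @export
grantham <- function(a, b) {
  if (!(a %in% .aa20) || !(b %in% .aa20)) return(NA_real_)
  .grantham_mat[a, b]
}
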