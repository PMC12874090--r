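# BLOSUM62 in the canonical ARNDCQEGHILKMFPSTWYV order (Henikoff & Henikoff
# log-odds, half-bit units), reordered at load into the package alphabet.
.BLOSUM62_TEXT <- "
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4
"

.parse_blosum <- function(txt) {
  lines <- strsplit(trimws(txt), "\n")[[1]]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  m <- matrix(0, length(header), length(header),
              dimnames = list(header, header))
  for (ln in lines[-1]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    m[f[1], ] <- as.numeric(f[-1])
  }
  m
}

# 21 x 21 scoring matrix in package alphabet order (AAX); 'X' row/column 0.
.SCORE_MATRICES <- local({
  b62 <- .parse_blosum(.BLOSUM62_TEXT)[AA20, AA20]
  full <- matrix(0, 21, 21, dimnames = list(AAX, AAX))
  full[AA20, AA20] <- b62
  list(BLOSUM62 = full)
})

#' Substitution matrix used for protein alignment
#'
#' Returns the 21x21 scoring matrix (20 amino acids plus `X`) for a named
#' substitution model. `X` scores 0 against every residue, including itself,
#' so ambiguous positions neither reward nor penalize an alignment.
#'
#' @param matrix_name Name of the substitution matrix. Only `"BLOSUM62"` is
#'   shipped.
#' @return A numeric matrix with dimnames over the package alphabet.
#' @export
scoring_matrix <- function(matrix_name = "BLOSUM62") {
  m <- .SCORE_MATRICES[[matrix_name]]
  if (is.null(m))
    input_error("unknown substitution matrix '%s'", matrix_name)
  m
}
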