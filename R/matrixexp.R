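#' Matrix exponential of a complex matrix
#'
#' Scaling-and-squaring with a degree-13 Pade approximant (the standard
#' dense algorithm). Written here because the installed matrix-exponential
#' routines operate on real matrices only, while Liouvillians are complex.
#'
#' @param a square complex (or real) matrix.
#' @return `exp(a)` as a complex matrix.
#' @keywords internal
#' @export
expm_complex <- function(a) {
  a <- as.matrix(a)
  d <- nrow(a)
  if (d != ncol(a)) stop("expm_complex needs a square matrix")
  if (!is.complex(a)) a <- a + 0i
  nrm <- max(colSums(Mod(a)))   # 1-norm
  theta13 <- 5.371920351148152
  s <- 0L
  if (nrm > theta13) {
    s <- ceiling(log2(nrm / theta13))
    a <- a / 2^s
  }
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  id <- diag(d) + 0i
  a2 <- a %*% a
  a4 <- a2 %*% a2
  a6 <- a2 %*% a4
  u <- a %*% (a6 %*% (b[14] * a6 + b[12] * a4 + b[10] * a2) +
              b[8] * a6 + b[6] * a4 + b[4] * a2 + b[2] * id)
  v <- a6 %*% (b[13] * a6 + b[11] * a4 + b[9] * a2) +
       b[7] * a6 + b[5] * a4 + b[3] * a2 + b[1] * id
  f <- solve(v - u, v + u)
  for (k in seq_len(s)) f <- f %*% f
  f
}
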