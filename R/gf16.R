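# GF(16) arithmetic and the (8,4) Reed-Solomon code protecting oligo indices.
#
# The field is GF(2^4) built modulo the primitive polynomial x^4 + x + 1
# (0x13), with alpha = x as the primitive element.  Index codewords are
# evaluations of the degree-<=3 message polynomial at alpha^0..alpha^7,
# brought to systematic form, so the code is MDS with minimum distance
# n - k + 1 = 5 and corrects any two symbol errors by bounded-distance
# decoding (syndrome table lookup).

.gf <- new.env(parent = emptyenv())

gf16Tables <- function() {
  if (!is.null(.gf$MUL)) return(.gf)
  exp <- integer(15L)
  v <- 1L
  for (i in 0:14) {
    exp[i + 1L] <- v
    v <- bitwShiftL(v, 1L)
    if (v >= 16L) v <- bitwXor(v, 19L) # reduce modulo x^4 + x + 1
  }
  log <- rep(NA_integer_, 16L)
  log[exp + 1L] <- 0:14
  MUL <- matrix(0L, 16L, 16L)
  for (a in 1:15) for (b in 1:15)
    MUL[a + 1L, b + 1L] <- exp[((log[a + 1L] + log[b + 1L]) %% 15L) + 1L]
  INV <- rep(NA_integer_, 16L)
  INV[exp + 1L] <- exp[((15L - (0:14)) %% 15L) + 1L]
  .gf$exp <- exp
  .gf$log <- log
  .gf$MUL <- MUL
  .gf$INV <- INV
  .gf$Gsys <- rsSystematicGenerator(MUL, INV, exp)
  .gf$Hrs <- rsParityCheck(.gf$Gsys)
  .gf$ERR <- NULL # syndrome table built lazily
  .gf
}

#' Multiply elements of GF(16)
#'
#' @param a,b Integer vectors with values in 0..15.
#' @return Elementwise product in GF(2^4) (primitive polynomial x^4 + x + 1).
#' @export
#' @examples
#' gf16Mul(2, 9)   # alpha * alpha^3 = alpha^4 = alpha + 1 = 3
gf16Mul <- function(a, b) {
  g <- gf16Tables()
  stopifnot(all(a >= 0 & a <= 15), all(b >= 0 & b <= 15))
  g$MUL[cbind(a + 1L, b + 1L)]
}

#' Multiplicative inverse in GF(16)
#'
#' @param a Integer vector with values in 1..15.
#' @return Elementwise inverse; `a` must be nonzero.
#' @export
gf16Inv <- function(a) {
  g <- gf16Tables()
  stopifnot(all(a >= 1 & a <= 15))
  g$INV[a + 1L]
}

# Vandermonde generator at points alpha^0..alpha^7, reduced to systematic
# form [I4 | P] by inverting its leading 4x4 block.
rsSystematicGenerator <- function(MUL, INV, exp) {
  G <- matrix(0L, 4L, 8L)
  for (i in 1:4) for (j in 1:8)
    G[i, j] <- exp[(((i - 1L) * (j - 1L)) %% 15L) + 1L]
  A <- cbind(G[, 1:4], diag(4L) * 1L) # augmented [A | I]
  # Gauss-Jordan over GF(16)
  for (col in 1:4) {
    piv <- which(A[col:4, col] != 0L)[1L] + col - 1L
    if (piv != col) A[c(col, piv), ] <- A[c(piv, col), ]
    inv <- INV[A[col, col] + 1L]
    A[col, ] <- MUL[cbind(rep(inv, 8L) + 1L, A[col, ] + 1L)]
    for (r in 1:4) {
      if (r != col && A[r, col] != 0L) {
        f <- A[r, col]
        A[r, ] <- bitwXor(A[r, ], MUL[cbind(rep(f, 8L) + 1L, A[col, ] + 1L)])
      }
    }
  }
  Ainv <- A[, 5:8]
  Gs <- matrix(0L, 4L, 8L)
  for (i in 1:4) for (j in 1:8) {
    acc <- 0L
    for (t in 1:4) acc <- bitwXor(acc, MUL[Ainv[i, t] + 1L, G[t, j] + 1L])
    Gs[i, j] <- acc
  }
  Gs
}

# H = [P^T | I4] for Gsys = [I4 | P]
rsParityCheck <- function(Gsys) {
  P <- Gsys[, 5:8]
  cbind(t(P), diag(4L) * 1L)
}

# GF(16) matrix (r x c) times symbol matrix (c x N), XOR-accumulated
gf16MatMul <- function(M, X) {
  g <- gf16Tables()
  X <- as.matrix(X)
  out <- matrix(0L, nrow(M), ncol(X))
  for (i in seq_len(nrow(M))) {
    acc <- integer(ncol(X))
    for (j in seq_len(ncol(M))) {
      if (M[i, j] != 0L)
        acc <- bitwXor(acc, g$MUL[M[i, j] + 1L, X[j, ] + 1L])
    }
    out[i, ] <- acc
  }
  out
}

#' Systematic (8,4) Reed-Solomon encoding over GF(16)
#'
#' Encodes 4 information symbols (the 8-nt index, 2 nt per symbol) into an
#' 8-symbol codeword whose first 4 symbols are the information symbols.
#'
#' @param info Integer vector of 4 symbols in 0..15, or a 4 x N matrix to
#'   encode N indices at once.
#' @return Integer vector of 8 symbols (or an 8 x N matrix).
#' @export
#' @examples
#' rsEncodeIndex(c(0, 0, 0, 0))
rsEncodeIndex <- function(info) {
  g <- gf16Tables()
  vec <- is.null(dim(info))
  X <- if (vec) matrix(as.integer(info), 4L, 1L) else info
  stopifnot(nrow(X) == 4L, all(X >= 0L & X <= 15L))
  cw <- gf16MatMul(t(g$Gsys), X)
  if (vec) drop(cw) else cw
}

# Build the syndrome -> error-pattern lookup table for all correctable
# patterns of weight <= 2 (6,420 of them; all syndromes distinct because
# d_min = 5).
rsErrorTable <- function() {
  g <- gf16Tables()
  if (!is.null(g$ERR)) return(g$ERR)
  pats <- matrix(0L, 8L, 1L) # weight 0
  for (p in 1:8) for (v in 1:15) {
    e <- integer(8L); e[p] <- v
    pats <- cbind(pats, e)
  }
  cmb <- utils::combn(8L, 2L)
  for (i in seq_len(ncol(cmb))) {
    p1 <- cmb[1L, i]; p2 <- cmb[2L, i]
    grid <- expand.grid(v1 = 1:15, v2 = 1:15)
    blk <- matrix(0L, 8L, nrow(grid))
    blk[p1, ] <- grid$v1
    blk[p2, ] <- grid$v2
    pats <- cbind(pats, blk)
  }
  syn <- gf16MatMul(g$Hrs, pats)
  key <- syn[1L, ] + 16L * syn[2L, ] + 256L * syn[3L, ] + 4096L * syn[4L, ]
  stopifnot(!anyDuplicated(key)) # distinct syndromes <=> t = 2 correctable
  ERR <- matrix(NA_integer_, 65536L, 8L)
  ERR[key + 1L, ] <- t(pats)
  .gf$ERR <- ERR
  ERR
}

#' Bounded-distance decoding of the (8,4) Reed-Solomon index code
#'
#' Corrects up to two symbol errors by syndrome table lookup.  Received words
#' farther than two symbols from every codeword are flagged as failures.
#'
#' @param received Integer vector of 8 symbols in 0..15 (or an 8 x N matrix).
#'   `NA` symbols force a decoding failure for that word.
#' @return A list with `info` (4 symbols, or 4 x N matrix; `NA` on failure),
#'   `codeword` (corrected 8-symbol word) and `status` (`"ok"`, `"corrected"`
#'   or `"fail"` per word).
#' @export
#' @examples
#' cw <- rsEncodeIndex(c(1, 2, 3, 4))
#' cw[7] <- bitwXor(cw[7], 5)
#' rsDecodeIndex(cw)$status
rsDecodeIndex <- function(received) {
  g <- gf16Tables()
  ERR <- rsErrorTable()
  vec <- is.null(dim(received))
  X <- if (vec) matrix(as.integer(received), 8L, 1L) else received
  stopifnot(nrow(X) == 8L)
  N <- ncol(X)
  bad <- colSums(is.na(X) | X < 0L | X > 15L) > 0L
  Xs <- X
  Xs[, bad] <- 0L
  syn <- gf16MatMul(g$Hrs, Xs)
  key <- syn[1L, ] + 16L * syn[2L, ] + 256L * syn[3L, ] + 4096L * syn[4L, ]
  E <- ERR[key + 1L, , drop = FALSE] # N x 8
  fail <- bad | is.na(E[, 1L])
  status <- ifelse(fail, "fail", ifelse(key == 0L, "ok", "corrected"))
  cw <- matrix(NA_integer_, 8L, N)
  ok <- !fail
  if (any(ok)) cw[, ok] <- bitwXor(X[, ok, drop = FALSE], t(E[ok, , drop = FALSE]))
  info <- cw[1:4, , drop = FALSE]
  if (vec) list(info = drop(info), codeword = drop(cw), status = status)
  else list(info = info, codeword = cw, status = status)
}

#' Minimum distance of the index code by exhaustive enumeration
#'
#' Encodes all 16^4 = 65,536 information words and returns the minimum
#' nonzero codeword Hamming weight (for a linear code this equals the
#' minimum pairwise distance).
#'
#' @return An integer (5 for this MDS code).
#' @export
rsMinDistance <- function() {
  v <- 0:65535
  info <- rbind(v %% 16L, (v %/% 16L) %% 16L,
                (v %/% 256L) %% 16L, (v %/% 4096L) %% 16L)
  cw <- rsEncodeIndex(info)
  w <- colSums(cw != 0L)
  as.integer(min(w[w > 0L]))
}

# index string(s) (8 nt) <-> 4 GF(16) symbols; first base of each 2-nt pair
# is the high 2 bits of the symbol.
indexToSymbols <- function(idx) {
  v <- baseValues(idx)
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  odd <- seq(1L, nrow(v) - 1L, by = 2L)
  4L * v[odd, , drop = FALSE] + v[odd + 1L, , drop = FALSE]
}

symbolsToBases <- function(sym) {
  sym <- as.matrix(sym)
  hi <- sym %/% 4L
  lo <- sym %% 4L
  v <- matrix(0L, 2L * nrow(sym), ncol(sym))
  v[seq(1L, nrow(v), by = 2L), ] <- hi
  v[seq(2L, nrow(v), by = 2L), ] <- lo
  ch <- matrix(c("A", "C", "G", "T")[v + 1L], nrow = nrow(v))
  do.call(paste0, lapply(seq_len(nrow(ch)), function(i) ch[i, ]))
}
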