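# The inter-oligo LDPC code: construction, systematic encoding, syndrome
# computation and log-domain sum-product (belief-propagation) decoding.
#
# The code is a near-regular binary LDPC code: every variable node has the
# requested column weight (one column carries one extra edge when the weight
# is even -- a constant even column weight forces the GF(2) row sum of H to
# zero, capping the rank at m - 1), check degrees are balanced, and no two
# columns share more than one check, so the Tanner graph has girth >= 6.
# Columns are permuted at construction so that positions 1..k are
# information bits and positions k+1..n parity bits.

#' @title LDPC code object
#'
#' @description S4 container for a binary low-density parity-check code used
#' in the inter-oligo direction: the sparse parity-check matrix, the edge
#' lists consumed by the belief-propagation decoder, and the cached packed
#' parity solver used for O(1)-per-codeword systematic encoding.
#'
#' @slot n Codeword length in bits (number of oligos).
#' @slot k Number of information bits (payload oligos).
#' @slot m Number of parity checks, `n - k`.
#' @slot columnWeight Nominal number of checks per variable node.
#' @slot seed Construction seed actually used.
#' @slot H Sparse parity-check matrix (`Matrix::sparseMatrix`).
#' @slot erow,ecol 0-based edge lists (check, variable) of `H`.
#' @slot pPacked Packed GF(2) parity solver (m rows of k bits).
#'
#' @export
setClass("LDPCCode",
  representation(n = "integer", k = "integer", m = "integer",
                 columnWeight = "integer", seed = "numeric",
                 H = "Matrix", erow = "integer", ecol = "integer",
                 pPacked = "raw"),
  validity = function(object) {
    msg <- character(0)
    if (object@m != object@n - object@k)
      msg <- c(msg, "m must equal n - k")
    if (!all(dim(object@H) == c(object@m, object@n)))
      msg <- c(msg, "H must be m x n")
    if (length(object@erow) != length(object@ecol))
      msg <- c(msg, "edge lists must have equal length")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "LDPCCode", function(object) {
  cat(sprintf(
    "LDPCCode: n = %d, k = %d, m = %d checks, rate %.3f\n",
    object@n, object@k, object@m, object@k / object@n))
  cat(sprintf("  column weight %d (+1 on one column), %d edges, girth >= 6\n",
              object@columnWeight, length(object@erow)))
  cat(sprintf("  construction seed %s\n", format(object@seed)))
})

#' Construct an LDPC code
#'
#' Places `columnWeight` edges per variable node on the `n - k` check nodes,
#' balancing check degrees and forbidding any two columns from sharing more
#' than one check (girth >= 6).  One column receives an extra edge when the
#' column weight is even so that H can reach full rank.  Columns are then
#' permuted to systematic order and the packed parity solver is cached.
#' Deterministic for a fixed seed.
#'
#' @param n Codeword length (bits).
#' @param k Information length (bits); `m = n - k` checks.
#' @param columnWeight Edges per variable node (default 4).
#' @param seed Construction seed.
#' @param maxRestarts Retry budget for edge placement and rank repair.
#' @return An [LDPCCode-class] object.
#' @export
#' @examples
#' code <- ldpcCode(16, 8, columnWeight = 2, seed = 1)
#' code
ldpcCode <- function(n, k, columnWeight = 4L, seed = 1L, maxRestarts = 30L) {
  n <- as.integer(n); k <- as.integer(k)
  m <- n - k
  if (!(n > k && k > 0L)) stop("need n > k > 0")
  for (off in 0:maxRestarts) {
    s <- as.numeric(seed) + 30011 * off
    edges <- ldpc_construct_cpp(m, n, as.integer(columnWeight), s,
                                as.integer(maxRestarts))
    if (length(edges) == 0L) {
      stop(sprintf(
        "LDPC construction infeasible: cannot place %d x %d girth->=6 edges on %d checks",
        columnWeight, n, m))
    }
    w <- which(edges >= 0L)
    erow <- as.integer(edges[w])
    ecol <- as.integer((w - 1L) %/% nrow(edges))
    g <- gf2_parity_cpp(erow, ecol, m, n)
    if (g$rank == m) {
      # permute columns to [info, parity] order and re-solve in that frame
      # (pivoting from the right then keeps the permutation the identity)
      perm <- c(g$infoCols, g$parityCols) # 0-based old positions
      newpos <- integer(n)
      newpos[perm + 1L] <- 0:(n - 1L)
      ecol2 <- newpos[ecol + 1L]
      g2 <- gf2_parity_cpp(erow, ecol2, m, n)
      stopifnot(g2$rank == m, identical(g2$infoCols, 0:(k - 1L)))
      H <- Matrix::sparseMatrix(i = erow + 1L, j = ecol2 + 1L, x = 1,
                                dims = c(m, n))
      return(new("LDPCCode", n = n, k = k, m = m,
                 columnWeight = as.integer(columnWeight), seed = s,
                 H = H, erow = erow, ecol = as.integer(ecol2),
                 pPacked = g2$p))
    }
  }
  stop("LDPC construction failed to reach full rank within the retry budget")
}

#' @describeIn codeDimensions Codeword length n.
#' @export
codeLength <- function(code) code@n

#' Code dimensions
#'
#' Accessors for the three dimensions of an [LDPCCode-class].
#'
#' @param code An [LDPCCode-class].
#' @return An integer.
#' @name codeDimensions
#' @export
infoLength <- function(code) code@k

#' @describeIn codeDimensions Number of parity checks m = n - k.
#' @export
numChecks <- function(code) code@m

#' Parity-check matrix
#'
#' @param code An [LDPCCode-class].
#' @return The sparse m x n parity-check matrix.
#' @export
parityMatrix <- function(code) code@H

#' Systematic LDPC encoding
#'
#' @param code An [LDPCCode-class].
#' @param info Vector of k information bits, or a k x C 0/1 matrix encoding C
#'   codewords at once (one per column).
#' @return Vector of n bits (or n x C matrix): information bits first, then
#'   the m parity bits.
#' @export
setGeneric("ldpcEncode", function(code, info) standardGeneric("ldpcEncode"))

#' @rdname ldpcEncode
setMethod("ldpcEncode", "LDPCCode", function(code, info) {
  vec <- is.null(dim(info))
  X <- if (vec) matrix(as.integer(info), ncol = 1L) else info
  if (nrow(X) != code@k) stop("info must have k = ", code@k, " bits per codeword")
  storage.mode(X) <- "integer"
  parity <- ldpc_encode_cpp(code@pPacked, code@m, code@k, X)
  out <- rbind(X, parity)
  if (vec) drop(out) else out
})

#' Syndrome of a word
#'
#' Computes H.w over GF(2).  A word is a codeword iff its syndrome is zero.
#'
#' @param code An [LDPCCode-class].
#' @param word Vector of n bits or an n x C matrix.
#' @return Vector of m syndrome bits (or m x C matrix).
#' @export
setGeneric("ldpcSyndrome", function(code, word) standardGeneric("ldpcSyndrome"))

#' @rdname ldpcSyndrome
setMethod("ldpcSyndrome", "LDPCCode", function(code, word) {
  vec <- is.null(dim(word))
  X <- if (vec) matrix(word, ncol = 1L) else word
  if (nrow(X) != code@n) stop("word must have n = ", code@n, " bits")
  s <- as.matrix(code@H %*% X) %% 2
  storage.mode(s) <- "integer"
  if (vec) drop(s) else s
})

#' Belief-propagation decoding
#'
#' Log-domain sum-product decoding with a flooding schedule.  The sign
#' convention is LLR = ln P(bit = 0) / P(bit = 1): positive values favour 0.
#' The syndrome of the running hard decision is tested before every message
#' round, so decoding a clean codeword converges with zero iterations used.
#' Variable-to-check messages are clipped to +/- `clip` for numerical
#' stability.  Non-convergence is reported, never raised.
#'
#' @param code An [LDPCCode-class].
#' @param llr Numeric vector of n channel LLRs, or an n x C matrix to decode
#'   C codewords.
#' @param maxIter Maximum message-passing iterations (default 50).
#' @param clip Message magnitude cap (default 30).
#' @return A list with `bits` (hard decisions, n vector or n x C matrix),
#'   `converged` (logical per codeword: zero syndrome reached) and
#'   `iterations` (message rounds used per codeword).
#' @export
setGeneric("bpDecode",
           function(code, llr, maxIter = 50L, clip = 30)
             standardGeneric("bpDecode"))

#' @rdname bpDecode
setMethod("bpDecode", "LDPCCode", function(code, llr, maxIter = 50L, clip = 30) {
  vec <- is.null(dim(llr))
  X <- if (vec) matrix(as.numeric(llr), ncol = 1L) else llr
  if (nrow(X) != code@n) stop("llr must have n = ", code@n, " entries")
  storage.mode(X) <- "double"
  stopifnot(all(is.finite(X)))
  r <- bp_decode_cpp(code@erow, code@ecol, code@m, code@n, X,
                     as.integer(maxIter), as.numeric(clip))
  if (vec) {
    list(bits = drop(r$bits), converged = r$converged[1L],
         iterations = r$iterations[1L])
  } else {
    list(bits = r$bits, converged = r$converged, iterations = r$iterations)
  }
})

#' Write an LDPC code to a plain-text file
#'
#' Line 1 is a JSON header (n, k, m, columnWeight, seed); each following line
#' lists the 0-based variable nodes of one check.  [readLDPCCode()] restores
#' a bit-identical code (the parity solver is recomputed from H, which is
#' stored in systematic column order).
#'
#' @param code An [LDPCCode-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeLDPCCode <- function(code, path) {
  hdr <- jsonlite::toJSON(list(n = code@n, k = code@k, m = code@m,
                               columnWeight = code@columnWeight,
                               seed = code@seed),
                          auto_unbox = TRUE, digits = NA)
  rows <- split(code@ecol, code@erow)
  lines <- character(code@m)
  lines[as.integer(names(rows)) + 1L] <-
    vapply(rows, function(v) paste(sort(v), collapse = " "), "")
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' Read an LDPC code written by [writeLDPCCode()]
#'
#' @param path File path.
#' @return An [LDPCCode-class].
#' @export
readLDPCCode <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1L])
  m <- as.integer(hdr$m); n <- as.integer(hdr$n); k <- as.integer(hdr$k)
  stopifnot(length(lines) == m + 1L)
  cols <- lapply(lines[-1L], function(l) as.integer(strsplit(l, " ")[[1L]]))
  erow <- rep(0:(m - 1L), lengths(cols))
  ecol <- unlist(cols)
  g <- gf2_parity_cpp(erow, ecol, m, n)
  stopifnot(g$rank == m, identical(g$infoCols, 0:(k - 1L)))
  H <- Matrix::sparseMatrix(i = erow + 1L, j = ecol + 1L, x = 1, dims = c(m, n))
  new("LDPCCode", n = n, k = k, m = m,
      columnWeight = as.integer(hdr$columnWeight), seed = as.numeric(hdr$seed),
      H = H, erow = as.integer(erow), ecol = as.integer(ecol), pPacked = g$p)
}
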