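# Bit-stream helpers.  Throughout the package a "bit vector" is an integer
# vector of 0s and 1s.  Byte <-> bit expansion follows rawToBits(): least
# significant bit of each byte first.  All other conventions (CRC, the
# pseudo-random keystream, the 2-bit base map) are defined on top of this
# single ordering, so encoder and decoder agree by construction.

#' Convert raw bytes to a bit vector
#'
#' @param bytes A raw vector.
#' @return Integer vector of 0/1, least significant bit of each byte first.
#' @export
#' @examples
#' bytesToBits(as.raw(1))
bytesToBits <- function(bytes) {
  as.integer(rawToBits(bytes))
}

#' Convert a bit vector back to raw bytes
#'
#' @param bits Integer vector of 0/1 whose length is a multiple of 8.
#' @return A raw vector.
#' @export
bitsToBytes <- function(bits) {
  if (length(bits) %% 8L != 0L)
    stop("bit vector length must be a multiple of 8")
  packBits(as.logical(bits), type = "raw")
}

# 64-bit big-endian length header (number of payload bytes), expanded to bits
lengthHeaderBits <- function(nbytes) {
  stopifnot(nbytes >= 0, nbytes < 2^53)
  bytes <- as.raw((nbytes %/% 256^(7:0)) %% 256)
  bytesToBits(bytes)
}

headerBitsToLength <- function(bits64) {
  bytes <- as.integer(bitsToBytes(bits64))
  sum(bytes * 256^(7:0))
}

# unsigned 32-bit value <-> 32 bits (little-endian byte order, LSB-first)
uint32ToBits <- function(v) {
  as.integer((v %/% 2^(0:31)) %% 2)
}

bitsToUint32 <- function(bits32) {
  sum(as.numeric(bits32) * 2^(0:31))
}

#' Randomize a bit vector with a seeded pseudo-random keystream
#'
#' XORs the input with a deterministic xorshift64* keystream.  The operation
#' is an involution: applying it twice with the same seed restores the input.
#' Randomization whitens the payload so that long homopolymer runs and
#' extreme GC content become statistically rare after base mapping.
#'
#' @param bits Integer vector of 0/1.
#' @param seed Keystream seed (integer).
#' @return Bit vector of the same length.
#' @export
#' @examples
#' b <- c(1L, 0L, 1L, 1L)
#' identical(randomizeBits(randomizeBits(b, 7), 7), b)
randomizeBits <- function(bits, seed) {
  if (length(bits) == 0L) return(integer(0))
  bitwXor(as.integer(bits), prbs_bits_cpp(length(bits), as.numeric(seed)))
}

#' Map a bit vector to a DNA base string
#'
#' Two consecutive bits form one base: A = 00, C = 01, G = 10, T = 11 (first
#' bit of the pair is the high bit).
#'
#' @param bits Integer vector of 0/1 with even length.
#' @return A single character string over A/C/G/T.
#' @export
#' @examples
#' bitsToBases(c(0L,0L, 0L,1L, 1L,0L, 1L,1L))  # "ACGT"
bitsToBases <- function(bits) {
  if (length(bits) %% 2L != 0L) stop("bit vector length must be even")
  if (length(bits) == 0L) return("")
  v <- 2L * bits[seq(1L, length(bits), by = 2L)] +
    bits[seq(2L, length(bits), by = 2L)]
  paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
}

#' Map a DNA base string back to bits
#'
#' Inverse of [bitsToBases()].
#'
#' @param bases A character string over A/C/G/T.
#' @return Integer vector of 0/1 of length `2 * nchar(bases)`.
#' @export
basesToBits <- function(bases) {
  if (nchar(bases) == 0L) return(integer(0))
  v <- baseValues(bases)
  if (anyNA(v)) stop("invalid base in input (expected A/C/G/T)")
  as.integer(rbind(v %/% 2L, v %% 2L))
}

# character string(s) -> integer base values A=0 C=1 G=2 T=3 (NA otherwise);
# for a single string returns a vector, for N same-length strings a L x N
# matrix.
baseValues <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = ""))
  lut <- rep(NA_integer_, 128L)
  lut[c(65L, 67L, 71L, 84L)] <- 0:3
  v <- lut[codes]
  if (length(x) > 1L) {
    L <- nchar(x[1L])
    matrix(v, nrow = L, ncol = length(x))
  } else {
    v
  }
}

# bit matrix (rows = oligos, 272 columns) -> character vector of 136-nt
# payload strings
bitsMatrixToSeqs <- function(mat) {
  stopifnot(ncol(mat) %% 2L == 0L)
  odd <- seq(1L, ncol(mat) - 1L, by = 2L)
  v <- 2L * mat[, odd, drop = FALSE] + mat[, odd + 1L, drop = FALSE]
  ch <- matrix(c("A", "C", "G", "T")[v + 1L], nrow = nrow(mat))
  do.call(paste0, lapply(seq_len(ncol(ch)), function(j) ch[, j]))
}
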