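# Encoder: binary file -> oligo pool.
#
# Pipeline: 64-bit big-endian length header ++ file bits, randomized by a
# seeded keystream, CRC-32 appended over the randomized stream, zero-padded
# to capacity and reshaped row-major into k rows of 272 bits.  The LDPC code
# is applied per bit position in the inter-oligo direction (each of the 272
# columns is one codeword), every row is mapped to 136 nt of payload, and an
# RS-protected 8-nt index plus 8 nt of index parity are prepended, giving
# 152-nt oligos (199 nt with sequencing primers).

#' @include ldpc.R
NULL

PAYLOAD_BITS <- 272L
PAYLOAD_NT <- 136L
INDEX_NT <- 8L
PARITY_NT <- 8L
OLIGO_NT <- 152L
PRIMER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
PRIMER3 <- "TGGAATTCTCGGGTGCCAAGG"

#' @title Storage codec configuration
#'
#' @description S4 container tying together everything both the encoder and
#' the decoder must agree on: the inter-oligo LDPC code, the canonical index
#' list, the randomization seed, the primer sequences, the edit-distance
#' eviction threshold and the re-decoding schedule.
#'
#' @slot code The inter-oligo [LDPCCode-class].
#' @slot indices Canonical 8-nt index per oligo ordinal (no homopolymer run
#'   above 3, balanced GC).
#' @slot prbsSeed Seed of the randomization keystream.
#' @slot primer5,primer3 Sequencing primers (26 nt / 21 nt).
#' @slot dTh Edit-distance threshold for abnormal-read eviction.
#' @slot epsilon0,deltaEpsilon,epsilonEnd Re-decoding schedule: round i uses
#'   channel parameter eps_i = epsilon0 - i * deltaEpsilon; rounds run while
#'   eps_i >= epsilonEnd (and > 0).
#'
#' @export
setClass("StorageCodec",
  representation(code = "LDPCCode", indices = "character",
                 prbsSeed = "numeric", primer5 = "character",
                 primer3 = "character", dTh = "numeric",
                 epsilon0 = "numeric", deltaEpsilon = "numeric",
                 epsilonEnd = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@indices) != object@code@n)
      msg <- c(msg, "need one index per oligo")
    if (any(nchar(object@indices) != INDEX_NT))
      msg <- c(msg, "indices must be 8 nt")
    if (object@epsilon0 <= 0 || object@epsilon0 >= 0.5)
      msg <- c(msg, "epsilon0 must be in (0, 0.5)")
    if (object@deltaEpsilon < 0) msg <- c(msg, "deltaEpsilon must be >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "StorageCodec", function(object) {
  cat(sprintf("StorageCodec: %d oligos of %d nt (%d payload + %d parity)\n",
              object@code@n, OLIGO_NT, object@code@k, object@code@m))
  cat(sprintf("  capacity %d bytes, writing cost %.2f bases/bit\n",
              capacityBytes(object),
              writingCost(object@code@n * OLIGO_NT,
                          object@code@k * PAYLOAD_BITS)))
  cat(sprintf("  d_th = %g, eps schedule %.3g - i*%.3g down to %.3g\n",
              object@dTh, object@epsilon0, object@deltaEpsilon,
              object@epsilonEnd))
})

#' Storage codec constructor
#'
#' @param code The inter-oligo [LDPCCode-class]; `ldpcCode(18432, 16572, 4)`
#'   is the full-scale design, smaller codes give scaled-down pools with the
#'   same 152-nt oligo geometry.
#' @param prbsSeed Randomization keystream seed.
#' @param primer5,primer3 Sequencing primers.
#' @param dTh Edit-distance eviction threshold (default 10).
#' @param epsilon0,deltaEpsilon,epsilonEnd Re-decoding schedule (defaults
#'   0.02, 0.005, 0.005, i.e. rounds at eps = 0.02, 0.015, 0.01, 0.005).
#' @return A [StorageCodec-class].
#' @export
#' @examples
#' codec <- storageCodec(ldpcCode(64, 48, columnWeight = 3, seed = 1))
#' codec
storageCodec <- function(code, prbsSeed = 2024L,
                         primer5 = PRIMER5, primer3 = PRIMER3,
                         dTh = 10, epsilon0 = 0.02, deltaEpsilon = 0.005,
                         epsilonEnd = 0.005) {
  new("StorageCodec", code = code, indices = generateIndices(code@n),
      prbsSeed = as.numeric(prbsSeed), primer5 = primer5, primer3 = primer3,
      dTh = dTh, epsilon0 = epsilon0, deltaEpsilon = deltaEpsilon,
      epsilonEnd = epsilonEnd)
}

#' Number of oligos / payload oligos of a codec
#'
#' @param codec A [StorageCodec-class].
#' @return An integer.
#' @export
totalOligos <- function(codec) codec@code@n

#' @rdname totalOligos
#' @export
payloadOligos <- function(codec) codec@code@k

#' Payload capacity in bytes
#'
#' The k x 272 payload bit matrix minus the 64-bit length header and the
#' 32-bit CRC.
#'
#' @param codec A [StorageCodec-class].
#' @return Capacity in bytes.
#' @export
capacityBytes <- function(codec) {
  (codec@code@k * PAYLOAD_BITS - 64L - 32L) %/% 8L
}

#' Generate the canonical index list
#'
#' Enumerates all 4^8 8-mers in lexicographic order (A < C < G < T), removes
#' those with a homopolymer run above 3 or a G+C count outside 2..6, and
#' returns the first `count` survivors.  Deterministic.
#'
#' @param count Number of indices required.
#' @return Character vector of `count` distinct 8-nt indices.
#' @export
#' @examples
#' head(generateIndices(16))
generateIndices <- function(count) {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(rev(rep(list(bases), INDEX_NT)), stringsAsFactors = FALSE)
  chm <- as.matrix(g)[, INDEX_NT:1L, drop = FALSE] # lexicographic order
  idx <- do.call(paste0, lapply(seq_len(INDEX_NT), function(j) chm[, j]))
  keep <- !grepl("AAAA|CCCC|GGGG|TTTT", idx)
  gc <- rowSums(chm == "G" | chm == "C")
  keep <- keep & gc >= 2L & gc <= 6L
  ok <- idx[keep]
  if (length(ok) < count)
    stop(sprintf("only %d candidate indices for %d oligos", length(ok), count))
  ok[seq_len(count)]
}

#' Pack a file into the payload bit matrix
#'
#' Prepends the 64-bit length header, randomizes, appends the CRC-32 of the
#' randomized stream, zero-pads to capacity and reshapes row-major into k
#' rows of 272 bits.
#'
#' @param fileBytes Raw vector (the file content).
#' @param codec A [StorageCodec-class].
#' @return Integer 0/1 matrix, `payloadOligos(codec)` x 272.
#' @export
packPayload <- function(fileBytes, codec) {
  k <- codec@code@k
  capacity <- k * PAYLOAD_BITS
  need <- 64L + 8L * length(fileBytes) + 32L
  if (need > capacity)
    stop(sprintf("file too large: %d bytes exceed the %d-byte capacity",
                 length(fileBytes), capacityBytes(codec)))
  bits <- c(lengthHeaderBits(length(fileBytes)), bytesToBits(fileBytes))
  stream <- crc32Append(randomizeBits(bits, codec@prbsSeed))
  stream <- c(stream, integer(capacity - length(stream)))
  matrix(stream, nrow = k, ncol = PAYLOAD_BITS, byrow = TRUE)
}

# inverse of packPayload (used by the decoder): bit matrix -> file bytes
unpackPayload <- function(payloadMat, codec) {
  stream <- as.integer(t(payloadMat))
  key64 <- prbs_bits_cpp(64, codec@prbsSeed)
  nbytes <- headerBitsToLength(bitwXor(stream[1:64], key64))
  ndata <- 64L + 8L * nbytes
  if (!is.finite(nbytes) || ndata + 32L > length(stream))
    return(list(bytes = NULL, crcOK = FALSE))
  crcOK <- crc32Check(stream[1:(ndata + 32L)])
  bits <- randomizeBits(stream[1:ndata], codec@prbsSeed)
  bytes <- if (nbytes > 0L) bitsToBytes(bits[-(1:64)]) else raw(0)
  list(bytes = bytes, crcOK = crcOK)
}

#' Inter-oligo LDPC encoding of the payload matrix
#'
#' Each of the 272 bit positions (columns) is one LDPC codeword running
#' across all oligos: rows 1..k carry data, rows k+1..n the LDPC parity.
#'
#' @param payloadMat k x 272 bit matrix from [packPayload()].
#' @param code An [LDPCCode-class].
#' @return n x 272 bit matrix; every column has zero syndrome.
#' @export
interOligoEncode <- function(payloadMat, code) {
  if (nrow(payloadMat) != code@k || ncol(payloadMat) != PAYLOAD_BITS)
    stop(sprintf("payload matrix must be %d x %d", code@k, PAYLOAD_BITS))
  ldpcEncode(code, payloadMat)
}

#' Assemble oligo records
#'
#' Per row of the code matrix: 8-nt index ++ 8-nt RS index parity ++ 136-nt
#' payload = 152 nt (199 nt when primer-flanked).
#'
#' @param codeMat n x 272 bit matrix from [interOligoEncode()].
#' @param codec A [StorageCodec-class].
#' @param withPrimers Flank every oligo with the sequencing primers.
#' @return A `Biostrings::DNAStringSet` with ordinal names; `mcols()` holds
#'   the index of each record.
#' @export
assembleOligos <- function(codeMat, codec, withPrimers = FALSE) {
  n <- codec@code@n
  if (nrow(codeMat) != n || ncol(codeMat) != PAYLOAD_BITS)
    stop(sprintf("code matrix must be %d x %d", n, PAYLOAD_BITS))
  payload <- bitsMatrixToSeqs(codeMat)
  sym <- indexToSymbols(codec@indices)
  cw <- rsEncodeIndex(sym)
  paritySeq <- symbolsToBases(cw[5:8, , drop = FALSE])
  seqs <- paste0(codec@indices, paritySeq, payload)
  if (withPrimers) seqs <- paste0(codec@primer5, seqs, codec@primer3)
  pool <- Biostrings::DNAStringSet(seqs)
  names(pool) <- sprintf("oligo_%06d", 0:(n - 1L))
  S4Vectors::mcols(pool)$index <- codec@indices
  pool
}

#' Encode a file into an oligo pool
#'
#' Runs the full encoding pipeline and optionally writes the pool to FASTA
#' plus a JSON sidecar with everything needed for decoding.
#'
#' @param input File path or raw vector.
#' @param codec A [StorageCodec-class].
#' @param fastaOut Optional FASTA output path.
#' @param metaOut Optional JSON sidecar path (see [writeCodecMeta()]); the
#'   LDPC code is written next to it with extension `.code`.
#' @param withPrimers Flank oligos with primers in the output.
#' @return The `DNAStringSet` pool, invisibly when written to file.
#' @export
encodeFile <- function(input, codec, fastaOut = NULL, metaOut = NULL,
                       withPrimers = FALSE) {
  bytes <- if (is.raw(input)) input
           else readBin(input, "raw", file.info(input)$size)
  codeMat <- interOligoEncode(packPayload(bytes, codec), codec@code)
  pool <- assembleOligos(codeMat, codec, withPrimers = withPrimers)
  if (!is.null(fastaOut)) Biostrings::writeXStringSet(pool, fastaOut)
  if (!is.null(metaOut)) writeCodecMeta(codec, metaOut)
  if (is.null(fastaOut)) pool else invisible(pool)
}

#' Write / read the codec sidecar
#'
#' The JSON sidecar records every parameter the decoder needs (randomization
#' seed, primers, thresholds, schedule and the path of the serialized LDPC
#' code, written next to the sidecar).  The canonical index list is
#' regenerated deterministically, not stored.
#'
#' @param codec A [StorageCodec-class].
#' @param path Sidecar path (`.json`).
#' @return `path` ([writeCodecMeta()]) or a [StorageCodec-class]
#'   ([readCodecMeta()]).
#' @export
writeCodecMeta <- function(codec, path) {
  codePath <- paste0(sub("\\.json$", "", path), ".code")
  writeLDPCCode(codec@code, codePath)
  meta <- list(codeFile = basename(codePath), prbsSeed = codec@prbsSeed,
               primer5 = codec@primer5, primer3 = codec@primer3,
               dTh = codec@dTh, epsilon0 = codec@epsilon0,
               deltaEpsilon = codec@deltaEpsilon,
               epsilonEnd = codec@epsilonEnd)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCodecMeta
#' @export
readCodecMeta <- function(path) {
  meta <- jsonlite::fromJSON(path)
  code <- readLDPCCode(file.path(dirname(path), meta$codeFile))
  storageCodec(code, prbsSeed = meta$prbsSeed, primer5 = meta$primer5,
               primer3 = meta$primer3, dTh = meta$dTh,
               epsilon0 = meta$epsilon0, deltaEpsilon = meta$deltaEpsilon,
               epsilonEnd = meta$epsilonEnd)
}
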