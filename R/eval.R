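# Cost metrics and the success-rate-versus-sampling-number experiment
# harness.

#' Writing cost and information density
#'
#' Writing cost is the number of synthesized bases divided by the number of
#' information bits; information density is its inverse (bits per nt).  For
#' the full-scale design, 18,432 oligos x 152 nt over 16,572 x 272
#' information bits gives 0.62 bases/bit and 1.61 bits/nt (2 dp).
#'
#' @param totalBases Number of synthesized bases (primers excluded, matching
#'   the convention the costs are quoted in).
#' @param infoBits Number of stored information bits.
#' @return The cost ratio, unrounded.
#' @export
#' @examples
#' writingCost(18432 * 152, 16572 * 272)
writingCost <- function(totalBases, infoBits) {
  if (infoBits <= 0) stop("infoBits must be positive")
  totalBases / infoBits
}

#' @rdname writingCost
#' @export
informationDensity <- function(totalBases, infoBits) {
  infoBits / totalBases
}

#' Reading cost of a sampling number
#'
#' Sequenced bases per information bit under the nominal-read-length
#' convention: `samplingNumber * 152 / (k * 272)`.
#'
#' @param samplingNumber Number of sampled reads.
#' @param codec A [StorageCodec-class].
#' @return Bases per information bit.
#' @export
readingCost <- function(samplingNumber, codec) {
  samplingNumber * OLIGO_NT / (codec@code@k * PAYLOAD_BITS)
}

#' Sequencing coverage
#'
#' @param samplingNumber Number of sampled reads.
#' @param totalOligos Number of distinct oligo sequences.
#' @return Reads per oligo sequence.
#' @export
#' @examples
#' coverageDepth(72500, 18432)  # ~3.93
coverageDepth <- function(samplingNumber, totalOligos) {
  if (totalOligos <= 0) stop("totalOligos must be positive")
  samplingNumber / totalOligos
}

#' Success-rate sweep over sampling numbers
#'
#' For every sampling number, samples a read corpus from the pool and runs
#' the full decoder `trials` times with per-trial deterministic seeds,
#' counting exact recoveries (byte-identical file and CRC pass).
#'
#' @param pool Oligo pool (`DNAStringSet` or character), primer-free.
#' @param codec The [StorageCodec-class] used to encode the pool.
#' @param fileBytes The original file content (raw) for exact comparison.
#' @param samplingNumbers Integer vector of sampling numbers.
#' @param trials Trials per sampling number.
#' @param params A [ChannelParams-class].
#' @param seed Base seed; trial seeds are derived deterministically.
#' @param ... Passed to [decodeReads()].
#' @return A data.frame with one row per sampling number: successes,
#'   success rate, coverage and reading cost.
#' @export
runSweep <- function(pool, codec, fileBytes, samplingNumbers, trials = 30L,
                     params = channelParams(), seed = 1L, ...) {
  res <- lapply(seq_along(samplingNumbers), function(si) {
    sn <- samplingNumbers[si]
    succ <- 0L
    for (tr in seq_len(trials)) {
      tseed <- (as.numeric(seed) * 7919 + si * 104729 + tr * 131) %% 2147483647
      reads <- sampleReads(pool, sn, params, seed = tseed)
      dec <- decodeReads(reads, codec, ...)
      if (dec$success && identical(dec$bytes, fileBytes)) succ <- succ + 1L
    }
    data.frame(samplingNumber = sn, trials = trials, successes = succ,
               successRate = succ / trials,
               coverage = coverageDepth(sn, codec@code@n),
               readingCost = readingCost(sn, codec))
  })
  do.call(rbind, res)
}
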