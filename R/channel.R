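# Synthesis -> PCR -> sequencing -> merge channel simulator.  Reads are
# emitted as already-merged, primer-free 152-nt-frame reads: per-base
# substitution, insertion and deletion errors, an elevated substitution rate
# at the final base, Phred quality scores conditioned on per-base
# correctness, and a merge/trim artifact process producing short reads that
# the length filter discards.  Coverage-dependent dropout emerges from
# uniform sampling with replacement.

#' @title Channel parameters
#'
#' @description S4 container for the synthetic sequencing channel.  Defaults
#' emulate merged Illumina-style corpora: ~1% total base error rate
#' dominated by substitutions (indel rates on Illumina platforms are orders
#' of magnitude below substitution rates), ~96% of bases at Q30 or above,
#' ~93% of reads at the full 152 nt and ~1.3% shortened to 150/151 nt, with
#' the remaining reads lost to merge/trim artifacts shorter than 150 nt.
#'
#' @slot subRate Per-base substitution probability.
#' @slot insRate Per-base insertion probability.
#' @slot delRate Per-base deletion probability.
#' @slot lastBaseMultiplier Factor (>= 1) applied to `subRate` at the final
#'   base, reflecting the elevated error rate there.
#' @slot artifactRate Probability that a read is truncated to below 150 nt
#'   (failed merging/trimming); such reads are dropped by [lengthFilter()].
#' @slot artifactRange Truncation length range (inclusive).
#' @slot qCorrectVals,qCorrectProbs Discrete Phred distribution for correct
#'   bases (peaked at Q38).
#' @slot qErrorVals,qErrorProbs Discrete Phred distribution for erroneous
#'   bases (peaked at Q15).
#' @slot lengthKeep Read lengths retained by [lengthFilter()].
#'
#' @export
setClass("ChannelParams",
  representation(subRate = "numeric", insRate = "numeric", delRate = "numeric",
                 lastBaseMultiplier = "numeric", artifactRate = "numeric",
                 artifactRange = "integer",
                 qCorrectVals = "integer", qCorrectProbs = "numeric",
                 qErrorVals = "integer", qErrorProbs = "numeric",
                 lengthKeep = "integer"),
  validity = function(object) {
    msg <- character(0)
    rates <- c(object@subRate, object@insRate, object@delRate,
               object@artifactRate)
    if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must be in [0, 1]")
    if (object@lastBaseMultiplier < 1)
      msg <- c(msg, "lastBaseMultiplier must be >= 1")
    if (abs(sum(object@qCorrectProbs) - 1) > 1e-9 ||
        abs(sum(object@qErrorProbs) - 1) > 1e-9)
      msg <- c(msg, "quality distributions must sum to 1")
    if (length(object@qCorrectVals) != length(object@qCorrectProbs) ||
        length(object@qErrorVals) != length(object@qErrorProbs))
      msg <- c(msg, "quality values and probabilities must align")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ChannelParams", function(object) {
  cat(sprintf(
    "ChannelParams: sub %.4g, ins %.4g, del %.4g (total %.4g), last-base x%g\n",
    object@subRate, object@insRate, object@delRate,
    object@subRate + object@insRate + object@delRate,
    object@lastBaseMultiplier))
  cat(sprintf("  merge-artifact rate %.3g (truncation to %d-%d nt)\n",
              object@artifactRate, object@artifactRange[1L],
              object@artifactRange[2L]))
  cat(sprintf("  kept read lengths: %s\n",
              paste(object@lengthKeep, collapse = ", ")))
})

#' Channel parameter constructor
#'
#' @param subRate,insRate,delRate Per-base error probabilities.  The defaults
#'   sum to ~1%.
#' @param lastBaseMultiplier Substitution-rate multiplier at the final base.
#' @param artifactRate Probability of merge/trim truncation below 150 nt.
#' @param artifactRange Truncation length range.
#' @param qCorrectVals,qCorrectProbs Phred distribution of correct bases.
#' @param qErrorVals,qErrorProbs Phred distribution of erroneous bases.
#' @param lengthKeep Read lengths retained by [lengthFilter()].
#' @return A [ChannelParams-class] object.
#' @export
#' @examples
#' channelParams()
channelParams <- function(subRate = 0.0098,
                          insRate = 5e-05,
                          delRate = 9.5e-05,
                          lastBaseMultiplier = 3,
                          artifactRate = 0.05,
                          artifactRange = c(80L, 149L),
                          qCorrectVals = c(20L, 22L, 25L, 28L, 30L, 31L, 32L,
                                           33L, 34L, 35L, 36L, 37L, 38L),
                          qCorrectProbs = c(0.004, 0.006, 0.008, 0.010, 0.022,
                                            0.020, 0.030, 0.040, 0.050, 0.060,
                                            0.080, 0.120, 0.550),
                          qErrorVals = c(8L, 10L, 12L, 15L, 17L, 20L, 25L,
                                         30L, 34L),
                          qErrorProbs = c(0.04, 0.08, 0.18, 0.25, 0.17, 0.15,
                                          0.08, 0.03, 0.02),
                          lengthKeep = c(150L, 151L, 152L)) {
  new("ChannelParams", subRate = subRate, insRate = insRate,
      delRate = delRate, lastBaseMultiplier = lastBaseMultiplier,
      artifactRate = artifactRate, artifactRange = as.integer(artifactRange),
      qCorrectVals = as.integer(qCorrectVals), qCorrectProbs = qCorrectProbs,
      qErrorVals = as.integer(qErrorVals), qErrorProbs = qErrorProbs,
      lengthKeep = as.integer(lengthKeep))
}

#' Corrupt oligo sequences through the error channel
#'
#' One left-to-right pass per sequence: each base may be deleted (skipped) or
#' emitted with a substitution, and an extra uniform base may be inserted
#' after it.  The substitution rate at the final source base is multiplied
#' by `lastBaseMultiplier`.  Phred scores are drawn from the correct-base or
#' error-base distribution of `params`.  Deterministic for a fixed seed.
#'
#' @param oligos Character vector (or `Biostrings::DNAStringSet`) of source
#'   sequences.
#' @param params A [ChannelParams-class].
#' @param seed Integer seed.
#' @return A list with character vectors `seq` and `qual` (Phred+33).
#' @export
corruptOligos <- function(oligos, params = channelParams(), seed = 1L) {
  if (methods::is(oligos, "XStringSet")) oligos <- as.character(oligos)
  corrupt_reads_cpp(oligos, params@subRate, params@insRate, params@delRate,
                    params@lastBaseMultiplier, params@artifactRate,
                    cumsum(params@qCorrectProbs), params@qCorrectVals,
                    cumsum(params@qErrorProbs), params@qErrorVals,
                    params@artifactRange[1L], params@artifactRange[2L],
                    as.numeric(seed))
}

#' Sample a read corpus from an oligo pool
#'
#' Draws `samplingNumber` source oligos i.i.d. uniformly with replacement
#' (so low sampling numbers naturally leave some oligos with zero reads) and
#' corrupts each through the channel.  Deterministic for a fixed seed.
#'
#' @param pool `Biostrings::DNAStringSet` or character vector of 152-nt
#'   oligos (primer-free).
#' @param samplingNumber Number of reads to draw.
#' @param params A [ChannelParams-class].
#' @param seed Integer seed.
#' @return A `Biostrings::QualityScaledDNAStringSet`; the 0-based ground
#'   truth source ordinal of every read is stored in
#'   `mcols(reads)$sourceOrdinal` (for evaluation only -- the decoder never
#'   reads it).
#' @export
sampleReads <- function(pool, samplingNumber, params = channelParams(),
                        seed = 1L) {
  seqs <- if (methods::is(pool, "XStringSet")) as.character(pool) else pool
  if (length(seqs) == 0L) stop("oligo pool is empty")
  samplingNumber <- as.integer(samplingNumber)
  draw <- withr::with_seed(as.integer(seed), list(
    src = if (samplingNumber > 0L)
      sample.int(length(seqs), samplingNumber, replace = TRUE) else integer(0),
    cseed = as.numeric(sample.int(.Machine$integer.max, 1L))))
  src <- draw$src
  cseed <- draw$cseed
  cr <- corruptOligos(seqs[src], params, cseed)
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(cr$seq),
    Biostrings::PhredQuality(cr$qual))
  if (samplingNumber > 0L)
    names(reads) <- sprintf("read_%07d", seq_len(samplingNumber))
  S4Vectors::mcols(reads)$sourceOrdinal <- src - 1L
  reads
}

#' Filter reads by length
#'
#' Keeps reads whose length is one of `keep` (by default 150, 151 and 152
#' nt: the full-length frame plus the shortened variable-length reads the
#' decoder can exploit).  The kept fraction is attached as attribute
#' `keptFraction`.
#'
#' @param reads A `QualityScaledDNAStringSet`, or a plain list with `seq`
#'   and `qual` character vectors.
#' @param keep Integer vector of lengths to retain.
#' @return The filtered reads.
#' @export
lengthFilter <- function(reads, keep = c(150L, 151L, 152L)) {
  if (is.list(reads) && !is.null(reads$seq)) {
    w <- nchar(reads$seq)
    sel <- w %in% keep
    out <- list(seq = reads$seq[sel], qual = reads$qual[sel])
  } else {
    w <- Biostrings::width(reads)
    sel <- w %in% keep
    out <- reads[sel]
  }
  attr(out, "keptFraction") <- if (length(w)) mean(sel) else 1
  out
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param path Output path.  A sidecar TSV of ground-truth source ordinals
#'   can be written with `truthPath` (evaluation only).
#' @param truthPath Optional TSV path for read id -> source ordinal.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path, truthPath = NULL) {
  clean <- reads
  S4Vectors::mcols(clean) <- NULL # ground truth never enters the FASTQ
  Biostrings::writeQualityScaledXStringSet(clean, path)
  if (!is.null(truthPath)) {
    so <- S4Vectors::mcols(reads)$sourceOrdinal
    utils::write.table(
      data.frame(read = names(reads), sourceOrdinal = so),
      truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a FASTQ file of merged reads
#'
#' @param path FASTQ path (Phred+33).
#' @return A `QualityScaledDNAStringSet`.
#' @export
readReadsFastq <- function(path) {
  # readQualityScaledDNAStringSet() parks the qualities in metadata columns
  # internally and warns when they are moved into the quality slot
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
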