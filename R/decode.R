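# Sequence-analysis-aided decoder: FASTQ -> file.
#
# Reads are length-filtered (150/151/152 nt), clustered by their RS-decoded
# index, purged of abnormal members by edit distance, and routed per
# cluster:
#   condition 1 -- all members full length (152 nt): direct per-position
#                  voting, no alignment;
#   condition 2 -- not all full length, split into
#   condition 3 -- singleton variable-length read: all payload positions are
#                  erasures except the final base, which votes on the last
#                  two bits when its Phred score exceeds 30;
#   condition 4 -- multi-read variable-length cluster: center-star multiple
#                  alignment, then
#   condition 5 -- alignment length 152: aligned rows vote, gaps as
#                  erasures;
#   condition 6 -- alignment length != 152: each member falls back to the
#                  condition-3 last-base rescue.
# Vote counts (k0, k1, ke) per oligo and bit position become LLRs
# (k0 - k1) * ln((1 - eps_i)/eps_i); zero-coverage oligos contribute
# all-zero LLR rows (erasure sequences).  The 272 inter-oligo codewords are
# belief-propagation decoded; codewords that fail are re-decoded with eps
# reduced by deltaEpsilon per round.  The payload is de-randomized and
# verified against its CRC-32 tag.

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitutions, insertions and deletions all cost
#' one), as used for abnormal-read eviction.
#'
#' @param a,b Character strings (vectorized; recycled pairwise).
#' @return Integer vector of distances.
#' @export
#' @examples
#' editDistance("GATTACA", "GACTACA")
editDistance <- function(a, b) {
  as.integer(adist(a, b)[cbind(seq_along(a), seq_along(b))])
}

# normalize a read container to plain vectors
readVectors <- function(reads) {
  if (is.list(reads) && !is.null(reads$seq)) {
    seqs <- reads$seq
    quals <- reads$qual
  } else {
    seqs <- as.character(reads)
    quals <- as.character(Biostrings::quality(reads))
  }
  w <- nchar(seqs)
  lastQ <- rep(-1L, length(seqs))
  nz <- w > 0L
  if (any(nz)) {
    lastQ[nz] <- utf8ToInt(paste(substr(quals[nz], w[nz], w[nz]),
                                 collapse = "")) - 33L
  }
  list(seq = seqs, qual = quals, width = w, lastQ = lastQ)
}

#' Cluster reads by their RS-decoded index
#'
#' RS-decodes the first 16 nt of every read (8-nt index + 8-nt parity).
#' Reads whose index decoding fails, or whose decoded index is not in the
#' codec's canonical list, are discarded.
#'
#' @param reads A `QualityScaledDNAStringSet` (or a list with `seq`/`qual`
#'   character vectors), already length-filtered.
#' @param codec A [StorageCodec-class].
#' @return A list with `ordinal` (1-based cluster ordinal per read, `NA` for
#'   discarded reads), `status` (RS decoder status per read) and counts
#'   `rsFailed`, `unknownIndex`, `correctedIndex`.
#' @export
indexCluster <- function(reads, codec) {
  rv <- readVectors(reads)
  n <- length(rv$seq)
  ordinal <- rep(NA_integer_, n)
  status <- rep("fail", n)
  long <- rv$width >= 16L
  if (any(long)) {
    v <- baseValues(substr(rv$seq[long], 1L, 16L))
    if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
    odd <- seq(1L, 15L, by = 2L)
    sym <- 4L * v[odd, , drop = FALSE] + v[odd + 1L, , drop = FALSE]
    dec <- rsDecodeIndex(sym)
    status[long] <- dec$status
    ok <- dec$status != "fail"
    if (any(ok)) {
      idxStr <- symbolsToBases(dec$info[, ok, drop = FALSE])
      ordinal[long][ok] <- match(idxStr, codec@indices)
    }
  }
  rsFailed <- sum(status == "fail")
  unknownIndex <- sum(status != "fail" & is.na(ordinal))
  correctedIndex <- sum(status == "corrected" & !is.na(ordinal))
  list(ordinal = ordinal, status = status, rsFailed = rsFailed,
       unknownIndex = unknownIndex, correctedIndex = correctedIndex)
}

#' Edit-distance eviction of abnormal reads
#'
#' In clusters of two or more reads, a member is abnormal when its minimum
#' edit distance to every other member exceeds `dTh`; abnormal members are
#' removed simultaneously (in a 2-read cluster at mutual distance above the
#' threshold, both fall).  Singletons pass unchanged.
#'
#' @param members Character vector of the cluster's read sequences.
#' @param dTh Eviction threshold (default 10).
#' @return Logical vector: which members are kept.
#' @export
#' @examples
#' edFilter(c("ACGTACGT", "ACGTACGT", "TTTTTTTTTTTTTTTTTTTT"))
edFilter <- function(members, dTh = 10) {
  nm <- length(members)
  if (nm < 2L) return(rep(TRUE, nm))
  as.logical(ed_filter_keep_cpp(members, as.integer(dTh)))
}

#' Route a cluster to its processing condition
#'
#' @param widths Integer vector of member read lengths (after eviction).
#' @return `"direct"` (all full length), `"singleton_vl"` (one
#'   variable-length read) or `"msa"` (multi-read variable-length cluster).
#' @export
routeCluster <- function(widths) {
  if (length(widths) == 0L) stop("empty cluster has no route")
  if (all(widths == 152L)) "direct"
  else if (length(widths) == 1L) "singleton_vl"
  else "msa"
}

#' Last-base rescue votes of a singleton variable-length read
#'
#' All 272 payload bit positions of the read are erasures except, when the
#' final base's Phred score is strictly above 30, the last two bits (payload
#' bit positions 271 and 272), which receive the final base's bits: the
#' final base is positionally reliable from the read's end even when an
#' interior deletion shifted everything else.
#'
#' @param seq Read sequence (150 or 151 nt typically).
#' @param lastQ Phred score of the final base.
#' @return `NULL` when the read contributes only erasures, otherwise a list
#'   with `positions = c(271, 272)` and `bits` (the base's two bits).
#' @export
#' @examples
#' singletonVLVotes(strrep("A", 150), 35)
singletonVLVotes <- function(seq, lastQ) {
  if (lastQ <= 30L || nchar(seq) == 0L) return(NULL)
  v <- baseValues(substr(seq, nchar(seq), nchar(seq)))
  if (is.na(v)) return(NULL)
  list(positions = c(271L, 272L), bits = c(v %/% 2L, v %% 2L))
}

#' Center-star multiple alignment of a cluster
#'
#' The member closest to 152 nt (ties: highest mean Phred score, then first)
#' is the center; every other member is globally aligned to it with unit
#' costs and the pairwise gap patterns are merged ("once a gap, always a
#' gap").
#'
#' @param seqs Character vector of at least two sequences.
#' @param quals Optional Phred+33 quality strings for the tie-break.
#' @return A list with `rows` (gapped strings in input order, all of length
#'   `L`) and the alignment length `L`.
#' @export
#' @examples
#' msaAlign(c("ACGTACGT", "ACGACGT"))
msaAlign <- function(seqs, quals = NULL) {
  nm <- length(seqs)
  if (nm < 2L) stop("center-star alignment needs at least two sequences")
  dist152 <- abs(nchar(seqs) - 152L)
  meanQ <- if (is.null(quals)) rep(0, nm)
           else vapply(quals, function(q) {
             if (nchar(q) == 0L) return(0)
             mean(utf8ToInt(q)) - 33
           }, 0, USE.NAMES = FALSE)
  ci <- order(dist152, -meanQ)[1L]
  center <- seqs[ci]
  Lc <- nchar(center)
  others <- setdiff(seq_len(nm), ci)
  pair <- lapply(others, function(o) nw_align_cpp(center, seqs[o]))
  if (!any(vapply(pair, function(al) grepl("-", al[1L], fixed = TRUE), TRUE))) {
    # no pairwise alignment gaps the center: rows are the aligned members
    rows <- character(nm)
    rows[ci] <- center
    rows[others] <- vapply(pair, `[`, "", 2L)
    return(list(rows = rows, L = Lc))
  }
  # per-alignment gap counts after t = 0..Lc consumed center characters
  gaps <- matrix(0L, length(others), Lc + 1L)
  alns <- vector("list", length(others))
  for (t in seq_along(others)) {
    al <- pair[[t]]
    ca <- strsplit(al[1L], "")[[1L]]
    oa <- strsplit(al[2L], "")[[1L]]
    pos <- cumsum(ca != "-") # center chars consumed at each column
    g <- tabulate(pos[ca == "-"] + 1L, nbins = Lc + 1L)
    gaps[t, ] <- g
    alns[[t]] <- list(ca = ca, oa = oa, g = g)
  }
  master <- apply(gaps, 2L, max)
  if (length(others) == 0L) master <- integer(Lc + 1L)
  L <- Lc + sum(master)
  rows <- character(nm)
  # center row
  blocks <- character(2L * Lc + 1L)
  blocks[seq(1L, 2L * Lc + 1L, by = 2L)] <- strrep("-", master)
  blocks[seq(2L, 2L * Lc, by = 2L)] <- strsplit(center, "")[[1L]]
  rows[ci] <- paste(blocks, collapse = "")
  for (t in seq_along(others)) {
    a <- alns[[t]]
    cc <- cumsum(a$ca != "-")
    out <- character(2L * Lc + 1L)
    for (tt in 0:Lc) {
      blk <- a$oa[a$ca == "-" & cc == tt]
      out[2L * tt + 1L] <- paste0(paste(blk, collapse = ""),
                                  strrep("-", master[tt + 1L] - a$g[tt + 1L]))
      if (tt < Lc) out[2L * tt + 2L] <- a$oa[a$ca != "-" & cc == tt + 1L][1L]
    }
    rows[others[t]] <- paste(out, collapse = "")
  }
  stopifnot(all(nchar(rows) == L))
  list(rows = rows, L = L)
}

# process all clusters: returns vote contributions and routing statistics
processClusters <- function(rv, ordinal, codec, useQscore = TRUE) {
  nOligos <- codec@code@n
  groups <- split(which(!is.na(ordinal)), ordinal[!is.na(ordinal)])
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", length(groups)); acc$nrows <- 0L
  acc$ord <- vector("list", length(groups))
  acc$lastQ <- vector("list", length(groups))
  acc$rescueOrd <- vector("list", length(groups)); acc$nresc <- 0L
  acc$rescueBits <- vector("list", length(groups))
  erasureContrib <- integer(nOligos) # reads contributing only erasures
  cond <- c(direct = 0L, singleton = 0L, msa = 0L, msaOK = 0L, msaFallback = 0L)
  edDiscarded <- 0L
  usedReads <- 0L
  addRows <- function(seqs, ord0, lastQ) {
    i <- acc$nrows <- acc$nrows + 1L
    acc$rows[[i]] <- seqs
    acc$ord[[i]] <- rep(ord0, length(seqs))
    acc$lastQ[[i]] <- lastQ
  }
  rescueRead <- function(i, ord0) {
    v <- singletonVLVotes(rv$seq[i], rv$lastQ[i])
    if (useQscore && !is.null(v)) {
      t <- acc$nresc <- acc$nresc + 1L
      acc$rescueOrd[[t]] <- ord0
      acc$rescueBits[[t]] <- v$bits
      usedReads <<- usedReads + 1L
    } else {
      erasureContrib[ord0 + 1L] <<- erasureContrib[ord0 + 1L] + 1L
    }
  }
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    ord0 <- as.integer(gname) - 1L # 0-based oligo ordinal
    keep <- edFilter(rv$seq[idx], codec@dTh)
    edDiscarded <- edDiscarded + sum(!keep)
    idx <- idx[keep]
    if (length(idx) == 0L) next
    widths <- rv$width[idx]
    route <- routeCluster(widths)
    if (route == "direct") {
      cond["direct"] <- cond["direct"] + 1L
      addRows(rv$seq[idx], ord0, rv$lastQ[idx])
      usedReads <- usedReads + length(idx)
    } else if (route == "singleton_vl") {
      cond["singleton"] <- cond["singleton"] + 1L
      rescueRead(idx, ord0)
    } else {
      cond["msa"] <- cond["msa"] + 1L
      al <- msaAlign(rv$seq[idx], rv$qual[idx])
      if (al$L == 152L) {
        cond["msaOK"] <- cond["msaOK"] + 1L
        addRows(al$rows, ord0, rv$lastQ[idx])
        usedReads <- usedReads + length(idx)
      } else {
        cond["msaFallback"] <- cond["msaFallback"] + 1L
        for (i in idx) rescueRead(i, ord0)
      }
    }
  }
  nr <- acc$nresc
  list(fullRows = unlist(acc$rows[seq_len(acc$nrows)], use.names = FALSE),
       fullOrd = unlist(acc$ord[seq_len(acc$nrows)], use.names = FALSE),
       fullLastQ = unlist(acc$lastQ[seq_len(acc$nrows)], use.names = FALSE),
       rescueOrd = unlist(acc$rescueOrd[seq_len(nr)], use.names = FALSE),
       rescueBits = if (nr) matrix(unlist(acc$rescueBits[seq_len(nr)]), 2L)
                    else matrix(0L, 2L, 0L),
       erasureContrib = erasureContrib, cond = cond,
       edDiscarded = edDiscarded, usedReads = usedReads)
}

#' Accumulate per-position vote counts
#'
#' Converts routed cluster contributions into the (k0, k1, ke) triples per
#' oligo ordinal and payload bit position.  Full-length and aligned rows
#' vote at every position (gaps as erasures); when `useQscore` is set, votes
#' on the last two bits are only counted for reads whose final base has a
#' Phred score strictly above 20, and rescue reads contribute their final
#' base's bits at positions 271/272.
#'
#' @param reads A `QualityScaledDNAStringSet` or `list(seq=, qual=)`.
#' @param codec A [StorageCodec-class].
#' @param useQscore Apply the Q-score gates (disable to emulate a
#'   quality-blind decoder).
#' @return A list with integer matrices `k0`, `k1`, `ke` (n x 272), the
#'   per-oligo contributing-read count `contributors`, and the routing
#'   statistics of the cluster pass.
#' @export
accumulateCounts <- function(reads, codec, useQscore = TRUE) {
  rv <- readVectors(reads)
  cl <- indexCluster(reads, codec)
  pc <- processClusters(rv, cl$ordinal, codec, useQscore = useQscore)
  countsFromContributions(pc, codec, useQscore, cl)
}

countsFromContributions <- function(pc, codec, useQscore, cl = NULL) {
  nOligos <- codec@code@n
  cv <- count_votes_cpp(as.character(pc$fullRows), as.integer(pc$fullOrd),
                        as.integer(pc$fullLastQ), nOligos,
                        isTRUE(useQscore), 20L)
  k0 <- cv$k0; k1 <- cv$k1
  contributors <- cv$contributors
  if (length(pc$rescueOrd)) {
    for (t in seq_along(pc$rescueOrd)) {
      o <- pc$rescueOrd[t] + 1L
      for (b in 1:2) {
        col <- 270L + b
        if (pc$rescueBits[b, t] == 1L) k1[o, col] <- k1[o, col] + 1L
        else k0[o, col] <- k0[o, col] + 1L
      }
      contributors[o] <- contributors[o] + 1L
    }
  }
  contributors <- contributors + pc$erasureContrib
  ke <- matrix(contributors, nOligos, 272L) - k0 - k1
  list(k0 = k0, k1 = k1, ke = ke, contributors = contributors,
       cond = pc$cond, edDiscarded = pc$edDiscarded,
       usedReads = pc$usedReads,
       rsFailed = if (is.null(cl)) NA_integer_ else cl$rsFailed,
       unknownIndex = if (is.null(cl)) NA_integer_ else cl$unknownIndex,
       correctedIndex = if (is.null(cl)) NA_integer_ else cl$correctedIndex)
}

#' Vote counts to log-likelihood ratio
#'
#' `(k0 - k1) * ln((1 - eps_i)/eps_i)` with `eps_i = epsilon0 -
#' i * deltaEpsilon`: erasure votes carry no information and do not enter;
#' every re-decoding round shrinks the assumed channel error rate, so the
#' LLR magnitude grows strictly with `i` for `k0 != k1`.
#'
#' @param k0,k1 Vote counts (vectors or matrices, same shape).
#' @param i Re-decoding round (0 for the first decoding attempt).
#' @param epsilon0,deltaEpsilon,epsilonEnd Schedule parameters; an error is
#'   raised when the schedule is exhausted (`eps_i < epsilonEnd` or
#'   `eps_i <= 0`).
#' @return LLR values with the convention positive = bit 0 more likely.
#' @export
#' @examples
#' computeLLR(3, 0, i = 0)   # 3 * ln(0.98/0.02)
computeLLR <- function(k0, k1, i = 0L, epsilon0 = 0.02, deltaEpsilon = 0.005,
                       epsilonEnd = 0.005) {
  eps <- epsilon0 - i * deltaEpsilon
  if (eps < epsilonEnd - 1e-12 || eps <= 0 || eps >= 0.5)
    stop("re-decoding schedule exhausted (eps_i = ", eps, ")")
  (k0 - k1) * log((1 - eps) / eps)
}

#' Iterative LDPC re-decoding
#'
#' Decodes all 272 inter-oligo codewords at round i = 0; codewords whose
#' belief propagation does not reach a zero syndrome are re-decoded with
#' LLRs recomputed at round i + 1 (smaller eps, larger magnitudes).  Only
#' failed codewords are re-processed.  Rounds run while `eps_i >=
#' epsilonEnd`.
#'
#' @param counts Vote counts as returned by [accumulateCounts()] (only `k0`
#'   and `k1` are used).
#' @param code An [LDPCCode-class].
#' @param epsilon0,deltaEpsilon,epsilonEnd Schedule (defaults as in
#'   [StorageCodec-class]).
#' @param maxIter BP iteration cap per codeword and round.
#' @return A list with `bits` (n x 272 hard decisions), `converged` (per
#'   codeword), `iterations` (BP iterations of the last round run per
#'   codeword), `redecodeRounds` (extra rounds beyond the first pass) and
#'   `failedColumns`.
#' @export
iterativeRedecode <- function(counts, code, epsilon0 = 0.02,
                              deltaEpsilon = 0.005, epsilonEnd = 0.005,
                              maxIter = 50L) {
  nCw <- ncol(counts$k0)
  stopifnot(nrow(counts$k0) == code@n)
  bits <- matrix(0L, code@n, nCw)
  converged <- logical(nCw)
  iterations <- integer(nCw)
  active <- seq_len(nCw)
  i <- 0L
  rounds <- 0L
  repeat {
    eps <- epsilon0 - i * deltaEpsilon
    if (eps < epsilonEnd - 1e-12 || eps <= 0) break
    llr <- computeLLR(counts$k0[, active, drop = FALSE],
                      counts$k1[, active, drop = FALSE], i,
                      epsilon0, deltaEpsilon, epsilonEnd)
    r <- bpDecode(code, llr, maxIter = maxIter)
    bits[, active] <- r$bits
    converged[active] <- r$converged
    iterations[active] <- r$iterations
    active <- active[!r$converged]
    if (i > 0L) rounds <- rounds + 1L
    if (length(active) == 0L) break
    i <- i + 1L
  }
  list(bits = bits, converged = converged, iterations = iterations,
       redecodeRounds = rounds, failedColumns = active)
}

#' Decode a read corpus back to the stored file
#'
#' Full decoding pipeline: length filter, index clustering, edit-distance
#' eviction, condition routing (with center-star alignment of
#' variable-length clusters), Q-score-gated vote counting, iterative LDPC
#' re-decoding, de-randomization and CRC-32 verification.
#'
#' @param reads A `QualityScaledDNAStringSet` (e.g. from [sampleReads()] or
#'   [readReadsFastq()]).
#' @param codec The [StorageCodec-class] used at encoding time.
#' @param useVL Keep the shortened 150/151-nt reads (disable to use only
#'   full-length reads).
#' @param useQscore Apply the Q>30 last-base rescue gate and the Q>20
#'   last-two-bit counting gate (disable for a quality-blind decoder;
#'   `useVL = FALSE, useQscore = FALSE` reproduces a conventional
#'   fixed-length decoder).
#' @param maxIter BP iteration cap.
#' @return A list with `bytes` (the recovered file, or `NULL`), `success`
#'   (exact recovery: all codewords converged and CRC passed) and `report`
#'   (read accounting, routing conditions, erasure sequences, re-decoding
#'   rounds, CRC status).
#' @export
decodeReads <- function(reads, codec, useVL = TRUE, useQscore = TRUE,
                        maxIter = 50L) {
  keepLens <- if (useVL) c(150L, 151L, 152L) else 152L
  total <- length(if (is.list(reads)) reads$seq else reads)
  kept <- lengthFilter(reads, keep = keepLens)
  keptFraction <- attr(kept, "keptFraction")
  counts <- accumulateCounts(kept, codec, useQscore = useQscore)
  dec <- iterativeRedecode(counts, codec@code,
                           epsilon0 = codec@epsilon0,
                           deltaEpsilon = codec@deltaEpsilon,
                           epsilonEnd = codec@epsilonEnd, maxIter = maxIter)
  up <- unpackPayload(dec$bits[seq_len(codec@code@k), , drop = FALSE], codec)
  success <- all(dec$converged) && isTRUE(up$crcOK)
  report <- list(
    totalReads = total,
    keptReads = length(if (is.list(kept)) kept$seq else kept),
    keptFraction = keptFraction,
    rsFailed = counts$rsFailed,
    unknownIndex = counts$unknownIndex,
    correctedIndex = counts$correctedIndex,
    edDiscarded = counts$edDiscarded,
    usedReads = counts$usedReads,
    usedFraction = counts$usedReads / max(total, 1L),
    erasureSequences = sum(counts$contributors == 0L),
    conditions = counts$cond,
    bpIterations = dec$iterations,
    redecodeRounds = dec$redecodeRounds,
    failedColumns = dec$failedColumns,
    crcOK = isTRUE(up$crcOK))
  list(bytes = up$bytes, success = success, report = report)
}

#' Decode a FASTQ file using a codec sidecar
#'
#' @param fastq Path to the merged-read FASTQ (Phred+33).
#' @param meta Path to the JSON sidecar written by [writeCodecMeta()] (or a
#'   [StorageCodec-class] directly).
#' @param out Optional output path for the recovered file.
#' @param ... Passed to [decodeReads()] (`useVL`, `useQscore`, `maxIter`).
#' @return As [decodeReads()]; when `out` is given the recovered bytes are
#'   also written there (only on success).
#' @export
decodeFile <- function(fastq, meta, out = NULL, ...) {
  codec <- if (methods::is(meta, "StorageCodec")) meta else readCodecMeta(meta)
  res <- decodeReads(readReadsFastq(fastq), codec, ...)
  if (!is.null(out) && res$success)
    writeBin(res$bytes, out)
  res
}
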