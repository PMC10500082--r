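---
title: "Storing files in DNA with one inter-oligo LDPC code and soft-information decoding"
author: "LDPCStorage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing files in DNA with one inter-oligo LDPC code and soft-information decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LDPCStorage)
```

## The problem

Archival storage in synthetic DNA writes a binary file into a pool of short
oligonucleotides and reads it back by sequencing. Both directions are noisy:
synthesis and Illumina-style sequencing substitute roughly 1% of bases, a
much smaller fraction of bases is inserted or deleted, and at realistic
sequencing depths some oligos are never observed at all (dropout). The two
costs that matter are the *writing cost* (synthesized bases per stored
information bit) and the *reading cost* (sequenced bases per information
bit), and they trade off against each other through the amount of
error-correction redundancy.

`LDPCStorage` implements a codec built around a single high-rate
low-density parity-check (LDPC) code applied in the **inter-oligo**
direction: the code runs across the same bit position of all oligos, so the
loss or corruption of one oligo appears to each codeword as a single
erasure or substitution. No per-oligo (intra-oligo) payload code is needed,
which is what keeps the writing cost at 0.62 bases/bit (information density
1.61 bits/nt) for the full-scale layout.

## Encoding

The full-scale layout stores a file of up to
`(16572 * 272 - 96) / 8` bytes (about 548 KB):

1. a 64-bit big-endian length header is prepended and the stream is
   **randomized** by XOR with a seeded xorshift64\* keystream. Randomization
   whitens the payload so long homopolymer runs and extreme GC content
   become statistically rare after base mapping (they are not strictly
   forbidden — the whitening argument is statistical, which matches how
   such pools behave in practice);
2. a **CRC-32** checksum (IEEE polynomial, reflected form) of the
   randomized stream is appended; it is the end-to-end integrity arbiter
   after decoding;
3. the stream is zero-padded and reshaped row-major into 16,572 rows of
   272 bits;
4. each of the 272 bit positions is encoded by the **(18432, 16572) LDPC
   code**, adding 1,860 parity rows;
5. bits are mapped to bases two at a time (A = 00, C = 01, G = 10, T = 11),
   giving 136-nt payloads;
6. every row receives an 8-nt **index** drawn from a canonical list (all
   4^8 8-mers in lexicographic order, minus those with a homopolymer run
   above 3 or a G+C count outside 2..6), protected by an **(8,4)
   Reed–Solomon code over GF(16)** whose 4 parity symbols occupy 8 further
   nt. The RS code is MDS (minimum distance 5) and corrects any two symbol
   errors, so index-based clustering survives heavy local damage;
7. oligos are optionally flanked by the sequencing primers (26 + 21 nt),
   giving 199-nt molecules.

The index list policy deserves a note: any "robust" subset of 8-mers would
do, and robustness beyond the homopolymer rule is not sharply defined. We
fix a deterministic, reproducible policy (homopolymer ≤ 3, GC between 2 and
6, first 18,432 in lexicographic order) and treat it as part of the codec
configuration.

### The LDPC code

The code is near-regular with column weight 4, built by seeded greedy
placement that balances check degrees and forbids any two columns from
sharing more than one check, so the Tanner graph has girth at least 6. One
column carries a fifth edge: with a constant even column weight the GF(2)
sum of H's rows is zero and the rank cannot exceed m − 1, so one odd-weight
column is necessary (and in practice sufficient) for H to reach the full
rank m = 1,860 that makes k exactly 16,572. Columns are permuted once at
construction so positions 1..k are information bits; the parity solver is
obtained by Gaussian elimination over GF(2) and cached, making per-codeword
encoding O(1) sparse-matrix work. The construction is deterministic in its
seed and serializes to a plain-text file, so encoder and decoder provably
share bit-identical codes.

## The synthetic channel

`channelParams()` emulates merged Illumina-style read corpora. The defaults
are calibrated once against the statistics such corpora show and are then
treated as the study conditions, not as tuning knobs:

| parameter | default | rationale |
|---|---|---|
| substitution rate | 0.98% /base | total base error rate ≈ 1%, dominated by substitutions |
| insertion rate | 5·10⁻⁵ /base | Illumina indel rates are orders of magnitude below substitution rates |
| deletion rate | 9.5·10⁻⁵ /base | slightly above insertions; yields ~1.3% of reads shortened to 150/151 nt |
| last-base multiplier | 3 | the final base is markedly more error-prone |
| merge-artifact rate | 5% | reads truncated below 150 nt by failed merging/trimming, discarded by the length filter |
| correct-base Phred | peak Q38, P(Q ≥ 30) = 0.972 | corpus Q30 fraction ≈ 96% |
| error-base Phred | peak Q15, P(Q ≥ 30) = 0.05 | low-quality calls concentrate on errors |

Under these defaults a corpus shows ~93% full-length (152-nt) reads, ~1.3%
at 150/151 nt and a Q30 fraction near 96%, which the test suite checks on a
100,000-read corpus. Reads are drawn i.i.d. uniformly with replacement, so
dropout emerges naturally at low coverage (the never-sampled count follows
the occupancy law n(1 − 1/n)^N).

What the simulator does **not** model: PCR amplification bias, chimeras,
nanopore error profiles, and the paired-end merge step itself (reads are
emitted already merged and primer-free). Passing end-to-end tests on this
channel therefore demonstrates the decoder's error- and dropout-handling
logic under realistic Illumina-like statistics, not robustness to
platform-specific artifacts outside that envelope.

## Decoding

1. **Length filter** — only 150/151/152-nt reads are used. Shortened reads
   carry exploitable information; anything else is discarded.
2. **Index-based clustering** — the first 16 nt are RS-decoded; reads whose
   decoding fails, or whose decoded index is not in the canonical list, are
   discarded (RS decoding alone can emit codewords of unused indices).
3. **Edit-distance eviction** — within each cluster a member whose minimum
   edit distance to every other member exceeds `d_th = 10` is evicted.
   The threshold sits comfortably between typical same-oligo distances
   (a few edits at 1% error) and different-oligo distances (≈ 100 for
   random 152-mers). In a 2-read cluster with mutual distance above the
   threshold both members fall — a deliberate, documented edge: with no
   third read there is no evidence which member is genuine. The eviction
   rule is computed with a banded, early-terminating Levenshtein kernel,
   which is exact for the ≤-threshold decision.
4. **Condition routing** — clusters whose members are all full-length vote
   directly. A singleton variable-length read contributes erasures
   everywhere except its final base, which votes on the last two payload
   bits when its Phred score is strictly above 30: after a deletion the
   absolute positions downstream are unreliable, but the final base is
   positionally exact from the read's end. Multi-read variable-length
   clusters are co-registered by a center-star multiple alignment (unit
   costs, center = member closest to 152 nt, ties broken by mean quality);
   if the merged alignment frame has length 152 the aligned rows vote with
   gaps as erasures, otherwise the cluster falls back to the last-base
   rescue, read by read.
5. **Quality-gated counting** — per oligo and payload bit position the
   decoder counts zeros (k0), ones (k1) and erasures (ke). Votes on the
   last two bits are only counted when the read's final base exceeds Phred
   20. Zero-coverage oligos become all-zero LLR rows — one clean erasure
   per codeword.
6. **Soft decoding with iterative re-decoding** — the LLR of a position is
   (k0 − k1)·ln((1 − ε_i)/ε_i), with ε_0 = 0.02 and ε reduced by Δε = 0.005
   per re-decoding round down to ε_end = 0.005 (rounds run while
   ε_i ≥ ε_end, i.e. i ∈ {0,1,2,3} at the defaults). All 272 codewords are
   decoded by flooding sum-product belief propagation (max 50 iterations,
   messages clipped to ±30, convergence = zero syndrome, tested before
   every round so clean inputs cost zero iterations); only codewords that
   fail are re-decoded at the next round. Because counts are fixed, a round
   only rescales each column's LLRs — but belief propagation is not
   scale-invariant, and the sharpened magnitudes do rescue borderline
   codewords at small extra cost.
7. **Finalization** — the 16,572×272 systematic part is reassembled
   row-major, the header is de-randomized to learn the file length, the
   CRC-32 is verified over the randomized stream, and the exact bytes are
   emitted. Success means every codeword converged *and* the CRC passed.

Setting `useVL = FALSE, useQscore = FALSE` in `decodeReads()` reproduces a
conventional fixed-length, quality-blind decoder; the acceptance suite
checks that enabling both strictly increases the used-read fraction and
never increases the number of erasure sequences on corpora containing
shortened reads.

## Numerical and design choices

* **LLR sign convention**: positive = bit 0 more likely, everywhere.
* **GF(16)**: primitive polynomial x⁴ + x + 1, α = x; RS evaluation points
  α⁰..α⁷ in systematic form. Any MDS-preserving choice works; fixing one
  makes codewords reproducible. RS decoding is bounded-distance via a
  precomputed syndrome table (6,420 correctable patterns; all syndromes
  distinct because d_min = 5).
* **CRC-32 variant**: the ubiquitous reflected polynomial (0x04C11DB7 /
  0xEDB88320) with standard init/final XOR; check value 0xCBF43926.
* **Bit order**: bit streams are the `rawToBits()` expansion of bytes
  (LSB-first within a byte); the CRC, keystream and base map are all
  defined on that single ordering, so the pipeline is self-consistent by
  construction.
* **Whether CRC precedes or follows randomization** is a free choice; we
  randomize first and checksum the randomized stream, symmetric in the
  decoder.
* **Ties in BP hard decisions** (total LLR exactly 0) resolve to bit 0.
* **Schedule end**: ε_end defaults to 0.005 and the round at ε = ε_end runs
  ("minimum allowed value", inclusive).
* **Degenerate inputs**: empty files round-trip (header + CRC + padding);
  empty clusters route nowhere and become erasure rows; an all-zero LLR
  column is reported non-converged rather than raised.

## Problem sizes used by the test suite

The suite exercises the full-scale (18432, 16572) encoder once (construction,
encoding, syndrome verification of all 272 codewords). End-to-end channel
experiments run on scaled codes with the same 152-nt oligo geometry: a
rate-0.899 code (n = 2048, k = 1842, capacity ≈ 61 KB) carries a 50 KB file
through 100 seeded channel round trips at coverage 5, and a smaller
n = 256 code drives the success-rate-versus-sampling-number sweep
(5 sampling levels × 30 trials) whose transition mirrors the full-scale
behaviour. These sizes were chosen so the whole suite exercises every
pipeline stage at meaningful scale while remaining comfortably runnable on
a laptop.

## Known limitations

* The LDPC constructor is a greedy girth-6 placement, not a
  structured algebraic construction; any regular girth-≥6 code of the same
  dimensions is an equally valid instantiation, and the decoder depends
  only on the structural invariants.
* The center-star aligner is exact for the dominant single-indel clusters
  but is a heuristic for multi-indel tangles; such clusters fall back to
  the conservative last-base rescue via the length-152 frame test.
* Reading-cost conventions differ across the literature; `readingCost()`
  uses sampled reads × nominal read length (152) over information bits and
  documents exactly that.
* The simulator's error processes are i.i.d. per base; correlated error
  bursts and coverage bias are out of scope.
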