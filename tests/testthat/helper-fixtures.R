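suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Track built directly from 1-based closed intervals (no file round trip).
makeTrack <- function(chrom, start, end, value, label = "t",
                      seqlengths = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), score = value)
  coverageTrack(gr, label = label, seqlengths = seqlengths)
}

# A uniform-coverage track over [1, len] on each chromosome.
uniformTrack <- function(value, len = 50000L, chroms = "chr1",
                         label = "u") {
  makeTrack(rep(chroms, each = 1L), 1L, len, value, label = label,
            seqlengths = setNames(rep(len, length(chroms)), chroms))
}

# Independent per-base oracle: expands interval definitions to a plain
# numeric vector (1-based positions from..to), never touching package
# internals.
perBaseOracle <- function(chrom, start, end, value, qchrom, from, to) {
  chrom <- rep_len(chrom, length(start))
  out <- numeric(to - from + 1L)
  for (i in seq_along(start)) {
    if (chrom[i] != qchrom) next
    lo <- max(start[i], from); hi <- min(end[i], to)
    if (lo <= hi) out[(lo - from + 1L):(hi - from + 1L)] <- out[(lo - from + 1L):(hi - from + 1L)] + value[i]
  }
  out
}

# Enumeration oracle for the hypergeometric pmf via choose().
hyperPmf <- function(k, K, n, N) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

writeTmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
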