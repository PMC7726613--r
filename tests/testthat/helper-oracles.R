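## Independent oracles used across the suite. These deliberately re-derive
## results by brute force, separate from the package implementation.

rcOracle <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

## brute-force overlap merge: scan every offset of revcomp(read2) along
## read1, apply the scoring rule (lowest mismatch fraction, then largest
## overlap, then smallest offset; quality-winner consensus, read1 on ties)
bruteMerge <- function(r1, q1, r2, q2, minOverlap = 12L,
                       maxMismatchFrac = 0.25) {
  s1 <- strsplit(r1, "")[[1]]; p1 <- strsplit(q1, "")[[1]]
  s2 <- strsplit(rcOracle(r2), "")[[1]]
  p2 <- rev(strsplit(q2, "")[[1]])
  L1 <- length(s1); L2 <- length(s2)
  best <- NULL
  for (off in 0:(L1 - minOverlap)) {
    ov <- min(L1 - off, L2)
    if (ov < minOverlap) next
    mm <- sum(s1[off + seq_len(ov)] != s2[seq_len(ov)])
    frac <- mm / ov
    if (frac > maxMismatchFrac) next
    if (is.null(best) || frac < best$frac - 1e-12 ||
        (abs(frac - best$frac) <= 1e-12 && ov > best$ov)) {
      best <- list(off = off, ov = ov, frac = frac)
    }
  }
  if (is.null(best)) return(NA_character_)
  off <- best$off; ov <- best$ov
  cons <- character(ov)
  for (k in seq_len(ov)) {
    a <- s1[off + k]; b <- s2[k]
    cons[k] <- if (a == b) a
               else if (p2[k] > p1[off + k]) b else a
  }
  tail_ <- if (off + L2 > L1) s2[(ov + 1):L2]
           else if (L1 > off + ov) s1[(off + ov + 1):L1]
           else character(0)
  paste(c(s1[seq_len(off)], cons, tail_), collapse = "")
}

## Gotoh (affine-gap) alignment of the full query against a reference with
## free end gaps on the reference, scoring match 2 / mismatch -2 and a gap
## of length L costing open + L * ext; returns percent identity =
## matches / alignment length of the optimal alignment.
dpIdentity <- function(query, ref, match = 2, mismatch = -2,
                       open = 4, ext = 2) {
  q <- strsplit(query, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  ## state matrices over (i = query pos, j = ref pos): score and, for
  ## traceback-free identity, track (matches, length) of the best path
  M <- matrix(NEG, n + 1, m + 1);  Ix <- M; Iy <- M
  Mm <- matrix(0L, n + 1, m + 1); Ml <- Mm
  Xm <- Mm; Xl <- Mm; Ym <- Mm; Yl <- Mm
  M[1, ] <- 0                      # free leading ref gap: start anywhere
  for (i in 2:(n + 1)) {
    ## query must be fully aligned: leading query gap vs nothing is a real
    ## gap only when j = 1 handled through Iy
    Iy[i, 1] <- -(open + ext * (i - 1))
    Ym[i, 1] <- 0L; Yl[i, 1] <- i - 1L
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == r[j - 1]) match else mismatch
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      w <- which.max(prev)
      M[i, j] <- prev[w] + s
      pm <- c(Mm[i - 1, j - 1], Xm[i - 1, j - 1], Ym[i - 1, j - 1])[w]
      pl <- c(Ml[i - 1, j - 1], Xl[i - 1, j - 1], Yl[i - 1, j - 1])[w]
      Mm[i, j] <- pm + as.integer(q[i - 1] == r[j - 1])
      Ml[i, j] <- pl + 1L
      ## Ix: gap in query (consume ref)
      cand <- c(M[i, j - 1] - open - ext, Ix[i, j - 1] - ext)
      wx <- which.max(cand)
      Ix[i, j] <- cand[wx]
      Xm[i, j] <- c(Mm[i, j - 1], Xm[i, j - 1])[wx]
      Xl[i, j] <- c(Ml[i, j - 1], Xl[i, j - 1])[wx] + 1L
      ## Iy: gap in ref (consume query)
      cand <- c(M[i - 1, j] - open - ext, Iy[i - 1, j] - ext)
      wy <- which.max(cand)
      Iy[i, j] <- cand[wy]
      Ym[i, j] <- c(Mm[i - 1, j], Ym[i - 1, j])[wy]
      Yl[i, j] <- c(Ml[i - 1, j], Yl[i - 1, j])[wy] + 1L
    }
  }
  ## free trailing ref gap: best over all end columns and states
  finals <- rbind(
    data.frame(s = M[n + 1, ], m = Mm[n + 1, ], l = Ml[n + 1, ]),
    data.frame(s = Ix[n + 1, ], m = Xm[n + 1, ], l = Xl[n + 1, ]),
    data.frame(s = Iy[n + 1, ], m = Ym[n + 1, ], l = Yl[n + 1, ]))
  best <- finals[which.max(finals$s), ]
  100 * best$m / best$l
}

## all permutations of 1:n (n small)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

## random toy count table as a UniqueSeqTable
toySeqTable <- function(counts, seqs, locus = "parasite") {
  df <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
    data.frame(sample_id = colnames(counts)[j], locus = locus,
               sequence = seqs, n = counts[, j])
  }))
  dereplicate(df[df$n > 0, ], locus)
}
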