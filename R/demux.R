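#' Assign read pairs to samples by exact barcode match
#'
#' Exact-match lookup of the read-1 prefix against the barcode table; reads
#' whose prefix matches no barcode (including reads shorter than the
#' barcode) are returned as \code{"UNASSIGNED"}. No mismatch tolerance is
#' applied.
#'
#' @param read1 character vector of read-1 sequences.
#' @param barcodes named character vector (sample id -> barcode), all one
#'   length.
#' @return Character vector of sample ids or \code{"UNASSIGNED"}.
#' @export
assignSample <- function(read1, barcodes) {
  stopIfNot(length(barcodes) > 0L, "barcode table is empty")
  stopIfNot(length(unique(nchar(barcodes))) == 1L,
            "barcodes must share one length")
  bl <- nchar(barcodes[[1]])
  pre <- substr(read1, 1L, bl)
  pre[nchar(read1) < bl] <- ""
  hit <- match(pre, barcodes)
  out <- names(barcodes)[hit]
  out[is.na(hit)] <- "UNASSIGNED"
  out
}

#' Identify the locus of a read from its primer prefix
#'
#' Scans for an exact primer match anchored immediately after the barcode
#' (i.e. at the start of the supplied sequence); when one primer is a
#' prefix of another, the longest matching primer wins.
#'
#' @param seqAfterBarcode character vector of read-1 sequences with the
#'   barcode removed.
#' @param primers named character vector (locus -> forward primer), all
#'   18-27 nt.
#' @return Character vector of locus names or \code{"UNKNOWN"}.
#' @export
identifyLocus <- function(seqAfterBarcode, primers) {
  stopIfNot(all(nchar(primers) >= 18L & nchar(primers) <= 27L),
            "primers must be 18-27 nt")
  ord <- order(nchar(primers), decreasing = TRUE)  # longest match wins
  out <- rep("UNKNOWN", length(seqAfterBarcode))
  todo <- rep(TRUE, length(seqAfterBarcode))
  for (j in ord) {
    p <- primers[[j]]
    hit <- todo & substr(seqAfterBarcode, 1L, nchar(p)) == p
    out[hit] <- names(primers)[j]
    todo[hit] <- FALSE
  }
  out
}

#' Merge read pairs into consensus amplicons
#'
#' Best-scoring ungapped overlap merge: read 2 is reverse-complemented and
#' slid along read 1; the overlap must span at least \code{minOverlap}
#' bases with a mismatch fraction at most \code{maxMismatchFrac}. At
#' mismatched overlap positions the higher-quality base is kept (read 1 on
#' ties). Pairs with no qualifying overlap yield \code{NA}.
#'
#' @param read1,read2 character vectors (read 2 as sequenced).
#' @param qual1,qual2 Phred+33 quality strings; default constant.
#' @param minOverlap minimum overlap in bases (default 12).
#' @param maxMismatchFrac maximum mismatch fraction in the overlap.
#' @return Character vector of merged sequences, \code{NA} on failure.
#' @examples
#' mergePairs("ACGTACGTACGTTT", revComp("ACGTACGTACGTTT"))
#' @export
mergePairs <- function(read1, read2, qual1 = strrep("I", nchar(read1)),
                       qual2 = strrep("I", nchar(read2)),
                       minOverlap = 12L, maxMismatchFrac = 0.25) {
  .merge_pairs_cpp(read1, qual1, read2, qual2, as.integer(minOverlap),
                   maxMismatchFrac)
}

#' Trim primers from merged amplicon sequences
#'
#' If both primers are found, the span between them is retained (primers
#' removed). If only the forward primer is found, the forward primer is
#' removed and the sequence is otherwise left untrimmed, except that loci
#' with an expected amplicon shorter than 300 bp additionally lose 50 bp
#' from the 5' end (a guard against primer dimers and low-quality starts).
#' Sequences not starting with the forward primer are unroutable and
#' returned as \code{NA}.
#'
#' @param seqs character vector of merged (or read-1-only) sequences,
#'   beginning at the forward primer.
#' @param forward,reverse the locus primer pair.
#' @param expectedLen expected full amplicon length of the locus in bp.
#' @param shortAmpliconTrim bases removed from the 5' end of untrimmed
#'   sequences at short-amplicon (< 300 bp) loci.
#' @return Character vector of trimmed sequences (\code{NA} = unroutable).
#' @export
trimAmplicon <- function(seqs, forward, reverse, expectedLen,
                         shortAmpliconTrim = 50L) {
  out <- rep(NA_character_, length(seqs))
  hasF <- startsWith(seqs, forward)
  revRC <- revComp(reverse)
  body <- substr(seqs, nchar(forward) + 1L, nchar(seqs))
  revAt <- regexpr(revRC, body, fixed = TRUE)
  both <- hasF & revAt > 0L
  out[both] <- substr(body[both], 1L, revAt[both] - 1L)
  fOnly <- hasF & revAt <= 0L
  if (expectedLen < 300L) {
    out[fOnly] <- substr(body[fOnly], shortAmpliconTrim + 1L,
                         nchar(body[fOnly]))
  } else {
    out[fOnly] <- body[fOnly]
  }
  out
}

#' Length-filter trimmed sequences
#'
#' @param seqs character vector.
#' @param minLen sequences are kept only if strictly longer than this
#'   (default 90 bp).
#' @return Logical vector: keep (\code{TRUE}) or discard.
#' @export
lengthFilter <- function(seqs, minLen = 90L) {
  !is.na(seqs) & nchar(seqs) > minLen
}

#' Demultiplex, merge and trim a multiplexed paired-end run
#'
#' Routes every read pair to a sample (exact barcode match on the read-1
#' prefix) and a locus (exact anchored primer match), merges the pair into
#' a consensus amplicon, trims primers and applies the length filter.
#' Pairs that fail to merge are kept as read-1-only sequences
#' (\code{unmerged-kept}) and flow through the same trimming; pairs with no
#' barcode or primer match are \code{discarded-unroutable}; trimmed
#' sequences at or under the length floor are \code{discarded-short}.
#' Every input pair lands in exactly one disposition tally.
#'
#' @param fastq1,fastq2 paths to the paired FASTQ files.
#' @param panel a \linkS4class{PanelDesign}.
#' @param minOverlap,maxMismatchFrac merge parameters (see
#'   \code{\link{mergePairs}}).
#' @param minLen length floor (strictly-greater-than, default 90).
#' @return A \linkS4class{RoutedRun}.
#' @export
demuxRun <- function(fastq1, fastq2, panel, minOverlap = 12L,
                     maxMismatchFrac = 0.25, minLen = 90L) {
  fq1 <- readFastq(fastq1)
  fq2 <- readFastq(fastq2)
  stopIfNot(length(fq1$seq) == length(fq2$seq),
            "read 1 and read 2 files differ in read count")
  n <- length(fq1$seq)
  bc <- panelBarcodes(panel)
  loci <- panelLoci(panel)
  primers <- stats::setNames(loci$forward, loci$locus)
  bl <- nchar(bc[[1]])

  sid <- assignSample(fq1$seq, bc)
  body1 <- substr(fq1$seq, bl + 1L, nchar(fq1$seq))
  qbody1 <- substr(fq1$qual, bl + 1L, nchar(fq1$qual))
  locus <- identifyLocus(body1, primers)
  locus[sid == "UNASSIGNED"] <- "UNKNOWN"
  routable <- sid != "UNASSIGNED" & locus != "UNKNOWN"

  nUnassigned <- sum(sid == "UNASSIGNED")
  nUnknown <- sum(sid != "UNASSIGNED" & locus == "UNKNOWN")

  out <- data.table::data.table()
  if (any(routable)) {
    dt <- data.table::data.table(
      sample_id = sid[routable], locus = locus[routable],
      r1 = body1[routable], q1 = qbody1[routable],
      r2 = fq2$seq[routable], q2 = fq2$qual[routable])
    ## merge unique (r1, r2) combinations once, then re-expand by count
    agg <- dt[, .N, by = .(sample_id, locus, r1, q1, r2, q2)]
    agg[, merged := mergePairs(r1, r2, q1, q2, minOverlap, maxMismatchFrac)]
    agg[, disposition := ifelse(is.na(merged), "unmerged-kept", "merged")]
    agg[is.na(merged), merged := r1]  # read-1-only fallback
    for (loc in unique(agg$locus)) {
      pr <- primerFor(panel, loc)
      rows <- agg$locus == loc
      agg[rows, trimmed := trimAmplicon(merged, pr$forward, pr$reverse,
                                        pr$expected_len)]
    }
    agg[, keep := lengthFilter(trimmed, minLen)]
    out <- agg[keep == TRUE,
               .(n = sum(N)), by = .(sample_id, locus, sequence = trimmed,
                                     disposition)]
    nShort <- sum(agg$N[!agg$keep])
  } else {
    nShort <- 0L
  }
  tallies <- data.frame(
    disposition = c("merged", "unmerged-kept", "discarded-short",
                    "unassigned-barcode", "unknown-locus"),
    n = c(sum(out$n[out$disposition == "merged"]) %||% 0L,
          sum(out$n[out$disposition == "unmerged-kept"]) %||% 0L,
          nShort, nUnassigned, nUnknown))
  new("RoutedRun", sequences = as.data.frame(out), summary = tallies,
      nPairs = as.integer(n))
}

#' Write routed sequences as per-locus, per-sample FASTA
#'
#' @param routed a \linkS4class{RoutedRun}.
#' @param dir output directory; files are named
#'   \code{<locus>/<sample>.fasta}, one record per retained read with a
#'   running index.
#' @return Invisibly, the written file paths.
#' @export
writeRoutedFasta <- function(routed, dir) {
  sq <- routed@sequences
  paths <- character(0)
  for (loc in unique(sq$locus)) {
    d <- file.path(dir, loc)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    sub <- sq[sq$locus == loc, , drop = FALSE]
    for (sid in unique(sub$sample_id)) {
      rows <- sub[sub$sample_id == sid, , drop = FALSE]
      ss <- Biostrings::DNAStringSet(rep(rows$sequence, rows$n))
      names(ss) <- sprintf("%s_%s_%06d", sid, loc, seq_along(ss))
      p <- file.path(d, paste0(sid, ".fasta"))
      Biostrings::writeXStringSet(ss, p, width = 80)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
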