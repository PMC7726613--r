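## internal constructor
newUniqueSeqTable <- function(counts, sequences, locus) {
  counts <- as.matrix(counts)
  mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("%s_seq_%05d", locus, seq_len(nrow(counts)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(sequence = unname(as.character(sequences)),
                                   row.names = rownames(counts)))
  S4Vectors::metadata(se)$locus <- locus
  new("UniqueSeqTable", se)
}

#' Dereplicate routed sequences into a unique-sequence count table
#'
#' Groups the retained sequences of one locus by exact string identity and
#' records, for each unique sequence, how many times it was observed in
#' each sample. Sequences containing \code{N} are dropped beforehand. Rows
#' are ordered by decreasing total count (ties by sequence); empty input
#' yields an empty table.
#'
#' @param routed a \linkS4class{RoutedRun}, or a data.frame with columns
#'   \code{sample_id}, \code{sequence} and optionally \code{n} (default 1).
#' @param locus the locus to extract.
#' @return A \linkS4class{UniqueSeqTable}.
#' @export
dereplicate <- function(routed, locus) {
  df <- if (is(routed, "RoutedRun")) routed@sequences else as.data.frame(routed)
  if (!"n" %in% names(df)) df$n <- 1L
  if ("locus" %in% names(df)) df <- df[df$locus == locus, , drop = FALSE]
  df <- df[!grepl("N", df$sequence, fixed = TRUE), , drop = FALSE]
  if (!nrow(df))
    return(newUniqueSeqTable(matrix(0L, 0L, 0L), character(0), locus))
  dt <- data.table::as.data.table(df[, c("sample_id", "sequence", "n")])
  agg <- dt[, .(n = sum(n)), by = .(sequence, sample_id)]
  samples <- sort(unique(agg$sample_id))
  seqs <- agg[, .(total = sum(n)), by = sequence]
  data.table::setorder(seqs, -total, sequence)
  counts <- matrix(0L, nrow(seqs), length(samples),
                   dimnames = list(NULL, samples))
  counts[cbind(match(agg$sequence, seqs$sequence),
               match(agg$sample_id, samples))] <- as.integer(agg$n)
  newUniqueSeqTable(counts, seqs$sequence, locus)
}

#' Remove globally rare unique sequences
#'
#' Drops rows observed fewer than \code{minTotal} times summed across all
#' samples (default: fewer than 10), the guard against error-bearing
#' sequences. Idempotent.
#'
#' @param x a \linkS4class{UniqueSeqTable}.
#' @param minTotal minimum total count a row needs to be retained.
#' @return The filtered \linkS4class{UniqueSeqTable}.
#' @export
filterRare <- function(x, minTotal = 10L) {
  keep <- rowSums(seqCounts(x)) >= minTotal
  x[keep, ]
}

#' Exclude samples below the per-locus read floor
#'
#' Removes sample columns whose total read count falls below the locus
#' threshold (bacterial 16S: fewer than 5000 reads are discarded; kdr,
#' S200X6.1, cox1 and blood-meal samples need at least 1000 reads). Loci
#' without a configured floor (the parasite/virus stream) raise an error
#' unless \code{threshold} is given explicitly.
#'
#' @param x a \linkS4class{UniqueSeqTable}.
#' @param threshold read floor; defaults to
#'   \code{\link{depthThreshold}(locusName(x))}.
#' @return A list with the filtered \code{table} and the character vector
#'   of \code{excluded} sample ids.
#' @export
sampleDepthFilter <- function(x, threshold = depthThreshold(locusName(x))) {
  tot <- colSums(seqCounts(x))
  keep <- tot >= threshold
  list(table = x[, keep], excluded = colnames(x)[!keep])
}

#' Serialise a unique-sequence table to TSV
#'
#' @param x a \linkS4class{UniqueSeqTable}.
#' @param path output path; columns are \code{sequence} then one count
#'   column per sample.
#' @return Invisibly, \code{path}.
#' @export
writeSeqTable <- function(x, path) {
  df <- data.frame(sequence = SummarizedExperiment::rowData(x)$sequence,
                   seqCounts(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
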