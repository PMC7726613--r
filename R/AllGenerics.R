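#' Accessors for panel, truth and table objects
#'
#' \code{panelLoci} returns the locus/primer table of a panel;
#' \code{panelBarcodes} the named barcode vector; \code{referenceDb} the
#' per-locus reference \link[Biostrings]{DNAStringSet} list;
#' \code{referenceInfo} the parsed per-locus reference annotations;
#' \code{truthTable} the per-sample truth data.frame of a simulated cohort;
#' \code{communityTruth} its ASV x sample relative-abundance matrix;
#' \code{seqCounts} the counts assay of a \linkS4class{UniqueSeqTable};
#' \code{uniqueSequences} its row sequences as a
#' \link[Biostrings]{DNAStringSet}; \code{locusName} its locus.
#'
#' @param x a \linkS4class{PanelDesign}, \linkS4class{CohortTruth} or
#'   \linkS4class{UniqueSeqTable}.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases panelLoci panelBarcodes referenceDb referenceInfo truthTable
#'   communityTruth seqCounts uniqueSequences locusName
NULL

#' @rdname accessors
#' @export
setGeneric("panelLoci", function(x) standardGeneric("panelLoci"))
#' @rdname accessors
#' @export
setGeneric("panelBarcodes", function(x) standardGeneric("panelBarcodes"))
#' @rdname accessors
#' @export
setGeneric("referenceDb", function(x) standardGeneric("referenceDb"))
#' @rdname accessors
#' @export
setGeneric("referenceInfo", function(x) standardGeneric("referenceInfo"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("communityTruth", function(x) standardGeneric("communityTruth"))
#' @rdname accessors
#' @export
setGeneric("seqCounts", function(x) standardGeneric("seqCounts"))
#' @rdname accessors
#' @export
setGeneric("uniqueSequences", function(x) standardGeneric("uniqueSequences"))
#' @rdname accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @rdname accessors
setMethod("panelLoci", "PanelDesign", function(x) x@loci)
#' @rdname accessors
setMethod("panelBarcodes", "PanelDesign", function(x) x@barcodes)
#' @rdname accessors
setMethod("referenceDb", "PanelDesign", function(x) x@referenceDb)
#' @rdname accessors
setMethod("referenceInfo", "PanelDesign", function(x) x@referenceInfo)
#' @rdname accessors
setMethod("truthTable", "CohortTruth", function(x) x@samples)
#' @rdname accessors
setMethod("communityTruth", "CohortTruth", function(x) x@community)
#' @rdname accessors
setMethod("seqCounts", "UniqueSeqTable",
          function(x) SummarizedExperiment::assay(x, "counts"))
#' @rdname accessors
setMethod("uniqueSequences", "UniqueSeqTable", function(x)
  Biostrings::DNAStringSet(stats::setNames(
    SummarizedExperiment::rowData(x)$sequence, rownames(x))))
#' @rdname accessors
setMethod("locusName", "UniqueSeqTable",
          function(x) S4Vectors::metadata(x)$locus)

setMethod("show", "PanelDesign", function(object) {
  cat("PanelDesign with", nrow(object@loci), "loci and",
      length(object@barcodes), "sample barcodes\n")
  nref <- vapply(object@referenceDb, length, integer(1))
  for (i in seq_len(nrow(object@loci))) {
    loc <- object@loci$locus[i]
    cat(sprintf("  %-10s fwd %2d nt / rev %2d nt, amplicon ~%d bp, %d refs\n",
                loc, nchar(object@loci$forward[i]),
                nchar(object@loci$reverse[i]),
                object@loci$expected_len[i], nref[[loc]] %||% 0L))
  }
})

setMethod("show", "CohortTruth", function(object) {
  s <- object@samples
  cat("CohortTruth:", nrow(s), "samples (", sum(s$is_control),
      "extraction controls ) over", length(unique(s$site[!s$is_control])),
      "sites;", nrow(object@community), "community ASVs\n")
  cat("  planted between-site community effect:", object@siteEffect, "\n")
})

setMethod("show", "PermanovaResult", function(object) {
  cat("Sequential (Type I) distance-based PERMANOVA,",
      object@nPerm, "permutations\n")
  tab <- object@table
  tab$SumOfSqs <- signif(tab$SumOfSqs, 5)
  tab$R2 <- round(tab$R2, 4)
  tab$F <- round(tab$F, 4)
  print(tab)
  invisible(object)
})

setMethod("show", "RoutedRun", function(object) {
  cat("RoutedRun:", object@nPairs, "read pairs\n")
  print(object@summary, row.names = FALSE)
})
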