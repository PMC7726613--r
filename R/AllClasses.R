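#' @import methods
NULL

#' PanelDesign: the multiplexed amplicon panel
#'
#' Describes the six-locus screening panel: per-locus primer pairs and
#' expected amplicon lengths, the per-sample barcodes used for
#' demultiplexing, and a reference database of named marker sequences per
#' locus (full amplicons, primers included).
#'
#' @slot loci data.frame with columns \code{locus}, \code{forward},
#'   \code{reverse}, \code{expected_len} (full amplicon length in bp).
#' @slot barcodes named character vector, sample id -> barcode sequence.
#'   All barcodes share one length.
#' @slot referenceDb named list (by locus) of \link[Biostrings]{DNAStringSet}
#'   reference amplicons.
#' @slot referenceInfo named list (by locus) of data.frames with at least a
#'   \code{name} column plus any attributes parsed from the FASTA headers
#'   (e.g. \code{group}, \code{taxonomy}, \code{resistant}).
#' @exportClass PanelDesign
setClass("PanelDesign",
  slots = c(loci = "data.frame", barcodes = "character",
            referenceDb = "list", referenceInfo = "list"))

setValidity("PanelDesign", function(object) {
  msg <- character(0)
  lo <- object@loci
  need <- c("locus", "forward", "reverse", "expected_len")
  if (!all(need %in% names(lo)))
    return(paste("loci table must have columns:", paste(need, collapse = ", ")))
  plen <- nchar(c(lo$forward, lo$reverse))
  if (any(plen < 18L | plen > 27L))
    msg <- c(msg, "all primers must be 18-27 nt long")
  if (anyDuplicated(lo$locus))
    msg <- c(msg, "duplicated locus names")
  bc <- object@barcodes
  if (length(bc)) {
    if (anyDuplicated(bc)) msg <- c(msg, "barcodes must be unique")
    if (length(unique(nchar(bc))) > 1L)
      msg <- c(msg, "barcodes must all have the same length")
    if (is.null(names(bc)) || anyDuplicated(names(bc)))
      msg <- c(msg, "barcodes must be named by unique sample ids")
  }
  for (loc in names(object@referenceDb)) {
    if (!loc %in% lo$locus) {
      msg <- c(msg, paste0("reference set for unknown locus '", loc, "'"))
      next
    }
    i <- match(loc, lo$locus)
    refs <- as.character(object@referenceDb[[loc]])
    okF <- startsWith(refs, lo$forward[i])
    okR <- endsWith(refs, revComp(lo$reverse[i]))
    if (!all(okF & okR))
      msg <- c(msg, paste0("locus '", loc, "': reference sequences must ",
                           "begin with the forward primer and end with the ",
                           "reverse-complemented reverse primer"))
  }
  if (length(msg)) msg else TRUE
})

#' CohortTruth: ground truth for a simulated mosquito cohort
#'
#' Per-sample truth for a simulated multiplexed run: collection site,
#' Anopheles species (or F1 hybrid), kdr L1014F genotype, blood-meal mixture,
#' infection set and bacterial community composition, plus which samples are
#' extraction controls.
#'
#' @slot samples data.frame with columns \code{sample_id}, \code{site},
#'   \code{species}, \code{kdr_genotype} (RR/SS/RS), \code{blood_meal}
#'   (semicolon-joined \code{host:proportion} pairs, empty string if unfed),
#'   \code{infections} (semicolon-joined reference names, empty if none) and
#'   \code{is_control}.
#' @slot community numeric matrix of bacterial relative abundances,
#'   ASVs x samples; each non-control column sums to 1.
#' @slot siteEffect the planted between-site share of community variance.
#' @slot seed the seed the cohort was drawn with.
#' @exportClass CohortTruth
setClass("CohortTruth",
  slots = c(samples = "data.frame", community = "matrix",
            siteEffect = "numeric", seed = "integer"))

setValidity("CohortTruth", function(object) {
  msg <- character(0)
  s <- object@samples
  need <- c("sample_id", "site", "species", "kdr_genotype", "blood_meal",
            "infections", "is_control")
  if (!all(need %in% names(s)))
    return(paste("samples table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$sample_id)) msg <- c(msg, "duplicated sample ids")
  if (!identical(colnames(object@community), s$sample_id))
    msg <- c(msg, "community columns must match samples$sample_id")
  ctrl <- s$is_control
  if (any(ctrl)) {
    bad <- ctrl & (s$species != "" | s$kdr_genotype != "" |
                     s$blood_meal != "" | s$infections != "")
    if (any(bad))
      msg <- c(msg, "extraction controls must carry empty biological truth")
  }
  cs <- colSums(object@community)
  if (any(abs(cs[!ctrl] - 1) > 1e-9))
    msg <- c(msg, "non-control community compositions must sum to 1 (+-1e-9)")
  if (any(abs(cs[ctrl]) > 1e-9))
    msg <- c(msg, "control community compositions must be zero")
  if (length(msg)) msg else TRUE
})

#' RunConfig: sequencing-run simulation parameters
#'
#' @slot depth named numeric vector of mean per-sample read depth per locus
#'   (samples carrying template at that locus).
#' @slot unfedMammalFraction fraction of the mammal-locus depth that unfed
#'   mosquitoes still yield (environmental carry-over); their reads derive
#'   from human template but stay far below the 1000-read blood-meal floor.
#' @slot dispersion negative-binomial size parameter for the depth draw;
#'   \code{0} means exact (non-random) depths; larger values are tighter.
#' @slot errorRate per-base substitution error probability, in [0, 0.1].
#' @slot readLength read length in nt.
#' @slot contaminationRate fraction of each sample's reads leaked into a
#'   random extraction control (flat index mis-assignment model).
#' @slot seed integer seed; identical (truth, panel, config) give
#'   byte-identical FASTQ output.
#' @exportClass RunConfig
setClass("RunConfig",
  slots = c(depth = "numeric", unfedMammalFraction = "numeric",
            dispersion = "numeric", errorRate = "numeric",
            readLength = "integer", contaminationRate = "numeric",
            seed = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (any(object@depth < 0)) msg <- c(msg, "depths must be non-negative")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msg <- c(msg, "errorRate must lie in [0, 0.1]")
  if (object@contaminationRate < 0 || object@contaminationRate > 1)
    msg <- c(msg, "contaminationRate must lie in [0, 1]")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' UniqueSeqTable: unique merged sequences by sample, for one locus
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding the
#' dereplicated amplicon table of one locus: rows are unique merged
#' sequences (the sequence itself in \code{rowData()$sequence}), columns are
#' samples, and the \code{counts} assay records how often each sequence was
#' observed in each sample.
#'
#' @exportClass UniqueSeqTable
setClass("UniqueSeqTable", contains = "SummarizedExperiment")

setValidity("UniqueSeqTable", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
  sq <- SummarizedExperiment::rowData(object)$sequence
  if (is.null(sq)) msg <- c(msg, "rowData must carry a 'sequence' column")
  else if (anyDuplicated(sq)) msg <- c(msg, "duplicate row sequences")
  if (is.null(S4Vectors::metadata(object)$locus))
    msg <- c(msg, "metadata must name the locus")
  if (length(msg)) msg else TRUE
})

#' AsvTable: bacterial community table with sample metadata
#'
#' A \linkS4class{UniqueSeqTable} specialised for the bacterial 16S stream:
#' rows are ASVs (exact unique sequences after abundance filtering), with
#' optional rank-delimited taxonomy in \code{rowData()$taxonomy}, and the
#' sample metadata used by the community statistics (site, species, kdr
#' genotype, blood-meal and infection status) in \code{colData()}.
#'
#' @exportClass AsvTable
setClass("AsvTable", contains = "UniqueSeqTable")

#' PermanovaResult: sequential distance-based variance partition
#'
#' @slot table data.frame with one row per factor plus a residual row:
#'   \code{Df}, \code{SumOfSqs}, \code{R2}, \code{F}, \code{Pr} (permutation
#'   p-value, NA for the residual and for degenerate terms).
#' @slot ssTotal total sum of squared dissimilarity, \code{tr(G)}.
#' @slot nPerm number of permutations used.
#' @slot seed seed of the permutation stream.
#' @slot factorOrder the sequential (Type I) term order.
#' @exportClass PermanovaResult
setClass("PermanovaResult",
  slots = c(table = "data.frame", ssTotal = "numeric", nPerm = "integer",
            seed = "integer", factorOrder = "character"))

setValidity("PermanovaResult", function(object) {
  tab <- object@table
  need <- c("Df", "SumOfSqs", "R2", "F", "Pr")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (abs(sum(tab$SumOfSqs) - object@ssTotal) >
      1e-9 * max(1, abs(object@ssTotal)))
    return("factor + residual sums of squares must add to ssTotal")
  TRUE
})

#' RoutedRun: demultiplexed and merged reads of one sequencing run
#'
#' @slot sequences data.frame of routed, merged (or read-1-only) amplicon
#'   sequences aggregated by identity: columns \code{sample_id},
#'   \code{locus}, \code{sequence}, \code{disposition}
#'   (\code{merged}/\code{unmerged-kept}), \code{n}.
#' @slot summary data.frame of read-pair disposition tallies (one row per
#'   disposition, columns \code{disposition}, \code{n}); tallies sum to
#'   \code{nPairs}.
#' @slot nPairs number of input read pairs.
#' @exportClass RoutedRun
setClass("RoutedRun",
  slots = c(sequences = "data.frame", summary = "data.frame",
            nPairs = "integer"))

setValidity("RoutedRun", function(object) {
  if (sum(object@summary$n) != object@nPairs)
    return("disposition tallies must sum to the input pair count")
  TRUE
})
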