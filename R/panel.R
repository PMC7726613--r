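#' Build the multiplexed amplicon panel
#'
#' Assembles a \linkS4class{PanelDesign} from a primer table, per-locus
#' reference FASTA files and a freshly generated set of sample barcodes.
#' With the default arguments the packaged synthetic reference panel is
#' used: six loci named for the screening targets (bacterial 16S rRNA,
#' S200X6.1, cox1, kdr, mammalian 16S rRNA, parasite/virus markers), a kdr
#' reference carrying both the resistant (L1014F) and wild-type alleles,
#' S200X6.1 references for four Anopheles species (An. nili deliberately
#' absent, mirroring its failure to amplify at that locus), cox1 references
#' for all five species, mammalian blood-meal hosts, parasite/virus markers
#' and 60 bacterial ASVs with taxonomy.
#'
#' @param referenceFastas named character vector of FASTA paths, one per
#'   locus (names must match the primer table loci). \code{NULL} uses the
#'   packaged synthetic references.
#' @param primerFile TSV with columns \code{locus}, \code{forward},
#'   \code{reverse}, \code{expected_len}. \code{NULL} uses the packaged
#'   panel.
#' @param nBarcodes number of sample barcodes to generate (>= 1).
#' @param barcodeLength barcode length in nt.
#' @param sampleIds optional sample ids (length \code{nBarcodes}); default
#'   \code{mosq_001} ...
#' @param seed seed for barcode generation; the same seed yields the same
#'   barcode set.
#' @return A validated \linkS4class{PanelDesign}.
#' @examples
#' panel <- buildPanel(nBarcodes = 8)
#' panel
#' @export
buildPanel <- function(referenceFastas = NULL, primerFile = NULL,
                       nBarcodes = 96L, barcodeLength = 8L,
                       sampleIds = NULL, seed = 1L) {
  stopIfNot(nBarcodes >= 1L, "nBarcodes must be >= 1")
  if (is.null(primerFile))
    primerFile <- system.file("extdata", "synthetic_panel_primers.tsv",
                              package = "AmpliScreen", mustWork = TRUE)
  loci <- utils::read.delim(primerFile, stringsAsFactors = FALSE)
  if (is.null(referenceFastas)) {
    files <- c(bact16S = "synthetic_16s_asvs.fasta",
               S200X6.1 = "synthetic_s200_species.fasta",
               cox1 = "synthetic_cox1_species.fasta",
               kdr = "synthetic_kdr_alleles.fasta",
               mamm16S = "synthetic_mammal16s.fasta",
               parasite = "synthetic_parasite_virus.fasta")
    referenceFastas <- vapply(files, function(f)
      system.file("extdata", f, package = "AmpliScreen", mustWork = TRUE),
      character(1))
  }
  stopIfNot(!is.null(names(referenceFastas)) &&
              all(names(referenceFastas) %in% loci$locus),
            "referenceFastas must be named by panel loci")
  refDb <- list(); refInfo <- list()
  for (loc in names(referenceFastas)) {
    ss <- Biostrings::readDNAStringSet(referenceFastas[[loc]])
    stopIfNot(length(ss) >= 1L, "empty reference FASTA for locus ", loc)
    attrs <- parseFastaAttrs(names(ss))
    names(ss) <- names(attrs)
    keys <- unique(unlist(lapply(attrs, names)))
    info <- data.frame(name = names(attrs), stringsAsFactors = FALSE)
    for (k in keys)
      info[[k]] <- vapply(attrs, function(a) a[k] %||% NA_character_,
                          character(1))
    refDb[[loc]] <- ss
    refInfo[[loc]] <- info
  }
  barcodes <- makeBarcodes(nBarcodes, barcodeLength, seed)
  if (is.null(sampleIds))
    sampleIds <- sprintf("mosq_%03d", seq_len(nBarcodes))
  stopIfNot(length(sampleIds) == nBarcodes && !anyDuplicated(sampleIds),
            "sampleIds must be ", nBarcodes, " unique ids")
  names(barcodes) <- sampleIds
  new("PanelDesign", loci = loci, barcodes = barcodes,
      referenceDb = refDb, referenceInfo = refInfo)
}

## draw unique fixed-length barcodes; errors out when the alphabet is
## exhausted instead of looping forever
makeBarcodes <- function(n, len, seed) {
  stopIfNot(n <= 4^len / 2,
            "cannot generate ", n, " unique barcodes of length ", len,
            ": alphabet exhausted")
  set.seed(seed)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    out <- unique(c(out, randomDNA(n, len)))
    tries <- tries + 1L
    if (tries > 100L)
      stop("barcode generation failed to find ", n, " unique barcodes")
  }
  out[seq_len(n)]
}

## insert (primer-free) reference sequences for a locus
referenceInserts <- function(panel, locus) {
  i <- match(locus, panelLoci(panel)$locus)
  stopIfNot(!is.na(i), "unknown locus: ", locus)
  refs <- referenceDb(panel)[[locus]]
  stopIfNot(!is.null(refs), "no references for locus: ", locus)
  fwd <- panelLoci(panel)$forward[i]
  rev <- panelLoci(panel)$reverse[i]
  ins <- substr(as.character(refs), nchar(fwd) + 1L,
                Biostrings::width(refs) - nchar(rev))
  stats::setNames(ins, names(refs))
}

primerFor <- function(panel, locus) {
  i <- match(locus, panelLoci(panel)$locus)
  stopIfNot(!is.na(i), "unknown locus: ", locus)
  list(forward = panelLoci(panel)$forward[i],
       reverse = panelLoci(panel)$reverse[i],
       expected_len = panelLoci(panel)$expected_len[i])
}

#' Default per-sample read-depth floors per locus
#'
#' The screening thresholds: bacterial 16S samples need at least 5000 reads
#' to enter the microbiota analysis, and kdr, species (S200X6.1/cox1) and
#' blood-meal calls need at least 1000 reads. The parasite/virus stream has
#' no per-sample floor (only the global rare-sequence filter applies).
#'
#' @param locus a panel locus name.
#' @return The integer read floor for that locus.
#' @export
depthThreshold <- function(locus) {
  thresholds <- c(bact16S = 5000L, kdr = 1000L, S200X6.1 = 1000L,
                  cox1 = 1000L, mamm16S = 1000L)
  if (!locus %in% names(thresholds))
    stop("no per-sample depth threshold is defined for locus '", locus, "'")
  thresholds[[locus]]
}
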