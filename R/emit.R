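#' Sequencing-run configuration
#'
#' Constructor for \linkS4class{RunConfig}. Default per-locus depths follow
#' the per-mosquito averages of the assay this pipeline models (16S 11730,
#' kdr 2436, S200X6.1 2917, cox1 1181, parasite 1876 reads; the blood-meal
#' locus average is not published and defaults to 3000 for fed mosquitoes).
#'
#' @param depth named numeric vector of mean reads per sample per locus.
#' @param unfedMammalFraction fraction of the mammal-locus depth emitted for
#'   unfed mosquitoes (environmental human carry-over, well under the
#'   1000-read blood-meal floor).
#' @param dispersion negative-binomial size of the depth draw; 0 = exact.
#' @param errorRate per-base substitution error rate in [0, 0.1].
#' @param readLength read length in nt.
#' @param contaminationRate fraction of a sample's reads leaked into a
#'   random extraction control.
#' @param seed integer seed.
#' @return A validated \linkS4class{RunConfig}.
#' @export
runConfig <- function(depth = c(bact16S = 11730, kdr = 2436,
                                S200X6.1 = 2917, cox1 = 1181,
                                mamm16S = 3000, parasite = 1876),
                      unfedMammalFraction = 0.02, dispersion = 10,
                      errorRate = 0.001, readLength = 250L,
                      contaminationRate = 0.0005, seed = 1L) {
  new("RunConfig", depth = depth, unfedMammalFraction = unfedMammalFraction,
      dispersion = dispersion, errorRate = errorRate,
      readLength = as.integer(readLength),
      contaminationRate = contaminationRate, seed = as.integer(seed))
}

## per-sample template pool (named proportions over reference amplicons)
templatePool <- function(truthRow, comp, locus, refs) {
  sp <- truthRow$species
  switch(locus,
    bact16S = {
      w <- comp[comp > 0]
      if (!length(w)) return(NULL)
      w / sum(w)
    },
    kdr = switch(truthRow$kdr_genotype,
      RR = c(kdr_L1014F = 1), SS = c(kdr_L1014L = 1),
      RS = c(kdr_L1014F = 0.5, kdr_L1014L = 0.5), NULL),
    S200X6.1 = {
      if (sp == "" || sp == "Anopheles_nili") return(NULL)
      if (sp == HYBRID_LABEL)
        c(Anopheles_gambiae = 0.5, Anopheles_coluzzii = 0.5)
      else stats::setNames(1, sp)
    },
    cox1 = {
      if (sp == "") return(NULL)
      if (sp == HYBRID_LABEL) c(Anopheles_gambiae = 1)
      else stats::setNames(1, sp)
    },
    mamm16S = {
      bm <- parseBloodMeal(truthRow$blood_meal)
      if (length(bm)) bm else c(Homo_sapiens = 1)  # unfed carry-over
    },
    parasite = {
      if (truthRow$infections == "") return(NULL)
      tx <- strsplit(truthRow$infections, ";", fixed = TRUE)[[1]]
      stats::setNames(rep(1 / length(tx), length(tx)), tx)
    },
    stop("no template model for locus '", locus, "'"))
}

#' Emit a simulated multiplexed sequencing run
#'
#' Writes paired-end FASTQ for a simulated cohort: each read pair carries
#' the sample barcode and forward primer at the start of read 1 and the
#' reverse primer at the start of read 2 (reads are the two ends of the
#' barcoded amplicon, so in-range amplicons overlap well beyond the merge
#' minimum). Substitution errors are applied at the configured rate, and a
#' configurable fraction of each sample's reads is re-assigned to a random
#' extraction control, emulating cross-contamination / index mis-assignment.
#' Ground-truth tables and a manifest are written alongside.
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @param panel a \linkS4class{PanelDesign} whose barcodes cover every truth
#'   sample id.
#' @param config a \linkS4class{RunConfig}.
#' @param outDir output directory (created if needed).
#' @param gzip write gzip-compressed FASTQ.
#' @return Invisibly, a named list of written file paths.
#' @export
emitRun <- function(truth, panel, config, outDir, gzip = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  st <- truthTable(truth)
  bc <- panelBarcodes(panel)
  missing <- setdiff(st$sample_id, names(bc))
  stopIfNot(length(missing) == 0L,
            "truth samples missing from panel barcodes: ",
            paste(utils::head(missing, 5), collapse = ", "))
  loci <- panelLoci(panel)
  bcLen <- nchar(bc[[1]])
  stopIfNot(config@readLength > bcLen + max(nchar(loci$forward)),
            "read length must exceed barcode + primer length")
  set.seed(config@seed)

  comp <- communityTruth(truth)
  ctrlIds <- st$sample_id[st$is_control]
  recSample <- character(0); recTemplate <- character(0)
  recLocus <- character(0); recCount <- integer(0)

  for (i in seq_len(nrow(st))) {
    if (st$is_control[i]) next
    sid <- st$sample_id[i]
    for (loc in loci$locus) {
      mu <- if (loc %in% names(config@depth)) config@depth[[loc]] else 0
      if (mu <= 0) next
      pool <- templatePool(st[i, ], comp[, sid], loc,
                           referenceDb(panel)[[loc]])
      if (is.null(pool)) next
      if (loc == "mamm16S" && st$blood_meal[i] == "")
        mu <- mu * config@unfedMammalFraction
      n <- if (config@dispersion == 0) as.integer(round(mu))
           else rnbinom(1L, mu = mu, size = config@dispersion)
      if (n <= 0L) next
      cnt <- rmultinom(1L, n, pool)[, 1]
      keep <- cnt > 0L
      if (!any(keep)) next
      recSample <- c(recSample, rep(sid, sum(keep)))
      recTemplate <- c(recTemplate, names(pool)[keep])
      recLocus <- c(recLocus, rep(loc, sum(keep)))
      recCount <- c(recCount, cnt[keep])
    }
  }

  ## leak a fraction of each record's reads into random controls
  if (length(ctrlIds) && config@contaminationRate > 0 && length(recCount)) {
    leak <- rbinom(length(recCount), recCount, config@contaminationRate)
    has <- leak > 0L
    if (any(has)) {
      recCount[has] <- recCount[has] - leak[has]
      dest <- lapply(which(has), function(j) {
        tab <- table(sample(ctrlIds, leak[j], replace = TRUE))
        data.frame(sample_id = names(tab), template = recTemplate[j],
                   locus = recLocus[j], n = as.integer(tab))
      })
      dest <- do.call(rbind, dest)
      recSample <- c(recSample, dest$sample_id)
      recTemplate <- c(recTemplate, dest$template)
      recLocus <- c(recLocus, dest$locus)
      recCount <- c(recCount, dest$n)
    }
    drop <- recCount <= 0L
    if (any(drop)) {
      recSample <- recSample[!drop]; recTemplate <- recTemplate[!drop]
      recLocus <- recLocus[!drop]; recCount <- recCount[!drop]
    }
  }

  ## expand template records into read pairs
  ampOf <- function(loc, tmpl)
    as.character(referenceDb(panel)[[loc]][tmpl])
  amp <- vapply(seq_along(recCount),
                function(j) ampOf(recLocus[j], recTemplate[j]), character(1))
  r1t <- substr(paste0(bc[recSample], amp), 1L, config@readLength)
  r2t <- substr(revComp(amp), 1L, config@readLength)
  r1 <- rep(r1t, recCount)
  r2 <- rep(r2t, recCount)
  nReads <- length(r1)
  if (nReads > 0L) {
    ord <- sample.int(nReads)
    r1 <- .add_errors_cpp(r1[ord], config@errorRate)
    r2 <- .add_errors_cpp(r2[ord], config@errorRate)
  }
  ids <- sprintf("sim_%07d", seq_len(max(nReads, 0L)))

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list(
    fastq1 = file.path(outDir, paste0("run_R1", ext)),
    fastq2 = file.path(outDir, paste0("run_R2", ext)),
    samples = file.path(outDir, "truth_samples.tsv"),
    community = file.path(outDir, "truth_community.tsv"),
    barcodes = file.path(outDir, "barcodes.tsv"),
    manifest = file.path(outDir, "manifest.tsv"))
  writeFastq(ids, r1, strrep("I", nchar(r1)), paths$fastq1)
  writeFastq(ids, r2, strrep("I", nchar(r2)), paths$fastq2)
  write.table(st, paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(asv = rownames(comp), comp, check.names = FALSE),
              paths$community, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(bc), barcode = unname(bc)),
              paths$barcodes, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    key = c("fastq1", "fastq2", "truth_samples", "truth_community",
            "barcodes", "n_read_pairs", "seed"),
    value = c(basename(paths$fastq1), basename(paths$fastq2),
              basename(paths$samples), basename(paths$community),
              basename(paths$barcodes), nReads, config@seed))
  write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
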