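#' Read and validate a flat key=value pipeline configuration
#'
#' Unknown keys are rejected, thresholds must be non-negative, and any
#' referenced input path must exist. Values are returned with defaults
#' filled in.
#'
#' @param path configuration file (\code{key = value} per line, \code{#}
#'   comments), or \code{NULL} for all defaults.
#' @param overrides named list applied on top of the file.
#' @return A named list of configuration values.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    output_dir = "ampliscreen_out", seed = 1L,
    simulate = TRUE, n_samples = 96L, n_sites = 6L, site_effect_size = 0.2,
    n_controls = 95L,
    depth_bact16S = 11730, depth_kdr = 2436, depth_S200X6.1 = 2917,
    depth_cox1 = 1181, depth_mamm16S = 3000, depth_parasite = 1876,
    dispersion = 10, error_rate = 0.001, read_length = 250L,
    contamination_rate = 5e-04,
    fastq1 = "", fastq2 = "", metadata_file = "",
    min_overlap = 12L, max_mismatch_frac = 0.25, min_len = 90L,
    min_total = 10L, min_depth_16s = 5000L, min_reads_call = 1000L,
    ratio_lower = 0.15, ratio_upper = 0.35, min_identity = 70,
    n_perm = 999L, tree_file = "",
    factor_order = "site,species,kdr_genotype,fed,infected")
  cfg <- defaults
  if (!is.null(path)) {
    stopIfNot(file.exists(path), "config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      stopIfNot(length(kv) == 2L, "malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      stopIfNot(key %in% names(defaults), "unknown config key: ", key)
      cfg[[key]] <- if (is.numeric(defaults[[key]])) as.numeric(val)
                    else if (is.logical(defaults[[key]]))
                      toupper(val) %in% c("TRUE", "1", "YES")
                    else val
    }
  }
  for (key in names(overrides)) {
    stopIfNot(key %in% names(defaults), "unknown config key: ", key)
    cfg[[key]] <- overrides[[key]]
  }
  num <- c("n_samples", "n_sites", "n_controls", "min_overlap", "min_len",
           "min_total", "min_depth_16s", "min_reads_call", "n_perm",
           "read_length", "seed", "error_rate", "contamination_rate",
           grep("^depth_", names(cfg), value = TRUE))
  for (key in num)
    stopIfNot(cfg[[key]] >= 0, "config value must be non-negative: ", key)
  for (key in c("fastq1", "fastq2", "metadata_file", "tree_file"))
    if (nzchar(cfg[[key]]))
      stopIfNot(file.exists(cfg[[key]]), "missing input path for ", key,
                ": ", cfg[[key]])
  if (!cfg$simulate)
    stopIfNot(nzchar(cfg$fastq1) && nzchar(cfg$fastq2),
              "fastq1/fastq2 are required when simulate = FALSE")
  cfg
}

runDepths <- function(cfg) {
  keys <- grep("^depth_", names(cfg), value = TRUE)
  stats::setNames(vapply(keys, function(k) as.numeric(cfg[[k]]), numeric(1)),
                  sub("^depth_", "", keys))
}

#' Simulate a run from a pipeline configuration
#'
#' Builds the panel, draws the cohort truth and emits the FASTQ + truth
#' bundle with a manifest, as the \code{simulate} stage of
#' \code{\link{runPipeline}} does.
#'
#' @param cfg a configuration list from \code{\link{readPipelineConfig}}.
#' @return List with \code{panel}, \code{truth} and the emitted \code{paths}.
#' @export
simulateRun <- function(cfg = readPipelineConfig()) {
  truth <- simulateCohort(cfg$n_samples, nSites = cfg$n_sites,
                          siteEffectSize = cfg$site_effect_size,
                          nControls = cfg$n_controls, seed = cfg$seed)
  ids <- truthTable(truth)$sample_id
  panel <- buildPanel(nBarcodes = length(ids), sampleIds = ids,
                      seed = cfg$seed)
  config <- runConfig(depth = runDepths(cfg), dispersion = cfg$dispersion,
                      errorRate = cfg$error_rate,
                      readLength = as.integer(cfg$read_length),
                      contaminationRate = cfg$contamination_rate,
                      seed = cfg$seed)
  paths <- emitRun(truth, panel, config, file.path(cfg$output_dir, "run"))
  list(panel = panel, truth = truth, paths = paths)
}

setSummary <- function(x) sort(unique(x))

## host / infection set concordance of calls against truth
concordance <- function(truth, kdrCalls, spCalls, bmCalls, detections) {
  st <- truthTable(truth)
  st <- st[!st$is_control, , drop = FALSE]
  ids <- st$sample_id
  kdrBy <- stats::setNames(kdrCalls$call, kdrCalls$sample_id)
  spBy <- stats::setNames(spCalls$species, spCalls$sample_id)
  genotype <- mean(kdrBy[ids] == st$kdr_genotype, na.rm = FALSE)
  species <- mean(spBy[ids] == st$species, na.rm = FALSE)
  bmOk <- vapply(seq_along(ids), function(i) {
    want <- names(parseBloodMeal(st$blood_meal[i]))
    rows <- bmCalls[bmCalls$sample_id == ids[i] & bmCalls$fed, , drop = FALSE]
    got <- rows$host[!is.na(rows$host)]
    setequal(setSummary(want), setSummary(got))
  }, logical(1))
  infOk <- vapply(seq_along(ids), function(i) {
    want <- if (st$infections[i] == "") character(0)
            else strsplit(st$infections[i], ";", fixed = TRUE)[[1]]
    got <- detections$species[detections$sample_id == ids[i]]
    setequal(setSummary(want), setSummary(got))
  }, logical(1))
  list(genotype = unname(genotype), species = unname(species),
       blood_meal = mean(bmOk), infections = mean(infOk))
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate (optional) -> demultiplex/merge -> dereplicate and
#' filter -> per-locus calls -> community statistics, writing every stage's
#' TSV outputs plus a consolidated JSON summary (per-stage read and sample
#' counts, calls per category, the PERMANOVA table, and concordance against
#' truth when the run was simulated).
#'
#' @param cfg a configuration list from \code{\link{readPipelineConfig}}
#'   (or a path to a configuration file).
#' @param panel optional pre-built \linkS4class{PanelDesign} (required when
#'   analysing external FASTQ, since it carries barcodes and references).
#' @return Invisibly, a list with the per-stage objects and the summary.
#' @export
runPipeline <- function(cfg = readPipelineConfig(), panel = NULL) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    message("[simulate] cohort of ", cfg$n_samples, " mosquitoes + ",
            cfg$n_controls, " controls")
    sim <- simulateRun(cfg)
    panel <- sim$panel; truth <- sim$truth
    fq1 <- sim$paths$fastq1; fq2 <- sim$paths$fastq2
  } else {
    stopIfNot(!is.null(panel), "a PanelDesign is required for external FASTQ")
    fq1 <- cfg$fastq1; fq2 <- cfg$fastq2
  }

  message("[demux] routing read pairs")
  routed <- demuxRun(fq1, fq2, panel, minOverlap = cfg$min_overlap,
                     maxMismatchFrac = cfg$max_mismatch_frac,
                     minLen = cfg$min_len)
  write.table(routed@summary,
              file.path(cfg$output_dir, "routing_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  message("[tables] dereplicating per locus")
  tables <- list()
  for (loc in panelLoci(panel)$locus) {
    tab <- filterRare(dereplicate(routed, loc), cfg$min_total)
    tables[[loc]] <- tab
    writeSeqTable(tab, file.path(cfg$output_dir,
                                 paste0("seqtable_", loc, ".tsv")))
  }

  message("[call] kdr, species, blood meal, infections")
  ctrlIds <- if (!is.null(truth))
    truthTable(truth)$sample_id[truthTable(truth)$is_control]
  else character(0)
  kdrCalls <- callKdr(tables$kdr, panel, minReads = cfg$min_reads_call,
                      lower = cfg$ratio_lower, upper = cfg$ratio_upper,
                      minIdentity = cfg$min_identity)
  spCalls <- callSpecies(tables$S200X6.1, tables$cox1, panel,
                         minReads = cfg$min_reads_call,
                         hetCutoff = cfg$ratio_upper,
                         minIdentity = cfg$min_identity)
  bmCalls <- callBloodMeal(tables$mamm16S, panel,
                           minReads = cfg$min_reads_call,
                           minIdentity = cfg$min_identity)
  detections <- flagContamination(
    detectInfections(tables$parasite, panel, controlIds = ctrlIds,
                     minIdentity = cfg$min_identity))
  for (nm in c("kdrCalls", "spCalls", "bmCalls", "detections")) {
    obj <- as.data.frame(get(nm))
    write.table(obj, file.path(cfg$output_dir, paste0(
      c(kdrCalls = "genotypes", spCalls = "species", bmCalls = "blood_meal",
        detections = "detections")[[nm]], ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ## drop control-sample calls from the per-mosquito summaries
  kdrCalls <- kdrCalls[!kdrCalls$sample_id %in% ctrlIds, ]
  spCalls <- spCalls[!spCalls$sample_id %in% ctrlIds, ]
  bmCalls <- bmCalls[!bmCalls$sample_id %in% ctrlIds, ]

  message("[community] 16S table, dissimilarities, ordination, PERMANOVA")
  metadata <- if (nzchar(cfg$metadata_file)) {
    utils::read.delim(cfg$metadata_file, stringsAsFactors = FALSE)
  } else {
    ## factor set of the variance partition, built from the calls (the
    ## study flow), site from truth when simulated
    md <- data.frame(sample_id = kdrCalls$sample_id,
                     kdr_genotype = kdrCalls$call, stringsAsFactors = FALSE)
    md$species <- spCalls$species[match(md$sample_id, spCalls$sample_id)]
    fedBy <- tapply(bmCalls$fed, bmCalls$sample_id, any)
    md$fed <- as.logical(fedBy[md$sample_id])
    md$fed[is.na(md$fed)] <- FALSE
    md$infected <- md$sample_id %in% detections$sample_id[!detections$control]
    if (!is.null(truth)) {
      tt <- truthTable(truth)
      md$site <- tt$site[match(md$sample_id, tt$sample_id)]
    }
    md
  }
  factors <- strsplit(cfg$factor_order, ",", fixed = TRUE)[[1]]
  community <- NULL
  asv <- tryCatch({
    tax <- assignTaxonomy16S(tables$bact16S, panel,
                             minIdentity = cfg$min_identity)
    buildAsvTable(tables$bact16S, metadata, minDepth = cfg$min_depth_16s,
                  taxonomy = tax)
  }, error = function(e) {
    message("[community] skipped: ", conditionMessage(e)); NULL
  })
  if (!is.null(asv)) {
    bray <- brayCurtis(asv)
    treeFile <- if (nzchar(cfg$tree_file)) cfg$tree_file
                else system.file("extdata", "synthetic_16s_tree.nwk",
                                 package = "AmpliScreen", mustWork = TRUE)
    wuf <- tryCatch(weightedUnifrac(renameToAsvRefs(asv, panel), treeFile),
                    error = function(e) NULL)
    ord <- pcoaOrdination(bray)
    pmv <- permanova(bray, as.data.frame(SummarizedExperiment::colData(asv)),
                     intersect(factors, names(SummarizedExperiment::colData(asv))),
                     nPerm = cfg$n_perm, seed = cfg$seed)
    dmat <- as.matrix(bray)
    write.table(data.frame(sample_id = rownames(dmat), dmat,
                           check.names = FALSE),
                file.path(cfg$output_dir, "bray_curtis.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(ord$points), ord$points,
                           check.names = FALSE),
                file.path(cfg$output_dir, "pcoa_coordinates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(axis_variance = ord$varExplained),
      file.path(cfg$output_dir, "pcoa_axes.json"), auto_unbox = TRUE,
      digits = NA)
    ptab <- permanovaTable(pmv)
    write.table(data.frame(Factor = rownames(ptab), ptab,
                           check.names = FALSE),
                file.path(cfg$output_dir, "permanova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    community <- list(asv = asv, bray = bray, unifrac = wuf, pcoa = ord,
                      permanova = pmv)
  }

  summary <- list(
    n_read_pairs = routed@nPairs,
    dispositions = stats::setNames(as.list(routed@summary$n),
                                   routed@summary$disposition),
    unique_sequences = lapply(tables, nrow),
    calls = list(
      kdr = as.list(table(kdrCalls$call)),
      species = as.list(table(spCalls$species)),
      blood_fed = sum(tapply(bmCalls$fed, bmCalls$sample_id, any)),
      detections = nrow(detections[!detections$control, ])),
    permanova = if (!is.null(community)) {
      ptab <- permanovaTable(community$permanova)
      lapply(stats::setNames(rownames(ptab), rownames(ptab)), function(r)
        list(Df = ptab[r, "Df"], R2 = ptab[r, "R2"], Pr = ptab[r, "Pr"]))
    })
  if (!is.null(truth))
    summary$concordance <- concordance(truth, kdrCalls, spCalls, bmCalls,
                                       detections)
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(config = cfg, panel = panel, truth = truth,
                 routed = routed, tables = tables, kdr = kdrCalls,
                 species = spCalls, bloodMeal = bmCalls,
                 detections = detections, community = community,
                 summary = summary))
}

## rows of a 16S table renamed to the packaged ASV ids they exactly match,
## for tree-based metrics (non-matching rows are dropped)
renameToAsvRefs <- function(x, panel) {
  ins <- referenceInserts(panel, "bact16S")
  hit <- match(SummarizedExperiment::rowData(x)$sequence, ins)
  keep <- !is.na(hit)
  out <- x[keep, ]
  rownames(out) <- names(ins)[hit[keep]]
  out
}
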