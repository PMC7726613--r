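#' Rank reference hits for a query sequence by global percent identity
#'
#' End-gap-free alignment of the full query against each reference
#' (\code{Biostrings::pairwiseAlignment}, type \code{"global-local"});
#' identity is matches over alignment length. Hits under \code{minIdentity}
#' (70 by default) are suppressed; exact ties are all returned.
#'
#' @param query a single sequence (character).
#' @param references named character vector or
#'   \link[Biostrings]{DNAStringSet} of reference sequences.
#' @param minIdentity minimum percent identity for a reported hit.
#' @return data.frame with columns \code{name}, \code{identity}, sorted by
#'   decreasing identity. Zero rows if nothing reaches the floor; queries
#'   shorter than 20 nt return zero rows with a \code{reason} attribute.
#' @examples
#' matchReference("ACGTACGTACGTACGTACGTACGT",
#'                c(ref = "ACGTACGTACGTACGTACGTACGT"))
#' @export
matchReference <- function(query, references, minIdentity = 70) {
  stopIfNot(length(references) > 0L, "reference set is empty")
  refs <- stats::setNames(as.character(references), names(references))
  stopIfNot(!is.null(names(refs)), "references must be named")
  empty <- data.frame(name = character(0), identity = numeric(0))
  if (is.na(query) || nchar(query) < 20L) {
    attr(empty, "reason") <- "query_too_short"
    return(empty)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  ident <- vapply(refs, function(r) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(r),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 2)
    Biostrings::pid(aln, type = "PID1")
  }, numeric(1))
  keep <- ident >= minIdentity
  if (!any(keep)) return(empty)
  out <- data.frame(name = names(refs)[keep], identity = unname(ident[keep]))
  out[order(-out$identity, out$name), , drop = FALSE]
}

## best-hit set (all exact ties at the top identity), or NULL
bestHits <- function(query, references, minIdentity = 70) {
  hits <- matchReference(query, references, minIdentity)
  if (!nrow(hits)) return(NULL)
  top <- hits$identity >= hits$identity[1] - 1e-9
  list(names = hits$name[top], identity = hits$identity[1])
}

## per-sample top-two rows of a count table (ties broken lexicographically
## by sequence; dereplicate() already orders rows that way globally, but the
## per-sample order is recomputed here)
topTwo <- function(counts, seqs, sample) {
  col <- counts[, sample]
  ord <- order(-col, seqs)
  ord <- ord[col[ord] > 0L]
  list(i1 = if (length(ord) >= 1L) ord[1] else NA_integer_,
       i2 = if (length(ord) >= 2L) ord[2] else NA_integer_)
}

#' Call kdr (L1014F) genotypes from the allele-ratio statistic
#'
#' For each sample the two most abundant unique sequences (Seq1, Seq2;
#' count ties broken lexicographically by sequence) define the ratio
#' Seq2/(Seq1+Seq2): near 0 for homozygotes (Seq2 is then sequencing
#' error), near 0.5 for heterozygotes. Ratios below \code{lower} call a
#' homozygote (RR if Seq1 best-matches the resistant L1014F reference
#' allele, SS otherwise), ratios above \code{upper} call a heterozygote
#' (RS), and the band between is left uncalled, as are samples under
#' \code{minReads} total reads. A sample with a single unique sequence has
#' ratio 0.
#'
#' @param x \linkS4class{UniqueSeqTable} for the kdr locus (rare sequences
#'   already filtered).
#' @param panel a \linkS4class{PanelDesign} carrying the kdr allele
#'   references.
#' @param minReads per-sample read floor (default 1000).
#' @param lower,upper the homozygous/heterozygous ratio cut-offs
#'   (defaults 0.15 and 0.35).
#' @param minIdentity reference-match identity floor.
#' @return \link[S4Vectors]{DataFrame} with one row per sample: allele
#'   sequences and counts, \code{ratio}, \code{total}, \code{call}
#'   (RR/SS/RS/NO_CALL) and \code{reason} for uncalled samples.
#' @export
callKdr <- function(x, panel, minReads = 1000L, lower = 0.15, upper = 0.35,
                    minIdentity = 70) {
  counts <- seqCounts(x)
  seqs <- SummarizedExperiment::rowData(x)$sequence
  refs <- referenceInserts(panel, "kdr")
  info <- referenceInfo(panel)$kdr
  resistantName <- info$name[info$resistant %in% "true"]
  res <- lapply(colnames(counts), function(sid) {
    tt <- topTwo(counts, seqs, sid)
    c1 <- if (!is.na(tt$i1)) counts[tt$i1, sid] else 0L
    c2 <- if (!is.na(tt$i2)) counts[tt$i2, sid] else 0L
    total <- sum(counts[, sid])
    ratio <- if (c1 + c2 > 0) c2 / (c1 + c2) else NA_real_
    call <- "NO_CALL"; reason <- ""
    if (total < minReads) {
      reason <- if (total == 0L) "no_reads" else "low_depth"
    } else if (is.na(ratio)) {
      reason <- "no_reads"
    } else if (ratio > upper) {
      call <- "RS"
    } else if (ratio < lower) {
      hit <- bestHits(seqs[tt$i1], refs, minIdentity)
      if (is.null(hit)) reason <- "no_reference_hit"
      else call <- if (any(hit$names %in% resistantName)) "RR" else "SS"
    } else {
      reason <- "ambiguous_ratio"
    }
    S4Vectors::DataFrame(
      sample_id = sid,
      seq1 = if (!is.na(tt$i1)) seqs[tt$i1] else NA_character_,
      seq2 = if (!is.na(tt$i2)) seqs[tt$i2] else NA_character_,
      count1 = c1, count2 = c2,
      ratio = if (is.na(ratio)) NA_real_ else ratio,
      total = total, call = call, reason = reason)
  })
  do.call(rbind, res)
}

#' Call Anopheles species from S200X6.1 with a cox1 fallback
#'
#' The most abundant S200X6.1 sequence of each sample with at least
#' \code{minReads} reads is matched against the species references. If the
#' top two sequences pass the heterozygosity ratio cut-off (the same 0.35
#' used for kdr) and map to different species, the sample is flagged as a
#' likely F1 hybrid and labelled with both species. Samples without an
#' S200X6.1 call but with at least \code{minReads} cox1 reads are called
#' from cox1 (this rescues An. nili, which the S200X6.1 primers fail to
#' amplify).
#'
#' @param s200,cox1 \linkS4class{UniqueSeqTable}s for the two loci.
#' @param panel a \linkS4class{PanelDesign}.
#' @param minReads per-sample read floor (default 1000).
#' @param hetCutoff top-two ratio above which two distinct species hits are
#'   reported as a hybrid.
#' @param minIdentity reference-match identity floor.
#' @return \link[S4Vectors]{DataFrame}: \code{sample_id}, \code{species},
#'   \code{evidence_locus}, \code{reads}, \code{hybrid}, \code{reason}.
#' @export
callSpecies <- function(s200, cox1, panel, minReads = 1000L,
                        hetCutoff = 0.35, minIdentity = 70) {
  refsS <- referenceInserts(panel, "S200X6.1")
  refsC <- referenceInserts(panel, "cox1")
  cntS <- seqCounts(s200); seqS <- SummarizedExperiment::rowData(s200)$sequence
  cntC <- seqCounts(cox1); seqC <- SummarizedExperiment::rowData(cox1)$sequence
  samples <- sort(unique(c(colnames(cntS), colnames(cntC))))
  res <- lapply(samples, function(sid) {
    totS <- if (sid %in% colnames(cntS)) sum(cntS[, sid]) else 0L
    totC <- if (sid %in% colnames(cntC)) sum(cntC[, sid]) else 0L
    species <- "NO_CALL"; locus <- NA_character_; hybrid <- FALSE
    reads <- 0L; reason <- ""
    if (totS >= minReads) {
      tt <- topTwo(cntS, seqS, sid)
      hit1 <- bestHits(seqS[tt$i1], refsS, minIdentity)
      if (is.null(hit1)) {
        reason <- "no_reference_hit"
      } else {
        species <- hit1$names[1]; locus <- "S200X6.1"; reads <- totS
        if (!is.na(tt$i2)) {
          c1 <- cntS[tt$i1, sid]; c2 <- cntS[tt$i2, sid]
          if (c2 / (c1 + c2) > hetCutoff) {
            hit2 <- bestHits(seqS[tt$i2], refsS, minIdentity)
            if (!is.null(hit2) && hit2$names[1] != hit1$names[1]) {
              hybrid <- TRUE
              species <- paste(sort(c(hit1$names[1], hit2$names[1])),
                               collapse = " x ")
            }
          }
        }
      }
    } else if (totC >= minReads) {
      tt <- topTwo(cntC, seqC, sid)
      hit <- bestHits(seqC[tt$i1], refsC, minIdentity)
      if (is.null(hit)) reason <- "no_reference_hit"
      else { species <- hit$names[1]; locus <- "cox1"; reads <- totC }
    } else {
      reason <- "low_depth"
    }
    S4Vectors::DataFrame(sample_id = sid, species = species,
                         evidence_locus = locus, reads = reads,
                         hybrid = hybrid, reason = reason)
  })
  do.call(rbind, res)
}

#' Call blood-meal composition from the mammalian 16S locus
#'
#' A mosquito is considered blood fed if its mammalian 16S locus yielded at
#' least \code{minReads} reads (1000 by default). For fed mosquitoes every
#' unique sequence is matched against the mammal references and read counts
#' are aggregated per host species; multi-host profiles are reported as
#' multiple rows.
#'
#' @param x \linkS4class{UniqueSeqTable} for the mammalian 16S locus.
#' @param panel a \linkS4class{PanelDesign}.
#' @param minReads blood-fed read floor (default 1000).
#' @param minIdentity reference-match identity floor.
#' @return \link[S4Vectors]{DataFrame} with one row per sample-host pair
#'   (or a single host-NA row for unfed samples): \code{sample_id},
#'   \code{fed}, \code{total_reads}, \code{host}, \code{reads}.
#' @export
callBloodMeal <- function(x, panel, minReads = 1000L, minIdentity = 70) {
  counts <- seqCounts(x)
  seqs <- SummarizedExperiment::rowData(x)$sequence
  refs <- referenceInserts(panel, "mamm16S")
  hitCache <- lapply(seqs, bestHits, references = refs,
                     minIdentity = minIdentity)
  res <- lapply(colnames(counts), function(sid) {
    total <- sum(counts[, sid])
    if (total < minReads)
      return(S4Vectors::DataFrame(sample_id = sid, fed = FALSE,
                                  total_reads = total, host = NA_character_,
                                  reads = NA_integer_))
    present <- which(counts[, sid] > 0L)
    host <- vapply(present, function(i) {
      h <- hitCache[[i]]
      if (is.null(h)) NA_character_ else paste(h$names, collapse = "/")
    }, character(1))
    ok <- !is.na(host)
    if (!any(ok))
      return(S4Vectors::DataFrame(sample_id = sid, fed = TRUE,
                                  total_reads = total, host = NA_character_,
                                  reads = NA_integer_))
    agg <- tapply(counts[present[ok], sid], host[ok], sum)
    agg <- sort(agg, decreasing = TRUE)
    S4Vectors::DataFrame(sample_id = sid, fed = TRUE, total_reads = total,
                         host = names(agg), reads = as.integer(agg))
  })
  do.call(rbind, res)
}

#' Detect eukaryotic parasites and viruses
#'
#' Matches every unique sequence of the parasite/virus stream against the
#' packaged marker references and reports, per sample and taxon group, the
#' best-hit species name(s) (exact identity ties joined with \code{"/"}),
#' the percent identity and the supporting read count. Extraction controls
#' are flagged. Apply \code{\link{filterRare}} first; no per-sample depth
#' floor applies to this stream.
#'
#' @param x \linkS4class{UniqueSeqTable} for the parasite/virus locus.
#' @param panel a \linkS4class{PanelDesign}.
#' @param controlIds sample ids of extraction controls.
#' @param minIdentity identity floor for a reported hit (default 70).
#' @return \link[S4Vectors]{DataFrame}: \code{sample_id}, \code{group},
#'   \code{species}, \code{identity}, \code{reads}, \code{control}.
#' @export
detectInfections <- function(x, panel, controlIds = character(0),
                             minIdentity = 70) {
  counts <- seqCounts(x)
  seqs <- SummarizedExperiment::rowData(x)$sequence
  refs <- referenceInserts(panel, "parasite")
  info <- referenceInfo(panel)$parasite
  groupOf <- stats::setNames(info$group, info$name)
  hitCache <- lapply(seqs, bestHits, references = refs,
                     minIdentity = minIdentity)
  rows <- list()
  for (sid in colnames(counts)) {
    present <- which(counts[, sid] > 0L)
    if (!length(present)) next
    recs <- lapply(present, function(i) {
      h <- hitCache[[i]]
      if (is.null(h)) return(NULL)
      data.frame(group = unname(groupOf[h$names[1]]),
                 species = paste(h$names, collapse = "/"),
                 identity = h$identity, reads = counts[i, sid])
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) next
    agg <- data.table::as.data.table(recs)[
      , .(identity = max(identity), reads = sum(reads)),
      by = .(group, species)]
    rows[[sid]] <- S4Vectors::DataFrame(
      sample_id = sid, group = agg$group, species = agg$species,
      identity = agg$identity, reads = as.integer(agg$reads),
      control = sid %in% controlIds)
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(sample_id = character(0),
                                group = character(0), species = character(0),
                                identity = numeric(0), reads = integer(0),
                                control = logical(0)))
  do.call(rbind, rows)
}

#' Annotate detections that resemble extraction-control contamination
#'
#' Any non-control detection whose read count falls below
#' \code{ratioThreshold} times the mean read count of control detections of
#' the same target is annotated as possible contamination. With no control
#' detections nothing is annotated.
#'
#' @param detections output of \code{\link{detectInfections}}.
#' @param ratioThreshold multiplier on the same-target control mean.
#' @return The input with a logical \code{possible_contamination} column.
#' @export
flagContamination <- function(detections, ratioThreshold = 2) {
  det <- detections
  det$possible_contamination <- FALSE
  ctrl <- det[det$control, , drop = FALSE]
  if (!nrow(ctrl)) return(det)
  ctrlMean <- tapply(ctrl$reads, ctrl$species, mean)
  idx <- which(!det$control & det$species %in% names(ctrlMean))
  if (length(idx)) {
    lim <- ratioThreshold * ctrlMean[det$species[idx]]
    det$possible_contamination[idx] <- det$reads[idx] < lim
  }
  det
}
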