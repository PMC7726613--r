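#' Assign taxonomy to 16S unique sequences from the packaged references
#'
#' Matches each unique sequence against the packaged 16S ASV references and
#' returns the rank-delimited taxonomy string of the best hit (empty when
#' nothing reaches the identity floor).
#'
#' @param x a \linkS4class{UniqueSeqTable} for locus \code{bact16S}.
#' @param panel a \linkS4class{PanelDesign}.
#' @param minIdentity identity floor (default 70).
#' @return Character vector of taxonomy strings, one per row of \code{x}.
#' @export
assignTaxonomy16S <- function(x, panel, minIdentity = 70) {
  refs <- referenceInserts(panel, "bact16S")
  info <- referenceInfo(panel)$bact16S
  taxOf <- stats::setNames(info$taxonomy, info$name)
  ## exact matches dominate (error-filtered unique sequences); fall back to
  ## alignment only for the rest
  seqs <- SummarizedExperiment::rowData(x)$sequence
  exact <- match(seqs, refs)
  vapply(seq_along(seqs), function(i) {
    if (!is.na(exact[i])) return(unname(taxOf[names(refs)[exact[i]]]))
    h <- bestHits(seqs[i], refs, minIdentity)
    if (is.null(h)) "" else unname(taxOf[h$names[1]])
  }, character(1))
}

#' Build the bacterial community table for the statistics layer
#'
#' Applies the microbiota sample floor (samples with fewer than
#' \code{minDepth} = 5000 reads are discarded as likely cross-contamination)
#' and joins the per-sample analysis metadata; optional taxonomy is stored
#' per ASV.
#'
#' @param x a \linkS4class{UniqueSeqTable} for locus \code{bact16S}, after
#'   \code{\link{filterRare}}.
#' @param metadata data.frame keyed by \code{sample_id} covering every
#'   retained sample (an error names any sample left uncovered).
#' @param minDepth microbiota read floor (default 5000).
#' @param taxonomy optional character vector of rank-delimited taxonomy
#'   strings, one per ASV row of \code{x}.
#' @return An \linkS4class{AsvTable}.
#' @export
buildAsvTable <- function(x, metadata, minDepth = 5000L, taxonomy = NULL) {
  flt <- sampleDepthFilter(x, threshold = minDepth)
  tab <- flt$table
  if (ncol(tab) == 0L)
    stop("no samples remain above the ", minDepth, "-read microbiota floor")
  tab <- tab[rowSums(seqCounts(tab)) > 0L, ]
  stopIfNot("sample_id" %in% names(metadata),
            "metadata must have a sample_id column")
  hit <- match(colnames(tab), metadata$sample_id)
  if (anyNA(hit))
    stop("metadata missing for retained sample(s): ",
         paste(colnames(tab)[is.na(hit)], collapse = ", "))
  md <- metadata[hit, setdiff(names(metadata), "sample_id"), drop = FALSE]
  SummarizedExperiment::colData(tab) <-
    S4Vectors::DataFrame(md, row.names = colnames(tab))
  if (!is.null(taxonomy)) {
    stopIfNot(length(taxonomy) == nrow(x),
              "taxonomy must have one entry per ASV row of x")
    keepRows <- match(rownames(tab), rownames(x))
    SummarizedExperiment::rowData(tab)$taxonomy <- taxonomy[keepRows]
  }
  new("AsvTable", tab)
}

#' Mean relative abundance per group at a taxonomic rank
#'
#' Per-sample proportions are aggregated at the requested rank, averaged
#' within each metadata group (collection site by default), and ranks whose
#' overall mean proportion falls below \code{aggregateBelow} are pooled
#' into a single low-abundance category.
#'
#' @param x an \linkS4class{AsvTable} with taxonomy.
#' @param rank taxonomic rank, one of kingdom, phylum, class, order,
#'   family, genus.
#' @param groupBy a \code{colData} column to average within (default
#'   \code{"site"}).
#' @param aggregateBelow pooling threshold on the overall mean proportion
#'   (default 0.01).
#' @return Matrix of mean proportions, rank categories x groups; columns
#'   sum to 1.
#' @export
relativeAbundance <- function(x, rank = "phylum", groupBy = "site",
                              aggregateBelow = 0.01) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  ri <- match(tolower(rank), ranks)
  if (is.na(ri)) stop("unknown rank '", rank, "'")
  tax <- SummarizedExperiment::rowData(x)$taxonomy
  stopIfNot(!is.null(tax), "taxonomy is not set on this table")
  lab <- vapply(strsplit(tax, ";", fixed = TRUE), function(p)
    if (length(p) >= ri && nzchar(p[ri])) p[ri] else "unclassified",
    character(1))
  cnt <- seqCounts(x)
  prop <- sweep(cnt, 2, colSums(cnt), "/")
  byRank <- rowsum(prop, lab)
  overall <- rowMeans(byRank)
  low <- overall < aggregateBelow
  if (any(low)) {
    pooled <- colSums(byRank[low, , drop = FALSE])
    byRank <- rbind(byRank[!low, , drop = FALSE], "<1% abund." = pooled)
  }
  grp <- SummarizedExperiment::colData(x)[[groupBy]]
  stopIfNot(!is.null(grp), "no '", groupBy, "' column in colData")
  groups <- unique(grp)
  out <- matrix(vapply(groups, function(g)
    rowMeans(byRank[, grp == g, drop = FALSE]), numeric(nrow(byRank))),
    nrow = nrow(byRank), dimnames = list(rownames(byRank), groups))
  out[order(-rowMeans(out)), , drop = FALSE]
}

asMatrixSamplesByTaxa <- function(x) {
  m <- if (is(x, "UniqueSeqTable")) t(seqCounts(x)) else as.matrix(x)
  stopIfNot(nrow(m) >= 2L, "need at least 2 samples")
  if (any(rowSums(m) == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  m
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{ij} = 1 - 2 \sum_k \min(x_{ik}, x_{jk}) / (\sum_k x_{ik} +
#' \sum_k x_{jk})}, computed on raw counts (via
#' \code{vegan::\link[vegan]{vegdist}}).
#'
#' @param x an \linkS4class{UniqueSeqTable}/\linkS4class{AsvTable} (columns
#'   = samples) or a samples-by-taxa count matrix.
#' @return A \code{\link[stats]{dist}} over samples, entries in [0, 1].
#' @export
brayCurtis <- function(x) {
  vegan::vegdist(asMatrixSamplesByTaxa(x), method = "bray")
}

#' Weighted UniFrac distance between samples
#'
#' Raw weighted UniFrac: the sum over tree branches of branch length times
#' the absolute difference in the proportion of each sample's reads
#' descending from that branch. With \code{normalized = TRUE} the sum is
#' divided by the same branch sum of \eqn{p_A + p_B}.
#'
#' @param x an \linkS4class{UniqueSeqTable}/\linkS4class{AsvTable} or a
#'   samples-by-taxa count matrix whose taxa are tree leaves.
#' @param tree an \code{ape::phylo} (or path to a newick file); every taxon
#'   must be a leaf (extra leaves are dropped).
#' @param normalized divide by the branch-weighted total proportion mass.
#' @return A \code{\link[stats]{dist}} over samples.
#' @export
weightedUnifrac <- function(x, tree, normalized = FALSE) {
  m <- asMatrixSamplesByTaxa(x)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, colnames(m))
  if (length(extra) && length(tree$tip.label) - length(extra) >= 2L)
    tree <- ape::drop.tip(tree, extra)
  nTip <- length(tree$tip.label)
  nSamp <- nrow(m)
  prop <- m / rowSums(m)                      # samples x taxa
  ## per-node descending proportion mass, by postorder accumulation
  nNode <- nTip + tree$Nnode
  P <- matrix(0, nNode, nSamp)
  P[seq_len(nTip), ] <- t(prop[, tree$tip.label, drop = FALSE])
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edge)))
    P[edge[e, 1L], ] <- P[edge[e, 1L], ] + P[edge[e, 2L], ]
  len <- tree$edge.length
  stopIfNot(!is.null(len) && all(len >= 0), "tree needs non-negative branch lengths")
  child <- tree$edge[, 2L]
  D <- matrix(0, nSamp, nSamp, dimnames = list(rownames(m), rownames(m)))
  N <- D
  for (i in seq_len(nSamp - 1L)) {
    pi <- P[child, i]
    for (j in (i + 1L):nSamp) {
      pj <- P[child, j]
      D[j, i] <- sum(len * abs(pi - pj))
      N[j, i] <- sum(len * (pi + pj))
    }
  }
  if (normalized) {
    nz <- N > 0
    D[nz] <- D[nz] / N[nz]
  }
  stats::as.dist(D)
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Gower double-centering of the squared dissimilarities followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues, and each axis explains
#' eigenvalue / sum(positive eigenvalues) of the variance. Negative
#' eigenvalues are dropped (no Cailliez/Lingoes correction by default).
#'
#' @param d a \code{\link[stats]{dist}} or symmetric matrix.
#' @param k maximum number of axes to return.
#' @return A list with \code{points} (samples x axes), \code{eig} (all
#'   eigenvalues) and \code{varExplained} (per returned axis).
#' @export
pcoaOrdination <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  stopIfNot(n >= 2L, "need at least 2 samples")
  if (is.null(k)) k <- n - 1L
  mds <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1L), eig = TRUE))
  eig <- mds$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)]
  pts <- mds$points
  if (length(pos) == 0L) {
    pts <- matrix(0, n, 1L, dimnames = list(attr(d, "Labels"), "Axis1"))
    return(list(points = pts, eig = eig, varExplained = 0))
  }
  nAxes <- min(ncol(pts), length(pos))
  pts <- pts[, seq_len(nAxes), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(nAxes))
  list(points = pts, eig = eig,
       varExplained = pos[seq_len(nAxes)] / sum(pos))
}
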