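## Gower-centred inner-product matrix G = -1/2 C D^2 C
gowerG <- function(d) {
  D <- as.matrix(stats::as.dist(d))
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A); gm <- mean(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
}

## hat matrix of a model matrix, via QR with a rank tolerance
hatMatrix <- function(X, tol = 1e-8) {
  qr_ <- qr(X, tol = tol)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Sequential distance-based PERMANOVA
#'
#' Partitions the total squared dissimilarity among an ordered list of
#' factors (sequential, Type I, as in vegan's \code{adonis2(by = "terms")}):
#' with Gower-centred \eqn{G} and cumulative-model hat matrices \eqn{H_k},
#' each term's sum of squares is \eqn{tr((H_k - H_{k-1}) G)}, its
#' \eqn{R^2} is that over \eqn{tr(G)}, and pseudo-F compares the term's
#' mean square to the residual mean square. Significance comes from
#' permuting samples (rows and columns of the dissimilarity jointly);
#' p-values use the add-one convention \eqn{(1 + \#\{F^* \ge F\}) /
#' (1 + nPerm)}, so 999 permutations give a floor of 0.001. Constant or
#' fully collinear terms get zero df and an NA p-value.
#'
#' @param d a \code{\link[stats]{dist}} or symmetric dissimilarity matrix.
#' @param metadata data.frame of factors, rows aligned with the samples of
#'   \code{d} (matched by \code{sample_id} column when present and
#'   \code{d} has labels, positionally otherwise).
#' @param factors character vector naming the metadata columns in model
#'   order.
#' @param nPerm number of permutations (default 999).
#' @param seed seed for the permutation stream.
#' @return A \linkS4class{PermanovaResult}.
#' @examples
#' md <- data.frame(g = rep(c("a", "b"), each = 3))
#' d <- stats::dist(c(1, 1.1, 0.9, 5, 5.2, 4.8))
#' permanova(d, md, "g", nPerm = 99)
#' @export
permanova <- function(d, metadata, factors, nPerm = 999L, seed = 1L) {
  D <- as.matrix(stats::as.dist(d))
  n <- nrow(D)
  if (!is.null(rownames(D)) && "sample_id" %in% names(metadata)) {
    hit <- match(rownames(D), metadata$sample_id)
    stopIfNot(!anyNA(hit), "metadata missing for samples: ",
              paste(rownames(D)[is.na(hit)], collapse = ", "))
    metadata <- metadata[hit, , drop = FALSE]
  }
  stopIfNot(nrow(metadata) == n, "metadata rows must match samples")
  stopIfNot(all(factors %in% names(metadata)),
            "unknown factor(s): ",
            paste(setdiff(factors, names(metadata)), collapse = ", "))
  miss <- factors[vapply(factors, function(f) anyNA(metadata[[f]]),
                         logical(1))]
  stopIfNot(length(miss) == 0L,
            "factor(s) undefined (NA) on some samples: ",
            paste(miss, collapse = ", "))

  G <- gowerG(D)
  ssTotal <- sum(diag(G))
  K <- length(factors)

  ## cumulative hat matrices and term projectors
  X <- matrix(1, n, 1L)
  Hprev <- hatMatrix(X)
  rankPrev <- 1L
  B <- vector("list", K)       # H_k - H_{k-1}
  df <- integer(K)
  for (k in seq_len(K)) {
    f <- factor(metadata[[factors[k]]])
    Xk <- if (nlevels(f) >= 2L) stats::model.matrix(~f)[, -1L, drop = FALSE]
          else NULL
    X <- cbind(X, Xk)
    qrX <- qr(X, tol = 1e-8)
    Hk <- hatMatrix(X)
    df[k] <- qrX$rank - rankPrev
    B[[k]] <- Hk - Hprev
    Hprev <- Hk; rankPrev <- qrX$rank
  }
  HK <- Hprev
  dfRes <- n - rankPrev
  stopIfNot(dfRes > 0L, "no residual degrees of freedom")

  ss <- vapply(B, function(b) sum(b * G), numeric(1))
  ssRes <- ssTotal - sum(ss)
  Fobs <- ifelse(df > 0L, (ss / df) / (ssRes / dfRes), NA_real_)

  pvals <- rep(NA_real_, K)
  if (nPerm > 0L && any(df > 0L)) {
    set.seed(seed)
    exceed <- numeric(K)
    for (p in seq_len(nPerm)) {
      perm <- sample.int(n)
      Gp <- G[perm, perm]
      ssP <- vapply(B, function(b) sum(b * Gp), numeric(1))
      ssResP <- ssTotal - sum(HK * Gp)
      Fp <- ifelse(df > 0L, (ssP / df) / (ssResP / dfRes), NA_real_)
      exceed <- exceed + as.numeric(!is.na(Fp) & Fp >= Fobs - 1e-12)
    }
    pvals[df > 0L] <- (1 + exceed[df > 0L]) / (1 + nPerm)
  }

  tab <- data.frame(
    Df = c(df, dfRes),
    SumOfSqs = c(ss, ssRes),
    R2 = c(ss, ssRes) / ssTotal,
    F = c(Fobs, NA_real_),
    Pr = c(pvals, NA_real_),
    row.names = c(factors, "Residual"))
  new("PermanovaResult", table = tab, ssTotal = ssTotal,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      factorOrder = factors)
}

#' Extract the PERMANOVA table as a data.frame
#' @param x a \linkS4class{PermanovaResult}.
#' @return The per-term data.frame (Df, SumOfSqs, R2, F, Pr).
#' @export
permanovaTable <- function(x) {
  stopIfNot(is(x, "PermanovaResult"), "not a PermanovaResult")
  x@table
}
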