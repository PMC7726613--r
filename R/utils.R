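#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rbinom rnbinom rnorm rmultinom runif approx quantile
#' @importFrom utils read.delim write.table
#' @import S4Vectors
NULL

DNA_BASES <- c("A", "C", "G", "T")

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

randomDNA <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

## substitute k random positions of a sequence with a different base
mutateSeq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Read a FASTQ file into sequences, qualities and ids
#'
#' Minimal four-line FASTQ reader used by the demultiplexer. Files may be
#' gzip-compressed (detected from the \code{.gz} extension).
#'
#' @param path path to a FASTQ file.
#' @return A list with character vectors \code{id}, \code{seq}, \code{qual}.
#' @export
readFastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) / 4L
  idx <- seq_len(n) * 4L
  list(id = sub("^@", "", lines[idx - 3L]),
       seq = toupper(lines[idx - 2L]),
       qual = lines[idx])
}

writeFastq <- function(id, seq, qual, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", id), seq, "+", qual)), con)
  invisible(path)
}

## parse "key=value" attributes from FASTA description lines
parseFastaAttrs <- function(headers) {
  name <- sub("\\s.*$", "", headers)
  attrs <- lapply(headers, function(h) {
    toks <- regmatches(h, gregexpr("[A-Za-z_0-9]+=[^ ]+", h))[[1]]
    if (!length(toks)) return(character(0))
    kv <- strsplit(toks, "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, character(1), 2L),
                    vapply(kv, `[`, character(1), 1L))
  })
  names(attrs) <- name
  attrs
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
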