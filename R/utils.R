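#' @useDynLib vdjplace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize setNames runif aggregate sd
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity -> compatible base indicator (row = code, col = ACGT)
iupac_matrix <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  m <- t(vapply(strsplit(unname(map), ""), function(b) as.numeric(BASES %in% b),
                numeric(4)))
  rownames(m) <- names(map)
  rbind(m, "-" = rep(1, 4), "." = rep(1, 4), "?" = rep(1, 4))
})

#' Reverse complement of a nucleotide string
#' @param x a single nucleotide string
#' @return the reverse complement, ambiguity codes included
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string
#'
#' Translation starts at the first position; trailing partial codons are
#' dropped. Codons containing ambiguity codes translate to `X`.
#' @param x nucleotide string
#' @return amino-acid string (stops as `*`)
#' @export
translate_nt <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1, n)), if.fuzzy.codon = "X")))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# base -> integer code: A=0 C=1 G=2 T=3, anything else (gap/ambiguity) = 4
nt_codes <- function(x) {
  i <- match(chars(toupper(x)), BASES)
  i[is.na(i)] <- 5L
  as.integer(i - 1L)
}

# 4 x n conditional-likelihood matrix for an observed (gapped) sequence
nt_partials <- function(x) {
  cc <- chars(toupper(x))
  idx <- match(cc, rownames(iupac_matrix))
  idx[is.na(idx)] <- match("N", rownames(iupac_matrix))
  t(iupac_matrix[idx, , drop = FALSE])
}

# read FASTA (or FASTQ; qualities ignored) from a file path, or FASTA from
# text (single string / character lines)
read_fasta <- function(x) {
  if (length(x) == 1 && !grepl("[>\n]", x) && file.exists(x)) {
    fmt <- if (startsWith(readLines(x, n = 1), "@")) "fastq" else "fasta"
    ss <- Biostrings::readBStringSet(x, format = fmt)
    nm <- if (fmt == "fastq") sub("\\s.*$", "", names(ss)) else names(ss)
    return(setNames(as.character(ss), nm))
  }
  lines <- if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  ss <- Biostrings::readBStringSet(tf)
  setNames(as.character(ss), names(ss))
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  out <- character(2 * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
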