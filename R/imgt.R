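#' Parse germline alleles from an IMGT-style reference FASTA
#'
#' Accepts the IMGT reference-directory dialect: pipe-delimited headers whose
#' second field is the allele name (e.g. `IGHV5-51*01`) and fourth field the
#' functionality class (`F`, `ORF` or `P`, possibly parenthesised), and `.`
#' gap characters inside sequences. Plain headers consisting of just an
#' allele name are also accepted (functionality defaults to `F`).
#'
#' Gap characters are stripped from the returned `sequence`; the original
#' gapped row (with `.` converted to `-`) is kept in `gapped` so that
#' pre-aligned reference sets survive parsing.
#'
#' @param x FASTA file path, FASTA text, or character vector of lines
#' @param region one of `"V"`, `"D"`, `"J"`
#' @param include_pseudogenes keep `P` records as well (default drops them,
#'   retaining only `F` and `ORF`)
#' @return data.frame with columns `name`, `gene`, `family`, `region`,
#'   `functionality`, `sequence` (ungapped) and `gapped`
#' @export
parse_imgt_fasta <- function(x, region = c("V", "D", "J"),
                             include_pseudogenes = FALSE) {
  region <- match.arg(region)
  seqs <- read_fasta(x)
  if (length(seqs) == 0) {
    return(data.frame(name = character(), gene = character(),
                      family = character(), region = character(),
                      functionality = character(), sequence = character(),
                      gapped = character(), stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_along(seqs), function(i) {
    fields <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) >= 4) {
      name <- fields[2]
      fun <- gsub("[()\\[\\] ]", "", fields[4])
    } else if (length(fields) == 1 && nzchar(fields[1])) {
      name <- fields[1]
      fun <- "F"
    } else {
      stop(sprintf("malformed FASTA header in record %d: '%s'",
                   i, names(seqs)[i]))
    }
    parsed <- tryCatch(parse_allele_name(name), error = function(e)
      stop(sprintf("record %d: %s", i, conditionMessage(e))))
    gapped <- gsub(".", "-", toupper(seqs[[i]]), fixed = TRUE)
    data.frame(name = name, gene = parsed$gene, family = parsed$family,
               region = region, functionality = fun,
               sequence = gsub("-", "", gapped, fixed = TRUE),
               gapped = gapped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  keep <- out$functionality %in% c("F", "ORF") |
    (include_pseudogenes & out$functionality == "P")
  out <- out[keep, , drop = FALSE]
  if (any(!nzchar(out$sequence)))
    stop("empty sequence for allele(s): ",
         paste(out$name[!nzchar(out$sequence)], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Parse an immunoglobulin allele name into its naming hierarchy
#'
#' `IGHV5-51*01` parses to family `IGHV5`, gene `IGHV5-51`, allele `01`.
#' D and J names are analogous (J genes usually carry no `-` part, e.g.
#' `IGHJ4*02` has family = gene = `IGHJ4`).
#'
#' @param name allele name string
#' @return list with `region` (e.g. `IGHV`), `family`, `gene`, `allele`
#' @export
parse_allele_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)([0-9][^*]*)\\*([0-9A-Za-z]+)$",
                                name))[[1]]
  if (length(m) == 0)
    stop(sprintf("unparseable allele name '%s'", name))
  region <- m[2]
  gene <- paste0(m[2], m[3])
  family <- sub("^([A-Za-z]+[0-9]+).*$", "\\1", gene)
  list(region = region, family = family, gene = gene, allele = m[4])
}

#' Remove duplicate germline alleles
#'
#' Alleles whose ungapped sequences are identical are collapsed to the
#' first-seen representative; dropped names are recorded in a synonym map so
#' that evaluation can count an assignment to either name as correct.
#'
#' @param alleles data.frame from [parse_imgt_fasta()]
#' @return list with `alleles` (deduplicated data.frame) and `synonyms`
#'   (named character vector, dropped name -> kept name)
#' @export
dedupe_alleles <- function(alleles) {
  first <- !duplicated(alleles$sequence)
  keeper <- alleles$name[first][match(alleles$sequence, alleles$sequence[first])]
  synonyms <- setNames(keeper[!first], alleles$name[!first])
  out <- alleles[first, , drop = FALSE]
  rownames(out) <- NULL
  list(alleles = out, synonyms = synonyms)
}

# resolve a name through the synonym map (identity if absent)
resolve_synonym <- function(name, synonyms) {
  hit <- match(name, names(synonyms))
  ifelse(is.na(hit), name, unname(synonyms[hit]))
}
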