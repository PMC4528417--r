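# D-allele assignment: affine-gap Smith-Waterman of the junction against
# the forward + inverted germline D dictionary.

#' Default D-assignment alignment scoring
#' @return list: match 5, mismatch -4, gap open 10, gap extend 1 (penalties
#'   positive); min score 15 corresponds to three matched codons
#' @export
default_d_scoring <- function() {
  list(match = 5, mismatch = -4, gap_open = 10, gap_extend = 1)
}

#' Affine-gap Smith-Waterman local alignment score
#'
#' Standard local alignment with affine gap penalties (a thin wrapper over
#' the Biostrings aligner). The score of the empty alignment is 0, so the
#' result is always non-negative.
#'
#' @param a,b nucleotide strings (non-empty)
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#' @param details return aligned substring coordinates as well
#' @return numeric score, or a list with `score` and 1-based `a_range` /
#'   `b_range` when `details = TRUE`
#' @export
sw_align <- function(a, b, scoring = default_d_scoring(), details = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("sw_align: empty input sequence")
  sm <- sub_matrix(scoring)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend)
  sc <- max(Biostrings::score(aln), 0)
  if (!details) return(sc)
  list(score = sc,
       a_range = c(Biostrings::start(Biostrings::pattern(aln)),
                   Biostrings::end(Biostrings::pattern(aln))),
       b_range = c(Biostrings::start(Biostrings::subject(aln)),
                   Biostrings::end(Biostrings::subject(aln))))
}

#' Assign D allele(s) to a junction
#'
#' Every forward and inverted dictionary entry is aligned locally to the
#' junction nucleotides; the argmax set is reported (all alleles tied at
#' the maximum score are equally likely). Below `min_score` no D is
#' assigned.
#'
#' @param junction_nt junction nucleotide string
#' @param d_dictionary data.frame with `name`, `orientation`, `sequence`
#'   (as in a bundle's `$d`)
#' @param scoring alignment parameters ([default_d_scoring()])
#' @param min_score minimum score to report an assignment
#' @return list: `alleles` (data.frame name/orientation/score, empty when
#'   nothing reaches `min_score`), `alignment` (junction coordinates of the
#'   best hit, 1-based)
#' @export
assign_d <- function(junction_nt, d_dictionary,
                     scoring = default_d_scoring(), min_score = 15) {
  stopifnot(nzchar(junction_nt))
  scores <- vapply(d_dictionary$sequence, function(s)
    sw_align(junction_nt, s, scoring), numeric(1), USE.NAMES = FALSE)
  mx <- max(scores)
  if (mx < min_score)
    return(list(alleles = data.frame(name = character(),
                                     orientation = character(),
                                     score = numeric()),
                alignment = NULL))
  tied <- which(scores == mx)
  tied <- tied[order(d_dictionary$name[tied], d_dictionary$orientation[tied])]
  best <- sw_align(junction_nt, d_dictionary$sequence[tied[1]], scoring,
                   details = TRUE)
  list(alleles = data.frame(name = d_dictionary$name[tied],
                            orientation = d_dictionary$orientation[tied],
                            score = scores[tied],
                            stringsAsFactors = FALSE),
       alignment = best$a_range)
}

# formatted tie list for TSV output, e.g. "IGHD3-10*01;IGHD3-3*02|inv"
format_d_call <- function(dcall) {
  if (nrow(dcall$alleles) == 0) return("")
  paste(ifelse(dcall$alleles$orientation == "inv",
               paste0(dcall$alleles$name, "|inv"), dcall$alleles$name),
        collapse = ";")
}
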