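# Homology mapping of query reads against V+J reference templates.
#
# Queries are aligned (affine-gap local alignment, both strands) against
# the MRCA(V)+MRCA(J) concatenation and every *01 V x *01 J concatenation;
# the best-scoring mapping fixes the query orientation, reading frame and
# the correspondence between query positions and reference alignment
# columns, through which FR/CDR boundaries and the junction are transferred.

default_map_scoring <- function() {
  list(match = 5, mismatch = -4, gap_open = 10, gap_extend = 1)
}

sub_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

# template table: MRCA(V)+MRCA(J) plus every *01 V x *01 J concatenation
mapping_templates <- function(bundle) {
  vmap <- function(gapped) ungapped_col_map(gapped)
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  tpls <- list()
  add <- function(name, vname, jname, vgapped, jgapped) {
    vseq <- degap(vgapped); jseq <- degap(jgapped)
    tpls[[name]] <<- list(name = name, vname = vname, jname = jname,
                          seq = paste0(vseq, jseq), vlen = nchar(vseq),
                          vcols = vmap(vgapped), jcols = vmap(jgapped))
  }
  add("MRCA", "MRCA", "MRCA", bundle$v$mrca, bundle$j$mrca)
  for (v in bundle$meta$primary_v)
    for (j in bundle$meta$primary_j)
      add(paste0(v, "|", j), v, j,
          bundle$v$alignment[[v]], bundle$j$alignment[[j]])
  tpls[order(names(tpls))]
}

# aligned (query, template) position pairs from a PairwiseAlignments object,
# 0-based, strictly increasing in both coordinates
alignment_pairs <- function(aln) {
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  s <- chars(as.character(Biostrings::alignedSubject(aln)))
  qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  ti <- Biostrings::start(Biostrings::subject(aln)) - 1L
  qpos <- integer(0); tpos <- integer(0)
  for (i in seq_along(p)) {
    pg <- p[i] == "-"; sg <- s[i] == "-"
    if (!pg && !sg) { qpos <- c(qpos, qi); tpos <- c(tpos, ti) }
    if (!pg) qi <- qi + 1L
    if (!sg) ti <- ti + 1L
  }
  data.frame(qpos = qpos, tpos = tpos)
}

#' Frame-aware affine-gap local alignment of a query to one template
#'
#' Both strands are tried; the better-scoring orientation is returned. The
#' reading frame is derived from the codon-aligned reference columns of the
#' matched template rather than estimated from the query.
#'
#' @param query nucleotide string (>= 30 nt for reliable mapping; shorter
#'   queries are flagged `too_short` but still aligned)
#' @param template a template entry (see [best_mapping()]) or a plain
#'   nucleotide string
#' @param bundle the `vdj_bundle` (needed for frame/column transfer when
#'   `template` is a template entry)
#' @param scoring match/mismatch/gap parameters
#' @return a pairwise map: `template_name`, `score`, `orientation`,
#'   `aligned_pairs` (0-based query/template coordinates), `frame_offset`
#' @export
codon_align_query <- function(query, template, bundle = NULL,
                              scoring = default_map_scoring()) {
  tpl <- if (is.character(template)) list(name = "template", seq = template,
                                          vlen = nchar(template),
                                          vcols = seq_len(nchar(template)) - 1L,
                                          jcols = integer(0),
                                          vname = NA, jname = NA)
         else template
  sm <- sub_matrix(scoring)
  orientations <- c(forward = query, `reverse-complement` = revcomp(query))
  alns <- lapply(orientations, function(q)
    Biostrings::pairwiseAlignment(Biostrings::DNAString(q),
                                  Biostrings::DNAString(tpl$seq),
                                  type = "local", substitutionMatrix = sm,
                                  gapOpening = scoring$gap_open,
                                  gapExtension = scoring$gap_extend))
  sc <- vapply(alns, Biostrings::score, numeric(1))
  ori <- names(orientations)[which.max(sc)]
  aln <- alns[[which.max(sc)]]
  pr <- alignment_pairs(aln)
  build_map(tpl, pr, ori, max(sc), orientations[[which.max(sc)]],
            bundle, too_short = nchar(query) < 30)
}

build_map <- function(tpl, pr, orientation, score, oriented_query, bundle,
                      too_short = FALSE) {
  region <- ifelse(pr$tpos < tpl$vlen, "V", "J")
  col <- integer(nrow(pr))
  col[region == "V"] <- tpl$vcols[pr$tpos[region == "V"] + 1L]
  col[region == "J"] <- tpl$jcols[pr$tpos[region == "J"] - tpl$vlen + 1L]
  pairs <- data.frame(qpos = pr$qpos, tpos = pr$tpos,
                      region = region, col = col,
                      stringsAsFactors = FALSE)
  frame <- NA_integer_
  vp <- pairs[pairs$region == "V", ]
  if (nrow(vp) > 0) {
    frame <- (vp$qpos[1] - vp$col[1] %% 3L) %% 3L
  } else if (nrow(pairs) > 0 && !is.null(bundle)) {
    trp <- bundle$j$trp_column
    jp <- pairs[pairs$region == "J", ]
    frame <- (jp$qpos[1] - (jp$col[1] - trp) %% 3L) %% 3L
  }
  structure(list(template_name = tpl$name, vname = tpl$vname,
                 jname = tpl$jname, score = score,
                 orientation = orientation, query_mapped = oriented_query,
                 pairs = pairs, frame_offset = as.integer(frame),
                 too_short = too_short),
            class = "pairwise_map")
}

# dinucleotide-preserving shuffle (random successor walk with retries;
# falls back to a plain permutation if no complete walk is found)
dinuc_shuffle <- function(seq) {
  cc <- chars(seq)
  n <- length(cc)
  if (n < 4) return(paste(sample(cc), collapse = ""))
  for (try in 1:20) {
    succ <- split(cc[-1], cc[-n])
    succ <- lapply(succ, sample)
    out <- character(n)
    out[1] <- cc[1]
    ok <- TRUE
    for (i in 2:n) {
      s <- succ[[out[i - 1]]]
      if (is.null(s) || length(s) == 0) { ok <- FALSE; break }
      out[i] <- s[1]
      succ[[out[i - 1]]] <- s[-1]
    }
    if (ok) return(paste(out, collapse = ""))
  }
  paste(sample(cc), collapse = "")
}

# mapping rejection floor: mean + 3 SD of best template scores of
# dinucleotide-shuffled copies of a sample query
mapping_floor <- function(bundle, sample_query, n_shuffle = 100,
                          scoring = default_map_scoring()) {
  prep <- get_prep(bundle)
  shufs <- vapply(seq_len(n_shuffle), function(i) dinuc_shuffle(sample_query),
                  character(1))
  sm <- sub_matrix(scoring)
  pat <- Biostrings::DNAStringSet(shufs)
  best <- rep(-Inf, n_shuffle)
  for (tpl in prep$templates) {
    sc <- Biostrings::pairwiseAlignment(pat, Biostrings::DNAString(tpl$seq),
                                        type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = scoring$gap_open,
                                        gapExtension = scoring$gap_extend,
                                        scoreOnly = TRUE)
    best <- pmax(best, sc)
  }
  mean(best) + 3 * stats::sd(best)
}

#' Map a query against all reference templates and keep the best
#'
#' Templates are the MRCA(V)+MRCA(J) concatenation and every *01 V x *01 J
#' concatenation; the mapping with the best homology score wins, ties
#' broken lexicographically by template name. Queries scoring below `floor`
#' are returned with `unmappable = TRUE`.
#'
#' @param query nucleotide string
#' @param bundle a `vdj_bundle`
#' @param scoring match/mismatch/gap parameters
#' @param floor optional rejection score floor (see [mapping_floor()])
#' @return a pairwise map as in [codon_align_query()], with template V/J
#'   names and an `unmappable` flag
#' @export
best_mapping <- function(query, bundle, scoring = default_map_scoring(),
                         floor = NULL) {
  prep <- get_prep(bundle)
  tpls <- prep$templates
  sm <- sub_matrix(scoring)
  qf <- Biostrings::DNAString(query)
  qr <- Biostrings::DNAString(revcomp(query))
  nt <- length(tpls)
  scores <- matrix(-Inf, nt, 2,
                   dimnames = list(names(tpls),
                                   c("forward", "reverse-complement")))
  for (i in seq_len(nt)) {
    subj <- Biostrings::DNAString(tpls[[i]]$seq)
    scores[i, 1] <- Biostrings::pairwiseAlignment(qf, subj, type = "local",
      substitutionMatrix = sm, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
    scores[i, 2] <- Biostrings::pairwiseAlignment(qr, subj, type = "local",
      substitutionMatrix = sm, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
  }
  best <- which(scores == max(scores), arr.ind = TRUE)
  best <- best[order(rownames(scores)[best[, 1]], best[, 2]), , drop = FALSE]
  ti <- best[1, 1]; oi <- best[1, 2]
  tpl <- tpls[[ti]]
  ori <- colnames(scores)[oi]
  oq <- if (ori == "forward") query else revcomp(query)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(oq),
                                       Biostrings::DNAString(tpl$seq),
                                       type = "local", substitutionMatrix = sm,
                                       gapOpening = scoring$gap_open,
                                       gapExtension = scoring$gap_extend)
  map <- build_map(tpl, alignment_pairs(aln), ori, max(scores), oq, bundle,
                   too_short = nchar(query) < 30)
  map$unmappable <- !is.null(floor) && map$score < floor
  map
}

#' Transfer FR/CDR region boundaries onto query coordinates
#'
#' Reference column intervals are pushed through the aligned pairs; regions
#' whose columns are not covered (e.g. truncated read edges) are reported
#' absent rather than raising an error.
#'
#' @param map a pairwise map from [best_mapping()]
#' @param bundle the `vdj_bundle`
#' @return a region map: list of 0-based half-open query intervals
#'   (`FR1`..`FR3`, `junction`, `Jregion`), `frame`, `productive`,
#'   `stop_codon_found`, junction details
#' @export
segment_regions <- function(map, bundle) {
  pairs <- map$pairs
  vp <- pairs[pairs$region == "V", ]
  regions <- list()
  for (rn in names(bundle$v$boundaries)) {
    iv <- bundle$v$boundaries[[rn]]
    hit <- vp$qpos[vp$col >= iv[1] & vp$col < iv[2]]
    regions[[rn]] <- if (length(hit) > 0) c(min(hit), max(hit) + 1L) else NULL
  }
  jp <- pairs[pairs$region == "J", ]
  if (nrow(jp) > 0) regions$Jregion <- c(min(jp$qpos), max(jp$qpos) + 1L)
  jn <- extract_junction(map, bundle)
  regions$junction <- jn$interval
  structure(list(regions = regions, frame = map$frame_offset,
                 productive = jn$productive,
                 stop_codon_found = jn$stop_codon_found,
                 junction = jn),
            class = "region_map")
}

#' Extract the junction / CDR3 from a mapped query
#'
#' The junction spans from the codon of the germline FW3 3' cysteine to the
#' start of the J region, defined by the first `[FW]G.G` amino-acid motif
#' in the J region or, when the motif is absent, the position preceding the
#' conserved tryptophan column of the J alignment. A rearrangement is
#' productive if an in-frame junction can be extracted and the mapped query
#' translation is free of stop codons.
#'
#' @param map a pairwise map from [best_mapping()]
#' @param bundle the `vdj_bundle`
#' @return list: `interval` (0-based half-open, or NULL), `nt`, `aa`,
#'   `cdr3_aa` (junction interior, Cys excluded), `cdr3_length`,
#'   `terminating_rule`, `productive`, `stop_codon_found`
#' @export
extract_junction <- function(map, bundle) {
  pairs <- map$pairs
  query <- map$query_mapped
  out <- list(interval = NULL, nt = "", aa = "", cdr3_aa = "",
              cdr3_length = NA_integer_, terminating_rule = NA_character_,
              productive = FALSE, stop_codon_found = FALSE)
  cys <- bundle$v$cys_column
  vp <- pairs[pairs$region == "V", ]
  jp <- pairs[pairs$region == "J", ]
  hit <- vp$qpos[vp$col == cys]
  if (length(hit) == 0) return(out)
  js <- hit[1]
  # stop codons over the mapped query, read in the mapping frame
  lo <- min(pairs$qpos); hi <- max(pairs$qpos)
  fr <- ((js - lo) %% 3 + lo) %% 3  # first codon start >= lo in js's frame
  start0 <- lo + (js - lo) %% 3
  aa_all <- translate_nt(substr(query, start0 + 1, hi + 1))
  out$stop_codon_found <- grepl("*", aa_all, fixed = TRUE)

  je <- NULL; rule <- NA_character_
  aa_j <- translate_nt(substr(query, js + 1, nchar(query)))
  if (nrow(jp) > 0) {
    jq0 <- min(jp$qpos)
    m <- gregexpr("[FW]G.G", aa_j)[[1]]
    if (m[1] != -1) {
      starts <- js + (as.integer(m) - 1L) * 3L
      okm <- starts[starts >= jq0 - 2L]
      if (length(okm) > 0) { je <- okm[1]; rule <- "J-motif" }
    }
    if (is.null(je)) {
      trp_hit <- jp$qpos[jp$col == bundle$j$trp_column]
      if (length(trp_hit) > 0) { je <- trp_hit[1]; rule <- "conserved-Trp-fallback" }
    }
  }
  if (is.null(je) || je <= js) return(out)
  nt <- substr(query, js + 1, je)
  aa <- translate_nt(nt)
  out$interval <- c(js, je)
  out$nt <- nt
  out$aa <- aa
  out$cdr3_aa <- if (nchar(aa) > 1) substr(aa, 2, nchar(aa)) else ""
  out$cdr3_length <- max(nchar(aa) - 1L, 0L)
  out$terminating_rule <- rule
  out$productive <- (je - js) %% 3 == 0 && !out$stop_codon_found
  out
}
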