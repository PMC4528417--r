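# V(D)J rearrangement and somatic-hypermutation simulator.
#
# Generates ground-truth repertoires: simple concatenations of *01 alleles,
# realistic rearrangements with exonuclease deletions and non-templated N
# additions, context-dependent hypermutation under a 5-mer
# mutability/substitution model, and clonal families.

#' Default rearrangement simulation parameters
#'
#' Deletion-length and N-length distributions are shipped as self-contained
#' synthetic stand-ins: truncated geometric laws whose means follow
#' published junction-structure statistics (around 2 nt trimmed from the V
#' 3' end, 4 nt from each D end and the J 5' end, and 7 nt of non-templated
#' addition per joint), with uniform N composition. Empirically inferred
#' tables in the same shape can be supplied instead via
#' [read_length_table()].
#'
#' @param max_del,max_n distribution supports (lengths 0..max)
#' @return `rearrangement_params` list: `del_v3`, `del_d5`, `del_d3`,
#'   `del_j5`, `n1_len`, `n2_len` (probability vectors over length 0..K),
#'   `n_comp` (ACGT frequencies), `cdr3_regex`, `j_motifs`
#' @export
rearrangement_params <- function(max_del = 10, max_n = 18) {
  geom_pmf <- function(mean, kmax) {
    p <- 1 / (1 + mean)
    x <- p * (1 - p)^(0:kmax)
    x / sum(x)
  }
  structure(list(del_v3 = geom_pmf(2, max_del),
                 del_d5 = geom_pmf(4, max_del),
                 del_d3 = geom_pmf(4, max_del),
                 del_j5 = geom_pmf(4, max_del),
                 n1_len = geom_pmf(7, max_n),
                 n2_len = geom_pmf(7, max_n),
                 n_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 cdr3_regex = "C[A-Z]{2,32}W",
                 j_motifs = c("[FW]G.G", "TVSS")),
            class = "rearrangement_params")
}

validate_params <- function(params) {
  for (nm in c("del_v3", "del_d5", "del_d3", "del_j5", "n1_len", "n2_len")) {
    p <- params[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("malformed distribution '", nm, "': must be non-negative and sum to 1")
  }
  if (abs(sum(params$n_comp) - 1) > 1e-9)
    stop("malformed N composition: must sum to 1")
  invisible(params)
}

#' Read a length distribution or 5-mer table from TSV
#'
#' Two schemas are understood: length tables with columns `length` and
#' `probability`, and 5-mer tables with columns `fivemer`, `mutability`
#' and optionally `A`, `C`, `G`, `T` substitution probabilities.
#'
#' @param path TSV file
#' @return a probability vector (length tables, index 1 = length 0) or a
#'   list with `mutability` and `substitution` (5-mer tables)
#' @export
read_length_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("length", "probability") %in% names(tab))) {
    v <- numeric(max(tab$length) + 1)
    v[tab$length + 1] <- tab$probability
    if (abs(sum(v) - 1) > 1e-9) stop("length table does not sum to 1: ", path)
    return(v)
  }
  if (all(c("fivemer", "mutability") %in% names(tab))) {
    mut <- setNames(tab$mutability, toupper(tab$fivemer))
    sub <- NULL
    if (all(BASES %in% names(tab))) {
      sub <- as.matrix(tab[, BASES])
      rownames(sub) <- toupper(tab$fivemer)
      bad <- abs(rowSums(sub) - 1) > 1e-9
      if (any(bad)) stop("substitution rows do not sum to 1: ", path)
    }
    return(list(mutability = mut, substitution = sub))
  }
  stop("unrecognised table schema in ", path)
}

#' 5-mer hypermutation model
#'
#' @param mutability named non-negative vector over 5-mers (missing 5-mers
#'   have mutability 0); default: all 1024 5-mers equally mutable
#' @param substitution matrix (rows = 5-mers, cols = ACGT) of replacement
#'   probabilities; the centre base must have probability 0; default:
#'   uniform over the three alternative bases
#' @return `s5f_model` list
#' @export
s5f_model <- function(mutability = NULL, substitution = NULL) {
  all5 <- apply(expand.grid(BASES, BASES, BASES, BASES, BASES)[, 5:1], 1,
                paste, collapse = "")
  if (is.null(mutability)) mutability <- setNames(rep(1, length(all5)), all5)
  if (is.null(substitution)) {
    substitution <- matrix(1 / 3, length(all5), 4,
                           dimnames = list(all5, BASES))
    centre <- substr(all5, 3, 3)
    substitution[cbind(seq_along(all5), match(centre, BASES))] <- 0
  }
  bad <- abs(rowSums(substitution) - 1) > 1e-9
  if (any(bad)) stop("substitution rows must sum to 1")
  structure(list(mutability = mutability, substitution = substitution),
            class = "s5f_model")
}

# mutability weights for all positions of a sequence (vectorised over the
# string); first/last two positions are 0
fivemer_weights <- function(seq, model) {
  n <- nchar(seq)
  w <- numeric(n)
  if (n >= 5) {
    idx <- 3:(n - 2)
    fm <- substring(seq, idx - 2, idx + 2)
    wi <- unname(model$mutability[fm])
    wi[is.na(wi)] <- 0
    w[idx] <- wi
  }
  w
}

#' Context-dependent hypermutation
#'
#' Introduces exactly `n_mut` substitutions. Positions are drawn with
#' 5-mer mutability weights, recomputed after every mutation so that
#' contexts update (only the five positions around a hit need refreshing);
#' the first and last two positions are never mutated, and a mutated site
#' is not revisited, so the Hamming distance to the input is exactly
#' `n_mut`. Replacement bases follow the 5-mer's substitution row.
#'
#' @param sequence nucleotide string
#' @param n_mut number of substitutions
#' @param model an [s5f_model()]
#' @return mutated sequence (same length)
#' @export
s5f_mutate <- function(sequence, n_mut, model = s5f_model()) {
  if (n_mut == 0) return(sequence)
  seq <- sequence
  n <- nchar(seq)
  if (n_mut >= n - 4)
    stop("n_mut exceeds the number of mutable positions")
  w <- fivemer_weights(seq, model)
  hit <- logical(n)
  for (m in seq_len(n_mut)) {
    if (sum(w) <= 0) stop("all-zero mutability; cannot place mutation")
    pos <- sample.int(n, 1, prob = w)
    fm <- substring(seq, pos - 2, pos + 2)
    old <- substring(seq, pos, pos)
    probs <- model$substitution[fm, ]
    probs[match(old, BASES)] <- 0
    if (sum(probs) <= 0) probs <- as.numeric(BASES != old)
    substr(seq, pos, pos) <- sample(BASES, 1, prob = probs)
    hit[pos] <- TRUE
    upd <- max(3, pos - 2):min(n - 2, pos + 2)
    fmu <- substring(seq, upd - 2, upd + 2)
    wu <- unname(model$mutability[fmu])
    wu[is.na(wu)] <- 0
    w[upd] <- wu
    w[hit] <- 0
  }
  seq
}

truth_record <- function(read_id, v, d, j, del = c(0, 0, 0, 0),
                         n1 = "", n2 = "", n_mutations = 0,
                         clone_id = NA_character_) {
  data.frame(read_id = read_id, v = v, d = d, j = j,
             del_v3 = del[1], del_d5 = del[2], del_d3 = del[3],
             del_j5 = del[4], n1 = n1, n2 = n2,
             n_mutations = n_mutations, clone_id = clone_id,
             stringsAsFactors = FALSE)
}

#' Simple rearrangements: all *01 V x D x J concatenations
#'
#' Pure concatenation of germline sequences: no deletions, no N regions,
#' no mutations, no retention filters.
#'
#' @param bundle a `vdj_bundle`
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame)
#' @export
simulate_simple <- function(bundle) {
  vs <- bundle$meta$primary_v
  ds <- unique(bundle$d$name[bundle$d$orientation == "fwd"])
  ds <- grep("\\*01$", ds, value = TRUE)
  js <- bundle$meta$primary_j
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  dseq <- setNames(bundle$d$sequence[bundle$d$orientation == "fwd"],
                   bundle$d$name[bundle$d$orientation == "fwd"])
  grid <- expand.grid(v = vs, d = ds, j = js, stringsAsFactors = FALSE)
  reads <- vapply(seq_len(nrow(grid)), function(i)
    paste0(degap(bundle$v$alignment[[grid$v[i]]]), dseq[[grid$d[i]]],
           degap(bundle$j$alignment[[grid$j[i]]])), character(1))
  ids <- sprintf("simple%05d", seq_len(nrow(grid)))
  names(reads) <- ids
  truth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    truth_record(ids[i], grid$v[i], grid$d[i], grid$j[i])))
  list(reads = reads, truth = truth)
}

# allele sampling weights: inverse of the number of alleles per gene, so
# genes are equiprobable regardless of allelic richness
inverse_gene_weights <- function(names) {
  genes <- vapply(names, function(n) parse_allele_name(n)$gene, character(1))
  1 / table(genes)[genes]
}

passes_filters <- function(seq, params) {
  aa <- translate_nt(seq)
  if (grepl("*", aa, fixed = TRUE)) return(FALSE)         # (i) stop-free
  if (!grepl(params$cdr3_regex, aa)) return(FALSE)        # (ii) CDR3 regex
  all(vapply(params$j_motifs, grepl, logical(1), x = aa)) # (iii) J motifs
}

#' Simulate one realistic rearrangement
#'
#' Samples alleles with inverse-alleles-per-gene weights, draws deletion
#' and N lengths independently from the parameter distributions, assembles
#' trimmed-V + N1 + trimmed-D + N2 + trimmed-J, and applies the three
#' retention filters (stop-free translation, recognisable CDR3, in-frame J
#' with the conserved motifs). Rejected draws are redrawn up to
#' `max_attempts`.
#'
#' @param bundle a `vdj_bundle`
#' @param params a [rearrangement_params()]
#' @param max_attempts rejection-sampling cap
#' @return list with `sequence`, `truth` (one-row data.frame) and
#'   `attempts`, or NULL if every draw was rejected
#' @export
simulate_rearrangement <- function(bundle, params = rearrangement_params(),
                                   max_attempts = 200) {
  validate_params(params)
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  vseqs <- vapply(bundle$v$alignment, degap, character(1))
  jseqs <- vapply(bundle$j$alignment, degap, character(1))
  dfwd <- bundle$d$orientation == "fwd"
  dseqs <- setNames(bundle$d$sequence[dfwd], bundle$d$name[dfwd])
  wv <- inverse_gene_weights(names(vseqs))
  wd <- inverse_gene_weights(names(dseqs))
  wj <- inverse_gene_weights(names(jseqs))
  draw_len <- function(p) sample.int(length(p), 1, prob = p) - 1L
  draw_n <- function(len) if (len == 0) "" else
    paste(sample(BASES, len, replace = TRUE, prob = params$n_comp),
          collapse = "")
  for (att in seq_len(max_attempts)) {
    v <- sample(names(vseqs), 1, prob = wv)
    d <- sample(names(dseqs), 1, prob = wd)
    j <- sample(names(jseqs), 1, prob = wj)
    del <- c(draw_len(params$del_v3), draw_len(params$del_d5),
             draw_len(params$del_d3), draw_len(params$del_j5))
    vs <- vseqs[[v]]; dsq <- dseqs[[d]]; jsq <- jseqs[[j]]
    if (del[1] >= nchar(vs) || del[2] + del[3] >= nchar(dsq) ||
        del[4] >= nchar(jsq)) next
    n1 <- draw_n(draw_len(params$n1_len))
    n2 <- draw_n(draw_len(params$n2_len))
    seq <- paste0(substr(vs, 1, nchar(vs) - del[1]), n1,
                  substr(dsq, del[2] + 1, nchar(dsq) - del[3]), n2,
                  substr(jsq, del[4] + 1, nchar(jsq)))
    if (passes_filters(seq, params))
      return(list(sequence = seq,
                  truth = truth_record("sim", v, d, j, del, n1, n2),
                  attempts = att))
  }
  NULL
}

#' Simulate a repertoire of realistic rearrangements
#'
#' @param bundle a `vdj_bundle`
#' @param n number of reads
#' @param params a [rearrangement_params()]
#' @param n_mut mutations added per read (0 = unmutated)
#' @param model an [s5f_model()] for `n_mut > 0`
#' @param seed RNG seed (fully deterministic given it)
#' @return list with `reads` and `truth` as in [simulate_simple()]
#' @export
simulate_repertoire <- function(bundle, n, params = rearrangement_params(),
                                n_mut = 0, model = s5f_model(), seed = 1) {
  with_seed(seed, {
    reads <- character(n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      sim <- simulate_rearrangement(bundle, params)
      if (is.null(sim)) stop("simulator failed to produce an accepted read")
      sq <- sim$sequence
      if (n_mut > 0) sq <- s5f_mutate(sq, n_mut, model)
      reads[i] <- sq
      tr <- sim$truth
      tr$read_id <- sprintf("sim%05d", i)
      tr$n_mutations <- n_mut
      truth[[i]] <- tr
    }
    names(reads) <- sprintf("sim%05d", seq_len(n))
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

#' Simulate clonal families
#'
#' Each clone is one accepted unmutated rearrangement, replicated
#' `clone_size` times with independent mutations per member.
#'
#' @param bundle a `vdj_bundle`
#' @param n_clones,clone_size family count and size
#' @param n_mut mutations per member
#' @param params,model simulator parameters
#' @param seed RNG seed
#' @return list with `reads`, `truth` (including `clone_id`)
#' @export
simulate_clones <- function(bundle, n_clones = 100, clone_size = 100,
                            n_mut = 40, params = rearrangement_params(),
                            model = s5f_model(), seed = 1) {
  with_seed(seed, {
    reads <- character(0); truth <- list()
    for (cl in seq_len(n_clones)) {
      sim <- simulate_rearrangement(bundle, params)
      if (is.null(sim)) stop("simulator failed to produce an accepted clone seed")
      cid <- sprintf("clone%03d", cl)
      for (m in seq_len(clone_size)) {
        sq <- if (n_mut > 0) s5f_mutate(sim$sequence, n_mut, model)
              else sim$sequence
        id <- sprintf("%s_%03d", cid, m)
        reads[id] <- sq
        tr <- sim$truth
        tr$read_id <- id; tr$n_mutations <- n_mut; tr$clone_id <- cid
        truth[[length(truth) + 1]] <- tr
      }
    }
    list(reads = reads, truth = do.call(rbind, truth))
  })
}
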