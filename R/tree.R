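# most fully resolved label level shared by a set of allele names:
# allele > gene > family > region
shared_label <- function(names) {
  parsed <- lapply(names, parse_allele_name)
  if (length(unique(names)) == 1) return(names[1])
  genes <- unique(vapply(parsed, `[[`, "", "gene"))
  if (length(genes) == 1) return(genes)
  fams <- unique(vapply(parsed, `[[`, "", "family"))
  if (length(fams) == 1) return(fams)
  regs <- unique(vapply(parsed, `[[`, "", "region"))
  if (length(regs) == 1) return(regs)
  "mixed"
}

#' Label internal nodes of a germline reference tree
#'
#' Applies two rules, children before parents. Rule 1: a node with a child
#' whose branch length is (numerically) zero inherits that child's label,
#' the phylogenetic justification being that a zero-length branch implies an
#' identical sequence at both ends. Rule 2: otherwise the node receives the
#' most fully resolved level of the naming hierarchy (allele > gene >
#' family > region) shared by all of its descendant tips.
#'
#' Labels are recomputed from tip labels alone, so relabelling an already
#' labelled tree is a no-op.
#'
#' @param tree rooted `phylo` whose tip labels are parseable allele names
#' @param tol branch lengths at or below `tol` count as zero
#' @return the tree with `node.label` filled in
#' @export
label_internal_nodes <- function(tree, tol = 1e-9) {
  ntip <- length(tree$tip.label)
  bad <- vapply(tree$tip.label, function(l)
    inherits(try(parse_allele_name(l), silent = TRUE), "try-error"), logical(1))
  if (any(bad))
    stop("unparseable tip label(s): ",
         paste(tree$tip.label[bad], collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  labels <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  desc <- c(as.list(tree$tip.label), vector("list", tree$Nnode))
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (parent in unique(po$edge[, 1])) {
    rows <- kids[[as.character(parent)]]
    ch <- po$edge[rows, 2]
    desc[[parent]] <- unlist(desc[ch])
    zero <- ch[po$edge.length[rows] <= tol]
    if (length(zero) > 0) {
      cand <- sort(labels[zero])
      labels[parent] <- cand[1]
    } else {
      labels[parent] <- shared_label(desc[[parent]])
    }
  }
  tree$node.label <- labels[(ntip + 1):(ntip + tree$Nnode)]
  tree
}

#' Build a reference topology by neighbour joining on ML distances
#'
#' Fallback used when no externally computed tree is supplied: BioNJ on
#' pairwise ML distances under the supplied model, rooted so that as many
#' families as possible form monophyletic clades (ties broken by the longest
#' root branch), falling back to midpoint rooting.
#'
#' @param alignment named character vector of gapped sequences
#' @param model a [gtr_model()] used for the pairwise distances
#' @return rooted `phylo`
#' @export
build_reference_tree <- function(alignment, model = gtr_model()) {
  n <- length(alignment)
  stopifnot(n >= 3)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- ml_distance(alignment[[i]], alignment[[j]], model)
  tr <- ape::bionj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  root_for_families(tr)
}

# root an unrooted tree to make families monophyletic where possible
root_for_families <- function(tree) {
  fams <- vapply(tree$tip.label,
                 function(l) parse_allele_name(l)$family, character(1))
  famsets <- split(tree$tip.label, fams)
  famsets <- famsets[lengths(famsets) > 1]
  score <- function(tr) sum(vapply(famsets, function(tips)
    ape::is.monophyletic(tr, tips), logical(1)))
  ntip <- length(tree$tip.label)
  cands <- if (is.null(tree$edge.length)) list()
           else list(suppressWarnings(phangorn::midpoint(tree)))
  for (r in seq_len(nrow(tree$edge))) {
    child <- tree$edge[r, 2]
    tips <- if (child <= ntip) tree$tip.label[child]
            else ape::extract.clade(tree, child)$tip.label
    if (length(tips) %in% c(0, ntip)) next
    rt <- try(suppressWarnings(
      ape::root(tree, outgroup = tips, resolve.root = TRUE)), silent = TRUE)
    if (!inherits(rt, "try-error")) cands <- c(cands, list(rt))
  }
  scores <- vapply(cands, score, numeric(1))
  best <- cands[scores == max(scores)]
  rootlen <- vapply(best, function(tr) {
    ntp <- length(tr$tip.label)
    root <- ntp + 1
    max(c(tr$edge.length[tr$edge[, 1] == root], 0))
  }, numeric(1))
  best[[which.max(rootlen)]]
}
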