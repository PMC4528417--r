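#' Build the classifier reference bundle
#'
#' Assembles everything per-query classification needs: deduplicated,
#' pre-aligned V and J reference alignments, rooted trees with fitted GTR
#' model and branch lengths, internal-node labels, joint-ML ancestral
#' sequences (including the V and J MRCAs used as mapping templates), and
#' the D dictionary with forward and reverse-complement entries.
#'
#' Reference alignments are ingested, not computed: every region's FASTA
#' must already contain equal-length rows (IMGT-style `.` gaps are
#' understood). Trees may be supplied as newick (text or file); otherwise a
#' BioNJ topology on pairwise ML distances is built and branch lengths are
#' re-optimised either way.
#'
#' @param v_fasta,j_fasta,d_fasta FASTA paths or texts per region
#' @param config list; recognised entries: `v_boundaries` (named list of
#'   FR1/CDR1/FR2/CDR2/FR3 0-based half-open column intervals, required),
#'   `v_cys_column` (0-based start column of the FW3 3' Cys codon; default
#'   last FR3 codon), `j_trp_column` (0-based column of the conserved Trp
#'   codon; auto-detected from the `[FW]G.G` motif if absent), `provenance`
#'   (free-text reference release string)
#' @param v_tree,j_tree optional newick strings/files with the reference
#'   topologies
#' @param include_pseudogenes retain `P` records (default `FALSE`, i.e. the
#'   F+ORF functionality filter)
#' @return object of class `vdj_bundle`
#' @export
build_bundle <- function(v_fasta, j_fasta, d_fasta, config = list(),
                         v_tree = NULL, j_tree = NULL,
                         include_pseudogenes = FALSE) {
  if (is.null(config$v_boundaries))
    stop("config$v_boundaries (FR/CDR column intervals) is required")
  v <- build_region(v_fasta, "V", v_tree, include_pseudogenes)
  j <- build_region(j_fasta, "J", j_tree, include_pseudogenes)
  if (nchar(v$alignment[[1]]) %% 3 != 0)
    stop("V alignment length must be divisible by 3 (codon alignment)")
  v$boundaries <- lapply(config$v_boundaries, as.integer)
  v$cys_column <- as.integer(config$v_cys_column %||%
                               (v$boundaries$FR3[2] - 3L))
  j$trp_column <- as.integer(config$j_trp_column %||%
                               detect_trp_column(j$alignment))

  dal <- parse_imgt_fasta(d_fasta, "D", include_pseudogenes)
  if (nrow(dal) == 0) stop("empty D reference")
  d <- data.frame(
    name = c(dal$name, dal$name),
    orientation = rep(c("fwd", "inv"), each = nrow(dal)),
    sequence = c(dal$sequence, vapply(dal$sequence, revcomp, character(1))),
    stringsAsFactors = FALSE)

  bundle <- structure(list(
    v = v, j = j, d = d,
    meta = list(provenance = config$provenance %||% "unspecified",
                config = config,
                primary_v = grep("\\*01$", names(v$alignment), value = TRUE),
                primary_j = grep("\\*01$", names(j$alignment), value = TRUE))),
    class = "vdj_bundle")
  bundle
}

build_region <- function(fasta, region, tree_in, include_pseudogenes) {
  alleles <- parse_imgt_fasta(fasta, region, include_pseudogenes)
  if (nrow(alleles) < 3) stop("need at least 3 ", region, " reference alleles")
  dd <- dedupe_alleles(alleles)
  alleles <- dd$alleles
  widths <- nchar(alleles$gapped)
  if (length(unique(widths)) != 1)
    stop(region, " reference is not aligned (row lengths ",
         paste(unique(widths), collapse = ", "),
         "); supply a pre-aligned FASTA")
  alignment <- setNames(alleles$gapped, alleles$name)

  if (!is.null(tree_in)) {
    tree <- if (inherits(tree_in, "phylo")) tree_in
            else if (length(tree_in) == 1 && file.exists(tree_in))
              ape::read.tree(tree_in)
            else ape::read.tree(text = tree_in)
    drop <- setdiff(tree$tip.label, names(alignment))
    if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
    missing <- setdiff(names(alignment), tree$tip.label)
    if (length(missing) > 0)
      stop(region, " tree/alignment mismatch; alignment rows missing from ",
           "tree: ", paste(missing, collapse = ", "))
    if (!ape::is.rooted(tree)) tree <- root_for_families(tree)
  } else {
    tree <- build_reference_tree(alignment)
  }
  fit <- fit_reference_model(alignment, tree)
  tree <- label_internal_nodes(fit$tree)
  anc <- reconstruct_ancestors(tree, alignment, fit$model)
  list(alignment = alignment, synonyms = dd$synonyms,
       alleles = alleles[, c("name", "gene", "family", "functionality")],
       tree = tree, model = list(rates = fit$model$rates, bf = fit$model$bf),
       logLik = fit$logLik, ancestors = anc$sequences, mrca = anc$mrca,
       root_node = anc$root_node)
}

# conserved Trp column of the J alignment: start column (0-based) of the
# first codon where the majority translation matches [FW]G.G
detect_trp_column <- function(alignment) {
  aa <- vapply(alignment, function(s)
    translate_nt(gsub("-", "N", s, fixed = TRUE)), character(1))
  hits <- vapply(aa, function(p) {
    m <- regexpr("[FW]G.G", p)
    as.integer(m)
  }, integer(1))
  hits <- hits[hits > 0]
  if (length(hits) == 0)
    stop("could not locate the conserved [FW]G.G motif in the J alignment; ",
         "supply config$j_trp_column")
  pos <- as.integer(names(sort(table(hits), decreasing = TRUE))[1])
  (pos - 1L) * 3L
}

#' @export
print.vdj_bundle <- function(x, ...) {
  cat("V(D)J classifier bundle\n")
  cat(sprintf("  V: %d alleles (%d synonyms), tree with %d internal nodes\n",
              length(x$v$alignment), length(x$v$synonyms), x$v$tree$Nnode))
  cat(sprintf("  J: %d alleles (%d synonyms)\n",
              length(x$j$alignment), length(x$j$synonyms)))
  cat(sprintf("  D: %d entries (forward + inverted)\n", nrow(x$d)))
  cat(sprintf("  provenance: %s\n", x$meta$provenance))
  invisible(x)
}

phylo_to_list <- function(tree) {
  list(tip_labels = tree$tip.label,
       node_labels = tree$node.label %||% character(),
       edge = unname(as.matrix(tree$edge)),
       edge_length = tree$edge.length)
}

phylo_from_list <- function(x) {
  edge <- matrix(as.integer(unlist(x$edge)), ncol = 2,
                 byrow = is.list(x$edge))
  tr <- structure(list(edge = edge,
                       tip.label = as.character(x$tip_labels),
                       edge.length = as.numeric(x$edge_length),
                       Nnode = length(unique(edge[, 1])),
                       node.label = as.character(x$node_labels)),
                  class = "phylo")
  attr(tr, "order") <- "cladewise"
  tr
}

#' Serialize a bundle to a single JSON container
#'
#' The container holds alignments, trees (edge lists plus newick for
#' interoperability), model parameters, ancestral sequences, the D
#' dictionary and provenance. [read_bundle()] restores an identical bundle;
#' a write/read/write cycle is byte-identical.
#'
#' @param bundle a `vdj_bundle`
#' @param path output file
#' @export
write_bundle <- function(bundle, path) {
  pack_region <- function(r, extra) {
    c(list(alignment = as.list(r$alignment),
           synonyms = as.list(r$synonyms),
           alleles = r$alleles,
           tree = phylo_to_list(r$tree),
           newick = ape::write.tree(r$tree),
           model = r$model, logLik = r$logLik,
           ancestors = as.list(r$ancestors), mrca = r$mrca,
           root_node = r$root_node), extra)
  }
  obj <- list(
    format = "vdjplace-bundle-1",
    v = pack_region(bundle$v, list(boundaries = bundle$v$boundaries,
                                   cys_column = bundle$v$cys_column)),
    j = pack_region(bundle$j, list(trp_column = bundle$j$trp_column)),
    d = bundle$d,
    meta = bundle$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = FALSE)
  invisible(path)
}

#' Load a bundle written by [write_bundle()]
#' @param path JSON file
#' @return a `vdj_bundle`
#' @export
read_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vdjplace-bundle-1"))
    stop("not a vdjplace bundle: ", path)
  unpack_region <- function(r) {
    out <- list(alignment = unlist(r$alignment),
                synonyms = unlist(r$synonyms) %||%
                  setNames(character(), character()),
                alleles = as.data.frame(r$alleles),
                tree = phylo_from_list(r$tree),
                model = list(rates = as.numeric(r$model$rates),
                             bf = as.numeric(r$model$bf)),
                logLik = r$logLik,
                ancestors = unlist(r$ancestors), mrca = r$mrca,
                root_node = r$root_node)
    if (!is.null(r$boundaries)) {
      out$boundaries <- lapply(r$boundaries, as.integer)
      out$cys_column <- as.integer(r$cys_column)
    }
    if (!is.null(r$trp_column)) out$trp_column <- as.integer(r$trp_column)
    out
  }
  meta <- obj$meta
  meta$config$v_boundaries <- lapply(meta$config$v_boundaries, as.integer)
  structure(list(v = unpack_region(obj$v), j = unpack_region(obj$j),
                 d = as.data.frame(obj$d), meta = meta),
            class = "vdj_bundle")
}
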