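# Per-bundle preprocessing for phylogenetic attachment scoring.
#
# For every branch of each reference tree we precompute the two
# conditional-likelihood matrices a query attachment needs: the inside
# partial of the subtree below the branch (Du) and the outside partial of
# the rest of the tree at the branch's parent end (Ou). By time
# reversibility, the likelihood of the full tree with the query attached
# mid-branch is then exactly a three-taxon computation against these
# partials, independent of tree size. Columns are per-node scaled to avoid
# underflow; scale constants are carried separately and added per site.

region_prep <- function(reg) {
  model <- gtr_model(reg$model$rates, reg$model$bf)
  tree <- reg$tree
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncols <- nchar(reg$alignment[[1]])
  root <- po$edge[nrow(po$edge), 1]

  Pm <- lapply(seq_len(nrow(po$edge)),
               function(r) gtr_pmat(model, po$edge.length[r]))
  # inside (down) partials, scaled
  D <- vector("list", nnode); dscale <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    D[[i]] <- nt_partials(reg$alignment[[tree$tip.label[i]]])
    dscale[[i]] <- numeric(ncols)
  }
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (parent in unique(po$edge[, 1])) {
    rows <- kids[[as.character(parent)]]
    part <- NULL; sc <- numeric(ncols)
    for (r in rows) {
      ch <- po$edge[r, 2]
      msg <- Pm[[r]] %*% D[[ch]]
      part <- if (is.null(part)) msg else part * msg
      sc <- sc + dscale[[ch]]
    }
    mx <- apply(part, 2, max); mx[mx == 0] <- 1
    D[[parent]] <- sweep(part, 2, mx, "/")
    dscale[[parent]] <- sc + log(mx)
  }

  # outside (up) partials per edge, preorder
  nedge <- nrow(po$edge)
  O <- vector("list", nedge); oscale <- vector("list", nedge)
  edge_of_child <- integer(nnode)
  edge_of_child[po$edge[, 2]] <- seq_len(nedge)
  for (r in rev(seq_len(nedge))) {       # preorder: parents before children
    u <- po$edge[r, 1]; v <- po$edge[r, 2]
    part <- matrix(1, 4, ncols); sc <- numeric(ncols)
    rows <- kids[[as.character(u)]]
    for (r2 in rows) {
      w <- po$edge[r2, 2]
      if (w == v) next
      part <- part * (Pm[[r2]] %*% D[[w]])
      sc <- sc + dscale[[w]]
    }
    if (u != root) {
      rin <- edge_of_child[u]
      part <- part * (Pm[[rin]] %*% O[[rin]])
      sc <- sc + oscale[[rin]]
    }
    mx <- apply(part, 2, max); mx[mx == 0] <- 1
    O[[r]] <- sweep(part, 2, mx, "/")
    oscale[[r]] <- sc + log(mx)
  }

  node_label <- function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else tree$node.label[nd - ntip]
  }
  edges <- data.frame(
    id = seq_len(nedge),
    parent = po$edge[, 1], child = po$edge[, 2],
    length = po$edge.length,
    label = vapply(po$edge[, 2], node_label, character(1)),
    stringsAsFactors = FALSE)

  # column pattern classes per edge (identical (Ou, Du) columns collapse)
  edata <- lapply(seq_len(nedge), function(r) {
    M <- signif(rbind(O[[r]], D[[po$edge[r, 2]]]), 12)
    sig <- apply(M, 2, paste, collapse = ",")
    cls <- match(sig, unique(sig))
    keep <- !duplicated(cls)
    list(Ou = O[[r]][, keep, drop = FALSE],
         Du = D[[po$edge[r, 2]]][, keep, drop = FALSE],
         class_of_col = cls - 1L,
         scale_col = oscale[[r]] + dscale[[po$edge[r, 2]]])
  })

  # per-column log-likelihood of the reference alignment alone: added to
  # off-segment ("background") sites so that assigning a site to the other
  # segment still accounts for the reference data at its column
  ref_col_ll <- log(colSums(model$bf * D[[root]])) + dscale[[root]]

  list(model = model, tree = tree, edges = edges, edata = edata,
       ncols = ncols, root = root, log_bf = log(model$bf),
       ref_col_ll = ref_col_ll)
}

#' Prepare a bundle for classification
#'
#' Computes the eigendecomposed GTR models and the per-branch conditional
#' likelihood matrices for both reference trees, plus the mapping template
#' set. The result is cached on the bundle so repeated calls are free.
#'
#' @param bundle a `vdj_bundle`
#' @return the bundle with a `prep` attribute (invisibly reused by the
#'   classifier functions)
#' @export
classifier_prep <- function(bundle) {
  if (!is.null(attr(bundle, "prep"))) return(bundle)
  prep <- list(v = region_prep(bundle$v), j = region_prep(bundle$j),
               templates = mapping_templates(bundle))
  attr(bundle, "prep") <- prep
  bundle
}

get_prep <- function(bundle) {
  p <- attr(bundle, "prep")
  if (is.null(p)) attr(classifier_prep(bundle), "prep") else p
}

# ungapped position -> 0-based alignment column map for one gapped row
ungapped_col_map <- function(gapped) {
  cc <- chars(gapped)
  which(cc != "-" & cc != ".") - 1L
}

#' Small-sample corrected Akaike information criterion
#'
#' @param logL log-likelihood
#' @param k number of estimated parameters
#' @param n number of observations (alignment columns scored)
#' @return AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)
#' @export
aicc <- function(logL, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: need n > k + 1 (segment too short to score)")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights over a set of models
#'
#' `exp(-0.5 (AICc - min AICc))`, normalised to sum to one. Order is
#' preserved.
#'
#' @param aicc_values numeric vector of AICc scores (finite)
#' @return numeric vector of weights summing to 1
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0) stop("no models to weight")
  w <- exp(-0.5 * (aicc_values - min(aicc_values)))
  w / sum(w)
}

# --- per-query scoring data ----------------------------------------------

# site tables from a query mapping: qpos (0-based), col (0-based), qb code
query_score_data <- function(bundle, map) {
  prep <- get_prep(bundle)
  qcodes <- nt_codes(map$query_mapped)
  build <- function(sites, rprep) {
    ord <- order(sites$qpos)
    sites <- sites[ord, , drop = FALSE]
    qb <- qcodes[sites$qpos + 1L]
    ek <- lapply(rprep$edata, function(ed) ed$class_of_col[sites$col + 1L])
    esc <- lapply(rprep$edata, function(ed)
      cumsum(ed$scale_col[sites$col + 1L]))
    logpi <- ifelse(qb < 4L, rprep$log_bf[qb + 1L], 0) +
      rprep$ref_col_ll[sites$col + 1L]
    list(qpos = sites$qpos, col = sites$col, qb = qb,
         klass = ek, cum_scale = esc, cum_logpi = cumsum(logpi))
  }
  vs <- build(map$pairs[map$pairs$region == "V", ], prep$v)
  js <- build(map$pairs[map$pairs$region == "J", ], prep$j)
  list(v = vs, j = js, n = length(vs$qpos) + length(js$qpos), map = map)
}

#' Score one attachment model (three-taxon log-likelihood)
#'
#' Attaches the query's V segment (positions before `breakpoint`) mid-branch
#' on the V tree and the J segment on the J tree, optimising the three
#' branch lengths of each three-taxon star by maximum likelihood under the
#' bundle's GTR model. Sites on the wrong side of the breakpoint for their
#' mapped region contribute their stationary probability, so every model of
#' a query is scored on the same `n` columns.
#'
#' @param bundle a prepared `vdj_bundle`
#' @param qdat query scoring data (from the mapping step; internal structure)
#' @param v_edge,j_edge edge ids in the prepared V / J trees
#' @param breakpoint query coordinate (0-based) separating the segments
#' @return list with `logL`, `lengths` (t_p, t_c, t_q for the V segment,
#'   then the same for the J segment), `k`, `n`, `aicc`
#' @export
attachment_loglik <- function(bundle, qdat, v_edge, j_edge, breakpoint) {
  res <- score_pair(bundle, qdat, v_edge, j_edge, breakpoint)
  list(logL = res$logL[1], lengths = res$lengths[1, ], k = res$k,
       n = res$n, aicc = res$aicc[1])
}

# scan one (v_edge, j_edge) pair over breakpoints; returns vectors
score_pair <- function(bundle, qdat, v_edge, j_edge, bps) {
  prep <- get_prep(bundle)
  ev <- prep$v$edata[[v_edge]]; ej <- prep$j$edata[[j_edge]]
  eig_v <- prep$v$model$eigen; eig_j <- prep$j$model$eigen
  # branch-length order per segment: (t_p parent side, t_c child side,
  # t_q query pendant)
  initV <- c(max(prep$v$edges$length[v_edge] / 2, 1e-3),
             max(prep$v$edges$length[v_edge] / 2, 1e-3), 0.05)
  initJ <- c(max(prep$j$edges$length[j_edge] / 2, 1e-3),
             max(prep$j$edges$length[j_edge] / 2, 1e-3), 0.05)
  bps <- as.integer(bps)
  # segments share one GTR model per region tree; Brent in C++
  fit <- cpp_pair_scan(eig_v$U, eig_v$Uinv, eig_v$lambda, prep$v$model$bf,
                       ev$Ou, ev$Du, qdat$v$klass[[v_edge]], qdat$v$qb,
                       as.integer(qdat$v$qpos),
                       eig_j$U, eig_j$Uinv, eig_j$lambda, prep$j$model$bf,
                       ej$Ou, ej$Du, qdat$j$klass[[j_edge]], qdat$j$qb,
                       as.integer(qdat$j$qpos),
                       bps, initV, initJ, 0, 10, 1e-6, 50L)
  nv <- length(qdat$v$qpos); nj <- length(qdat$j$qpos)
  vcut <- findInterval(bps - 0.5, qdat$v$qpos + 1L)
  jcut <- findInterval(bps - 0.5, qdat$j$qpos + 1L)
  vscale <- ifelse(vcut > 0, qdat$v$cum_scale[[v_edge]][pmax(vcut, 1)], 0)
  jtot <- if (nj > 0) qdat$j$cum_scale[[j_edge]][nj] else 0
  jscale <- jtot - ifelse(jcut > 0, qdat$j$cum_scale[[j_edge]][pmax(jcut, 1)], 0)
  # stationary background: V sites at/after bp, J sites before bp
  vtot_pi <- if (nv > 0) qdat$v$cum_logpi[nv] else 0
  bg <- (vtot_pi - ifelse(vcut > 0, qdat$v$cum_logpi[pmax(vcut, 1)], 0)) +
    ifelse(jcut > 0, qdat$j$cum_logpi[pmax(jcut, 1)], 0)
  logL <- unname(fit$logL_v + vscale + fit$logL_j + jscale + bg)
  k <- 7L
  list(logL = logL, lengths = fit$lengths, k = k, n = qdat$n,
       aicc = aicc(logL, k, qdat$n))
}
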