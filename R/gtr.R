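#' Construct a GTR substitution model
#'
#' Builds the reversible rate matrix Q from six exchangeabilities and base
#' frequencies, normalised to one expected substitution per site per unit
#' branch length, together with its eigendecomposition (computed on the
#' similarity-transformed symmetric matrix, so eigenvalues are real).
#'
#' @param rates exchangeabilities in the order AC, AG, AT, CG, CT, GT
#' @param bf base frequencies (A, C, G, T); need not be pre-normalised
#' @return object of class `gtr_model` with elements `rates`, `bf`, `Q`,
#'   `eigen` (list `U`, `Uinv`, `lambda`)
#' @export
gtr_model <- function(rates = rep(1, 6), bf = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, length(bf) == 4, all(rates > 0), all(bf > 0))
  bf <- bf / sum(bf)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- rates[k] * bf[j]
    Q[j, i] <- rates[k] * bf[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q <- Q / mu
  s <- sqrt(bf)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / s) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(s)
  structure(list(rates = rates, bf = bf, Q = Q,
                 eigen = list(U = U, Uinv = Uinv, lambda = e$values)),
            class = "gtr_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model a [gtr_model()]
#' @param t branch length (substitutions/site, >= 0)
#' @return 4x4 matrix, rows = ancestral state, cols = descendant state (ACGT)
#' @export
gtr_pmat <- function(model, t) {
  e <- model$eigen
  P <- e$U %*% (exp(e$lambda * t) * e$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Felsenstein pruning log-likelihood on a fixed tree
#'
#' Plain pruning with per-node log-scaling. Gaps and ambiguity codes in the
#' alignment are treated as missing data.
#'
#' @param tree rooted `phylo` with branch lengths
#' @param alignment named character vector of equal-length (gapped) sequences
#'   covering every tip label
#' @param model a [gtr_model()]
#' @return total log-likelihood (sum over columns)
#' @export
pruning_loglik <- function(tree, alignment, model) {
  stopifnot(all(tree$tip.label %in% names(alignment)))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncol <- nchar(alignment[[1]])
  part <- vector("list", nnode)
  logscale <- numeric(nnode)
  for (i in seq_len(ntip))
    part[[i]] <- nt_partials(alignment[[tree$tip.label[i]]])
  for (r in seq_len(nrow(po$edge))) {
    child <- po$edge[r, 2]; parent <- po$edge[r, 1]
    P <- gtr_pmat(model, po$edge.length[r])
    msg <- P %*% part[[child]]
    if (is.null(part[[parent]])) {
      part[[parent]] <- msg
      logscale[parent] <- logscale[child]
    } else {
      part[[parent]] <- part[[parent]] * msg
      logscale[parent] <- logscale[parent] + logscale[child]
    }
    mx <- apply(part[[parent]], 2, max)
    mx[mx == 0] <- 1
    part[[parent]] <- sweep(part[[parent]], 2, mx, "/")
    logscale[parent] <- logscale[parent] + sum(log(mx))
  }
  root <- po$edge[nrow(po$edge), 1]
  sitelik <- colSums(model$bf * part[[root]])
  sum(log(sitelik)) + logscale[root]
  }

#' Maximum-likelihood distance between two sequences
#'
#' Optimises the single branch length of a two-taxon tree under the given
#' model. Under the Jukes-Cantor special case this reproduces the closed
#' form -3/4 log(1 - 4p/3).
#'
#' @param a,b nucleotide strings of equal length
#' @param model a [gtr_model()]
#' @param upper upper bound for the distance
#' @return the ML branch length
#' @export
ml_distance <- function(a, b, model = gtr_model(), upper = 10) {
  pa <- nt_partials(a); pb <- nt_partials(b)
  f <- function(t) {
    P <- gtr_pmat(model, t)
    sum(log(colSums((model$bf * pa) * (P %*% pb))))
  }
  if (f(1e-8) >= f(1e-4)) return(0)
  optimize(f, c(0, upper), maximum = TRUE, tol = 1e-9)$maximum
}

#' Fit a GTR model and ML branch lengths on a fixed topology
#'
#' Exchangeabilities and branch lengths are optimised by maximum likelihood
#' with `phangorn::optim.pml` on the fixed topology; base frequencies are
#' empirical. The optimiser's log-likelihood is monotone non-decreasing by
#' construction.
#'
#' @param alignment named character vector of equal-length gapped sequences
#' @param tree `phylo` topology whose tip labels appear in `alignment`
#' @return list with `model` (a [gtr_model()]), `tree` (branch lengths
#'   re-optimised) and `logLik`
#' @export
fit_reference_model <- function(alignment, tree) {
  if (length(alignment) < 3)
    stop("need at least 3 sequences to fit the reference model")
  stopifnot(all(tree$tip.label %in% names(alignment)))
  mat <- do.call(rbind, strsplit(toupper(alignment[tree$tip.label]), ""))
  rownames(mat) <- tree$tip.label
  dat <- phangorn::phyDat(mat, type = "DNA")
  bf <- nt_base_freq(alignment)
  t0 <- tree
  if (is.null(t0$edge.length)) t0$edge.length <- rep(0.05, nrow(t0$edge))
  t0$edge.length[t0$edge.length < 1e-8] <- 1e-8
  outgroup <- if (ape::is.rooted(t0)) {
    root <- length(t0$tip.label) + 1
    first <- t0$edge[t0$edge[, 1] == root, 2][1]
    if (first <= length(t0$tip.label)) t0$tip.label[first]
    else ape::extract.clade(t0, first)$tip.label
  }
  fit <- phangorn::pml(t0, dat, bf = bf, k = 1)
  fit <- suppressWarnings(
    phangorn::optim.pml(fit, optEdge = TRUE, optQ = TRUE, optBf = FALSE,
                        optNni = FALSE, optGamma = FALSE, optInv = FALSE,
                        control = phangorn::pml.control(trace = 0)))
  if (!is.finite(fit$logLik)) stop("non-finite reference likelihood")
  model <- gtr_model(rates = fit$Q, bf = fit$bf)
  tr <- fit$tree
  # edge-length optimisation unroots; restore the input rooting
  if (!ape::is.rooted(tr) && !is.null(outgroup) &&
      length(outgroup) < length(tr$tip.label))
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  # the optimiser floors branch lengths around 1e-8; snap those to an exact
  # zero so zero-length branches are recognised downstream (label rule 1)
  tr$edge.length[tr$edge.length < 1e-7] <- 0
  list(model = model, tree = tr, logLik = fit$logLik)
}

# empirical base frequencies over an alignment, ignoring gaps/ambiguity
nt_base_freq <- function(alignment) {
  cc <- unlist(strsplit(toupper(alignment), ""))
  n <- table(factor(cc, levels = BASES))
  f <- as.numeric(n) / max(sum(n), 1)
  if (any(f == 0)) f <- (f + 1e-4) / sum(f + 1e-4)
  f
}

#' Joint maximum-likelihood ancestral reconstruction
#'
#' Reconstructs one sequence per internal node by joint ML (max-sum dynamic
#' programming over the tree, the Pupko et al. algorithm). Ties are broken
#' deterministically in the fixed order A < C < G < T. Columns that are gaps
#' in every tip are reported as gaps; other gap/ambiguity cells are treated
#' as missing data.
#'
#' @param tree rooted `phylo` with branch lengths
#' @param alignment named character vector of gapped sequences
#' @param model a [gtr_model()]
#' @return object with `sequences`: named character vector, one gapped
#'   sequence per internal node (names `node<k>` by node number; the root
#'   additionally available as `mrca`)
#' @export
reconstruct_ancestors <- function(tree, alignment, model) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncol <- nchar(alignment[[1]])
  root <- po$edge[nrow(po$edge), 1]
  logP <- vector("list", nrow(po$edge))
  for (r in seq_len(nrow(po$edge)))
    logP[[r]] <- log(pmax(gtr_pmat(model, po$edge.length[r]), 1e-300))
  tippart <- lapply(tree$tip.label, function(l) nt_partials(alignment[[l]]))
  allgap <- Reduce(`&`, lapply(tree$tip.label, function(l) {
    cc <- chars(toupper(alignment[[l]])); cc == "-" | cc == "."
  }))
  # C[[node]][s_parent, col]: best log-lik of subtree given parent state
  # B[[node]][s_parent, col]: argmax own state
  C <- vector("list", nnode); B <- vector("list", nnode)
  S <- vector("list", nnode)  # accumulated children scores at internal nodes
  for (r in seq_len(nrow(po$edge))) {
    child <- po$edge[r, 2]; parent <- po$edge[r, 1]
    own <- if (child <= ntip) log(pmax(tippart[[child]], 1e-300))
           else S[[child]]
    Cc <- matrix(0, 4, ncol); Bc <- matrix(0L, 4, ncol)
    for (sp in 1:4) {
      cand <- logP[[r]][sp, ] + own           # 4 x ncol
      w <- max.col(t(cand), ties.method = "first")
      Bc[sp, ] <- w
      Cc[sp, ] <- cand[cbind(w, seq_len(ncol))]
    }
    C[[child]] <- Cc; B[[child]] <- Bc
    S[[parent]] <- if (is.null(S[[parent]])) Cc else S[[parent]] + Cc
  }
  states <- matrix(0L, nnode, ncol)
  rootcand <- log(model$bf) + S[[root]]
  states[root, ] <- max.col(t(rootcand), ties.method = "first")
  for (r in rev(seq_len(nrow(po$edge)))) {
    child <- po$edge[r, 2]; parent <- po$edge[r, 1]
    if (child <= ntip) next
    states[child, ] <- B[[child]][cbind(states[parent, ], seq_len(ncol))]
  }
  internal <- (ntip + 1):nnode
  seqs <- vapply(internal, function(nd) {
    b <- BASES[states[nd, ]]
    b[allgap] <- "-"
    paste(b, collapse = "")
  }, character(1))
  names(seqs) <- paste0("node", internal)
  structure(list(sequences = seqs, mrca = unname(seqs[paste0("node", root)]),
                 root_node = root), class = "ancestor_set")
}
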