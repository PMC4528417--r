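# Shared fixtures and independent oracles. The bundle is built once per
# test session (tree fitting is the slow part) and reused everywhere.

.fx_env <- new.env(parent = emptyenv())

fx_bundle <- function() {
  if (is.null(.fx_env$bundle)) {
    .fx_env$bundle <- classifier_prep(synthetic_bundle(seed = 42))
  }
  .fx_env$bundle
}

fx_germline <- function() {
  if (is.null(.fx_env$germline)) .fx_env$germline <- synthetic_germline(seed = 42)
  .fx_env$germline
}

# --- exhaustive likelihood oracle: sum over all internal-state assignments
enum_loglik <- function(tree, alignment, model) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncols <- nchar(alignment[[1]])
  internal <- (ntip + 1):nnode
  Pm <- lapply(seq_len(nrow(po$edge)), function(r)
    vdjplace::gtr_pmat(model, po$edge.length[r]))
  leafp <- lapply(tree$tip.label, function(l)
    vdjplace:::nt_partials(alignment[[l]]))
  root <- po$edge[nrow(po$edge), 1]
  states <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (col in seq_len(ncols)) {
    lik <- 0
    for (s in seq_len(nrow(states))) {
      st <- integer(nnode)
      st[internal] <- states[s, ]
      p <- model$bf[st[root]]
      for (r in seq_len(nrow(po$edge))) {
        a <- st[po$edge[r, 1]]; ch <- po$edge[r, 2]
        p <- p * if (ch <= ntip) sum(Pm[[r]][a, ] * leafp[[ch]][, col])
                 else Pm[[r]][a, st[ch]]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# --- affine-gap Smith-Waterman oracle (Gotoh recurrences, plain R)
sw_oracle <- function(a, b, match = 5, mismatch = -4,
                      gap_open = 10, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch or fresh
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (consume b)
  F <- matrix(-Inf, n + 1, m + 1) # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# random stop-free in-frame sequence
random_cds <- function(n_codons) {
  paste(replicate(n_codons, {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                   collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) break
    }
    cod
  }), collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random rooted tree with branch lengths, tips named as parseable alleles
random_allele_tree <- function(ntip, mean_bl = 0.1) {
  tr <- ape::rtree(ntip, rooted = TRUE,
                   tip.label = sprintf("IGHV%d-1*01", seq_len(ntip)))
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_bl)
  tr
}

# evolve an alignment down a tree under the model (for property tests)
evolve_alignment <- function(tree, ncols, model) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- po$edge[nrow(po$edge), 1]
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample(1:4, ncols, replace = TRUE, prob = model$bf)
  for (r in rev(seq_len(nrow(po$edge)))) {
    P <- vdjplace::gtr_pmat(model, po$edge.length[r])
    parent <- seqs[[po$edge[r, 1]]]
    seqs[[po$edge[r, 2]]] <- vapply(parent, function(s)
      sample(1:4, 1, prob = P[s, ]), integer(1))
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(c("A", "C", "G", "T")[seqs[[i]]], collapse = ""), character(1))
  stats::setNames(out, tree$tip.label)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# quick GA settings for tests that only need a working search
fast_ga <- function() ga_defaults(max_restarts = 2, max_generations = 80)

# --- J-segment-only scoring problems against the fixture J tree ----------

j_only_qdat <- function(b, query) {
  map <- list(query_mapped = query,
              pairs = data.frame(qpos = 0:(nchar(query) - 1), tpos = NA,
                                 region = "J", col = 0:(nchar(query) - 1),
                                 stringsAsFactors = FALSE))
  vdjplace:::query_score_data(b, map)
}

j_segment_loglik <- function(b, qdat, edge_id, lengths) {
  prep <- attr(b, "prep")
  eig <- prep$j$model$eigen
  ed <- prep$j$edata[[edge_id]]
  vdjplace:::cpp_segment_loglik(eig$U, eig$Uinv, eig$lambda,
                                prep$j$model$bf, ed$Ou, ed$Du,
                                qdat$j$klass[[edge_id]], qdat$j$qb,
                                lengths) + sum(ed$scale_col)
}

# graft the query onto edge `edge_id` of the J tree with explicit
# (t_p, t_c, t_q); returns the grafted phylo (tip "QUERY")
graft_query <- function(b, edge_id, tp, tc, tq) {
  prep <- attr(b, "prep")
  tree <- ape::reorder.phylo(prep$j$tree, "postorder")
  child <- prep$j$edges$child[edge_id]
  g <- phytools::bind.tip(tree, "QUERY", edge.length = tq, where = child,
                          position = prep$j$edges$length[edge_id] / 2)
  qtip <- which(g$tip.label == "QUERY")
  w <- g$edge[g$edge[, 2] == qtip, 1]
  newchild <- which(c(g$tip.label, rep(NA, g$Nnode)) %in%
                      prep$j$tree$tip.label[child])
  if (child > length(tree$tip.label)) {
    # internal child: find it as the non-QUERY child of w
    kids <- g$edge[g$edge[, 1] == w, 2]
    newchild <- setdiff(kids, qtip)
  }
  g$edge.length[g$edge[, 2] == qtip] <- tq
  g$edge.length[g$edge[, 2] == newchild] <- tc
  g$edge.length[g$edge[, 2] == w] <- tp
  g
}

# --- shared acceptance datasets (classified once per session) -------------

acc_synonyms <- function(b) list(v = b$v$synonyms, j = b$j$synonyms)

# all *01 x *01 x *01 simple concatenations, classified
acc_simple <- function() {
  if (is.null(.fx_env$acc_simple)) {
    b <- fx_bundle()
    sim <- simulate_simple(b)
    calls <- classify_reads(sim$reads, b, seed = 2001)
    .fx_env$acc_simple <- list(reads = sim$reads, truth = sim$truth,
                               calls = calls)
  }
  .fx_env$acc_simple
}

# realistic rearrangements (deletions + N additions), n_mut mutations
acc_realistic <- function(n, n_mut, seed) {
  key <- sprintf("acc_real_%d_%d_%d", n, n_mut, seed)
  if (is.null(.fx_env[[key]])) {
    b <- fx_bundle()
    rep_ <- simulate_repertoire(b, n, n_mut = n_mut, seed = seed)
    calls <- classify_reads(rep_$reads, b, seed = seed + 5000)
    .fx_env[[key]] <- list(reads = rep_$reads, truth = rep_$truth,
                           calls = calls)
  }
  .fx_env[[key]]
}

# summed credible-set weight on the true V allele (synonym-resolved)
true_v_support <- function(call, truth_v, syn) {
  tv <- vdjplace:::resolve_synonym(truth_v, syn$v)
  cv <- vdjplace:::resolve_synonym(call$credible_set$v, syn$v)
  sum(call$credible_set$weight[cv == tv])
}
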