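test_that("IMGT-style FASTA parsing strips gaps and parses names", {
  txt <- c(">X1|IGHV5-51*01|Homo sapiens|F|V-REGION", "CAG.GTG",
           ">X2|IGHV5-51*02|Homo sapiens|ORF|V-REGION", "CAGGTT",
           ">X3|IGHV5-10*01|Homo sapiens|P|V-REGION", "CAGGAA")
  out <- parse_imgt_fasta(txt, "V")
  expect_equal(out$name, c("IGHV5-51*01", "IGHV5-51*02"))  # P dropped
  expect_equal(out$sequence[1], "CAGGTG")
  expect_equal(out$gapped[1], "CAG-GTG")
  expect_equal(out$family[1], "IGHV5")
  expect_equal(out$gene[1], "IGHV5-51")
  withp <- parse_imgt_fasta(txt, "V", include_pseudogenes = TRUE)
  expect_equal(nrow(withp), 3)
  expect_equal(nrow(parse_imgt_fasta(character(0), "V")), 0)
  expect_error(parse_imgt_fasta(c(">A|not a name|x|F|", "ACGT"), "V"),
               "unparseable")
})

test_that("allele names parse into the family > gene > allele hierarchy", {
  p <- parse_allele_name("IGHV5-51*01")
  expect_equal(p$family, "IGHV5")
  expect_equal(p$gene, "IGHV5-51")
  expect_equal(p$allele, "01")
  pj <- parse_allele_name("IGHJ4*02")
  expect_equal(pj$gene, "IGHJ4")
  expect_equal(pj$family, "IGHJ4")
  expect_error(parse_allele_name("garbage"), "unparseable")
})

test_that("deduplication keeps first-seen alleles and maps synonyms", {
  al <- data.frame(name = c("IGHV1-1*01", "IGHV1-1*02", "IGHV1-2*01"),
                   sequence = c("ACGT", "ACGT", "ACGG"),
                   stringsAsFactors = FALSE)
  dd <- dedupe_alleles(al)
  expect_equal(dd$alleles$name, c("IGHV1-1*01", "IGHV1-2*01"))
  expect_equal(dd$synonyms, c("IGHV1-1*02" = "IGHV1-1*01"))
  # all-distinct input is the identity
  al2 <- data.frame(name = c("a1*01", "a2*01"), sequence = c("AA", "AC"))
  expect_length(dedupe_alleles(al2)$synonyms, 0)
  # partition: every input maps to exactly one retained allele
  set.seed(1)
  al3 <- data.frame(name = sprintf("IGHV1-%d*01", 1:20),
                    sequence = sample(c("AAAA", "CCCC", "GGGG"), 20,
                                      replace = TRUE))
  dd3 <- dedupe_alleles(al3)
  mapped <- vdjplace:::resolve_synonym(al3$name, dd3$synonyms)
  expect_true(all(mapped %in% dd3$alleles$name))
  expect_equal(sort(unique(mapped)), sort(dd3$alleles$name))
})

test_that("internal-node labelling applies the zero-branch and shared-prefix rules", {
  # 4-leaf tree, families monophyletic: family nodes and region root
  tr <- ape::read.tree(text =
    "((IGHV1-2*01:0.1,IGHV1-3*01:0.1):0.1,(IGHV2-5*01:0.1,IGHV2-70*01:0.1):0.1);")
  lab <- label_internal_nodes(tr)
  expect_setequal(lab$node.label, c("IGHV", "IGHV1", "IGHV2"))
  # zero-length child: label inherited from the child
  tr2 <- ape::read.tree(text =
    "((IGHV5-51*01:0.0,IGHV5-51*02:0.2):0.1,IGHV5-10*01:0.3);")
  lab2 <- label_internal_nodes(tr2)
  expect_equal(lab2$node.label, c("IGHV5", "IGHV5-51*01"))
  # cherry with both branches > 0: shared gene label
  tr3 <- ape::read.tree(text =
    "((IGHV1-2*01:0.1,IGHV1-2*02:0.1):0.1,IGHV1-3*01:0.3);")
  lab3 <- label_internal_nodes(tr3)
  expect_equal(lab3$node.label, c("IGHV1", "IGHV1-2"))
  # idempotent: relabelling changes nothing
  expect_equal(label_internal_nodes(lab3), lab3)
  tr_bad <- tr3; tr_bad$tip.label[1] <- "nonsense"
  expect_error(label_internal_nodes(tr_bad), "nonsense")
})

test_that("two-sequence ML distance reproduces the Jukes-Cantor closed form", {
  jc <- gtr_model(rep(1, 6), rep(0.25, 4))
  n <- 3000
  set.seed(7)
  a <- random_nt(n)
  for (p in c(0.05, 0.1, 0.2)) {
    bb <- strsplit(a, "")[[1]]
    idx <- sample(n, round(p * n))
    bb[idx] <- vapply(bb[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    d <- ml_distance(a, paste(bb, collapse = ""), jc)
    expect_equal(d, -3 / 4 * log(1 - 4 * p / 3), tolerance = 0.03)
  }
  expect_equal(ml_distance(a, a, jc), 0)
})

test_that("pruning likelihood equals exhaustive state enumeration", {
  set.seed(11)
  # fixed toy 4-taxon case with 100 columns
  tr <- random_allele_tree(4)
  model <- gtr_model(c(1, 2, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3))
  aln <- evolve_alignment(tr, 100, model)
  expect_equal(pruning_loglik(tr, aln, model), enum_loglik(tr, aln, model),
               tolerance = 1e-10)
  # randomized property: trees up to 5 leaves, up to 50 columns
  for (rep in 1:5) {
    nt <- sample(3:5, 1)
    tr <- random_allele_tree(nt)
    m <- gtr_model(runif(6, 0.5, 3), prop.table(runif(4, 0.5, 2)))
    aln <- evolve_alignment(tr, sample(10:50, 1), m)
    expect_equal(pruning_loglik(tr, aln, m), enum_loglik(tr, aln, m),
                 tolerance = 1e-8)
  }
})

test_that("reference model fitting needs 3+ rows and shrinks identical-sequence branches", {
  expect_error(fit_reference_model(c(a = "ACGT", b = "ACGT"), NULL), "at least 3")
  aln <- c("IGHV1-1*01" = "ACGTACGTACGTACGTACGT",
           "IGHV1-2*01" = "ACGTACGTACGTACGTACGT",
           "IGHV1-3*01" = "ACGTACGTACGTACGTACGT")
  tr <- ape::read.tree(text = "(IGHV1-1*01,IGHV1-2*01,IGHV1-3*01);")
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  fit <- fit_reference_model(aln, tr)
  expect_true(all(fit$tree$edge.length < 1e-6))
})

test_that("joint ancestral reconstruction matches per-column brute force", {
  set.seed(3)
  model <- gtr_model(c(1, 3, 1, 1, 3, 1), c(0.3, 0.2, 0.2, 0.3))
  tr <- ape::read.tree(text =
    "(IGHV1-1*01:0.2,IGHV1-2*01:0.15,IGHV2-1*01:0.3);")
  aln <- evolve_alignment(tr, 60, model)
  anc <- reconstruct_ancestors(tr, aln, model)
  # 3-taxon star: single internal node; brute-force best root state per col
  leafp <- lapply(tr$tip.label, function(l) vdjplace:::nt_partials(aln[[l]]))
  Pm <- lapply(1:3, function(r) gtr_pmat(model, tr$edge.length[r]))
  po <- ape::reorder.phylo(tr, "postorder")
  expected <- vapply(seq_len(60), function(col) {
    sc <- vapply(1:4, function(s) {
      p <- model$bf[s]
      for (r in seq_len(nrow(po$edge)))
        p <- p * max(Pm[[r]][s, ] * leafp[[po$edge[r, 2]]][, col])
      p
    }, numeric(1))
    c("A", "C", "G", "T")[which.max(sc)]
  }, character(1))
  expect_equal(anc$mrca, paste(expected, collapse = ""))
  # identical sequences: every ancestor equals the leaves
  aln2 <- stats::setNames(rep(aln[[1]], 3), tr$tip.label)
  anc2 <- reconstruct_ancestors(tr, aln2, model)
  expect_true(all(anc2$sequences == aln[[1]]))
  # parsimony-unambiguous column under equal rates and branch lengths
  tr4 <- ape::read.tree(text =
    "((IGHV1-1*01:0.1,IGHV1-2*01:0.1):0.1,(IGHV2-1*01:0.1,IGHV2-2*01:0.1):0.1);")
  aln4 <- c("IGHV1-1*01" = "A", "IGHV1-2*01" = "A",
            "IGHV2-1*01" = "A", "IGHV2-2*01" = "C")
  anc4 <- reconstruct_ancestors(tr4, aln4, gtr_model())
  expect_equal(unname(anc4$mrca), "A")
})

test_that("bundle construction, D inversion and JSON round-trip", {
  b <- fx_bundle()
  expect_s3_class(b, "vdj_bundle")
  expect_length(b$v$alignment, 18)
  expect_equal(length(b$v$tree$tip.label), 18)
  expect_true(all(nzchar(b$v$tree$node.label)))
  expect_lte(length(b$v$ancestors), 17)
  # every inverted D entry is the reverse complement of its forward partner
  fwd <- b$d[b$d$orientation == "fwd", ]
  inv <- b$d[b$d$orientation == "inv", ]
  expect_equal(inv$sequence[match(fwd$name, inv$name)],
               vapply(fwd$sequence, revcomp, character(1)),
               ignore_attr = TRUE)
  g <- fx_germline()
  d2 <- parse_imgt_fasta(c(">x|IGHD9-9*01|s|F|D-REGION", "GGTATAACT"), "D")
  expect_equal(revcomp(d2$sequence), "AGTTATACC")

  tf <- tempfile(fileext = ".json")
  write_bundle(b, tf)
  b2 <- read_bundle(tf)
  tf2 <- tempfile(fileext = ".json")
  write_bundle(b2, tf2)
  expect_identical(readBin(tf, "raw", file.size(tf)),
                   readBin(tf2, "raw", file.size(tf2)))
  # reloaded bundle classifies identically
  sim <- simulate_simple(b)
  c1 <- classify_read(sim$reads[[10]], b, seed = 3)
  c2 <- classify_read(sim$reads[[10]], classifier_prep(b2), seed = 3)
  expect_equal(c1[setdiff(names(c1), "read_id")],
               c2[setdiff(names(c2), "read_id")])
})

test_that("tree/alignment mismatches are reported with offenders", {
  g <- fx_germline()
  bad_tree <- "(IGHV1-1*01,IGHV1-1*02,IGHV1-2*01);"
  expect_error(
    build_bundle(g$v_fasta, g$j_fasta, g$d_fasta, config = g$config,
                 v_tree = bad_tree, j_tree = g$j_tree),
    "IGHV2-1\\*01")
})
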