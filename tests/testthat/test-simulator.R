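test_that("simple rearrangements are the *01 Cartesian product of concatenations", {
  b <- fx_bundle()
  sim <- simulate_simple(b)
  # 9 V genes x 3 D genes x 2 J genes, *01 alleles only
  expect_length(sim$reads, 9 * 3 * 2)
  expect_equal(nrow(sim$truth), length(sim$reads))
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  for (i in sample(length(sim$reads), 10)) {
    v <- degap(b$v$alignment[[sim$truth$v[i]]])
    expect_equal(substr(sim$reads[[i]], 1, nchar(v)), v)  # V exact prefix
  }
})

test_that("degenerate distributions reduce realistic simulation to concatenation", {
  b <- fx_bundle()
  params <- rearrangement_params()
  point0 <- function(k) c(1, rep(0, k))
  for (nm in c("del_v3", "del_d5", "del_d3", "del_j5"))
    params[[nm]] <- point0(10)
  params$n1_len <- point0(15); params$n2_len <- point0(15)
  set.seed(51)
  sim <- simulate_rearrangement(b, params)
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  dseq <- b$d$sequence[b$d$name == sim$truth$d & b$d$orientation == "fwd"]
  expect_equal(sim$sequence,
               paste0(degap(b$v$alignment[[sim$truth$v]]), dseq,
                      degap(b$j$alignment[[sim$truth$j]])))
  expect_equal(sim$truth$n1, "")
  expect_equal(unlist(sim$truth[c("del_v3", "del_d5", "del_d3", "del_j5")]),
               c(del_v3 = 0, del_d5 = 0, del_d3 = 0, del_j5 = 0))
})

test_that("allele sampling uses inverse alleles-per-gene weights", {
  names <- c(sprintf("IGHV1-1*%02d", 1:4), "IGHV1-2*01")
  w <- vdjplace:::inverse_gene_weights(names)
  expect_equal(unname(as.numeric(w)), c(rep(1 / 4, 4), 1))
  # empirical: the two genes are sampled equally often
  set.seed(53)
  draws <- sample(names, 10000, replace = TRUE, prob = w)
  gene <- sub("\\*.*", "", draws)
  p <- mean(gene == "IGHV1-1")
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(p - 0.5), 3 * se)
})

test_that("retention filters reject stops, missing CDR3 and broken J motifs", {
  params <- rearrangement_params()
  good <- paste0("ATGGCA", "TGT", "GCAGGA", "TGGGGCCAAGGG", "ACCGTCTCCTCA")
  expect_true(vdjplace:::passes_filters(good, params))
  # stop codon in the junction
  expect_false(vdjplace:::passes_filters(sub("GCAGGA", "TAAGGA", good), params))
  # CDR3 regex needs the Cys
  expect_false(vdjplace:::passes_filters(sub("TGT", "GGT", good), params))
  # out-of-frame J: the [FW]G.G and TVSS motifs disappear
  expect_false(vdjplace:::passes_filters(
    paste0("ATGGCA", "TGT", "GCAGG", "TGGGGCCAAGGG", "ACCGTCTCCTCA"), params))
})

test_that("emitted reads pass the retention filters when re-checked", {
  b <- fx_bundle()
  rep1 <- simulate_repertoire(b, 25, seed = 57)
  params <- rearrangement_params()
  expect_true(all(vapply(rep1$reads, vdjplace:::passes_filters, logical(1),
                         params = params)))
  # unmutated reads reassemble exactly from their truth records
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  for (i in sample(25, 5)) {
    tr <- rep1$truth[i, ]
    v <- degap(b$v$alignment[[tr$v]])
    dseq <- b$d$sequence[b$d$name == tr$d & b$d$orientation == "fwd"]
    j <- degap(b$j$alignment[[tr$j]])
    expect_equal(unname(rep1$reads[[i]]),
                 paste0(substr(v, 1, nchar(v) - tr$del_v3), tr$n1,
                        substr(dseq, tr$del_d5 + 1, nchar(dseq) - tr$del_d3),
                        tr$n2, substr(j, tr$del_j5 + 1, nchar(j))))
  }
})

test_that("simulation is deterministic given the seed", {
  b <- fx_bundle()
  r1 <- simulate_repertoire(b, 10, n_mut = 15, seed = 59)
  r2 <- simulate_repertoire(b, 10, n_mut = 15, seed = 59)
  expect_identical(r1, r2)
  r3 <- simulate_repertoire(b, 10, n_mut = 15, seed = 60)
  expect_false(identical(r1$reads, r3$reads))
  c1 <- simulate_clones(b, n_clones = 2, clone_size = 3, n_mut = 10, seed = 61)
  c2 <- simulate_clones(b, n_clones = 2, clone_size = 3, n_mut = 10, seed = 61)
  expect_identical(c1, c2)
})

test_that("deletion lengths follow the parameter distributions", {
  b <- fx_bundle()
  rep1 <- simulate_repertoire(b, 400, seed = 63)
  params <- rearrangement_params()
  # chi-square goodness of fit on V 3' deletions (binned tail)
  obs <- table(factor(pmin(rep1$truth$del_v3, 4), levels = 0:4))
  p <- params$del_v3
  pexp <- c(p[1:4], sum(p[-(1:4)]))
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pexp))
  expect_gt(chi$p.value, 1e-4)
})

test_that("hypermutation places exactly n substitutions by context weight", {
  set.seed(65)
  s <- random_cds(120)  # 360 nt
  expect_identical(s5f_mutate(s, 0), s)
  m <- s5f_mutate(s, 40)
  expect_equal(hamming(s, m), 40)
  expect_error(s5f_mutate("ACGTACGT", 10), "mutable")

  # uniform model: mutated positions uniform over the mutable interior
  pos <- unlist(lapply(1:150, function(i) {
    mm <- s5f_mutate(s, 10)
    which(strsplit(s, "")[[1]] != strsplit(mm, "")[[1]])
  }))
  expect_true(all(pos >= 3 & pos <= nchar(s) - 2))
  counts <- table(cut(pos, breaks = seq(2.5, nchar(s) - 1.5, length.out = 9)))
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 1e-4)

  # single hot 5-mer: the first mutation hits its centre almost surely
  hot <- "ACGTA"
  seq1 <- paste0("GGGGG", hot, "GGGGG")
  mut <- setNames(rep(1e-6, 1024),
                  apply(expand.grid(rep(list(c("A","C","G","T")), 5))[5:1], 1,
                        paste, collapse = ""))
  mut[hot] <- 1
  model <- s5f_model(mutability = mut)
  hits <- vapply(1:400, function(i) {
    mm <- s5f_mutate(seq1, 1, model)
    which(strsplit(seq1, "")[[1]] != strsplit(mm, "")[[1]])
  }, numeric(1))
  expect_gte(mean(hits == 8), 0.99)  # centre of the hot 5-mer
})

test_that("substitutions follow the 5-mer substitution rows", {
  # force every mutation of the hot context to become T
  all5 <- apply(expand.grid(rep(list(c("A","C","G","T")), 5))[5:1], 1,
                paste, collapse = "")
  sub <- matrix(0, 1024, 4, dimnames = list(all5, c("A", "C", "G", "T")))
  sub[, "T"] <- 1
  sub[substr(all5, 3, 3) == "T", ] <- matrix(rep(c(1, 0, 0, 0), 1),
                                             sum(substr(all5, 3, 3) == "T"),
                                             4, byrow = TRUE)
  model <- s5f_model(substitution = sub)
  set.seed(67)
  s <- paste(rep("G", 30), collapse = "")
  m <- s5f_mutate(s, 5, model)
  changed <- strsplit(m, "")[[1]][strsplit(s, "")[[1]] != strsplit(m, "")[[1]]]
  expect_true(all(changed == "T"))
})

test_that("clonal families share truth and stay within the mutation radius", {
  b <- fx_bundle()
  cl <- simulate_clones(b, n_clones = 4, clone_size = 6, n_mut = 12, seed = 69)
  expect_length(cl$reads, 24)
  expect_equal(length(unique(cl$truth$clone_id)), 4)
  for (cid in unique(cl$truth$clone_id)) {
    idx <- which(cl$truth$clone_id == cid)
    expect_equal(length(unique(cl$truth$v[idx])), 1)
    rs <- cl$reads[idx]
    for (i in seq_along(rs)[-1]) {
      expect_equal(nchar(rs[[i]]), nchar(rs[[1]]))
      expect_lte(hamming(rs[[1]], rs[[i]]), 2 * 12)
    }
  }
})

test_that("parameter tables load and validate from TSV", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("length\tprobability", "0\t0.5", "1\t0.3", "2\t0.2"), tf)
  v <- read_length_table(tf)
  expect_equal(v, c(0.5, 0.3, 0.2))
  writeLines(c("length\tprobability", "0\t0.5", "1\t0.3"), tf)
  expect_error(read_length_table(tf), "sum to 1")
  writeLines(c("fivemer\tmutability\tA\tC\tG\tT",
               "AAAAA\t2.0\t0\t0.5\t0.25\t0.25",
               "AAAAC\t0.5\t0\t0.5\t0.25\t0.25"), tf)
  tab <- read_length_table(tf)
  expect_equal(unname(tab$mutability["AAAAA"]), 2)
  expect_equal(rownames(tab$substitution), c("AAAAA", "AAAAC"))
  bad <- c("fivemer\tmutability\tA\tC\tG\tT", "AAAAA\t1\t0.9\t0.5\t0\t0")
  writeLines(bad, tf)
  expect_error(read_length_table(tf), "sum to 1")
})

test_that("malformed simulator distributions error at validation", {
  params <- rearrangement_params()
  params$del_v3 <- c(0.5, 0.4)  # sums to 0.9
  b <- fx_bundle()
  expect_error(simulate_rearrangement(b, params), "malformed")
})
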