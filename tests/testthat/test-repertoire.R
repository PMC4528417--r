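# construct rearrangement_call objects directly (no classification needed)
fake_call <- function(id, pairs, weights, best = 1, d = character(0),
                      cdr3_len = 14, productive = TRUE) {
  vj <- do.call(rbind, strsplit(pairs, "/", fixed = TRUE))
  cs <- data.frame(v = vj[, 1], j = vj[, 2], weight = weights,
                   stringsAsFactors = FALSE)
  cs <- cs[order(-cs$weight), ]
  structure(list(read_id = id, unmappable = FALSE,
                 best_v = cs$v[best], best_j = cs$j[best],
                 v_support = sum(cs$weight[cs$v == cs$v[best]]),
                 j_support = sum(cs$weight[cs$j == cs$j[best]]),
                 rearrangement_support = cs$weight[best],
                 credible_set = cs,
                 d_call = list(alleles = data.frame(
                   name = d, orientation = rep("fwd", length(d)),
                   score = rep(20, length(d)), stringsAsFactors = FALSE)),
                 junction = list(cdr3_length = cdr3_len),
                 productive = productive),
            class = "rearrangement_call")
}

test_that("reads sharing a credible rearrangement cluster together", {
  calls <- list(
    fake_call("r1", "IGHV1-2*01/IGHJ4*02", 1),
    fake_call("r2", c("IGHV1-2*01/IGHJ4*02", "IGHV1-3*01/IGHJ4*02"),
              c(0.7, 0.3)),
    fake_call("r3", "IGHV3-3*01/IGHJ1*01", 1))
  g <- cluster_by_shared_rearrangement(calls)
  expect_equal(unname(g$components[c("r1", "r2")]),
               rep(g$components[["r1"]], 2))
  expect_false(g$components[["r3"]] == g$components[["r1"]])
  expect_equal(sort(g$sizes), c(1, 2))

  # disjoint credible sets everywhere: all singletons
  singles <- list(fake_call("a", "IGHV1-1*01/IGHJ1*01", 1),
                  fake_call("b", "IGHV1-2*01/IGHJ1*01", 1),
                  fake_call("c", "IGHV1-3*01/IGHJ1*01", 1))
  gs <- cluster_by_shared_rearrangement(singles)
  expect_equal(max(gs$sizes), 1)

  # permutation invariance of the partition
  gp <- cluster_by_shared_rearrangement(calls[c(3, 1, 2)])
  same <- function(g, a, b) g$components[[a]] == g$components[[b]]
  expect_equal(same(gp, "r1", "r2"), same(g, "r1", "r2"))
  expect_equal(same(gp, "r1", "r3"), same(g, "r1", "r3"))
})

test_that("clone support aggregates mean credible weight and modal best", {
  calls <- list(
    fake_call("r1", c("IGHV1-1*01/IGHJ1*01", "IGHV1-2*01/IGHJ1*01"),
              c(0.6, 0.4)),
    fake_call("r2", "IGHV1-1*01/IGHJ1*01", 0.2))
  agg <- aggregate_clone_support(calls)
  expect_equal(agg$support$support[agg$support$v == "IGHV1-1*01"], 0.4)
  expect_equal(agg$support$support[agg$support$v == "IGHV1-2*01"], 0.2)
  expect_equal(agg$modal_best$pair, "IGHV1-1*01/IGHJ1*01")
  expect_equal(agg$modal_best$count, 2)
  # sum mode
  aggs <- aggregate_clone_support(calls, stat = "sum")
  expect_equal(aggs$support$support[aggs$support$v == "IGHV1-1*01"], 0.8)
  # single read: its own credible set
  one <- aggregate_clone_support(calls[1])
  expect_equal(one$support$support, c(0.6, 0.4))
})

test_that("evaluation columns follow the benchmark table semantics", {
  truth <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                      v = c("IGHV1-1*01", "IGHV1-1*01", "IGHV1-1*01",
                            "IGHV1-1*01"),
                      d = rep("IGHD1-1*01", 4), j = rep("IGHJ1*01", 4),
                      stringsAsFactors = FALSE)
  perfect <- lapply(truth$read_id, function(id)
    fake_call(id, "IGHV1-1*01/IGHJ1*01", 1, d = "IGHD1-1*01"))
  ev <- evaluate_assignments(perfect, truth)
  expect_equal(ev$correct_top, c(100, 100, 100))
  expect_equal(ev$wrong, c(0, 0, 0))
  expect_equal(ev$no_assignment, c(0, 0, 0))

  # one of four assigned a wrong allele of the right gene:
  # wrong 25%, wrong_gene 0%
  mixed <- perfect
  mixed[[4]] <- fake_call("r4", "IGHV1-1*02/IGHJ1*01", 1, d = "IGHD1-1*01")
  ev2 <- evaluate_assignments(mixed, truth)
  vrow <- ev2[ev2$region == "V", ]
  expect_equal(vrow$wrong, 25)
  expect_equal(vrow$wrong_gene, 0)
  expect_equal(vrow$correct_top, 75)

  # synonyms: assignment to a duplicate allele counts as correct
  ev3 <- evaluate_assignments(mixed, truth,
    synonyms = list(v = c("IGHV1-1*02" = "IGHV1-1*01")))
  expect_equal(ev3[ev3$region == "V", ]$correct_top, 100)

  # truth in credible set but not on top
  cred <- perfect
  cred[[4]] <- fake_call("r4", c("IGHV1-2*01/IGHJ1*01",
                                 "IGHV1-1*01/IGHJ1*01"), c(0.6, 0.4))
  ev4 <- evaluate_assignments(cred, truth)
  vrow4 <- ev4[ev4$region == "V", ]
  expect_equal(vrow4$correct_in_credible, 25)
  expect_equal(vrow4$wrong, 0)

  # ancestral (gene-level) best assignment is tallied separately
  anc <- perfect
  anc[[4]] <- fake_call("r4", c("IGHV1-1/IGHJ1*01"), 1)
  ev5 <- evaluate_assignments(anc, truth)
  vrow5 <- ev5[ev5$region == "V", ]
  expect_equal(vrow5$ancestral_top, 25)
  expect_equal(vrow5$wrong, 0)

  # missing D call: no_assignment; rows sum to 100
  nod <- perfect
  nod[[2]] <- fake_call("r2", "IGHV1-1*01/IGHJ1*01", 1, d = character(0))
  ev6 <- evaluate_assignments(nod, truth)
  drow <- ev6[ev6$region == "D", ]
  expect_equal(drow$no_assignment, 25)
  sums <- rowSums(ev6[, c("correct_top", "correct_in_credible",
                          "ancestral_top", "wrong", "no_assignment")])
  expect_equal(unname(sums), c(100, 100, 100), tolerance = 0.011)

  expect_error(evaluate_assignments(perfect, truth[1:2, ]), "absent")
})

test_that("repertoire summaries nest family > gene > allele frequencies", {
  calls <- c(
    lapply(1:3, function(i)
      fake_call(paste0("a", i), "IGHV3-23*01/IGHJ6*02", 1, cdr3_len = 12)),
    list(fake_call("b1", "IGHV3-7*01/IGHJ6*02", 1, cdr3_len = 15),
         fake_call("c1", "IGHV1-2*01/IGHJ4*02", 1, cdr3_len = 15,
                   productive = FALSE)))
  s <- summarize_repertoire(calls)
  expect_equal(s$v$allele[["IGHV3-23*01"]], 3 / 5)
  expect_equal(s$v$gene[["IGHV3-7"]], 1 / 5)
  expect_equal(s$v$family[["IGHV3"]], 4 / 5)
  expect_equal(s$productive_fraction, 4 / 5)
  expect_equal(s$cdr3_length_histogram[["15"]], 2)
  # family frequency dominates every gene frequency within the family
  for (fam in names(s$v$family)) {
    genes <- s$v$gene[startsWith(names(s$v$gene), fam)]
    expect_gte(s$v$family[[fam]], max(unlist(genes)))
  }
  # single-assignment degenerate case
  s1 <- summarize_repertoire(calls[1])
  expect_equal(s1$v$allele[["IGHV3-23*01"]], 1)
})

test_that("per-read TSV and JSON writers round-trip the key columns", {
  calls <- list(
    fake_call("r1", "IGHV1-1*01/IGHJ1*01", 1, d = "IGHD1-1*01"),
    structure(list(read_id = "r2", unmappable = TRUE, reason = "low score"),
              class = "rearrangement_call"))
  calls[[1]]$junction <- list(nt = "TGTGCG", aa = "CA", cdr3_aa = "A",
                              cdr3_length = 1, terminating_rule = "J-motif")
  calls[[1]]$orientation <- "forward"
  calls[[1]]$n_models <- 10
  tf <- tempfile(fileext = ".tsv")
  write_calls_tsv(calls, tf)
  tab <- utils::read.delim(tf)
  expect_equal(tab$best_v[1], "IGHV1-1*01")
  expect_equal(tab$status, c("ok", "unmappable"))
  tj <- tempfile(fileext = ".json")
  write_calls_json(calls, tj)
  js <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(js$best$v[1], "IGHV1-1*01")
  expect_true(js$unmappable[2])
})
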