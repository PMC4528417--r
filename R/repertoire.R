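# Repertoire-level analyses: clonal clustering through shared credible
# rearrangements, evaluation against simulated truth, and summary tables.

credible_pairs <- function(call) {
  if (isTRUE(call$unmappable) || is.null(call$credible_set)) return(character(0))
  paste(call$credible_set$v, call$credible_set$j, sep = "/")
}

#' Cluster reads by shared credible rearrangements
#'
#' Builds an undirected graph with one node per read and an edge wherever
#' two reads share at least one (V, J) rearrangement between their credible
#' sets, then partitions it into connected components. Reads with empty
#' credible sets (including unmappable reads) are singletons.
#'
#' @param calls list of `rearrangement_call` objects
#' @return `clonal_graph`: list with `graph` (igraph), `components` (named
#'   membership vector), `sizes`
#' @export
cluster_by_shared_rearrangement <- function(calls) {
  ids <- vapply(calls, `[[`, "", "read_id")
  sets <- lapply(calls, credible_pairs)
  pair_of <- data.frame(
    read = rep(ids, lengths(sets)),
    pair = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  edges <- character(0)
  if (nrow(pair_of) > 0) {
    by_pair <- split(pair_of$read, pair_of$pair)
    # connect reads sharing a rearrangement via a star per rearrangement
    # (same connected components as the full pairwise edge set)
    edges <- unlist(lapply(by_pair, function(r) {
      r <- unique(r)
      if (length(r) < 2) return(character(0))
      rbind(r[1], r[-1])
    }))
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (length(edges) > 0) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  structure(list(graph = g,
                 components = setNames(comp$membership, ids),
                 sizes = comp$csize),
            class = "clonal_graph")
}

#' Aggregate rearrangement support across a set of reads
#'
#' For every (V, J) pair, reports the mean of its summed Akaike weight
#' across the reads (reads without the pair contribute 0), plus the modal
#' best assignment and its count.
#'
#' @param calls list of `rearrangement_call` objects
#' @param stat `"mean"` (default) or `"sum"` aggregation
#' @return list: `support` (data.frame v, j, support, sorted), `modal_best`
#'   (list pair / count)
#' @export
aggregate_clone_support <- function(calls, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  calls <- Filter(function(x) !isTRUE(x$unmappable), calls)
  if (length(calls) == 0) stop("no mappable calls to aggregate")
  tabs <- lapply(calls, function(cl)
    stats::setNames(cl$credible_set$weight,
                    paste(cl$credible_set$v, cl$credible_set$j, sep = "/")))
  pairs <- unique(unlist(lapply(tabs, names)))
  total <- vapply(pairs, function(p)
    sum(vapply(tabs, function(tb) {
      v <- unname(tb[p])
      if (length(v) == 0 || is.na(v)) 0 else v
    }, numeric(1))), numeric(1))
  support <- total / if (stat == "mean") length(calls) else 1
  vj <- do.call(rbind, strsplit(pairs, "/", fixed = TRUE))
  sup <- data.frame(v = vj[, 1], j = vj[, 2], support = unname(support),
                    stringsAsFactors = FALSE)
  sup <- sup[order(-sup$support, sup$v, sup$j), , drop = FALSE]
  rownames(sup) <- NULL
  best <- table(vapply(calls, function(cl)
    paste(cl$best_v, cl$best_j, sep = "/"), character(1)))
  best <- sort(best, decreasing = TRUE)
  list(support = sup,
       modal_best = list(pair = names(best)[1], count = as.integer(best[1]),
                         n = length(calls)))
}

region_truth <- function(truth, region) {
  switch(region, V = truth$v, D = truth$d, J = truth$j)
}

is_allele_label <- function(x) grepl("*", x, fixed = TRUE)

# best / credible labels for one region from a call
region_labels <- function(call, region) {
  if (isTRUE(call$unmappable))
    return(list(best = NA_character_, credible = character(0)))
  if (region == "D") {
    al <- call$d_call$alleles
    best <- if (nrow(al) > 0) al$name else NA_character_
    return(list(best = best, credible = unique(al$name)))
  }
  col <- if (region == "V") "v" else "j"
  list(best = call[[paste0("best_", col)]],
       credible = unique(call$credible_set[[col]]))
}

#' Evaluate rearrangement calls against simulated truth
#'
#' Per region (V, D, J) the classic benchmarking columns: `correct_top`
#' (the true allele, up to synonyms, received the highest model-averaged
#' support; for D, membership in the top-score tie set counts), `correct_in_credible`
#' (true allele in the credible set but not on top), `ancestral_top` (the
#' best assignment is an internal gene/family-level label ancestral to the
#' truth — reported separately rather than silently counted either way),
#' `wrong` (with `wrong_gene` the subset naming a different gene) and
#' `no_assignment`. Percentages are rounded to 2 decimals; per region
#' correct_top + correct_in_credible counted inside `correct` convention:
#' columns sum to 100 up to rounding.
#'
#' @param calls list of `rearrangement_call` objects
#' @param truth data.frame with `read_id`, `v`, `d`, `j`
#' @param synonyms named list with `v`, `j` synonym maps (dropped -> kept),
#'   e.g. from the bundle regions; assignments to either name count
#' @return `evaluation_table`: data.frame, one row per region
#' @export
evaluate_assignments <- function(calls, truth, synonyms = list()) {
  ids <- vapply(calls, `[[`, "", "read_id")
  missing <- setdiff(ids, truth$read_id)
  if (length(missing) > 0)
    stop("reads absent from truth: ", paste(head(missing, 5), collapse = ", "))
  truth <- truth[match(ids, truth$read_id), ]
  rows <- lapply(c("V", "D", "J"), function(region) {
    syn <- synonyms[[tolower(region)]] %||% setNames(character(), character())
    tv <- resolve_synonym(region_truth(truth, region), syn)
    n <- length(calls)
    cat_of <- vapply(seq_len(n), function(i) {
      lab <- region_labels(calls[[i]], region)
      best <- resolve_synonym(lab$best, syn)
      cred <- resolve_synonym(lab$credible, syn)
      if (all(is.na(best)) || length(best) == 0) return("no_assignment")
      if (tv[i] %in% best) return("correct_top")
      if (any(!is_allele_label(best))) {
        pt <- parse_allele_name(tv[i])
        if (any(best %in% c(pt$gene, pt$family, pt$region)))
          return("ancestral_top")
      }
      if (tv[i] %in% cred) return("correct_in_credible")
      truegene <- parse_allele_name(tv[i])$gene
      bestgene <- tryCatch(
        unique(vapply(best[is_allele_label(best)],
                      function(b) parse_allele_name(b)$gene, character(1))),
        error = function(e) character(0))
      if (length(bestgene) > 0 && !truegene %in% bestgene) return("wrong_gene")
      "wrong"
    }, character(1))
    tab <- table(factor(cat_of, levels = c("correct_top", "correct_in_credible",
                                           "ancestral_top", "wrong",
                                           "wrong_gene", "no_assignment")))
    pct <- round(100 * as.numeric(tab) / n, 2)
    data.frame(region = region,
               correct_top = pct[1], correct_in_credible = pct[2],
               ancestral_top = pct[3],
               wrong = pct[4] + pct[5], wrong_gene = pct[5],
               no_assignment = pct[6], n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_table", class(out))
  out
}

#' Summarise a repertoire of calls
#'
#' Nested family > gene > allele frequency tables for V and J over assigned
#' reads, the CDR3 amino-acid length histogram, and the productive
#' fraction; JSON-ready.
#'
#' @param calls list of `rearrangement_call` objects
#' @return `repertoire_summary` list
#' @export
summarize_repertoire <- function(calls) {
  ok <- Filter(function(x) !isTRUE(x$unmappable), calls)
  if (length(ok) == 0) stop("no mappable calls to summarise")
  level_freq <- function(labels) {
    freq <- function(x) {
      t <- table(x) / length(x)
      as.list(setNames(as.numeric(t), names(t)))
    }
    parsed <- lapply(labels, function(l)
      tryCatch(parse_allele_name(l),
               error = function(e) list(family = l, gene = l)))
    list(family = freq(vapply(parsed, `[[`, "", "family")),
         gene = freq(vapply(parsed, `[[`, "", "gene")),
         allele = freq(labels))
  }
  cdr3 <- vapply(ok, function(cl)
    cl$junction$cdr3_length %||% NA_integer_, numeric(1))
  cdr3 <- cdr3[!is.na(cdr3)]
  structure(list(
    n_reads = length(calls), n_assigned = length(ok),
    v = level_freq(vapply(ok, `[[`, "", "best_v")),
    j = level_freq(vapply(ok, `[[`, "", "best_j")),
    cdr3_length_histogram = as.list(table(cdr3)),
    productive_fraction =
      mean(vapply(ok, function(cl) isTRUE(cl$productive), logical(1)))),
    class = "repertoire_summary")
}

#' Write per-read calls as TSV
#'
#' One row per read: best V/J with supports, D tie list, junction, CDR3
#' and productivity. Coordinates are 1-based inclusive.
#'
#' @param calls list of `rearrangement_call` objects
#' @param path output TSV
#' @export
write_calls_tsv <- function(calls, path) {
  rows <- lapply(calls, function(cl) {
    if (isTRUE(cl$unmappable))
      return(data.frame(read_id = cl$read_id, status = "unmappable",
                        best_v = "", best_j = "", v_support = NA,
                        j_support = NA, rearrangement_support = NA,
                        d_call = "", junction_nt = "", cdr3_aa = "",
                        cdr3_length = NA, productive = NA,
                        orientation = "", stringsAsFactors = FALSE))
    data.frame(read_id = cl$read_id, status = "ok",
               best_v = cl$best_v, best_j = cl$best_j,
               v_support = round(cl$v_support, 4),
               j_support = round(cl$j_support, 4),
               rearrangement_support = round(cl$rearrangement_support, 4),
               d_call = format_d_call(cl$d_call),
               junction_nt = cl$junction$nt, cdr3_aa = cl$junction$cdr3_aa,
               cdr3_length = cl$junction$cdr3_length,
               productive = cl$productive, orientation = cl$orientation,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full JSON report (credible sets and per-read details)
#' @param calls list of `rearrangement_call` objects
#' @param path output JSON
#' @export
write_calls_json <- function(calls, path) {
  payload <- lapply(calls, function(cl) {
    if (isTRUE(cl$unmappable))
      return(list(read_id = cl$read_id, unmappable = TRUE,
                  reason = cl$reason))
    list(read_id = cl$read_id, unmappable = FALSE,
         best = list(v = cl$best_v, j = cl$best_j,
                     support = cl$rearrangement_support),
         marginal_support = list(v = cl$v_support, j = cl$j_support),
         credible_set = cl$credible_set,
         d_call = cl$d_call$alleles,
         junction = cl$junction[c("nt", "aa", "cdr3_aa", "cdr3_length",
                                  "terminating_rule")],
         productive = cl$productive, orientation = cl$orientation,
         n_models = cl$n_models)
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
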