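# CHC genetic-algorithm search over (V branch, J branch, breakpoint)
# attachment models, AICc-scored, summarised by Akaike weights.

#' Default genetic-algorithm settings
#'
#' CHC-style: elitist survivor selection, free (uniform) recombination,
#' incest prevention with a decaying distance threshold, cataclysmic
#' restarts from the elite, small population.
#'
#' @param pop_size population size
#' @param incest_init initial minimum genome distance for mating
#' @param cataclysm_rate per-locus mutation probability at restarts
#' @param max_restarts consecutive improvement-free restarts before stopping
#' @param bp_near breakpoints this close count as equal for genome distance
#' @param max_generations hard safety cap
#' @return list of settings
#' @export
ga_defaults <- function(pop_size = 32, incest_init = 1, cataclysm_rate = 0.35,
                        max_restarts = 3, bp_near = 3, max_generations = 150) {
  list(pop_size = pop_size, incest_init = incest_init,
       cataclysm_rate = cataclysm_rate, max_restarts = max_restarts,
       bp_near = bp_near, max_generations = max_generations)
}

# breakpoint search window: from 30 nt 5' of the FW3 Cys codon to the
# first mapped J column (query coordinates)
breakpoint_window <- function(map, bundle) {
  pairs <- map$pairs
  vp <- pairs[pairs$region == "V", ]
  jp <- pairs[pairs$region == "J", ]
  if (nrow(pairs) == 0) return(NULL)
  hi <- if (nrow(jp) > 0) min(jp$qpos) else max(pairs$qpos) + 1L
  cysq <- vp$qpos[vp$col == bundle$v$cys_column]
  lo <- if (length(cysq) > 0) cysq[1] - 30L
        else if (nrow(vp) > 0) max(vp$qpos) - 30L
        else hi
  lo <- max(lo, if (nrow(vp) > 0) min(vp$qpos) + 1L else 0L)
  lo <- min(max(lo, 0L), hi)
  c(lo, hi)
}

new_model_cache <- function() {
  env <- new.env(parent = emptyenv())
  env$keys <- character(0)
  env
}

# batch-evaluate one (v, j) pair over many breakpoints into the cache
scan_into_cache <- function(cache, bundle, qdat, vi, ji, bps) {
  bps <- bps[!vapply(bps, function(b)
    exists(paste(vi, ji, b, sep = ":"), envir = cache, inherits = FALSE),
    logical(1))]
  if (length(bps) == 0) return(invisible(NULL))
  res <- score_pair(bundle, qdat, vi, ji, bps)
  for (i in seq_along(bps)) {
    key <- paste(vi, ji, bps[i], sep = ":")
    assign(key, list(v_edge = vi, j_edge = ji, breakpoint = bps[i],
                     logL = res$logL[i], aicc = res$aicc[i],
                     lengths = res$lengths[i, ]), envir = cache)
    cache$keys <- c(cache$keys, key)
  }
  invisible(NULL)
}

eval_model <- function(cache, bundle, qdat, vi, ji, bp) {
  key <- paste(vi, ji, bp, sep = ":")
  hit <- get0(key, envir = cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  res <- score_pair(bundle, qdat, vi, ji, bp)
  rec <- list(v_edge = vi, j_edge = ji, breakpoint = bp,
              logL = res$logL[1], aicc = res$aicc[1],
              lengths = res$lengths[1, ])
  assign(key, rec, envir = cache)
  cache$keys <- c(cache$keys, key)
  rec
}

cache_models <- function(cache) {
  recs <- lapply(cache$keys, function(k) get(k, envir = cache))
  data.frame(v_edge = vapply(recs, `[[`, 0, "v_edge"),
             j_edge = vapply(recs, `[[`, 0, "j_edge"),
             breakpoint = vapply(recs, `[[`, 0, "breakpoint"),
             logL = vapply(recs, `[[`, 0, "logL"),
             aicc = vapply(recs, `[[`, 0, "aicc"))
}

finish_population <- function(cache, converged, generations, seed) {
  models <- cache_models(cache)
  models$weight <- akaike_weights(models$aicc)
  structure(list(models = models, best_aicc = min(models$aicc),
                 converged = converged, generations = generations,
                 seed = seed),
            class = "model_population")
}

#' CHC genetic-algorithm search for the best attachment model
#'
#' Searches over (V branch, J branch, breakpoint) genomes. Offspring are
#' produced by free recombination between sufficiently distant parents
#' (incest prevention); survivors are the elitist best-of-union; when the
#' mating threshold is exhausted the population is cataclysmically restarted
#' from mutated copies of the elite. The search stops after
#' `max_restarts` consecutive restarts without AICc improvement. Every
#' distinct model evaluated anywhere in the search is retained and receives
#' an Akaike weight.
#'
#' @param bundle a prepared `vdj_bundle`
#' @param qdat query scoring data from [query_score_data()]
#' @param window integer breakpoint window `c(lo, hi)` (query coordinates)
#' @param seed RNG seed; results are reproducible given it
#' @param config settings from [ga_defaults()]
#' @return a `model_population`: all evaluated models with AICc and Akaike
#'   weights (summing to one), plus convergence metadata
#' @export
chc_search <- function(bundle, qdat, window, seed = 1,
                       config = ga_defaults()) {
  nv <- nrow(get_prep(bundle)$v$edges)
  nj <- nrow(get_prep(bundle)$j$edges)
  bps <- seq.int(window[1], window[2])
  cache <- new_model_cache()
  with_seed(seed, {
    rnd <- function() c(sample.int(nv, 1), sample.int(nj, 1), sample(bps, 1))
    # stratified initial population: cycle through shuffled branch lists so
    # initial coverage of the V and J trees is as even as the population
    # size allows (random restarts still explore freely)
    vinit <- sample(rep(sample.int(nv), length.out = config$pop_size))
    jinit <- sample(rep(sample.int(nj), length.out = config$pop_size))
    pop <- lapply(seq_len(config$pop_size), function(i)
      c(vinit[i], jinit[i], sample(bps, 1)))
    fit <- vapply(pop, function(g)
      eval_model(cache, bundle, qdat, g[1], g[2], g[3])$aicc, numeric(1))
    thresh <- config$incest_init
    restarts <- 0; gen <- 0
    best <- min(fit); best_at_restart <- Inf
    converged <- FALSE
    dist_g <- function(a, b)
      (a[1] != b[1]) + (a[2] != b[2]) + (abs(a[3] - b[3]) > config$bp_near)
    while (gen < config$max_generations) {
      gen <- gen + 1
      idx <- sample(config$pop_size)
      children <- list()
      for (k in seq_len(config$pop_size %/% 2)) {
        a <- pop[[idx[2 * k - 1]]]; b <- pop[[idx[2 * k]]]
        if (dist_g(a, b) <= thresh) next
        pick <- runif(3) < 0.5
        children <- c(children, list(ifelse(pick, a, b), ifelse(pick, b, a)))
      }
      accepted <- FALSE
      if (length(children) > 0) {
        cfit <- vapply(children, function(g)
          eval_model(cache, bundle, qdat, g[1], g[2], g[3])$aicc, numeric(1))
        allg <- c(pop, children); allf <- c(fit, cfit)
        keep <- order(allf)[seq_len(config$pop_size)]
        accepted <- any(keep > config$pop_size)
        pop <- allg[keep]; fit <- allf[keep]
      }
      if (min(fit) < best - 1e-9) best <- min(fit)
      if (!accepted) thresh <- thresh - 1
      if (thresh < 0) {
        # cataclysm: keep the elite, refill with mutated copies of it
        elite <- pop[[which.min(fit)]]
        if (best < best_at_restart - 1e-9) restarts <- 0 else
          restarts <- restarts + 1
        best_at_restart <- best
        if (restarts >= config$max_restarts) { converged <- TRUE; break }
        pop <- c(list(elite), lapply(seq_len(config$pop_size - 1), function(i) {
          g <- elite
          if (runif(1) < config$cataclysm_rate) g[1] <- sample.int(nv, 1)
          if (runif(1) < config$cataclysm_rate) g[2] <- sample.int(nj, 1)
          if (runif(1) < config$cataclysm_rate) g[3] <- sample(bps, 1)
          g
        }))
        fit <- vapply(pop, function(g)
          eval_model(cache, bundle, qdat, g[1], g[2], g[3])$aicc, numeric(1))
        thresh <- config$incest_init
      }
    }
    # elite polish: deterministic coordinate sweeps around the best model
    # (breakpoint at 1-nt resolution, then every branch in each tree at the
    # best breakpoint), repeated while the optimum keeps moving
    best_of <- function() {
      aiccs <- vapply(cache$keys, function(k)
        get(k, envir = cache)$aicc, numeric(1))
      get(cache$keys[which.min(aiccs)], envir = cache)
    }
    for (sweep in 1:3) {
      el <- best_of()
      scan_into_cache(cache, bundle, qdat, el$v_edge, el$j_edge, bps)
      for (vi in seq_len(nv))
        eval_model(cache, bundle, qdat, vi, el$j_edge, el$breakpoint)
      for (ji in seq_len(nj))
        eval_model(cache, bundle, qdat, el$v_edge, ji, el$breakpoint)
      el2 <- best_of()
      if (el2$aicc >= el$aicc - 1e-9) break
    }
    finish_population(cache, converged, gen, seed)
  })
}

#' Exhaustive attachment-model search (test oracle)
#'
#' Evaluates every (V branch, J branch, breakpoint grid point) model.
#' Output contract is identical to [chc_search()]. Intended for small
#' fixture references; errors beyond `cap` models.
#'
#' @param bundle a prepared `vdj_bundle`
#' @param qdat query scoring data
#' @param window breakpoint window `c(lo, hi)`
#' @param grid breakpoint step (nt)
#' @param cap maximum number of models
#' @return a `model_population`
#' @export
exhaustive_search <- function(bundle, qdat, window, grid = 3, cap = 2e5) {
  prep <- get_prep(bundle)
  nv <- nrow(prep$v$edges); nj <- nrow(prep$j$edges)
  bps <- seq.int(window[1], window[2], by = grid)
  if (nv * nj * length(bps) > cap)
    stop("exhaustive search would evaluate ", nv * nj * length(bps),
         " models (> cap); use chc_search for references this size")
  recs <- vector("list", nv * nj)
  i <- 0
  for (vi in seq_len(nv)) for (ji in seq_len(nj)) {
    res <- score_pair(bundle, qdat, vi, ji, bps)
    i <- i + 1
    recs[[i]] <- data.frame(v_edge = vi, j_edge = ji, breakpoint = bps,
                            logL = res$logL, aicc = res$aicc)
  }
  models <- do.call(rbind, recs)
  models$weight <- akaike_weights(models$aicc)
  structure(list(models = models, best_aicc = min(models$aicc),
                 converged = TRUE, generations = 0, seed = NA_integer_),
            class = "model_population")
}

#' Summarise a model population into a rearrangement call
#'
#' Model weights are summed by (V branch label, J branch label) pair; the
#' top pair is the inferred rearrangement and every pair with summed weight
#' >= 0.01 forms the credible set (sorted by weight, ties broken by label).
#' Marginal V and J supports are also reported.
#'
#' @param population a `model_population`
#' @param bundle the prepared `vdj_bundle`
#' @return list: `best_v`, `best_j`, `v_support`, `j_support`,
#'   `rearrangement_support`, `credible_set` (data.frame v, j, weight)
#' @export
call_rearrangement <- function(population, bundle) {
  prep <- get_prep(bundle)
  m <- population$models
  vlab <- prep$v$edges$label[m$v_edge]
  jlab <- prep$j$edges$label[m$j_edge]
  pw <- stats::aggregate(m$weight, by = list(v = vlab, j = jlab), FUN = sum)
  names(pw)[3] <- "weight"
  pw <- pw[order(-pw$weight, pw$v, pw$j), , drop = FALSE]
  rownames(pw) <- NULL
  vw <- stats::aggregate(m$weight, by = list(v = vlab), FUN = sum)
  jw <- stats::aggregate(m$weight, by = list(j = jlab), FUN = sum)
  best <- pw[1, ]
  credible <- pw[pw$weight >= 0.01, , drop = FALSE]
  list(best_v = best$v, best_j = best$j,
       v_support = vw$x[vw$v == best$v],
       j_support = jw$x[jw$j == best$j],
       rearrangement_support = best$weight,
       credible_set = credible)
}

#' Classify a single read
#'
#' Runs the full per-read pipeline: template mapping, region segmentation,
#' junction extraction, the attachment-model search, model averaging, and D
#' assignment on the junction.
#'
#' @param query nucleotide string
#' @param bundle a `vdj_bundle` (prepared automatically)
#' @param read_id identifier carried into the output
#' @param seed RNG seed for the GA
#' @param method `"ga"` or `"exhaustive"`
#' @param config GA settings ([ga_defaults()])
#' @param floor optional unmappable score floor
#' @param keep_population retain the full `model_population` in the result
#' @param d_scoring,d_min_score D assignment parameters ([assign_d()])
#' @return a `rearrangement_call` (list), or an unmappable record
#' @export
classify_read <- function(query, bundle, read_id = "read", seed = 1,
                          method = c("ga", "exhaustive"),
                          config = ga_defaults(), floor = NULL,
                          keep_population = FALSE,
                          d_scoring = default_d_scoring(), d_min_score = 15) {
  method <- match.arg(method)
  bundle <- classifier_prep(bundle)
  map <- best_mapping(query, bundle, floor = floor)
  if (isTRUE(map$unmappable)) {
    return(structure(list(read_id = read_id, unmappable = TRUE,
                          reason = sprintf("score %.1f below floor %.1f",
                                           map$score, floor)),
                     class = "rearrangement_call"))
  }
  rm_ <- segment_regions(map, bundle)
  qdat <- query_score_data(bundle, map)
  if (qdat$n <= 8)
    return(structure(list(read_id = read_id, unmappable = TRUE,
                          reason = "too few mapped columns to score"),
                     class = "rearrangement_call"))
  window <- breakpoint_window(map, bundle)
  pop <- if (method == "ga") chc_search(bundle, qdat, window, seed, config)
         else exhaustive_search(bundle, qdat, window)
  call <- call_rearrangement(pop, bundle)
  jn <- rm_$junction
  dcall <- if (nchar(jn$nt) > 0)
    assign_d(jn$nt, bundle$d, scoring = d_scoring, min_score = d_min_score)
  else list(alleles = data.frame(name = character(), orientation = character(),
                                 score = numeric()))
  out <- c(list(read_id = read_id, unmappable = FALSE,
                orientation = map$orientation, frame = map$frame_offset,
                template = map$template_name, map_score = map$score,
                regions = rm_$regions, junction = jn,
                productive = rm_$productive,
                d_call = dcall, n_models = nrow(pop$models),
                best_aicc = pop$best_aicc,
                converged = pop$converged, seed = seed),
           call)
  if (keep_population) out$population <- pop
  structure(out, class = "rearrangement_call")
}

#' Classify a set of reads
#'
#' Reads are independent; any execution order yields identical per-read
#' results. Per-read seeds are derived as `seed + index`.
#'
#' @param reads named character vector of sequences, or a FASTA path
#' @param bundle a `vdj_bundle`
#' @param seed base RNG seed
#' @param use_floor estimate the unmappable score floor from the first read
#'   (dinucleotide-shuffle null) and apply it to all reads
#' @param progress print a dot every 20 reads
#' @inheritParams classify_read
#' @return list of `rearrangement_call` objects, named by read id
#' @export
classify_reads <- function(reads, bundle, seed = 1,
                           method = c("ga", "exhaustive"),
                           config = ga_defaults(), use_floor = FALSE,
                           progress = FALSE, ...) {
  method <- match.arg(method)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fasta(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  bundle <- classifier_prep(bundle)
  floor <- if (use_floor)
    with_seed(seed, mapping_floor(bundle, reads[[1]])) else NULL
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- classify_read(reads[[i]], bundle, read_id = names(reads)[i],
                              seed = seed + i, method = method,
                              config = config, floor = floor, ...)
    if (progress && i %% 20 == 0) cat(".")
  }
  if (progress) cat("\n")
  names(out) <- names(reads)
  out
}
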