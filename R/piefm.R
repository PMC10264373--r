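#' Configuration for a PiEFM run
#'
#' @param n_seed_lps Number of biomass-seeded random-objective LPs solved in
#'   the seeding phase (the paper-style parameter `n`), on top of the
#'   per-reaction coverage pass.
#' @param rng_seed Integer seed; all randomness of a run flows through it.
#' @param biomass Biomass reaction id used for seeding step (b). When `NULL`
#'   the network's recorded biomass reaction is used; when that is also
#'   absent, step (b) falls back to random singleton positive seeds (a
#'   documented deviation switch).
#' @param max_efms Stop after this many distinct EFMs (default unlimited).
#' @param max_time Wall-clock budget in seconds (default unlimited).
#' @param coefficient_range Interval the random positive objective
#'   coefficients are drawn from, uniformly. The lower bound is kept away
#'   from zero so objectives stay well conditioned.
#' @return A `piefm_config` list.
#' @export
piefm_config <- function(n_seed_lps = 0L, rng_seed = 1L, biomass = NULL,
                         max_efms = Inf, max_time = Inf,
                         coefficient_range = c(0.1, 1.0)) {
  stopifnot(n_seed_lps >= 0, length(coefficient_range) == 2,
            all(coefficient_range > 0),
            coefficient_range[1] <= coefficient_range[2])
  structure(list(n_seed_lps = as.integer(n_seed_lps),
                 rng_seed = as.integer(rng_seed),
                 biomass = biomass, max_efms = max_efms,
                 max_time = max_time,
                 coefficient_range = coefficient_range),
            class = "piefm_config")
}

new_trace <- function(net, config) {
  structure(list(collection = efm_collection(net),
                 events = tibble::tibble(step = integer(), efm = integer(),
                                         source = character()),
                 lp_count = 0L, pivot_count = 0L, rank_failures = 0L,
                 skipped_no_irreversible = 0L,
                 config = config, net = net, elapsed = 0),
            class = "piefm_trace")
}

#' @export
print.piefm_trace <- function(x, ...) {
  cat("<piefm_trace> ", length(x$collection), " EFMs | ",
      x$lp_count, " LPs | ", x$pivot_count, " pivots | efficiency ",
      signif(length(x$collection) / max(1L, x$lp_count), 4), "\n", sep = "")
  invisible(x)
}

random_objective <- function(n, range) stats::runif(n, range[1], range[2])

record_event <- function(trace, idx, source) {
  trace$events <- tibble::add_row(trace$events,
                                  step = nrow(trace$events) + 1L,
                                  efm = idx, source = source)
  trace
}

#' Seeding phase: biased LP coverage of the network
#'
#' Step (a): for every reaction `r`, one LP with positive constraint
#' `v[r] = 1` and a randomly weighted minimized objective is solved and its
#' EFM recorded — so every (non-blocked) reaction appears in at least one
#' seed EFM. Step (b): `n_seed_lps` further LPs with the biomass positive
#' constraint and fresh random objectives. Occurrence counts are updated on
#' every solve; duplicates are not re-added.
#'
#' @param net A preprocessed (all-irreversible, non-blocked)
#'   [metabolic_network()].
#' @param config A [piefm_config()].
#' @return A `piefm_trace` (collection + event log + LP/pivot counters).
#' @export
seed_phase <- function(net, config = piefm_config()) {
  stopifnot(inherits(net, "metabolic_network"))
  set.seed(config$rng_seed)
  trace <- new_trace(net, config)
  n <- n_reactions(net)
  t0 <- proc.time()[["elapsed"]]
  for (r in net$reactions) {          # (a) coverage pass, network order
    if (length(trace$collection) >= config$max_efms) break
    lp <- build_lp(net, random_objective(n, config$coefficient_range),
                   sense = "min", positive_seed = r)
    st <- solve_lp(lp)
    trace$lp_count <- trace$lp_count + 1L
    if (st$status != "optimal")
      stop("seeding LP for reaction ", r, " is ", st$status,
           ": the reaction is blocked; preprocess the network first",
           call. = FALSE)
    if (efm_add(trace$collection, st$solution))
      trace <- record_event(trace, length(trace$collection), "seed_coverage")
  }
  biomass <- config$biomass %||% (if (!is.na(net$biomass)) net$biomass)
  for (i in seq_len(config$n_seed_lps)) {   # (b) biomass-seeded pass
    if (length(trace$collection) >= config$max_efms) break
    seed <- biomass %||% sample(net$reactions, 1L)
    lp <- build_lp(net, random_objective(n, config$coefficient_range),
                   sense = "min", positive_seed = seed)
    st <- solve_lp(lp)
    trace$lp_count <- trace$lp_count + 1L
    if (st$status != "optimal")
      stop("biomass seeding LP is ", st$status, call. = FALSE)
    if (efm_add(trace$collection, st$solution))
      trace <- record_event(trace, length(trace$collection), "seed_biomass")
  }
  trace$elapsed <- proc.time()[["elapsed"]] - t0
  trace
}

#' Pick the next EFM to explore
#'
#' Among unexplored EFMs, returns one with the minimal occurrence count
#' (ties broken by earliest discovery) and marks it explored; `NULL` when
#' the queue is exhausted.
#'
#' @param collection An [efm_collection()].
#' @return An `efm` (with its index as attribute `"index"`) or `NULL`.
#' @export
select_next <- function(collection) {
  stopifnot(inherits(collection, "efm_collection"))
  open <- which(!collection$explored)
  if (length(open) == 0L) return(NULL)
  i <- open[which.min(collection$occurrences[open])]  # which.min = earliest tie
  collection$explored[i] <- TRUE
  e <- collection$efms[[i]]
  attr(e, "index") <- i
  e
}

#' Exploration LP anchored at one EFM
#'
#' Builds the LP whose unique optimum (value 0) is the given EFM: positive
#' constraint `sum_{i in I} v[i] = 1` over the originally-irreversible
#' reactions `I` of the EFM's support, minimizing the total flux outside the
#' support. Its final tableau is the launch pad for pivoting to adjacent
#' vertices. Returns `NULL` when `I` is empty (an EFM supported entirely on
#' split reaction copies cannot be anchored this way and is skipped).
#'
#' @param net The preprocessed network.
#' @param efm An `efm` object (or flux vector).
#' @return An `lp_problem`, or `NULL` for the skip signal.
#' @export
exploration_lp <- function(net, efm) {
  if (!inherits(efm, "efm")) efm <- canonicalize_efm(net, efm)
  dirs <- net$origin$direction[match(efm$support_ids, net$origin$reaction)]
  I <- efm$support_ids[dirs == "native"]
  if (length(I) == 0L) return(NULL)
  obj <- rep(1, n_reactions(net))
  obj[efm$support] <- 0
  build_lp(net, obj, sense = "min", positive_seed = I)
}

#' Expansion phase: pivot exploration of the flux cone
#'
#' Repeatedly selects the least-recomputed unexplored EFM, solves its
#' exploration LP, pivots from the optimal tableau to all feasible adjacent
#' vertices, verifies each candidate with the rank test and adds it to the
#' collection (updating occurrence counts). Stops when `max_efms` is
#' reached, `max_time` is exceeded, or the queue is exhausted.
#'
#' @inheritParams seed_phase
#' @param trace The `piefm_trace` returned by [seed_phase()].
#' @return The updated `piefm_trace`.
#' @export
expand_phase <- function(net, trace, config = trace$config) {
  stopifnot(inherits(trace, "piefm_trace"))
  t0 <- proc.time()[["elapsed"]]
  col <- trace$collection
  repeat {
    if (length(col) >= config$max_efms) break
    if (proc.time()[["elapsed"]] - t0 > config$max_time) break
    e <- select_next(col)
    if (is.null(e)) break                        # queue exhausted
    lp <- exploration_lp(net, e)
    if (is.null(lp)) {
      trace$skipped_no_irreversible <- trace$skipped_no_irreversible + 1L
      next
    }
    st <- solve_lp(lp)
    trace$lp_count <- trace$lp_count + 1L
    if (st$status != "optimal") next             # cannot happen on a valid EFM
    for (v in pivot_neighbors(st)) {
      trace$pivot_count <- trace$pivot_count + 1L
      if (max(v) <= 0) next
      if (!is_efm(net, v)) {                     # numerical guard
        trace$rank_failures <- trace$rank_failures + 1L
        warning("pivot candidate failed the rank test; discarded",
                call. = FALSE)
        next
      }
      if (efm_add(col, v)) {
        trace <- record_event(trace, length(col), "pivot")
        if (length(col) >= config$max_efms) break
      }
    }
  }
  trace$elapsed <- trace$elapsed + proc.time()[["elapsed"]] - t0
  trace
}

#' Write / read an extraction trace as JSON-lines
#'
#' One JSON object per discovery event (`step`, `efm` id, `source`,
#' `support`, `occurrences` at end of run), the inter-command contract the
#' metric suite consumes. External tools exporting the same format can be
#' analyzed with the same metrics.
#'
#' @param trace A `piefm_trace`.
#' @param path File path.
#' @return `write_trace_jsonl` returns `path` invisibly; `read_trace_jsonl`
#'   returns a tibble with a `support` list-column, in event order.
#' @export
write_trace_jsonl <- function(trace, path) {
  stopifnot(inherits(trace, "piefm_trace"))
  ev <- trace$events
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    jsonlite::toJSON(list(step = ev$step[i], efm = ev$efm[i],
                          source = ev$source[i],
                          support = trace$collection$efms[[ev$efm[i]]]$support_ids,
                          occurrences = trace$collection$occurrences[ev$efm[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace_jsonl
#' @export
read_trace_jsonl <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  tibble::tibble(
    step = vapply(recs, function(r) as.integer(r$step), integer(1)),
    efm = vapply(recs, function(r) as.integer(r$efm), integer(1)),
    source = vapply(recs, function(r) r$source, character(1)),
    occurrences = vapply(recs, function(r) as.integer(r$occurrences), integer(1)),
    support = lapply(recs, function(r) as.character(r$support)))
}

#' Run the full PiEFM extraction
#'
#' Seeding phase ([seed_phase()]) followed by pivot expansion
#' ([expand_phase()]). Identical configuration and seed give an identical
#' trace.
#'
#' @inheritParams seed_phase
#' @param ... Passed to [piefm_config()] when `config` is not supplied.
#' @param config A [piefm_config()]; overrides `...`.
#' @return A `piefm_trace`.
#' @examples
#' net <- make_diamond()
#' tr <- run_piefm(net, rng_seed = 1)
#' length(tr$collection)   # 2: both pathways through the diamond
#' @export
run_piefm <- function(net, ..., config = piefm_config(...)) {
  trace <- seed_phase(net, config)
  expand_phase(net, trace, config)
}
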