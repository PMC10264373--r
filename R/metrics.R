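#' @title Representativeness and stability metrics
#' @description A biased extractor yields a subset `E'` of the full EFM set
#'   `E`. `E'` is representative for a parameter (mean support length, the
#'   per-reaction proportion `p(r)` of EFMs containing `r`) when the value on
#'   `E'` approximates the value on `E`. When `E` is unavailable the
#'   necessary surrogate is stability: agreement of the parameter between two
#'   prefixes of the same extraction stream. These functions compute both
#'   families from any ordered EFM list (a collection, a trace, or supports
#'   read from the interchange TSV).
#' @name metrics
NULL

# Normalize any EFM carrier into an ordered list of character supports.
as_support_list <- function(x) {
  if (inherits(x, c("efm_collection", "enumeration_result", "piefm_trace")))
    return(lapply(collection_efms(x), function(e) e$support_ids))
  if (is.list(x) && (length(x) == 0L || is.character(x[[1]]) ||
                     inherits(x[[1]], "efm"))) {
    return(lapply(x, function(e) if (inherits(e, "efm")) e$support_ids else e))
  }
  stop("cannot interpret input as an ordered EFM list", call. = FALSE)
}

metric_universe <- function(x, universe) {
  if (!is.null(universe)) return(universe)
  if (inherits(x, c("efm_collection", "enumeration_result", "piefm_trace"))) {
    net <- if (inherits(x, "efm_collection")) x$net else
      if (inherits(x, "enumeration_result")) x$collection$net else x$net
    return(net$reactions)
  }
  sort(unique(unlist(as_support_list(x))))
}

new_trace_tbl <- function(k, value, parameter) {
  out <- tibble::tibble(k = as.numeric(k), value = as.numeric(value))
  class(out) <- c("parameter_trace", class(out))
  attr(out, "parameter") <- parameter
  out
}

default_checkpoints <- function(n, step = 500L, from = min(n, step)) {
  if (n < from) return(numeric())
  unique(c(seq(from, n, by = step), n))
}

#' Trace of the mean support length
#'
#' The value at checkpoint `k` is the mean support length over the first `k`
#' EFMs of the stream — the primary reaction-agnostic representativeness
#' parameter.
#'
#' @param efms Ordered EFMs: an [efm_collection()], extraction trace,
#'   enumeration result, or list of supports.
#' @param checkpoints Increasing integer checkpoints; default every 500 EFMs
#'   (plus the final count).
#' @return A `parameter_trace` tibble with columns `k`, `value`.
#' @export
mean_length_trace <- function(efms, checkpoints = NULL) {
  supp <- as_support_list(efms)
  n <- length(supp)
  checkpoints <- checkpoints %||% default_checkpoints(n)
  stopifnot(all(checkpoints >= 1), all(checkpoints <= n),
            !is.unsorted(checkpoints, strictly = TRUE))
  lens <- cumsum(lengths(supp))
  new_trace_tbl(checkpoints, lens[checkpoints] / checkpoints, "mean_length")
}

#' Per-reaction proportions p(r)
#'
#' `p(r)` is the fraction of EFMs in the list whose support contains `r` —
#' the primary reaction-based representativeness parameter.
#'
#' @inheritParams mean_length_trace
#' @param universe Reaction set `R'` over which proportions are reported;
#'   defaults to the network's reactions (or the union of supports for bare
#'   lists).
#' @return A tibble with columns `reaction`, `p`, in `universe` order.
#' @export
reaction_proportions <- function(efms, universe = NULL) {
  universe <- metric_universe(efms, universe)
  supp <- as_support_list(efms)
  n <- length(supp)
  counts <- table(factor(unlist(supp), levels = universe))
  tibble::tibble(reaction = universe,
                 p = if (n == 0L) rep(NA_real_, length(universe))
                     else as.numeric(counts) / n)
}

as_pmap <- function(p) {
  if (is.data.frame(p)) stats::setNames(p$p, p$reaction)
  else if (!is.null(names(p))) p
  else stop("proportions must be a reaction_proportions tibble or named vector",
            call. = FALSE)
}

#' Mean relative error between two proportion maps
#'
#' `mre(p_est, p_ref) = mean over r in R' of |p_est(r) - p_ref(r)| / p_ref(r)`,
#' always in absolute value. Reactions with zero reference proportion carry
#' an undefined relative error; they are excluded from `R'` and their count
#' attached as attribute `n_zero_ref`.
#'
#' @param p_est,p_ref Proportion maps ([reaction_proportions()] tibbles or
#'   named vectors): the estimate and the reference (denominator).
#' @param universe Reaction set `R'`; defaults to the reference's reactions.
#' @return A single number with attribute `n_zero_ref`.
#' @export
mre <- function(p_est, p_ref, universe = NULL) {
  est <- as_pmap(p_est); ref <- as_pmap(p_ref)
  universe <- universe %||% names(ref)
  missing <- setdiff(universe, names(ref))
  if (length(missing))
    stop("reference proportions missing for: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  r <- unname(ref[universe])
  e <- unname(est[universe])
  e[is.na(e)] <- 0
  ok <- r > 0
  out <- mean(abs(e[ok] - r[ok]) / r[ok])
  attr(out, "n_zero_ref") <- sum(!ok)
  out
}

cumulative_counts <- function(supp, universe, at) {
  # per-reaction containment counts over prefixes of length `at` (sorted)
  counts <- stats::setNames(integer(length(universe)), universe)
  out <- vector("list", length(at))
  ai <- 1L
  for (i in seq_along(supp)) {
    hit <- intersect(supp[[i]], universe)
    counts[hit] <- counts[hit] + 1L
    while (ai <= length(at) && at[ai] == i) { out[[ai]] <- counts; ai <- ai + 1L }
  }
  out
}

#' d-offset stability trace
#'
#' The value at checkpoint `k` is the mean relative error between the
#' proportions over the first `k` EFMs and those over the first `k - d` —
#' the self-comparison that diagnoses whether continuing the extraction
#' still changes the picture. Defined for `k >= 2d` so the reference prefix
#' is meaningful; reactions with `p_{k-d}(r) = 0` are dropped from that
#' checkpoint's average (their number is in the `n_zero_ref` column).
#' Typical offsets: `d = 2000` at core scale, `d = 10000` at genome scale.
#'
#' @inheritParams reaction_proportions
#' @param d Offset (number of EFMs) between the two compared prefixes.
#' @param checkpoints Checkpoints, all `>= 2 * d`; default every 500 from
#'   `2 * d`.
#' @return A `parameter_trace` tibble with columns `k`, `value`,
#'   `n_zero_ref`.
#' @export
stability_trace <- function(efms, d, checkpoints = NULL, universe = NULL) {
  supp <- as_support_list(efms)
  universe <- metric_universe(efms, universe)
  n <- length(supp)
  checkpoints <- checkpoints %||% default_checkpoints(n, from = 2 * d)
  checkpoints <- sort(unique(checkpoints))
  stopifnot(all(checkpoints >= 2 * d), all(checkpoints <= n))
  if (length(checkpoints) == 0L)
    return(new_trace_tbl(numeric(), numeric(), "stability"))
  at <- sort(unique(c(checkpoints, checkpoints - d)))
  snaps <- cumulative_counts(supp, universe, at)
  names(snaps) <- at
  vals <- numeric(length(checkpoints)); nz <- integer(length(checkpoints))
  for (i in seq_along(checkpoints)) {
    k <- checkpoints[i]
    pk <- snaps[[as.character(k)]] / k
    pkd <- snaps[[as.character(k - d)]] / (k - d)
    m <- mre(pk, pkd)
    vals[i] <- m; nz[i] <- attr(m, "n_zero_ref")
  }
  out <- new_trace_tbl(checkpoints, vals, "stability")
  out$n_zero_ref <- nz
  out
}

#' Stopping rule on a stability trace
#'
#' The smallest checkpoint from which `consecutive` successive stability
#' values are all below `threshold` — the point at which the extraction
#' process "can stop", in the sense that its own parameter estimates have
#' stopped moving.
#'
#' @param stability A `parameter_trace` from [stability_trace()] (or any
#'   tibble with `k`, `value`).
#' @param threshold Stability threshold (default 0.05).
#' @param consecutive Required run length of sub-threshold checkpoints.
#' @return The checkpoint `k` starting the run, or `NA` if none.
#' @export
stopping_index <- function(stability, threshold = 0.05, consecutive = 3L) {
  v <- stability$value
  m <- length(v) - consecutive + 1L
  if (m >= 1L) {
    for (i in seq_len(m)) {
      if (all(v[i:(i + consecutive - 1L)] < threshold))
        return(stability$k[i])
    }
  }
  NA_real_
}

#' Reactions compatible with a given reaction
#'
#' Two reactions are compatible when at least one EFM contains both in its
#' support. Returns the union of supports of all EFMs containing `r` (so
#' `r` itself is included iff it occurs). The count of reactions compatible
#' with the biomass reaction is the variability metric: a small count flags
#' a highly biased, self-similar EFM sample.
#'
#' @inheritParams mean_length_trace
#' @param r Reaction id.
#' @return Character vector of compatible reactions (possibly empty).
#' @export
compatible_reactions <- function(efms, r) {
  supp <- as_support_list(efms)
  hit <- supp[vapply(supp, function(s) r %in% s, logical(1))]
  as.character(sort(unique(unlist(hit))))
}

#' Partial-coupling classes from a complete enumeration
#'
#' Reactions are partially coupled when each appears in the support of
#' exactly the same EFMs. Over a complete enumeration, the classes are the
#' equivalence classes of identical indicator patterns across all EFMs;
#' reactions in singleton classes are the non-partially-coupled ones used
#' by the coupling-corrected error analysis.
#'
#' @param efms A complete enumeration (documented requirement — the classes
#'   are only meaningful over the full set).
#' @param universe Reaction set to partition; defaults to the network's
#'   reactions.
#' @return A tibble with columns `reaction`, `class`, `class_size`.
#' @export
coupled_classes <- function(efms, universe = NULL) {
  universe <- metric_universe(efms, universe)
  supp <- as_support_list(efms)
  pattern <- vapply(universe, function(r)
    paste(vapply(supp, function(s) r %in% s, logical(1)), collapse = ""),
    character(1))
  cls <- match(pattern, unique(pattern))
  size <- as.integer(table(cls)[as.character(cls)])
  tibble::tibble(reaction = universe, class = cls, class_size = size)
}

#' Drop or collapse partially coupled reactions
#'
#' Helper for the coupling-corrected error analysis. `mode = "drop"`
#' (default) removes every member of a non-singleton coupling class;
#' `mode = "representative"` keeps the first member of each class.
#'
#' @inheritParams coupled_classes
#' @param mode `"drop"` or `"representative"`.
#' @return Character vector of retained reactions.
#' @export
uncoupled_reactions <- function(efms, universe = NULL,
                                mode = c("drop", "representative")) {
  mode <- match.arg(mode)
  cc <- coupled_classes(efms, universe)
  if (mode == "drop") cc$reaction[cc$class_size == 1L]
  else cc$reaction[!duplicated(cc$class)]
}

#' Simulate k-shortest / k-largest extraction by sorting
#'
#' Given a complete enumeration, returns the first `k` EFMs after a stable
#' sort by support length (ascending for `"shortest"`, descending for
#' `"largest"`; ties keep enumeration order). This simulates
#' length-ordered extraction methods without running them.
#'
#' @inheritParams mean_length_trace
#' @param order `"shortest"` or `"largest"`.
#' @param k Number of EFMs to keep.
#' @return A list of supports (ordered), usable by all metric functions.
#' @export
simulate_k_extreme <- function(efms, order = c("shortest", "largest"), k) {
  order <- match.arg(order)
  supp <- as_support_list(efms)
  stopifnot(k >= 1, k <= length(supp))
  len <- lengths(supp)
  idx <- if (order == "shortest") base::order(len) else base::order(-len)
  supp[idx[seq_len(k)]]
}

#' Jaccard distance between consecutive EFMs
#'
#' The value at step `i` (reported at `k = i + 1`) is
#' `1 - |supp_i int supp_{i+1}| / |supp_i un supp_{i+1}|`: near-zero runs
#' reveal an extractor emitting near-duplicate EFMs.
#'
#' @inheritParams mean_length_trace
#' @return A `parameter_trace` tibble with columns `k`, `value`.
#' @export
jaccard_trace <- function(efms) {
  supp <- as_support_list(efms)
  n <- length(supp)
  stopifnot(n >= 2)
  vals <- vapply(seq_len(n - 1L), function(i) {
    1 - length(intersect(supp[[i]], supp[[i + 1L]])) /
      length(union(supp[[i]], supp[[i + 1L]]))
  }, numeric(1))
  new_trace_tbl(2:n, vals, "jaccard")
}
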