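.support_tol <- 1e-7   # on the canonical (max = 1) scale
.rank_rtol <- 1e-9     # singular values > rtol * largest count toward rank

#' Support of a flux vector
#'
#' The support of a mode is the set of reactions carrying flux above
#' tolerance.
#'
#' @param v Numeric flux vector (named by reaction or positional).
#' @param tol Threshold below which a flux is treated as zero.
#' @return Character vector of reaction ids when `v` is named, else integer
#'   indices.
#' @export
support_of <- function(v, tol = .support_tol) {
  idx <- which(v > tol)
  if (!is.null(names(v))) names(v)[idx] else idx
}

numeric_rank <- function(M, rtol = .rank_rtol) {
  if (length(M) == 0L || all(M == 0)) return(0L)
  sv <- svd(M, nu = 0, nv = 0)$d
  sum(sv > rtol * sv[1])
}

#' Test whether a mode is elementary (rank characterization)
#'
#' A mode `v` (with `S v = 0`, `v >= 0`, `v != 0`) is an elementary flux mode
#' iff the submatrix of `S` restricted to the columns of `supp(v)` (and the
#' rows of metabolites occurring in those columns) has rank `|supp(v)| - 1`.
#' Rank is computed from singular values with a relative threshold of
#' `1e-9` times the largest.
#'
#' @param net A [metabolic_network()].
#' @param v Numeric flux vector over the network's reactions.
#' @param tol Support tolerance, applied after scaling `v` to max = 1.
#' @return `TRUE` iff the rank test passes.
#' @export
is_efm <- function(net, v, tol = .support_tol) {
  stopifnot(inherits(net, "metabolic_network"))
  v <- as_flux(net, v)
  if (all(v == 0)) stop("the zero vector is not a mode", call. = FALSE)
  supp <- which(v / max(v) > tol)
  k <- length(supp)
  Sv <- net$S[, supp, drop = FALSE]
  Sv <- Sv[rowSums(abs(Sv)) > 0, , drop = FALSE]
  numeric_rank(Sv) == k - 1L
}

as_flux <- function(net, v) {
  if (inherits(v, "efm")) return(v$flux)
  if (!is.null(names(v))) {
    out <- rep(0, n_reactions(net))
    out[rxn_index(net, names(v))] <- unname(v)
    names(out) <- net$reactions
    out
  } else {
    stopifnot(length(v) == n_reactions(net))
    v <- as.numeric(v)
    names(v) <- net$reactions
    v
  }
}

#' Canonicalize a flux vector into an EFM object
#'
#' Scales the flux so its maximum component is 1 (the canonical scale),
#' zeroes components below the support tolerance, and records the support.
#' By the rank characterization the solution space over a fixed elementary
#' support is one-dimensional, so the support is a sound identity key; flux
#' values are kept for reporting.
#'
#' @inheritParams is_efm
#' @return An object of class `efm` with fields `flux`, `support` (integer
#'   indices), `support_ids`, `length`.
#' @export
canonicalize_efm <- function(net, v, tol = .support_tol) {
  v <- as_flux(net, v)
  mx <- max(v)
  if (mx <= 0) stop("cannot canonicalize the zero vector", call. = FALSE)
  flux <- v / mx
  flux[flux <= tol] <- 0
  support <- which(flux > 0)
  structure(list(flux = flux, support = support,
                 support_ids = net$reactions[support],
                 length = length(support)),
            class = "efm")
}

#' @export
print.efm <- function(x, ...) {
  cat("<efm> length ", x$length, ": ",
      paste(x$support_ids, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Detect the futile two-cycle artifact of reversible splitting
#'
#' Splitting a reversible reaction into forward/backward copies creates a
#' spurious length-2 EFM `{r_fwd, r_bwd}` that passes the rank test but has
#' no biological meaning. Collections exclude these by default.
#'
#' @param net A [metabolic_network()] (with origin records from splitting).
#' @param efm An `efm` object or flux vector.
#' @return `TRUE` iff the support is exactly the forward+backward pair of
#'   one original reversible reaction.
#' @export
is_futile_pair <- function(net, efm) {
  if (!inherits(efm, "efm")) efm <- canonicalize_efm(net, efm)
  if (efm$length != 2L) return(FALSE)
  o <- net$origin[match(efm$support_ids, net$origin$reaction), ]
  o$original_id[1] == o$original_id[2] &&
    setequal(o$direction, c("forward", "backward"))
}

#' Create an EFM collection
#'
#' An ordered multiset of EFMs keyed by support: discovery order, occurrence
#' counts (how many times each EFM was recomputed) and an explored flag per
#' EFM. The collection is a mutable reference object so the extraction loop
#' can update counts in place.
#'
#' @param net The [metabolic_network()] the EFMs live on.
#' @param keep_futile Keep futile two-cycles? Default drops them.
#' @return An object of class `efm_collection`.
#' @export
efm_collection <- function(net, keep_futile = FALSE) {
  col <- new.env(parent = emptyenv())
  col$net <- net
  col$efms <- list()
  col$occurrences <- integer()
  col$explored <- logical()
  col$keep_futile <- keep_futile
  col$index <- new.env(parent = emptyenv(), hash = TRUE)
  class(col) <- "efm_collection"
  col
}

#' Add an EFM to a collection
#'
#' If the support is already present its occurrence count is incremented and
#' `FALSE` is returned; otherwise the EFM is appended (occurrence 1,
#' unexplored) and `TRUE` is returned. Futile two-cycles are rejected
#' unless the collection keeps them.
#'
#' @param collection An [efm_collection()].
#' @param v An `efm` object or flux vector.
#' @return Logical: was the EFM new?
#' @export
efm_add <- function(collection, v) {
  stopifnot(inherits(collection, "efm_collection"))
  e <- if (inherits(v, "efm")) v else canonicalize_efm(collection$net, v)
  if (!collection$keep_futile && is_futile_pair(collection$net, e))
    return(FALSE)
  key <- support_key(e$support)
  hit <- collection$index[[key]]
  if (!is.null(hit)) {
    collection$occurrences[hit] <- collection$occurrences[hit] + 1L
    return(FALSE)
  }
  k <- length(collection$efms) + 1L
  collection$efms[[k]] <- e
  collection$occurrences[k] <- 1L
  collection$explored[k] <- FALSE
  collection$index[[key]] <- k
  TRUE
}

#' @export
length.efm_collection <- function(x) length(x$efms)

#' @export
print.efm_collection <- function(x, ...) {
  cat("<efm_collection> ", length(x$efms), " EFMs on ",
      n_reactions(x$net), " reactions\n", sep = "")
  invisible(x)
}

#' List of supports in a collection
#' @param collection An [efm_collection()] or list of `efm` objects.
#' @return List of character vectors (reaction ids), discovery order.
#' @export
efm_supports <- function(collection) {
  lapply(collection_efms(collection), function(e) e$support_ids)
}

collection_efms <- function(x) {
  if (inherits(x, "efm_collection")) x$efms
  else if (inherits(x, "enumeration_result")) x$collection$efms
  else if (inherits(x, "piefm_trace")) x$collection$efms
  else x
}

#' Write / read the EFM interchange TSV
#'
#' One row per EFM: the reaction ids of its support, tab-separated. This is
#' the interchange surface between the extractor and the metric suite (and
#' any external tool exporting the same format).
#'
#' @param collection An [efm_collection()], enumeration or extraction result.
#' @param path File path.
#' @param header Optional character vector written as leading `#` comment
#'   lines (e.g. serialized run configuration, for provenance).
#' @return `write_efm_tsv` returns `path` invisibly; `read_efm_tsv` returns
#'   a list of character supports (`#` comment lines are skipped).
#' @export
write_efm_tsv <- function(collection, path, header = NULL) {
  lines <- vapply(efm_supports(collection), paste, "", collapse = "\t")
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_efm_tsv
#' @export
read_efm_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  strsplit(lines, "\t", fixed = TRUE)
}
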