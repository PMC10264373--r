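#' Construct a metabolic network
#'
#' A metabolic network is a triple (M, R, S): a set of internal metabolites M,
#' a set of reactions R, and a stoichiometric matrix `S` with one row per
#' metabolite and one column per reaction. Reversibility is carried per
#' reaction; after [split_reversible()] every reaction is irreversible and the
#' flux cone is `C = {v : S v = 0, v >= 0}`.
#'
#' @param S Numeric matrix, metabolites x reactions. Row and column names are
#'   used as metabolite and reaction identifiers when present.
#' @param reversible Logical vector, one entry per reaction (column of `S`).
#' @param metabolites,reactions Character identifiers; default to the
#'   dimnames of `S` or generated `M1..`/`R1..` names.
#' @param biomass Optional identifier of the biomass reaction.
#' @param origin Optional tibble tracking reversible splitting, with columns
#'   `reaction`, `original_id`, `direction` (one of `"forward"`, `"backward"`,
#'   `"native"`). Populated automatically by [split_reversible()].
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(S, reversible = rep(FALSE, ncol(S)),
                              metabolites = NULL, reactions = NULL,
                              biomass = NULL, origin = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (is.null(metabolites)) {
    metabolites <- rownames(S) %||% paste0("M", seq_len(nrow(S)))
  }
  if (is.null(reactions)) {
    reactions <- colnames(S) %||% paste0("R", seq_len(ncol(S)))
  }
  if (length(metabolites) != nrow(S))
    stop("length(metabolites) must equal nrow(S)", call. = FALSE)
  if (length(reactions) != ncol(S))
    stop("length(reactions) must equal ncol(S)", call. = FALSE)
  if (anyDuplicated(metabolites))
    stop("duplicate metabolite identifiers", call. = FALSE)
  if (anyDuplicated(reactions))
    stop("duplicate reaction identifiers", call. = FALSE)
  if (length(reversible) != ncol(S))
    stop("length(reversible) must equal ncol(S)", call. = FALSE)
  if (!is.null(biomass) && !is.na(biomass) && !biomass %in% reactions)
    stop("biomass reaction '", biomass, "' not among reactions", call. = FALSE)
  dimnames(S) <- list(metabolites, reactions)
  if (is.null(origin)) {
    origin <- tibble::tibble(reaction = reactions,
                             original_id = reactions,
                             direction = "native")
  }
  structure(
    list(S = S,
         metabolites = metabolites,
         reactions = reactions,
         reversible = as.logical(reversible),
         origin = origin,
         biomass = if (is.null(biomass)) NA_character_ else biomass),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", sum(x$reversible),
      " reversible)\n", sep = "")
  if (!is.na(x$biomass)) cat("  biomass: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolic_network <- function(x) dim(x$S)

n_reactions <- function(net) length(net$reactions)
n_metabolites <- function(net) length(net$metabolites)

rxn_index <- function(net, id) {
  i <- match(id, net$reactions)
  if (anyNA(i)) stop("unknown reaction(s): ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Split reversible reactions into forward/backward pairs
#'
#' Every reversible reaction `r` is decoupled into two irreversible reactions
#' `r_fwd` (same column) and `r_bwd` (negated column), placed adjacently in
#' the original column order so runs are reproducible. The origin table links
#' both back to the parent reaction; irreversible reactions pass through with
#' direction `"native"`.
#'
#' @param net A [metabolic_network()].
#' @return An all-irreversible `metabolic_network`.
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!any(net$reversible)) return(net)
  cols <- list(); ids <- character(); orig <- list()
  bio <- net$biomass
  for (j in seq_along(net$reactions)) {
    id <- net$reactions[j]
    if (net$reversible[j]) {
      fid <- paste0(id, "_fwd"); bid <- paste0(id, "_bwd")
      cols[[length(cols) + 1L]] <- net$S[, j]
      cols[[length(cols) + 1L]] <- -net$S[, j]
      ids <- c(ids, fid, bid)
      orig[[length(orig) + 1L]] <- c(fid, id, "forward")
      orig[[length(orig) + 1L]] <- c(bid, id, "backward")
      if (!is.na(bio) && bio == id) bio <- fid
    } else {
      cols[[length(cols) + 1L]] <- net$S[, j]
      ids <- c(ids, id)
      orig[[length(orig) + 1L]] <- c(id, id, "native")
    }
  }
  S2 <- do.call(cbind, cols)
  om <- do.call(rbind, orig)
  origin <- tibble::tibble(reaction = om[, 1], original_id = om[, 2],
                           direction = om[, 3])
  metabolic_network(S2, reversible = rep(FALSE, ncol(S2)),
                    metabolites = net$metabolites, reactions = ids,
                    biomass = if (is.na(bio)) NULL else bio, origin = origin)
}

#' Merge split directions back into signed reversible columns
#'
#' Inverse of [split_reversible()]: forward/backward column pairs are
#' collapsed onto the parent reaction (the forward column), restoring the
#' original stoichiometric matrix exactly.
#'
#' @param net A split `metabolic_network`.
#' @return A `metabolic_network` in the original reversible form.
#' @export
merge_directions <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  keep <- net$origin$direction != "backward"
  S2 <- net$S[, keep, drop = FALSE]
  ids <- net$origin$original_id[keep]
  rev <- ids %in% net$origin$original_id[net$origin$direction == "backward"]
  bio <- net$biomass
  if (!is.na(bio)) bio <- net$origin$original_id[match(bio, net$origin$reaction)]
  metabolic_network(S2, reversible = rev, metabolites = net$metabolites,
                    reactions = ids,
                    biomass = if (is.na(bio)) NULL else bio)
}

#' Detect blocked reactions
#'
#' A reaction is blocked when it carries zero flux in every steady-state mode.
#' Detection is FVA-style: for each reaction the LP `max v[r]` subject to
#' `S v = 0`, `0 <= v <= 1` is solved (unit box bounds keep the cone bounded);
#' `r` is blocked iff the optimum is at most `tol`. Reactions seen active in
#' an earlier optimum are skipped.
#'
#' @param net An all-irreversible [metabolic_network()].
#' @param tol Blocking tolerance on the boxed optimum.
#' @return Character vector of blocked reaction identifiers (possibly empty).
#' @export
find_blocked <- function(net, tol = 1e-9) {
  stopifnot(inherits(net, "metabolic_network"))
  if (any(net$reversible))
    stop("find_blocked expects an all-irreversible network; call split_reversible() first",
         call. = FALSE)
  n <- n_reactions(net)
  if (n == 0L) return(character())
  # boxed cone: variables [v; s], constraints S v = 0 and v + s = 1
  A <- rbind(cbind(net$S, matrix(0, nrow(net$S), n)),
             cbind(diag(n), diag(n)))
  b <- c(rep(0, nrow(net$S)), rep(1, n))
  seen_active <- rep(FALSE, n)
  blocked <- logical(n)
  for (j in seq_len(n)) {
    if (seen_active[j]) next
    cc <- rep(0, 2L * n); cc[j] <- -1  # maximize v_j
    st <- simplex_solve(A, b, cc)
    if (st$status != "optimal")
      stop("LP solver failed while probing reaction ", net$reactions[j],
           call. = FALSE)
    v <- st$solution[seq_len(n)]
    seen_active <- seen_active | (v > tol)
    blocked[j] <- v[j] <= tol
  }
  net$reactions[blocked]
}

#' Remove blocked reactions (and orphaned metabolites)
#'
#' Deletes all blocked reactions, then drops metabolites that no longer occur
#' in any remaining reaction. Origin records are preserved.
#'
#' @inheritParams find_blocked
#' @return A `metabolic_network` with [find_blocked()] empty.
#' @export
remove_blocked <- function(net, tol = 1e-9) {
  blocked <- find_blocked(net, tol = tol)
  if (length(blocked) == 0L) return(net)
  keep <- !(net$reactions %in% blocked)
  if (!any(keep))
    stop("all reactions are blocked: empty network", call. = FALSE)
  S2 <- net$S[, keep, drop = FALSE]
  used <- rowSums(abs(S2)) > 0
  S2 <- S2[used, , drop = FALSE]
  bio <- net$biomass
  if (!is.na(bio) && !(bio %in% net$reactions[keep])) bio <- NA_character_
  metabolic_network(S2, reversible = net$reversible[keep],
                    metabolites = net$metabolites[used],
                    reactions = net$reactions[keep],
                    biomass = if (is.na(bio)) NULL else bio,
                    origin = net$origin[net$origin$reaction %in% net$reactions[keep], ])
}

#' Preprocess a network into the all-irreversible, non-blocked form
#'
#' Convenience pipeline: [split_reversible()] then [remove_blocked()]. All
#' downstream machinery (LP seeding, pivot expansion, enumeration) assumes
#' this form.
#'
#' @inheritParams find_blocked
#' @return A preprocessed `metabolic_network`.
#' @export
preprocess_network <- function(net, tol = 1e-9) {
  remove_blocked(split_reversible(net), tol = tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
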