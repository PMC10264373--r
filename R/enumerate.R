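#' Exact EFM enumeration
#'
#' Two independent routes to the complete EFM set of a small-to-medium
#' all-irreversible network: a nullspace-style double description method
#' (`method = "ddm"`, the workhorse) and a brute-force oracle over candidate
#' supports (`method = "bruteforce"`, the ground truth for testing). Both
#' return the same supports on networks small enough for the brute force.
#'
#' @param net An all-irreversible, non-blocked [metabolic_network()].
#' @param method `"ddm"` or `"bruteforce"`.
#' @param keep_futile Keep futile two-cycles from reversible splitting?
#' @param ... Passed to the method (`max_rays` for ddm; `max_support` for
#'   bruteforce).
#' @return An object of class `enumeration_result`: fields `collection`
#'   (an [efm_collection()]), `method`, `certified_max_size`, `n_futile`.
#' @export
enumerate_efms <- function(net, method = c("ddm", "bruteforce"),
                           keep_futile = FALSE, ...) {
  method <- match.arg(method)
  switch(method,
         ddm = enumerate_ddm(net, keep_futile = keep_futile, ...),
         bruteforce = enumerate_bruteforce(net, keep_futile = keep_futile, ...))
}

new_enumeration_result <- function(net, fluxes, method, certified, keep_futile) {
  col <- efm_collection(net, keep_futile = keep_futile)
  n_futile <- 0L
  for (v in fluxes) {
    e <- canonicalize_efm(net, v)
    if (is_futile_pair(net, e)) n_futile <- n_futile + 1L
    efm_add(col, e)
  }
  structure(list(collection = col, method = method,
                 certified_max_size = certified, n_futile = n_futile),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("<enumeration_result> ", length(x$collection), " EFMs (method: ",
      x$method, ", futile two-cycles seen: ", x$n_futile, ")\n", sep = "")
  invisible(x)
}

#' @export
length.enumeration_result <- function(x) length(x$collection)

#' Double description enumeration of the flux cone's extreme rays
#'
#' Starts from the unit rays of the positive orthant and intersects with one
#' steady-state (metabolite) constraint at a time: rays on the hyperplane are
#' kept, and each adjacent plus/minus pair is combined into a new ray on it.
#' Adjacency uses the combinatorial test (no third ray's zero set contains
#' the pair's common zero set). Rows are processed in order of fewest
#' plus-minus combinations. The surviving rays are the extreme rays of
#' `{v : S v = 0, v >= 0}` — exactly the EFMs.
#'
#' @inheritParams enumerate_efms
#' @param max_rays Abort if the intermediate ray count exceeds this cap.
#' @param tol Zero tolerance on normalized ray components.
#' @rdname enumerate_efms
#' @export
enumerate_ddm <- function(net, keep_futile = FALSE, max_rays = 1e5, tol = 1e-9) {
  stopifnot(inherits(net, "metabolic_network"))
  if (any(net$reversible))
    stop("enumerate_ddm expects an all-irreversible network", call. = FALSE)
  n <- n_reactions(net)
  rays <- diag(n)                      # columns are rays
  todo <- seq_len(n_metabolites(net))
  while (length(todo)) {
    vals <- net$S[todo, , drop = FALSE] %*% rays
    npos <- rowSums(vals > tol); nneg <- rowSums(vals < -tol)
    pick <- which.min(npos * nneg)
    row <- todo[pick]; todo <- todo[-pick]
    s <- vals[pick, ]
    zero <- which(abs(s) <= tol)
    plus <- which(s > tol)
    minus <- which(s < -tol)
    keep <- rays[, zero, drop = FALSE]
    if (length(plus) && length(minus)) {
      zsets <- lapply(seq_len(ncol(rays)),
                      function(j) which(rays[, j] <= tol))
      newcols <- list()
      for (p in plus) for (q in minus) {
        common <- intersect(zsets[[p]], zsets[[q]])
        adjacent <- TRUE
        for (r in seq_len(ncol(rays))) {
          if (r == p || r == q) next
          if (all(common %in% zsets[[r]])) { adjacent <- FALSE; break }
        }
        if (!adjacent) next
        z <- s[p] * rays[, q] - s[q] * rays[, p]
        z <- z / max(z)
        z[z <= tol] <- 0
        newcols[[length(newcols) + 1L]] <- z
      }
      if (length(newcols))
        keep <- cbind(keep, do.call(cbind, newcols))
    }
    if (ncol(keep) == 0L)
      stop("flux cone is trivial: no ray satisfies all steady-state constraints",
           call. = FALSE)
    if (ncol(keep) > max_rays)
      stop("intermediate ray count ", ncol(keep), " exceeds max_rays = ",
           max_rays, call. = FALSE)
    rays <- keep
  }
  fluxes <- lapply(seq_len(ncol(rays)), function(j) rays[, j])
  new_enumeration_result(net, fluxes, "nullspace_ddm", Inf, keep_futile)
}

#' Brute-force oracle over candidate supports
#'
#' Tests every support subset up to `max_support` directly against the rank
#' characterization: `rank(S_supp) = |supp| - 1` and the one-dimensional
#' kernel of `S_supp` admits a sign-constant vector nonzero on all of the
#' support. Independent of the double description path (no ray arithmetic),
#' so it serves as its oracle. Guarded to small networks.
#'
#' @inheritParams enumerate_efms
#' @param max_support Largest support size searched; defaults to all
#'   reactions.
#' @rdname enumerate_efms
#' @export
enumerate_bruteforce <- function(net, keep_futile = FALSE, max_support = NULL,
                                 tol = 1e-9) {
  stopifnot(inherits(net, "metabolic_network"))
  n <- n_reactions(net)
  max_support <- max_support %||% n
  if (n > 22L && max_support >= n)
    stop("brute force guarded to <= 22 reactions (or bound max_support)",
         call. = FALSE)
  found <- list()        # integer supports of accepted EFMs, for pruning
  fluxes <- list()
  for (k in seq_len(min(max_support, n))) {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      supp <- combos[, ci]
      skip <- FALSE
      for (f in found) if (all(f %in% supp)) { skip <- TRUE; break }
      if (skip) next                   # a superset of an EFM is never elementary
      Sv <- net$S[, supp, drop = FALSE]
      Sv <- Sv[rowSums(abs(Sv)) > 0, , drop = FALSE]
      if (nrow(Sv) == 0L) Sv <- matrix(0, 1, k)
      if (numeric_rank(Sv) != k - 1L) next
      kern <- svd(Sv, nu = 0, nv = k)$v[, k]
      if (any(abs(kern) <= tol)) next  # kernel vector must cover the support
      if (max(kern) * min(kern) < 0) next   # must be sign-constant
      v <- rep(0, n)
      v[supp] <- abs(kern)
      found[[length(found) + 1L]] <- supp
      fluxes[[length(fluxes) + 1L]] <- v
    }
  }
  new_enumeration_result(net, fluxes, "support_bruteforce",
                         min(max_support, n), keep_futile)
}
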