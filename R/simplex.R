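#' @title Tableau simplex engine
#' @description Dense two-phase primal simplex with Bland's anti-cycling rule.
#'   The final tableau is kept so that post-optimal pivots can enumerate
#'   adjacent vertices of the feasible polytope — the step the pivot-expansion
#'   phase of the extraction algorithm relies on. A bespoke engine (rather
#'   than an external solver) keeps the tableau accessible and the pivot
#'   order deterministic.
#' @name simplex-engine
#' @keywords internal
NULL

.zero_tol <- 1e-9   # pivot / entering-column tolerance
.feas_tol <- 1e-7   # feasibility tolerance on basic solutions

# Run Bland-rule simplex iterations on a canonical tableau.
# T: (m+1) x (p+1) matrix, objective (reduced-cost) row last, RHS column last.
# Returns list(T, basis, status) with status "optimal" or "unbounded".
bland_iterate <- function(T, basis, allowed, max_iter = 1e5L) {
  m <- nrow(T) - 1L
  p <- ncol(T) - 1L
  obj <- m + 1L
  rhs <- p + 1L
  for (it in seq_len(max_iter)) {
    cand <- allowed[T[obj, allowed] < -.zero_tol]
    if (length(cand) == 0L)
      return(list(T = T, basis = basis, status = "optimal"))
    j <- min(cand)                              # Bland: smallest index enters
    col <- T[seq_len(m), j]
    pos <- which(col > .zero_tol)
    if (length(pos) == 0L)
      return(list(T = T, basis = basis, status = "unbounded"))
    ratio <- T[pos, rhs] / col[pos]
    theta <- min(ratio)
    tie <- pos[ratio <= theta + .zero_tol]
    i <- tie[which.min(basis[tie])]             # Bland: smallest basic leaves
    T[i, ] <- T[i, ] / T[i, j]
    other <- setdiff(seq_len(m + 1L), i)
    T[other, ] <- T[other, ] - outer(T[other, j], T[i, ])
    T[, j] <- 0; T[i, j] <- 1                   # kill round-off in pivot col
    basis[i] <- j
  }
  stop("simplex iteration guard exceeded (possible numerical cycling)",
       call. = FALSE)
}

# Solve min c'x s.t. A x = b, x >= 0 by the two-phase tableau method.
# Returns list(status, solution, objective, tableau, basis, nonbasic).
# The stored tableau has only the structural columns (plus RHS); artificial
# variables never survive into it.
simplex_solve <- function(A, b, cost) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cost) == n)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  # phase 1: artificials with unit cost
  T <- matrix(0, m + 1L, n + m + 1L)
  T[seq_len(m), seq_len(n)] <- A
  T[seq_len(m), n + seq_len(m)] <- diag(m)
  T[seq_len(m), n + m + 1L] <- b
  basis <- n + seq_len(m)
  T[m + 1L, seq_len(n)] <- -colSums(A)
  T[m + 1L, n + m + 1L] <- -sum(b)
  res <- bland_iterate(T, basis, allowed = seq_len(n + m))
  if (res$status != "optimal" || -res$T[m + 1L, n + m + 1L] > .feas_tol)
    return(list(status = "infeasible", solution = rep(0, n),
                objective = NA_real_, tableau = NULL, basis = integer()))
  T <- res$T; basis <- res$basis

  # drive remaining artificials out of the basis; redundant rows are dropped
  drop_rows <- integer()
  for (i in seq_len(m)) {
    if (basis[i] <= n) next
    piv <- which(abs(T[i, seq_len(n)]) > .zero_tol)
    piv <- setdiff(piv, basis)
    if (length(piv) == 0L) { drop_rows <- c(drop_rows, i); next }
    j <- piv[1L]
    T[i, ] <- T[i, ] / T[i, j]
    other <- setdiff(seq_len(m + 1L), i)
    T[other, ] <- T[other, ] - outer(T[other, j], T[i, ])
    T[, j] <- 0; T[i, j] <- 1
    basis[i] <- j
  }
  if (length(drop_rows)) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  m2 <- length(basis)
  T <- T[, c(seq_len(n), n + m + 1L), drop = FALSE]   # shed artificial columns

  # phase 2: restore the true objective row
  T[m2 + 1L, ] <- 0
  T[m2 + 1L, seq_len(n)] <- cost
  for (i in seq_len(m2))
    T[m2 + 1L, ] <- T[m2 + 1L, ] - cost[basis[i]] * T[i, ]
  res <- bland_iterate(T, basis, allowed = seq_len(n))
  if (res$status == "unbounded")
    return(list(status = "unbounded", solution = rep(0, n),
                objective = -Inf, tableau = NULL, basis = integer()))
  T <- res$T; basis <- res$basis
  x <- rep(0, n)
  x[basis] <- T[seq_len(m2), n + 1L]
  x[x < 0 & x > -.feas_tol] <- 0
  list(status = "optimal", solution = x,
       objective = sum(cost * x),
       tableau = T[seq_len(m2), , drop = FALSE],
       basis = basis,
       nonbasic = setdiff(seq_len(n), basis))
}

#' Build an LP over the flux cone
#'
#' Encodes the clean LP `optimize f = sum a_i v[i]` subject to `S v = 0`,
#' `v >= 0`, optionally extended with a positive seed constraint
#' `sum_{T1} v[i] = 1` (forces at least one reaction of `T1` active) and/or a
#' negative seed constraint `sum_{T2} v[i] = 0` (forbids all of `T2`). With a
#' single positive seed, non-negative coefficients and minimization, the
#' optimum is a vertex of the constrained cone and hence an elementary flux
#' mode after scaling.
#'
#' @param net A [metabolic_network()].
#' @param objective Numeric vector of coefficients `a_i`, either of length
#'   `n_reactions` or named by reaction; missing reactions get 0. Default:
#'   all ones.
#' @param sense `"min"` or `"max"`.
#' @param positive_seed,negative_seed Character vectors of reaction ids for
#'   the seed constraints. `positive_seed`, when given, must be non-empty.
#' @return An object of class `lp_problem`.
#' @export
build_lp <- function(net, objective = NULL, sense = c("min", "max"),
                     positive_seed = NULL, negative_seed = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  sense <- match.arg(sense)
  n <- n_reactions(net)
  if (is.null(objective)) {
    obj <- rep(1, n)
  } else if (!is.null(names(objective))) {
    obj <- rep(0, n)
    obj[rxn_index(net, names(objective))] <- unname(objective)
  } else {
    stopifnot(length(objective) == n)
    obj <- as.numeric(objective)
  }
  if (any(!is.finite(obj))) stop("objective coefficients must be finite", call. = FALSE)
  if (!is.null(positive_seed)) {
    if (length(positive_seed) == 0L)
      stop("positive seed must be non-empty (an empty positive constraint is unsatisfiable)",
           call. = FALSE)
    rxn_index(net, positive_seed)
  }
  if (!is.null(negative_seed) && length(negative_seed)) rxn_index(net, negative_seed)
  structure(list(net = net, objective = obj, sense = sense,
                 positive_seed = positive_seed,
                 negative_seed = negative_seed),
            class = "lp_problem")
}

#' Solve a flux-cone LP
#'
#' Runs the two-phase tableau simplex on the problem built by [build_lp()]
#' and returns the final state: status, vertex solution, objective, and the
#' optimal tableau/basis needed by [pivot_neighbors()].
#'
#' @param lp An `lp_problem`.
#' @return An object of class `simplex_state` with fields `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `solution` (named flux
#'   vector), `objective`, `tableau`, `basis`, `nonbasic`.
#' @export
solve_lp <- function(lp) {
  stopifnot(inherits(lp, "lp_problem"))
  net <- lp$net
  n <- n_reactions(net)
  A <- net$S
  b <- rep(0, nrow(A))
  if (!is.null(lp$positive_seed)) {
    row <- rep(0, n); row[rxn_index(net, lp$positive_seed)] <- 1
    A <- rbind(A, row); b <- c(b, 1)
  }
  if (!is.null(lp$negative_seed) && length(lp$negative_seed)) {
    row <- rep(0, n); row[rxn_index(net, lp$negative_seed)] <- 1
    A <- rbind(A, row); b <- c(b, 0)
  }
  cost <- if (lp$sense == "max") -lp$objective else lp$objective
  st <- simplex_solve(A, b, cost)
  sol <- st$solution
  names(sol) <- net$reactions
  structure(list(status = st$status, solution = sol,
                 objective = if (lp$sense == "max") -st$objective else st$objective,
                 tableau = st$tableau, basis = st$basis,
                 nonbasic = st$nonbasic, lp = lp),
            class = "simplex_state")
}

#' @export
print.simplex_state <- function(x, ...) {
  cat("<simplex_state> status:", x$status)
  if (x$status == "optimal")
    cat(", objective:", signif(x$objective, 6),
        ", support size:", sum(x$solution > 1e-7))
  cat("\n")
  invisible(x)
}

#' Enumerate adjacent vertices by post-optimal pivoting
#'
#' From the optimal tableau, every nonbasic variable defines an entering
#' direction; a pivot exchanging it with a basic variable is accepted only
#' when the pivot element is nonzero and the minimum-ratio test is attained
#' at that basic variable's row, so the resulting basic solution stays
#' feasible — i.e. is again a vertex of the constrained flux cone. Pivots
#' that change the basis but not the support (degenerate vertices) are
#' folded away by support-level deduplication; the current vertex is never
#' returned.
#'
#' @param state An optimal `simplex_state`.
#' @return A list of named flux vectors, one per distinct adjacent vertex
#'   (empty when the vertex has no feasible neighbor).
#' @export
pivot_neighbors <- function(state) {
  stopifnot(inherits(state, "simplex_state"))
  if (state$status != "optimal")
    stop("pivot_neighbors requires an optimal simplex state", call. = FALSE)
  T <- state$tableau
  basis <- state$basis
  m <- nrow(T); n <- ncol(T) - 1L
  rhs <- T[, n + 1L]
  cur_support <- support_key(which(state$solution > .feas_tol))
  seen <- cur_support
  out <- list()
  for (j2 in state$nonbasic) {
    col <- T[, j2]
    pos <- which(col > .zero_tol)
    if (length(pos) == 0L) next                # unbounded direction: no vertex
    ratio <- rhs[pos] / col[pos]
    theta <- min(ratio)
    hit <- pos[ratio <= theta + .feas_tol]     # rows attaining the min ratio
    for (i in hit) {
      x <- rep(0, n)
      x[basis] <- rhs - theta * col
      x[j2] <- theta
      x[x < 0 & x > -.feas_tol] <- 0
      if (any(x < 0)) next
      key <- support_key(which(x > .feas_tol))
      if (key %in% seen) next
      seen <- c(seen, key)
      names(x) <- state$lp$net$reactions
      out[[length(out) + 1L]] <- x
    }
  }
  out
}

support_key <- function(idx) paste(sort(idx), collapse = ",")
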