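#' Synthetic test networks
#'
#' Deterministic generators for small mass-balanced irreversible networks
#' with known, exactly enumerable EFM sets. These are the fixtures every
#' stage of the toolkit is tested against, without any model download.
#'
#' * `make_chain(m)`: a linear pathway `-> A1 -> ... -> Am ->` with `m + 1`
#'   reactions and exactly one EFM (of length `m + 1`).
#' * `make_fan(b)`: one imported metabolite with `b` parallel exits; exactly
#'   `b` EFMs of length 2. `make_fan(2)` is the 3-reaction linear toy.
#' * `make_diamond()`: import, two parallel two-step branches, export; exactly
#'   2 EFMs of length 4.
#' * `make_toy_rev()`: `-> A`, a reversible `A <-> B`, `B ->`; after splitting
#'   it has one genuine EFM plus the futile two-cycle artifact.
#' * `make_toy_blk()`: `-> A -> B` with no consumer of `B`; both reactions
#'   are blocked (steady state forces zero flux).
#'
#' @param m Chain length (number of internal metabolites), `m >= 1`.
#' @param b Number of parallel exit reactions, `b >= 1`.
#' @return A [metabolic_network()].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
make_chain <- function(m) {
  stopifnot(m >= 1)
  mets <- paste0("A", seq_len(m))
  rxns <- paste0("r", seq_len(m + 1L))
  S <- matrix(0, m, m + 1L, dimnames = list(mets, rxns))
  S[1, 1] <- 1                       # import -> A1
  for (i in seq_len(m - 1L)) { S[i, i + 1L] <- -1; S[i + 1L, i + 1L] <- 1 }
  S[m, m + 1L] <- -1                 # Am -> export
  metabolic_network(S)
}

#' @rdname fixtures
#' @export
make_fan <- function(b) {
  stopifnot(b >= 1)
  S <- matrix(c(1, rep(-1, b)), 1, b + 1L,
              dimnames = list("A", paste0("r", seq_len(b + 1L))))
  metabolic_network(S)
}

#' @rdname fixtures
#' @export
make_diamond <- function() {
  S <- matrix(0, 4, 6, dimnames = list(c("A", "B", "C", "D"),
                                       paste0("r", 1:6)))
  S["A", "r1"] <- 1
  S["A", "r2"] <- -1; S["B", "r2"] <- 1
  S["A", "r3"] <- -1; S["C", "r3"] <- 1
  S["B", "r4"] <- -1; S["D", "r4"] <- 1
  S["C", "r5"] <- -1; S["D", "r5"] <- 1
  S["D", "r6"] <- -1
  metabolic_network(S, biomass = "r6")
}

#' @rdname fixtures
#' @export
make_toy_rev <- function() {
  S <- matrix(0, 2, 3, dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
  S["A", "r1"] <- 1
  S["A", "r2"] <- -1; S["B", "r2"] <- 1
  S["B", "r3"] <- -1
  metabolic_network(S, reversible = c(FALSE, TRUE, FALSE))
}

#' @rdname fixtures
#' @export
make_toy_blk <- function() {
  S <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("r1", "r2")))
  S["A", "r1"] <- 1
  S["A", "r2"] <- -1; S["B", "r2"] <- 1
  metabolic_network(S)
}

#' Random sparse mass-balanced network
#'
#' Draws `n_rxn - 2` internal columns with integer coefficients in
#' `{-2, -1, 1, 2}` (each entry present with probability `density`), plus a
#' guaranteed import column into the first metabolite and export column from
#' the last; blocked reactions are then removed. Draws are repeated within
#' the seeded stream until at least one reaction survives (hence at least
#' one EFM exists). Deterministic per seed; the global RNG state is
#' restored on exit.
#'
#' @param n_met,n_rxn Numbers of metabolites and reactions before pruning.
#' @param density Per-entry inclusion probability for internal columns.
#' @param rng_seed Integer seed; the same seed always yields the same `S`.
#' @return An all-irreversible, non-blocked [metabolic_network()].
#' @export
make_random <- function(n_met = 4, n_rxn = 10, density = 0.35, rng_seed = 1) {
  stopifnot(n_rxn >= 3, n_met >= 2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  for (attempt in 1:100) {
    S <- matrix(0, n_met, n_rxn)
    S[1, 1] <- 1
    S[n_met, n_rxn] <- -1
    for (j in 2:(n_rxn - 1L)) {
      repeat {
        mask <- stats::runif(n_met) < density
        if (any(mask)) break
      }
      S[mask, j] <- sample(c(-2, -1, 1, 2), sum(mask), replace = TRUE)
    }
    net <- metabolic_network(
      S, metabolites = paste0("M", seq_len(n_met)),
      reactions = paste0("r", seq_len(n_rxn)))
    pruned <- tryCatch(remove_blocked(net), error = function(e) NULL)
    if (!is.null(pruned)) return(pruned)
  }
  stop("could not draw a network with a non-empty flux cone in 100 attempts",
       call. = FALSE)
}

#' Look up a named fixture
#'
#' @param name One of `"chain"`, `"fan"`, `"diamond"`, `"lin"`, `"rev"`,
#'   `"blk"`, `"random"`.
#' @param ... Passed to the builder (e.g. `m`, `b`, `rng_seed`).
#' @return A [metabolic_network()].
#' @export
fixture_network <- function(name, ...) {
  switch(name,
         chain = make_chain(...),
         fan = make_fan(...),
         diamond = make_diamond(),
         lin = make_fan(2),
         rev = make_toy_rev(),
         blk = make_toy_blk(),
         random = make_random(...),
         stop("unknown fixture: ", name, call. = FALSE))
}
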