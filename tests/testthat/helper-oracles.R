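# Shared helpers: canonical support strings and an independent LP oracle.

support_strings <- function(x) {
  sort(vapply(piefm::efm_supports(x), function(s)
    paste(sort(s), collapse = ","), character(1)))
}

expect_same_efm_sets <- function(a, b) {
  expect_identical(support_strings(a), support_strings(b))
}

# Independent LP oracle: enumerate every basis (column subset of size m),
# solve the square system, keep feasible basic solutions, take the best
# objective. No simplex machinery involved.
lp_oracle_optimum <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  best <- Inf
  for (J in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, J, drop = FALSE]
    if (abs(det(B)) <= tol) next
    xB <- solve(B, b)
    if (any(xB < -1e-9)) next
    best <- min(best, sum(cost[J] * xB))
  }
  best
}

# Assemble the constraint system of a singleton-positive-seed flux LP with
# linearly independent rows (NULL when the seed row is dependent on S).
seeded_lp_system <- function(net, seed_rxn) {
  n <- length(net$reactions)
  S <- unname(net$S)
  qs <- qr(t(S))
  keep <- sort(qs$pivot[seq_len(qs$rank)])
  row <- rep(0, n); row[match(seed_rxn, net$reactions)] <- 1
  A <- rbind(S[keep, , drop = FALSE], row)
  if (qr(t(A))$rank < nrow(A)) return(NULL)
  list(A = A, b = c(rep(0, nrow(A) - 1L), 1))
}

random_fixture_nets <- function(seeds = 1:5) {
  c(list(piefm::make_fan(2), piefm::make_fan(5), piefm::make_diamond(),
         piefm::make_chain(4),
         piefm::preprocess_network(piefm::make_toy_rev())),
    lapply(seeds, function(s) piefm::make_random(4, 10, 0.35, rng_seed = s)))
}
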