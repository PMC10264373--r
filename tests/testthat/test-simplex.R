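test_that("seeded minimization finds the scaled EFM with the stated objective", {
  lin <- make_fan(2)
  st <- solve_lp(build_lp(lin, positive_seed = "r1"))
  expect_identical(st$status, "optimal")
  # both EFMs of the fan have total flux 2 once scaled to v[r1] = 1
  expect_equal(st$objective, 2, tolerance = 1e-9)

  st2 <- solve_lp(build_lp(lin, positive_seed = "r2"))
  expect_setequal(support_of(st2$solution), c("r1", "r2"))

  expect_identical(
    solve_lp(build_lp(lin, positive_seed = "r2", negative_seed = "r1"))$status,
    "infeasible")
  expect_identical(
    solve_lp(build_lp(lin, positive_seed = "r1", negative_seed = "r1"))$status,
    "infeasible")
})

test_that("a clean minimization with no seeds has the trivial optimum", {
  st <- solve_lp(build_lp(make_diamond()))
  expect_identical(st$status, "optimal")
  expect_equal(st$objective, 0)
  expect_equal(unname(st$solution), rep(0, 6))
})

test_that("an empty positive seed is rejected at build time", {
  expect_error(build_lp(make_fan(2), positive_seed = character()), "non-empty")
  expect_error(build_lp(make_fan(2), objective = c(1, NA, 1)), "finite")
})

test_that("seeded optimum on the diamond lands on one of its two pathways", {
  dia <- make_diamond()
  st <- solve_lp(build_lp(dia, objective = c(r2 = 1, r3 = 1, r4 = 1, r5 = 1, r6 = 1),
                          positive_seed = "r1"))
  supp <- support_of(st$solution)
  expect_length(supp, 4)
  expect_true(setequal(supp, c("r1", "r2", "r4", "r6")) ||
                setequal(supp, c("r1", "r3", "r5", "r6")))
})

test_that("pivoting reaches the adjacent vertex and only that", {
  dia <- make_diamond()
  st <- solve_lp(build_lp(dia, objective = c(r3 = 1, r5 = 1), positive_seed = "r1"))
  expect_setequal(support_of(st$solution), c("r1", "r2", "r4", "r6"))
  nb <- pivot_neighbors(st)
  keys <- vapply(nb, function(v) paste(sort(support_of(v)), collapse = ","),
                 character(1))
  expect_true("r1,r3,r5,r6" %in% keys)
  expect_false(any(keys == "r1,r2,r4,r6"))   # never the current vertex

  lin <- make_fan(2)
  st2 <- solve_lp(build_lp(lin, objective = c(r3 = 1), positive_seed = "r1"))
  nb2 <- pivot_neighbors(st2)
  expect_identical(
    vapply(nb2, function(v) paste(sort(support_of(v)), collapse = ","), ""),
    "r1,r3")

  chain <- make_chain(1)                     # unique EFM: unique vertex
  st3 <- solve_lp(build_lp(chain, positive_seed = "r1"))
  expect_length(pivot_neighbors(st3), 0)

  expect_error(pivot_neighbors(
    solve_lp(build_lp(lin, positive_seed = "r1", negative_seed = "r1"))),
    "optimal")
})

test_that("solver optimum matches exhaustive basis enumeration on random LPs", {
  set.seed(11)
  checked <- 0L
  for (s in 1:12) {
    net <- make_random(4, 10, 0.35, rng_seed = s)
    for (rep in 1:3) {
      seed_rxn <- sample(net$reactions, 1)
      sys <- seeded_lp_system(net, seed_rxn)
      if (is.null(sys)) next
      cost <- runif(length(net$reactions), 0.1, 1)
      st <- solve_lp(build_lp(net, cost, positive_seed = seed_rxn))
      expect_identical(st$status, "optimal")
      expect_equal(st$objective, lp_oracle_optimum(sys$A, sys$b, cost),
                   tolerance = 1e-6)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 25)
})

test_that("solutions and pivot outputs satisfy cone feasibility and the rank test", {
  set.seed(5)
  for (net in random_fixture_nets(1:3)) {
    seed_rxn <- sample(net$reactions, 1)
    st <- solve_lp(build_lp(net, runif(length(net$reactions), 0.1, 1),
                            positive_seed = seed_rxn))
    vs <- c(list(st$solution), pivot_neighbors(st))
    for (v in vs) {
      expect_lte(max(abs(net$S %*% v)), 1e-6)
      expect_gte(min(v), -1e-9)
      expect_true(is_efm(net, v))
    }
    expect_lte(length(vs) - 1L, length(st$basis) * length(st$nonbasic))
  }
})
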