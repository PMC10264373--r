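dia_full <- function() enumerate_bruteforce(make_diamond())

test_that("mean length trace is the running mean of support sizes", {
  expect_equal(mean_length_trace(list(c("a", "b"), c("c", "d")), 1:2)$value,
               c(2, 2))
  expect_equal(mean_length_trace(list(c("a", "b"), c("c", "d", "e", "f")), 1:2)$value,
               c(2, 3))
  tr <- mean_length_trace(dia_full(), 1:2)
  expect_equal(tr$value[2], 4)
})

test_that("reaction proportions count support membership exactly", {
  p <- reaction_proportions(dia_full())
  expect_identical(p$reaction, paste0("r", 1:6))
  expect_equal(p$p, c(1, 0.5, 0.5, 0.5, 0.5, 1))
  single <- reaction_proportions(list(c("r1", "r2")), universe = c("r1", "r2", "r3"))
  expect_equal(single$p, c(1, 1, 0))       # indicator of the support
})

test_that("mean relative error matches hand arithmetic and a brute-force recount", {
  p <- reaction_proportions(dia_full())
  expect_equal(as.numeric(mre(p, p)), 0)
  est <- c(r1 = 1, r2 = 0.25)
  ref <- c(r1 = 1, r2 = 0.5)
  expect_equal(as.numeric(mre(est, ref)), 0.25)
  # zero-reference reactions are dropped and counted
  m <- mre(c(a = 0.5, b = 0.2), c(a = 0.5, b = 0), universe = c("a", "b"))
  expect_equal(as.numeric(m), 0)
  expect_identical(attr(m, "n_zero_ref"), 1L)

  # half of a shuffled full enumeration vs an independent recount
  net <- make_random(4, 12, 0.35, rng_seed = 6)
  full <- efm_supports(enumerate_bruteforce(net))
  set.seed(2); full <- sample(full)
  half <- full[seq_len(length(full) %/% 2)]
  p_ref <- reaction_proportions(full, universe = net$reactions)
  p_half <- reaction_proportions(half, universe = net$reactions)
  # independent recount: direct loops, no shared code path
  count_in <- function(r, ss) sum(vapply(ss, function(s) r %in% s, logical(1)))
  rs <- net$reactions[vapply(net$reactions, count_in, 0L, ss = full) > 0]
  manual <- mean(vapply(rs, function(r) {
    pr <- count_in(r, full) / length(full)
    pe <- count_in(r, half) / length(half)
    abs(pe - pr) / pr
  }, numeric(1)))
  expect_equal(as.numeric(mre(p_half, p_ref)), manual)
})

test_that("stability of a repeated stream is identically zero", {
  stream <- rep(list(c("r1", "r2")), 40)
  st <- stability_trace(stream, d = 5, checkpoints = seq(10, 40, 5))
  expect_equal(st$value, rep(0, nrow(st)))
  # identical halves at k = 2d
  two <- c(rep(list(c("a", "b")), 3), rep(list(c("a", "b")), 3))
  expect_equal(stability_trace(two, d = 3, checkpoints = 6)$value, 0)
})

test_that("stability of uniform sampling from a finite set decays toward zero", {
  supps <- efm_supports(dia_full())
  early <- numeric(10); late <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    stream <- supps[sample(2, 400, replace = TRUE)]
    st <- stability_trace(stream, d = 20, checkpoints = c(40, 400))
    early[s] <- st$value[1]; late[s] <- st$value[2]
  }
  expect_lt(mean(late), mean(early))
  expect_lt(mean(late), 0.05)
})

test_that("the stopping rule needs an uninterrupted sub-threshold run", {
  mk <- function(v) tibble::tibble(k = seq_along(v) * 100, value = v)
  expect_equal(stopping_index(mk(c(0.2, 0.04, 0.03, 0.02)), 0.05, 3), 200)
  expect_true(is.na(stopping_index(mk(c(0.3, 0.2, 0.1)), 0.05, 3)))
  expect_equal(stopping_index(mk(c(0.04, 0.2, 0.04, 0.04, 0.04)), 0.05, 3), 300)
  # monotone in the threshold: looser threshold stops no later
  v <- mk(c(0.2, 0.12, 0.04, 0.04, 0.01, 0.04))
  s1 <- stopping_index(v, 0.05, 2); s2 <- stopping_index(v, 0.15, 2)
  expect_lte(s2, s1)
})

test_that("compatible reactions are the union of co-occurring supports", {
  full <- dia_full()
  expect_setequal(compatible_reactions(full, "r6"), paste0("r", 1:6))
  expect_setequal(compatible_reactions(full, "r2"), c("r1", "r2", "r4", "r6"))
  expect_length(compatible_reactions(list(), "r1"), 0)
})

test_that("partial-coupling classes group identical indicator patterns", {
  cc <- coupled_classes(dia_full())
  split_classes <- split(cc$reaction, cc$class)
  expect_identical(unname(lapply(split_classes, sort)),
                   list(c("r1", "r6"), c("r2", "r4"), c("r3", "r5")))
  cc_lin <- coupled_classes(enumerate_bruteforce(make_fan(2)))
  expect_identical(cc_lin$class_size, rep(1L, 3))
  one <- coupled_classes(list(c("r1", "r2")), universe = c("r1", "r2"))
  expect_identical(one$class, c(1L, 1L))

  # correction modes: drop all coupled members vs keep one representative
  expect_length(uncoupled_reactions(dia_full()), 0)
  expect_identical(uncoupled_reactions(dia_full(), mode = "representative"),
                   c("r1", "r2", "r3"))
  expect_identical(uncoupled_reactions(enumerate_bruteforce(make_fan(2))),
                   paste0("r", 1:3))
})

test_that("length-ordered simulation is a stable sort with the sandwich property", {
  supp <- list(c("a", "b"), c("c"), c("d", "e", "f"), c("g"))
  expect_identical(simulate_k_extreme(supp, "shortest", 2),
                   list(c("c"), c("g")))                 # ties keep order
  expect_identical(simulate_k_extreme(supp, "largest", 4)[[1]],
                   c("d", "e", "f"))
  expect_identical(simulate_k_extreme(supp, "shortest", 4),
                   supp[c(2, 4, 1, 3)])
  for (net in list(make_diamond(), make_random(4, 12, 0.35, rng_seed = 8))) {
    full <- efm_supports(enumerate_bruteforce(net))
    overall <- mean(lengths(full))
    for (k in seq_along(full)) {
      lo <- mean(lengths(simulate_k_extreme(full, "shortest", k)))
      hi <- mean(lengths(simulate_k_extreme(full, "largest", k)))
      expect_lte(lo, overall + 1e-12)
      expect_gte(hi, overall - 1e-12)
    }
  }
})

test_that("Jaccard distance between consecutive supports", {
  expect_equal(jaccard_trace(list(c("a", "b"), c("a", "b")))$value, 0)
  expect_equal(jaccard_trace(list(c("a"), c("b")))$value, 1)
  expect_equal(jaccard_trace(list(c("r1", "r2"), c("r1", "r3")))$value,
               1 - 1 / 3, tolerance = 1e-9)
})
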