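# Belief propagation: exactness on trees, symmetry, normalization.

test_that("BP equals exhaustive enumeration on random acyclic problems", {
  config <- ssa_config(bp_tol_msg = 1e-10, bp_max_iters = 500L)
  set.seed(20240301)
  n_checked <- 0L
  for (rep in seq_len(110)) {
    n_sys <- sample(2:6, 1)
    n_pos <- sample(n_sys:7, 1)
    prob <- random_acyclic_problem(n_sys, n_pos)
    id2idx <- stats::setNames(as.list(seq_len(n_sys)), seq_len(n_sys))
    factors <- ssassign:::bp_build_factors(prob$doms, prob$links, id2idx)
    sol <- bp_sum_product(prob$psis, prob$doms, factors, config)
    expect_true(sol$converged)
    exact <- enumerate_marginals(prob$psis, prob$doms, factors, config)
    for (i in seq_len(n_sys)) {
      expect_equal(unname(sol$beliefs[[i]]), exact[[i]], tolerance = 1e-6)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("BP is exact on a two-variable problem with exclusion", {
  config <- ssa_config(bp_tol_msg = 1e-10)
  doms <- list(c(0L, 1L, 2L), c(0L, 2L, 3L))
  psis <- list(c(0.1, 0.5, 0.4), c(0.2, 0.6, 0.2))
  links <- data.frame(from_id = integer(0), to_id = integer(0),
                      score = numeric(0))
  factors <- ssassign:::bp_build_factors(doms, links,
                                         list(`1` = 1L, `2` = 2L))
  expect_length(factors, 1L)   # shared position 2 -> one exclusion factor
  sol <- bp_sum_product(psis, doms, factors, config)
  exact <- enumerate_marginals(psis, doms, factors, config)
  expect_equal(unname(sol$beliefs[[1]]), exact[[1]], tolerance = 1e-8)
  expect_equal(unname(sol$beliefs[[2]]), exact[[2]], tolerance = 1e-8)
})

test_that("interchangeable systems split their probability evenly", {
  # two identical variables competing for the same two positions
  doms <- list(c(0L, 1L, 2L), c(0L, 1L, 2L))
  psis <- list(c(1e-6, 1, 1), c(1e-6, 1, 1))
  factors <- ssassign:::bp_build_factors(
    doms, data.frame(from_id = integer(0), to_id = integer(0),
                     score = numeric(0)),
    list(`1` = 1L, `2` = 2L))
  sol <- bp_sum_product(psis, doms, factors, ssa_config())
  b <- sol$beliefs[[1]]
  expect_equal(unname(b[["1"]]), unname(b[["2"]]), tolerance = 1e-9)
  expect_equal(sol$beliefs[[1]], sol$beliefs[[2]], tolerance = 1e-9)
})

test_that("a single matching system concentrates at its position", {
  fx <- make_clean_fixture(c("G", "A"), seed = 2,
                           experiments = c("CANCO", "NCA", "NCO",
                                           "NCACB-3D", "NCACO"))
  m <- assemble_matrix(fx$pls, c(C = 0.2, N = 0.3), STATS)
  links <- link_spin_systems(m, c(C = 0.2, N = 0.3))
  bp <- run_belief_propagation(m, links, c("G", "A"), STATS)
  mapres <- ssassign:::map_assignment(bp$beliefs, bp$domains)
  placed <- which(mapres$position == 2L)
  expect_length(placed, 1L)
  expect_gt(mapres$prob[placed], 0.95)
})

test_that("marginals normalize whether or not BP converged", {
  set.seed(7)
  for (rep in 1:10) {
    prob <- random_acyclic_problem(4, 6)
    # force an early stop to exercise the non-converged path
    config <- ssa_config(bp_max_iters = 2L, bp_tol_msg = 1e-15)
    factors <- ssassign:::bp_build_factors(
      prob$doms, prob$links, stats::setNames(as.list(1:4), 1:4))
    sol <- bp_sum_product(prob$psis, prob$doms, factors, config)
    for (b in sol$beliefs) expect_equal(sum(b), 1, tolerance = 1e-6)
  }
})

test_that("BP output is deterministic for fixed inputs", {
  set.seed(99)
  prob <- random_acyclic_problem(5, 7)
  factors <- ssassign:::bp_build_factors(
    prob$doms, prob$links, stats::setNames(as.list(1:5), 1:5))
  s1 <- bp_sum_product(prob$psis, prob$doms, factors, ssa_config())
  s2 <- bp_sum_product(prob$psis, prob$doms, factors, ssa_config())
  expect_identical(s1$beliefs, s2$beliefs)
})
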