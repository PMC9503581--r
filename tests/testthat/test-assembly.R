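# Root finding, strip attachment, quality, and tolerance optimization.

tolv <- c(C = 0.2, N = 0.3)

make_pl <- function(experiment, ...) {
  rows <- list(...)
  d <- length(rows[[1]])
  df <- as.data.frame(stats::setNames(
    lapply(seq_len(d), function(k) vapply(rows, `[[`, 0, k)),
    paste0("w", seq_len(d))))
  peak_list(experiment, df)
}

test_that("roots read directly off root experiments (axis order per profile)", {
  pl <- make_pl("CANCO", c(54.9, 120.3, 176.0))
  roots <- find_roots(list(pl), tolv)
  expect_equal(nrow(roots), 1L)
  expect_equal(roots$co_prev, 176.0)
  expect_equal(roots$n, 120.3)
  expect_equal(roots$ca, 54.9)
})

test_that("roots join NCO and NCA evidence on the shared nitrogen", {
  nco <- make_pl("NCO", c(120.3, 176.0))
  nca <- make_pl("NCA", c(120.3, 54.9))
  roots <- find_roots(list(nco, nca), tolv)
  expect_equal(nrow(roots), 1L)
  expect_equal(roots$co_prev, 176.0)
  expect_equal(roots$ca, 54.9)
})

test_that("near-duplicate roots merge to a weighted centroid", {
  pl <- make_pl("CANCO", c(54.90, 120.30, 176.00), c(54.91, 120.31, 176.01))
  roots <- find_roots(list(pl), tolv)
  expect_equal(nrow(roots), 1L)
  expect_equal(roots$ca, 54.905, tolerance = 1e-9)
  expect_equal(roots$weight, 2)
})

test_that("zero roots is a diagnostic, not an exception", {
  expect_message(roots <- find_roots(list(make_pl("CC", c(54, 30))), tolv),
                 "no root triples")
  expect_equal(nrow(roots), 0L)
})

test_that("strip peaks fill own and preceding slots off the root anchors", {
  canco <- make_pl("CANCO", c(54.9, 120.3, 176.0))
  ncacb <- make_pl("NCACB-3D", c(120.3, 54.9, 19.2))
  ncocacb <- make_pl("NCOCACB", c(120.3, 176.0, 58.7),
                     c(120.3, 176.0, 63.8))
  # a second list so the support pruning keeps the system
  m <- assemble_matrix(list(canco, ncacb, ncocacb), tolv, STATS)
  expect_equal(length(m$systems), 1L)
  sys <- m$systems[[1]]
  expect_equal(unname(sys$own[["CB"]]), 19.2)
  expect_equal(unname(sys$prev[["CA"]]), 58.7)   # serine-like CA/CB pair
  expect_equal(unname(sys$prev[["CB"]]), 63.8)
  expect_equal(unname(sys$prev[["C"]]), 176.0)
  # every contributing peak is recorded in the support trail
  expect_setequal(unique(sys$support$experiment),
                  c("CANCO", "NCACB-3D", "NCOCACB"))
})

test_that("a root with no strips keeps only the triple", {
  canco <- make_pl("CANCO", c(54.9, 120.3, 176.0))
  ncacb <- make_pl("NCACB-3D", c(99.0, 30.0, 19.2))  # matches nothing
  m <- attach_correlations(find_roots(list(canco), tolv),
                           list(canco, ncacb), tolv, STATS)
  sys <- m$systems[[1]]
  expect_equal(sort(names(sys$own)), c("CA", "N"))
  expect_length(sys$own_cx, 0L)
})

test_that("assembly is deterministic and ordered by root nitrogen", {
  fx <- make_clean_fixture(strsplit("MQYKLASTVG", "")[[1]], seed = 5)
  m1 <- assemble_matrix(fx$pls, tolv, STATS)
  m2 <- assemble_matrix(fx$pls, tolv, STATS)
  expect_equal(dump_matrix(m1), dump_matrix(m2))
  ns <- vapply(m1$systems, function(s) s$own[["N"]], 0)
  expect_equal(ns, sort(ns))
})

test_that("quality is 1 on complete clean data and 0 with no peaks", {
  seq10 <- strsplit("MQYKLASTVG", "")[[1]]
  fx <- make_clean_fixture(seq10, seed = 5)
  m <- assemble_matrix(fx$pls, tolv, STATS)
  expect_equal(assess_quality(m, seq10, stats = STATS), 1, tolerance = 0.02)

  empty <- structure(list(systems = list(), tolerances = tolv,
                          quality = NA_real_),
                     class = "spin_system_matrix")
  expect_equal(assess_quality(empty, seq10, stats = STATS), 0)
  expect_error(assess_quality(m, character(0)), "empty sequence")
})

test_that("halving the spin systems halves the system ratio", {
  seq10 <- strsplit("MQYKLASTVG", "")[[1]]
  fx <- make_clean_fixture(seq10, seed = 5)
  m <- assemble_matrix(fx$pls, tolv, STATS)
  full_ids <- which(vapply(m$systems, function(s)
    !is.na(s$root[["CO_prev"]]), TRUE))
  drop <- full_ids[seq(1, length(full_ids), by = 2)]
  m2 <- m
  m2$systems <- m$systems[-drop]
  links2 <- link_spin_systems(m2, tolv)
  q2 <- assess_quality(m2, seq10, links = links2, stats = STATS)
  kept <- length(full_ids) - length(drop)
  n_link <- length(unique(links2$from_id))
  expected <- sqrt((kept / 9) * min(1, n_link / 9))
  expect_equal(q2, expected, tolerance = 1e-9)
})

test_that("adding expected peaks never lowers clean-data quality", {
  seq8 <- strsplit("MQYKLAST", "")[[1]]
  tab <- simulate_shift_table(seq8, STATS, seed = 3, min_separation = 0.8)
  subsets <- list(c("CANCO", "NCO", "NCA"),
                  c("CANCO", "NCO", "NCA", "NCACX"),
                  c("CANCO", "NCO", "NCA", "NCACX", "NCOCX", "NCOCA"))
  qs <- vapply(subsets, function(ex) {
    pls <- generate_peaklists(tab, seq8, ex, synthetic_options(seed = 4))
    m <- assemble_matrix(pls, tolv, STATS)
    assess_quality(m, seq8, stats = STATS)
  }, 0)
  expect_true(all(diff(qs) >= -1e-9))
})

test_that("tolerance search prefers the smallest grid on clean data", {
  seq10 <- strsplit("MQYKLASTVG", "")[[1]]
  fx <- make_clean_fixture(seq10, seed = 9)
  opt <- optimize_tolerances(fx$pls, seq10, STATS)
  expect_equal(unname(opt$tol), c(0.2, 0.3))
  expect_gte(opt$matrix$quality, 0.95)
  expect_equal(nrow(opt$trace) %% 1, 0)
  expect_true(all(opt$trace$quality <= 1))

  # empty peak lists: all-zero trace, no matrix content
  empties <- lapply(c("CANCO", "NCA", "NCO"), function(e)
    peak_list(e, as.data.frame(stats::setNames(
      rep(list(numeric(0)), get_profile(e)$dimensionality),
      paste0("w", seq_len(get_profile(e)$dimensionality))))))
  suppressMessages(opt0 <- optimize_tolerances(empties, seq10, STATS))
  expect_true(all(opt0$trace$quality == 0))
})

test_that("the quality gate is a closed lower bound", {
  expect_true(gate_quality(1.0, 0.3)$proceed)
  expect_true(gate_quality(0.3, 0.3)$proceed)
  g <- gate_quality(0.0, 0.3)
  expect_false(g$proceed)
  expect_match(g$message, "more information is required")
})
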