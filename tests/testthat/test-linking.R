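# Di-peptide linking and pentapeptide fragments.

tolv <- c(C = 0.2, N = 0.3)

fake_system <- function(id, n, ca, co_prev = NA_real_, own = c(), prev = c(),
                        own_cx = numeric(0), prev_cx = numeric(0)) {
  sys <- ssassign:::.new_system(id, co_prev, n, ca)
  for (a in names(own)) {
    sys$own[a] <- own[[a]]; sys$weights$own[a] <- 1; sys$spec$own[a] <- 2
  }
  for (a in names(prev)) {
    sys$prev[a] <- prev[[a]]; sys$weights$prev[a] <- 1; sys$spec$prev[a] <- 2
  }
  sys$own_cx <- own_cx; sys$prev_cx <- prev_cx
  sys
}

fake_matrix <- function(...) {
  structure(list(systems = list(...), tolerances = tolv, quality = NA_real_),
            class = "spin_system_matrix")
}

test_that("identical own/prev carbons give a perfect link", {
  a <- fake_system(1, 110, 52.0, 170.0, own = c(CB = 19.0, C = 176.0))
  b <- fake_system(2, 118, 58.0, 176.0,
                   prev = c(CA = 52.0, CB = 19.0))
  links <- link_spin_systems(fake_matrix(a, b), tolv)
  li <- links[links$from_id == 1 & links$to_id == 2, ]
  expect_equal(nrow(li), 1L)
  expect_equal(li$score, 1.0)
  expect_gte(li$n_shared, 3L)   # CA, CB, C (root carbonyl)
})

test_that("a single shared atom at the tolerance scores exp(-2)", {
  # tolerance 0.25 is exactly representable, so delta == tol holds exactly
  tol25 <- c(C = 0.25, N = 0.3)
  a <- fake_system(1, 110, 52.0)
  b <- fake_system(2, 118, 58.0, 176.0, prev = c(CA = 52.0 + 0.25))
  # b's prev carbonyl must not block: a has no own C
  links <- link_spin_systems(fake_matrix(a, b), tol25)
  li <- links[links$from_id == 1 & links$to_id == 2, ]
  expect_equal(li$n_shared, 1L)
  expect_equal(li$score, exp(-2), tolerance = 1e-9)
})

test_that("a named mismatch beyond tolerance vetoes the link", {
  a <- fake_system(1, 110, 52.0, own = c(CB = 19.0))
  b <- fake_system(2, 118, 58.0, 176.0, prev = c(CA = 52.0, CB = 24.0))
  links <- link_spin_systems(fake_matrix(a, b), tolv)
  expect_equal(nrow(links[links$from_id == 1 & links$to_id == 2, ]), 0L)
})

test_that("a clean unique-shift 10-mer yields exactly 9 correct links", {
  seq10 <- strsplit("MQYKLASTVG", "")[[1]]
  fx <- make_clean_fixture(seq10, seed = 5)
  m <- assemble_matrix(fx$pls, tolv, STATS)
  links <- link_spin_systems(m, tolv)
  expect_equal(nrow(links), 9L)
  # verify every link joins consecutive residues via the table's CA values
  ca <- fx$tab$value[fx$tab$atom == "CA"]
  pos_of <- function(id) which.min(abs(ca - m$systems[[id]]$root[["CA"]]))
  for (r in seq_len(nrow(links))) {
    expect_equal(pos_of(links$to_id[r]), pos_of(links$from_id[r]) + 1L)
  }
})

test_that("pentapeptide fragments place a unique chain correctly", {
  seq5 <- strsplit("MQYKL", "")[[1]]
  fx <- make_clean_fixture(seq5, seed = 13)
  m <- assemble_matrix(fx$pls, tolv, STATS)
  links <- link_spin_systems(m, tolv)
  pp <- generate_pentapeptides(links, m, seq5, STATS)
  # the full-length chain must survive with its correct placement
  penta <- pp$fragments[pp$fragments$length == 5, ]
  expect_true(nrow(penta) >= 1L)
  expect_true(1 %in% penta$start)
  best <- penta[which.max(penta$score), ]
  expect_equal(best$start, 1L)
  # every system's domain covers its true position
  ca <- fx$tab$value[fx$tab$atom == "CA"]
  for (i in seq_along(m$systems)) {
    tp <- which.min(abs(ca - m$systems[[i]]$root[["CA"]]))
    expect_true(tp %in% pp$domains[[i]])
  }
})

test_that("without links only singleton domains arise", {
  a <- fake_system(1, 110, 52.0)
  m <- fake_matrix(a)
  links <- link_spin_systems(m, tolv)
  expect_equal(nrow(links), 0L)
  pp <- generate_pentapeptides(links, m, c("A", "G"), STATS)
  expect_equal(nrow(pp$fragments), 0L)
  expect_true(length(pp$domains[[1]]) >= 1L)
})

test_that("fragments containing glycine-impossible systems score zero there", {
  # a system with a well-anchored CB cannot sit on a glycine position
  a <- fake_system(1, 110, 45.0, own = c(CB = 19.0))
  m <- fake_matrix(a)
  U <- ssassign:::unary_scores(m, c("G", "A"), STATS)
  expect_equal(U[1, 1], 0)
  expect_gt(U[1, 2], 0)
})
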