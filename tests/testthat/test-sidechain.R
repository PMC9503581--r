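# Side-chain carbon assignment.

SEQ10 <- strsplit("MQYKLASTVG", "")[[1]]

sidechain_result <- function(seed) {
  fx <- make_clean_fixture(SEQ10, seed = seed)
  res <- iterate_assignment(fx$pls, SEQ10, STATS)
  list(fx = fx, res = assign_sidechains(res, fx$pls, STATS))
}

test_that("clean data yields correct side chains for distinctive atoms", {
  out <- sidechain_result(5)
  sh <- as.data.frame(out$res$shifts)
  ref <- as.data.frame(out$fx$tab)
  side <- sh[!(sh$atom %in% c("N", "CA", "CB", "C")), ]
  expect_gt(nrow(side), 5L)
  m <- merge(side, ref, by = c("seq_id", "atom"), suffixes = c(".got", ".ref"))
  # degenerate pairs (CE1/CE2, CG1/CG2, near-equal methyls) may swap, but
  # they carry low confidence; everything at or above the recommended 0.6
  # cutoff must agree with the table
  conf <- m[m$prob.got >= 0.6, ]
  expect_gt(nrow(conf), 3L)
  expect_true(all(abs(conf$value.got - conf$value.ref) <= 0.3))
  # a side-chain atom never lands on a type that lacks it
  for (r in seq_len(nrow(side))) {
    type <- out$res$sequence[side$seq_id[r]]
    expect_true(side$atom[r] %in% ssassign:::SIDECHAIN_CARBONS[[type]])
  }
  # side-chain probability never exceeds the backbone probability
  for (r in seq_len(nrow(side))) {
    bb <- out$res$residues$best_prob[side$seq_id[r]]
    expect_lte(side$prob[r], bb + 1e-9)
  }
})

test_that("a lone candidate at the statistics mean is matched confidently", {
  # alanine system with one extra strip carbon exactly at the CB mean
  sys <- ssassign:::.new_system(1L, 172.0, 123.2, 53.1)
  sys$own["CB"] <- NA  # not named; candidate arrives via the CX pool
  sys$own <- sys$own[!is.na(sys$own)]
  sys$own_cx <- unname(STATS$mean[["A CB"]])
  sys$support <- data.frame(experiment = c("CANCO", "NCACX"), peak = c(1L, 1L),
                            axis = 1L, slot = "own.CA", value = 53.1)
  mtx <- structure(list(systems = list(sys), tolerances = c(C = 0.2, N = 0.3),
                        quality = 1), class = "spin_system_matrix")
  res <- structure(list(
    terminated = FALSE,
    shifts = shift_table(1, "A", c("N", "CA"), c(123.2, 53.1),
                         prob = c(0.99, 0.99)),
    residues = data.frame(seq_id = 1, res_type = "A", best_prob = 0.99,
                          bin = "cyan"),
    assign = 1L, system_prob = 0.99, matrix = mtx, sequence = "A"),
    class = "assignment_result")
  out <- assign_sidechains(res, list(), STATS)
  cb <- as.data.frame(out$shifts)
  cb <- cb[cb$atom == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$value, unname(STATS$mean[["A CB"]]))
  expect_equal(cb$prob, 0.99, tolerance = 1e-6)  # match posterior ~ 1
})

test_that("residues without candidates stay backbone-only", {
  sys <- ssassign:::.new_system(1L, 172.0, 109.7, 45.4)
  sys$support <- data.frame(experiment = "CANCO", peak = 1L, axis = 1L,
                            slot = "own.CA", value = 45.4)
  mtx <- structure(list(systems = list(sys), tolerances = c(C = 0.2, N = 0.3),
                        quality = 1), class = "spin_system_matrix")
  res <- structure(list(
    terminated = FALSE,
    shifts = shift_table(1, "G", c("N", "CA"), c(109.7, 45.4),
                         prob = c(0.95, 0.95)),
    residues = data.frame(seq_id = 1, res_type = "G", best_prob = 0.95,
                          bin = "cyan"),
    assign = 1L, system_prob = 0.95, matrix = mtx, sequence = "G"),
    class = "assignment_result")
  out <- assign_sidechains(res, list(), STATS)
  expect_equal(nrow(out$shifts), 2L)
})

test_that("degenerate leucine methyls break ties by ascending ppm/atom name", {
  sys <- ssassign:::.new_system(1L, 176.9, 121.8, 55.6)
  sys$own_cx <- c(24.9, 23.9)   # two methyl candidates
  sys$support <- data.frame(experiment = "CANCO", peak = 1L, axis = 1L,
                            slot = "own.CA", value = 55.6)
  mtx <- structure(list(systems = list(sys), tolerances = c(C = 0.2, N = 0.3),
                        quality = 1), class = "spin_system_matrix")
  res <- structure(list(
    terminated = FALSE,
    shifts = shift_table(1, "L", c("N", "CA"), c(121.8, 55.6),
                         prob = c(0.99, 0.99)),
    residues = data.frame(seq_id = 1, res_type = "L", best_prob = 0.99,
                          bin = "cyan"),
    assign = 1L, system_prob = 0.99, matrix = mtx, sequence = "L"),
    class = "assignment_result")
  out <- assign_sidechains(res, list(), STATS)
  sh <- as.data.frame(out$shifts)
  # CD1 statistics mean (24.7) sits above CD2 (24.1): the matching must
  # assign 24.9 -> CD1 and 23.9 -> CD2
  expect_equal(sh$value[sh$atom == "CD1"], 24.9)
  expect_equal(sh$value[sh$atom == "CD2"], 23.9)
})

test_that("anchored carbon-carbon peaks contribute candidates", {
  sys <- ssassign:::.new_system(1L, 172.0, 123.2, 53.1)
  sys$support <- data.frame(experiment = "CANCO", peak = 1L, axis = 1L,
                            slot = "own.CA", value = 53.1)
  mtx <- structure(list(systems = list(sys), tolerances = c(C = 0.2, N = 0.3),
                        quality = 1), class = "spin_system_matrix")
  res <- structure(list(
    terminated = FALSE,
    shifts = shift_table(1, "A", c("N", "CA"), c(123.2, 53.1),
                         prob = c(0.99, 0.99)),
    residues = data.frame(seq_id = 1, res_type = "A", best_prob = 0.99,
                          bin = "cyan"),
    assign = 1L, system_prob = 0.99, matrix = mtx, sequence = "A"),
    class = "assignment_result")
  cc <- peak_list("CC", data.frame(w1 = 53.1, w2 = 19.0))
  out <- assign_sidechains(res, list(cc), STATS)
  sh <- as.data.frame(out$shifts)
  expect_equal(sh$value[sh$atom == "CB"], 19.0)
})
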