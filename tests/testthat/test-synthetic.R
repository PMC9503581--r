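# Synthetic peak-list generation.

test_that("clean generation instantiates exactly the expected templates", {
  gas <- c("G", "A", "S")
  tab <- simulate_shift_table(gas, STATS, seed = 2)
  pls <- generate_peaklists(tab, gas, c("NCA"), synthetic_options())
  expect_equal(nrow(pls$NCA$peaks), 3L)
  lookup <- stats::setNames(tab$value, paste0(tab$seq_id, ".", tab$atom))
  expect_setequal(round(pls$NCA$peaks$w1, 6),
                  round(unname(lookup[paste0(1:3, ".N")]), 6))
  expect_setequal(round(pls$NCA$peaks$w2, 6),
                  round(unname(lookup[paste0(1:3, ".CA")]), 6))

  # conservation across all experiments: peaks == templates - skipped
  for (e in BENCH_EXPERIMENTS) {
    pl <- generate_peaklists(tab, gas, e, synthetic_options())[[1]]
    tpl <- expected_peaks(e, gas)
    expect_equal(nrow(pl$peaks) + attr(pl, "skipped_templates"), nrow(tpl))
  }
})

test_that("templates touching missing shifts are skipped and counted", {
  gas <- c("G", "A")
  tab <- shift_table(c(1, 1, 2, 2), c("G", "G", "A", "A"),
                     c("N", "CA", "N", "CA"), c(108.9, 45.2, 122.5, 52.4))
  pls <- generate_peaklists(tab, gas, "NCACO", synthetic_options())
  # every NCACO template needs the carbonyl, which is absent
  expect_equal(nrow(pls$NCACO$peaks), 0L)
  expect_equal(attr(pls$NCACO, "skipped_templates"),
               nrow(expected_peaks("NCACO", gas)))
})

test_that("missing rate one empties every list", {
  gas <- c("G", "A", "S")
  tab <- simulate_shift_table(gas, STATS, seed = 2)
  pls <- generate_peaklists(tab, gas, c("NCA", "NCO"),
                            synthetic_options(missing_rate = 1))
  expect_true(all(vapply(pls, function(p) nrow(p$peaks) == 0L, TRUE)))
})

test_that("generation is byte-identical for a fixed seed", {
  gas <- strsplit("MQYKLAST", "")[[1]]
  tab <- simulate_shift_table(gas, STATS, seed = 2)
  opts <- synthetic_options(jitter_c = 0.1, jitter_n = 0.2,
                            missing_rate = 0.2, false_positive_rate = 0.3,
                            seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_peaklists(generate_peaklists(tab, gas, c("NCA", "NCOCX"), opts),
                  d1, opts)
  write_peaklists(generate_peaklists(tab, gas, c("NCA", "NCOCX"), opts),
                  d2, opts)
  for (f in c("NCA.list", "NCOCX.list"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("dropout rate matches the requested missing rate statistically", {
  gas <- strsplit("MQYKLASTVGWDENR", "")[[1]]
  tab <- simulate_shift_table(gas, STATS, seed = 2)
  n_tpl <- nrow(expected_peaks("NCACX", gas))
  m <- 0.3
  fractions <- vapply(1:50, function(s) {
    pl <- generate_peaklists(tab, gas, "NCACX",
                             synthetic_options(missing_rate = m,
                                               seed = s))[[1]]
    1 - nrow(pl$peaks) / n_tpl
  }, 0)
  se <- sqrt(m * (1 - m) / n_tpl) / sqrt(50)
  expect_lt(abs(mean(fractions) - m), 3 * se + 0.01)
})

test_that("per-experiment offsets shift emitted coordinates additively", {
  gas <- c("G", "A", "S")
  tab <- simulate_shift_table(gas, STATS, seed = 2)
  base <- generate_peaklists(tab, gas, "NCA", synthetic_options())[[1]]
  off <- generate_peaklists(tab, gas, "NCA",
    synthetic_options(offsets = list(NCA = c(C = 0.5, N = -0.2))))[[1]]
  expect_equal(off$peaks$w1, base$peaks$w1 - 0.2)
  expect_equal(off$peaks$w2, base$peaks$w2 + 0.5)
})

test_that("generator validates its inputs", {
  expect_error(synthetic_options(missing_rate = 1.5))
  expect_error(synthetic_options(jitter_c = -1))
  gas <- c("G", "A")
  expect_error(generate_peaklists(
    shift_table(integer(0), character(0), character(0), numeric(0)),
    gas, "NCA", synthetic_options()), "empty")
})
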