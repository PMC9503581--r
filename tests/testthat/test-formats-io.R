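# Peak-list, sequence, and shift-table I/O.

test_that("Sparky peak lists parse positions, heights, and labels", {
  path <- withr::local_tempfile(fileext = ".list")
  writeLines(c("     Assignment     w1     w2     w3   Data Height", "",
               "       ?-?-?  176.02  120.31   54.88  1.2e6"), path)
  pl <- read_peak_list(path, "NCOCX")
  expect_equal(nrow(pl$peaks), 1L)
  expect_equal(unlist(pl$peaks[1, c("w1", "w2", "w3")]),
               c(w1 = 176.02, w2 = 120.31, w3 = 54.88))
  expect_equal(pl$peaks$height[1], 1.2e6)

  # empty body under a valid header
  writeLines("Assignment w1 w2 w3 Data Height", path)
  expect_equal(nrow(read_peak_list(path, "NCOCX")$peaks), 0L)

  # label-free rows and missing heights are fine
  writeLines(c("120.31 54.88", "121.00 55.00 3e4"), path)
  pl2 <- read_peak_list(path, "NCA", format_hint = "sparky")
  expect_equal(nrow(pl2$peaks), 2L)
  expect_true(is.na(pl2$peaks$height[1]))
})

test_that("XEASY peak lists parse coordinates and intensity", {
  path <- withr::local_tempfile(fileext = ".peaks")
  writeLines(c("# Number of dimensions 3",
               "1 120.31 176.02 54.88 1 U 1.2e6 0.0e0 - 0 0 0 0"), path)
  pl <- read_peak_list(path, "NCOCX", axis_permutation = c(2, 1, 3))
  expect_equal(unlist(pl$peaks[1, c("w1", "w2", "w3")]),
               c(w1 = 176.02, w2 = 120.31, w3 = 54.88))
  expect_equal(pl$peaks$height[1], 1.2e6)
})

test_that("unparseable peak lines are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".list")
  writeLines(c("120.1 54.2", "garbage line here", "121.5 55.1"), path)
  expect_message(pl <- read_peak_list(path, "NCA"), "skipped")
  expect_equal(nrow(pl$peaks), 2L)
  expect_equal(pl$n_skipped, 1L)
})

test_that("format inference and errors behave", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines("120.1 54.2", path)
  expect_error(read_peak_list(path, "NCA"), "format")
  expect_error(read_peak_list(tempfile(), "NCA"), "no such file")
})

test_that("peak list writers round-trip through the readers", {
  df <- data.frame(w1 = c(120.311, 115.007), w2 = c(54.882, 61.350),
                   height = c(1e5, 2e5), label = NA_character_)
  pl <- peak_list("NCA", df)
  sp <- withr::local_tempfile(fileext = ".list")
  xe <- withr::local_tempfile(fileext = ".peaks")
  write_sparky_list(pl, sp)
  write_xeasy_peaks(pl, xe)
  back_sp <- read_peak_list(sp, "NCA")
  back_xe <- read_peak_list(xe, "NCA")
  expect_equal(back_sp$peaks$w1, df$w1, tolerance = 1e-3)
  expect_equal(back_sp$peaks$w2, df$w2, tolerance = 1e-3)
  expect_equal(back_xe$peaks$w1, df$w1, tolerance = 1e-3)
  expect_equal(back_xe$peaks$w2, df$w2, tolerance = 1e-3)
})

test_that("sequences parse from one- and three-letter files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("MQYK", path)
  s1 <- read_sequence(path)
  expect_equal(s1$residues, c("M", "Q", "Y", "K"))
  expect_equal(s1$origin, 1L)

  writeLines("met GLN Tyr LYS", path)
  expect_equal(read_sequence(path)$residues, s1$residues)

  writeLines(c("MQYK", "LAST"), path)
  expect_length(read_sequence(path)$residues, 8L)

  writeLines("MQXZ", path)
  expect_error(read_sequence(path), "unknown residue token")
})

test_that("NMR-STAR shift tables round-trip in both dialects", {
  set.seed(11)
  for (dialect in c("3.1", "2.1")) {
    n <- 12L
    tab <- shift_table(sample(1:6, n, replace = TRUE),
                       sample(c("A", "G", "S", "L"), n, replace = TRUE),
                       sample(c("N", "CA", "C"), n, replace = TRUE),
                       round(stats::runif(n, 10, 180), 3),
                       prob = round(stats::runif(n), 3))
    tab <- tab[!duplicated(paste(tab$seq_id, tab$atom)), ]
    path <- withr::local_tempfile(fileext = ".str")
    write_shift_table(tab, path, dialect = dialect)
    back <- load_shift_table(path)
    key <- order(tab$seq_id, tab$atom)
    bkey <- order(back$seq_id, back$atom)
    expect_equal(back$seq_id[bkey], tab$seq_id[key])
    expect_equal(back$atom[bkey], tab$atom[key])
    expect_equal(back$value[bkey], tab$value[key], tolerance = 1e-3)
  }
})

test_that("shift-table writer refuses empty input and counts rows", {
  tab <- shift_table(c(1, 1, 1, 2, 2, 2, 2), c("G", "G", "G", "A", "A", "A", "A"),
                     c("N", "CA", "C", "N", "CA", "CB", "C"),
                     c(108.9, 45.2, 173.8, 122.5, 52.4, 19.1, 177.5))
  path <- withr::local_tempfile(fileext = ".str")
  write_shift_table(tab, path)
  body <- readLines(path)
  loop_rows <- grep("^  \\s*[0-9]+ ", body)
  expect_length(loop_rows, 7L)
  expect_error(write_shift_table(tab[0, ], path), "empty")
})

test_that("Sparky resonance lists round-trip and omit missing shifts", {
  tab <- shift_table(c(1, 1), c("G", "G"), c("N", "CA"), c(108.95, NA))
  path <- withr::local_tempfile(fileext = ".txt")
  write_sparky_resonances(tab, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines[1], "^G1 N 108.950$")
  back <- read_sparky_resonances(path)
  expect_equal(back$value, 108.95)
  expect_equal(back$res_type, "G")
})

test_that("tabular shift tables load and filter protons", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 ALA CA 52.3", "2 ALA HA 4.2", "3 GLY N 108.1"), path)
  tab <- load_shift_table(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$res_type[tab$atom == "CA"], "A")
  expect_equal(tab$value[tab$atom == "CA"], 52.3)
})

test_that("STAR loader filters protons and reconstructs a sequence", {
  path <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_test", "loop_",
    "  _Atom_chem_shift.ID", "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID", "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Atom_type", "  _Atom_chem_shift.Val",
    "  1 1 GLY N  N 108.9", "  2 1 GLY CA C  45.2",
    "  3 1 GLY HA H   3.9", "  4 2 ALA N  N 122.5",
    "  5 2 ALA CA C  52.4", "  6 2 ALA HB H   1.4",
    "  7 2 ALA CB C  19.1", "  8 3 SER HA H   4.4",
    "  9 4 LEU CA C  55.3",
    "stop_"), path)
  tab <- load_shift_table(path)
  expect_equal(nrow(tab), 6L)   # three H rows dropped
  entry <- load_bmrb_star(path)
  expect_equal(entry$sequence$residues[1:2], c("G", "A"))
  expect_true(3 %in% entry$missing_residues)  # only a proton at residue 3
})
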