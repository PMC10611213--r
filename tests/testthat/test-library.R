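toy_activity_rows <- function() {
  tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    smiles = c("CCO", "CCN", "CCC"),
    target_id = c("T1", "T1", "T2"),
    target_class = c("GPCR", "GPCR", "Enzyme"),
    activity_type = "IC50",
    value_nm = c(100, 50, 2000),
    moa = "inhibitor",
    source = "toy")
}

test_that("to_pactivity implements 9 - log10(nM) and round-trips", {
  expect_equal(to_pactivity(100), 7.0)
  expect_equal(to_pactivity(1), 9.0)
  expect_equal(to_pactivity(1000), 6.0) # 1 uM = the sub-uM boundary
  expect_error(to_pactivity(0), class = "offtarget_value_error")
  expect_error(to_pactivity(-5), class = "offtarget_value_error")
  v <- c(0.3, 7, 123.4, 99000)
  expect_equal(from_pactivity(to_pactivity(v)), v, tolerance = 1e-9)
})

test_that("a toy activity table loads into a consistent library", {
  lib <- make_reference_library(toy_activity_rows())
  expect_equal(nrow(lib$compounds), 3)
  expect_equal(nrow(lib$targets), 2)
  expect_equal(nrow(check_library_integrity(lib)), 0)
  expect_error(make_reference_library(toy_activity_rows()[, -2]),
               class = "offtarget_schema_error")
})

test_that("replicate activities collapse to the most potent measurement", {
  rows <- dplyr::bind_rows(
    toy_activity_rows(),
    tibble::tibble(compound_id = "c1", smiles = "CCO", target_id = "T1",
                   target_class = "GPCR", activity_type = "IC50",
                   value_nm = 10, moa = "inhibitor", source = "toy"))
  lib <- make_reference_library(rows)
  kept <- lib$activities[lib$activities$compound_id == "c1", ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$value_nm, 10)
})

test_that("unparsable structures are rejected, reported, and counted", {
  rows <- dplyr::bind_rows(
    toy_activity_rows(),
    tibble::tibble(compound_id = "bad", smiles = "X&", target_id = "T1",
                   target_class = "GPCR", activity_type = "IC50",
                   value_nm = 5, moa = "inhibitor", source = "toy"))
  lib <- suppressMessages(make_reference_library(rows))
  expect_equal(nrow(lib$compounds), 3)
  rej <- lib$rejected
  expect_equal(nrow(rej$compounds), 1)
  expect_equal(rej$compounds$compound_id, "bad")
  expect_equal(rej$n_activity_rows, 1)
})

test_that("ligand sets respect the inclusive cutoff and are deterministic", {
  rows <- toy_activity_rows()
  rows$value_nm <- from_pactivity(c(5.9, 6.0, 7.2))
  rows$target_id <- "T1"; rows$target_class <- "GPCR"
  lib <- make_reference_library(rows)
  expect_equal(ligand_set(lib, "T1", cutoff = 6.0), c("c2", "c3"))
  expect_equal(ligand_set(lib, "T1", cutoff = 10), character(0))
  expect_identical(ligand_set(lib, "T1", 6.0), ligand_set(lib, "T1", 6.0))
  expect_error(ligand_set(lib, "nope"), class = "offtarget_value_error")
})

test_that("save + load round-trips the library and is byte-stable", {
  lib <- make_reference_library(toy_activity_rows())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_library(lib, d1)
  lib2 <- load_library_dir(d1)
  expect_equal(lib2$compounds, lib$compounds)
  expect_equal(lib2$targets, lib$targets)
  a1 <- lib2$activities; a2 <- lib$activities
  attr(a1, "rejected") <- NULL; attr(a2, "rejected") <- NULL
  expect_equal(as.data.frame(a1), as.data.frame(a2), tolerance = 1e-9)
  save_library(lib2, d2)
  for (f in c("compounds.tsv", "targets.tsv", "activities.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the integrity checker flags a corrupted library", {
  lib <- make_reference_library(toy_activity_rows())
  lib$activities$target_id[1] <- "GHOST"
  issues <- check_library_integrity(lib)
  expect_gt(nrow(issues), 0)
  expect_true(any(issues$problem == "unknown target_id"))
})

test_that("load_library reads the CSV schema from disk", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(toy_activity_rows(), path)
  lib <- load_library(path)
  expect_s3_class(lib, "reference_library")
  expect_equal(nrow(lib$compounds), 3)
  expect_error(load_library("no-such-file.csv"), class = "offtarget_io_error")
})
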