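fixture_path <- function(file) system.file("extdata", file, package = "erec")

test_that("the packaged demonstration survey loads completely", {
  recs <- read_survey(fixture_path("worked_example.csv"),
                      fixture_path("worked_example_mapping.yaml"))
  expect_equal(nrow(recs), 100)
  expect_equal(nrow(attr(recs, "rejects")), 0)
  expect_true(all(c("residence", "weight") %in% names(recs)))
  cls <- classify_records(recs, quiet = TRUE)
  expect_equal(as.vector(table(cls$need_category)[c("MET", "UNDER_MET", "UNMET", "NO_NEED")]),
               c(25, 5, 50, 20))
})

test_that("bad rows are rejected with reasons while the rest load", {
  tmp <- tempfile(fileext = ".csv")
  lines <- readLines(fixture_path("worked_example.csv"))
  lines[2] <- sub("6/18", "six/12", lines[2])     # unparseable acuity
  lines[3] <- sub("^u002,no", "u002,maybe", lines[3])  # unparseable boolean
  writeLines(lines, tmp)
  expect_message(recs2 <- read_survey(tmp, fixture_path("worked_example_mapping.yaml")),
                 "rejected")
  rejects <- attr(recs2, "rejects")
  expect_equal(nrow(recs2), 98)
  expect_equal(sort(rejects$row), c(1, 2))
  expect_match(rejects$reason[rejects$row == 1], "six/12")
  expect_match(rejects$reason[rejects$row == 2], "wears_correction")
  # rejected + loaded = input rows
  expect_equal(nrow(recs2) + nrow(rejects), 100)
})

test_that("structural failures stop early with a clear message", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("id,glasses", tmp)  # header lacks the mapped acuity columns
  expect_error(read_survey(tmp, fixture_path("worked_example_mapping.yaml")),
               "missing from input header")
  # >50% rejected rows means the mapping is wrong
  writeLines(c(readLines(fixture_path("worked_example.csv"))[1],
               "x1,maybe,6/6,,,,,,40,male,urban",
               "x2,maybe,6/6,,,,,,40,male,urban",
               "x3,yes,6/6,,,,,,40,male,urban"), tmp)
  expect_error(read_survey(tmp, fixture_path("worked_example_mapping.yaml")),
               "50%")
  expect_error(read_survey("/nonexistent/file.csv",
                           fixture_path("worked_example_mapping.yaml")),
               "not found")
  expect_error(column_mapping(list(person_id = "id")), "wears_correction")
})

test_that("an empty file with a valid header warns and returns no records", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(readLines(fixture_path("worked_example.csv"))[1], tmp)
  expect_warning(recs <- read_survey(tmp, fixture_path("worked_example_mapping.yaml")),
                 "no rows")
  expect_equal(nrow(recs), 0)
})

test_that("tab-delimited input and JSON mappings are accepted", {
  csv <- readLines(fixture_path("worked_example.csv"))
  tmp <- tempfile(fileext = ".tsv")
  writeLines(gsub(",", "\t", csv), tmp)
  map <- yaml::read_yaml(fixture_path("worked_example_mapping.yaml"))
  jmap <- tempfile(fileext = ".json")
  jsonlite::write_json(map, jmap, auto_unbox = TRUE)
  recs <- read_survey(tmp, jmap)
  expect_equal(nrow(recs), 100)
})

test_that("booleans accept 1/0, yes/no, true/false case-insensitively", {
  parsed <- erec:::.parse_bool(c("1", "0", "Yes", "NO", "TRUE", "false", "", "2"))
  expect_identical(parsed[1:6], c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_true(is.na(parsed[7]))
  expect_identical(attr(parsed, "bad"),
                   c(rep(FALSE, 7), TRUE))
})

test_that("writing a synthetic cohort and reading it back is lossless", {
  td <- tempfile()
  expect_equal(cli_main(c("simulate", "--n", "150", "--seed", "8",
                          "--out-dir", td)), 0L)
  recs <- read_survey(file.path(td, "cohort.csv"), file.path(td, "mapping.yaml"))
  cohort <- generate_population(generator_config(n = 150, seed = 8))
  expect_equal(nrow(recs), 150)
  expect_identical(recs$person_id, cohort$records$person_id)
  expect_identical(recs$wears_correction, cohort$records$wears_correction)
  for (col in c("ucva_left", "ucva_right", "cva_left", "cva_right",
                "pinhole_left", "pinhole_right")) {
    expect_equal(recs[[col]], cohort$records[[col]], tolerance = 1e-9,
                 label = col)
  }
  expect_identical(recs$age_band, cohort$records$age_band)
})

test_that("reports round-trip through JSON and have the expected CSV shape", {
  recs <- worked_example_records()
  report <- multi_threshold_report(recs, c("6/12", "6/18"), c("6/12", "6/18"),
                                   by = "residence", ci_method = "wilson")
  jpath <- tempfile(fileext = ".json")
  write_report(report, jpath, "json")
  back <- read_report(jpath)
  expect_equal(back$estimates$value_pct, round(report$estimates$value_pct, 6))
  expect_equal(back$metadata$n_records, 100)
  cpath <- tempfile(fileext = ".csv")
  write_report(report, cpath, "csv")
  tab <- utils::read.csv(cpath)
  # indicators x threshold pairs x (strata + overall)
  expect_equal(nrow(tab), 3 * 2 * (2 + 1))
})

test_that("identical inputs and seeds give byte-identical outputs", {
  t1 <- tempfile(); t2 <- tempfile()
  cli_main(c("simulate", "--n", "120", "--seed", "5", "--out-dir", t1))
  cli_main(c("simulate", "--n", "120", "--seed", "5", "--out-dir", t2))
  for (f in c("cohort.csv", "truth.csv", "config.yaml")) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)),
                     label = f)
  }
  o1 <- tempfile(fileext = ".json"); o2 <- tempfile(fileext = ".json")
  args <- c("compute", "--input", file.path(t1, "cohort.csv"),
            "--mapping", file.path(t1, "mapping.yaml"),
            "--ci", "bootstrap", "--reps", "200", "--seed", "4")
  expect_equal(suppressMessages(cli_main(c(args, "--out", o1))), 0L)
  expect_equal(suppressMessages(cli_main(c(args, "--out", o2))), 0L)
  expect_identical(readLines(o1), readLines(o2))
})

test_that("the command line rejects bad invocations with a nonzero status", {
  expect_equal(suppressMessages(cli_main(character(0))), 1L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
  expect_equal(suppressMessages(cli_main("compute")), 1L)  # missing --input
  expect_equal(suppressMessages(
    cli_main(c("compute", "--input", "x.csv", "--mapping", "y.yaml",
               "--reference", "z.csv"))), 1L)  # reference without --by
})

test_that("the compute subcommand reproduces the demonstration coverage", {
  out <- tempfile(fileext = ".json")
  status <- suppressMessages(cli_main(c(
    "compute",
    "--input", fixture_path("worked_example.csv"),
    "--mapping", fixture_path("worked_example_mapping.yaml"),
    "--out", out)))
  expect_equal(status, 0L)
  report <- read_report(out)
  e <- report$estimates
  expect_equal(e$value_pct[e$indicator == "eREC"], 31.25)
  expect_equal(e$value_pct[e$indicator == "REC"], 37.5)
  expect_equal(round_half_up(e$value_pct[e$indicator == "quality_gap"], 1), 16.7)
})
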