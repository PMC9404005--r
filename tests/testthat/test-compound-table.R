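test_that("packaged table has the documented composition", {
  tbl <- compound_table()
  expect_equal(nrow(tbl), 73)
  counts <- table(tbl$class)
  expect_equal(unname(counts[["neutral"]]), 26)
  expect_equal(unname(counts[["carboxylic_or_phenolic_acid"]]), 33)
  expect_equal(unname(counts[["sulfonic_acid"]]), 14)
  expect_equal(attr(tbl, "ph"), 7)
  # all solutes neutral or anionic at pH 7; descriptor sign conventions
  expect_true(all(tbl$n_e <= 0))
  expect_true(all(tbl$a >= 0) && all(tbl$b >= 0))
  # W1 row parsed as printed
  w1 <- tbl[tbl$id == "W1", ]
  expect_equal(w1$name, "benzoic acid")
  expect_equal(w1$log_p, 1.87)
  expect_equal(w1$pka, 4.20)
  expect_equal(w1$log_d_ref, -0.93)
})

test_that("missing-value tokens parse as NA, never zero", {
  tbl <- compound_table()
  # "/" rows: strongly ionized, unretained in IS mode
  expect_true(is.na(tbl$log_kw_is[tbl$id == "W21"]))
  expect_true(is.na(tbl$log_d_ref[tbl$id == "S1"]))
  # "NA" rows: no literature log P / pKa
  expect_true(is.na(tbl$log_p[tbl$id == "S2"]))
  expect_false(any(tbl$log_kw_is == 0, na.rm = TRUE) &&
    all(is.na(tbl$log_kw_is)))
})

test_that("transposition repair swaps only the N5/N6 log_kw pair", {
  raw <- compound_table(repair_transposition = FALSE)
  fixed <- compound_table()
  expect_equal(raw$log_kw_is[raw$id == "N5"], 5.60)
  expect_equal(fixed$log_kw_is[fixed$id == "N5"], 2.64)
  expect_equal(fixed$log_kw_is[fixed$id == "N6"], 5.60)
  expect_match(raw$note[raw$id == "N5"], "transposition")
  untouched <- setdiff(names(raw), c("note"))
  others <- raw$id != "N5" & raw$id != "N6"
  expect_identical(raw[others, untouched], fixed[others, untouched])
  # log P / log D columns never touched
  expect_identical(raw$log_p, fixed$log_p)
  expect_identical(raw$log_d_ref, fixed$log_d_ref)
})

test_that("the repair is what makes the table self-consistent", {
  # with the verbatim table the four-descriptor IS fit degrades sharply and
  # the retention coefficient collapses; the repaired table restores the fit
  # quality the reference statistics report
  raw_fit <- fit_qsrr(
    compound_table(repair_transposition = FALSE),
    predictors = c("log_kw_is", "n_e", "a", "b"),
    ids = cascade_ids()$stage1_training
  )
  fixed_fit <- fit_qsrr(
    compound_table(),
    predictors = c("log_kw_is", "n_e", "a", "b"),
    ids = cascade_ids()$stage1_training
  )
  expect_lt(raw_fit$r2, 0.9)
  expect_gt(fixed_fit$r2, 0.95)
  expect_lt(raw_fit$coefficients$estimate[2], 0.9)
  expect_gt(fixed_fit$coefficients$estimate[2], 1.0)
})

test_that("neutral compounds carry one log_kw across modes", {
  tbl <- compound_table()
  neut <- tbl[tbl$class == "neutral", ]
  expect_equal(neut$log_kw_is, neut$log_kw_ip)
  broken <- tbl
  broken$log_kw_ip[broken$id == "N1"] <- broken$log_kw_is[broken$id == "N1"] + 0.5
  expect_error(validate_compounds(broken), class = "logdqsrr_validation_error")
})

test_that("reader handles empty tables, bad cells and duplicate ids", {
  header <- paste(c(compound_columns, "note"), collapse = ",")
  empty <- read_compound_table(write_temp_compounds(header))
  expect_equal(nrow(empty), 0)

  bad <- write_temp_compounds(c(
    header,
    "X1,foo,neutral,not_a_number,,1.0,1.0,1.0,0,0,0,"
  ))
  expect_error(read_compound_table(bad), class = "logdqsrr_parse_error")

  dup <- write_temp_compounds(c(
    header,
    "X1,foo,neutral,1.0,,1.0,1.0,1.0,0,0,0,",
    "X1,bar,neutral,2.0,,2.0,2.0,2.0,0,0,0,"
  ))
  expect_error(read_compound_table(dup), class = "logdqsrr_validation_error")

  missing_col <- write_temp_compounds(c("id,name", "X1,foo"))
  expect_error(read_compound_table(missing_col), class = "logdqsrr_schema_error")
})

test_that("write/read round trip is exact for both dialects", {
  tbl <- compound_table()
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_compound_table(tbl, path, dialect = dialect)
    back <- read_compound_table(path, dialect = dialect)
    expect_identical(as.data.frame(back), as.data.frame(tbl))
  }
})

test_that("select_by_ids preserves order and rejects bad requests", {
  tbl <- compound_table()
  sub <- select_by_ids(tbl, c("S1", "N3", "W20"))
  expect_equal(sub$id, c("S1", "N3", "W20"))
  expect_equal(attr(sub, "ph"), 7)

  s1 <- select_by_ids(tbl, c(paste0("N", 1:26), paste0("W", 1:20)))
  expect_equal(nrow(s1), 46)

  expect_equal(nrow(select_by_ids(tbl, character(0))), 0)
  expect_error(select_by_ids(tbl, c("N1", "N1")), class = "logdqsrr_lookup_error")
  expect_error(select_by_ids(tbl, "NOPE"), class = "logdqsrr_lookup_error")
})

test_that("reference log D column agrees with the ionization correction", {
  tbl <- compound_table()
  w <- tbl[tbl$id %in% paste0("W", 1:20), ]
  recomputed <- logd_at_ph(w$log_p, w$pka, ph = 7)
  # two-decimal printing tolerance
  expect_true(all(abs(recomputed - w$log_d_ref) <= 0.005))
  neutrals <- tbl[tbl$class == "neutral", ]
  expect_equal(neutrals$log_d_ref, neutrals$log_p)
})
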