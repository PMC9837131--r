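# cohort builder: code mapping, key dates, windows, labels, feature matrix

test_that("code mapping looks up, counts misses, and passes through", {
  map <- c("250.00" = "250.2", "E11" = "250.2")
  expect_equal(as.character(map_codes("250.00", map)), "250.2")
  m <- map_codes(c("X999", "E11"), map)
  expect_true(is.na(m[1]))
  expect_equal(attr(m, "n_unmapped"), 1L)
  ident <- map_codes(c("a", "b"), NULL)
  expect_equal(as.character(ident), c("a", "b"))
  expect_equal(attr(ident, "n_unmapped"), 0L)
})

test_that("mapping tables reject malformed and duplicate rows", {
  f <- tempfile()
  writeLines(c("source,target", "a,1", "b,"), f)
  expect_error(read_code_map(f), "malformed")
  writeLines(c("source,target", "a,1", "a,2"), f)
  expect_error(read_code_map(f), "duplicate")
})

test_that("index dates take the earliest target-drug event", {
  ev <- data.frame(
    patient_id = c("A", "A", "B"),
    date = as.Date(c("2020-01-03", "2020-01-07", "2020-01-02")),
    code_system = c("drug", "drug", "diagnosis"),
    code = c("RXT", "RXT", "DX1"),
    hospitalization_flag = FALSE, death_flag = FALSE)
  cfg <- cohort_config("RXT")
  idx <- assign_index_date(ev, cfg)
  expect_equal(unname(idx["A"]), as.Date("2020-01-03"))
  expect_true(is.na(idx["B"]))   # no target drug: excluded
})

test_that("a required diagnosis defers the index to the first treatment after it", {
  ev <- data.frame(
    patient_id = "A",
    date = as.Date(c("2020-01-03", "2020-01-05", "2020-01-09")),
    code_system = c("drug", "diagnosis", "drug"),
    code = c("RXT", "CRC", "RXT"),
    hospitalization_flag = FALSE, death_flag = FALSE)
  cfg <- cohort_config("RXT", required_diagnosis_codes = "CRC")
  expect_equal(unname(assign_index_date(ev, cfg)["A"]),
               as.Date("2020-01-09"))
})

test_that("baseline is strictly pre-index; follow-up closes at last drug + 30", {
  ev <- data.frame(
    patient_id = "A",
    date = as.Date("2020-01-01") + c(0, 4, 5, 4 + 30, 4 + 31),
    code_system = c("diagnosis", "drug", "diagnosis", "diagnosis",
                    "diagnosis"),
    code = c("DX1", "RXT", "DX2", "DX3", "DX4"),
    hospitalization_flag = FALSE, death_flag = FALSE)
  cfg <- cohort_config("RXT")
  idx <- assign_index_date(ev, cfg)
  sp <- split_baseline_followup(ev, idx, cfg)
  expect_equal(sp$baseline$code, "DX1")
  # index-date event itself is follow-up; +30 is inside, +31 outside
  expect_setequal(sp$followup$code, c("RXT", "DX2", "DX3"))
  expect_equal(unname(sp$followup_end["A"]), as.Date("2020-01-05") + 30)
})

test_that("SAE labels honour flags and an optional qualifying code set", {
  fu <- data.frame(
    patient_id = c("A", "B", "C"),
    date = as.Date("2020-02-01"),
    code_system = "diagnosis",
    code = c("DX1", "DX2", "DX3"),
    hospitalization_flag = c(FALSE, TRUE, TRUE),
    death_flag = c(TRUE, FALSE, FALSE))
  y <- label_sae(fu, c("A", "B", "C", "D"))
  expect_equal(unname(y), c(1L, 1L, 1L, 0L))
  y2 <- label_sae(fu, c("A", "B", "C"), sae_codes = "DX1")
  expect_equal(unname(y2), c(1L, 0L, 0L))
})

test_that("age one-hot uses half-open uniform bins", {
  expect_equal(names(which(discretize_age(77) == 1)), "age:[70,80)")
  expect_equal(names(which(discretize_age(80) == 1)), "age:[80,90)")
  expect_equal(unname(discretize_age(0)[1]), 1L)
  expect_error(discretize_age(-1), "nonnegative")
  expect_equal(rowSums(discretize_age(c(5, 15, 77))), rep(1, 3))
})

test_that("the feature matrix equals hand enumeration on a tiny cohort", {
  ev <- tiny_events()
  cfg <- cohort_config("RXT")
  co <- build_cohort(ev, cfg)
  # C has no RXT event: excluded with a reason
  expect_equal(co$exclusions$patient_id, "C")
  expect_setequal(co$patient_ids, c("A", "B"))
  # A: baseline {DX1}; B: baseline empty (demographics still populated)
  expect_equal(unname(co$X["dx:DX1", "A"]), 1)
  expect_equal(sum(co$X[grep("^dx:", rownames(co$X)), "B"]), 0)
  expect_equal(unname(co$X["age:[70,80)", "A"]), 1)
  expect_equal(unname(co$X["age:[80,90)", "B"]), 1)
  # A's hospitalization at index+9d is inside the window -> SAE
  expect_equal(unname(co$y["A"]), 1L)
  # B's hospitalization is 80 days after its only drug event -> outside
  expect_equal(unname(co$y["B"]), 0L)
  # repeated baseline events binarize to 1, not 2
  ev2 <- rbind(ev, data.frame(patient_id = "A", date = as.Date("2020-02-02"),
                              code_system = "diagnosis", code = "DX1",
                              hospitalization_flag = FALSE,
                              death_flag = FALSE))
  expect_equal(unname(build_cohort(ev2, cfg)$X["dx:DX1", "A"]), 1)
})

test_that("the matrix is invariant to event order and bit-reproducible", {
  ev <- tiny_events()
  cfg <- cohort_config("RXT")
  co1 <- build_cohort(ev, cfg)
  set.seed(1)
  co2 <- build_cohort(ev[sample.int(nrow(ev)), ], cfg)
  expect_identical(co1$X, co2$X)
  expect_identical(co1$y, co2$y)
  expect_identical(co1, build_cohort(ev, cfg))
})

test_that("unmapped codes are dropped with a logged count", {
  ev <- rbind(tiny_events(),
              data.frame(patient_id = "A", date = as.Date("2020-02-05"),
                         code_system = "diagnosis", code = "DX9",
                         hospitalization_flag = FALSE, death_flag = FALSE))
  cfg <- cohort_config("RXT")
  dxm <- c(DX1 = "PHE1")   # DX9 (baseline) is unmapped
  co <- build_cohort(ev, cfg, diagnosis_map = dxm)
  expect_false(any(grepl("DX9", rownames(co$X))))
  expect_true("dx:PHE1" %in% rownames(co$X))
  expect_false(any(grepl("DX2", rownames(co$X))))
  expect_gte(co$unmapped["diagnosis"], 1L)
})

test_that("a synthetic event stream round-trips through the builder exactly", {
  s <- simulate_event_stream(n_patients = 50, seed = 14)
  co <- build_cohort(s$events, s$config)
  expect_setequal(co$patient_ids, names(s$truth$index_date))
  expect_equal(co$index_date[co$patient_ids],
               s$truth$index_date[co$patient_ids])
  expect_equal(co$y[co$patient_ids], s$truth$y[co$patient_ids])
  # planted binary baseline features match, column by column
  code_feats <- rownames(co$X)[grepl("^(dx|rx):", rownames(co$X))]
  planted <- t(s$truth$features[co$patient_ids, code_feats])
  expect_equal(unname(co$X[code_feats, ]), unname(planted))
  # same-seed regeneration is byte-identical end to end
  s2 <- simulate_event_stream(n_patients = 50, seed = 14)
  expect_identical(s$events, s2$events)
  expect_identical(co, build_cohort(s2$events, s2$config))
})

test_that("cohort artifacts survive a write/read round trip", {
  s <- simulate_event_stream(n_patients = 20, seed = 5)
  co <- build_cohort(s$events, s$config)
  d <- tempfile()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(unname(back$X), unname(co$X))
  expect_equal(back$y, co$y)
  expect_equal(back$index_date, co$index_date)
})

test_that("event files validate dates and schema", {
  f <- tempfile()
  writeLines(c("patient_id,date,code_system,code,hospitalization_flag,death_flag",
               "A,2020-13-45,diagnosis,DX1,0,0"), f)
  expect_error(read_events(f), "row")
  writeLines(c("patient_id,date,code_system,code,hospitalization_flag,death_flag",
               "A,2020-01-02,imaging,DX1,0,0"), f)
  expect_warning(read_events(f), "code_system")
})
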