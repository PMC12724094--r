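test_that("service-use records round-trip through write and read", {
  dir <- withr::local_tempdir()
  b <- toy_bundle()
  write_trial_bundle(b, dir)
  b2 <- read_trial_bundle(dir)
  expect_tables_identical(b$service_use, b2$service_use)
  expect_tables_identical(b$roster, b2$roster)
  expect_tables_identical(b$therapy, b2$therapy)
  expect_identical(b$eq5d$mobility, b2$eq5d$mobility)
  expect_tables_identical(b$assessments, b2$assessments)
})

test_that("an empty service-use file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,period,service,contact_count,inpatient_days",
             path)
  expect_identical(nrow(load_service_use(path)), 0L)
})

test_that("invalid service-use rows are rejected with row numbers", {
  write_use <- function(lines) {
    path <- tempfile(fileext = ".csv")
    writeLines(c("participant_id,period,service,contact_count,inpatient_days",
                 lines), path)
    path
  }
  expect_error(load_service_use(write_use("A,w16,GP,-1,0")),
               "non-negative integer.*rows: 1")
  expect_error(load_service_use(write_use("A,w16,chiropodist,1,0")),
               "unknown service")
  expect_error(load_service_use(write_use("A,w16,GP,1,3")),
               "non-inpatient")
  expect_error(
    load_service_use(write_use("A,w16,inpatient_mental_health,0,113")),
    "exceeds the period span")
  # alias table maps nonstandard labels instead of rejecting them
  x <- load_service_use(write_use("A,w16,gp visit,2,0"),
                        aliases = c("gp visit" = "GP"))
  expect_identical(x$service, "GP")
})

test_that("therapy and EQ-5D loaders enforce their invariants", {
  tpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,arm,sessions", "A,TAU,3"), tpath)
  expect_error(load_therapy(tpath), "TAU participants")

  epath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,week,mobility,selfcare,activity,pain,anxiety",
               "A,16,1,2,6,1,1"), epath)
  expect_error(load_eq5d(epath), "1..5")
  writeLines(c("participant_id,week,mobility,selfcare,activity,pain,anxiety",
               "A,16,1,2,,1,1"), epath)
  expect_error(load_eq5d(epath), "wholly missing")
  writeLines(c("participant_id,week,mobility,selfcare,activity,pain,anxiety",
               "A,16,,,,,"), epath)
  expect_true(is.na(load_eq5d(epath)$mobility))
})

test_that("unit-cost tables round-trip and fail loudly on gaps", {
  uc <- default_unit_costs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_unit_costs(uc, path)
  uc2 <- load_unit_costs(path)
  expect_equal(tibble::as_tibble(uc2)[c("service", "unit", "cost")],
               tibble::as_tibble(uc)[c("service", "unit", "cost")])

  # a table missing the therapist rate is rejected at load time
  writeLines(c("service,unit,cost", "GP,per_contact,41",
               "inpatient_mental_health,per_day,341",
               "fixed_tech,per_recipient,50"), path)
  expect_error(load_unit_costs(path), "therapist_session")

  # costing a service with no unit cost names the service
  uc3 <- toy_unit_costs()
  b <- toy_bundle()
  b$service_use$service[1] <- "psychologist"
  expect_error(cost_components(b$service_use, b$roster, uc3),
               "psychologist")

  # an all-zero table is valid and costs everything at zero
  uc0 <- uc
  uc0$cost[] <- 0
  costs <- participant_costs(toy_bundle()$service_use, toy_bundle()$therapy,
                             toy_bundle()$roster, uc0)
  expect_true(all(costs$total == 0))
})

test_that("validate_dataset reports orphans, duplicates and protocol breaks", {
  b <- toy_bundle()
  expect_identical(nrow(validate_dataset(b$service_use, b$therapy, b$eq5d,
                                         b$roster)), 0L)

  b$service_use <- dplyr::bind_rows(b$service_use, b$service_use[1, ])
  b$service_use$participant_id[2] <- "ZZZ"
  b$therapy$sessions[1] <- 3L   # a TAU participant with sessions
  rep <- validate_dataset(b$service_use, b$therapy, b$eq5d, b$roster)
  expect_setequal(unique(rep$check),
                  c("orphan_participant", "duplicate_service_row",
                    "tau_with_sessions"))
  dup <- rep[rep$check == "duplicate_service_row", ]
  expect_setequal(dup$row, c(1L, 4L))  # both rows of the duplicated pair
  expect_error(validate_dataset(b$service_use, b$therapy, b$eq5d, b$roster,
                                strict = TRUE), "validation failed")
})
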