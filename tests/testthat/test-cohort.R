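# Cohort data model: I/O, validation, eligibility, age standardization,
# incidence.

test_that("well-formed input round-trips through CSV identically", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(file.path(dir, "baseline.csv"),
                     file.path(dir, "visits.csv"),
                     file.path(dir, "outcomes.csv"))
  expect_equal(co2$baselines, co$baselines)
  expect_equal(co2$visits, co$visits)
  expect_equal(co2$outcomes, co$outcomes)
  expect_false(is.unsorted(co2$visits$time_years[co2$visits$patient_id == "A"]))
})

test_that("marker dialects normalize; indefinite-for-dysplasia becomes missing", {
  baselines <- data.frame(patient_id = "A", age_years = 60, female = 0)
  visits <- data.frame(patient_id = c("A", "A", "A"),
                       time_years = c(0, 1, 2),
                       lgd = c("NDBE", "IND", "LGD"),
                       p53 = c("normal", "aberrant", ""),
                       sox2 = c("0", "1", ""),
                       esophagitis = 0, long_segment = 1)
  outcomes <- data.frame(patient_id = "A", event_time_years = 4, event = 0)
  co <- new_cohort(baselines, visits, outcomes)
  expect_equal(co$visits$lgd, c(0, NA, 1))
  expect_equal(co$visits$p53, c(0, 1, NA))
  expect_equal(co$visits$sox2, c(0, 1, NA))
  # other fields intact on the IND row
  expect_equal(co$visits$esophagitis[2], 0)
})

test_that("structural and validation errors name the offender", {
  co <- tiny_cohort()
  visits_bad <- rbind(co$visits,
                      data.frame(patient_id = "ZZ", time_years = 0, lgd = 0,
                                 p53 = 0, sox2 = 0, esophagitis = 0,
                                 long_segment = 0))
  expect_error(new_cohort(co$baselines, visits_bad, co$outcomes), "ZZ")
  # visit after the event time, naming patient and time
  visits_late <- co$visits
  visits_late$time_years[visits_late$patient_id == "A" &
                           visits_late$time_years == 2.4] <- 5.0
  expect_error(new_cohort(co$baselines, visits_late, co$outcomes),
               "A.*5", ignore.case = TRUE)
  # duplicate visit time
  visits_dup <- rbind(co$visits, co$visits[1, ])
  expect_error(new_cohort(co$baselines, visits_dup, co$outcomes),
               "duplicate")
  # two outcome records
  oc_dup <- rbind(co$outcomes, co$outcomes[1, ])
  expect_error(new_cohort(co$baselines, co$visits, oc_dup),
               "more than one outcome")
})

test_that("missing covariates carry forward; missing at index errors", {
  baselines <- data.frame(patient_id = "A", age_years = 60, female = 0)
  visits <- data.frame(patient_id = c("A", "A"), time_years = c(0, 1),
                       lgd = 0, p53 = 0, sox2 = 0,
                       esophagitis = c(1, NA), long_segment = c(0, NA))
  outcomes <- data.frame(patient_id = "A", event_time_years = 3, event = 0)
  co <- new_cohort(baselines, visits, outcomes)
  expect_equal(co$visits$esophagitis, c(1, 1))
  expect_equal(co$visits$long_segment, c(0, 0))
  visits$esophagitis <- c(NA, 1)
  expect_error(new_cohort(baselines, visits, outcomes), "index")
})

test_that("eligibility filters exclude short follow-up and no-marker patients", {
  co <- tiny_cohort()
  # add one early progressor and one patient with no marker data at all
  bl <- rbind(co$baselines,
              data.frame(patient_id = c("C", "D"), age_years = c(55, 70),
                         female = c(0, 0)))
  vs <- rbind(co$visits,
              data.frame(patient_id = c("C", "D"), time_years = 0,
                         lgd = c(0, NA), p53 = c(NA, NA), sox2 = c(NA, NA),
                         esophagitis = 0, long_segment = 1))
  oc <- rbind(co$outcomes,
              data.frame(patient_id = c("C", "D"),
                         event_time_years = c(0.4, 6), event = c(1, 0),
                         entry_time_years = 0))
  full <- new_cohort(bl, vs, oc)
  res <- apply_eligibility_filters(full)
  expect_equal(res$report$n_eligible, 4)
  expect_equal(res$report$n_excluded_short_followup, 1)
  expect_equal(res$report$n_excluded_no_marker_data, 1)
  expect_equal(res$report$n_included, 2)
  expect_setequal(res$cohort$baselines$patient_id, c("A", "B"))
  expect_true(all(res$cohort$outcomes$entry_time_years == 0.5))
  # idempotence
  res2 <- apply_eligibility_filters(res$cohort)
  expect_equal(res2$cohort$baselines, res$cohort$baselines)
  expect_equal(res2$report$n_included, 2)
  expect_equal(res2$report$n_excluded_short_followup +
                 res2$report$n_excluded_no_marker_data, 0)
})

test_that("a 728-patient eligible set with 97 all-missing-marker patients keeps 631", {
  n <- 728
  ids <- sprintf("P%03d", seq_len(n))
  baselines <- data.frame(patient_id = ids, age_years = 50 + seq_len(n) %% 30,
                          female = seq_len(n) %% 2)
  visits <- data.frame(patient_id = ids, time_years = 0,
                       lgd = 0, p53 = 0, sox2 = 0,
                       esophagitis = 0, long_segment = 1)
  no_marker <- seq_len(97)
  visits$lgd[no_marker] <- NA
  visits$p53[no_marker] <- NA
  visits$sox2[no_marker] <- NA
  outcomes <- data.frame(patient_id = ids, event_time_years = 2 + (seq_len(n) %% 9),
                         event = as.integer(seq_len(n) %% 12 == 0))
  co <- new_cohort(baselines, visits, outcomes)
  res <- apply_eligibility_filters(co)
  expect_equal(res$report$n_included, 631)
  expect_equal(res$report$n_excluded_no_marker_data, 97)
})

test_that("age standardization freezes the sample scaler and scores new ages", {
  baselines <- data.frame(patient_id = c("A", "B", "C"),
                          age_years = c(50, 60, 70), female = 0)
  visits <- data.frame(patient_id = c("A", "B", "C"), time_years = 0,
                       lgd = 0, p53 = 0, sox2 = 0, esophagitis = 0,
                       long_segment = 0)
  outcomes <- data.frame(patient_id = c("A", "B", "C"),
                         event_time_years = 5, event = 0)
  co <- standardize_age(new_cohort(baselines, visits, outcomes))
  expect_equal(unname(co$age_scaler), c(60, 10))
  expect_equal(barrettjm:::scaled_age(c(50, 60, 70), co$age_scaler),
               c(-1, 0, 1))
  # new patient scored against the frozen scaler
  expect_equal(barrettjm:::scaled_age(80, co$age_scaler), 2)
  # zero variance errors
  baselines$age_years <- 60
  co2 <- new_cohort(baselines, visits, outcomes)
  expect_error(standardize_age(co2), "distinct|variance")
})

test_that("incidence rate is events per 100 person-years with exact Poisson CI", {
  co <- incidence_cohort(54, 577, 4475)
  inc <- compute_incidence(co)
  expect_equal(inc$person_years, 4475, tolerance = 1e-10)
  expect_equal(round(inc$rate, 1), 1.2)
  expect_equal(round(inc$lower, 1), 0.9)
  expect_equal(round(inc$upper, 1), 1.6)
  # degenerate cases
  co0 <- incidence_cohort(0, 10, 1000)
  expect_equal(compute_incidence(co0)$rate, 0)
  co1 <- incidence_cohort(1, 9, 50)
  expect_equal(compute_incidence(co1)$rate, 2.0)
  # invariance to patient ordering
  perm <- rev(seq_len(nrow(co$baselines)))
  co_perm <- new_cohort(co$baselines[perm, ], co$visits, co$outcomes,
                        age_scaler = co$age_scaler)
  expect_equal(compute_incidence(co_perm)$rate, inc$rate)
})

test_that("person-years after filtering equals sum of follow-up minus run-in", {
  res <- make_analysis_cohort(n = 60, seed = 5)
  oc <- res$cohort$outcomes
  expect_equal(compute_incidence(res$cohort)$person_years,
               sum(oc$event_time_years - 0.5))
})
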