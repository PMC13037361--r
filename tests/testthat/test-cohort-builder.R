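test_that("eligibility filter applies the three rules with strict/inclusive boundaries", {
  rec <- make_records(numeric(0), n_healthy = 5)
  rec$h05[2] <- 1200       # anomalous reading
  rec$bmi[3] <- 27.5       # below BMI cutoff
  rec$h11[4] <- 1000       # exactly at the threshold: kept
  rec$bmi[5] <- 29.0       # exactly at the cutoff: kept
  fv <- filter_valid(rec)
  expect_equal(fv$kept$id, rec$id[c(1, 4, 5)])
  expect_equal(fv$rejections$reason, c("anomalous_reading", "low_bmi"))

  # missing hourly value takes precedence over the other rules
  rec$h00[1] <- NA
  rec$bmi[1] <- 20
  fv2 <- filter_valid(rec)
  expect_equal(fv2$rejections$reason[fv2$rejections$id == rec$id[1]],
               "missing_hourly")

  empty <- filter_valid(rec[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejections), 0)
})

test_that("filter agrees with an independent per-rule oracle on randomized records", {
  withr::with_seed(101, {
    n <- 1000
    rec <- make_records(numeric(0), n_healthy = n)
    h <- matrix(runif(n * 24, 0, 900), n, 24)
    # inject anomalies, exact boundaries and missing values
    h[sample(length(h), 40)] <- runif(40, 1000.0001, 1500)
    h[sample(length(h), 20)] <- 1000
    h[sample(length(h), 30)] <- NA
    h[sample(length(h), 5)] <- Inf
    rec[, HOURS] <- h
    rec$bmi <- round(runif(n, 26, 34), 1)
    rec$bmi[sample(n, 30)] <- 29.0
  })
  fv <- filter_valid(rec)
  orc <- oracle_filter(rec)
  expect_identical(fv$kept$id, orc$kept_ids)
  expect_identical(fv$rejections$reason,
                   orc$reason[!is.na(orc$reason)])
})

test_that("disease status follows diagnosis timing relative to the wear week", {
  rec <- make_records(c(-2, 4, 7, 0, 12), n_healthy = 1)
  cls <- classify_status(rec)
  expect_equal(as.character(cls$status),
               c("diagnosed", "prodromal", "prodromal", "diagnosed",
                 "beyond_window", "healthy"))
  expect_equal(cls$within_5y, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))

  # qualifying code but no offset is a data-integrity error
  bad <- make_records(3)
  bad$diagnosis_offset_years <- NA_real_
  expect_error(classify_status(bad), "integrity")

  # prefix matching on M17 catches sub-codes
  sub <- make_records(1)
  sub$icd10 <- "M17.9"
  expect_equal(as.character(classify_status(sub)$status), "prodromal")
})

test_that("status labelling partitions any generated cohort", {
  co <- generate_population(synthetic_config(n_participants = 800,
                                             case_fraction = 0.3,
                                             seed = 3))
  cls <- classify_status(co)
  expect_equal(sum(table(cls$status)), nrow(co))
  expect_true(all(cls$within_5y[cls$status != "prodromal"] == FALSE))
})

test_that("matched undersampling reduces covariate imbalance deterministically", {
  withr::with_seed(77, {
    n <- 2000
    cases <- make_records(rep(-1, 400))
    cases$age <- rnorm(400, 70, 5)
    cases$bmi <- rnorm(400, 33, 2)
    cases$sex <- factor(sample(c("female", "male"), 400, TRUE,
                               prob = c(0.3, 0.7)),
                        levels = c("female", "male"))
    controls <- make_records(numeric(0), n_healthy = n)
    controls$age <- rnorm(n, 60, 5)  # ten years younger on average
    controls$bmi <- rnorm(n, 31, 2)
    controls$sex <- factor(sample(c("female", "male"), n, TRUE),
                           levels = c("female", "male"))
    controls$id <- sprintf("C%04d", 1:n)
  })
  sel <- suppressWarnings(matched_undersample(controls, cases, seed = 9))
  expect_equal(nrow(sel), 400)
  expect_equal(anyDuplicated(sel$id), 0)
  # fields untouched: every selected row is an original control row
  expect_true(all(sel$id %in% controls$id))
  orig <- controls[match(sel$id, controls$id), ]
  rownames(orig) <- NULL
  selc <- sel
  rownames(selc) <- NULL
  expect_identical(selc, orig)
  pre <- abs(compute_smd(cases$age, controls$age))
  post <- abs(compute_smd(cases$age, sel$age))
  expect_lt(post, pre)
  pre_b <- abs(compute_smd(cases$bmi, controls$bmi))
  post_b <- abs(compute_smd(cases$bmi, sel$bmi))
  expect_true(post_b < pre_b || post_b < 0.1)

  sel2 <- suppressWarnings(matched_undersample(controls, cases, seed = 9))
  expect_identical(sel, sel2)
  expect_error(matched_undersample(controls[1:10, ], cases), "infeasible")
})

test_that("null matching keeps already-balanced groups balanced", {
  withr::with_seed(5, {
    cases <- make_records(rep(-1, 300))
    cases$age <- rnorm(300, 65, 5)
    cases$bmi <- rnorm(300, 32, 2)
    controls <- make_records(numeric(0), n_healthy = 1500)
    controls$age <- rnorm(1500, 65, 5)
    controls$bmi <- rnorm(1500, 32, 2)
  })
  sel <- suppressWarnings(matched_undersample(controls, cases, seed = 1))
  expect_lt(abs(compute_smd(cases$age, sel$age)), 0.2)
  expect_lt(abs(compute_smd(cases$bmi, sel$bmi)), 0.2)
})

test_that("scenario assembly matches the counting oracle", {
  withr::with_seed(55, {
    rec <- make_records(
      c(runif(50, -10, 0),              # diagnosed
        runif(20, 5.0001, 10),          # prodromal, beyond 5 years
        runif(10, 0.0001, 5)),          # prodromal within 5 years
      n_healthy = 500)
    rec$age <- rnorm(nrow(rec), 65, 5)
    rec$bmi <- rnorm(nrow(rec), 32, 2)
  })
  s1 <- suppressWarnings(build_scenario(rec, 1, seed = 2))
  expect_equal(sum(s1$labels == 0), 80)
  expect_equal(sum(s1$labels == 1), 80)
  s2 <- build_scenario(rec, 2, seed = 2)
  expect_equal(sum(s2$labels == 0), 30)   # prodromal
  expect_equal(sum(s2$labels == 1), 50)   # diagnosed
  expect_equal(length(s2$labels), 80)     # all eligible retained
  s3 <- suppressWarnings(build_scenario(rec, 3, seed = 2))
  expect_equal(sum(s3$labels == 0), 10)
  expect_equal(sum(s3$labels == 1), 10)
  expect_equal(unname(s1$provenance$counts["healthy"]), 500)
  expect_equal(unname(s1$provenance$counts["prodromal_within_5y"]), 10)

  no_prod <- make_records(runif(20, -10, 0), n_healthy = 100)
  expect_error(build_scenario(no_prod, 3, seed = 1), "empty class")
})
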