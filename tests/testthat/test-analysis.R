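test_that("migration matrices cross-tabulate assignments correctly", {
  ids <- sprintf("P%d", 1:6)
  a <- data.frame(patient_id = ids,
                  risk_class = c("low", "low", "intermediate", "high",
                                 "high", "advanced_metastatic"))
  m <- migration_matrix(a, a, row_label = "x", col_label = "x")
  expect_equal(sum(m$counts), 6)
  expect_equal(unname(diag(m$counts)), c(2, 1, 0, 2, 1))
  expect_equal(sum(m$counts) - sum(diag(m$counts)), 0)

  b <- a
  b$risk_class[1] <- "high"
  m <- migration_matrix(a, b)
  expect_equal(m$counts["low", "high"], 1)

  single <- a[1, ]
  m1 <- migration_matrix(single, single)
  expect_equal(unname(m1$counts["low", "low"]), 1)
  expect_equal(m1$n, 1)

  expect_error(migration_matrix(a, b[-1, ]), "same patients")
  expect_error(migration_matrix(a, transform(a, patient_id = paste0(ids, "z"))),
               "same patients")
})

test_that("a patient multiset reproduces its encoded cross-tabulation", {
  ref <- reference_cohort_tables()
  grid <- ref$cross_esmo2016_vs_esgo2020_known
  rows <- which(grid > 0, arr.ind = TRUE)
  cls <- risk_classes()
  rc <- rep(cls[rows[, 1]], grid[rows])
  cc <- rep(cls[rows[, 2]], grid[rows])
  ids <- sprintf("M%03d", seq_along(rc))
  m <- migration_matrix(data.frame(patient_id = ids, risk_class = rc),
                        data.frame(patient_id = ids, risk_class = cc))
  expect_equal(unname(m$counts), unname(grid))
})

test_that("migration summaries split off-diagonal mass by direction", {
  ident <- as_migration_matrix(diag(c(10, 5, 3, 2, 1)))
  s <- migration_summary(ident)
  expect_equal(s$n_changed, 0)
  expect_equal(s$frac_changed, 0)
  expect_equal(s$n_down + s$n_up, 0)

  m <- matrix(0, 5, 5)
  m[3, 1] <- 4   # down two classes
  m[1, 4] <- 2   # up three classes
  m[2, 2] <- 4
  s <- migration_summary(as_migration_matrix(m))
  expect_equal(s$n_down, 4)
  expect_equal(s$n_up, 2)
  expect_equal(s$frac_changed, 0.6)
  expect_error(as_migration_matrix(matrix(1, 4, 4)), "5x5")
})

test_that("association tests pick the right test and match closed forms", {
  # balanced 2x2: chi-square exactly 0, p = 1
  co <- do.call(make_cohort, c(
    lapply(1:20, function(i) make_patient(grade = "low")),
    lapply(1:20, function(i) make_patient(grade = "high"))))
  mol <- data.frame(patient_id = co$patient_id,
                    subgroup = rep(c("MMRd", "NSMP"), 20))
  res <- association_tests(co, mol, covariates = "grade")
  expect_equal(res$test, "chisq")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand-computed Pearson chi-square for [[20,5],[5,20]]:
  # (ad-bc)^2 * n / (r1 r2 c1 c2) = 375^2 * 50 / 25^4 = 18
  grades <- c(rep("low", 20), rep("high", 5), rep("low", 5), rep("high", 20))
  co <- do.call(make_cohort, lapply(seq_along(grades), function(i)
    make_patient(grade = grades[i])))
  mol <- data.frame(patient_id = co$patient_id,
                    subgroup = rep(c("MMRd", "NSMP"), each = 25))
  res <- association_tests(co, mol, covariates = "grade")
  expect_equal(res$statistic, 18)
  expect_equal(res$p_value, stats::pchisq(18, 1, lower.tail = FALSE))

  # numeric covariates use Kruskal-Wallis
  co$age_years <- seq_len(50)
  res <- association_tests(co, mol, covariates = "age_years")
  expect_equal(res$test, "kruskal_wallis")
  kw <- stats::kruskal.test(co$age_years, factor(mol$subgroup))
  expect_equal(res$p_value, kw$p.value)

  # single-category covariate reported NA with a reason, not an error
  res <- association_tests(co, mol, covariates = "histotype")
  expect_true(is.na(res$p_value))
  expect_match(res$note, "degenerate")
})

test_that("a sparse subgroup-by-nodes table triggers the exact test at the reported magnitude", {
  # node status by subgroup: negative 15/54/29/74, positive 1/12/14/6,
  # published two-sided p 0.0029
  neg <- c(15, 54, 29, 74)
  pos <- c(1, 12, 14, 6)
  subs <- molecular_subgroups()
  rows <- list()
  for (j in 1:4) {
    for (k in seq_len(neg[j]))
      rows[[length(rows) + 1]] <- list(sub = subs[j], nodes = "negative")
    for (k in seq_len(pos[j]))
      rows[[length(rows) + 1]] <- list(sub = subs[j], nodes = "positive")
  }
  co <- do.call(make_cohort, lapply(seq_along(rows), function(i)
    make_patient(lymph_nodes = rows[[i]]$nodes)))
  mol <- data.frame(patient_id = co$patient_id,
                    subgroup = vapply(rows, `[[`, "", "sub"))
  res <- association_tests(co, mol, covariates = "lymph_nodes")
  expect_equal(res$test, "fisher")   # expected POLE-positive cell < 5
  # the exact-vs-asymptotic choice is unstated upstream; accept the order of
  # magnitude of the reported 0.0029
  expect_gt(res$p_value, 5e-4)
  expect_lt(res$p_value, 1e-2)
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km <- km_estimate(c(1, 2), c(TRUE, TRUE))
  expect_equal(km$event_times, c(1, 2))
  expect_equal(km$survival, c(0.5, 0))

  # n = 3: event at 1, censored at 2, event at 3 -> the censored subject has
  # left the risk set, so S = (1 - 1/3) * (1 - 1/1) = 2/3 then 0
  km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$at_risk, c(3, 1))
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5, 10)),
               c(1, 2 / 3, 2 / 3, 0))
  # with the last subject censored instead, S stays at 2/3 * 1/2 = 1/3
  km <- km_estimate(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(km$survival, c(3 / 4, 3 / 8))

  km <- km_estimate(c(5, 8, 13), c(FALSE, FALSE, FALSE))
  expect_length(km$event_times, 0)
  expect_equal(km_survival_at(km, c(1, 100)), c(1, 1))

  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("KM equals empirical survival whenever censoring is absent", {
  set.seed(21)
  for (rep in 1:5) {
    t <- round(stats::rexp(40, 0.05), 2) + 0.01
    km <- km_estimate(t, rep(TRUE, 40))
    emp <- vapply(km$event_times, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp)
  }
})

test_that("log-rank behaves at the degenerate and separated extremes", {
  t <- c(3, 6, 9, 12, 15)
  e <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(t, e, rep("a", 5)), "2 non-empty groups")

  set.seed(33)
  t1 <- stats::rexp(200, 0.01)
  t2 <- stats::rexp(200, 0.04)   # hazard ratio 4
  lr <- logrank_test(c(t1, t2), rep(TRUE, 400), rep(c("a", "b"), each = 200))
  expect_lt(lr$p_value, 1e-4)
  # invariance to relabeling
  lr2 <- logrank_test(c(t2, t1), rep(TRUE, 400), rep(c("x", "y"), each = 200))
  expect_equal(lr2$chisq, lr$chisq)
})

test_that("survival_by_risk_class stitches curves and the global test", {
  sim <- generate_cohort(cohort_spec(n = 500), seed = 9)
  mol <- classify_molecular(sim$cohort, sim$variants)
  assign <- classify_esgo2020(sim$cohort, mol)
  sv <- survival_by_risk_class(sim$cohort, assign)
  expect_true(all(names(sv$curves) %in% risk_classes()))
  expect_equal(sv$logrank$df, length(sv$curves) - 1)
  for (cu in sv$curves)
    expect_true(all(diff(cu$survival) <= 0))   # non-increasing
})
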