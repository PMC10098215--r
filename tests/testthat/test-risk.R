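test_that("worked stratification examples classify as expected", {
  # low-grade stage IA with focal LVSI: high-intermediate under the 2016
  # binary LVSI reading, low under 2020 where focal LVSI is not adverse
  p <- make_patient(lvsi = "focal")
  expect_equal(classify_esmo2016(p)$risk_class, "high_intermediate")
  expect_equal(classify_esgo2020(p)$risk_class, "low")

  expect_equal(classify_esmo2016(make_patient())$risk_class, "low")
  expect_equal(classify_esmo2016(make_patient(histotype = "serous"))$risk_class,
               "high")

  # POLE down-staging: high-grade deeply invasive stage IB, substantial LVSI
  p <- make_patient(grade = "high", figo_stage = "IB",
                    myometrial_invasion = "ge50", lvsi = "substantial")
  expect_equal(classify_esmo2016(p)$risk_class, "high")
  mol_pole <- data.frame(patient_id = "P1", subgroup = "POLE")
  expect_equal(classify_esgo2020(p, mol_pole)$risk_class, "low")

  # p53abn up-staging: high-grade stage IA with invasion
  p <- make_patient(grade = "high")
  mol_p53 <- data.frame(patient_id = "P1", subgroup = "p53abn")
  expect_equal(classify_esgo2020(p, mol_p53)$risk_class, "high")
  # ... but without myometrial invasion it is intermediate
  p$myometrial_invasion <- "none"
  expect_equal(classify_esgo2020(p, mol_p53)$risk_class, "intermediate")

  # stage IVB is advanced/metastatic in every system and mode
  p <- make_patient(figo_stage = "IVB", residual_disease = TRUE)
  expect_equal(classify_esmo2016(p)$risk_class, "advanced_metastatic")
  expect_equal(classify_esgo2020(p)$risk_class, "advanced_metastatic")
  for (s in molecular_subgroups())
    expect_equal(classify_esgo2020(
      p, data.frame(patient_id = "P1", subgroup = s))$risk_class,
      "advanced_metastatic")

  # stage II POLE-mutant is low; stage II MMRd/NSMP is high-intermediate
  p <- make_patient(figo_stage = "II", myometrial_invasion = "ge50")
  expect_equal(classify_esgo2020(p, mol_pole)$risk_class, "low")
  for (s in c("MMRd", "NSMP"))
    expect_equal(classify_esgo2020(
      p, data.frame(patient_id = "P1", subgroup = s))$risk_class,
      "high_intermediate")
})

test_that("every rule system is total and unique over the exhaustive grid", {
  g <- profile_grid()
  for (fn in list(classify_esmo2016, classify_esgo2020)) {
    a <- fn(g)
    expect_equal(nrow(a), nrow(g))
    expect_true(all(a$risk_class %in% risk_classes()))
    expect_true(all(nzchar(a$fired_rule)))
  }
  for (s in molecular_subgroups()) {
    mol <- data.frame(patient_id = g$patient_id, subgroup = s)
    a <- classify_esgo2020(g, mol)
    expect_true(all(a$risk_class %in% risk_classes()))
    expect_true(all(nzchar(a$fired_rule)))
  }
  # determinism: a second evaluation is identical
  expect_identical(classify_esgo2020(g), classify_esgo2020(g))
})

test_that("molecular overrides are monotone at stage I-II", {
  g <- profile_grid()
  early <- g[g$figo_stage %in% c("IA", "IB", "II"), ]
  rank <- function(x) match(x, risk_classes())
  base <- list()
  for (s in molecular_subgroups())
    base[[s]] <- rank(classify_esgo2020(
      early, data.frame(patient_id = early$patient_id,
                        subgroup = s))$risk_class)
  # POLE never raises the class relative to any other subgroup
  for (s in c("MMRd", "p53abn", "NSMP"))
    expect_true(all(base$POLE <= base[[s]]))
  # p53abn with myometrial invasion never lowers the class
  inv <- early$myometrial_invasion != "none"
  for (s in c("MMRd", "NSMP"))
    expect_true(all(base$p53abn[inv] >= base[[s]][inv]))
})

test_that("absent vs focal LVSI is immaterial in 2020 but not in 2016", {
  g <- profile_grid()
  a <- g[g$lvsi == "absent", ]
  f <- a
  f$lvsi <- "focal"
  expect_equal(classify_esgo2020(a)$risk_class, classify_esgo2020(f)$risk_class)
  for (s in molecular_subgroups()) {
    mol <- data.frame(patient_id = a$patient_id, subgroup = s)
    expect_equal(classify_esgo2020(a, mol)$risk_class,
                 classify_esgo2020(f, mol)$risk_class)
  }
  # the 2016 binary reading must distinguish at least some of these profiles
  expect_true(any(classify_esmo2016(a)$risk_class !=
                    classify_esmo2016(f)$risk_class))
})

test_that("classify_cohort returns one assignment per system and reports failures", {
  co <- make_cohort(make_patient("P1"), make_patient("P2", grade = "high"),
                    make_patient("P3", histotype = "serous",
                                 p53_ihc = "null_pattern"),
                    make_patient("P4", figo_stage = "III",
                                 myometrial_invasion = "ge50"),
                    make_patient("P5", mlh1 = "lost", pms2 = "lost"))
  a <- classify_cohort(co)
  expect_equal(nrow(a), 15)
  expect_equal(nrow(attr(a, "errors")), 0)

  # POLE never tested: excluded from known mode and named in the error report
  co$pole_status[2] <- "not_tested"
  a <- classify_cohort(co)
  expect_equal(nrow(a), 14)
  errs <- attr(a, "errors")
  expect_equal(errs$patient_id, "P2")
  expect_match(errs$reason, "insufficient markers")

  # empty cohort classifies to an empty table
  expect_equal(nrow(classify_cohort(co[0, ])), 0)

  # known mode with an explicitly incomplete molecular table is a hard error
  expect_error(classify_esgo2020(co, data.frame(patient_id = "P1",
                                                subgroup = "POLE")),
               "complete molecular call")
})

test_that("the shipped rule table resource matches the engine's rule ids", {
  tab <- risk_rule_table()
  expect_equal(tab$version, 1)
  yaml_ids <- c(vapply(tab$esmo2016, `[[`, "", "id"),
                vapply(tab$esgo2020_unknown, `[[`, "", "id"),
                vapply(tab$esgo2020_known$overrides, `[[`, "", "id"))
  g <- profile_grid()
  fired <- unique(c(classify_esmo2016(g)$fired_rule,
                    classify_esgo2020(g)$fired_rule,
                    unlist(lapply(molecular_subgroups(), function(s)
                      classify_esgo2020(g, data.frame(
                        patient_id = g$patient_id,
                        subgroup = s))$fired_rule))))
  expect_true(all(fired %in% yaml_ids))
})
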