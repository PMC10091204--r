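test_that("bmi follows the published formula", {
    expect_equal(bmi(list(height = 73, weight = 220)), 29.0223, tolerance = 1e-4)
    expect_identical(bmi(list(height = 1, weight = 1)), 703)
    expect_equal(bmi(list(height = 64, weight = 260)),
                 2 * bmi(list(height = 64, weight = 130)))
    expect_error(bmi(list(height = 0, weight = 150)), "domain error|height")
    expect_error(bmi(list(weight = 150)), "height")
})

test_that("feature derivation computes the five derived quantities", {
    expect_equal(deriveFeatures(list(stroke_volume = 70,
                                     heart_rate = 60))$cardiac_output, 4200)
    expect_equal(deriveFeatures(list(height_cm = 180,
                                     weight_kg = 80))$bsa, 2)
    f <- genPatient(1, profile = "eligible_all")$features
    d <- deriveFeatures(f)
    expect_true(all(c("bmi", "bsa", "cardiac_output", "creatinine_clearance",
                      "cv_risk") %in% names(d)))
    expect_gt(d$cv_risk, 0); expect_lt(d$cv_risk, 1)
    ## Cockcroft-Gault with the female correction
    male <- deriveFeatures(list(age = 60, weight = 176, gender = "Male",
                                creatinine = 1.0))
    expect_equal(male$creatinine_clearance,
                 (140 - 60) * 176 * 0.45359237 / 72)
    female <- deriveFeatures(list(age = 60, weight = 176, gender = "Female",
                                  creatinine = 1.0))
    expect_equal(female$creatinine_clearance, male$creatinine_clearance * 0.85)
    ## a missing input suppresses only that derived feature
    partial <- deriveFeatures(list(height = 70, weight = 160))
    expect_true("bmi" %in% names(partial))
    expect_false("cardiac_output" %in% names(partial))
})

test_that("eligibility follows the catalog criteria", {
    catalog <- serviceCatalog()
    expect_identical(length(catalog), 21L)

    all21 <- deriveFeatures(genPatient(1, profile = "eligible_all")$features)
    expect_identical(eligibleServices(all21, catalog), sort(names(catalog)))

    male <- all21; male$gender <- "Male"
    expect_false("BRE" %in% eligibleServices(male, catalog))

    minor <- all21; minor$age <- 17
    expect_identical(eligibleServices(minor, catalog), character())
})

test_that("mortality adjustment is a capped multiplicative step function", {
    q <- seq(0.05, 0.6, length.out = 12)
    sched <- MortalitySchedule(q, 40)
    clean <- list(smoking_status = "never", drinks_per_week = 0, bmi = 24)
    expect_identical(scheduleRates(adjustMortality(sched, clean)), q)

    smoker <- list(smoking_status = "current", drinks_per_week = 0, bmi = 24)
    adj <- scheduleRates(adjustMortality(sched, smoker))
    expect_equal(adj, pmin(1, q * 2))
    expect_identical(adj[q >= 0.5], rep(1, sum(q >= 0.5)))   # cap rule

    ## multiplicativity: joint adjustment equals sequential adjustment
    both <- list(smoking_status = "current", drinks_per_week = 20, bmi = 37)
    joint <- adjustMortality(sched, both)
    a <- defaultRiskAdjustments()
    stepwise <- sched
    for (k in names(a))
        stepwise <- adjustMortality(stepwise, both, a[k])
    expect_equal(scheduleRates(joint), scheduleRates(stepwise))
})

test_that("net benefit has the null effect, closed form, and hr monotonicity", {
    sched <- MortalitySchedule(rep(0.2, 100), 50)
    expect_identical(netBenefit(list(code = "X", hr = 1),
                                list(), sched)$life_gain, 0)
    gain <- netBenefit(list(code = "X", hr = 0.5), list(), sched)$life_gain
    expect_equal(gain, 5, tolerance = 1e-2)   # 9 - 4 geometric
    gains <- vapply(seq(0.1, 1, by = 0.1), function(hr)
        netBenefit(list(code = "X", hr = hr), list(), sched)$life_gain,
        numeric(1))
    expect_true(all(diff(gains) <= 0))
    expect_true(all(gains >= 0))
    expect_error(netBenefit(list(code = "X", hr = 1.2), list(), sched),
                 "config error")
    expect_error(netBenefit(list(code = "X", hr = 0), list(), sched),
                 "config error")
})

test_that("detection gain is the undiagnosed fraction of the treated gain", {
    sched <- MortalitySchedule(rep(0.1, 80), 40)
    svc <- function(p) list(code = "HIV", hr = 0.6, p_undiagnosed = p)
    expect_identical(detectionGain(svc(0), list(), sched)$life_gain, 0)
    full <- netBenefit(list(code = "HIV", hr = 0.6), list(), sched)$life_gain
    expect_identical(detectionGain(svc(1), list(), sched)$life_gain, full)
    expect_equal(detectionGain(svc(0.4), list(), sched)$life_gain, 0.4 * full)
})

test_that("diet risk is a two-level table with a capped absolute risk", {
    p <- list(rr_adherent = 1.0, rr_nonadherent = 1.5, baseline = 0.8)
    good <- dietRisk(list(diet_adherent = TRUE), p)
    expect_identical(good$relative_risk, 1)
    expect_identical(good$absolute_risk, 0.8)
    bad <- dietRisk(list(diet_adherent = FALSE), p)
    expect_identical(bad$relative_risk, 1.5)
    expect_identical(bad$absolute_risk, 1)    # 0.8 * 1.5 capped
    expect_true(all(c(good$relative_risk, bad$relative_risk) %in%
                    c(p$rr_adherent, p$rr_nonadherent)))
    expect_error(dietRisk(list(), p), "diet_adherent")
})

test_that("background risk is a proper logistic in its features", {
    expect_identical(backgroundRisk(list(), list(intercept = 0,
                                                 coefficients = c(x = 1))), 0.5)
    params <- list(intercept = -2, coefficients = c(a = 0.5, b = -0.3))
    set.seed(8)
    for (i in 1:20) {
        f <- list(a = stats::runif(1, -10, 10), b = stats::runif(1, -10, 10))
        r <- backgroundRisk(f, params)
        expect_gt(r, 0); expect_lt(r, 1)
        up <- f; up$a <- up$a + 1
        expect_gt(backgroundRisk(up, params), r)   # monotone in positive-coef feature
    }
})

test_that("service ranking sorts by gain with lexicographic ties", {
    r <- rankServices(c(ASA = 0.3, DIA = 1.6, CRC = 0.09))
    expect_identical(r$code, c("DIA", "ASA", "CRC"))
    expect_identical(nrow(rankServices(numeric())), 0L)
    tied <- rankServices(c(ZZZ = 0.5, AAA = 0.5, MMM = 0.7))
    expect_identical(tied$code, c("MMM", "AAA", "ZZZ"))
    set.seed(2)
    for (i in 1:10) {
        v <- stats::setNames(round(stats::runif(8), 3),
                             paste0("S", sample(100, 8)))
        r <- rankServices(v)
        expect_setequal(r$code, names(v))                  # permutation
        expect_identical(r$life_gain, unname(sort(v, decreasing = TRUE)))
    }
    expect_identical(lifeGain(4, 3.5), 0.5)
    expect_identical(lifeGain(2, 2), 0)
    expect_identical(lifeGain(1, 3), -lifeGain(3, 1))
})

test_that("synthetic patients are complete, physiologic, and reproducible", {
    p <- genPatient(5)
    expect_identical(sort(names(p$features)), sort(patientSchema()))
    core <- c("age", "race", "gender", "height", "weight", "systolic",
              "diastolic", "totalcholesterol", "HDL", "LDL", "triglycerides",
              "a1c", "cvd")
    expect_true(all(core %in% names(p$features)))
    expect_gte(p$features$age, 18); expect_lte(p$features$age, 100)
    expect_gt(p$features$height, 0); expect_gt(p$features$weight, 0)
    expect_identical(genPatient(5), genPatient(5))
    expect_false(identical(genPatient(5)$features, genPatient(6)$features))

    ## archetypes apply their qualitative overrides
    expect_identical(genPatient(3, "smoker")$features$smoking_status, "current")
    expect_gte(genPatient(3, "uncontrolled-diabetic")$features$a1c, 10)
    expect_error(genPatient(3, "nope"), "unknown patient profile")

    ## JSON round-trip in the wire dialect
    path <- tempfile(fileext = ".json")
    writePatient(p, path)
    p2 <- readPatient(path)
    expect_identical(p2$id, p$id)
    expect_equal(p2$features[order(names(p2$features))],
                 p$features[order(names(p$features))])
})
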