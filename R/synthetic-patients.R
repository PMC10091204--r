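## Synthetic inputs: patient records, toy calculator packages, and
## random KO packages for round-trip testing. Everything is
## deterministic per seed and self-contained.

## Schema of the synthetic patient record: 112 keyed features. The 13
## core keys (age .. cvd) follow the published input-record excerpt;
## the remainder are invented, documented synthetic stand-ins for the
## unpublished balance of the >100-feature schema.
.patientSchemaDef <- function() {
    num <- function(lo, hi, digits = 0) list(kind = "num", lo = lo, hi = hi,
                                             digits = digits)
    cat_ <- function(...) list(kind = "cat", levels = c(...))
    flag <- function(p = 0.3) list(kind = "flag", p = p)
    list(
        ## core printed keys
        age = num(25, 90), race = cat_("Black", "White", "Other"),
        gender = cat_("Male", "Female"), height = num(58, 77),
        weight = num(100, 300), systolic = num(95, 180),
        diastolic = num(55, 110), totalcholesterol = num(120, 320),
        HDL = num(25, 90), LDL = num(40, 220), triglycerides = num(50, 400),
        a1c = num(4.5, 13, 1), cvd = flag(0.15),
        ## vitals and labs
        heart_rate = num(50, 110), stroke_volume = num(50, 100),
        respiratory_rate = num(10, 22), temperature = num(97, 99.5, 1),
        spo2 = num(92, 100), creatinine = num(0.5, 2.5, 2),
        egfr = num(30, 120), bun = num(7, 30), sodium = num(132, 146),
        potassium = num(3.3, 5.3, 1), calcium = num(8.4, 10.6, 1),
        glucose_fasting = num(70, 220), hemoglobin = num(10, 18, 1),
        hematocrit = num(30, 52), platelets = num(140, 420),
        wbc = num(3.5, 12, 1), alt = num(8, 70), ast = num(8, 70),
        bilirubin = num(0.2, 1.6, 1), albumin = num(3, 5.2, 1),
        ## behaviours
        smoking_status = cat_("never", "former", "current"),
        smoker_ever = flag(0.45), pack_years = num(0, 60),
        years_since_quit = num(0, 30), drinks_per_week = num(0, 30),
        binge_episodes_per_month = num(0, 10), diet_adherent = flag(0.5),
        fruit_veg_servings_per_day = num(0, 8),
        exercise_minutes_per_week = num(0, 400),
        sedentary_hours_per_day = num(2, 14),
        caffeine_cups_per_day = num(0, 8), sleep_hours = num(4, 10, 1),
        ## diagnoses
        diabetes = flag(0.2), hypertension = flag(0.35),
        hyperlipidemia = flag(0.3), ckd = flag(0.08), copd = flag(0.08),
        asthma = flag(0.1), afib = flag(0.05), stroke_history = flag(0.05),
        mi_history = flag(0.06), heart_failure = flag(0.04),
        cancer_history = flag(0.07), depression_history = flag(0.15),
        anxiety_history = flag(0.15), osteoporosis_history = flag(0.08),
        arthritis = flag(0.2), liver_disease = flag(0.04),
        thyroid_disease = flag(0.08), hiv_diagnosed = flag(0.01),
        hepatitis_b = flag(0.02), obesity_diagnosis = flag(0.25),
        ## family history
        family_history_breast = flag(0.1), family_history_crc = flag(0.1),
        family_history_cvd = flag(0.25), family_history_diabetes = flag(0.2),
        family_history_lung = flag(0.08), family_history_prostate = flag(0.1),
        family_history_osteoporosis = flag(0.1),
        family_history_depression = flag(0.15),
        ## screening and prevention history
        hcv_tested = flag(0.4), flu_vaccinated = flag(0.5),
        pneumococcal_vaccinated = flag(0.3), tdap_vaccinated = flag(0.5),
        shingles_vaccinated = flag(0.25), colonoscopy_done = flag(0.4),
        mammogram_done = flag(0.4), pap_smear_done = flag(0.5),
        bone_density_done = flag(0.25), last_physical_years = num(0, 10),
        aspirin_user = flag(0.2), statin_user = flag(0.25),
        antihypertensive_user = flag(0.3), metformin_user = flag(0.15),
        ssri_user = flag(0.12),
        ## assessment scores
        phq2 = num(0, 6), phq9 = num(0, 27), audit_c = num(0, 12),
        falls_risk = flag(0.2), frailty_score = num(0, 10),
        gad7 = num(0, 21), mmse = num(20, 30), adl_score = num(0, 6),
        ## reproductive and social
        sexually_active = flag(0.6), pregnancies = num(0, 8),
        menopause = flag(0.4), contraceptive_use = flag(0.3),
        marital_status = cat_("single", "married", "divorced", "widowed"),
        education_years = num(8, 20),
        income_bracket = cat_("low", "middle", "high"),
        insurance_status = cat_("private", "public", "uninsured"),
        ## utilisation and misc
        medication_count = num(0, 15), allergy_count = num(0, 6),
        er_visits_last_year = num(0, 5), hospitalizations_last_year = num(0, 3),
        pcp_visits_last_year = num(0, 12), waist_circumference = num(26, 55),
        occupational_exposure = flag(0.1))
}

#' The synthetic patient feature schema
#'
#' @return character vector of the feature keys every generated patient
#'   record carries (112 keys; the first 13 are the published ones).
#' @export
patientSchema <- function() names(.patientSchemaDef())

## fixed values that jointly satisfy all 21 inclusion criteria
.eligibleAllOverrides <- function() list(
    age = 55, race = "Black", gender = "Female", height = 64, weight = 190,
    systolic = 147, diastolic = 88, totalcholesterol = 240, HDL = 38,
    LDL = 150, triglycerides = 210, a1c = 9, cvd = FALSE,
    smoking_status = "current", smoker_ever = TRUE, pack_years = 25,
    drinks_per_week = 16, diet_adherent = FALSE,
    exercise_minutes_per_week = 60, diabetes = TRUE, sexually_active = TRUE,
    hiv_diagnosed = FALSE, hcv_tested = FALSE, flu_vaccinated = FALSE,
    phq2 = 2, falls_risk = TRUE, creatinine = 1.1)

.archetypeOverrides <- list(
    smoker = list(smoking_status = "current", smoker_ever = TRUE,
                  pack_years = 40, drinks_per_week = 2),
    `uncontrolled-diabetic` = list(diabetes = TRUE, a1c = 11.2,
                                   glucose_fasting = 240, metformin_user = TRUE),
    `heavy-drinker` = list(drinks_per_week = 28, binge_episodes_per_month = 8,
                           audit_c = 10),
    obese = list(weight = 280, height = 66, diet_adherent = FALSE,
                 exercise_minutes_per_week = 30, obesity_diagnosis = TRUE),
    healthy = list(smoking_status = "never", smoker_ever = FALSE,
                   pack_years = 0, drinks_per_week = 2, diet_adherent = TRUE,
                   exercise_minutes_per_week = 240, a1c = 5.2, systolic = 112,
                   totalcholesterol = 165, weight = 150, height = 68))

#' Generate a synthetic patient record
#'
#' Produces a complete record with every schema key (see
#' [patientSchema()]), values within physiologic ranges, deterministic
#' per seed. The `eligible_all` profile fixes the features that the 21
#' inclusion criteria test, so the resulting patient is eligible for
#' every catalog service; the archetype profiles (smoker,
#' uncontrolled-diabetic, heavy-drinker, obese, healthy) are
#' qualitative presets over an otherwise random record.
#'
#' @param seed integer seed.
#' @param profile "random" (default), "eligible_all", or an archetype
#'   name.
#' @return list(id, features).
#' @examples
#' p <- genPatient(1, profile = "eligible_all")
#' length(p$features)
#' @export
genPatient <- function(seed = 1L, profile = "random") {
    schema <- .patientSchemaDef()
    set.seed(as.integer(seed))
    features <- lapply(schema, function(sp) {
        switch(sp$kind,
            num = round(stats::runif(1L, sp$lo, sp$hi), sp$digits),
            cat = sample(sp$levels, 1L),
            flag = stats::runif(1L) < sp$p)
    })
    overrides <- if (identical(profile, "eligible_all")) .eligibleAllOverrides()
        else if (identical(profile, "random")) list()
        else if (profile %in% names(.archetypeOverrides))
            .archetypeOverrides[[profile]]
        else stop("unknown patient profile '", profile, "'")
    for (nm in names(overrides)) features[[nm]] <- overrides[[nm]]
    ## keep dependent features coherent
    if (identical(features$smoking_status, "never")) {
        features$smoker_ever <- FALSE
        features$pack_years <- 0
    }
    if (identical(features$smoking_status, "current"))
        features$smoker_ever <- TRUE
    list(id = sprintf("ipp-patient-S%02d", as.integer(seed) %% 100L),
         features = features)
}

#' Read or write a patient record as JSON
#'
#' The on-the-wire dialect: `{"patient": {"id": ..., "features": {...}}}`.
#'
#' @param path JSON file path.
#' @param patient list(id, features) as from [genPatient()].
#' @return `readPatient` the patient list; `writePatient` the path,
#'   invisibly.
#' @export
readPatient <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(doc$patient)) doc$patient else doc
}

#' @rdname readPatient
#' @export
writePatient <- function(patient, path) {
    jsonlite::write_json(list(patient = patient), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(path)
}

## ---------------------------------------------------------------------
## Toy and random packages

.TOY_SOURCES <- list(
    double = "double <- function(inputs) list(value = inputs$value * 2)\n",
    add_one = "add_one <- function(inputs) list(value = inputs$value + 1)\n",
    square = "square <- function(inputs) list(value = inputs$value^2)\n",
    negate = "negate <- function(inputs) list(value = -inputs$value)\n")

#' Toy calculator Knowledge Objects
#'
#' Small self-contained packages used throughout the tests and
#' examples: the BMI calculator (weight/height^2 * 703 on a features
#' record) and one-line arithmetic models (`double`, `add_one`,
#' `square`, `negate`) that map `{"value": x}` records.
#'
#' @param name one of "bmi", "double", "add_one", "square", "negate".
#' @return a valid [KnowledgeObjectPackage-class] (engine "r").
#' @export
toyCalculatorPackage <- function(name = "bmi") {
    if (identical(name, "bmi")) {
        id <- PersistentId("ipp", "bmicalculator", "1.0")
        return(KnowledgeObjectPackage(
            metadata = KoMetadata(id, title = "BMI Calc",
                                  contributors = "Model Stewards",
                                  description = "Calculates BMI"),
            deployment = DeploymentSpec("/bmi", "r", "bmi.R", "bmi"),
            service = ServiceSpec("/ipp/bmicalculator/1.0", "/bmi",
                                  title = "BMI Calc", serviceVersion = "1.0",
                                  licenseName = "GPL-3"),
            payload = list(bmi.R = .srcBmi())))
    }
    src <- .TOY_SOURCES[[name]]
    if (is.null(src)) stop("unknown toy calculator '", name, "'")
    id <- PersistentId("toy", name, "1.0")
    KnowledgeObjectPackage(
        metadata = KoMetadata(id, title = paste("Toy calculator:", name)),
        deployment = DeploymentSpec(paste0("/", name), "r",
                                    paste0(name, ".R"), name),
        service = ServiceSpec(sprintf("/toy/%s/1.0", name),
                              paste0("/", name),
                              title = paste("Toy", name)),
        payload = structure(list(src), names = paste0(name, ".R")))
}

#' Generate a random valid Knowledge Object package
#'
#' Random identifier, metadata, endpoint, and payload (one R entry
#' artifact plus 0-2 extra artifacts, one of which is random binary
#' bytes) -- used for write/load round-trip testing. Deterministic per
#' seed; always passes validation.
#'
#' @param seed integer seed.
#' @return a valid [KnowledgeObjectPackage-class].
#' @export
genRandomPackage <- function(seed = 1L) {
    set.seed(as.integer(seed))
    slug <- function(n) paste(sample(letters, n, replace = TRUE), collapse = "")
    naan <- slug(3L)
    name <- slug(8L)
    version <- paste(sample(0:9, 1L), sample(0:9, 1L), sep = ".")
    fn <- slug(5L)
    path <- paste0("/", slug(4L))
    k <- sample(1:50, 1L)
    entry <- paste0(fn, ".R")
    payload <- structure(
        list(charToRaw(sprintf("%s <- function(inputs) list(value = inputs$value + %d)\n",
                               fn, k))),
        names = entry)
    extra <- sample(0:2, 1L)
    if (extra >= 1L)
        payload[["data.bin"]] <- as.raw(sample(0:255, sample(16:128, 1L),
                                               replace = TRUE))
    if (extra >= 2L)
        payload[["notes.txt"]] <- charToRaw(paste(sample(letters, 40,
                                                         replace = TRUE),
                                                  collapse = ""))
    KnowledgeObjectPackage(
        metadata = KoMetadata(PersistentId(naan, name, version),
                              title = paste("Random model", name),
                              contributors = slug(6L),
                              description = "Synthetic round-trip fixture"),
        deployment = DeploymentSpec(path, "r", entry, fn,
                                    artifacts = names(payload)),
        service = ServiceSpec(sprintf("/%s/%s/%s", naan, name, version),
                              path, title = name, serviceVersion = version),
        payload = payload)
}
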