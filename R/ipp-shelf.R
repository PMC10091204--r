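## Generator for the demonstration shelf: 42 Knowledge Objects across
## 11 submodel types, wired as one top-level executive with 29 direct
## callees (3 of them lower-level executives that together call 13
## submodels, one of which -- the life-expectancy estimator -- is also a
## direct callee of the top level). Payload sources are generated text;
## quantitative steps call the package's exported formulas so the
## gateway-level and library-level computations cannot drift apart.

.IPP_NAAN <- "ipp"
.IPP_VERSION <- "1.0"

.ippKey <- function(name, path)
    sprintf("/%s/%s/%s%s", .IPP_NAAN, name, .IPP_VERSION, path)

.ippPackage <- function(name, path, functionName, source, title, description = "") {
    id <- PersistentId(.IPP_NAAN, name, .IPP_VERSION)
    KnowledgeObjectPackage(
        metadata = KoMetadata(id, title = title, description = description),
        deployment = DeploymentSpec(endpointPath = path, engine = "r",
                                    entry = paste0(functionName, ".R"),
                                    functionName = functionName),
        service = ServiceSpec(baseUrl = sprintf("/%s/%s/%s", .IPP_NAAN, name,
                                                .IPP_VERSION),
                              paths = path, title = title,
                              serviceVersion = .IPP_VERSION),
        payload = structure(list(source), names = paste0(functionName, ".R")))
}

## ---- endpoint directory ---------------------------------------------

.ippEndpoints <- function() {
    list(
        top      = .ippKey("composite", "/ipp"),
        derive   = .ippKey("derivedfeatures", "/run"),
        mortality = .ippKey("mortalityschedule", "/run"),
        diet     = .ippKey("dietriskcomposite", "/run"),
        bmi      = .ippKey("bmicalculator", "/bmi"),
        bsa      = .ippKey("bsacalculator", "/bsa"),
        co       = .ippKey("cardiacoutput", "/co"),
        crcl     = .ippKey("creatinineclearance", "/crcl"),
        cvrisk   = .ippKey("cvriskscore", "/cvrisk"),
        criteria = .ippKey("servicecriteria", "/eligible"),
        lifetable = .ippKey("lifetable", "/q"),
        le       = .ippKey("lifeexpectancy", "/le"),
        gain     = .ippKey("lifegain", "/gain"),
        dietrr   = .ippKey("dietrelativerisk", "/rr"),
        dietabs  = .ippKey("dietabsoluterisk", "/abs"))
}

.nbName <- function(code) paste0("nb", tolower(code))
.bgName <- function(model) paste0("bg", model)

## ---- payload sources -------------------------------------------------

.srcBmi <- function() "
bmi <- function(inputs) {
    height <- inputs$features$height
    weight <- inputs$features$weight
    if (is.null(height) || is.null(weight))
        stop(\"missing 'height' or 'weight' feature\")
    if (height == 0) stop(\"division by zero: height is 0\")
    if (height < 0) stop(\"domain error: height must be > 0\")
    weight / height / height * 703
}
"

.srcBsa <- function() "
bsa <- function(inputs) {
    f <- inputs$features
    hcm <- if (!is.null(f$height_cm)) f$height_cm else f$height * 2.54
    wkg <- if (!is.null(f$weight_kg)) f$weight_kg else f$weight * 0.45359237
    if (is.null(hcm) || is.null(wkg)) stop(\"missing height/weight features\")
    sqrt(hcm * wkg / 3600)
}
"

.srcCardiacOutput <- function() "
co <- function(inputs) {
    f <- inputs$features
    if (is.null(f$stroke_volume) || is.null(f$heart_rate))
        stop(\"missing 'stroke_volume' or 'heart_rate' feature\")
    f$stroke_volume * f$heart_rate
}
"

.srcCrCl <- function() "
crcl <- function(inputs) {
    f <- inputs$features
    if (is.null(f$age) || is.null(f$creatinine) || f$creatinine <= 0)
        stop(\"missing or invalid 'age'/'creatinine' feature\")
    wkg <- if (!is.null(f$weight_kg)) f$weight_kg else f$weight * 0.45359237
    v <- (140 - f$age) * wkg / (72 * f$creatinine)
    if (identical(f$gender, \"Female\")) v <- v * 0.85
    v
}
"

.srcCvRisk <- function() "
cvrisk <- function(inputs) {
    f <- koactivator::deriveFeatures(inputs$features)
    if (is.null(f$cv_risk)) stop(\"insufficient features for the cv risk score\")
    f$cv_risk
}
"

.srcDeriveExecutive <- function(ep) {
    refs <- c(bmi = ep$bmi, bsa = ep$bsa, cardiac_output = ep$co,
              creatinine_clearance = ep$crcl, cv_risk = ep$cvrisk)
    paste0(
".refs <- ", .deparse1(refs), "
composite <- function(inputs) {
    f <- inputs$features
    if (is.null(f$height_cm) && !is.null(f$height)) f$height_cm <- f$height * 2.54
    if (is.null(f$weight_kg) && !is.null(f$weight)) f$weight_kg <- f$weight * 0.45359237
    for (key in names(.refs)) {
        v <- tryCatch(kgrid_call(.refs[[key]], list(features = f)),
                      error = function(e) NULL)
        if (!is.null(v)) f[[key]] <- v
    }
    list(features = f)
}
")
}

.srcLifeTable <- function(lifeTab) {
    tb <- lifeTable(lifeTab)
    strata <- split(tb[order(tb$age), "q"],
                    paste(tb$sex, tb$race, sep = "|")[order(tb$age)])
    paste0(
".qtab <- ", .deparse1(lapply(strata, unname)), "
qslice <- function(inputs) {
    key <- paste(inputs$sex, inputs$race, sep = \"|\")
    q <- .qtab[[key]]
    if (is.null(q))
        stop(sprintf(\"no life-table stratum for (sex = %s, race = %s)\",
                     inputs$sex, inputs$race))
    age <- inputs$age
    horizon <- if (is.null(inputs$horizon)) 100 - age else inputs$horizon
    idx <- seq(age, min(age + horizon, 100)) + 1
    list(start_age = age, rates = q[idx])
}
")
}

.srcAdjustment <- function(adjName, adjSpec) {
    paste0(
".adj <- ", .deparse1(list(x = adjSpec)), "
adjust <- function(inputs) {
    rr <- koactivator::relativeRisks(inputs$features, .adj)[[\"x\"]]
    list(rates = pmin(1, unlist(inputs$rates) * rr), rr = rr)
}
")
}

.srcLifeExpectancy <- function() "
le <- function(inputs) koactivator::lifeExpectancy(unlist(inputs$rates))
"

.srcLifeGain <- function() "
gain <- function(inputs) {
    if (is.null(inputs$le_with) || is.null(inputs$le_without))
        stop(\"missing 'le_with' or 'le_without'\")
    inputs$le_with - inputs$le_without
}
"

.srcMortalityExecutive <- function(ep, adjustments) {
    refs <- list(lifetable = ep$lifetable,
                 obesity = .ippKey("obesityadjustment", "/adjust"),
                 alcohol = .ippKey("alcoholadjustment", "/adjust"),
                 tobacco = .ippKey("tobaccoadjustment", "/adjust"),
                 le = ep$le)
    paste0(
".refs <- ", .deparse1(refs), "
composite <- function(inputs) {
    f <- inputs$features
    base <- kgrid_call(.refs$lifetable,
                       list(age = f$age, sex = f$gender, race = f$race))
    rates <- unlist(base$rates)
    adj <- rates
    rr <- list()
    for (k in c(\"obesity\", \"alcohol\", \"tobacco\")) {
        out <- kgrid_call(.refs[[k]], list(features = f, rates = adj))
        adj <- unlist(out$rates)
        rr[[k]] <- out$rr
    }
    list(start_age = base$start_age, baseline_rates = rates,
         adjusted_rates = adj, rr = rr,
         le_baseline = kgrid_call(.refs$le, list(rates = rates)),
         le_adjusted = kgrid_call(.refs$le, list(rates = adj)))
}
")
}

.srcCriteria <- function(catalog) {
    crit <- lapply(catalog, function(s) list(criteria = s$criteria))
    paste0(
".catalog <- ", .deparse1(crit), "
eligible <- function(inputs) {
    as.list(koactivator::eligibleServices(inputs$features, .catalog))
}
")
}

.srcDietRelativeRisk <- function(dietParams) {
    paste0(
".params <- ", .deparse1(dietParams), "
rr <- function(inputs) {
    out <- koactivator::dietRisk(inputs$features, .params)
    list(relative_risk = out$relative_risk)
}
")
}

.srcDietAbsoluteRisk <- function(dietParams) {
    paste0(
".params <- ", .deparse1(dietParams), "
absrisk <- function(inputs) {
    if (is.null(inputs$relative_risk)) stop(\"missing 'relative_risk'\")
    list(absolute_risk = min(1, .params$baseline * inputs$relative_risk))
}
")
}

.srcDietExecutive <- function(ep) {
    refs <- list(rr = ep$dietrr, abs = ep$dietabs,
                 bg = .ippKey(.bgName("cardiometabolic"), "/risk"))
    paste0(
".refs <- ", .deparse1(refs), "
composite <- function(inputs) {
    rel <- kgrid_call(.refs$rr, list(features = inputs$features))
    abs <- kgrid_call(.refs$abs, list(relative_risk = rel$relative_risk))
    bg <- kgrid_call(.refs$bg, list(features = inputs$features))
    list(relative_risk = rel$relative_risk,
         absolute_risk = abs$absolute_risk, background = bg)
}
")
}

.srcBackgroundRisk <- function(modelParams) {
    paste0(
".params <- ", .deparse1(modelParams), "
risk <- function(inputs) koactivator::backgroundRisk(inputs$features, .params)
")
}

.srcNetBenefit <- function(code, hr, ep, link) {
    paste0(
".code <- ", .deparse1(code), "
.hr <- ", .deparse1(hr), "
.link <- ", .deparse1(link), "
.le_ref <- ", .deparse1(ep$le), "
.gain_ref <- ", .deparse1(ep$gain), "
benefit <- function(inputs) {
    q <- unlist(inputs$rates)
    le_without <- kgrid_call(.le_ref, list(rates = q))
    le_with <- kgrid_call(.le_ref, list(rates = pmin(1, q * .hr)))
    g <- kgrid_call(.gain_ref, list(le_with = le_with, le_without = le_without))
    if (!is.null(inputs$background))
        g <- g * (.link$base + .link$slope * inputs$background)
    list(code = .code, life_gain = g)
}
")
}

.srcDetection <- function(code, hr, pUndiagnosed, ep) {
    paste0(
".code <- ", .deparse1(code), "
.hr <- ", .deparse1(hr), "
.p <- ", .deparse1(pUndiagnosed), "
.le_ref <- ", .deparse1(ep$le), "
.gain_ref <- ", .deparse1(ep$gain), "
detect <- function(inputs) {
    q <- unlist(inputs$rates)
    le_without <- kgrid_call(.le_ref, list(rates = q))
    le_with <- kgrid_call(.le_ref, list(rates = pmin(1, q * .hr)))
    g <- kgrid_call(.gain_ref, list(le_with = le_with, le_without = le_without))
    list(code = .code, life_gain = .p * g)
}
")
}

.srcTopExecutive <- function(ep, catalog, params, adjustments) {
    services <- lapply(catalog, function(s) {
        out <- list(type = s$type)
        if (s$type == "net_benefit") {
            out$ref <- .ippKey(.nbName(s$code), "/benefit")
            out$background <- s$background
        } else if (s$type == "detection") {
            out$ref <- .ippKey("hivdetection", "/detect")
        } else {
            out$mechanism <- s$mechanism
            out$hr <- s$hr
        }
        out
    })
    bgRefs <- vapply(setdiff(names(params$background_models), "cardiometabolic"),
                     function(m) .ippKey(.bgName(m), "/risk"), character(1))
    refs <- list(derive = ep$derive, criteria = ep$criteria,
                 mortality = ep$mortality, diet = ep$diet,
                 le = ep$le, gain = ep$gain)
    required <- c("age", "race", "gender", "height", "weight", "systolic",
                  "diastolic", "totalcholesterol", "HDL", "LDL",
                  "triglycerides", "a1c", "cvd")
    paste0(
".refs <- ", .deparse1(refs), "
.bg_refs <- ", .deparse1(bgRefs), "
.services <- ", .deparse1(services), "
.link <- ", .deparse1(params$background_link), "
.adjust <- ", .deparse1(adjustments), "
.required <- ", .deparse1(required), "
.step_rr <- function(x, adj) adj$rr[findInterval(x, adj$breaks, left.open = TRUE) + 1]
composite <- function(inputs) {
    p <- if (!is.null(inputs$patient)) inputs$patient else inputs
    f <- p$features
    if (is.null(f))
        stop(errorCondition(\"input record has no 'features'\",
                            missing = list(\"features\"), class = \"ko_bad_input\"))
    absent <- .required[vapply(.required, function(k) is.null(f[[k]]), logical(1))]
    if (length(absent))
        stop(errorCondition(paste(\"missing required feature(s):\",
                                  paste(absent, collapse = \", \")),
                            missing = as.list(absent), class = \"ko_bad_input\"))
    f <- kgrid_call(.refs$derive, list(features = f))$features
    elig <- unlist(kgrid_call(.refs$criteria, list(features = f)))
    mort <- kgrid_call(.refs$mortality, list(features = f))
    base_rates <- unlist(mort$baseline_rates)
    adj <- unlist(mort$adjusted_rates)
    rrs <- mort$rr
    le_adj <- mort$le_adjusted
    diet <- kgrid_call(.refs$diet, list(features = f))
    bg <- lapply(.bg_refs, function(r) kgrid_call(r, list(features = f)))
    le_for <- function(rates) kgrid_call(.refs$le, list(rates = rates))
    gain_vs_adjusted <- function(le_with)
        kgrid_call(.refs$gain, list(le_with = le_with, le_without = le_adj))
    gains <- numeric(0)
    for (code in elig) {
        svc <- .services[[code]]
        g <- if (svc$type %in% c(\"net_benefit\", \"detection\")) {
            payload <- list(features = f, rates = adj)
            if (!is.null(svc$background)) payload$background <- bg[[svc$background]]
            kgrid_call(svc$ref, payload)$life_gain
        } else if (svc$mechanism == \"fixed_hr\") {
            gain_vs_adjusted(le_for(pmin(1, adj * svc$hr)))
        } else if (svc$mechanism %in% c(\"remove_tobacco_rr\", \"remove_alcohol_rr\")) {
            drop <- if (svc$mechanism == \"remove_tobacco_rr\") \"tobacco\" else \"alcohol\"
            keep <- 1
            for (k in setdiff(names(rrs), drop)) keep <- keep * rrs[[k]]
            gain_vs_adjusted(le_for(pmin(1, base_rates * keep)))
        } else if (svc$mechanism == \"weight_loss\") {
            bmi2 <- (f$weight - 10) / f$height / f$height * 703
            keep <- .step_rr(bmi2, .adjust$obesity)
            for (k in setdiff(names(rrs), \"obesity\")) keep <- keep * rrs[[k]]
            gain_vs_adjusted(le_for(pmin(1, base_rates * keep)))
        } else if (svc$mechanism == \"diet_rr\") {
            hr <- 1 / diet$relative_risk
            scale <- .link$base + .link$slope * diet$background
            gain_vs_adjusted(le_for(pmin(1, adj * hr))) * scale
        } else stop(sprintf(\"unknown benefit mechanism for service '%s'\", code))
        gains[code] <- g
    }
    ord <- order(-gains, names(gains))
    keyed <- list()
    for (code in names(gains))
        keyed[[code]] <- list(total = list(`life-gain` = gains[[code]]))
    list(patient_id = p$id, lifeexpectancy = keyed,
         ranking = lapply(ord, function(i)
             list(code = names(gains)[i], `life-gain` = gains[[i]])),
         baseline = list(le_baseline = mort$le_baseline, le_adjusted = le_adj))
}
")
}

## ---- shelf assembly --------------------------------------------------

#' Generate the full demonstration shelf
#'
#' Writes one valid Knowledge Object per submodel of the demonstration
#' composite -- 42 packages across 11 submodel types -- into `dir`, one
#' directory per package, plus a `manifest.json`. The wiring: the
#' top-level executive calls 29 submodels directly, 3 of which are
#' lower-level executives (feature derivation, mortality schedule, diet
#' risk) that together call 13 submodels; the life-expectancy estimator
#' is a callee of both levels, which is how 1 + 29 + 13 distinct
#' references span exactly 42 objects. Benefit estimates for the five
#' behavioural services (ALC, DIET, PHY, SMO, WEI) are computed inline
#' by the top-level executive. Everything is deterministic per seed,
#' byte for byte.
#'
#' @param dir writable destination directory.
#' @param seed integer seed (drives the synthetic life table).
#' @param params composite parameters, as from [ippParams()].
#' @param adjustments mortality risk adjustments, as from
#'   [defaultRiskAdjustments()].
#' @return a [ShelfManifest-class].
#' @seealso [activateShelf()], [runIppComposite()]
#' @export
buildDemoShelf <- function(dir, seed = 1L, params = ippParams(),
                           adjustments = defaultRiskAdjustments()) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ep <- .ippEndpoints()
    catalog <- serviceCatalog(params)
    lifeTab <- genLifeTable(seed)
    link <- params$background_link

    kos <- list()
    addKo <- function(pkg, type) {
        kos[[length(kos) + 1L]] <<- list(pkg = pkg, type = type)
    }

    ## executives (4)
    addKo(.ippPackage("composite", "/ipp", "composite",
                      .srcTopExecutive(ep, catalog, params, adjustments),
                      "Prevention composite (top-level executive)"),
          "executive")
    addKo(.ippPackage("derivedfeatures", "/run", "composite",
                      .srcDeriveExecutive(ep),
                      "Derived-features executive"), "executive")
    addKo(.ippPackage("mortalityschedule", "/run", "composite",
                      .srcMortalityExecutive(ep, adjustments),
                      "Mortality-schedule executive"), "executive")
    addKo(.ippPackage("dietriskcomposite", "/run", "composite",
                      .srcDietExecutive(ep),
                      "Diet-risk executive"), "executive")

    ## patient feature derivation (5)
    addKo(.ippPackage("bmicalculator", "/bmi", "bmi", .srcBmi(),
                      "BMI Calc"), "feature_derivation")
    addKo(.ippPackage("bsacalculator", "/bsa", "bsa", .srcBsa(),
                      "Body surface area"), "feature_derivation")
    addKo(.ippPackage("cardiacoutput", "/co", "co", .srcCardiacOutput(),
                      "Cardiac output"), "feature_derivation")
    addKo(.ippPackage("creatinineclearance", "/crcl", "crcl", .srcCrCl(),
                      "Creatinine clearance"), "feature_derivation")
    addKo(.ippPackage("cvriskscore", "/cvrisk", "cvrisk", .srcCvRisk(),
                      "Cardiovascular risk score"), "feature_derivation")

    ## service criteria (1), life table (1), LE estimator (1), LE gain (1)
    addKo(.ippPackage("servicecriteria", "/eligible", "eligible",
                      .srcCriteria(catalog), "Preventive-service criteria"),
          "service_criteria")
    addKo(.ippPackage("lifetable", "/q", "qslice", .srcLifeTable(lifeTab),
                      "Baseline mortality life table"), "life_table")
    addKo(.ippPackage("lifeexpectancy", "/le", "le", .srcLifeExpectancy(),
                      "Life expectancy estimator"), "life_expectancy")
    addKo(.ippPackage("lifegain", "/gain", "gain", .srcLifeGain(),
                      "Life-expectancy gain estimator"), "life_gain")

    ## net benefit estimators (15)
    for (code in names(catalog)) {
        svc <- catalog[[code]]
        if (svc$type != "net_benefit") next
        addKo(.ippPackage(.nbName(code), "/benefit", "benefit",
                          .srcNetBenefit(code, svc$hr, ep, link),
                          paste("Net benefit:", svc$label)), "net_benefit")
    }

    ## detection gain (1)
    hiv <- catalog$HIV
    addKo(.ippPackage("hivdetection", "/detect", "detect",
                      .srcDetection("HIV", hiv$hr, hiv$p_undiagnosed, ep),
                      "HIV detection gain"), "detection_gain")

    ## diet risk (2)
    dietParams <- list(rr_adherent = 1.0, rr_nonadherent = 1.4, baseline = 0.12)
    addKo(.ippPackage("dietrelativerisk", "/rr", "rr",
                      .srcDietRelativeRisk(dietParams),
                      "Diet relative risk"), "diet_risk")
    addKo(.ippPackage("dietabsoluterisk", "/abs", "absrisk",
                      .srcDietAbsoluteRisk(dietParams),
                      "Diet absolute risk"), "diet_risk")

    ## mortality risk adjustment (3)
    for (adjName in c("obesity", "alcohol", "tobacco"))
        addKo(.ippPackage(paste0(adjName, "adjustment"), "/adjust", "adjust",
                          .srcAdjustment(adjName, adjustments[[adjName]]),
                          paste("Mortality adjustment:", adjName)),
              "mortality_adjustment")

    ## partial background risk (8)
    for (model in names(params$background_models))
        addKo(.ippPackage(.bgName(model), "/risk", "risk",
                          .srcBackgroundRisk(params$background_models[[model]]),
                          paste("Background risk:", model)), "background_risk")

    ## write out
    rows <- lapply(kos, function(k) {
        pkg <- k$pkg
        writeKnowledgeObject(pkg, file.path(dir, pkg@metadata@id@name))
        data.frame(puid = formatPersistentId(koId(pkg)), type = k$type,
                   engine = pkg@deployment@engine,
                   endpointKey = endpointKey(pkg), stringsAsFactors = FALSE)
    })
    packages <- do.call(rbind, rows)
    counts <- table(packages$type)
    countsByType <- stats::setNames(as.integer(counts), names(counts))

    nbKeys <- sort(packages$endpointKey[packages$type == "net_benefit"])
    bgDirect <- vapply(setdiff(names(params$background_models), "cardiometabolic"),
                       function(m) .ippKey(.bgName(m), "/risk"), character(1))
    wiring <- list(
        top = ep$top,
        topDirect = unname(c(ep$derive, ep$mortality, ep$diet, ep$criteria,
                             ep$le, ep$gain, nbKeys,
                             .ippKey("hivdetection", "/detect"), bgDirect)),
        lower = list(
            derivedfeatures = unname(c(ep$bmi, ep$bsa, ep$co, ep$crcl, ep$cvrisk)),
            mortalityschedule = unname(c(ep$lifetable,
                .ippKey("obesityadjustment", "/adjust"),
                .ippKey("alcoholadjustment", "/adjust"),
                .ippKey("tobaccoadjustment", "/adjust"), ep$le)),
            dietriskcomposite = unname(c(ep$dietrr, ep$dietabs,
                .ippKey(.bgName("cardiometabolic"), "/risk")))))

    manifest <- new("ShelfManifest", seed = as.integer(seed),
                    packages = packages, countsByType = countsByType,
                    wiring = wiring)
    jsonlite::write_json(
        list(seed = seed, packages = packages,
             counts_by_type = as.list(countsByType), wiring = wiring),
        file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    manifest
}

setMethod("show", "ShelfManifest", function(object) {
    cat("ShelfManifest:", nrow(object@packages), "packages, seed",
        object@seed, "\n")
    for (tp in names(object@countsByType))
        cat(sprintf("  %-22s %d\n", tp, object@countsByType[[tp]]))
})

#' @rdname ShelfManifest-class
#' @param x a [ShelfManifest-class].
#' @export
shelfPackages <- function(x) x@packages

#' @rdname ShelfManifest-class
#' @export
shelfCounts <- function(x) x@countsByType

#' @rdname ShelfManifest-class
#' @export
shelfWiring <- function(x) x@wiring
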