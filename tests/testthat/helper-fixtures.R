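## Shared fixtures: descriptor texts in the printed dialects, a cached
## activated demo shelf, and the direct (gateway-free) evaluator used
## as the composition oracle.

box3DeploymentText <- function() paste(
    "/bmi:",
    "  post:",
    "    engine: node",
    "    entry: bmi.js",
    "    artifact: bmi.js",
    "    function: bmi",
    sep = "\n")

box4ServiceText <- function() paste(
    "openapi: 3.0.0",
    "info:",
    "  version: '1.0'",
    "  title: BMI Calc",
    "  description: Calculates BMI",
    "  license:",
    "    name: GNU General Public License v3 (GPL-3)",
    "  contact:",
    "    name: Model Stewards",
    "servers:",
    "  - url: /ipp/bmicalculator/1.0",
    "    description: BMI Calculator",
    "paths:",
    "  /bmi:",
    "    post:",
    "      summary: Calculate BMI",
    sep = "\n")

bmiFixtureDir <- function()
    system.file("extdata", "bmi-ko", package = "koactivator")

## The demo shelf is expensive enough to build and activate once per
## test run; tests that mutate a context make their own.
.shelfCache <- new.env(parent = emptyenv())

demoShelf <- function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(.shelfCache[[key]])) {
        dir <- file.path(tempdir(), sprintf("ko-demo-shelf-%d", seed))
        manifest <- buildDemoShelf(dir, seed = seed)
        ctx <- runtimeContext()
        activateShelf(dir, ctx)
        .shelfCache[[key]] <- list(dir = dir, manifest = manifest, ctx = ctx)
    }
    .shelfCache[[key]]
}

## Direct evaluation of the composite with package functions and no
## gateway: the independent comparator for gateway transparency. The
## arithmetic follows the same sequential capping order as the wired
## submodels so agreement can be required exactly.
ippOracleGains <- function(patient, lifeTab,
                           params = ippParams(),
                           adjustments = defaultRiskAdjustments()) {
    catalog <- serviceCatalog(params)
    link <- params$background_link
    dietParams <- list(rr_adherent = 1.0, rr_nonadherent = 1.4, baseline = 0.12)
    f <- deriveFeatures(patient$features)
    elig <- eligibleServices(f, catalog)
    sched <- mortalitySchedule(lifeTab, f$age, f$gender, f$race)
    base_rates <- scheduleRates(sched)
    rrs <- list()
    adj <- base_rates
    for (k in c("obesity", "alcohol", "tobacco")) {
        rr <- relativeRisks(f, adjustments[k])[[1L]]
        adj <- pmin(1, adj * rr)
        rrs[[k]] <- rr
    }
    le_adj <- lifeExpectancy(adj)
    diet <- dietRisk(f, dietParams)
    bg <- lapply(params$background_models, function(m) backgroundRisk(f, m))
    gains <- numeric(0)
    for (code in elig) {
        svc <- catalog[[code]]
        g <- if (identical(svc$type, "net_benefit")) {
            g0 <- netBenefit(list(code = code, hr = svc$hr), f,
                             MortalitySchedule(adj, f$age))$life_gain
            if (!is.null(svc$background))
                g0 * (link$base + link$slope * bg[[svc$background]])
            else g0
        } else if (identical(svc$type, "detection")) {
            detectionGain(list(code = code, hr = svc$hr,
                               p_undiagnosed = svc$p_undiagnosed), f,
                          MortalitySchedule(adj, f$age))$life_gain
        } else if (identical(svc$mechanism, "fixed_hr")) {
            lifeExpectancy(pmin(1, adj * svc$hr)) - le_adj
        } else if (svc$mechanism %in% c("remove_tobacco_rr", "remove_alcohol_rr")) {
            drop <- if (identical(svc$mechanism, "remove_tobacco_rr")) "tobacco"
                    else "alcohol"
            keep <- 1
            for (k in setdiff(names(rrs), drop)) keep <- keep * rrs[[k]]
            lifeExpectancy(pmin(1, base_rates * keep)) - le_adj
        } else if (identical(svc$mechanism, "weight_loss")) {
            bmi2 <- (f$weight - 10) / f$height / f$height * 703
            ob <- adjustments$obesity
            keep <- ob$rr[findInterval(bmi2, ob$breaks, left.open = TRUE) + 1L]
            for (k in setdiff(names(rrs), "obesity")) keep <- keep * rrs[[k]]
            lifeExpectancy(pmin(1, base_rates * keep)) - le_adj
        } else if (identical(svc$mechanism, "diet_rr")) {
            (lifeExpectancy(pmin(1, adj * (1 / diet$relative_risk))) - le_adj) *
                (link$base + link$slope * bg$cardiometabolic)
        } else stop("unknown mechanism in oracle")
        gains[code] <- g
    }
    gains
}

## gains as reported by the activated composite, as a named vector
compositeGains <- function(out)
    vapply(out$lifeexpectancy, function(x) x$total[["life-gain"]], numeric(1))
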