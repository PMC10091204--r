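## The quantitative submodels of the prevention composite: feature
## derivation, survival arithmetic, hazard-ratio benefit estimation,
## and ranking. All parameters are synthetic and configurable; the
## architecture (which submodels exist and how they feed each other) is
## the point, not the coefficient values.

#' Body mass index
#'
#' BMI = weight / height^2 * 703, with weight in pounds and height in
#' inches.
#'
#' @param features named list with numeric `height` (inches, > 0) and
#'   `weight` (pounds).
#' @return numeric(1), the index in lb/in^2 x 703.
#' @examples
#' bmi(list(height = 73, weight = 220))
#' @export
bmi <- function(features) {
    h <- features$height
    w <- features$weight
    if (is.null(h) || is.null(w)) stop("bmi requires 'height' and 'weight'")
    if (h <= 0) stop("domain error: height must be > 0")
    w / h / h * 703
}

#' Derive additional patient features
#'
#' The feature-derivation submodels: adds `bmi`; body surface area
#' `bsa` by the Mosteller formula sqrt(height_cm * weight_kg / 3600)
#' (m^2); `cardiac_output` = stroke_volume x heart_rate (mL/min) when
#' those features are present; `creatinine_clearance` by
#' Cockcroft-Gault (mL/min); and a synthetic logistic cardiovascular
#' risk score `cv_risk` in (0,1). Metric height/weight are derived from
#' inches/pounds when not supplied. A derived feature whose inputs are
#' missing is simply absent from the result; the others are still
#' computed.
#'
#' @param features named list of patient features.
#' @return the features list, extended with the derived keys.
#' @export
deriveFeatures <- function(features) {
    f <- features
    tryOr <- function(expr) tryCatch(expr, error = function(e) NULL)
    if (is.null(f$height_cm) && !is.null(f$height)) f$height_cm <- f$height * 2.54
    if (is.null(f$weight_kg) && !is.null(f$weight)) f$weight_kg <- f$weight * 0.45359237
    b <- tryOr(bmi(f))
    if (!is.null(b)) f$bmi <- b
    if (!is.null(f$height_cm) && !is.null(f$weight_kg))
        f$bsa <- sqrt(f$height_cm * f$weight_kg / 3600)
    if (!is.null(f$stroke_volume) && !is.null(f$heart_rate))
        f$cardiac_output <- f$stroke_volume * f$heart_rate
    if (!is.null(f$age) && !is.null(f$weight_kg) && !is.null(f$creatinine) &&
        f$creatinine > 0) {
        crcl <- (140 - f$age) * f$weight_kg / (72 * f$creatinine)
        if (identical(f$gender, "Female")) crcl <- crcl * 0.85
        f$creatinine_clearance <- crcl
    }
    if (!is.null(f$age) && !is.null(f$systolic) && !is.null(f$totalcholesterol) &&
        !is.null(f$HDL)) {
        smoker <- as.numeric(identical(f$smoking_status, "current"))
        diabetic <- as.numeric(isTRUE(f$diabetes) ||
                               (!is.null(f$a1c) && f$a1c >= 6.5))
        f$cv_risk <- backgroundRisk(f, list(
            intercept = -9,
            coefficients = c(age = 0.065, systolic = 0.012,
                             totalcholesterol = 0.004, HDL = -0.02)))
        f$cv_risk <- min(1, f$cv_risk * (1 + 0.8 * smoker + 0.6 * diabetic))
    }
    f
}

#' Life expectancy from an age-ordered mortality schedule
#'
#' Discrete survival sum: LE = sum over k = 1..H of the product of
#' (1 - q_j) for j < k -- the expected number of whole years lived, no
#' half-year correction. For a constant hazard q this is the geometric
#' partial sum (1-q)(1-(1-q)^H)/q.
#'
#' @param sched a [MortalitySchedule-class], or a bare numeric vector of
#'   annual mortality probabilities.
#' @return numeric(1), expected years lived.
#' @examples
#' lifeExpectancy(rep(0.2, 100))   # ~ (1 - 0.2) / 0.2 = 4
#' @export
lifeExpectancy <- function(sched) {
    q <- if (is(sched, "MortalitySchedule")) scheduleRates(sched) else as.numeric(sched)
    if (!length(q)) stop("empty mortality schedule")
    if (any(!is.finite(q)) || any(q < 0 | q > 1))
        stop("domain error: all mortality probabilities must lie in [0,1]")
    sum(cumprod(1 - q))
}

#' Marginal life gain between two life-expectancy estimates
#'
#' @param leWith life expectancy with the intervention, years.
#' @param leWithout life expectancy without it, years.
#' @return numeric(1), `leWith - leWithout`.
#' @export
lifeGain <- function(leWith, leWithout) {
    stopifnot(is.finite(leWith), is.finite(leWithout))
    leWith - leWithout
}

#' Default behavioural mortality risk adjustments
#'
#' Step-function relative risks for the three adjustment submodels:
#' obesity (by BMI), alcohol (by weekly drinks), tobacco (by smoking
#' status). Each spec is either numeric breaks with one more `rr` value
#' than breaks, or a categorical level -> rr map.
#'
#' @return named list of adjustment specifications.
#' @export
defaultRiskAdjustments <- function() list(
    obesity = list(feature = "bmi", breaks = c(30, 35), rr = c(1, 1.2, 1.5)),
    alcohol = list(feature = "drinks_per_week", breaks = c(7, 14),
                   rr = c(1, 1.15, 1.3)),
    tobacco = list(feature = "smoking_status",
                   levels = c(never = 1, former = 1.15, current = 2.0)))

#' Relative risks implied by a patient's features
#'
#' @param features named list of patient features.
#' @param adjustments as from [defaultRiskAdjustments()].
#' @return named numeric vector of multiplicative relative risks, one
#'   per adjustment; a missing feature contributes RR = 1.
#' @export
relativeRisks <- function(features, adjustments = defaultRiskAdjustments()) {
    vapply(adjustments, function(adj) {
        x <- features[[adj$feature]]
        if (is.null(x)) return(1)
        if (!is.null(adj$levels)) {
            rr <- adj$levels[[as.character(x)]]
            if (is.null(rr)) 1 else rr
        } else {
            adj$rr[findInterval(x, adj$breaks, left.open = TRUE) + 1L]
        }
    }, numeric(1))
}

#' Adjust a mortality schedule for behavioural risk factors
#'
#' Applies the product of the per-factor relative risks to every annual
#' probability, capped at 1: q' = min(1, q * RR_obesity * RR_alcohol *
#' RR_tobacco). Multiplicative, so adjusting for several factors at
#' once equals adjusting sequentially.
#'
#' @param sched a [MortalitySchedule-class].
#' @param features named list of patient features.
#' @param adjustments as from [defaultRiskAdjustments()].
#' @return the adjusted [MortalitySchedule-class].
#' @export
adjustMortality <- function(sched, features,
                            adjustments = defaultRiskAdjustments()) {
    rr <- prod(relativeRisks(features, adjustments))
    MortalitySchedule(pmin(1, scheduleRates(sched) * rr),
                      startAge = scheduleStartAge(sched))
}

#' Net benefit of a preventive service as marginal life gain
#'
#' The benefit mechanism shared by the net-benefit estimators: the
#' service scales every annual mortality probability by its all-cause
#' hazard ratio (capped at 1), and the benefit is the life-expectancy
#' difference between the scaled and unscaled schedules. hr = 1 yields
#' exactly 0; smaller hr yields larger gains.
#'
#' @param service a service definition list with elements `code` and
#'   `hr` (hazard ratio in (0, 1]).
#' @param features named list of patient features (carried for
#'   interface uniformity; the default mechanism does not use it).
#' @param sched the individual's adjusted [MortalitySchedule-class].
#' @return list(code, life_gain) -- life gain in years, >= 0.
#' @export
netBenefit <- function(service, features, sched) {
    hr <- service$hr
    if (is.null(hr) || hr <= 0 || hr > 1)
        stop("config error: service '", service$code,
             "' needs a hazard ratio in (0, 1]")
    q <- scheduleRates(sched)
    gain <- lifeGain(lifeExpectancy(pmin(1, q * hr)), lifeExpectancy(q))
    list(code = service$code, life_gain = gain)
}

#' Life-expectancy gain from detection through routine testing
#'
#' Expected benefit of detecting an undiagnosed condition: the
#' probability of being undiagnosed times the net-benefit-style gain
#' under the treated hazard ratio.
#'
#' @param service service definition list with `code`, `hr` (treated
#'   hazard ratio) and `p_undiagnosed` in \[0, 1\].
#' @param features named list of patient features.
#' @param sched the individual's adjusted [MortalitySchedule-class].
#' @return list(code, life_gain).
#' @export
detectionGain <- function(service, features, sched) {
    p <- service$p_undiagnosed
    stopifnot(!is.null(p), p >= 0, p <= 1)
    base <- netBenefit(list(code = service$code, hr = service$hr),
                       features, sched)
    list(code = service$code, life_gain = p * base$life_gain)
}

#' Diet-related relative and absolute risk
#'
#' Two-level configured table: one relative risk for adherents to a
#' healthy diet, one for non-adherents; the absolute risk is the
#' configured baseline scaled by the applicable RR, capped at 1.
#'
#' @param features named list; must contain the logical
#'   `diet_adherent` feature.
#' @param params list(rr_adherent, rr_nonadherent, baseline).
#' @return list(relative_risk, absolute_risk).
#' @export
dietRisk <- function(features,
                     params = list(rr_adherent = 1.0, rr_nonadherent = 1.4,
                                   baseline = 0.12)) {
    if (is.null(features$diet_adherent))
        stop("dietRisk requires feature 'diet_adherent'")
    rr <- if (isTRUE(features$diet_adherent)) params$rr_adherent
          else params$rr_nonadherent
    list(relative_risk = rr, absolute_risk = min(1, params$baseline * rr))
}

#' Partial background risk by a logistic form
#'
#' 1 / (1 + exp(-(b0 + sum of b_i x_i))), with logical features coerced
#' to 0/1 and missing features contributing 0.
#'
#' @param features named list of patient features.
#' @param params list(intercept, coefficients = named numeric).
#' @return numeric(1) in (0, 1).
#' @export
backgroundRisk <- function(features, params) {
    eta <- params$intercept
    for (nm in names(params$coefficients)) {
        x <- features[[nm]]
        if (is.null(x)) x <- 0
        eta <- eta + params$coefficients[[nm]] * as.numeric(x)
    }
    1 / (1 + exp(-eta))
}

#' Rank services by estimated life gain
#'
#' Descending by life gain; ties broken lexicographically by service
#' code. The output is a permutation of the input.
#'
#' @param benefits named numeric vector (or list), service code ->
#'   life gain in years.
#' @return data.frame(code, life_gain), ranked.
#' @examples
#' rankServices(c(ASA = 0.3, DIA = 1.6, CRC = 0.09))
#' @export
rankServices <- function(benefits) {
    benefits <- unlist(benefits)
    if (!length(benefits))
        return(data.frame(code = character(), life_gain = numeric(),
                          stringsAsFactors = FALSE))
    ord <- order(-benefits, names(benefits))
    data.frame(code = names(benefits)[ord], life_gain = unname(benefits[ord]),
               stringsAsFactors = FALSE)
}
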