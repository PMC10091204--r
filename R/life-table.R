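## Life tables and mortality schedules: the survival substrate of the
## prevention composite.

#' @rdname GompertzParams-class
#' @param A baseline hazard at age 0.
#' @param B log-hazard slope per year of age.
#' @param sexMultipliers,raceMultipliers named multiplicative stratum
#'   effects.
#' @export
gompertzParams <- function(A = 5e-5, B = 0.085,
                           sexMultipliers = c(Male = 1.15, Female = 0.85),
                           raceMultipliers = c(White = 0.95, Black = 1.10,
                                               Other = 1.00))
    new("GompertzParams", A = A, B = B, sexMultipliers = sexMultipliers,
        raceMultipliers = raceMultipliers)

#' Construct a life table from a long data.frame
#'
#' @param table data.frame with columns sex, race, age, q; each
#'   (sex, race) stratum must cover ages 0..100 with q(100) = 1.
#' @return a [LifeTable-class].
#' @export
LifeTable <- function(table) {
    table <- table[order(table$sex, table$race, table$age), , drop = FALSE]
    rownames(table) <- NULL
    new("LifeTable", table = table)
}

#' @rdname LifeTable-class
#' @param x a [LifeTable-class].
#' @export
lifeTableStrata <- function(x) unique(x@table[, c("sex", "race")])

setMethod("show", "LifeTable", function(object) {
    st <- lifeTableStrata(object)
    cat("LifeTable: ages 0..100,", nrow(st), "strata\n")
    cat("  sexes:", paste(unique(st$sex), collapse = ", "), "\n")
    cat("  races:", paste(unique(st$race), collapse = ", "), "\n")
})

#' Generate a synthetic stratified life table
#'
#' A Gompertz stand-in for a national all-cause life table:
#' q(a) = min(1, m * A * exp(B * a)) for ages 0..100, with the terminal
#' closure q(100) = 1 forced, where m is the product of the sex and
#' race multipliers, optionally jittered. The default parameters give a
#' remaining life expectancy of about 32 years at age 50 in the
#' reference stratum (multiplier 1) -- a plausible, not authoritative,
#' mortality surface.
#'
#' @param seed integer seed; the table is reproducible per seed.
#' @param params a [GompertzParams-class].
#' @param jitter relative standard deviation of a seeded log-normal
#'   perturbation of each stratum multiplier; 0 (default) disables it,
#'   making the table a pure function of `params`.
#' @return a [LifeTable-class].
#' @examples
#' lt <- genLifeTable(1)
#' head(lifeTable(lt))
#' @export
genLifeTable <- function(seed = 1L, params = gompertzParams(), jitter = 0) {
    set.seed(as.integer(seed))
    sexes <- names(params@sexMultipliers)
    races <- names(params@raceMultipliers)
    ages <- 0:100
    rows <- list()
    for (s in sexes) for (r in races) {
        m <- params@sexMultipliers[[s]] * params@raceMultipliers[[r]]
        if (jitter > 0) m <- m * exp(stats::rnorm(1L, 0, jitter))
        q <- pmin(1, m * params@A * exp(params@B * ages))
        if (any(q[ages < 60] >= 1))
            warning("Gompertz parameters saturate q at 1 before age 60 in ",
                    "stratum (", s, ", ", r, ")", call. = FALSE)
        q[length(q)] <- 1   # terminal closure
        rows[[paste(s, r)]] <- data.frame(sex = s, race = r, age = ages, q = q,
                                          stringsAsFactors = FALSE)
    }
    LifeTable(do.call(rbind, rows))
}

#' Read or write a life table as CSV
#'
#' Plain CSV with columns sex, race, age, q.
#'
#' @param path CSV file path.
#' @param x a [LifeTable-class].
#' @return `readLifeTable` a [LifeTable-class]; `writeLifeTable` the
#'   path, invisibly.
#' @export
readLifeTable <- function(path)
    LifeTable(utils::read.csv(path, stringsAsFactors = FALSE))

#' @rdname readLifeTable
#' @export
writeLifeTable <- function(x, path) {
    utils::write.csv(x@table, path, row.names = FALSE)
    invisible(path)
}

#' @rdname LifeTable-class
#' @export
lifeTable <- function(x) x@table

#' Construct a mortality schedule directly
#'
#' @param rates annual mortality probabilities in age order.
#' @param startAge starting age in years.
#' @return a [MortalitySchedule-class].
#' @export
MortalitySchedule <- function(rates, startAge = 0L)
    new("MortalitySchedule", startAge = as.integer(startAge),
        rates = as.numeric(rates))

#' @rdname MortalitySchedule-class
#' @param x a [MortalitySchedule-class].
#' @export
scheduleRates <- function(x) x@rates

#' @rdname MortalitySchedule-class
#' @export
scheduleStartAge <- function(x) x@startAge

setMethod("show", "MortalitySchedule", function(object) {
    cat(sprintf("MortalitySchedule: ages %d..%d (%d annual rates)\n",
                object@startAge, object@startAge + length(object@rates) - 1L,
                length(object@rates)))
})

#' Slice an individual's mortality schedule out of a life table
#'
#' Returns the annual mortality probabilities for ages
#' `age .. min(age + horizon, 100)` in age order from the (sex, race)
#' stratum. With the default horizon the schedule runs to the terminal
#' age 100, whose closure rate is 1.
#'
#' @param table a [LifeTable-class].
#' @param age starting age (within the table's range).
#' @param sex,race stratum labels.
#' @param horizon number of additional years beyond `age`; 0 yields the
#'   single rate q(age).
#' @return a [MortalitySchedule-class].
#' @export
mortalitySchedule <- function(table, age, sex, race, horizon = 100L - age) {
    tb <- table@table
    sub <- tb[tb$sex == sex & tb$race == race, , drop = FALSE]
    if (!nrow(sub))
        stop("no life-table stratum for (sex = ", sex, ", race = ", race, ")")
    if (age < min(sub$age) || age > max(sub$age))
        stop("age ", age, " outside the table's range")
    top <- min(age + horizon, 100L)
    sub <- sub[sub$age >= age & sub$age <= top, , drop = FALSE]
    sub <- sub[order(sub$age), , drop = FALSE]
    MortalitySchedule(sub$q, startAge = age)
}
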