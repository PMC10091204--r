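## The preventive-service catalog: 21 services, their inclusion
## criteria, benefit parameters, and the background-risk submodel
## configurations. All numeric parameters are synthetic placeholders
## read from one YAML file.

#' Load the composite-model parameter file
#'
#' @param path YAML parameter file; defaults to the synthetic
#'   parameterisation shipped with the package.
#' @return list with elements `services`, `background_models`,
#'   `background_link`.
#' @export
ippParams <- function(path = system.file("extdata", "ipp-params.yaml",
                                         package = "koactivator")) {
    params <- yaml::read_yaml(path)
    stopifnot(!is.null(params$services), !is.null(params$background_models))
    params
}

#' The preventive-service catalog
#'
#' @param params as from [ippParams()].
#' @return named list of service definitions; each has `code`, `label`,
#'   `type` (net_benefit, detection, or inline), `criteria`, and its
#'   benefit parameters (`hr`, `p_undiagnosed`, `mechanism`,
#'   `background` as applicable). Hazard ratios are checked to lie in
#'   (0, 1] here, at configuration time.
#' @export
serviceCatalog <- function(params = ippParams()) {
    services <- params$services
    for (code in names(services)) {
        services[[code]]$code <- code
        hr <- services[[code]]$hr
        if (!is.null(hr) && (hr <= 0 || hr > 1))
            stop("config error: hazard ratio for service '", code,
                 "' must lie in (0, 1], got ", hr)
        if (is.null(services[[code]]$criteria))
            stop("config error: service '", code, "' declares no criteria")
    }
    services
}

.meetsCriterion <- function(features, cr) {
    x <- features[[cr$feature]]
    if (is.null(x) || length(x) != 1L || is.na(x)) return(FALSE)
    if (!is.null(cr$min) && !(is.numeric(x) && x >= cr$min)) return(FALSE)
    if (!is.null(cr$max) && !(is.numeric(x) && x <= cr$max)) return(FALSE)
    if (!is.null(cr$eq) && as.character(x) != as.character(cr$eq)) return(FALSE)
    if (!is.null(cr[["in"]]) &&
        !(as.character(x) %in% as.character(unlist(cr[["in"]])))) return(FALSE)
    TRUE
}

#' Services whose inclusion criteria a patient satisfies
#'
#' Each service's criteria are a conjunction of per-feature conditions
#' (age range, sex, thresholds on labs or behaviours); a missing
#' feature fails its condition. Criteria may refer to derived features
#' (e.g. BMI), so eligibility is evaluated on the derived feature
#' record.
#'
#' @param features named list of (derived) patient features.
#' @param catalog as from [serviceCatalog()].
#' @return sorted character vector of eligible service codes.
#' @export
eligibleServices <- function(features, catalog = serviceCatalog()) {
    if (!length(catalog)) stop("empty service catalog")
    hit <- vapply(catalog, function(svc)
        all(vapply(svc$criteria, function(cr) .meetsCriterion(features, cr),
                   logical(1))), logical(1))
    sort(names(catalog)[hit])
}
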