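## Package validation. Findings are collected, never raised.

.emptyFindings <- function()
    data.frame(severity = character(), code = character(),
               message = character(), component = character(),
               stringsAsFactors = FALSE)

.finding <- function(severity, code, message, component)
    data.frame(severity = severity, code = code, message = message,
               component = component, stringsAsFactors = FALSE)

.validationReport <- function(findings) {
    new("ValidationReport", ok = !any(findings$severity == "error"),
        findings = findings)
}

#' Default engine allow-list
#'
#' Engines the validator recognises. Packages declaring other engines
#' validate with a warning, not an error: the format layer does not
#' know which adapters a given activator registers.
#'
#' @return character vector of engine tokens.
#' @export
defaultEngineAllowList <- function() c("r", "node", "python")

#' Validate a Knowledge Object package
#'
#' Checks cross-component consistency: the entry artifact (and every
#' declared artifact) present in the payload; the deployment path
#' declared among the service paths; the PUID and version strings
#' well-formed; the engine on the allow-list (warning otherwise); and,
#' as a convention warning, the base URL ending with the service-version
#' segment.
#'
#' @param pkg a [KnowledgeObjectPackage-class].
#' @param engineAllowList engines accepted without a warning.
#' @return a [ValidationReport-class]; `ok(report)` is TRUE exactly when
#'   no error-severity finding was produced.
#' @examples
#' report <- validateKnowledgeObject(toyCalculatorPackage("bmi"))
#' ok(report)
#' @export
validateKnowledgeObject <- function(pkg, engineAllowList = defaultEngineAllowList()) {
    stopifnot(is(pkg, "KnowledgeObjectPackage"))
    f <- .emptyFindings()
    dep <- pkg@deployment
    svc <- pkg@service
    md <- pkg@metadata

    missingArtifacts <- setdiff(dep@artifacts, names(pkg@payload))
    if (dep@entry %in% missingArtifacts)
        f <- rbind(f, .finding("error", "ENTRY_MISSING",
            sprintf("entry artifact '%s' is not present in the payload", dep@entry),
            "deployment"))
    other <- setdiff(missingArtifacts, dep@entry)
    if (length(other))
        f <- rbind(f, .finding("error", "ARTIFACT_MISSING",
            sprintf("declared artifact(s) missing from payload: %s",
                    paste(other, collapse = ", ")),
            "deployment"))

    if (!(dep@endpointPath %in% svc@paths))
        f <- rbind(f, .finding("error", "PATH_MISMATCH",
            sprintf("deployment path '%s' is not declared by the service description (paths: %s)",
                    dep@endpointPath, paste(svc@paths, collapse = ", ")),
            "service"))

    idOk <- tryCatch({ validObject(md@id); TRUE }, error = function(e) FALSE)
    if (!idOk)
        f <- rbind(f, .finding("error", "PUID_MALFORMED",
            sprintf("PUID '%s' is not well-formed", formatPersistentId(md@id)),
            "metadata"))

    for (v in c(service = svc@serviceVersion, ko = md@koVersion)) {
        if (!grepl("^[0-9]+\\.[0-9]+(\\.[0-9]+)?$", v))
            f <- rbind(f, .finding("error", "VERSION_MALFORMED",
                sprintf("version string '%s' does not match MAJOR.MINOR[.PATCH]", v),
                "metadata"))
    }

    if (!(dep@engine %in% engineAllowList))
        f <- rbind(f, .finding("warning", "ENGINE_UNLISTED",
            sprintf("engine '%s' is not on the allow-list (%s)",
                    dep@engine, paste(engineAllowList, collapse = ", ")),
            "deployment"))

    if (!endsWith(svc@baseUrl, paste0("/", svc@serviceVersion)))
        f <- rbind(f, .finding("warning", "BASE_URL_VERSION",
            sprintf("base URL '%s' does not end with the service-version segment '/%s'",
                    svc@baseUrl, svc@serviceVersion),
            "service"))

    .validationReport(f)
}

#' @rdname ValidationReport-class
#' @param x a [ValidationReport-class].
#' @export
ok <- function(x) x@ok

#' @rdname ValidationReport-class
#' @export
findings <- function(x) x@findings

#' Render a validation report as JSON
#'
#' @param x a [ValidationReport-class].
#' @return character(1), a JSON document with fields `ok` and `findings`.
#' @export
formatValidationReport <- function(x)
    jsonlite::toJSON(list(ok = x@ok, findings = x@findings),
                     auto_unbox = TRUE, pretty = TRUE)

setMethod("show", "ValidationReport", function(object) {
    cat("ValidationReport:", if (object@ok) "OK" else "NOT OK", "\n")
    if (nrow(object@findings)) {
        for (i in seq_len(nrow(object@findings)))
            cat(sprintf("  [%s] %s (%s): %s\n",
                        object@findings$severity[i], object@findings$code[i],
                        object@findings$component[i], object@findings$message[i]))
    } else cat("  no findings\n")
})
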