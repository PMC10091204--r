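## Writing KO packages: directory layout or a single zip archive.

#' Write a Knowledge Object package to disk
#'
#' Emits the standard layout -- `metadata.json`, `deployment.yaml`,
#' `service.yaml`, payload artifacts beside them -- either into a
#' directory or, when `location` ends in `.zip`, into a store-only zip
#' archive. Payload bytes are written verbatim, so a write/load cycle
#' is byte-identical. Packages that fail validation with errors are
#' refused; the [ValidationReport-class] travels on the error condition
#' as attribute `report`.
#'
#' @param pkg a [KnowledgeObjectPackage-class].
#' @param location destination directory or `.zip` path.
#' @return `location`, invisibly.
#' @seealso [loadKnowledgeObject()], [validateKnowledgeObject()]
#' @export
writeKnowledgeObject <- function(pkg, location) {
    report <- validateKnowledgeObject(pkg)
    if (!ok(report)) {
        cond <- simpleError(paste0(
            "refusing to write an invalid KO package (",
            paste(report@findings$code[report@findings$severity == "error"],
                  collapse = ", "), ")"))
        attr(cond, "report") <- report
        stop(cond)
    }
    files <- c(
        list(
            "metadata.json" = charToRaw(paste0(.formatMetadataJson(pkg@metadata), "\n")),
            "deployment.yaml" = charToRaw(formatDeploymentDescription(pkg@deployment)),
            "service.yaml" = charToRaw(formatServiceDescription(
                pkg@service, method = pkg@deployment@httpMethod))),
        pkg@payload)
    if (grepl("\\.zip$", location)) {
        parent <- dirname(location)
        if (!dir.exists(parent)) stop("destination not writable: ", parent)
        .zipWrite(files, location)
    } else {
        dir.create(location, recursive = TRUE, showWarnings = FALSE)
        if (!dir.exists(location)) stop("destination not writable: ", location)
        for (nm in names(files)) {
            path <- file.path(location, nm)
            dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
            writeBin(files[[nm]], path)
        }
    }
    invisible(location)
}
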