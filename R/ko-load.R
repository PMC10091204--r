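## Reading KO packages from disk. A package is a directory (or a zip
## archive of one) holding the three descriptor files at its root --
## metadata.json, deployment.yaml, service.yaml -- with the payload
## artifacts beside them.

.KO_DESCRIPTORS <- c("metadata.json", "deployment.yaml", "service.yaml")

.readFileRaw <- function(path) readBin(path, "raw", file.info(path)$size)

.parseMetadataJson <- function(text) {
    doc <- jsonlite::fromJSON(text, simplifyVector = TRUE)
    for (field in c("id", "title"))
        if (is.null(doc[[field]]))
            stop("metadata.json is missing required field '", field, "'")
    KoMetadata(id = parsePersistentId(doc$id), title = doc$title,
               contributors = if (is.null(doc$contributors)) character()
                              else as.character(doc$contributors),
               koVersion = if (is.null(doc$ko_version)) parsePersistentId(doc$id)@version
                           else doc$ko_version,
               description = if (is.null(doc$description)) "" else doc$description)
}

.formatMetadataJson <- function(md) {
    jsonlite::toJSON(list(
        id = formatPersistentId(md@id), title = md@title,
        contributors = md@contributors, ko_version = md@koVersion,
        description = md@description), auto_unbox = TRUE, pretty = TRUE)
}

#' Load a Knowledge Object package from a directory or zip archive
#'
#' Reads the three descriptor files and every payload artifact (bytes
#' loaded verbatim). Cross-file consistency is deliberately *not*
#' enforced here -- use [validateKnowledgeObject()] -- so that broken
#' packages can still be loaded and inspected.
#'
#' @param location path to a KO directory or a `.zip` archive of one.
#' @return a [KnowledgeObjectPackage-class].
#' @examples
#' dir <- system.file("extdata", "bmi-ko", package = "koactivator")
#' ko <- loadKnowledgeObject(dir)
#' ko
#' @export
loadKnowledgeObject <- function(location) {
    if (!file.exists(location))
        stop("no such file or directory: ", location)
    if (!dir.exists(location)) {
        if (!.isZipFile(location))
            stop("not a KO directory or zip archive: ", location)
        listing <- utils::unzip(location, list = TRUE)$Name
        listing <- basename(listing[!endsWith(listing, "/")])
        if (anyDuplicated(listing))
            stop("duplicate payload filenames in archive: ",
                 paste(unique(listing[duplicated(listing)]), collapse = ", "))
        location <- .zipExtract(location)
        ## archives may wrap the package in a single top-level directory
        if (!file.exists(file.path(location, "metadata.json"))) {
            inner <- list.dirs(location, recursive = FALSE)
            if (length(inner) == 1L) location <- inner
        }
    }
    files <- list.files(location, recursive = TRUE)
    missing <- setdiff(.KO_DESCRIPTORS, files)
    if (length(missing))
        stop("KO package at ", location, " is missing required file(s): ",
             paste(missing, collapse = ", "))
    readText <- function(f) rawToChar(.readFileRaw(file.path(location, f)))
    metadata <- .parseMetadataJson(readText("metadata.json"))
    deployment <- parseDeploymentDescription(readText("deployment.yaml"))
    service <- parseServiceDescription(readText("service.yaml"))
    payloadFiles <- sort(setdiff(files, .KO_DESCRIPTORS))
    payload <- lapply(payloadFiles, function(f) .readFileRaw(file.path(location, f)))
    names(payload) <- payloadFiles
    new("KnowledgeObjectPackage", metadata = metadata, deployment = deployment,
        service = service, payload = payload)
}
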