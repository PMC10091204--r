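## Constructors and the two descriptor parsers (deployment + service).

#' Construct a persistent identifier
#'
#' @param naan registrar token.
#' @param name object slug.
#' @param version semantic-version string, `MAJOR.MINOR[.PATCH]`.
#' @return a [PersistentId-class].
#' @examples
#' pid <- PersistentId("ipp", "bmicalculator", "1.0")
#' formatPersistentId(pid)
#' @export
PersistentId <- function(naan, name, version)
    new("PersistentId", naan = naan, name = name, version = version)

#' @rdname PersistentId
#' @param x a [PersistentId-class].
#' @export
formatPersistentId <- function(x) paste(x@naan, x@name, x@version, sep = "/")

#' @rdname PersistentId
#' @param string canonical PUID string `naan/name/version`.
#' @export
parsePersistentId <- function(string) {
    parts <- strsplit(string, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
        stop("malformed PUID (expected \"naan/name/version\"): ", string)
    PersistentId(parts[1L], parts[2L], parts[3L])
}

setMethod("show", "PersistentId", function(object)
    cat("PersistentId:", formatPersistentId(object), "\n"))

#' Construct KO metadata
#'
#' @param id a [PersistentId-class].
#' @param title nonempty title.
#' @param contributors character vector of contributor names.
#' @param koVersion version of the KO as a package (distinct from the
#'   service version in the service description).
#' @param description free text.
#' @return a [KoMetadata-class].
#' @export
KoMetadata <- function(id, title, contributors = character(),
                       koVersion = id@version, description = "")
    new("KoMetadata", id = id, title = title,
        contributors = as.character(contributors),
        koVersion = koVersion, description = description)

#' Construct a deployment specification
#'
#' @param endpointPath URL path segment beginning with "/".
#' @param engine runtime token, e.g. "r".
#' @param entry entry artifact filename.
#' @param functionName symbol the entry defines.
#' @param artifacts artifact filenames; defaults to just the entry.
#' @param httpMethod declared method; only "post" is supported.
#' @return a [DeploymentSpec-class].
#' @export
DeploymentSpec <- function(endpointPath, engine, entry, functionName,
                           artifacts = entry, httpMethod = "post")
    new("DeploymentSpec", endpointPath = endpointPath, httpMethod = httpMethod,
        engine = engine, entry = entry, artifacts = as.character(artifacts),
        functionName = functionName)

#' Construct a service specification
#'
#' @param baseUrl partial URL the service mounts under; by convention it
#'   ends with the service-version segment (e.g. "/ipp/bmicalculator/1.0").
#' @param paths endpoint paths declared by the API.
#' @param title service title.
#' @param serviceVersion API version (independent of the KO version).
#' @param apiFormatVersion OpenAPI format version.
#' @param licenseName,contact optional strings.
#' @return a [ServiceSpec-class].
#' @export
ServiceSpec <- function(baseUrl, paths, title = "", serviceVersion = "1.0",
                        apiFormatVersion = "3.0.0", licenseName = "",
                        contact = "")
    new("ServiceSpec", apiFormatVersion = apiFormatVersion,
        serviceVersion = serviceVersion, title = title, baseUrl = baseUrl,
        paths = as.character(paths), licenseName = licenseName,
        contact = contact)

#' Construct a Knowledge Object package in memory
#'
#' Payload entries given as character strings are encoded to raw bytes.
#'
#' @param metadata a [KoMetadata-class].
#' @param deployment a [DeploymentSpec-class].
#' @param service a [ServiceSpec-class].
#' @param payload named list of raw vectors or character strings,
#'   filename -> contents.
#' @return a [KnowledgeObjectPackage-class].
#' @examples
#' ko <- toyCalculatorPackage("bmi")
#' validateKnowledgeObject(ko)
#' @export
KnowledgeObjectPackage <- function(metadata, deployment, service, payload) {
    payload <- lapply(payload, function(p) if (is.character(p)) charToRaw(p) else p)
    ## canonical order so equality is layout-independent
    payload <- payload[order(names(payload))]
    new("KnowledgeObjectPackage", metadata = metadata, deployment = deployment,
        service = service, payload = payload)
}

setMethod("show", "KnowledgeObjectPackage", function(object) {
    cat("KnowledgeObjectPackage", formatPersistentId(koId(object)), "\n")
    cat("  title    :", object@metadata@title, "\n")
    cat("  endpoint :", object@deployment@httpMethod,
        paste0(object@service@baseUrl, object@deployment@endpointPath), "\n")
    cat("  engine   :", object@deployment@engine,
        sprintf("(entry %s, function %s)", object@deployment@entry,
                object@deployment@functionName), "\n")
    cat("  payload  :", length(object@payload), "artifact(s):",
        paste(names(object@payload), collapse = ", "), "\n")
})

## Endpoint key: the join of the service base URL and the deployment
## path, the reachable URL of the activated model.
#' @rdname ko-accessors
#' @export
endpointKey <- function(x) {
    if (is(x, "KnowledgeObjectPackage"))
        paste0(x@service@baseUrl, x@deployment@endpointPath)
    else if (is(x, "ContextEntry")) x@endpointKey
    else stop("no endpoint key for objects of class ", class(x))
}

## ---------------------------------------------------------------------
## Deployment description parser

#' Parse a deployment description
#'
#' Deployment descriptions are small YAML documents with a single
#' top-level endpoint path key, under which a single HTTP method key
#' (post) holds the engine, entry, artifact list, and function name:
#'
#' ```yaml
#' /bmi:
#'   post:
#'     engine: node
#'     entry: bmi.js
#'     artifact: bmi.js
#'     function: bmi
#' ```
#'
#' A scalar `artifact` value is normalized to a one-element list;
#' sequences keep their order. Exactly one path and one method are
#' accepted: a KO backs one endpoint.
#'
#' @param text YAML source of the deployment description.
#' @return a [DeploymentSpec-class].
#' @export
parseDeploymentDescription <- function(text) {
    doc <- tryCatch(yaml::yaml.load(paste(text, collapse = "\n")),
        error = function(e) stop("malformed deployment YAML: ",
                                 conditionMessage(e), call. = FALSE))
    if (!is.list(doc) || length(doc) != 1L || is.null(names(doc)))
        stop("deployment description must have exactly one top-level path key")
    endpointPath <- names(doc)[1L]
    methods <- doc[[1L]]
    if (!is.list(methods) || length(methods) != 1L || is.null(names(methods)))
        stop("deployment description must declare exactly one HTTP method")
    method <- tolower(names(methods)[1L])
    if (!identical(method, "post"))
        stop("unsupported HTTP method in deployment description: ", method)
    body <- methods[[1L]]
    for (field in c("engine", "entry", "function")) {
        if (is.null(body[[field]]) || !nzchar(body[[field]]))
            stop("deployment description is missing required field '", field, "'")
    }
    artifacts <- body[["artifact"]]
    if (is.null(artifacts)) artifacts <- body[["entry"]]
    artifacts <- as.character(unlist(artifacts))   # scalar -> length-1, order kept
    DeploymentSpec(endpointPath = endpointPath, engine = body[["engine"]],
                   entry = body[["entry"]], functionName = body[["function"]],
                   artifacts = artifacts, httpMethod = method)
}

#' Render a deployment specification back to its YAML dialect
#'
#' Inverse of [parseDeploymentDescription()]: parsing the emitted text
#' reproduces an identical specification.
#'
#' @param spec a [DeploymentSpec-class].
#' @return character(1), YAML text.
#' @export
formatDeploymentDescription <- function(spec) {
    doc <- list(list(list(
        engine = spec@engine, entry = spec@entry,
        artifact = as.list(spec@artifacts), `function` = spec@functionName)))
    names(doc) <- spec@endpointPath
    names(doc[[1L]]) <- spec@httpMethod
    yaml::as.yaml(doc)
}

## ---------------------------------------------------------------------
## Service description parser (OpenAPI 3.0 dialect)

#' Parse an OpenAPI 3.0 service description
#'
#' Extracts the fields the activator needs from an OpenAPI 3.0 YAML
#' document: the base URL from the first `servers` entry, the service
#' version from `info.version`, the title, license and contact, and the
#' endpoint paths in document order.
#'
#' @param text YAML source of the service description.
#' @return a [ServiceSpec-class].
#' @export
parseServiceDescription <- function(text) {
    doc <- tryCatch(yaml::yaml.load(paste(text, collapse = "\n")),
        error = function(e) stop("malformed service YAML: ",
                                 conditionMessage(e), call. = FALSE))
    if (!is.list(doc)) stop("service description must be a YAML mapping")
    info <- doc[["info"]]
    if (is.null(info) || is.null(info[["version"]]))
        stop("service description is missing 'info.version'")
    servers <- doc[["servers"]]
    if (is.null(servers) || !length(servers) || is.null(servers[[1L]][["url"]]))
        stop("service description is missing its 'servers' block")
    paths <- doc[["paths"]]
    if (is.null(paths) || !length(paths) || is.null(names(paths)))
        stop("service description declares no paths")
    lic <- info[["license"]]
    contact <- info[["contact"]]
    ServiceSpec(
        baseUrl = as.character(servers[[1L]][["url"]]),
        paths = names(paths),
        title = if (is.null(info[["title"]])) "" else info[["title"]],
        serviceVersion = as.character(info[["version"]]),
        apiFormatVersion = if (is.null(doc[["openapi"]])) "3.0.0"
                           else as.character(doc[["openapi"]]),
        licenseName = if (is.null(lic[["name"]])) "" else lic[["name"]],
        contact = if (is.null(contact[["name"]])) "" else contact[["name"]])
}

#' Render a service specification as an OpenAPI 3.0 document
#'
#' @param spec a [ServiceSpec-class].
#' @param method HTTP method to declare under each path.
#' @return character(1), YAML text.
#' @export
formatServiceDescription <- function(spec, method = "post") {
    paths <- lapply(spec@paths, function(p) {
        op <- list(list(summary = paste("Invoke", p),
                        responses = list(`200` = list(description = "result"))))
        names(op) <- method
        op
    })
    names(paths) <- spec@paths
    info <- list(version = spec@serviceVersion, title = spec@title)
    if (nzchar(spec@licenseName)) info$license <- list(name = spec@licenseName)
    if (nzchar(spec@contact)) info$contact <- list(name = spec@contact)
    yaml::as.yaml(list(
        openapi = spec@apiFormatVersion,
        info = info,
        servers = list(list(url = spec@baseUrl)),
        paths = paths))
}
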