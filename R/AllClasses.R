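#' @import methods
NULL

.scalar <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
.nonempty <- function(x) .scalar(x) && nzchar(x)

## semantic version: MAJOR.MINOR with optional .PATCH
.validVersion <- function(v) .scalar(v) && grepl("^[0-9]+\\.[0-9]+(\\.[0-9]+)?$", v)

#' Persistent unique identifier (PUID) for a Knowledge Object
#'
#' A PUID names a Knowledge Object on a shelf. It has three parts: a
#' registrar token (`naan`), an object slug (`name`), and a semantic
#' version string. Its canonical string form, produced by
#' [formatPersistentId()], is `naan/name/version` (ark-like).
#'
#' @slot naan character(1), registrar token.
#' @slot name character(1), object slug.
#' @slot version character(1), `MAJOR.MINOR` or `MAJOR.MINOR.PATCH`.
#' @seealso [persistentId()], [parsePersistentId()]
#' @exportClass PersistentId
setClass("PersistentId",
    representation(naan = "character", name = "character", version = "character"),
    validity = function(object) {
        msg <- character()
        if (!.nonempty(object@naan)) msg <- c(msg, "'naan' must be a nonempty string")
        if (!.nonempty(object@name)) msg <- c(msg, "'name' must be a nonempty string")
        if (!.validVersion(object@version))
            msg <- c(msg, "'version' must match MAJOR.MINOR[.PATCH]")
        if (length(msg)) msg else TRUE
    })

#' Descriptive metadata of a Knowledge Object
#'
#' The metadata component of a KO: its persistent identifier plus the
#' title, contributors, KO-level version and free-text description. The
#' KO version is distinct from the service version carried by the
#' service description: the packaged object and the web-service API it
#' backs evolve independently.
#'
#' @slot id a [PersistentId-class].
#' @slot title character(1), nonempty.
#' @slot contributors character vector of contributor names.
#' @slot koVersion character(1), version of the KO as a package.
#' @slot description character(1).
#' @exportClass KoMetadata
setClass("KoMetadata",
    representation(id = "PersistentId", title = "character",
                   contributors = "character", koVersion = "character",
                   description = "character"),
    validity = function(object) {
        msg <- character()
        if (!.nonempty(object@title)) msg <- c(msg, "'title' must be nonempty")
        if (!.scalar(object@koVersion)) msg <- c(msg, "'koVersion' must be a string")
        if (length(msg)) msg else TRUE
    })

#' Deployment description of a Knowledge Object
#'
#' Tells an activator how to instantiate the payload: the endpoint path
#' the function should answer on, the HTTP method (POST only), the
#' runtime engine token, the entry artifact, the full artifact list, and
#' the name of the instantiable function the entry defines.
#'
#' @slot endpointPath character(1), URL path segment beginning with "/".
#' @slot httpMethod character(1), currently always "post".
#' @slot engine character(1), runtime token (e.g. "r", "node").
#' @slot entry character(1), filename of the entry artifact.
#' @slot artifacts character vector of payload filenames; contains `entry`.
#' @slot functionName character(1), symbol the entry artifact defines.
#' @exportClass DeploymentSpec
setClass("DeploymentSpec",
    representation(endpointPath = "character", httpMethod = "character",
                   engine = "character", entry = "character",
                   artifacts = "character", functionName = "character"),
    validity = function(object) {
        msg <- character()
        if (!.nonempty(object@endpointPath) || !startsWith(object@endpointPath, "/"))
            msg <- c(msg, "'endpointPath' must start with \"/\"")
        if (!identical(object@httpMethod, "post"))
            msg <- c(msg, "'httpMethod' must be \"post\"")
        if (!.nonempty(object@engine)) msg <- c(msg, "'engine' must be nonempty")
        if (!.nonempty(object@entry)) msg <- c(msg, "'entry' must be nonempty")
        if (!length(object@artifacts)) msg <- c(msg, "'artifacts' must be nonempty")
        if (.nonempty(object@entry) && !(object@entry %in% object@artifacts))
            msg <- c(msg, "'entry' must be listed in 'artifacts'")
        if (!.nonempty(object@functionName)) msg <- c(msg, "'functionName' must be nonempty")
        if (length(msg)) msg else TRUE
    })

#' Service description of a Knowledge Object
#'
#' The OpenAPI 3.0 face of a KO: the partial base URL the service is
#' mounted under, the service version (independent of the KO version),
#' and the declared endpoint paths. Only the dialect fields the
#' activator needs are modelled; the full OpenAPI document is carried
#' verbatim in the package payload on disk.
#'
#' @slot apiFormatVersion character(1), e.g. "3.0.0".
#' @slot serviceVersion character(1), from `info.version`.
#' @slot title character(1).
#' @slot baseUrl character(1), partial URL from the first `servers` entry.
#' @slot paths character vector of endpoint paths, in document order.
#' @slot licenseName character(1), possibly empty.
#' @slot contact character(1), possibly empty.
#' @exportClass ServiceSpec
setClass("ServiceSpec",
    representation(apiFormatVersion = "character", serviceVersion = "character",
                   title = "character", baseUrl = "character",
                   paths = "character", licenseName = "character",
                   contact = "character"),
    validity = function(object) {
        msg <- character()
        if (!.nonempty(object@serviceVersion)) msg <- c(msg, "'serviceVersion' must be nonempty")
        if (!.nonempty(object@baseUrl)) msg <- c(msg, "'baseUrl' must be nonempty")
        if (!length(object@paths)) msg <- c(msg, "'paths' must be nonempty")
        if (length(msg)) msg else TRUE
    })

#' A Knowledge Object package
#'
#' The compound digital object at the centre of the stack: metadata
#' (with the PUID), a deployment description, a service description, and
#' the executable payload as a named list of raw byte vectors keyed by
#' filename. Cross-component consistency (entry artifact present in the
#' payload, deployment path declared by the service description, ...) is
#' checked by [validateKnowledgeObject()], not by class validity, so
#' that broken packages can be loaded and inspected.
#'
#' @slot metadata a [KoMetadata-class].
#' @slot deployment a [DeploymentSpec-class].
#' @slot service a [ServiceSpec-class].
#' @slot payload named list of raw vectors, filename -> bytes.
#' @exportClass KnowledgeObjectPackage
setClass("KnowledgeObjectPackage",
    representation(metadata = "KoMetadata", deployment = "DeploymentSpec",
                   service = "ServiceSpec", payload = "list"),
    validity = function(object) {
        msg <- character()
        nm <- names(object@payload)
        if (length(object@payload)) {
            if (is.null(nm) || any(!nzchar(nm)))
                msg <- c(msg, "'payload' must be a named list")
            else if (anyDuplicated(nm))
                msg <- c(msg, "duplicate payload filenames")
            if (!all(vapply(object@payload, is.raw, logical(1))))
                msg <- c(msg, "'payload' entries must be raw vectors")
        }
        if (length(msg)) msg else TRUE
    })

#' Validation report for a Knowledge Object package
#'
#' Findings are returned, never raised: each row of `findings` has a
#' severity ("error" or "warning"), a stable machine-readable code, a
#' human-readable message, and the package component it concerns. `ok`
#' is TRUE exactly when no error-severity finding is present.
#'
#' @slot ok logical(1).
#' @slot findings data.frame with columns severity, code, message, component.
#' @exportClass ValidationReport
setClass("ValidationReport",
    representation(ok = "logical", findings = "data.frame"),
    validity = function(object) {
        msg <- character()
        need <- c("severity", "code", "message", "component")
        if (!all(need %in% names(object@findings)))
            msg <- c(msg, "findings must have columns severity, code, message, component")
        else {
            nerr <- sum(object@findings$severity == "error")
            if (!identical(object@ok, nerr == 0L))
                msg <- c(msg, "'ok' must equal the absence of error findings")
        }
        if (length(msg)) msg else TRUE
    })

#' Handle to a deployed executable
#'
#' Opaque token returned by a runtime adapter's deploy step and used for
#' all later invocations; valid until undeployed.
#'
#' @slot token character(1) opaque token.
#' @slot engineName character(1).
#' @exportClass DeployedHandle
setClass("DeployedHandle",
    representation(token = "character", engineName = "character"))

#' One entry of the runtime context
#'
#' Records one activated model: the endpoint key it answers on (service
#' base URL joined with the deployment path), its PUID, the deployed
#' handle, the activation status and timestamp.
#'
#' @slot endpointKey character(1).
#' @slot puid character(1), canonical PUID string.
#' @slot handle a [DeployedHandle-class].
#' @slot status character(1), "active" or "failed".
#' @slot activatedAt POSIXct timestamp.
#' @slot method character(1), declared HTTP method.
#' @exportClass ContextEntry
setClass("ContextEntry",
    representation(endpointKey = "character", puid = "character",
                   handle = "DeployedHandle", status = "character",
                   activatedAt = "POSIXct", method = "character"),
    validity = function(object) {
        if (!object@status %in% c("active", "failed"))
            "'status' must be \"active\" or \"failed\"" else TRUE
    })

#' The activator's runtime context
#'
#' The dynamic registry of every model the activator has deployed,
#' keyed by endpoint. The mutable state (entries, invocation counters,
#' structured log, registered adapters) lives in an environment slot so
#' a context behaves by reference, as a live registry must: activation
#' and deactivation refresh it in place and every holder observes the
#' current state. Use the accessors ([contextEntries()],
#' [invocationCounts()], [gatewayLog()]) rather than touching the
#' environment.
#'
#' @slot state environment holding entries, counts, log, adapters, options.
#' @seealso [runtimeContext()], [activate()], [route()]
#' @exportClass RuntimeContext
setClass("RuntimeContext", representation(state = "environment"))

#' Virtual runtime-adapter contract
#'
#' An adapter connects the activator to one execution engine. Concrete
#' adapters implement [adapterDeploy()], [adapterInvoke()],
#' [adapterUndeploy()] and [engineName()]. Invocations must be stateless
#' for pure-function payloads, and deploying the same artifacts twice
#' must yield independently invokable handles.
#'
#' @seealso [nativeAdapter()] for the in-process R adapter shipped with
#'   the package.
#' @exportClass RuntimeAdapter
setClass("RuntimeAdapter", representation("VIRTUAL"))

#' In-process R runtime adapter
#'
#' Evaluates payload R source in an isolated environment (parent:
#' the base namespace) and invokes the named function with one argument.
#' The model-to-model context facility is injected into the payload
#' environment at invocation time under the well-known name
#' `kgrid_call`, so payload code never imports anything from the host.
#'
#' @slot registry environment mapping handle tokens to deployed state.
#' @exportClass NativeRAdapter
setClass("NativeRAdapter", contains = "RuntimeAdapter",
    representation(registry = "environment"))

#' Gateway response envelope
#'
#' What [route()] returns for every request: a status token, the body
#' record, and the endpoint key of the model involved (empty when no
#' model matched). `status == "ok"` exactly when the body carries a
#' `result` field.
#'
#' @slot status one of ok, not_found, method_not_allowed, model_error, bad_input.
#' @slot body named list (JSON-shaped record).
#' @slot modelRef character(1) endpoint key, or "".
#' @exportClass GatewayResponse
setClass("GatewayResponse",
    representation(status = "character", body = "list", modelRef = "character"),
    validity = function(object) {
        ok <- object@status %in%
            c("ok", "not_found", "method_not_allowed", "model_error", "bad_input")
        if (!ok) return("invalid 'status' token")
        if (identical(object@status, "ok") && !("result" %in% names(object@body)))
            return("status \"ok\" requires a 'result' field in the body")
        if (!identical(object@status, "ok") && ("result" %in% names(object@body)))
            return("only status \"ok\" may carry a 'result' field")
        TRUE
    })

#' Stratified life table of annual mortality probabilities
#'
#' Annual probabilities of death q(a) for ages 0..100, stratified by sex
#' and race. Stored long as a data.frame with columns sex, race, age, q.
#' Each stratum must be complete over the age range, every q in [0,1],
#' and q(100) = 1 (terminal closure).
#'
#' @slot table data.frame(sex, race, age, q).
#' @seealso [genLifeTable()], [readLifeTable()], [mortalitySchedule()]
#' @exportClass LifeTable
setClass("LifeTable",
    representation(table = "data.frame"),
    validity = function(object) {
        tb <- object@table
        need <- c("sex", "race", "age", "q")
        if (!all(need %in% names(tb)))
            return("life table needs columns sex, race, age, q")
        if (any(tb$q < 0 | tb$q > 1)) return("all q must lie in [0,1]")
        key <- paste(tb$sex, tb$race)
        for (k in unique(key)) {
            sub <- tb[key == k, ]
            if (!identical(sort(sub$age), 0:100))
                return(sprintf("stratum %s must cover ages 0..100 exactly", k))
            if (sub$q[sub$age == 100] != 1)
                return(sprintf("stratum %s must close with q(100) = 1", k))
        }
        TRUE
    })

#' Age-ordered mortality schedule for one individual
#'
#' The slice of a life table handed to the life-expectancy estimator:
#' the starting age and the ordered annual mortality probabilities from
#' that age onward.
#'
#' @slot startAge integer(1), years.
#' @slot rates numeric vector of annual q values, each in [0,1], nonempty.
#' @seealso [mortalitySchedule()], [lifeExpectancy()]
#' @exportClass MortalitySchedule
setClass("MortalitySchedule",
    representation(startAge = "integer", rates = "numeric"),
    validity = function(object) {
        if (!length(object@rates)) return("'rates' must be nonempty")
        if (any(!is.finite(object@rates)) || any(object@rates < 0 | object@rates > 1))
            return("all rates must lie in [0,1]")
        TRUE
    })

#' Manifest of a generated demonstration shelf
#'
#' Returned by [buildDemoShelf()]: the seed, the per-package listing
#' (PUID, submodel type, engine, endpoint key), the per-type counts, and
#' the composite wiring (direct callees of the top-level executive and
#' the callees of each lower-level executive).
#'
#' @slot seed integer(1).
#' @slot packages data.frame(puid, type, engine, endpointKey).
#' @slot countsByType named integer vector, submodel type -> quantity.
#' @slot wiring list with elements `top`, `topDirect`, `lower`.
#' @exportClass ShelfManifest
setClass("ShelfManifest",
    representation(seed = "integer", packages = "data.frame",
                   countsByType = "integer", wiring = "list"))

#' Gompertz parameters for synthetic life tables
#'
#' The synthetic stand-in for a CDC-style life table: baseline hazard
#' `A`, log-slope per year of age `B`, and multiplicative stratum
#' effects per sex and race. q(a) = min(1, m * A * exp(B * a)).
#'
#' @slot A numeric(1) > 0, hazard at age 0.
#' @slot B numeric(1) > 0, log-hazard slope per year.
#' @slot sexMultipliers named numeric, e.g. c(Male = 1.15, Female = 0.85).
#' @slot raceMultipliers named numeric.
#' @seealso [gompertzParams()], [genLifeTable()]
#' @exportClass GompertzParams
setClass("GompertzParams",
    representation(A = "numeric", B = "numeric",
                   sexMultipliers = "numeric", raceMultipliers = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@A <= 0) msg <- c(msg, "'A' must be > 0")
        if (object@B <= 0) msg <- c(msg, "'B' must be > 0")
        if (is.null(names(object@sexMultipliers)) || is.null(names(object@raceMultipliers)))
            msg <- c(msg, "stratum multipliers must be named")
        if (length(msg)) msg else TRUE
    })
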