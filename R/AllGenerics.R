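## Adapter contract -----------------------------------------------------

#' Runtime-adapter generics
#'
#' The communication protocol between the activator and an execution
#' engine. `adapterDeploy` instantiates payload artifacts and returns a
#' [DeployedHandle-class]; `adapterInvoke` runs the deployed function on
#' one input record, with the model-to-model context facility supplied
#' by the gateway; `adapterUndeploy` releases the handle; `engineName`
#' reports the engine token the adapter serves.
#'
#' @param adapter a [RuntimeAdapter-class].
#' @param artifacts named list of raw vectors (filename -> bytes).
#' @param entry character(1), entry artifact filename.
#' @param functionName character(1), symbol the entry defines.
#' @param handle a [DeployedHandle-class].
#' @param input named list, the input record.
#' @param contextFacility function(ref, payload) injected for
#'   model-to-model calls, or NULL.
#' @return `adapterDeploy` a handle; `adapterInvoke` the function value;
#'   `adapterUndeploy` invisibly TRUE; `engineName` character(1).
#' @name RuntimeAdapter-generics
#' @aliases adapterDeploy adapterInvoke adapterUndeploy engineName
#' @export
setGeneric("adapterDeploy", function(adapter, artifacts, entry, functionName)
    standardGeneric("adapterDeploy"))

#' @rdname RuntimeAdapter-generics
#' @export
setGeneric("adapterInvoke", function(adapter, handle, input, contextFacility = NULL)
    standardGeneric("adapterInvoke"))

#' @rdname RuntimeAdapter-generics
#' @export
setGeneric("adapterUndeploy", function(adapter, handle)
    standardGeneric("adapterUndeploy"))

#' @rdname RuntimeAdapter-generics
#' @export
setGeneric("engineName", function(adapter) standardGeneric("engineName"))

## Accessors -------------------------------------------------------------

#' Accessors for Knowledge Object packages
#'
#' @param x a [KnowledgeObjectPackage-class] (or component object).
#' @return `koMetadata`, `koDeployment`, `koService` return the
#'   respective component; `koPayload` the named list of raw vectors;
#'   `koId` the [PersistentId-class].
#' @name ko-accessors
#' @aliases koMetadata koDeployment koService koPayload koId
#' @export
setGeneric("koMetadata", function(x) standardGeneric("koMetadata"))
#' @rdname ko-accessors
#' @export
setGeneric("koDeployment", function(x) standardGeneric("koDeployment"))
#' @rdname ko-accessors
#' @export
setGeneric("koService", function(x) standardGeneric("koService"))
#' @rdname ko-accessors
#' @export
setGeneric("koPayload", function(x) standardGeneric("koPayload"))
#' @rdname ko-accessors
#' @export
setGeneric("koId", function(x) standardGeneric("koId"))

#' @rdname ko-accessors
#' @export
setMethod("koMetadata", "KnowledgeObjectPackage", function(x) x@metadata)
#' @rdname ko-accessors
#' @export
setMethod("koDeployment", "KnowledgeObjectPackage", function(x) x@deployment)
#' @rdname ko-accessors
#' @export
setMethod("koService", "KnowledgeObjectPackage", function(x) x@service)
#' @rdname ko-accessors
#' @export
setMethod("koPayload", "KnowledgeObjectPackage", function(x) x@payload)
#' @rdname ko-accessors
#' @export
setMethod("koId", "KnowledgeObjectPackage", function(x) x@metadata@id)
#' @rdname ko-accessors
#' @export
setMethod("koId", "KoMetadata", function(x) x@id)
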