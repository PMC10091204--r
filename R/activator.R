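## Activation, deactivation, and the API-gateway router.

#' Activate a Knowledge Object into a runtime context
#'
#' Validates the package, deploys its payload through the adapter
#' registered for its engine, and registers the resulting executable in
#' the context under its endpoint key (service base URL joined with the
#' deployment path). Activation is atomic: on any failure the set of
#' active entries is unchanged, and an unknown engine or a deploy
#' failure is recorded as a `status = "failed"` entry rather than
#' raised, so one bad package never disturbs the rest of a shelf.
#'
#' @param pkg a valid [KnowledgeObjectPackage-class].
#' @param ctx a [RuntimeContext-class].
#' @param replace replace an existing active entry under the same
#'   endpoint key? Default FALSE: re-activation of a live key is an
#'   error unless explicitly requested.
#' @return the new [ContextEntry-class] (possibly with status "failed").
#' @seealso [deactivate()], [route()], [activateShelf()]
#' @export
activate <- function(pkg, ctx, replace = FALSE) {
    stopifnot(is(pkg, "KnowledgeObjectPackage"), is(ctx, "RuntimeContext"))
    report <- validateKnowledgeObject(pkg, ctx@state$engineAllowList)
    if (!ok(report))
        stop("cannot activate an invalid KO package (",
             paste(findings(report)$code[findings(report)$severity == "error"],
                   collapse = ", "), ")")
    key <- endpointKey(pkg)
    puid <- formatPersistentId(koId(pkg))
    engine <- pkg@deployment@engine
    t0 <- proc.time()[["elapsed"]]

    fail <- function(reason) {
        entry <- new("ContextEntry", endpointKey = key, puid = puid,
                     handle = new("DeployedHandle", token = "", engineName = engine),
                     status = "failed", activatedAt = Sys.time(),
                     method = pkg@deployment@httpMethod)
        ctx@state$failures[[length(ctx@state$failures) + 1L]] <- entry
        .ctxLog(ctx, "activation_failed", key, reason)
        warning("activation of ", puid, " failed: ", reason, call. = FALSE)
        entry
    }

    adapter <- ctx@state$adapters[[engine]]
    if (is.null(adapter))
        return(fail(sprintf("no adapter registered for engine '%s'", engine)))
    if (key %in% activeKeys(ctx) && !replace)
        stop("endpoint key '", key, "' is already active; ",
             "use replace = TRUE to re-activate")
    handle <- tryCatch(
        adapterDeploy(adapter, pkg@payload, pkg@deployment@entry,
                      pkg@deployment@functionName),
        error = function(e) e)
    if (inherits(handle, "error"))
        return(fail(conditionMessage(handle)))
    if (key %in% activeKeys(ctx))   # replace = TRUE: swap only after success
        deactivate(key, ctx)
    entry <- new("ContextEntry", endpointKey = key, puid = puid,
                 handle = handle, status = "active", activatedAt = Sys.time(),
                 method = pkg@deployment@httpMethod)
    ctx@state$entries[[key]] <- entry
    .ctxLog(ctx, "activated", key, puid,
            elapsedMs = (proc.time()[["elapsed"]] - t0) * 1000)
    entry
}

#' Deactivate an activated model
#'
#' Undeploys the executable and removes the entry, so subsequent
#' [route()] calls to the key answer `not_found`. Deactivating an
#' unknown key is a warning no-op.
#'
#' @param endpointKey the key to remove.
#' @param ctx a [RuntimeContext-class].
#' @return the removed [ContextEntry-class], or NULL invisibly.
#' @export
deactivate <- function(endpointKey, ctx) {
    entry <- ctx@state$entries[[endpointKey]]
    if (is.null(entry)) {
        warning("endpoint key '", endpointKey, "' is not active; nothing to do")
        return(invisible(NULL))
    }
    adapter <- ctx@state$adapters[[entry@handle@engineName]]
    if (!is.null(adapter)) adapterUndeploy(adapter, entry@handle)
    ctx@state$entries[[endpointKey]] <- NULL
    .ctxLog(ctx, "deactivated", endpointKey, entry@puid)
    entry
}

## Shared invocation path for external routing and model-to-model calls.
## Depth counts gateway-mediated hops; at maxCallDepth the chain is
## declared cyclic.
.invokeEntry <- function(ctx, entry, payload, depth) {
    if (depth >= ctx@state$maxCallDepth)
        stop("cycle error: model-to-model call depth reached ",
             ctx@state$maxCallDepth, " at '", entry@endpointKey, "'")
    key <- entry@endpointKey
    n <- ctx@state$counts[[key]]
    ctx@state$counts[[key]] <- if (is.null(n)) 1L else n + 1L
    adapter <- ctx@state$adapters[[entry@handle@engineName]]
    facility <- function(ref, payload)
        resolveAndCall(ref, payload, ctx, depth = depth + 1L)
    adapterInvoke(adapter, entry@handle, payload, contextFacility = facility)
}

#' Resolve a model reference and call it
#'
#' The context facility behind model-to-model composition: given an
#' endpoint key of another activated model, invokes it through the
#' gateway and returns its result -- identical to what an external
#' [route()] on the same key and payload would report as `result`. The
#' caller never learns the callee's implementation details. Exposed
#' inside payload environments as `kgrid_call(ref, payload)`.
#'
#' @param ref endpoint key of the callee.
#' @param payload input record (named list).
#' @param ctx a [RuntimeContext-class].
#' @param depth current call depth (managed by the gateway).
#' @return the callee's result value.
#' @export
resolveAndCall <- function(ref, payload, ctx, depth = 0L) {
    entry <- ctx@state$entries[[ref]]
    if (is.null(entry))
        stop("resolution error: no active model at '", ref, "'")
    .invokeEntry(ctx, entry, payload, depth)
}

#' Route an external request through the API gateway
#'
#' Matches the request path against the active endpoint keys, checks
#' the HTTP method, invokes the model through its adapter, and wraps
#' the outcome in a [GatewayResponse-class]. Model failures surface as
#' `model_error` responses naming the model's endpoint key -- the
#' gateway itself never crashes on a model exception. Payload code may
#' signal `errorCondition(msg, class = "ko_bad_input")` to have its
#' complaint reported as `bad_input` instead.
#'
#' @param path request URL path.
#' @param method HTTP verb, e.g. "post".
#' @param payload input record (named list); anything else is `bad_input`.
#' @param ctx a [RuntimeContext-class].
#' @return a [GatewayResponse-class]. On success the body is
#'   `list(result = ..., info = list(ko = <puid>, endpoint = <key>))`.
#' @examples
#' ctx <- runtimeContext()
#' activate(toyCalculatorPackage("bmi"), ctx)
#' resp <- route("/ipp/bmicalculator/1.0/bmi", "post",
#'               list(features = list(height = 73, weight = 220)), ctx)
#' resp@body$result
#' @export
route <- function(path, method, payload, ctx) {
    t0 <- proc.time()[["elapsed"]]
    entry <- ctx@state$entries[[path]]
    if (is.null(entry)) {
        .ctxLog(ctx, "route_not_found", path)
        return(new("GatewayResponse", status = "not_found",
                   body = list(error = paste0("no active model at '", path, "'")),
                   modelRef = ""))
    }
    if (!identical(tolower(method), entry@method))
        return(new("GatewayResponse", status = "method_not_allowed",
                   body = list(error = sprintf(
                       "method '%s' not allowed on '%s' (declared: %s)",
                       method, path, entry@method)),
                   modelRef = path))
    if (!is.list(payload) || (length(payload) && is.null(names(payload))))
        return(new("GatewayResponse", status = "bad_input",
                   body = list(error = "payload must be a JSON object (named record)"),
                   modelRef = path))
    outcome <- tryCatch(
        list(value = .invokeEntry(ctx, entry, payload, depth = 0L)),
        ko_bad_input = function(e) e,
        error = function(e) e)
    .ctxLog(ctx, "route", path, entry@puid,
            elapsedMs = (proc.time()[["elapsed"]] - t0) * 1000)
    if (inherits(outcome, "ko_bad_input"))
        return(new("GatewayResponse", status = "bad_input",
                   body = list(error = conditionMessage(outcome),
                               missing = as.list(outcome$missing)),
                   modelRef = path))
    if (inherits(outcome, "error"))
        return(new("GatewayResponse", status = "model_error",
                   body = list(error = conditionMessage(outcome)),
                   modelRef = path))
    new("GatewayResponse", status = "ok",
        body = list(result = outcome$value,
                    info = list(ko = entry@puid, endpoint = path)),
        modelRef = path)
}

setMethod("show", "GatewayResponse", function(object) {
    cat("GatewayResponse:", object@status,
        if (nzchar(object@modelRef)) paste0("[", object@modelRef, "]") else "",
        "\n")
})

#' Activate every Knowledge Object under a shelf directory
#'
#' Loads each KO package found one level below `dir` (or any `.zip`
#' archive directly under it) and activates it. Per-package wall times
#' land in [gatewayLog()].
#'
#' @param dir shelf directory.
#' @param ctx a [RuntimeContext-class].
#' @return data.frame summary as from [contextEntries()].
#' @export
activateShelf <- function(dir, ctx) {
    entries <- c(list.dirs(dir, recursive = FALSE),
                 list.files(dir, pattern = "\\.zip$", full.names = TRUE))
    for (loc in sort(entries)) {
        pkg <- loadKnowledgeObject(loc)
        activate(pkg, ctx)
    }
    contextEntries(ctx)
}
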