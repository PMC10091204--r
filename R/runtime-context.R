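## The runtime context: the activator's live registry of deployed
## models. State lives in an environment so the registry behaves by
## reference and is refreshed in place by every activate/deactivate.

#' Create a runtime context
#'
#' @param adapters list of [RuntimeAdapter-class] objects; by default
#'   the in-process R adapter. Registered by their [engineName()].
#' @param maxCallDepth maximum model-to-model call depth before a chain
#'   is treated as a cycle.
#' @param engineAllowList engine tokens accepted during validation.
#' @return a [RuntimeContext-class].
#' @examples
#' ctx <- runtimeContext()
#' entry <- activate(toyCalculatorPackage("bmi"), ctx)
#' activeKeys(ctx)
#' @export
runtimeContext <- function(adapters = list(nativeAdapter()),
                           maxCallDepth = 32L,
                           engineAllowList = defaultEngineAllowList()) {
    stopifnot(maxCallDepth >= 1L)
    state <- new.env(parent = emptyenv())
    state$entries <- list()       # endpointKey -> ContextEntry (active)
    state$failures <- list()      # ContextEntry with status "failed"
    state$counts <- list()        # endpointKey -> invocation count
    state$log <- list()
    state$adapters <- list()
    state$maxCallDepth <- as.integer(maxCallDepth)
    state$engineAllowList <- engineAllowList
    ctx <- new("RuntimeContext", state = state)
    for (ad in adapters) registerAdapter(ctx, ad)
    ctx
}

#' Register a runtime adapter with a context
#'
#' @param ctx a [RuntimeContext-class].
#' @param adapter a [RuntimeAdapter-class].
#' @return `ctx`, invisibly.
#' @export
registerAdapter <- function(ctx, adapter) {
    ctx@state$adapters[[engineName(adapter)]] <- adapter
    invisible(ctx)
}

.ctxLog <- function(ctx, event, endpointKey = "", detail = "", elapsedMs = NA_real_) {
    ctx@state$log[[length(ctx@state$log) + 1L]] <- list(
        timestamp = Sys.time(), event = event, endpointKey = endpointKey,
        detail = detail, elapsedMs = elapsedMs)
    invisible(NULL)
}

#' Inspect a runtime context
#'
#' `contextEntries` summarises every entry (active and failed) as a
#' data.frame; `activeKeys` returns the endpoint keys currently
#' routable; `invocationCounts` the per-endpoint invocation counters
#' (model-to-model calls included); `gatewayLog` the structured log of
#' activate/deactivate/route events with wall-clock timings.
#'
#' @param ctx a [RuntimeContext-class].
#' @return see details above.
#' @name context-accessors
#' @export
contextEntries <- function(ctx) {
    all <- c(ctx@state$entries, ctx@state$failures)
    if (!length(all))
        return(data.frame(endpointKey = character(), puid = character(),
                          status = character(), engine = character(),
                          method = character(),
                          activatedAt = as.POSIXct(character()),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(unname(all), function(e)
        data.frame(endpointKey = e@endpointKey, puid = e@puid,
                   status = e@status, engine = e@handle@engineName,
                   method = e@method, activatedAt = e@activatedAt,
                   stringsAsFactors = FALSE)))
}

#' @rdname context-accessors
#' @export
activeKeys <- function(ctx) names(ctx@state$entries)

#' @rdname context-accessors
#' @export
invocationCounts <- function(ctx) {
    counts <- unlist(ctx@state$counts)
    if (is.null(counts)) counts <- integer()
    counts
}

#' @rdname context-accessors
#' @export
gatewayLog <- function(ctx) {
    if (!length(ctx@state$log))
        return(data.frame(timestamp = as.POSIXct(character()),
                          event = character(), endpointKey = character(),
                          detail = character(), elapsedMs = numeric(),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(ctx@state$log, function(l)
        data.frame(timestamp = l$timestamp, event = l$event,
                   endpointKey = l$endpointKey, detail = l$detail,
                   elapsedMs = l$elapsedMs, stringsAsFactors = FALSE)))
}

setMethod("show", "ContextEntry", function(object) {
    cat(sprintf("ContextEntry [%s] %s (%s, %s, activated %s)\n",
                object@status, object@endpointKey, object@puid,
                object@handle@engineName,
                format(object@activatedAt, "%Y-%m-%d %H:%M:%S")))
})

setMethod("show", "RuntimeContext", function(object) {
    ent <- contextEntries(object)
    cat("RuntimeContext with", sum(ent$status == "active"), "active /",
        sum(ent$status == "failed"), "failed entr(ies)\n")
    if (nrow(ent))
        for (i in seq_len(nrow(ent)))
            cat(sprintf("  [%s] %s (%s)\n", ent$status[i], ent$endpointKey[i],
                        ent$puid[i]))
})
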