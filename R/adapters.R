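## The shipped runtime adapter: executes payload R source in-process,
## inside an isolated namespace. Other engines (node, python runtimes)
## participate through the same four-generic contract.

#' Create the in-process R runtime adapter
#'
#' Payload artifacts are evaluated, in their declared order, inside a
#' fresh environment whose parent is the base namespace; the deployed
#' function is looked up there by name. The model-to-model context
#' facility is injected into that environment under the well-known name
#' `kgrid_call` at every invocation -- payload code calls
#' `kgrid_call(ref, payload)` without importing anything from the host,
#' which keeps the source engine-agnostic.
#'
#' @param engine engine token this adapter answers for; default "r".
#' @return a [NativeRAdapter-class].
#' @examples
#' ad <- nativeAdapter()
#' h <- adapterDeploy(ad, list(f.R = charToRaw("sq <- function(x) x$value^2")),
#'                    "f.R", "sq")
#' adapterInvoke(ad, h, list(value = 3))
#' @export
nativeAdapter <- function(engine = "r") {
    reg <- new.env(parent = emptyenv())
    reg$counter <- 0L
    reg$engine <- engine
    new("NativeRAdapter", registry = reg)
}

#' @rdname RuntimeAdapter-generics
#' @export
setMethod("engineName", "NativeRAdapter", function(adapter) adapter@registry$engine)

#' @rdname RuntimeAdapter-generics
#' @export
setMethod("adapterDeploy", "NativeRAdapter",
function(adapter, artifacts, entry, functionName) {
    if (!(entry %in% names(artifacts)))
        stop("deploy error: entry artifact '", entry, "' not supplied")
    env <- new.env(parent = asNamespace("base"))
    ## placeholder until the gateway injects the real facility
    env$kgrid_call <- function(ref, payload)
        stop("no context facility available: model was invoked outside a gateway")
    ## only R source artifacts are evaluated (the entry always is);
    ## other artifacts are data the model may carry along
    for (nm in names(artifacts)) {
        if (!identical(nm, entry) && !grepl("\\.[rR]$", nm)) next
        src <- artifacts[[nm]]
        if (is.raw(src)) src <- rawToChar(src)
        tryCatch(eval(parse(text = src), envir = env),
            error = function(e) stop("deploy error: artifact '", nm,
                                     "' failed to load: ", conditionMessage(e),
                                     call. = FALSE))
    }
    if (!exists(functionName, envir = env, inherits = FALSE) ||
        !is.function(get(functionName, envir = env)))
        stop("deploy error: entry did not define function '", functionName, "'")
    reg <- adapter@registry
    reg$counter <- reg$counter + 1L
    token <- sprintf("r-handle-%d", reg$counter)
    assign(token, list(env = env, fun = get(functionName, envir = env)), envir = reg)
    new("DeployedHandle", token = token, engineName = reg$engine)
})

#' @rdname RuntimeAdapter-generics
#' @export
setMethod("adapterInvoke", "NativeRAdapter",
function(adapter, handle, input, contextFacility = NULL) {
    reg <- adapter@registry
    if (!exists(handle@token, envir = reg, inherits = FALSE))
        stop("invoke error: handle '", handle@token, "' is not deployed")
    dep <- get(handle@token, envir = reg)
    if (!is.null(contextFacility))
        assign("kgrid_call", contextFacility, envir = dep$env)
    tryCatch(dep$fun(input),
        error = function(e) {
            if (inherits(e, "ko_bad_input")) stop(e)  # typed conditions pass through
            stop("invoke error: ", conditionMessage(e), call. = FALSE)
        })
})

#' @rdname RuntimeAdapter-generics
#' @export
setMethod("adapterUndeploy", "NativeRAdapter", function(adapter, handle) {
    reg <- adapter@registry
    if (exists(handle@token, envir = reg, inherits = FALSE))
        rm(list = handle@token, envir = reg)
    invisible(TRUE)
})
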