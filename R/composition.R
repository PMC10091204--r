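## Composite models via generated executive submodels. An executive is
## an ordinary KO whose payload encodes procedural knowledge: which
## other models to call, in what order, under what condition. The
## payload source is generated text, so composites are inspectable and
## shippable like any other package.

#' Reference to an activated model
#'
#' @param endpointKey endpoint key of the callee.
#' @param inputMapping optional named character vector mapping upstream
#'   output fields (names) to downstream input fields (values). When
#'   NULL the whole upstream output record is passed as the input.
#' @return a `modelReference` list.
#' @export
modelReference <- function(endpointKey, inputMapping = NULL) {
    stopifnot(is.character(endpointKey), length(endpointKey) == 1L,
              startsWith(endpointKey, "/"))
    if (!is.null(inputMapping))
        stopifnot(is.character(inputMapping), !is.null(names(inputMapping)))
    structure(list(ref = endpointKey, map = inputMapping),
              class = "modelReference")
}

.asModelReference <- function(x)
    if (inherits(x, "modelReference")) x else modelReference(x)

## shared by the generated payloads: apply an input mapping
.MAPPER_SRC <- "
.apply_map <- function(value, map) {
    if (is.null(map)) return(value)
    out <- list()
    for (i in seq_along(map)) out[[unname(map[[i]])]] <- value[[names(map)[i]]]
    out
}
"

.executivePackage <- function(id, title, source, description) {
    baseUrl <- sprintf("/%s/%s/%s", id@naan, id@name, id@version)
    KnowledgeObjectPackage(
        metadata = KoMetadata(id, title = title, description = description),
        deployment = DeploymentSpec(endpointPath = "/run", engine = "r",
                                    entry = "executive.R",
                                    functionName = "composite"),
        service = ServiceSpec(baseUrl = baseUrl, paths = "/run", title = title,
                              serviceVersion = id@version),
        payload = list(executive.R = source))
}

## deparse for code generation: digits17 so embedded doubles survive
## the text round-trip bit-exactly
.deparse1 <- function(x)
    paste(deparse(x, width.cutoff = 500L,
                  control = c("keepNA", "keepInteger", "niceNames",
                              "showAttributes", "digits17")),
          collapse = "\n")

#' Generate a serial composite executive
#'
#' Builds a KO whose payload, once activated, calls each referenced
#' model in order, piping each output through its input mapping into
#' the next. A one-element chain is equivalent to the referenced model
#' itself.
#'
#' @param refs nonempty list of [modelReference()]s (bare endpoint-key
#'   strings are accepted), in call order.
#' @param id a [PersistentId-class] for the new executive.
#' @param title title for the metadata.
#' @return a valid [KnowledgeObjectPackage-class].
#' @seealso [makeConditionalExecutive()], [oracleCompose()]
#' @export
makeSerialExecutive <- function(refs, id, title = "Serial composite executive") {
    if (!length(refs)) stop("a serial executive needs at least one model reference")
    steps <- lapply(refs, function(r) unclass(.asModelReference(r)))
    source <- paste0(
        ".steps <- ", .deparse1(steps), "\n",
        .MAPPER_SRC, "\n",
        "composite <- function(inputs) {\n",
        "    value <- inputs\n",
        "    for (s in .steps) value <- kgrid_call(s$ref, .apply_map(value, s$map))\n",
        "    value\n",
        "}\n")
    .executivePackage(id, title, source,
        sprintf("Serial composition of %d model(s): %s", length(steps),
                paste(vapply(steps, `[[`, "", "ref"), collapse = " -> ")))
}

#' Generate a conditional composite executive
#'
#' Builds a KO that dispatches each request to exactly one branch,
#' selected by the value of `predicateField` in the input record. An
#' unmapped value falls back to `default` when supplied and is a model
#' error otherwise; either way, at most one branch is invoked per
#' request, which invocation counters can verify.
#'
#' @param predicateField name of the input field to dispatch on; its
#'   value is matched as a string (`TRUE`/`FALSE` for logicals).
#' @param branchMap nonempty named list, predicate value ->
#'   [modelReference()] (or bare endpoint key).
#' @param id a [PersistentId-class] for the new executive.
#' @param default optional fallback [modelReference()].
#' @param title title for the metadata.
#' @return a valid [KnowledgeObjectPackage-class].
#' @export
makeConditionalExecutive <- function(predicateField, branchMap, id,
                                     default = NULL,
                                     title = "Conditional composite executive") {
    if (!length(branchMap) || is.null(names(branchMap)))
        stop("'branchMap' must be a nonempty named list")
    branches <- lapply(branchMap, function(r) unclass(.asModelReference(r)))
    defaultRef <- if (is.null(default)) NULL else unclass(.asModelReference(default))
    source <- paste0(
        ".branches <- ", .deparse1(branches), "\n",
        ".default <- ", .deparse1(defaultRef), "\n",
        ".field <- ", .deparse1(predicateField), "\n",
        .MAPPER_SRC, "\n",
        "composite <- function(inputs) {\n",
        "    key <- as.character(inputs[[.field]])\n",
        "    branch <- if (length(key) == 1L) .branches[[key]] else NULL\n",
        "    if (is.null(branch)) branch <- .default\n",
        "    if (is.null(branch))\n",
        "        stop(sprintf(\"no branch mapped for %s = '%s'\", .field, key))\n",
        "    kgrid_call(branch$ref, .apply_map(inputs, branch$map))\n",
        "}\n")
    .executivePackage(id, title, source,
        sprintf("Conditional composition on field '%s' over branches: %s",
                predicateField, paste(names(branches), collapse = ", ")))
}

#' Reference oracle: plain nested function composition
#'
#' Applies `functions` to `input` in order by direct nested application
#' with no gateway involved; the empty chain is the identity. Used as
#' the independent comparator when testing that gateway-mediated
#' composition is transparent.
#'
#' @param functions ordered list of one-argument functions.
#' @param input the initial value.
#' @return the final value.
#' @export
oracleCompose <- function(functions, input)
    Reduce(function(value, f) f(value), functions, input)
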