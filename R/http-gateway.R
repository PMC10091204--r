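## A small HTTP face for the gateway, written over base-R sockets. The
## request handling is factored into pure functions (parse -> dispatch
## -> render) so the HTTP behaviour is testable without opening
## sockets; serveGateway() is only the socket loop around them.

.HTTP_STATUS <- c(ok = 200L, bad_input = 400L, not_found = 404L,
                  method_not_allowed = 405L, model_error = 500L)
.HTTP_REASON <- c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found",
                  `405` = "Method Not Allowed", `500` = "Internal Server Error")

#' JSON rendering of a gateway response body
#'
#' The canonical JSON the HTTP server and the CLI both emit, so their
#' outputs agree byte-for-byte.
#'
#' @param resp a [GatewayResponse-class].
#' @return character(1) JSON.
#' @export
gatewayBodyJson <- function(resp)
    as.character(jsonlite::toJSON(resp@body, auto_unbox = TRUE, digits = NA,
                                  null = "null"))

#' Dispatch one HTTP request against a runtime context
#'
#' Understands `POST <endpoint key>` with a JSON object body (routed to
#' the model) and `GET /context` (a JSON listing of context entries).
#'
#' @param method HTTP verb as received.
#' @param path request path.
#' @param body request body text (JSON), possibly empty.
#' @param ctx a [RuntimeContext-class].
#' @return list(status = integer HTTP status, body = character JSON).
#' @export
handleGatewayRequest <- function(method, path, body, ctx) {
    method <- toupper(method)
    if (method == "GET" && path == "/context") {
        ent <- contextEntries(ctx)
        ent$activatedAt <- format(ent$activatedAt, "%Y-%m-%dT%H:%M:%S%z")
        return(list(status = 200L,
                    body = as.character(jsonlite::toJSON(ent, digits = NA))))
    }
    payload <- tryCatch(
        if (nzchar(body)) jsonlite::fromJSON(body, simplifyVector = FALSE)
        else structure(list(), names = character()),
        error = function(e) e)
    if (inherits(payload, "error"))
        return(list(status = 400L, body = as.character(jsonlite::toJSON(
            list(error = "request body is not valid JSON"), auto_unbox = TRUE))))
    resp <- route(path, tolower(method), payload, ctx)
    list(status = .HTTP_STATUS[[resp@status]], body = gatewayBodyJson(resp))
}

#' @rdname handleGatewayRequest
#' @param status integer HTTP status code.
#' @param body response body text.
#' @return `renderHttpResponse`: raw vector, the full HTTP/1.1 response.
#' @export
renderHttpResponse <- function(status, body) {
    bodyRaw <- charToRaw(body)
    head <- sprintf(paste0("HTTP/1.1 %d %s\r\n",
                           "Content-Type: application/json\r\n",
                           "Content-Length: %d\r\n",
                           "Connection: close\r\n\r\n"),
                    status, .HTTP_REASON[[as.character(status)]],
                    length(bodyRaw))
    c(charToRaw(head), bodyRaw)
}

## Read one HTTP request from a binary connection: header bytes up to
## the blank line, then Content-Length body bytes.
.readHttpRequest <- function(con, maxHeaderBytes = 65536L) {
    buf <- raw()
    marker <- charToRaw("\r\n\r\n")
    repeat {
        b <- readBin(con, "raw", 1L)
        if (!length(b)) break
        buf <- c(buf, b)
        if (length(buf) >= 4L &&
            identical(buf[(length(buf) - 3L):length(buf)], marker)) break
        if (length(buf) > maxHeaderBytes) stop("request header too large")
    }
    if (!length(buf)) return(NULL)
    lines <- strsplit(rawToChar(buf), "\r\n", fixed = TRUE)[[1L]]
    reqLine <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
    if (length(reqLine) < 2L) stop("malformed request line")
    headers <- lines[-1L]
    clen <- 0L
    m <- grep("^content-length:", headers, ignore.case = TRUE, value = TRUE)
    if (length(m)) clen <- as.integer(trimws(sub("^[^:]+:", "", m[1L])))
    body <- if (clen > 0L) {
        got <- raw()
        while (length(got) < clen) {
            chunk <- readBin(con, "raw", clen - length(got))
            if (!length(chunk)) break
            got <- c(got, chunk)
        }
        rawToChar(got)
    } else ""
    list(method = reqLine[1L], path = reqLine[2L], body = body)
}

#' Serve the gateway over HTTP
#'
#' A minimal blocking HTTP/1.1 server on base-R sockets: accepts one
#' connection at a time, answers `POST <endpoint key>` and
#' `GET /context`, and closes the connection after each response.
#' Intended for local demonstration and testing, not production.
#'
#' @param ctx a [RuntimeContext-class].
#' @param port TCP port in \[1024, 65535\].
#' @param host interface to bind; default loopback.
#' @param maxRequests stop after this many requests (Inf to run until
#'   interrupted).
#' @return number of requests served, invisibly.
#' @export
serveGateway <- function(ctx, port, host = "127.0.0.1", maxRequests = Inf) {
    stopifnot(port >= 1024, port <= 65535)
    srv <- serverSocket(port)
    on.exit(close(srv), add = TRUE)
    .ctxLog(ctx, "serve_start", detail = sprintf("%s:%d", host, port))
    served <- 0
    while (served < maxRequests) {
        con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 300)
        ans <- tryCatch({
            req <- .readHttpRequest(con)
            if (is.null(req)) NULL
            else {
                out <- handleGatewayRequest(req$method, req$path, req$body, ctx)
                renderHttpResponse(out$status, out$body)
            }
        }, error = function(e)
            renderHttpResponse(400L, as.character(jsonlite::toJSON(
                list(error = conditionMessage(e)), auto_unbox = TRUE))))
        if (!is.null(ans)) writeBin(ans, con)
        close(con)
        served <- served + 1
    }
    .ctxLog(ctx, "serve_stop", detail = sprintf("served %d request(s)", served))
    invisible(served)
}
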