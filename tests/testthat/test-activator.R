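test_that("activation registers the joined endpoint key", {
    ctx <- runtimeContext()
    entry <- activate(toyCalculatorPackage("bmi"), ctx)
    expect_identical(entry@endpointKey, "/ipp/bmicalculator/1.0/bmi")
    expect_identical(entry@status, "active")
    expect_identical(activeKeys(ctx), "/ipp/bmicalculator/1.0/bmi")
})

test_that("an unknown engine yields a failed entry and leaves others untouched", {
    ctx <- runtimeContext()
    activate(toyCalculatorPackage("double"), ctx)
    alien <- toyCalculatorPackage("bmi")
    alien@deployment@engine <- "node"   # allow-listed but no adapter registered
    expect_warning(entry <- activate(alien, ctx), "no adapter")
    expect_identical(entry@status, "failed")
    expect_identical(activeKeys(ctx), "/toy/double/1.0/double")
    ent <- contextEntries(ctx)
    expect_setequal(ent$status, c("active", "failed"))
    ## the surviving model still routes
    expect_identical(
        route("/toy/double/1.0/double", "post", list(value = 4), ctx)@status,
        "ok")
})

test_that("re-activation of a live key requires the replace flag", {
    ctx <- runtimeContext()
    first <- activate(toyCalculatorPackage("bmi"), ctx)
    expect_error(activate(toyCalculatorPackage("bmi"), ctx), "replace")
    Sys.sleep(0.02)
    second <- activate(toyCalculatorPackage("bmi"), ctx, replace = TRUE)
    expect_identical(length(activeKeys(ctx)), 1L)
    expect_gte(as.numeric(second@activatedAt), as.numeric(first@activatedAt))
})

test_that("deactivation removes routability and is reversible", {
    ctx <- runtimeContext()
    activate(toyCalculatorPackage("bmi"), ctx)
    key <- "/ipp/bmicalculator/1.0/bmi"
    removed <- deactivate(key, ctx)
    expect_identical(removed@endpointKey, key)
    expect_identical(route(key, "post", list(features = list(height = 73,
                                                             weight = 220)),
                           ctx)@status, "not_found")
    expect_warning(deactivate(key, ctx), "not active")
    activate(toyCalculatorPackage("bmi"), ctx)
    expect_identical(route(key, "post", list(features = list(height = 73,
                                                             weight = 220)),
                           ctx)@status, "ok")
})

test_that("the gateway routes, checks methods, and isolates model failures", {
    ctx <- runtimeContext()
    activate(toyCalculatorPackage("bmi"), ctx)
    key <- "/ipp/bmicalculator/1.0/bmi"

    okResp <- route(key, "post", list(features = list(height = 73, weight = 220)),
                    ctx)
    expect_identical(okResp@status, "ok")
    expect_equal(okResp@body$result, 29.0223, tolerance = 1e-4)
    expect_identical(okResp@body$info$ko, "ipp/bmicalculator/1.0")

    expect_identical(route(key, "get", list(), ctx)@status, "method_not_allowed")
    expect_identical(route("/nope/1.0/x", "post", list(), ctx)@status, "not_found")
    expect_identical(route(key, "post", "not-a-record", ctx)@status, "bad_input")

    boom <- route(key, "post", list(features = list(height = 0, weight = 220)), ctx)
    expect_identical(boom@status, "model_error")
    expect_identical(boom@modelRef, key)
    expect_match(boom@body$error, "division by zero")
    ## the gateway and the model survive
    expect_identical(route(key, "post",
                           list(features = list(height = 73, weight = 220)),
                           ctx)@status, "ok")
})

test_that("the native adapter deploys, invokes statelessly, and survives errors", {
    ad <- nativeAdapter()
    payload <- list(bmi.R = charToRaw(
        "bmi <- function(inputs) {\n h <- inputs$features$height\n if (h == 0) stop(\"division by zero\")\n inputs$features$weight / h / h * 703\n}"))
    h1 <- adapterDeploy(ad, payload, "bmi.R", "bmi")
    expect_equal(adapterInvoke(ad, h1, list(features = list(height = 1, weight = 1))),
                 703)
    expect_error(adapterInvoke(ad, h1, list(features = list(height = 0, weight = 1))),
                 "division by zero")
    ## adapter survives; repeated invocations equal fresh deployments
    inputs <- list(list(features = list(height = 73, weight = 220)),
                   list(features = list(height = 60, weight = 130)))
    again <- lapply(inputs, function(x) adapterInvoke(ad, h1, x))
    h2 <- adapterDeploy(ad, payload, "bmi.R", "bmi")
    fresh <- lapply(inputs, function(x) adapterInvoke(ad, h2, x))
    expect_identical(again, fresh)
    ## deploy errors are reported as such
    expect_error(adapterDeploy(ad, list(x.R = charToRaw("syntax error (")),
                               "x.R", "f"), "deploy error")
    expect_error(adapterDeploy(ad, list(x.R = charToRaw("g <- 1")), "x.R", "f"),
                 "did not define")
    adapterUndeploy(ad, h1)
    expect_error(adapterInvoke(ad, h1, list()), "not deployed")
})

test_that("gateway routing is transparent relative to direct adapter invocation", {
    ad <- nativeAdapter()
    ctx <- runtimeContext(adapters = list(ad))
    pkg <- toyCalculatorPackage("square")
    activate(pkg, ctx)
    direct <- adapterInvoke(ad, adapterDeploy(ad, pkg@payload,
                                              pkg@deployment@entry,
                                              pkg@deployment@functionName),
                            list(value = 7))
    viaGateway <- route("/toy/square/1.0/square", "post", list(value = 7), ctx)
    expect_identical(viaGateway@body$result, direct)
})

test_that("model-to-model resolution matches external routing and guards cycles", {
    ctx <- runtimeContext()
    activate(toyCalculatorPackage("double"), ctx)
    ## an executive that calls the double model through the context facility
    caller <- KnowledgeObjectPackage(
        metadata = KoMetadata(PersistentId("toy", "caller", "1.0"),
                              title = "caller"),
        deployment = DeploymentSpec("/go", "r", "caller.R", "go"),
        service = ServiceSpec("/toy/caller/1.0", "/go"),
        payload = list(caller.R =
            "go <- function(inputs) kgrid_call(\"/toy/double/1.0/double\", inputs)"))
    activate(caller, ctx)
    ext <- route("/toy/double/1.0/double", "post", list(value = 21), ctx)
    nested <- route("/toy/caller/1.0/go", "post", list(value = 21), ctx)
    expect_identical(nested@body$result, ext@body$result)

    bad <- route("/toy/caller/1.0/go", "post", list(value = 1),
                 runtimeContext())
    expect_identical(bad@status, "not_found")

    ## unknown reference propagates to the caller as a model error
    orphan <- KnowledgeObjectPackage(
        metadata = KoMetadata(PersistentId("toy", "orphan", "1.0"),
                              title = "orphan"),
        deployment = DeploymentSpec("/go", "r", "o.R", "go"),
        service = ServiceSpec("/toy/orphan/1.0", "/go"),
        payload = list(o.R =
            "go <- function(inputs) kgrid_call(\"/nope/1.0/x\", inputs)"))
    activate(orphan, ctx)
    resp <- route("/toy/orphan/1.0/go", "post", list(value = 1), ctx)
    expect_identical(resp@status, "model_error")
    expect_match(resp@body$error, "/nope/1.0/x")

    ## a self-calling model hits the depth guard instead of recursing forever
    selfie <- KnowledgeObjectPackage(
        metadata = KoMetadata(PersistentId("toy", "selfie", "1.0"),
                              title = "selfie"),
        deployment = DeploymentSpec("/go", "r", "s.R", "go"),
        service = ServiceSpec("/toy/selfie/1.0", "/go"),
        payload = list(s.R =
            "go <- function(inputs) kgrid_call(\"/toy/selfie/1.0/go\", inputs)"))
    activate(selfie, ctx)
    resp <- route("/toy/selfie/1.0/go", "post", list(value = 1), ctx)
    expect_identical(resp@status, "model_error")
    expect_match(resp@body$error, "depth reached 32")
})

test_that("routable paths always equal the set of active entries", {
    set.seed(42)
    pkgs <- lapply(1:8, function(i) {
        p <- genRandomPackage(i + 100L)
        p
    })
    keys <- vapply(pkgs, endpointKey, character(1))
    ctx <- runtimeContext()
    active <- character()
    probe <- function() {
        for (k in keys) {
            resp <- route(k, "post", list(value = 1), ctx)
            if (k %in% active) expect_false(identical(resp@status, "not_found"))
            else expect_identical(resp@status, "not_found")
        }
        expect_setequal(activeKeys(ctx), active)
    }
    for (step in 1:30) {
        i <- sample(length(pkgs), 1L)
        if (keys[i] %in% active) {
            deactivate(keys[i], ctx)
            active <- setdiff(active, keys[i])
        } else {
            activate(pkgs[[i]], ctx)
            active <- c(active, keys[i])
        }
        probe()
    }
})

test_that("the structured log records lifecycle events with timings", {
    ctx <- runtimeContext()
    activate(toyCalculatorPackage("bmi"), ctx)
    route("/ipp/bmicalculator/1.0/bmi", "post",
          list(features = list(height = 73, weight = 220)), ctx)
    deactivate("/ipp/bmicalculator/1.0/bmi", ctx)
    lg <- gatewayLog(ctx)
    expect_true(all(c("activated", "route", "deactivated") %in% lg$event))
    expect_true(is.finite(lg$elapsedMs[lg$event == "activated"][1L]))
})
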