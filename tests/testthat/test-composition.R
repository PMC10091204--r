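## helpers local to composition tests
.activateToys <- function(ctx, names) {
    for (nm in names) activate(toyCalculatorPackage(nm), ctx)
    invisible(ctx)
}
.toyKey <- function(nm) sprintf("/toy/%s/1.0/%s", nm, nm)
.toyFun <- function(nm) switch(nm,
    double = function(x) list(value = x$value * 2),
    add_one = function(x) list(value = x$value + 1),
    square = function(x) list(value = x$value^2),
    negate = function(x) list(value = -x$value))

test_that("a one-element serial executive is equivalent to the model itself", {
    ctx <- runtimeContext()
    .activateToys(ctx, "double")
    exec <- makeSerialExecutive(list(.toyKey("double")),
                                PersistentId("toy", "just-double", "1.0"))
    expect_true(ok(validateKnowledgeObject(exec)))
    activate(exec, ctx)
    direct <- route(.toyKey("double"), "post", list(value = 9), ctx)@body$result
    viaExec <- route(endpointKey(exec), "post", list(value = 9), ctx)@body$result
    expect_identical(viaExec, direct)
})

test_that("serial order matters: double-then-add-one is 11, reversed is 12", {
    ctx <- runtimeContext()
    .activateToys(ctx, c("double", "add_one"))
    fwd <- makeSerialExecutive(list(.toyKey("double"), .toyKey("add_one")),
                               PersistentId("toy", "fwd", "1.0"))
    rev <- makeSerialExecutive(list(.toyKey("add_one"), .toyKey("double")),
                               PersistentId("toy", "rev", "1.0"))
    activate(fwd, ctx); activate(rev, ctx)
    expect_equal(route(endpointKey(fwd), "post", list(value = 5),
                       ctx)@body$result$value, 11)
    expect_equal(route(endpointKey(rev), "post", list(value = 5),
                       ctx)@body$result$value, 12)
    expect_error(makeSerialExecutive(list(), PersistentId("toy", "none", "1.0")),
                 "at least one")
})

test_that("serial chains equal direct nested application on random inputs", {
    ctx <- runtimeContext()
    .activateToys(ctx, c("double", "add_one", "negate"))
    chain <- c("double", "add_one", "negate")
    exec <- makeSerialExecutive(lapply(chain, .toyKey),
                                PersistentId("toy", "chain3", "1.0"))
    activate(exec, ctx)
    set.seed(1)
    for (x in stats::runif(100, -50, 50)) {
        expect_identical(
            route(endpointKey(exec), "post", list(value = x), ctx)@body$result,
            oracleCompose(lapply(chain, .toyFun), list(value = x)))
    }
})

test_that("random 2-5 model chains through the gateway match the oracle", {
    ctx <- runtimeContext()
    toys <- c("double", "add_one", "square", "negate")
    .activateToys(ctx, toys)
    set.seed(7)
    for (i in 1:12) {
        chain <- sample(toys, sample(2:5, 1L), replace = TRUE)
        exec <- makeSerialExecutive(lapply(chain, .toyKey),
                                    PersistentId("toy", sprintf("rc%02d", i),
                                                 "1.0"))
        activate(exec, ctx)
        x <- stats::runif(1, -10, 10)
        expect_identical(
            route(endpointKey(exec), "post", list(value = x), ctx)@body$result,
            oracleCompose(lapply(chain, .toyFun), list(value = x)))
    }
})

test_that("input mappings rewire fields between chained models", {
    ctx <- runtimeContext()
    .activateToys(ctx, "double")
    exec <- makeSerialExecutive(
        list(modelReference(.toyKey("double"), c(amount = "value"))),
        PersistentId("toy", "mapped", "1.0"))
    activate(exec, ctx)
    out <- route(endpointKey(exec), "post", list(amount = 4), ctx)@body$result
    expect_equal(out$value, 8)
})

test_that("a conditional executive engages exactly one branch per request", {
    ctx <- runtimeContext()
    .activateToys(ctx, c("double", "add_one"))
    exec <- makeConditionalExecutive(
        "flag", list(`TRUE` = .toyKey("double"), `FALSE` = .toyKey("add_one")),
        PersistentId("toy", "cond", "1.0"))
    activate(exec, ctx)

    before <- invocationCounts(ctx)
    out <- route(endpointKey(exec), "post", list(flag = TRUE, value = 6),
                 ctx)@body$result
    expect_equal(out$value, 12)
    after <- invocationCounts(ctx)
    delta <- function(key) {
        a <- if (key %in% names(after)) after[[key]] else 0L
        b <- if (key %in% names(before)) before[[key]] else 0L
        a - b
    }
    expect_identical(delta(.toyKey("double")), 1L)
    expect_identical(delta(.toyKey("add_one")), 0L)

    ## unmapped value with no default is a model error
    resp <- route(endpointKey(exec), "post", list(flag = "maybe", value = 1), ctx)
    expect_identical(resp@status, "model_error")
    expect_match(resp@body$error, "no branch")

    ## with a default the miss is routed there
    withDefault <- makeConditionalExecutive(
        "flag", list(`TRUE` = .toyKey("double")),
        PersistentId("toy", "cond-default", "1.0"),
        default = .toyKey("add_one"))
    activate(withDefault, ctx)
    out <- route(endpointKey(withDefault), "post",
                 list(flag = "whatever", value = 6), ctx)@body$result
    expect_equal(out$value, 7)
})

test_that("branch counts over many random inputs match the predicate split", {
    ctx <- runtimeContext()
    .activateToys(ctx, c("double", "add_one"))
    exec <- makeConditionalExecutive(
        "flag", list(`TRUE` = .toyKey("double"), `FALSE` = .toyKey("add_one")),
        PersistentId("toy", "cond-count", "1.0"))
    activate(exec, ctx)
    set.seed(11)
    flags <- stats::runif(1000) < 0.3
    for (fl in flags)
        route(endpointKey(exec), "post", list(flag = fl, value = 1), ctx)
    counts <- invocationCounts(ctx)
    expect_identical(unname(counts[.toyKey("double")]), as.integer(sum(flags)))
    expect_identical(unname(counts[.toyKey("add_one")]),
                     as.integer(sum(!flags)))
    ## exclusivity: total branch calls equal total requests
    expect_identical(unname(counts[endpointKey(exec)]), length(flags))
})

test_that("hierarchical composition equals the flattened serial chain", {
    ctx <- runtimeContext()
    .activateToys(ctx, c("double", "add_one", "square"))
    inner <- makeSerialExecutive(lapply(c("add_one", "square"), .toyKey),
                                 PersistentId("toy", "inner", "1.0"))
    activate(inner, ctx)
    outer <- makeSerialExecutive(list(.toyKey("double"), endpointKey(inner)),
                                 PersistentId("toy", "outer", "1.0"))
    activate(outer, ctx)
    flat <- makeSerialExecutive(lapply(c("double", "add_one", "square"), .toyKey),
                                PersistentId("toy", "flat", "1.0"))
    activate(flat, ctx)
    for (x in c(-3, 0, 2.5, 10)) {
        expect_identical(
            route(endpointKey(outer), "post", list(value = x), ctx)@body$result,
            route(endpointKey(flat), "post", list(value = x), ctx)@body$result)
    }
    ## deactivating the outer executive leaves its callees active
    deactivate(endpointKey(outer), ctx)
    expect_identical(route(endpointKey(inner), "post", list(value = 1),
                           ctx)@status, "ok")
    expect_identical(route(.toyKey("double"), "post", list(value = 1),
                           ctx)@status, "ok")
})

test_that("a mixed serial/hierarchical/conditional tree matches direct evaluation", {
    ctx <- runtimeContext()
    toys <- c("double", "add_one", "square", "negate")
    .activateToys(ctx, toys)
    inner <- makeSerialExecutive(lapply(c("add_one", "double"), .toyKey),
                                 PersistentId("toy", "mix-inner", "1.0"))
    activate(inner, ctx)
    cond <- makeConditionalExecutive(
        "flag", list(`TRUE` = endpointKey(inner), `FALSE` = .toyKey("negate")),
        PersistentId("toy", "mix-cond", "1.0"))
    activate(cond, ctx)
    top <- makeSerialExecutive(list(endpointKey(cond), .toyKey("square")),
                               PersistentId("toy", "mix-top", "1.0"))
    activate(top, ctx)
    directEval <- function(flag, x) {
        v <- list(value = x, flag = flag)
        v <- if (flag) oracleCompose(lapply(c("add_one", "double"), .toyFun), v)
             else .toyFun("negate")(v)
        .toyFun("square")(v)
    }
    set.seed(5)
    for (i in 1:20) {
        x <- stats::runif(1, -5, 5)
        flag <- stats::runif(1) < 0.5
        got <- route(endpointKey(top), "post", list(value = x, flag = flag),
                     ctx)@body$result
        expect_equal(got$value, directEval(flag, x)$value)
    }
})

test_that("the composition oracle itself behaves as plain nesting", {
    f <- function(x) x + 1
    expect_identical(oracleCompose(list(f), 1), 2)
    expect_identical(oracleCompose(list(), 42), 42)
    expect_identical(oracleCompose(list(f, f, f), 0), 3)
})
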