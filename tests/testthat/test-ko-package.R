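test_that("deployment descriptions parse in the printed dialect", {
    spec <- parseDeploymentDescription(box3DeploymentText())
    expect_s4_class(spec, "DeploymentSpec")
    expect_identical(spec@endpointPath, "/bmi")
    expect_identical(spec@httpMethod, "post")
    expect_identical(spec@engine, "node")
    expect_identical(spec@entry, "bmi.js")
    expect_identical(spec@artifacts, "bmi.js")
    expect_identical(spec@functionName, "bmi")
})

test_that("scalar artifact values normalize to lists; sequences keep order", {
    twoArtifacts <- sub("artifact: bmi.js",
                        "artifact:\n    - bmi.js\n    - tables.js",
                        box3DeploymentText(), fixed = TRUE)
    spec <- parseDeploymentDescription(twoArtifacts)
    expect_identical(spec@artifacts, c("bmi.js", "tables.js"))
})

test_that("missing required deployment fields are schema errors naming the field", {
    noEngine <- sub("    engine: node\n", "", box3DeploymentText(), fixed = TRUE)
    expect_error(parseDeploymentDescription(noEngine), "engine")
    noFn <- sub("    function: bmi", "", box3DeploymentText(), fixed = TRUE)
    expect_error(parseDeploymentDescription(noFn), "function")
    expect_error(parseDeploymentDescription("a: [b,"), "malformed")
    expect_error(parseDeploymentDescription("/a:\n  post: {engine: r, entry: x.R, function: f}\n/b:\n  post: {engine: r, entry: y.R, function: g}"),
                 "one top-level path")
})

test_that("service descriptions parse in the OpenAPI 3.0 dialect", {
    spec <- parseServiceDescription(box4ServiceText())
    expect_identical(spec@serviceVersion, "1.0")
    expect_identical(spec@title, "BMI Calc")
    expect_identical(spec@baseUrl, "/ipp/bmicalculator/1.0")
    expect_identical(spec@paths, "/bmi")
    expect_match(spec@licenseName, "GPL-3")

    twoPaths <- sub("paths:", "paths:\n  /zzz:\n    post: {summary: z}",
                    box4ServiceText(), fixed = TRUE)
    expect_identical(parseServiceDescription(twoPaths)@paths, c("/zzz", "/bmi"))

    expect_error(parseServiceDescription("info:\n  version: '1.0'\npaths:\n  /x: {}"),
                 "servers")
    expect_error(parseServiceDescription(
        "info:\n  version: '1.0'\nservers:\n  - url: /a/1.0\npaths: {}"),
        "paths")
})

test_that("descriptor emission round-trips to identical specs", {
    dep <- parseDeploymentDescription(box3DeploymentText())
    expect_equal(parseDeploymentDescription(formatDeploymentDescription(dep)), dep)
    svc <- parseServiceDescription(box4ServiceText())
    svc2 <- parseServiceDescription(formatServiceDescription(svc))
    expect_identical(svc2@baseUrl, svc@baseUrl)
    expect_identical(svc2@paths, svc@paths)
    expect_identical(svc2@serviceVersion, svc@serviceVersion)
})

test_that("the fixture package loads with payload and function name intact", {
    ko <- loadKnowledgeObject(bmiFixtureDir())
    expect_identical(ko@deployment@functionName, "bmi")
    expect_true("bmi.R" %in% names(koPayload(ko)))
    expect_match(rawToChar(koPayload(ko)$bmi.R), "703")
    expect_identical(formatPersistentId(koId(ko)), "ipp/bmicalculator/1.0")
})

test_that("loading an empty directory names all three missing descriptors", {
    d <- tempfile(); dir.create(d)
    err <- tryCatch(loadKnowledgeObject(d), error = function(e) conditionMessage(e))
    expect_match(err, "metadata.json")
    expect_match(err, "deployment.yaml")
    expect_match(err, "service.yaml")
})

test_that("validation reports the constructed inconsistencies", {
    ko <- toyCalculatorPackage("bmi")
    expect_true(ok(validateKnowledgeObject(ko)))
    expect_identical(nrow(findings(validateKnowledgeObject(ko))), 0L)

    broken <- ko
    names(broken@payload) <- "other.R"
    rep <- validateKnowledgeObject(broken)
    expect_false(ok(rep))
    expect_true("ENTRY_MISSING" %in% findings(rep)$code)

    mismatched <- ko
    mismatched@service@paths <- "/bsa"
    rep <- validateKnowledgeObject(mismatched)
    expect_false(ok(rep))
    expect_true("PATH_MISMATCH" %in% findings(rep)$code)

    odd <- ko
    odd@deployment@engine <- "fortran"
    rep <- validateKnowledgeObject(odd)
    expect_true(ok(rep))   # warnings do not fail validation
    expect_true("ENGINE_UNLISTED" %in% findings(rep)$code)

    ## every finding names a component; ok is exactly absence of errors
    for (r in list(validateKnowledgeObject(broken), validateKnowledgeObject(odd))) {
        expect_true(all(nzchar(findings(r)$component)))
        expect_identical(ok(r), !any(findings(r)$severity == "error"))
    }
})

test_that("writing an invalid package is refused with the report attached", {
    broken <- toyCalculatorPackage("bmi")
    names(broken@payload) <- "other.R"
    err <- tryCatch(writeKnowledgeObject(broken, tempfile()),
                    error = function(e) e)
    expect_s3_class(err, "error")
    expect_s4_class(attr(err, "report"), "ValidationReport")
    expect_false(ok(attr(err, "report")))
})

test_that("write/load round-trips are exact for directories and zip archives", {
    for (seed in c(3L, 11L)) {
        p <- genRandomPackage(seed)
        d <- tempfile()
        writeKnowledgeObject(p, d)
        expect_equal(loadKnowledgeObject(d), p)
        z <- tempfile(fileext = ".zip")
        writeKnowledgeObject(p, z)
        p2 <- loadKnowledgeObject(z)
        expect_equal(p2, p)
        expect_identical(p2@payload, p@payload)   # byte-for-byte
    }
})

test_that("persistent identifiers enforce their shape", {
    expect_error(PersistentId("", "x", "1.0"), "naan")
    expect_error(PersistentId("a", "x", "v1"), "MAJOR.MINOR")
    expect_identical(formatPersistentId(parsePersistentId("ark/model/2.1.3")),
                     "ark/model/2.1.3")
    expect_error(parsePersistentId("no-slashes"), "malformed")
})
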