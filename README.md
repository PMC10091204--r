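# koactivator

Computable biomedical knowledge (CBK) — a risk score, a survival model, a
screening rule — is most useful when it runs as code that other software can
call. `koactivator` is an R implementation of an infrastructure for exactly
that, aimed at knowledge engineers and health-informatics researchers:

* **Knowledge Objects (KOs)** — compound digital objects that bundle a CBK
  model with a persistent unique identifier (`naan/name/version`), descriptive
  metadata, a YAML *deployment description* (engine, entry artifact, function
  name), and an OpenAPI 3.0 *service description*. The package reads, writes,
  and validates KO packages as directories or zip archives.
* **An activator and API gateway** — KOs are *activated* into a runtime via a
  pluggable adapter contract (an in-process R adapter ships with the package),
  registered in a live **runtime context**, and served behind a router that
  answers `POST <base-url><path>` requests and isolates model failures.
  Activated models can call each other through an injected context facility
  without knowing each other's implementation.
* **Composite models** — serial, hierarchical, and conditional compositions
  are expressed by generated *executive submodels*: ordinary KOs whose payload
  encodes the procedural wiring, so composites are inspectable and shippable.
* **A demonstration composite for individualized precision prevention** —
  42 submodels across 11 types (executives, feature derivation, service
  criteria, a life table, life-expectancy and life-gain estimators, net-benefit
  estimators, detection gain, diet risk, mortality risk adjustment, background
  risk) that rank 21 preventive services for a patient by estimated life gain
  in years. All benefit and risk parameters are synthetic placeholders; the
  architecture, not the coefficients, is the point.

The survival arithmetic at the core: given an age-ordered schedule of annual
mortality probabilities *q₁…q_H*, remaining life expectancy is the discrete
survival sum

    LE = Σ_{k=1..H} Π_{j<k} (1 − q_j)

and a preventive service with all-cause hazard ratio *hr* ∈ (0, 1] yields a
life gain of `LE(min(1, q·hr)) − LE(q)` years, computed on a schedule already
adjusted multiplicatively for obesity, alcohol, and tobacco relative risks.

## Worked example

```r
library(koactivator)

## activate the BMI calculator KO and route a request through the gateway
ctx <- runtimeContext()
activate(toyCalculatorPackage("bmi"), ctx)
resp <- route("/ipp/bmicalculator/1.0/bmi", "post",
              list(features = list(height = 73, weight = 220)), ctx)
resp@body$result
#> [1] 29.02233

## build, activate, and run the 42-model demonstration composite
## (a fresh context: the demo shelf includes its own BMI calculator)
shelf <- file.path(tempdir(), "demo-shelf")
buildDemoShelf(shelf, seed = 1)
ctx2 <- runtimeContext()
activateShelf(shelf, ctx2)
out <- runIppComposite(genPatient(1, profile = "eligible_all"), ctx2)
length(out$lifeexpectancy)
#> [1] 21
out$lifeexpectancy$DIA$total
#> $`life-gain`
#> [1] 0.6230249
vapply(out$ranking[1:3], `[[`, "", "code")
#> [1] "SMO" "ALC" "DIET"
```

The first number is the body-mass index for a 73-inch, 220-pound person. The
composite output keys each eligible service to its estimated life gain in
years (`total -> life-gain`); the ranking lists services in descending order
of benefit — for this synthetic heavy-smoking, heavy-drinking patient the
behavioural services dominate (6.27, 2.29, and 1.12 years for smoking
cessation, reduced alcohol use, and diet counseling). The same requests work
over HTTP (`serveGateway(ctx2, 8080)`) or from the shell:

```sh
inst/cli/koactivator validate inst/extdata/bmi-ko
inst/cli/koactivator build-demo /tmp/shelf --seed 1
inst/cli/koactivator run-ipp --patient patient.json --shelf /tmp/shelf
```

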