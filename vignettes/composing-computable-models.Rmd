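---
title: "Packaging, activating, and composing computable biomedical knowledge models"
author: "koactivator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Packaging, activating, and composing computable biomedical knowledge models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koactivator)
```

## The problem

A great deal of biomedical knowledge is computable — body-mass index, a
Cockcroft–Gault creatinine clearance, a logistic disease-risk model, a
life-table life-expectancy estimate — but it usually travels as prose,
spreadsheets, or code fragments welded into one application. This package
implements an infrastructure in which each such model is a **Knowledge
Object (KO)**: a self-describing package that a generic *activator* can turn
into a running web-service-backed function, and which can then be *composed*
with other activated models into larger composite models. The demonstration
composite ranks 21 preventive services for an individual patient by their
estimated life gain in years.

## Knowledge Object anatomy

A KO is a directory (or a zip archive) with three descriptor files and the
executable payload beside them:

* `metadata.json` — the persistent unique identifier (`naan/name/version`),
  title, contributors, KO version, description. Only these plainly needed
  fields are modelled; a full linked-data metadata vocabulary is out of scope
  here, and the JSON field names are the package's own choice since only the
  field *contents* are prescribed by the format's intent.
* `deployment.yaml` — one top-level endpoint path, one HTTP method (POST
  only), and under it the runtime `engine`, the `entry` artifact, the
  `artifact` list (a scalar is normalized to a one-element list), and the
  `function` to instantiate. One endpoint per KO: every worked example of the
  format shows exactly one, and a one-model-one-endpoint rule keeps
  activation, routing, and identity simple. Multi-path documents are rejected
  with a clear error.
* `service.yaml` — an OpenAPI 3.0 document; the activator consumes the first
  `servers` URL (the partial base URL, which by convention ends with the
  service-version segment, e.g. `/ipp/bmicalculator/1.0`), `info.version`,
  and the declared paths. The service version is deliberately distinct from
  the KO version: the API contract and the packaged object evolve
  independently.

`validateKnowledgeObject()` returns findings rather than raising: an
error-severity finding (entry artifact missing from the payload, deployment
path not declared by the service description, malformed PUID or version)
makes the report not-OK, while advisory findings (an engine outside the
allow-list, a base URL that does not end with the version segment) are
warnings. Payload bytes are carried verbatim as raw vectors, and the payload
listing is kept in a canonical sorted order, so write → load round-trips are
byte-identical regardless of filesystem enumeration order. Because no zip
writer is available as an R library dependency, the package writes archives
itself in the store-only (uncompressed) zip format with a table-driven
CRC-32 — about sixty lines — and reads them back with R's internal unzip.

## Activation, the runtime context, and the gateway

`activate()` validates a package, deploys its payload through the
**runtime adapter** registered for its engine, and records a context entry
under the *endpoint key* — the concatenation of the service base URL and the
deployment path (`/ipp/bmicalculator/1.0` + `/bmi`). The join rule is the
package's own convention; the two parts are prescribed but their composition
is not, and concatenation makes the key equal to the reachable URL path.

The **runtime context** is the activator's live registry. It has reference
semantics (state in an environment) because that is what a registry is: every
holder of the context observes activations and deactivations immediately, and
the set of routable paths is by construction exactly the set of active
entries. Activation is atomic — a validation failure raises before anything
is deployed, and an unknown engine or a deploy failure is recorded as a
`failed` entry without touching any active one, so one broken package never
takes down a shelf. Re-activating a live endpoint key is an error unless
`replace = TRUE`: reproducible shelves beat silent mutation. Activation and
routing events are logged with wall-clock timings (`gatewayLog()`); timing is
reported, never asserted, because it is hardware-dependent.

`route(path, method, payload, ctx)` is the API gateway: it resolves the path,
enforces the declared method, invokes the model, and wraps the outcome. Model
exceptions become `model_error` responses naming the model's endpoint key;
the gateway itself never crashes on a payload failure. A payload may signal a
condition of class `ko_bad_input` to have its complaint reported as
`bad_input` (the top-level composite uses this to list missing required
features).

The shipped adapter executes payload R source in an isolated environment
whose parent is the base namespace, and injects the model-to-model context
facility into that environment at each invocation under the well-known name
`kgrid_call`. Injection rather than import keeps payload code engine-
agnostic: the same calling convention could be provided by adapters for other
runtimes, which interact with the activator only through the four-generic
adapter contract (`adapterDeploy` / `adapterInvoke` / `adapterUndeploy` /
`engineName`). Model-to-model calls traverse the same gateway as external
requests — `kgrid_call(ref, payload)` is `resolveAndCall()` — so composition
is transparent: a chain of gateway hops returns exactly what direct nested
function application returns, a property the test suite checks on randomly
generated chains. A call-depth limit of 32 turns accidental reference cycles
into a clean error; the limit is a package decision (composition depth in
practice is single digits; 32 leaves ample headroom while failing fast).

## Composite models

Three composition kinds are expressed through **executive submodels** —
ordinary KOs whose generated payload encodes the wiring:

* *serial*: `makeSerialExecutive()` pipes each model's output through an
  optional field mapping into the next; the mapping defaults to identity
  (the whole record is passed on).
* *hierarchical*: an executive's reference list may include other
  executives; no special casing is needed, and a nested chain equals its
  flattened version.
* *conditional*: `makeConditionalExecutive()` dispatches each request to
  exactly one branch by the value of a predicate field, with an optional
  default; an unmapped value without a default is a model error. Invocation
  counters prove per request that unchosen branches are never engaged.

Executives declare their references in generated code (rather than in
metadata) because the reference list *is* procedural knowledge: the emitted
source is inspectable, shippable, and versionable like any other payload.

## The prevention composite

The demonstration shelf (`buildDemoShelf()`) contains 42 KOs across 11
submodel types: 4 executives, 5 feature-derivation models, 1 service-criteria
model, 1 life table, 1 life-expectancy estimator, 1 life-gain estimator, 15
net-benefit estimators, 1 detection-gain estimator, 2 diet-risk models, 3
mortality-risk adjustments, and 8 background-risk models. The top-level
executive calls 29 submodels directly; three of those are lower-level
executives (feature derivation; mortality schedule; diet risk) which together
call 13 submodels. The life-expectancy estimator is referenced at both levels
— the only wiring in which a 1 + 29 + 13 reference structure spans exactly 42
distinct objects, and a natural one: both the top level (for the inline
services) and the mortality executive need life expectancies. Benefits for
five behavioural services (ALC, DIET, PHY, SMO, WEI) are computed inline by
the top-level executive itself; the choice of which five follows from their
mechanisms, which reuse the mortality-adjustment relative risks the top level
already holds rather than a dedicated estimator submodel.

The data flow per request: derive features (BMI; Mosteller body-surface area
√(height_cm × weight_kg / 3600); cardiac output = stroke volume × heart rate;
Cockcroft–Gault creatinine clearance; a synthetic logistic cardiovascular
score) → evaluate the 21 services' inclusion criteria on the derived record →
slice the patient's (sex, race) stratum from the life table and adjust it
multiplicatively for obesity, alcohol, and tobacco step-function relative
risks, capped at 1 → conditionally dispatch *only the eligible services'*
estimators → rank descending by life gain, ties broken lexicographically by
code (the ranking semantics show no ties to imitate, and a deterministic
tie-break keeps runs reproducible). Output is keyed
`lifeexpectancy → <code> → total → life-gain`, in years.

Mechanisms, all hazard-ratio based because that is the minimal mechanism
consistent with "net benefit as marginal life gain":

* net benefit: `LE(min(1, q·hr)) − LE(q)` on the adjusted schedule; where a
  background-risk model is mapped to the service, the raw gain is scaled by
  `0.25 + 0.75 × risk`, so a person's attainable share of the gain grows with
  their background risk of the targeted condition.
* detection gain: the undiagnosed-probability-weighted net benefit under the
  treated hazard ratio.
* inline behavioural services: remove (or re-evaluate after the behaviour
  change) the corresponding adjustment relative risk and take the
  life-expectancy difference.

Life expectancy is the discrete survival sum `Σ_k Π_{j<k}(1 − q_j)` — whole
years, no half-year correction. This is the simplest convention consistent
with "life expectancy from age-ordered mortality rates"; it is isolated in
one function (`lifeExpectancy()`) and one KO so an actuarial refinement could
be swapped in. Schedules run to the terminal age 100, whose closure rate is
forced to 1. Constant-hazard schedules admit the geometric closed form
`(1−q)(1−(1−q)^H)/q`, which the tests require to 1e-9.

## Synthetic data: what it emulates and what it does not

No real data ships with or is downloaded by the package.

* **Life table** (`genLifeTable()`): a Gompertz stand-in for a national
  all-cause table, `q(a) = min(1, m·A·e^{B·a})` over ages 0–100 with sex and
  race multipliers. Defaults A = 5e-5, B = 0.085 give a remaining life
  expectancy of ≈32 years at age 50 in the unit-multiplier stratum — chosen
  once for plausibility (a 25–35-year band), documented as plausibility, not
  demographic fidelity. Real tables are not log-linear in age at the
  extremes; nothing downstream depends on that.
* **Patients** (`genPatient()`): 112-key records containing the 13 published
  core keys (age … cvd) plus invented, physiologically ranged keys that
  stand in for the unpublished balance of the >100-feature input schema. The
  `eligible_all` profile pins exactly the features the criteria test — a
  55-year-old woman who smokes, drinks, and has uncontrolled diabetes,
  hypertension, and high cholesterol — so that every service's inclusion
  predicate holds at once. Archetype profiles are qualitative presets only.
* **Service catalog** (`inst/extdata/ipp-params.yaml`): 12 of the 21 codes
  are the published letter codes (AAA, ALC, ASA, BP, BRE, CRC, DIA, DIET,
  STA, SMO, WEI, LUN); the remaining 9 (CER, CHL, DEP, HCV, HIV, IMM, OST,
  PHY, VIT) are invented to fill the catalog. Every hazard ratio, criterion
  threshold, and logistic coefficient is a synthetic placeholder: the
  composite's published numeric outputs derive from unpublished cohort-model
  regressions and are therefore *not* reproduction targets here. Passing
  tests consequently demonstrate architectural and computational
  correctness — counts, wiring, exclusivity, gateway transparency, survival
  arithmetic — not clinical validity.

Everything is deterministic per seed, byte for byte, including the generated
payload sources (numeric literals are embedded at 17 significant digits so
values survive the code-generation round-trip bit-exactly).

## Numerical and design notes

* Adjustment relative risks multiply and are capped at 1 after each factor;
  since all factors are ≥ 1, sequential and joint capping agree.
* `hr = 1` gives exactly zero gain (bitwise: `q·1 ≡ q`), and gains are
  nonincreasing in `hr` — both are test invariants.
* Degenerate inputs: an empty schedule, a rate outside [0, 1], or a
  non-positive height are domain errors; a division by zero inside a payload
  surfaces as a `model_error` response, never a gateway crash.
* The test problem sizes — a 42-model shelf, 50 random patients for the
  equivalence and exclusivity suites, 20 round-trip packages, 1000-request
  branch counts — were chosen to exercise every code path while keeping the
  default suite fast on a single CPU.
* The HTTP surface is a minimal single-connection HTTP/1.1 loop over base-R
  sockets, factored so that request parsing and dispatch are pure functions;
  it serves demonstration and testing, not production traffic, and there is
  deliberately no authentication, TLS, statefulness, or cross-runtime
  composition.

## Limitations

The in-process R adapter executes payload code in the host process: isolation
is by namespace, not by sandbox, so activating untrusted KOs is not safe.
Composition is limited to models deployed in the same runtime context.
The benefit mechanisms are deliberately simple hazard-ratio scalings; the
architecture would carry regression- or microsimulation-based estimators
unchanged, but none are included.
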