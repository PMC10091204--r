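## Running the composite against an activated shelf.

#' Run the prevention composite on one patient
#'
#' Posts the patient record to the top-level executive of an activated
#' demonstration shelf and returns its output record: per-service life
#' gains keyed as `lifeexpectancy -> <code> -> total -> life-gain`, the
#' ranked service list, and the baseline life expectancies. Only the
#' net-benefit submodels of services the patient is eligible for are
#' engaged (verifiable from [invocationCounts()]).
#'
#' @param patient a patient record: `list(patient = list(id, features))`
#'   or just `list(id, features)`.
#' @param ctx a [RuntimeContext-class] with the demo shelf activated
#'   (see [buildDemoShelf()] and [activateShelf()]).
#' @return the composite's output record.
#' @examples
#' \donttest{
#' shelf <- file.path(tempdir(), "demo-shelf")
#' buildDemoShelf(shelf, seed = 1)
#' ctx <- runtimeContext()
#' activateShelf(shelf, ctx)
#' out <- runIppComposite(genPatient(1, profile = "eligible_all"), ctx)
#' names(out$lifeexpectancy)
#' }
#' @export
runIppComposite <- function(patient, ctx) {
    if (!is.null(patient$patient)) patient <- patient$patient
    resp <- route(.ippEndpoints()$top, "post", list(patient = patient), ctx)
    if (resp@status != "ok") {
        cond <- simpleError(paste0("composite run failed (", resp@status, "): ",
                                   if (!is.null(resp@body$error)) resp@body$error
                                   else ""))
        attr(cond, "response") <- resp
        stop(cond)
    }
    resp@body$result
}
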