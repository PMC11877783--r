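#' Paths of the packaged ten-patient cohort manifests
#'
#' The package ships a synthetic ten-patient fixture transcribing the
#' mutation-sharing relations of a longitudinal GBM cohort: every
#' patient carries a TERT-promoter trunk variant shared by SVZ, primary
#' and recurrent tumor; two patients additionally carry inter-tumor
#' shared variants absent from the SVZ; six carry primary-private
#' variants extinct in the recurrence alongside recurrent-private
#' variants; and two have their deciding non-trunk calls blocked by
#' shallow coverage. Read counts are synthetic, drawn at panel-like
#' depths around 1000x; see `inst/extdata/cohort/README.txt`.
#'
#' @return named character vector of manifest file paths, one per
#'   patient.
#' @export
cohortManifests <- function() {
  dir <- system.file("extdata", "cohort", package = "clonalProvenance")
  files <- sort(list.files(dir, pattern = "\\.manifest$",
                           full.names = TRUE))
  stats::setNames(files, sub("\\.manifest$", "", basename(files)))
}

#' Load the packaged ten-patient cohort fixture
#'
#' @return named list (by patient id); each element holds `manifest`
#'   (a [PatientManifest-class]) and `variants` (the variant table).
#' @seealso [cohortManifests()]
#' @export
cohortFixture <- function() {
  lapply(cohortManifests(), function(mf) {
    manifest <- readPatientManifest(mf)
    list(manifest = manifest,
         variants = readVariantTable(manifest@samples$file[1]))
  })
}
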