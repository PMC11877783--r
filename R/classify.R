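#' Classify the recurrence pattern of one patient
#'
#' Rule-based provenance call for a patient with matched SVZ, primary and
#' recurrent samples, applied in fixed order:
#'
#' 1. If no SVZ-Tumor-shared variant is PRESENT in all three tissues,
#'    the lineage cannot be anchored: UNKNOWN.
#' 2. Otherwise, any Inter-Tumor-shared variant (both tumors, not the
#'    SVZ) directly links the tumors: PRIMARY_ASSOCIATED.
#' 3. Otherwise, if at least one Primary-private variant is confidently
#'    ABSENT (not merely INDETERMINATE) in the recurrent tumor — the
#'    dominant primary clone went extinct — the recurrence descends from
#'    the SVZ-linked early progenitor: SVZ_ASSOCIATED.
#' 4. Otherwise UNKNOWN.
#'
#' Inter-tumor evidence outranks extinction evidence because a shared
#' mutation ties the tumors together regardless of what else was lost.
#' UNRESOLVED variants never contribute evidence, so thin coverage
#' degrades to UNKNOWN rather than misclassifying.
#'
#' @param categories data.frame from [categorizePatient()].
#' @param calls the matching [PresenceCalls-class].
#' @param patientId identifier recorded in the result.
#' @param strictTrunkGene optional gene name (e.g. `"TERT"`); when set,
#'   only trunk variants in that gene count as rule-1 anchoring evidence.
#' @return a [RecurrenceCall-class] with the label and the variant keys
#'   firing each rule.
#' @export
classifyRecurrencePattern <- function(categories, calls,
                                      patientId = "patient",
                                      strictTrunkGene = NULL) {
  st <- calls@states
  if (!"RECURRENT" %in% colnames(st) ||
      all(is.na(st[!calls@germline, "RECURRENT"])))
    stopf("patient %s has no recurrent sample: recurrence pattern %s",
          patientId, "is only defined after recurrence")

  somatic <- st[!calls@germline, , drop = FALSE]
  key <- rownames(somatic)
  cats <- stats::setNames(categories$category, categories$variant)[key]
  genes <- stats::setNames(categories$gene, categories$variant)[key]

  allThree <- somatic[, "SVZ"] == "PRESENT" &
    somatic[, "PRIMARY"] == "PRESENT" & somatic[, "RECURRENT"] == "PRESENT"
  trunk <- key[cats == "SVZ_TUMOR_SHARED" & allThree]
  if (!is.null(strictTrunkGene))
    trunk <- trunk[genes[trunk] %in% strictTrunkGene]
  interTumor <- key[cats == "INTER_TUMOR_SHARED"]
  ## PRIMARY_PRIVATE already certifies recurrent ABSENT (an INDETERMINATE
  ## recurrent call makes the variant UNRESOLVED instead)
  extinct <- key[cats == "PRIMARY_PRIVATE" &
                 somatic[, "RECURRENT"] == "ABSENT"]

  label <- if (length(trunk) == 0L) "UNKNOWN"
    else if (length(interTumor) > 0L) "PRIMARY_ASSOCIATED"
    else if (length(extinct) > 0L) "SVZ_ASSOCIATED"
    else "UNKNOWN"

  new("RecurrenceCall", patientId = patientId, label = label,
      rationale = list(trunk = unname(trunk),
                       interTumor = unname(interTumor),
                       extinct = unname(extinct)))
}

#' Summarize recurrence patterns across a cohort
#'
#' Counts and one-decimal percentages per label, in the fixed order
#' SVZ_ASSOCIATED, PRIMARY_ASSOCIATED, UNKNOWN (other labels, e.g. marker
#' classes from lineage-tracing experiments, follow alphabetically).
#' Percentages are displayed to one decimal through an intermediate
#' two-decimal half-up rounding, the convention of spreadsheet-derived
#' clinical reports, so 7/13 prints as 53.9.
#'
#' @param results list of [RecurrenceCall-class] objects, or a character
#'   vector of labels.
#' @return list with `summary` (data.frame `pattern`, `n`, `percent`)
#'   and `patients` (per-patient label table; `NULL` for bare labels).
#' @examples
#' summarizeCohort(rep(c("GFP", "tdTomato", "Mix"), c(7, 4, 2)))$summary
#' @export
summarizeCohort <- function(results) {
  if (length(results) == 0L) stopf("empty cohort")
  if (is.character(results)) {
    labels <- results
    patients <- NULL
  } else {
    labels <- vapply(results, patternLabel, "")
    patients <- data.frame(
      patient = vapply(results, patientId, ""),
      pattern = labels, stringsAsFactors = FALSE)
  }
  lev <- c(intersect(RECURRENCE_PATTERNS, labels),
           sort(setdiff(unique(labels), RECURRENCE_PATTERNS)))
  tab <- table(factor(labels, levels = lev))
  summary <- data.frame(pattern = names(tab), n = as.integer(tab),
                        percent = roundPercent(100 * as.integer(tab) /
                                               length(labels)),
                        stringsAsFactors = FALSE)
  list(summary = summary, patients = patients)
}

#' Write a per-patient recurrence report
#'
#' Flat JSON with the patient id, label, and the variant keys behind each
#' rule firing.
#'
#' @param call a [RecurrenceCall-class].
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
writeRecurrenceReport <- function(call, path) {
  jsonlite::write_json(
    list(patient_id = call@patientId, pattern = call@label,
         trunk_evidence = call@rationale$trunk,
         inter_tumor_evidence = call@rationale$interTumor,
         extinct_primary_private = call@rationale$extinct),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
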