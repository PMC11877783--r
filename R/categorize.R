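#' Categorize one somatic variant from its presence triple
#'
#' Maps the per-tissue presence states onto the five-way sharing
#' taxonomy: SVZ_TUMOR_SHARED (SVZ plus at least one tumor),
#' INTER_TUMOR_SHARED (both tumors, not the SVZ), PRIMARY_PRIVATE,
#' RECURRENT_PRIVATE, SVZ_PRIVATE. Whenever an INDETERMINATE call sits in
#' a tissue the category hinges on, UNRESOLVED is returned instead of
#' guessing; a variant PRESENT in the SVZ and at least one tumor is
#' SVZ_TUMOR_SHARED regardless of the remaining tumor. A variant ABSENT
#' everywhere should not have been called and is an error.
#'
#' @param svz,primary,recurrent presence states
#'   (`"PRESENT"`/`"ABSENT"`/`"INDETERMINATE"`); `recurrent` may be `NA`
#'   for patients without a recurrence sample.
#' @return category string; see [MutationCategory levels][categorizePatient].
#' @examples
#' categorizeVariant("PRESENT", "PRESENT", "PRESENT")  # SVZ_TUMOR_SHARED
#' categorizeVariant("ABSENT", "PRESENT", "ABSENT")    # PRIMARY_PRIVATE
#' @export
categorizeVariant <- function(svz, primary, recurrent = NA_character_) {
  chk <- function(x, what) {
    if (!is.na(x) && !x %in% PRESENCE_STATES)
      stopf("invalid %s state '%s'", what, x)
    x
  }
  s <- chk(svz, "SVZ"); p <- chk(primary, "primary")
  r <- chk(recurrent, "recurrent")
  hasRec <- !is.na(r)

  P <- function(x) !is.na(x) && x == "PRESENT"
  A <- function(x) !is.na(x) && x == "ABSENT"
  I <- function(x) !is.na(x) && x == "INDETERMINATE"

  tumorPresent <- P(p) || P(r)
  if (P(s) && tumorPresent) return("SVZ_TUMOR_SHARED")

  if (A(s) && A(p) && (!hasRec || A(r)))
    stopf("variant ABSENT in every tissue: no somatic call to categorize")

  ## any indeterminate tissue now blocks the remaining categories
  if (I(s) || I(p) || (hasRec && I(r))) return("UNRESOLVED")

  if (P(s)) return("SVZ_PRIVATE")            # s PRESENT, tumors ABSENT
  if (P(p) && hasRec && P(r)) return("INTER_TUMOR_SHARED")
  if (P(p)) return("PRIMARY_PRIVATE")
  "RECURRENT_PRIVATE"                        # s,p ABSENT; r PRESENT
}

#' Categorize every somatic variant of a patient
#'
#' Applies [categorizeVariant()] to each non-germline row of a presence
#' matrix. Identity is allele-level, so two different mutations in one
#' gene are categorized (and counted) separately. For SVZ_TUMOR_SHARED
#' variants a `subtype` records which tumors share the variant
#' (`both`/`primary`/`recurrent`/`uncertain`).
#'
#' @param calls a [PresenceCalls-class] from [callPatient()].
#' @return data.frame with columns `variant`, `gene`, `category`,
#'   `subtype`; germline-flagged variants are omitted.
#' @export
categorizePatient <- function(calls) {
  st <- calls@states
  keep <- !calls@germline
  st <- st[keep, , drop = FALSE]
  genes <- calls@variants$gene[keep]
  hasRec <- "RECURRENT" %in% colnames(st)
  n <- nrow(st)
  category <- character(n); subtype <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- if (hasRec) st[i, "RECURRENT"] else NA_character_
    category[i] <- categorizeVariant(st[i, "SVZ"], st[i, "PRIMARY"], r)
    if (category[i] == "SVZ_TUMOR_SHARED") {
      pP <- st[i, "PRIMARY"] == "PRESENT"
      rP <- hasRec && st[i, "RECURRENT"] == "PRESENT"
      pI <- st[i, "PRIMARY"] == "INDETERMINATE"
      rI <- hasRec && st[i, "RECURRENT"] == "INDETERMINATE"
      subtype[i] <-
        if (pP && rP) "both"
        else if (pI || rI) "uncertain"
        else if (pP) "primary" else "recurrent"
    }
  }
  data.frame(variant = rownames(st), gene = genes, category = category,
             subtype = subtype, row.names = NULL, stringsAsFactors = FALSE)
}

#' Export an oncoplot-style category matrix
#'
#' Rows are `gene (variant)` labels, one column per patient, cells hold
#' the category token (empty when the patient lacks the variant), ready
#' for external plotting.
#'
#' @param categoryTables named list (by patient id) of
#'   [categorizePatient()] outputs.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
writeOncoplotMatrix <- function(categoryTables, path) {
  allRows <- unique(unlist(lapply(categoryTables, function(tb)
    paste0(tb$gene, " (", tb$variant, ")"))))
  out <- data.frame(variant = allRows, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (pid in names(categoryTables)) {
    tb <- categoryTables[[pid]]
    lab <- paste0(tb$gene, " (", tb$variant, ")")
    out[[pid]] <- tb$category[match(allRows, lab)]
    out[[pid]][is.na(out[[pid]])] <- ""
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
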