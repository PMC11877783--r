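#' @import methods
NULL

## tissue roles used throughout; BLOOD is the germline control and never
## enters the somatic presence matrix
TISSUE_ROLES <- c("BLOOD", "SVZ", "PRIMARY", "RECURRENT")
SOMATIC_ROLES <- c("SVZ", "PRIMARY", "RECURRENT")

PRESENCE_STATES <- c("PRESENT", "ABSENT", "INDETERMINATE")

MUTATION_CATEGORIES <- c("SVZ_TUMOR_SHARED", "INTER_TUMOR_SHARED",
                         "PRIMARY_PRIVATE", "RECURRENT_PRIVATE",
                         "SVZ_PRIVATE", "UNRESOLVED")

RECURRENCE_PATTERNS <- c("SVZ_ASSOCIATED", "PRIMARY_ASSOCIATED", "UNKNOWN")

GERMLINE_ROOT <- "GERMLINE"

#' Parameters for depth-aware presence calling
#'
#' Bundles the thresholds that turn per-sample read counts into
#' PRESENT/ABSENT/INDETERMINATE calls. A site is PRESENT when it has at
#' least `minAltReads` alternate reads and the one-sided binomial tail
#' probability of seeing that many alt reads from sequencing error alone
#' is at most `alpha`. A site may be declared ABSENT only when the depth
#' gives at least `powerFloor` probability of detecting a true variant at
#' allele fraction `vafDetect`; otherwise the call is INDETERMINATE.
#'
#' @slot minAltReads integer, minimum alternate reads for a PRESENT call.
#' @slot alpha numeric, significance level of the error-model tail test.
#' @slot errorRate numeric, assumed per-base miscall fraction.
#' @slot vafDetect numeric, allele fraction the study must be able to
#'   exclude before an ABSENT call is allowed.
#' @slot powerFloor numeric, required detection power at `vafDetect` for
#'   an ABSENT call.
#' @export
setClass("PresenceParams",
  representation(minAltReads = "integer", alpha = "numeric",
                 errorRate = "numeric", vafDetect = "numeric",
                 powerFloor = "numeric"),
  prototype(minAltReads = 3L, alpha = 1e-3, errorRate = 1e-3,
            vafDetect = 0.02, powerFloor = 0.9))

setValidity("PresenceParams", function(object) {
  msg <- character()
  if (length(object@minAltReads) != 1L || is.na(object@minAltReads) ||
      object@minAltReads < 1L)
    msg <- c(msg, "minAltReads must be a single integer >= 1")
  for (s in c("alpha", "errorRate", "vafDetect", "powerFloor")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0, 1]", s))
  }
  if (length(msg) == 0L && object@vafDetect <= object@errorRate)
    msg <- c(msg, "vafDetect must exceed errorRate")
  if (length(msg)) msg else TRUE
})

#' Patient manifest mapping sample names to tissue roles
#'
#' @slot patientId character, patient identifier.
#' @slot samples data.frame with columns `name`, `role`
#'   (BLOOD/SVZ/PRIMARY/RECURRENT) and `file` (path of the variant table,
#'   possibly `NA`).
#' @export
setClass("PatientManifest",
  representation(patientId = "character", samples = "data.frame"))

setValidity("PatientManifest", function(object) {
  s <- object@samples
  msg <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId) ||
      !nzchar(object@patientId))
    msg <- c(msg, "patientId must be a non-empty string")
  if (!all(c("name", "role", "file") %in% names(s)))
    msg <- c(msg, "samples needs columns name, role, file")
  else {
    if (!all(s$role %in% TISSUE_ROLES))
      msg <- c(msg, "roles must be BLOOD/SVZ/PRIMARY/RECURRENT")
    if (anyDuplicated(s$role))
      msg <- c(msg, "roles must be unique")
    if (anyDuplicated(s$name))
      msg <- c(msg, "sample names must be unique")
    for (r in c("BLOOD", "SVZ", "PRIMARY"))
      if (sum(s$role == r) != 1L)
        msg <- c(msg, sprintf("exactly one %s sample required", r))
    if (sum(s$role == "RECURRENT") > 1L)
      msg <- c(msg, "at most one RECURRENT sample allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth clonal phylogeny
#'
#' A rooted tree of clones plus the assignment of mutations to the branch
#' on which they arose. The germline root is the implicit parent marker
#' `"GERMLINE"` and carries no somatic mutations.
#'
#' @slot parent named character; `parent[clone]` is the parent clone id,
#'   or `"GERMLINE"` for clones descending directly from the root.
#' @slot mutationClone named character; `mutationClone[mutation_id]` is
#'   the clone whose founding branch acquired the mutation.
#' @export
setClass("ClonalTree",
  representation(parent = "character", mutationClone = "character"))

setValidity("ClonalTree", function(object) {
  msg <- character()
  clones <- names(object@parent)
  if (is.null(clones) || anyDuplicated(clones))
    msg <- c(msg, "parent must be named by unique clone ids")
  if (GERMLINE_ROOT %in% clones)
    msg <- c(msg, "the germline root is implicit and cannot be a clone")
  bad <- setdiff(object@parent, c(clones, GERMLINE_ROOT))
  if (length(bad))
    msg <- c(msg, paste("unknown parent clone(s):", paste(bad, collapse = ", ")))
  if (length(msg) == 0L && length(clones)) {
    ## rootedness/acyclicity: every clone must reach GERMLINE
    for (cl in clones) {
      seen <- character(); cur <- cl
      while (cur != GERMLINE_ROOT) {
        if (cur %in% seen) return(sprintf("cycle involving clone '%s'", cl))
        seen <- c(seen, cur)
        cur <- object@parent[[cur]]
      }
    }
    if (!all(object@mutationClone %in% clones))
      msg <- c(msg, "mutationClone refers to unknown clones")
    if (anyDuplicated(names(object@mutationClone)))
      msg <- c(msg, "mutation ids must be unique across clones")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a simulated four-sample patient
#'
#' Describes a branched clonal phylogeny, a mutation catalog, the matched
#' samples with their purities and clone compositions, and the read-count
#' noise model. [simulatePatient()] turns it into a variant table with
#' ground-truth labels.
#'
#' @slot tree a [ClonalTree-class] giving clone ancestry and the clone on
#'   which each catalog mutation arose.
#' @slot catalog data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `driver`.
#' @slot samples data.frame with columns `name`, `role`, `purity`,
#'   `meanDepth`.
#' @slot cloneFractions named list; for each sample name, a named numeric
#'   vector of per-clone fractions of the mutant lineage (summing to 1).
#' @slot errorRate numeric, per-base miscall fraction in [0, 0.01].
#' @slot noiseless logical; if TRUE, depths are exact and alt counts are
#'   rounded expectations (no sampling).
#' @slot fixedDepth logical; if TRUE, total depth equals `meanDepth`
#'   exactly instead of being Poisson-dispersed.
#' @slot seed integer seed; all randomness is local to this spec.
#' @export
setClass("SimulationSpec",
  representation(tree = "ClonalTree", catalog = "data.frame",
                 samples = "data.frame", cloneFractions = "list",
                 errorRate = "numeric", noiseless = "logical",
                 fixedDepth = "logical", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  cat_cols <- c("id", "chrom", "pos", "ref", "alt", "gene", "driver")
  if (!all(cat_cols %in% names(object@catalog)))
    msg <- c(msg, paste("catalog needs columns", paste(cat_cols, collapse = ", ")))
  smp_cols <- c("name", "role", "purity", "meanDepth")
  if (!all(smp_cols %in% names(object@samples)))
    msg <- c(msg, paste("samples needs columns", paste(smp_cols, collapse = ", ")))
  if (length(object@errorRate) != 1L || object@errorRate < 0 ||
      object@errorRate > 0.01)
    msg <- c(msg, "errorRate must lie in [0, 0.01]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) return(msg)

  if (!all(object@catalog$id %in% names(object@tree@mutationClone)))
    msg <- c(msg, "every catalog mutation must be placed on a clone")
  if (!all(names(object@tree@mutationClone) %in% object@catalog$id))
    msg <- c(msg, "every placed mutation must exist in the catalog")
  s <- object@samples
  if (!all(s$role %in% TISSUE_ROLES)) msg <- c(msg, "bad sample role")
  if (any(s$purity < 0 | s$purity > 1)) msg <- c(msg, "purity outside [0, 1]")
  if (any(s$purity[s$role == "BLOOD"] != 0))
    msg <- c(msg, "BLOOD purity must be 0")
  clones <- names(object@tree@parent)
  for (nm in s$name) {
    cf <- object@cloneFractions[[nm]]
    if (is.null(cf)) { msg <- c(msg, paste("no clone fractions for", nm)); next }
    if (!all(names(cf) %in% clones))
      msg <- c(msg, paste("unknown clone in fractions of", nm))
    if (any(cf < 0)) msg <- c(msg, paste("negative clone fraction in", nm))
    if (abs(sum(cf) - 1) > 1e-9)
      msg <- c(msg, paste("clone fractions of", nm, "must sum to 1"))
  }
  if (length(msg)) msg else TRUE
})

#' Simulated patient dataset with ground truth
#'
#' @slot patientId character.
#' @slot variants data.frame in the variant-table layout (`chrom`, `pos`,
#'   `ref`, `alt`, `gene`, then `<sample>.depth`/`<sample>.alt` pairs).
#' @slot manifest a [PatientManifest-class].
#' @slot truth list with elements `categories` (named by variant key),
#'   `pattern` (recurrence-pattern label), `presence` (logical truth
#'   presence matrix, variants x roles) and `expectedVAF` (numeric matrix
#'   variants x samples).
#' @slot tree the generating [ClonalTree-class].
#' @export
setClass("PatientDataset",
  representation(patientId = "character", variants = "data.frame",
                 manifest = "PatientManifest", truth = "list",
                 tree = "ClonalTree"))

#' Per-tissue presence calls for one patient
#'
#' Variant-by-tissue matrix of PRESENT/ABSENT/INDETERMINATE states with
#' the supporting VAF estimates and error-model p-values. Variants judged
#' PRESENT in blood are flagged germline and carry `NA` states; they are
#' excluded from all somatic analysis.
#'
#' @slot states character matrix, variants x roles (SVZ/PRIMARY/RECURRENT).
#' @slot vaf numeric matrix of observed alt/depth, same shape.
#' @slot pValues numeric matrix of one-sided error-model tail
#'   probabilities, same shape.
#' @slot germline named logical, TRUE where the variant is PRESENT in blood.
#' @slot variants data.frame of variant metadata (chrom, pos, ref, alt, gene).
#' @slot params the [PresenceParams-class] used.
#' @export
setClass("PresenceCalls",
  representation(states = "matrix", vaf = "matrix", pValues = "matrix",
                 germline = "logical", variants = "data.frame",
                 params = "PresenceParams"))

setValidity("PresenceCalls", function(object) {
  st <- object@states
  ok <- st[!is.na(st)] %in% PRESENCE_STATES
  if (!all(ok)) return("states must be PRESENT/ABSENT/INDETERMINATE")
  if (!identical(dim(st), dim(object@vaf)) ||
      !identical(dim(st), dim(object@pValues)))
    return("states, vaf and pValues must have identical shape")
  if (length(object@germline) != nrow(st))
    return("one germline flag per variant required")
  TRUE
})

#' Reconstructed lineage tree over variant clusters
#'
#' Nodes are VAF/presence clusters of variants plus the implicit germline
#' root; edges point parent to child and satisfy the containment
#' condition within the clustering tolerance. Sum-rule violations are
#' reported in `violations`, never repaired silently.
#'
#' @slot clusters named list; each element has `key`, `members` (variant
#'   keys), `vaf` (named mean VAF per role) and `profile` (named presence
#'   state per role).
#' @slot edges data.frame with columns `parent`, `child` (cluster keys;
#'   the root is `"GERMLINE"`).
#' @slot violations data.frame reporting containment/sum-rule breaches
#'   (columns `parent`, `sample`, `parentVAF`, `childSum`).
#' @slot tol numeric clustering/containment tolerance on the VAF scale.
#' @export
setClass("LineageTree",
  representation(clusters = "list", edges = "data.frame",
                 violations = "data.frame", tol = "numeric"))

setValidity("LineageTree", function(object) {
  e <- object@edges
  if (!all(c("parent", "child") %in% names(e)))
    return("edges needs parent and child columns")
  keys <- names(object@clusters)
  if (length(keys) && (anyDuplicated(e$child) ||
      !setequal(e$child, keys)))
    return("every cluster must have exactly one parent")
  TRUE
})

#' Patient-level recurrence-pattern call
#'
#' @slot patientId character.
#' @slot label one of SVZ_ASSOCIATED, PRIMARY_ASSOCIATED, UNKNOWN.
#' @slot rationale list of rule firings: `trunk`, `interTumor` and
#'   `extinct` each hold the variant keys supporting that clause.
#' @export
setClass("RecurrenceCall",
  representation(patientId = "character", label = "character",
                 rationale = "list"))

setValidity("RecurrenceCall", function(object) {
  if (length(object@label) != 1L || !object@label %in% RECURRENCE_PATTERNS)
    return("label must be one of SVZ_ASSOCIATED/PRIMARY_ASSOCIATED/UNKNOWN")
  TRUE
})
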