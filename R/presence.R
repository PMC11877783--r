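#' Construct presence-calling parameters
#'
#' Defaults suit deep hybrid-capture panels (~1000x): at least 3 alt
#' reads and an error-model tail probability below 1e-3 for PRESENT, and
#' at least 90% power to detect a 2% VAF variant before ABSENT may be
#' declared.
#'
#' @param minAltReads minimum alt reads for PRESENT.
#' @param alpha significance level of the binomial error-model test.
#' @param errorRate assumed per-base miscall fraction.
#' @param vafDetect allele fraction an ABSENT call must be able to exclude.
#' @param powerFloor required detection power at `vafDetect`.
#' @return a [PresenceParams-class].
#' @export
PresenceParams <- function(minAltReads = 3L, alpha = 1e-3,
                           errorRate = 1e-3, vafDetect = 0.02,
                           powerFloor = 0.9) {
  new("PresenceParams", minAltReads = as.integer(minAltReads),
      alpha = alpha, errorRate = errorRate, vafDetect = vafDetect,
      powerFloor = powerFloor)
}

## smallest alt count that satisfies both PRESENT criteria at a depth:
## k >= minAltReads and P(X >= k | n, errorRate) <= alpha
presentThreshold <- function(depth, params) {
  vapply(depth, function(n) {
    k <- stats::qbinom(params@alpha, n, params@errorRate,
                       lower.tail = FALSE) + 1L
    while (k > 1L &&
           stats::pbinom(k - 2L, n, params@errorRate,
                         lower.tail = FALSE) <= params@alpha)
      k <- k - 1L
    max(k, params@minAltReads)
  }, numeric(1))
}

#' Detection power at a given depth and allele fraction
#'
#' Probability that a true variant at allele fraction `vaf` sequenced to
#' `totalDepth` reads yields a PRESENT call: the upper binomial tail
#' `P(X >= k*)` under `Binomial(totalDepth, vaf)`, where `k*` is the
#' smallest alt count meeting the PRESENT criteria. Non-decreasing in
#' both depth and VAF; ABSENT calls require this to reach the power
#' floor at `params@vafDetect`.
#'
#' @param totalDepth read depth(s).
#' @param vaf true allele fraction(s) in (0, 0.5].
#' @param params a [PresenceParams-class].
#' @return numeric vector of detection probabilities.
#' @export
detectionPower <- function(totalDepth, vaf, params = PresenceParams()) {
  if (any(vaf <= 0) || any(vaf > 0.5)) stopf("vaf must lie in (0, 0.5]")
  n <- max(length(totalDepth), length(vaf))
  totalDepth <- rep_len(totalDepth, n); vaf <- rep_len(vaf, n)
  kstar <- presentThreshold(totalDepth, params)
  stats::pbinom(kstar - 1, totalDepth, vaf, lower.tail = FALSE)
}

#' Call variant presence in one tissue
#'
#' Three-state, detection-limit-aware call. PRESENT requires
#' `altCount >= minAltReads` and an error-only tail probability at most
#' `alpha`; failing that, ABSENT is returned only when the depth powers
#' detection of a `vafDetect` variant at `powerFloor`, and otherwise the
#' evidence is INDETERMINATE. The three states are exclusive and
#' exhaustive, and the call is monotone in the alt count.
#'
#' @param altCount alternate-read count(s).
#' @param totalDepth total depth(s), >= 1.
#' @param params a [PresenceParams-class].
#' @return data.frame with columns `state`, `vaf` (observed alt/depth)
#'   and `p.value` (error-model tail probability), one row per input.
#' @examples
#' callPresence(250, 1000)  # PRESENT
#' callPresence(0, 1000)    # ABSENT: power to exclude VAF 0.02 is ample
#' callPresence(1, 30)      # INDETERMINATE: too shallow to claim absence
#' @export
callPresence <- function(altCount, totalDepth, params = PresenceParams()) {
  n <- max(length(altCount), length(totalDepth))
  altCount <- rep_len(altCount, n); totalDepth <- rep_len(totalDepth, n)
  if (any(totalDepth < 1)) stopf("totalDepth must be >= 1")
  if (any(altCount < 0) || any(altCount > totalDepth))
    stopf("altCount must lie in [0, totalDepth]")
  p <- stats::pbinom(altCount - 1, totalDepth, params@errorRate,
                     lower.tail = FALSE)
  present <- altCount >= params@minAltReads & p <= params@alpha
  powered <- detectionPower(totalDepth, params@vafDetect, params) >=
    params@powerFloor
  state <- ifelse(present, "PRESENT",
                  ifelse(powered, "ABSENT", "INDETERMINATE"))
  data.frame(state = state, vaf = altCount / totalDepth, p.value = p,
             stringsAsFactors = FALSE)
}

#' Call presence for every variant and tissue of a patient
#'
#' Applies [callPresence()] to each non-blood sample of the patient.
#' Variants PRESENT in the blood sample are flagged germline: their
#' somatic states are set to `NA` and they are excluded from all
#' downstream categorization and classification.
#'
#' @param variants variant table data.frame ([readVariantTable()] layout).
#' @param manifest a [PatientManifest-class] resolving sample names to
#'   tissue roles; every manifest sample must have columns in `variants`.
#' @param params a [PresenceParams-class].
#' @return a [PresenceCalls-class].
#' @export
callPatient <- function(variants, manifest, params = PresenceParams()) {
  validObject(manifest)
  smp <- manifest@samples
  have <- variantTableSamples(variants)
  miss <- setdiff(smp$name, have)
  if (length(miss))
    stopf("variant table lacks counts for sample(s): %s",
          paste(miss, collapse = ", "))
  key <- variantKey(variants)
  nv <- nrow(variants)
  roles <- intersect(SOMATIC_ROLES, smp$role)
  states <- matrix(NA_character_, nv, length(roles),
                   dimnames = list(key, roles))
  vaf <- pv <- matrix(NA_real_, nv, length(roles),
                      dimnames = list(key, roles))

  germline <- stats::setNames(rep(FALSE, nv), key)
  bloodName <- roleSample(manifest, "BLOOD")
  if (nv > 0) {
    b <- callPresence(variants[[altCol(bloodName)]],
                      variants[[depthCol(bloodName)]], params)
    germline[] <- b$state == "PRESENT"
    for (rl in roles) {
      nm <- roleSample(manifest, rl)
      cl <- callPresence(variants[[altCol(nm)]],
                         variants[[depthCol(nm)]], params)
      states[, rl] <- cl$state
      vaf[, rl] <- cl$vaf
      pv[, rl] <- cl$p.value
    }
    states[germline, ] <- NA_character_
  }
  new("PresenceCalls", states = states, vaf = vaf, pValues = pv,
      germline = germline,
      variants = variants[, c("chrom", "pos", "ref", "alt", "gene")],
      params = params)
}

#' Export a presence matrix as TSV
#'
#' One row per somatic variant, one column per tissue role with
#' PRESENT/ABSENT/INDETERMINATE tokens; germline-flagged variants are
#' written with the token GERMLINE in every tissue column.
#'
#' @param calls a [PresenceCalls-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writePresenceMatrix <- function(calls, path) {
  st <- calls@states
  out <- data.frame(variant = rownames(st), calls@variants["gene"],
                    st, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in colnames(st)) out[[j]][calls@germline] <- "GERMLINE"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
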