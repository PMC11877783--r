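#' Construct a clonal tree
#'
#' @param parent named character vector mapping each clone id to its
#'   parent clone, with `"GERMLINE"` marking children of the root.
#' @param mutations named list mapping clone ids to the mutation ids
#'   acquired on the branch into that clone.
#' @return a [ClonalTree-class].
#' @examples
#' ClonalTree(c(trunk = "GERMLINE", branch = "trunk"),
#'            list(trunk = c("m1", "m2"), branch = "m3"))
#' @export
ClonalTree <- function(parent, mutations = list()) {
  mut <- character(0)
  for (cl in names(mutations)) {
    ids <- mutations[[cl]]
    mut <- c(mut, stats::setNames(rep(cl, length(ids)), ids))
  }
  new("ClonalTree", parent = parent, mutationClone = mut)
}

## clones in the subtree rooted at `clone` (inclusive)
cloneSubtree <- function(tree, clone) {
  clones <- names(tree@parent)
  out <- clone
  repeat {
    kids <- clones[tree@parent %in% out & !clones %in% out]
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

## cancer-cell fraction of each mutation in one sample: summed fractions
## of the carrying clone's subtree
mutationCCF <- function(tree, cloneFractions) {
  clones <- names(tree@parent)
  ccfByClone <- vapply(clones, function(cl) {
    sum(cloneFractions[intersect(cloneSubtree(tree, cl),
                                 names(cloneFractions))])
  }, numeric(1))
  stats::setNames(ccfByClone[tree@mutationClone], names(tree@mutationClone))
}

#' Convert cancer-cell fraction to expected variant allele fraction
#'
#' Assumes a copy-number-neutral, heterozygous somatic variant in a
#' diploid genome, so the expected VAF is `0.5 * purity * ccf`.
#'
#' @param ccf cancer-cell fraction in \[0, 1\].
#' @param purity fraction of cells in the specimen belonging to the
#'   mutant lineage, in \[0, 1\].
#' @return numeric expected VAF in \[0, 0.5\].
#' @examples
#' ccfToVaf(1, 1)      # clonal variant, pure sample -> 0.5
#' ccfToVaf(0.4, 0.6)  # 0.12
#' @export
ccfToVaf <- function(ccf, purity) {
  if (any(is.na(ccf)) || any(ccf < 0) || any(ccf > 1))
    stopf("ccf must lie in [0, 1]")
  if (any(is.na(purity)) || any(purity < 0) || any(purity > 1))
    stopf("purity must lie in [0, 1]")
  0.5 * purity * ccf
}

#' Sample sequencing read counts for a variant
#'
#' Total depth is Poisson-dispersed around the requested depth (or fixed
#' with `fixedDepth = TRUE`); the alt count is binomial with success
#' probability `vaf*(1-errorRate) + (1-vaf)*errorRate/3`, i.e. a uniform
#' miscall model sending a third of errors to each alternative base. In
#' noiseless mode the depth is exact and the alt count is the rounded
#' expectation.
#'
#' Uses the current RNG stream; callers wanting reproducibility seed it
#' (as [simulatePatient()] does via its spec seed).
#'
#' @param vaf true variant allele fraction(s) in \[0, 0.5\].
#' @param depth requested mean depth(s), >= 1.
#' @param errorRate per-base miscall fraction.
#' @param noiseless logical; return rounded expectations without sampling.
#' @param fixedDepth logical; keep total depth at `depth` exactly.
#' @return data.frame with columns `alt` and `depth`.
#' @examples
#' sampleReads(0.25, 1000, errorRate = 0, noiseless = TRUE)  # 250 / 1000
#' @export
sampleReads <- function(vaf, depth, errorRate = 1e-3, noiseless = FALSE,
                        fixedDepth = FALSE) {
  if (any(vaf < 0) || any(vaf > 0.5)) stopf("vaf must lie in [0, 0.5]")
  if (any(depth < 1)) stopf("depth must be >= 1")
  n <- max(length(vaf), length(depth))
  vaf <- rep_len(vaf, n); depth <- rep_len(depth, n)
  if (noiseless) {
    total <- as.integer(round(depth))
    alt <- as.integer(round(total * vaf))
  } else {
    total <- if (fixedDepth) as.integer(round(depth))
             else pmax(1L, stats::rpois(n, depth))
    p <- vaf * (1 - errorRate) + (1 - vaf) * errorRate / 3
    alt <- stats::rbinom(n, total, p)
  }
  data.frame(alt = alt, depth = total)
}

## definitional category from a boolean presence triple (ground truth
## side; the observational side lives in categorizeVariant)
truthCategoryFromPresence <- function(svz, primary, recurrent) {
  mapply(function(s, p, r) {
    if (is.na(r)) r <- FALSE
    if (s && (p || r)) "SVZ_TUMOR_SHARED"
    else if (!s && p && r) "INTER_TUMOR_SHARED"
    else if (!s && p && !r) "PRIMARY_PRIVATE"
    else if (!s && !p && r) "RECURRENT_PRIVATE"
    else if (s && !p && !r) "SVZ_PRIVATE"
    else NA_character_
  }, svz, primary, recurrent)
}

## definitional recurrence pattern from the truth presence matrix
truthPatternFromPresence <- function(presence) {
  s <- presence[, "SVZ"]; p <- presence[, "PRIMARY"]
  r <- presence[, "RECURRENT"]
  if (!any(s & p & r)) return("UNKNOWN")
  if (any(!s & p & r)) return("PRIMARY_ASSOCIATED")
  if (any(!s & p & !r)) return("SVZ_ASSOCIATED")
  "UNKNOWN"
}

#' Simulate a matched four-sample patient from a clonal phylogeny
#'
#' For every catalog mutation and sample, the cancer-cell fraction is the
#' summed clone fraction of the carrying clone's subtree, converted to an
#' expected VAF under the diploid-heterozygous model and turned into read
#' counts by [sampleReads()]. Ground-truth sharing categories and the
#' recurrence-pattern label are derived directly from clone membership.
#' Deterministic given the spec seed.
#'
#' @param spec a valid [SimulationSpec-class].
#' @param patientId identifier recorded in the dataset.
#' @return a [PatientDataset-class].
#' @export
simulatePatient <- function(spec, patientId = "SIM") {
  validObject(spec)
  cat_ <- spec@catalog
  smp <- spec@samples
  key <- variantKey(cat_)

  ccf <- sapply(smp$name, function(nm)
    mutationCCF(spec@tree, spec@cloneFractions[[nm]])[cat_$id])
  ccf <- matrix(ccf, nrow = nrow(cat_),
                dimnames = list(key, smp$name))
  evaf <- sweep(ccf, 2, smp$purity, `*`) * 0.5

  counts <- withSeed(spec@seed, {
    lapply(seq_len(nrow(smp)), function(j)
      sampleReads(evaf[, j], rep(smp$meanDepth[j], nrow(cat_)),
                  errorRate = spec@errorRate,
                  noiseless = spec@noiseless,
                  fixedDepth = spec@fixedDepth))
  })

  variants <- data.frame(chrom = cat_$chrom, pos = cat_$pos, ref = cat_$ref,
                         alt = cat_$alt, gene = cat_$gene,
                         check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(smp))) {
    variants[[depthCol(smp$name[j])]] <- counts[[j]]$depth
    variants[[altCol(smp$name[j])]] <- counts[[j]]$alt
  }
  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  ## truth presence by role over the non-blood tissues
  roleOf <- stats::setNames(smp$role, smp$name)
  truthPresence <- matrix(FALSE, nrow(cat_), length(SOMATIC_ROLES),
                          dimnames = list(key, SOMATIC_ROLES))
  for (nm in smp$name) {
    rl <- roleOf[[nm]]
    if (rl %in% SOMATIC_ROLES)
      truthPresence[, rl] <- ccf[, nm] > 0 & smp$purity[smp$name == nm] > 0
  }
  categories <- stats::setNames(
    truthCategoryFromPresence(truthPresence[, "SVZ"],
                              truthPresence[, "PRIMARY"],
                              truthPresence[, "RECURRENT"]), key)
  pattern <- truthPatternFromPresence(truthPresence)

  manifest <- new("PatientManifest", patientId = patientId,
                  samples = data.frame(name = smp$name, role = smp$role,
                                       file = NA_character_,
                                       stringsAsFactors = FALSE))
  new("PatientDataset", patientId = patientId, variants = variants,
      manifest = manifest,
      truth = list(categories = categories, pattern = pattern,
                   presence = truthPresence, expectedVAF = evaf,
                   keyMap = stats::setNames(key, cat_$id)),
      tree = spec@tree)
}

#' Preset emulating the whole-genome worked example patient
#'
#' A minimal three-clone branched phylogeny: a trunk carrying a
#' TERT-promoter-like and an EGFR-like driver shared by SVZ, primary and
#' recurrent tumor; a primary-restricted branch with five private
#' passengers; and a sibling recurrence-restricted branch with five
#' private passengers. The SVZ carries the trunk at low mutant-cell
#' fraction; hybrid-capture depth defaults to the panel-like 1063x.
#'
#' @param noiseless logical; exact expectations instead of sampled reads.
#' @param seed integer RNG seed stored in the spec.
#' @param svzFraction fraction of SVZ cells in the mutant lineage.
#' @param meanDepth mean sequencing depth for all samples.
#' @return a [SimulationSpec-class].
#' @export
gbm244Preset <- function(noiseless = FALSE, seed = 244L,
                         svzFraction = 0.05, meanDepth = 1063) {
  tree <- ClonalTree(
    parent = c(trunk = GERMLINE_ROOT, primaryBranch = "trunk",
               recurrentBranch = "trunk"),
    mutations = list(
      trunk = c("TERTp_C228T", "EGFR_A289V"),
      primaryBranch = paste0("PP", 1:5),
      recurrentBranch = paste0("RP", 1:5)))
  catalog <- data.frame(
    id = c("TERTp_C228T", "EGFR_A289V", paste0("PP", 1:5), paste0("RP", 1:5)),
    chrom = c("chr5", "chr7", paste0("chr", c(1, 2, 3, 9, 12)),
              paste0("chr", c(4, 6, 11, 16, 19))),
    pos = c(1295228L, 55154129L,
            10000000L + (1:5) * 137L, 20000000L + (1:5) * 211L),
    ref = c("G", "C", rep(c("A", "C", "G", "T", "A"), 2)),
    alt = c("A", "T", rep(c("T", "G", "A", "C", "G"), 2)),
    gene = c("TERT", "EGFR", paste0("PASS_P", 1:5), paste0("PASS_R", 1:5)),
    driver = c(TRUE, TRUE, rep(FALSE, 10)),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    name = c("blood", "svz", "primary", "recurrent"),
    role = c("BLOOD", "SVZ", "PRIMARY", "RECURRENT"),
    purity = c(0, svzFraction, 0.7, 0.6),
    meanDepth = meanDepth,
    stringsAsFactors = FALSE)
  cloneFractions <- list(
    blood = c(trunk = 1),          # purity 0: fractions never expressed
    svz = c(trunk = 1),
    primary = c(trunk = 0.1, primaryBranch = 0.9),
    recurrent = c(trunk = 0.15, recurrentBranch = 0.85))
  new("SimulationSpec", tree = tree, catalog = catalog, samples = samples,
      cloneFractions = cloneFractions, errorRate = 1e-3,
      noiseless = noiseless, fixedDepth = noiseless, seed = as.integer(seed))
}

#' Random patient spec with known recurrence-pattern truth
#'
#' Draws a branched phylogeny of the given scenario: `"SVZ_ASSOCIATED"`
#' gives trunk -> (primary branch, recurrent branch) with no clone shared
#' by the two tumors beyond the trunk; `"PRIMARY_ASSOCIATED"` inserts a
#' clone carried by both tumors but absent from the SVZ (the residual
#' dominant-primary lineage), whose mutations are inter-tumor shared.
#' Passenger counts per clone, purities, SVZ mutant fraction and clone
#' mixes are drawn from ranges typical of deep panel studies (SVZ mutant
#' fraction 0.02-0.10, tumor purity 0.5-0.8).
#'
#' @param seed integer seed (also stored in the spec).
#' @param scenario truth label the phylogeny encodes.
#' @param meanDepth mean sequencing depth.
#' @param noiseless logical, exact expectations.
#' @param minMutPerClone minimum mutations per clone (>= 1).
#' @return a [SimulationSpec-class].
#' @export
randomPatientSpec <- function(seed,
                              scenario = c("SVZ_ASSOCIATED",
                                           "PRIMARY_ASSOCIATED"),
                              meanDepth = 1063, noiseless = FALSE,
                              minMutPerClone = 3L) {
  scenario <- match.arg(scenario)
  withSeed(seed, {
    shared <- scenario == "PRIMARY_ASSOCIATED"
    cloneIds <- c("trunk", if (shared) "sharedPR", "primaryBranch",
                  "recurrentBranch")
    parent <- stats::setNames(
      c(GERMLINE_ROOT,
        if (shared) "trunk",
        if (shared) "sharedPR" else "trunk",
        if (shared) "sharedPR" else "trunk"),
      cloneIds)
    nmut <- sample(seq(minMutPerClone, minMutPerClone + 5L),
                   length(cloneIds), replace = TRUE)
    ids <- split(sprintf("M%03d", seq_len(sum(nmut))),
                 rep(seq_along(cloneIds), nmut))
    names(ids) <- cloneIds
    tree <- ClonalTree(parent, ids)

    n <- sum(nmut)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    catalog <- data.frame(
      id = unlist(ids, use.names = FALSE),
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n),
      ref = ref, alt = alt,
      gene = sprintf("GENE%03d", seq_len(n)),
      driver = unlist(ids, use.names = FALSE) %in% ids$trunk[1],
      stringsAsFactors = FALSE)

    svzPurity <- stats::runif(1, 0.02, 0.10)
    samples <- data.frame(
      name = c("blood", "svz", "primary", "recurrent"),
      role = c("BLOOD", "SVZ", "PRIMARY", "RECURRENT"),
      purity = c(0, svzPurity, stats::runif(1, 0.5, 0.8),
                 stats::runif(1, 0.5, 0.8)),
      meanDepth = meanDepth, stringsAsFactors = FALSE)

    mix <- function(branch) {
      if (shared) {
        a <- stats::runif(1, 0.05, 0.15); b <- stats::runif(1, 0.10, 0.30)
        stats::setNames(c(a, b, 1 - a - b), c("trunk", "sharedPR", branch))
      } else {
        a <- stats::runif(1, 0.05, 0.20)
        stats::setNames(c(a, 1 - a), c("trunk", branch))
      }
    }
    cloneFractions <- list(blood = c(trunk = 1), svz = c(trunk = 1),
                           primary = mix("primaryBranch"),
                           recurrent = mix("recurrentBranch"))
    new("SimulationSpec", tree = tree, catalog = catalog, samples = samples,
        cloneFractions = cloneFractions, errorRate = 1e-3,
        noiseless = noiseless, fixedDepth = noiseless,
        seed = as.integer(seed))
  })
}
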