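#' Cluster variants by presence profile and VAF
#'
#' Variants are first partitioned by their exact per-tissue presence
#' profile (variants seen in different tissue sets can never share a
#' clone), then single-linkage clustered within each profile on the
#' largest per-sample VAF distance, cutting at `tol`. Tie-breaking is
#' order-independent: variants are processed sorted by key and clusters
#' are keyed `C1..Ck` by decreasing total VAF (ties by smallest member
#' key).
#'
#' @param vaf numeric matrix, variants x samples, observed VAF.
#' @param presence character matrix of presence states, same rows.
#' @param tol clustering tolerance on the VAF scale, in (0, 0.2].
#' @return named list of clusters, each with `key`, `members`, `vaf`
#'   (per-sample mean) and `profile`.
#' @export
clusterVariantsByVAF <- function(vaf, presence, tol = 0.05) {
  if (tol <= 0 || tol > 0.2) stopf("tol must lie in (0, 0.2]")
  stopifnot(identical(rownames(vaf), rownames(presence)))
  ord <- order(rownames(vaf))
  vaf <- vaf[ord, , drop = FALSE]; presence <- presence[ord, , drop = FALSE]
  profiles <- apply(presence, 1, paste, collapse = "/")
  groups <- split(rownames(vaf), profiles)

  clusters <- list()
  for (g in groups) {
    sub <- vaf[g, , drop = FALSE]
    if (length(g) == 1L) { clusters <- c(clusters, list(g)); next }
    d <- stats::as.dist(vapply(seq_len(nrow(sub)), function(i)
      apply(abs(sweep(sub, 2, sub[i, ])), 1, max), numeric(nrow(sub))))
    hc <- stats::hclust(d, method = "single")
    cut <- stats::cutree(hc, h = tol)
    clusters <- c(clusters, split(g, cut))
  }

  objs <- lapply(clusters, function(members) {
    list(members = sort(members),
         vaf = colMeans(vaf[members, , drop = FALSE]),
         profile = presence[members[1], ])
  })
  ord <- order(-vapply(objs, function(x) sum(x$vaf), numeric(1)),
               vapply(objs, function(x) x$members[1], ""))
  objs <- objs[ord]
  for (i in seq_along(objs)) objs[[i]]$key <- sprintf("C%d", i)
  stats::setNames(objs, vapply(objs, `[[`, "", "key"))
}

## may A parent B? containment within tol plus presence coverage
canParent <- function(A, B, tol) {
  all(A$vaf >= B$vaf - tol) &&
    all(A$profile[B$profile == "PRESENT"] == "PRESENT")
}

#' Build a lineage tree from variant clusters
#'
#' Orders clusters by decreasing total VAF and attaches each to its
#' nearest valid ancestor: a cluster may parent another only if its mean
#' VAF dominates the child's within `tol` in every sample and it is
#' PRESENT wherever the child is. Among valid parents the one with the
#' smallest summed VAF excess wins (ties by lexicographic key); clusters
#' with no valid parent attach to the germline root. The pigeonhole
#' (sum) rule — per sample, parent VAF + tol must cover the summed VAF
#' of its children — is checked after construction and violations are
#' reported in the result, never silently repaired.
#'
#' @param clusters list from [clusterVariantsByVAF()].
#' @param tol containment tolerance on the VAF scale.
#' @return a [LineageTree-class].
#' @export
buildLineageTree <- function(clusters, tol = 0.05) {
  if (length(clusters) == 0L) stopf("at least one cluster required")
  keys <- names(clusters)
  parent <- stats::setNames(rep(GERMLINE_ROOT, length(keys)), keys)
  for (i in seq_along(clusters)) {
    B <- clusters[[i]]
    best <- NULL; bestExcess <- Inf
    for (j in seq_len(i - 1L)) {
      A <- clusters[[j]]
      if (!canParent(A, B, tol)) next
      excess <- sum(A$vaf - B$vaf)
      if (excess < bestExcess - 1e-12 ||
          (abs(excess - bestExcess) <= 1e-12 && !is.null(best) &&
           A$key < best)) {
        best <- A$key; bestExcess <- excess
      }
    }
    if (!is.null(best)) parent[i] <- best
  }
  edges <- data.frame(parent = unname(parent), child = keys,
                      stringsAsFactors = FALSE)

  ## sum rule: per parent and sample, children must fit inside the parent
  samples <- names(clusters[[1]]$vaf)
  viol <- list()
  rootVAF <- stats::setNames(rep(0.5, length(samples)), samples)
  for (p in unique(edges$parent)) {
    kids <- edges$child[edges$parent == p]
    kidSum <- colSums(do.call(rbind,
      lapply(clusters[kids], `[[`, "vaf")))
    pvaf <- if (p == GERMLINE_ROOT) rootVAF else clusters[[p]]$vaf
    bad <- which(pvaf + tol < kidSum)
    for (s in samples[bad])
      viol[[length(viol) + 1L]] <- data.frame(
        parent = p, sample = s, parentVAF = unname(pvaf[s]),
        childSum = unname(kidSum[s]), stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(parent = character(), sample = character(),
                    parentVAF = numeric(), childSum = numeric(),
                    stringsAsFactors = FALSE)
  new("LineageTree", clusters = clusters, edges = edges,
      violations = violations, tol = tol)
}

#' Infer a lineage tree straight from presence calls
#'
#' Convenience composition of [clusterVariantsByVAF()] and
#' [buildLineageTree()] over the somatic (non-germline, resolved)
#' variants of a patient.
#'
#' @param calls a [PresenceCalls-class].
#' @param tol clustering/containment tolerance.
#' @return a [LineageTree-class], or `NULL` when no somatic variant is
#'   left to place.
#' @export
inferLineage <- function(calls, tol = 0.05) {
  keep <- !calls@germline &
    apply(calls@states, 1, function(x) all(!is.na(x)) &&
            any(x == "PRESENT"))
  if (!any(keep)) return(NULL)
  clusters <- clusterVariantsByVAF(calls@vaf[keep, , drop = FALSE],
                                   calls@states[keep, , drop = FALSE], tol)
  buildLineageTree(clusters, tol)
}

## ancestor chain of a node given a parent map (excluding the node)
ancestorChain <- function(parentMap, node) {
  out <- character()
  while (!is.na(parentMap[node]) && parentMap[node] != GERMLINE_ROOT) {
    node <- parentMap[[node]]
    out <- c(out, node)
  }
  out
}

## pairwise relation of two mutations given node assignment + parent map
pairRelation <- function(parentMap, nodeOf, m1, m2) {
  n1 <- nodeOf[[m1]]; n2 <- nodeOf[[m2]]
  if (n1 == n2) return("same")
  if (n1 %in% ancestorChain(parentMap, n2)) return("anc>")
  if (n2 %in% ancestorChain(parentMap, n1)) return("anc<")
  "sibling"
}

#' Concordance of pairwise mutation relations between two trees
#'
#' For every unordered pair of mutations, the relation in a tree is one
#' of: same node, first-ancestral, second-ancestral, or sibling (neither
#' contains the other). The concordance is the fraction of pairs whose
#' relation agrees between the inferred tree and the truth phylogeny.
#'
#' @param inferred a [LineageTree-class].
#' @param truth a [ClonalTree-class].
#' @param keyMap named character translating truth mutation ids to the
#'   variant keys used by the inferred tree (default: identical ids).
#' @return fraction in \[0, 1\] (1 for a single-pair-free tree of one
#'   mutation).
#' @export
treeConcordance <- function(inferred, truth, keyMap = NULL) {
  truthMut <- names(truth@mutationClone)
  truthKeys <- if (is.null(keyMap)) stats::setNames(truthMut, truthMut)
    else keyMap[truthMut]
  infNode <- list()
  for (cl in inferred@clusters)
    for (m in cl$members) infNode[[m]] <- cl$key
  if (!setequal(names(infNode), unname(truthKeys)))
    stopf("mutation sets of the two trees differ")

  infParent <- stats::setNames(inferred@edges$parent, inferred@edges$child)
  truthParent <- truth@parent
  truthNode <- as.list(stats::setNames(truth@mutationClone[truthMut],
                                       unname(truthKeys)))

  keys <- sort(unname(truthKeys))
  if (length(keys) < 2L) return(1)
  agree <- 0L; total <- 0L
  for (i in seq_len(length(keys) - 1L))
    for (j in seq(i + 1L, length(keys))) {
      total <- total + 1L
      if (pairRelation(infParent, infNode, keys[i], keys[j]) ==
          pairRelation(truthParent, truthNode, keys[i], keys[j]))
        agree <- agree + 1L
    }
  agree / total
}

#' Export a lineage tree as Newick
#'
#' Cluster keys become node labels; the root is labelled GERMLINE.
#'
#' @param tree a [LineageTree-class].
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
writeNewick <- function(tree, path = NULL) {
  kids <- split(tree@edges$child, tree@edges$parent)
  fmt <- function(node) {
    ch <- kids[[node]]
    lab <- node
    if (is.null(ch)) return(lab)
    paste0("(", paste(vapply(sort(ch), fmt, ""), collapse = ","), ")", lab)
  }
  nwk <- paste0(fmt(GERMLINE_ROOT), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Export tree edges as TSV
#'
#' @param tree a [LineageTree-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeTreeEdges <- function(tree, path) {
  utils::write.table(tree@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-tissue VAF scatter table
#'
#' Per-variant VAF in one tissue against another (the axes of the
#' classic shared-vs-private scatter), with the variant's category
#' attached when supplied.
#'
#' @param calls a [PresenceCalls-class].
#' @param xRole,yRole tissue roles for the two axes.
#' @param categories optional [categorizePatient()] table.
#' @return data.frame with `variant`, `gene`, `x`, `y` (VAFs) and
#'   optionally `category`.
#' @export
vafScatter <- function(calls, xRole = "SVZ", yRole = "PRIMARY",
                       categories = NULL) {
  keep <- !calls@germline
  out <- data.frame(variant = rownames(calls@vaf)[keep],
                    gene = calls@variants$gene[keep],
                    x = calls@vaf[keep, xRole],
                    y = calls@vaf[keep, yRole],
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[3:4] <- c(paste0("vaf.", xRole), paste0("vaf.", yRole))
  if (!is.null(categories))
    out$category <- categories$category[match(out$variant,
                                              categories$variant)]
  out
}
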