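# build a cluster list directly (keys assigned by the constructor's
# ordering convention) for hand-crafted topologies
makeClusters <- function(vafRows, profiles, membersPerRow = 1L) {
  vaf <- do.call(rbind, vafRows)
  rownames(vaf) <- sprintf("v%02d", seq_len(nrow(vaf)))
  colnames(vaf) <- c("SVZ", "PRIMARY", "RECURRENT")
  prof <- do.call(rbind, profiles)
  dimnames(prof) <- dimnames(vaf)
  clusterVariantsByVAF(vaf, prof, tol = 0.05)
}

test_that("clustering partitions by profile first, then by VAF distance", {
  P <- "PRESENT"; A <- "ABSENT"
  # three variants, identical profile, VAFs within tolerance: one cluster
  cl <- makeClusters(list(c(0.02, 0.34, 0.30), c(0.025, 0.35, 0.31),
                          c(0.021, 0.33, 0.29)),
                     rep(list(c(P, P, P)), 3))
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 3L)

  # disjoint presence profiles are never merged however close the VAFs
  cl <- makeClusters(list(c(0, 0.30, 0), c(0, 0.30, 0.001)),
                     list(c(A, P, A), c(A, P, P)))
  expect_length(cl, 2L)

  # same profile, VAF gap beyond tol: split
  cl <- makeClusters(list(c(0, 0.40, 0), c(0, 0.10, 0)),
                     list(c(A, P, A), c(A, P, A)))
  expect_length(cl, 2L)
  expect_error(clusterVariantsByVAF(matrix(0.1), matrix("PRESENT"),
                                    tol = 0.5), "tol")
})

test_that("the noiseless worked example yields the three-clone topology", {
  ds <- simulatePatient(gbm244Preset(noiseless = TRUE), "GBM-244")
  calls <- callPatient(variantTable(ds), ds@manifest)
  tree <- inferLineage(calls)
  expect_length(treeClusters(tree), 3L)
  e <- treeEdges(tree)
  # trunk cluster under the germline root, both branches under the trunk
  expect_equal(e$parent[e$child == "C1"], "GERMLINE")
  expect_equal(e$parent[e$child %in% c("C2", "C3")], c("C1", "C1"))
  expect_equal(nrow(sumRuleViolations(tree)), 0L)
  expect_equal(writeNewick(tree), "((C2,C3)C1)GERMLINE;")
  # trunk cluster carries the two driver variants
  trunkGenes <- calls@variants$gene[match(treeClusters(tree)$C1$members,
                                          rownames(presenceStates(calls)))]
  expect_setequal(trunkGenes, c("TERT", "EGFR"))
})

test_that("a single cluster hangs from the root and crossing VAFs become siblings", {
  P <- "PRESENT"
  one <- makeClusters(list(c(0.02, 0.3, 0.3)), list(c(P, P, P)))
  t1 <- buildLineageTree(one)
  expect_equal(treeEdges(t1), data.frame(parent = "GERMLINE", child = "C1",
                                         stringsAsFactors = FALSE))

  # A > B in PRIMARY, B > A in RECURRENT beyond tol: brute force over the
  # three candidate topologies (A->B, B->A, siblings) leaves only siblings
  cross <- makeClusters(list(c(0, 0.40, 0.10), c(0, 0.10, 0.40)),
                        rep(list(c(P, P, P)), 2))
  contains <- function(A, B, tol = 0.05) all(A$vaf >= B$vaf - tol)
  expect_false(contains(cross[[1]], cross[[2]]))
  expect_false(contains(cross[[2]], cross[[1]]))
  t2 <- buildLineageTree(cross)
  expect_equal(sort(treeEdges(t2)$parent), c("GERMLINE", "GERMLINE"))
})

test_that("sum-rule violations are reported, not repaired", {
  P <- "PRESENT"; A <- "ABSENT"
  # two crossing sibling branches summing to 0.33 under a 0.25 parent
  cl <- makeClusters(list(c(0.05, 0.25, 0.25), c(0, 0.23, 0.10),
                          c(0, 0.10, 0.23)),
                     list(c(P, P, P), c(A, P, P), c(A, P, P)))
  tr <- buildLineageTree(cl)
  v <- sumRuleViolations(tr)
  expect_gt(nrow(v), 0L)
  expect_true(all(v$childSum > v$parentVAF + tr@tol))
})

test_that("tree concordance agrees with brute-force pair enumeration", {
  # enumeration oracle over all unordered pairs
  oracleConcordance <- function(parentA, nodeA, parentB, nodeB) {
    rel <- function(parent, node, m1, m2) {
      anc <- function(x) { out <- c(); while (parent[[x]] != "GERMLINE") {
        x <- parent[[x]]; out <- c(out, x) }; out }
      if (node[[m1]] == node[[m2]]) return("same")
      if (node[[m1]] %in% anc(node[[m2]])) return(">")
      if (node[[m2]] %in% anc(node[[m1]])) return("<")
      "sib"
    }
    keys <- names(nodeA); agree <- 0; tot <- 0
    for (i in seq_len(length(keys) - 1)) for (j in seq(i + 1, length(keys))) {
      tot <- tot + 1
      if (rel(parentA, nodeA, keys[i], keys[j]) ==
          rel(parentB, nodeB, keys[i], keys[j])) agree <- agree + 1
    }
    agree / tot
  }
  asTree <- function(parent, node) {
    members <- split(names(node), unlist(node))
    clusters <- lapply(names(parent), function(k)
      list(key = k, members = members[[k]],
           vaf = c(S = 0.1), profile = c(S = "PRESENT")))
    names(clusters) <- names(parent)
    new("LineageTree",
        clusters = clusters,
        edges = data.frame(parent = unlist(parent), child = names(parent),
                           stringsAsFactors = FALSE),
        violations = data.frame(), tol = 0.05)
  }
  chainP <- list(A = "GERMLINE", B = "A", C = "B")
  starP <- list(A = "GERMLINE", B = "GERMLINE", C = "GERMLINE")
  trunkStarP <- list(A = "GERMLINE", B = "A", C = "A")
  node <- list(m1 = "A", m2 = "B", m3 = "C")
  truthChain <- ClonalTree(c(A = "GERMLINE", B = "A", C = "B"),
                           list(A = "m1", B = "m2", C = "m3"))

  # identical trees agree perfectly
  expect_equal(treeConcordance(asTree(chainP, node), truthChain), 1.0)
  # root-star vs chain: every pair lineal in one, sibling in the other
  expect_equal(oracleConcordance(starP, node, chainP, node), 0)
  expect_equal(treeConcordance(asTree(starP, node), truthChain), 0)
  # trunk + two branches vs chain: the two trunk pairs agree
  expect_equal(oracleConcordance(trunkStarP, node, chainP, node), 2 / 3)
  expect_equal(treeConcordance(asTree(trunkStarP, node), truthChain), 2 / 3)

  expect_error(treeConcordance(asTree(chainP, node),
                               ClonalTree(c(A = "GERMLINE"),
                                          list(A = "mX"))), "differ")
})

test_that("noiseless random phylogenies are reconstructed exactly", {
  for (seed in 51:60) {
    sc <- if (seed %% 2) "SVZ_ASSOCIATED" else "PRIMARY_ASSOCIATED"
    ds <- simulatePatient(randomPatientSpec(seed, scenario = sc,
                                            noiseless = TRUE), "PT")
    calls <- callPatient(variantTable(ds), ds@manifest)
    tree <- inferLineage(calls)
    expect_equal(treeConcordance(tree, ds@tree, keyMap = ds@truth$keyMap),
                 1.0, label = paste("seed", seed))
  }
})

test_that("the built tree is self-consistent and deterministic", {
  ds <- simulatePatient(randomPatientSpec(77L, noiseless = TRUE), "PT")
  calls <- callPatient(variantTable(ds), ds@manifest)
  t1 <- inferLineage(calls); t2 <- inferLineage(calls)
  expect_identical(treeEdges(t1), treeEdges(t2))
  # containment holds on the data the tree was built from
  for (i in seq_len(nrow(treeEdges(t1)))) {
    p <- treeEdges(t1)$parent[i]; ch <- treeEdges(t1)$child[i]
    if (p == "GERMLINE") next
    expect_true(all(treeClusters(t1)[[p]]$vaf >=
                    treeClusters(t1)[[ch]]$vaf - t1@tol))
  }
})
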