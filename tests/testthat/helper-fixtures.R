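# shared in-memory fixtures for the test suite

# four-sample manifest with generic sample names
makeManifest <- function(pid = "PT") {
  new("PatientManifest", patientId = pid,
      samples = data.frame(
        name = c("blood", "svz", "primary", "recurrent"),
        role = c("BLOOD", "SVZ", "PRIMARY", "RECURRENT"),
        file = NA_character_, stringsAsFactors = FALSE))
}

# wide variant table from a compact per-variant count list:
# counts[[i]] = c(bDepth,bAlt, sDepth,sAlt, pDepth,pAlt, rDepth,rAlt)
makeVariantTable <- function(counts, genes = NULL) {
  n <- length(counts)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(n))
  df <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000L,
                   ref = "A", alt = "T", gene = genes,
                   stringsAsFactors = FALSE)
  m <- do.call(rbind, counts)
  smp <- c("blood", "svz", "primary", "recurrent")
  for (j in seq_along(smp)) {
    df[[paste0(smp[j], ".depth")]] <- m[, 2 * j - 1]
    df[[paste0(smp[j], ".alt")]] <- m[, 2 * j]
  }
  df
}

# single-clone spec: all mutations on the trunk, present in every tissue
trunkOnlySpec <- function(nMut = 3L, seed = 11L, noiseless = TRUE,
                          svzFraction = 0.05) {
  ids <- sprintf("T%d", seq_len(nMut))
  tree <- ClonalTree(c(trunk = "GERMLINE"), list(trunk = ids))
  catalog <- data.frame(id = ids, chrom = "chr1",
                        pos = seq_len(nMut) * 500L, ref = "C", alt = "G",
                        gene = sprintf("GENE%d", seq_len(nMut)),
                        driver = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(name = c("blood", "svz", "primary", "recurrent"),
                        role = c("BLOOD", "SVZ", "PRIMARY", "RECURRENT"),
                        purity = c(0, svzFraction, 0.7, 0.6),
                        meanDepth = 1063, stringsAsFactors = FALSE)
  new("SimulationSpec", tree = tree, catalog = catalog, samples = samples,
      cloneFractions = list(blood = c(trunk = 1), svz = c(trunk = 1),
                            primary = c(trunk = 1), recurrent = c(trunk = 1)),
      errorRate = 1e-3, noiseless = noiseless, fixedDepth = noiseless,
      seed = as.integer(seed))
}

# text of a small VCF with AD fields covering PASS filtering and
# multi-allelic splitting
writeTestVcf <- function(path, samples = c("S1", "S2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=artifact,Description=\"fails\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "C,T", ".", "PASS", ".", "GT:AD",
            "0/1:90,10,5", "0/0:100,0,0"), collapse = "\t"),
    paste(c("chr1", "200", ".", "G", "A", ".", "artifact", ".", "GT:AD",
            "0/1:50,50", "0/1:60,40"), collapse = "\t"),
    paste(c("chr2", "300", ".", "T", "G", ".", "PASS", ".", "GT:AD",
            "0/1:80,20", "0/0:99,1"), collapse = "\t")), path)
  path
}
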