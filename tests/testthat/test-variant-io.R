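test_that("variant tables round-trip through write/read unchanged", {
  ds <- simulatePatient(gbm244Preset(seed = 3L), "PT")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(variantTable(ds), path)
  back <- readVariantTable(path)
  expect_equal(back, variantTable(ds))

  # canonical ordering: shuffled input comes back sorted
  shuffled <- variantTable(ds)[sample(nrow(variantTable(ds))), ]
  writeVariantTable(shuffled, path)
  expect_equal(readVariantTable(path), variantTable(ds))
})

test_that("an empty record set writes a header-only table", {
  ds <- simulatePatient(gbm244Preset(seed = 3L), "PT")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(variantTable(ds)[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("malformed variant tables are rejected with diagnostics", {
  tab <- makeVariantTable(list(c(1000, 0, 1000, 20, 1000, 300, 1000, 250)))
  path <- withr::local_tempfile(fileext = ".tsv")

  bad <- tab; bad$primary.alt <- 1200  # alt exceeds depth
  writeVariantTable(bad, path)
  expect_error(readVariantTable(path), "row 1.*exceeds depth")

  writeVariantTable(tab, path)
  txt <- readLines(path)
  writeLines(gsub("\\bpos\\b", "position", txt), path)
  expect_error(readVariantTable(path), "lacks column")

  writeLines(sub("300", "300.5", txt), path)
  expect_error(readVariantTable(path), "non-integer")
})

test_that("the VCF reader filters, splits multi-allelics and sums AD", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(path)
  v <- readVcfVariants(path)
  expect_equal(nrow(v), 3L)               # artifact record dropped
  expect_false(any(v$pos == 200))
  biAll <- v[v$pos == 100, ]
  expect_equal(nrow(biAll), 2L)           # A>C and A>T are distinct
  expect_equal(biAll$ref, c("A", "A"))
  expect_equal(sort(biAll$alt), c("C", "T"))
  expect_equal(biAll$S1.depth, c(105L, 105L))  # 90+10+5
  expect_equal(biAll$S1.alt[biAll$alt == "C"], 10L)
  expect_equal(biAll$S1.alt[biAll$alt == "T"], 5L)
  # non-PASS retention behind the explicit flag
  expect_equal(nrow(readVcfVariants(path, keepNonPass = TRUE)), 4L)

  # uniformly bi-allelic files (AD parsed as an array, not a ragged list)
  bi <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "C", ".", "PASS", ".", "GT:AD",
            "0/1:90,10"), collapse = "\t")), bi)
  vb <- readVcfVariants(bi)
  expect_equal(vb$S1.depth, 100L)
  expect_equal(vb$S1.alt, 10L)
})

test_that("VCF and TSV readers agree on matched fixtures", {
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(vcfPath)
  v <- readVcfVariants(vcfPath)
  tsvPath <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(v, tsvPath)
  back <- readVariantTable(tsvPath)
  back$gene <- ifelse(back$gene == "NA", NA_character_, back$gene)
  expect_equal(variantKey(back), variantKey(v))
  expect_equal(back$S1.alt, v$S1.alt)
  expect_equal(back$S2.depth, v$S2.depth)
})

test_that("VCF samples must resolve against the manifest when given", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(path, samples = c("blood", "mystery"))
  expect_error(readVcfVariants(path, makeManifest()), "mystery")
})

test_that("manifests round-trip and enforce role structure", {
  m <- makeManifest("GBM-X")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pt.manifest")
  writePatientManifest(m, path, table = "pt.variants.tsv")
  back <- readPatientManifest(path)
  expect_equal(patientId(back), "GBM-X")
  expect_equal(back@samples$role, m@samples$role)
  expect_equal(unique(back@samples$file), file.path(dir, "pt.variants.tsv"))

  # roles must be unique and complete
  expect_error(new("PatientManifest", patientId = "x",
                   samples = data.frame(name = c("a", "b"),
                                        role = c("BLOOD", "BLOOD"),
                                        file = NA_character_)) |>
                 validObject(), "unique|exactly one")
  expect_error(new("PatientManifest", patientId = "x",
                   samples = data.frame(name = "a", role = "SVZ",
                                        file = NA_character_)) |>
                 validObject(), "exactly one BLOOD")
})
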