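#' Read a wide variant table
#'
#' The table dialect is UTF-8 TSV with `#`-prefixed comment lines, header
#' columns `chrom`, `pos`, `ref`, `alt`, `gene`, then one
#' `<sample>.depth` / `<sample>.alt` column pair per sample. Coordinates
#' are 1-based VCF convention; indels are left-anchored. Malformed rows
#' (non-integer counts, alt reads exceeding depth) are rejected with the
#' offending row number.
#'
#' @param path file to read.
#' @return data.frame in the same layout, one row per variant.
#' @seealso [writeVariantTable()], [readVcfVariants()]
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("variant table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  samples <- variantTableSamples(df)
  if (!length(samples))
    stopf("variant table %s has no <sample>.depth/<sample>.alt pairs", path)
  for (s in samples) {
    d <- df[[depthCol(s)]]; a <- df[[altCol(s)]]
    if (!is.numeric(d) || !is.numeric(a) ||
        any(d != floor(d), na.rm = TRUE) || any(a != floor(a), na.rm = TRUE))
      stopf("non-integer counts in sample '%s' of %s", s, path)
    bad <- which(a > d | a < 0 | d < 0)
    if (length(bad))
      stopf("row %d of %s: alt_count %d exceeds depth %d (sample '%s')",
            bad[1], path, a[bad[1]], d[bad[1]], s)
  }
  dup <- duplicated(variantKey(df))
  if (any(dup))
    stopf("row %d of %s: duplicate variant key", which(dup)[1], path)
  df
}

## sample names implied by the paired depth/alt columns
variantTableSamples <- function(df) {
  d <- sub("\\.depth$", "", grep("\\.depth$", names(df), value = TRUE))
  a <- sub("\\.alt$", "", grep("\\.alt$", names(df), value = TRUE))
  intersect(d, a)
}

#' Write a variant table
#'
#' Writes the TSV dialect of [readVariantTable()] with deterministic
#' column order and rows sorted by `(chrom, pos, alt)`.
#'
#' @param df variant table data.frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(df, path) {
  samples <- variantTableSamples(df)
  cols <- c("chrom", "pos", "ref", "alt", "gene",
            as.vector(rbind(depthCol(samples), altCol(samples))))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("cannot write: missing column(s) %s", paste(miss, collapse = ", "))
  df <- df[order(df$chrom, df$pos, df$alt), cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read somatic variants from a VCF
#'
#' Reads a VCF 4.x file with per-sample `AD` (allelic depth) genotype
#' fields, keeps `FILTER == PASS` records only (set `keepNonPass = TRUE`
#' for sensitivity analyses), splits multi-allelic records into one
#' variant per alternate allele, and returns the wide variant-table
#' layout. Total depth is the sum of all `AD` entries of the original
#' record; the alt count is the `AD` entry of the specific allele.
#'
#' @param path VCF file.
#' @param manifest optional [PatientManifest-class]; when given, every
#'   VCF sample must appear in the manifest.
#' @param keepNonPass retain records failing FILTER (default FALSE).
#' @return data.frame in the variant-table layout.
#' @export
readVcfVariants <- function(path, manifest = NULL, keepNonPass = FALSE) {
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stopf("VCF %s has no AD genotype field", path)
  vcfSamples <- colnames(vcf)
  if (!is.null(manifest)) {
    unknown <- setdiff(vcfSamples, manifest@samples$name)
    if (length(unknown))
      stopf("VCF sample(s) not in manifest: %s",
            paste(unknown, collapse = ", "))
  }
  filt <- VariantAnnotation::fixed(vcf)$FILTER
  keep <- keepNonPass | filt %in% c("PASS", ".")
  vcf <- vcf[keep, ]; ad <- ad[keep, , drop = FALSE]
  if (nrow(vcf) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), stringsAsFactors = FALSE)
    for (s in vcfSamples) { out[[depthCol(s)]] <- integer()
                            out[[altCol(s)]] <- integer() }
    return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altList)
  rows <- rep(seq_along(nAlt), nAlt)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[rows],
    pos = BiocGenerics::start(rr)[rows],
    ref = as.character(VariantAnnotation::ref(vcf))[rows],
    alt = as.character(unlist(altList)),
    gene = NA_character_,
    stringsAsFactors = FALSE)
  altIdx <- unlist(lapply(nAlt, seq_len))  # which alt within the record
  for (s in vcfSamples) {
    ## AD comes back as a list-matrix (ragged alt counts) or a 3D array
    ## (uniform); normalize to one AD vector per record
    adS <- if (length(dim(ad)) == 3L)
      lapply(seq_len(nrow(vcf)), function(i) ad[i, s, ])
    else ad[, s]
    total <- vapply(adS, function(x) sum(x, na.rm = TRUE), numeric(1))
    altCt <- mapply(function(x, i) x[i + 1L], adS[rows], altIdx)
    out[[depthCol(s)]] <- as.integer(total[rows])
    out[[altCol(s)]] <- as.integer(altCt)
  }
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a patient manifest
#'
#' Flat `key=value` text file (UTF-8, `#` comments) with keys
#' `patient_id`, then one line per tissue role (`blood`, `svz`,
#' `primary`, optionally `recurrent`) whose value is the sample name,
#' optionally followed by a tab and the variant-table path, and an
#' optional `table=` key naming a shared table for all samples. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest file.
#' @return a [PatientManifest-class]; a shared table path, when present,
#'   is recorded in the `file` column of every sample.
#' @export
readPatientManifest <- function(path) {
  if (!file.exists(path)) stopf("no such manifest: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L)) stopf("malformed manifest line in %s", path)
  keys <- tolower(trimws(vapply(kv, `[`, "", 2L)))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  getOne <- function(k) { i <- which(keys == k)
    if (length(i) > 1L) stopf("duplicate key '%s' in %s", k, path)
    if (length(i)) vals[i] else NA_character_ }
  pid <- getOne("patient_id")
  if (is.na(pid)) stopf("manifest %s lacks patient_id", path)
  sharedTable <- getOne("table")
  resolve <- function(f) {
    if (is.na(f) || f == "") return(NA_character_)
    if (!grepl("^/", f)) file.path(dirname(path), f) else f
  }
  rows <- list()
  for (role in tolower(TISSUE_ROLES)) {
    v <- getOne(role)
    if (is.na(v)) next
    parts <- strsplit(v, "\t", fixed = TRUE)[[1]]
    f <- if (length(parts) > 1L) parts[2] else sharedTable
    rows[[role]] <- data.frame(name = parts[1], role = toupper(role),
                               file = resolve(f), stringsAsFactors = FALSE)
  }
  m <- new("PatientManifest", patientId = pid,
           samples = do.call(rbind, unname(rows)))
  validObject(m)
  m
}

#' Write a patient manifest
#'
#' @param manifest a [PatientManifest-class].
#' @param path destination; sample file paths are written relative to it
#'   when they live in the same directory.
#' @param table optional shared table filename recorded as `table=`.
#' @return `path`, invisibly.
#' @export
writePatientManifest <- function(manifest, path, table = NULL) {
  s <- manifest@samples
  lines <- c(paste0("patient_id=", manifest@patientId),
             if (!is.null(table)) paste0("table=", table))
  for (i in seq_len(nrow(s)))
    lines <- c(lines, paste0(tolower(s$role[i]), "=", s$name[i]))
  writeLines(lines, path)
  invisible(path)
}

## role -> sample-name lookup for a manifest
roleSample <- function(manifest, role) {
  s <- manifest@samples
  hit <- s$name[s$role == role]
  if (length(hit)) hit else NA_character_
}
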