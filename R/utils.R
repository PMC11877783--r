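#' Canonical variant key
#'
#' Variant identity is allele-level: `(chrom, pos, ref, alt)`. Two
#' different alleles at one locus (or two loci in one gene) are distinct
#' variants.
#'
#' @param chrom,pos,ref,alt vectors or a data.frame in `chrom` with the
#'   four columns.
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
variantKey <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

## run code with a local RNG stream; the caller's .Random.seed is restored
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## percentage displayed to one decimal via an intermediate two-decimal
## rounding (half-up at both steps), the display chain of spreadsheet-
## derived clinical reports: 7/13 -> 53.85 -> 53.9
roundPercent <- function(x) {
  p2 <- floor(x * 100 + 0.5)
  floor(p2 / 10 + 0.5) / 10
}

## sample-column helpers for the wide variant-table layout
depthCol <- function(sample) paste0(sample, ".depth")
altCol <- function(sample) paste0(sample, ".alt")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
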