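#' Read variant positions from a VCF
#'
#' Extracts the site positions of population variants from a VCF file (plain
#' or bgzipped). Genotypes are ignored: only the set of segregating positions
#' matters for the SNP-density track. A multi-allelic record contributes one
#' position and duplicate records are collapsed.
#'
#' @param path Path to a VCF file.
#' @param genome Optional `ref_genome` (or tibble with a `chrom` column) used
#'   to filter records: positions on chromosomes absent from the index are
#'   dropped with a warning reporting the count.
#' @param snps_only If `TRUE` (default), only single-nucleotide records are
#'   kept (REF of length 1 and at least one single-base ALT); indels are
#'   dropped. Set to `FALSE` to count every variant record as a position.
#' @return A tibble with columns `chrom` and `pos` (0-based), sorted and
#'   unique, positions strictly increasing within each chromosome.
#' @export
read_variant_positions <- function(path, genome = NULL, snps_only = TRUE) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort_format("unreadable VCF %s: %s", path, conditionMessage(e))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer()))
  }
  tbl <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos1 = suppressWarnings(as.integer(fix[, "POS"])),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"])
  )
  if (anyNA(tbl$pos1)) abort_format("VCF %s: non-numeric POS field", path)
  if (snps_only) {
    alt_has_snv <- vapply(
      strsplit(ifelse(is.na(tbl$alt), "", tbl$alt), ",", fixed = TRUE),
      function(a) any(nchar(a) == 1L & a %in% DNA_BASES),
      logical(1)
    )
    tbl <- tbl[nchar(tbl$ref) == 1L & alt_has_snv, ]
  }
  if (!is.null(genome)) {
    known <- if (inherits(genome, "ref_genome")) genome$index$chrom else genome$chrom
    stray <- !(tbl$chrom %in% known)
    if (any(stray)) {
      warn(sprintf("dropped %d VCF record(s) on %d chromosome(s) not in the genome index",
                   sum(stray), length(unique(tbl$chrom[stray]))))
      tbl <- tbl[!stray, ]
    }
  }
  tbl |>
    mutate(pos = .data$pos1 - 1L) |>
    distinct(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos)
}
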