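#' Default chromosome lengths (NCBI m37, Mb)
#'
#' Lengths of the 19 mouse autosomes and the X chromosome in megabases on
#' the NCBI m37 (mm9) assembly.  All interval arithmetic in the package is
#' carried out in Mb on these coordinates.  The mitochondrial genome and
#' chromosome Y are not tracked anywhere in the package: the marker panels
#' used for line-status calls carry no informative SNPs for them.
#'
#' @param chroms optional character vector restricting the table to a subset
#'   of chromosomes (in the order given).
#' @return data.frame with columns `chrom` (character, "1".."19", "X") and
#'   `length_mb` (numeric).
#' @export
#' @examples
#' head(m37_chrom_lengths())
#' sum(m37_chrom_lengths()$length_mb)  # ~2639 Mb tracked genome
m37_chrom_lengths <- function(chroms = NULL) {
  bp <- c(
    "1" = 197195432, "2" = 181748087, "3" = 159599783, "4" = 155630120,
    "5" = 152537259, "6" = 149517037, "7" = 152524553, "8" = 131738871,
    "9" = 124076172, "10" = 129993255, "11" = 121843856, "12" = 121257530,
    "13" = 120284312, "14" = 125194864, "15" = 103494974, "16" = 98319150,
    "17" = 95272651, "18" = 90772031, "19" = 61342430, "X" = 166650296
  )
  tab <- data.frame(chrom = names(bp), length_mb = unname(bp) / 1e6,
                    stringsAsFactors = FALSE)
  if (!is.null(chroms)) {
    miss <- setdiff(chroms, tab$chrom)
    if (length(miss) > 0L)
      stop("unknown chromosome(s): ", paste(miss, collapse = ", "))
    tab <- tab[match(chroms, tab$chrom), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Validate a chromosome-length table
#'
#' @param chrom_lengths data.frame with columns `chrom` and `length_mb`.
#' @return the table, normalized (chrom as character, no duplicates).
#' @keywords internal
validate_chrom_lengths <- function(chrom_lengths) {
  stopifnot(is.data.frame(chrom_lengths),
            all(c("chrom", "length_mb") %in% names(chrom_lengths)))
  chrom_lengths$chrom <- as.character(chrom_lengths$chrom)
  if (anyDuplicated(chrom_lengths$chrom))
    stop("duplicated chromosome in chrom_lengths")
  if (any(!is.finite(chrom_lengths$length_mb)) ||
      any(chrom_lengths$length_mb <= 0))
    stop("chromosome lengths must be positive and finite")
  if (any(chrom_lengths$chrom %in% c("Y", "M", "MT")))
    stop("chromosome Y and the mitochondrial genome are not tracked")
  chrom_lengths
}

chrom_len <- function(chrom_lengths, chrom) {
  i <- match(chrom, chrom_lengths$chrom)
  if (anyNA(i)) stop("chromosome not in length table: ",
                     paste(chrom[is.na(i)], collapse = ", "))
  chrom_lengths$length_mb[i]
}
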