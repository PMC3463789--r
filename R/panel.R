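#' Biallelic SNP marker panel with founder alleles
#'
#' A `marker_panel` describes the genotyping array: one row per marker with
#' its chromosome, position in Mb (NCBI m37 coordinates), and the allele
#' (0 = A-allele, 1 = B-allele, NA = no call) carried by each of the eight
#' founder strains A..H.  The single-letter codes follow the standard
#' convention: A/J = A, C57BL/6J = B, 129S1/SvImJ = C, NOD/ShiLtJ = D,
#' NZO/H1LtJ = E, CAST/EiJ = F, PWK/PhJ = G, WSB/EiJ = H.
#'
#' Markers are sorted internally by (chromosome, position), so downstream
#' results do not depend on the row order of the input file.  A marker is
#' *informative* when both alleles are present among the founders with a
#' call.
#'
#' @param df data.frame with columns `marker`, `chrom`, `pos_mb` and the
#'   eight founder columns `A`..`H` (values 0, 1 or NA).
#' @param chrom_order optional character vector fixing chromosome order;
#'   defaults to autosomes 1..19 then X, with unknown chromosomes last.
#' @return object of class `marker_panel` (a data.frame with an
#'   `informative` logical column added).
#' @export
marker_panel <- function(df, chrom_order = NULL) {
  need <- c("marker", "chrom", "pos_mb", LETTERS[1:8])
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("marker panel lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$marker <- as.character(df$marker)
  df$chrom <- as.character(df$chrom)
  df$pos_mb <- as.numeric(df$pos_mb)
  for (f in LETTERS[1:8]) {
    v <- df[[f]]
    if (is.character(v)) v[v == "N"] <- NA
    df[[f]] <- as.integer(v)
    if (!all(df[[f]] %in% c(0L, 1L, NA)))
      stop("founder ", f, " alleles must be 0, 1 or N")
  }
  if (anyDuplicated(df$marker)) stop("duplicated marker ids")
  if (any(df$pos_mb < 0)) stop("negative marker position")
  if (is.null(chrom_order))
    chrom_order <- c(as.character(1:19), "X")
  lev <- c(chrom_order, setdiff(unique(df$chrom), chrom_order))
  df <- df[order(match(df$chrom, lev), df$pos_mb), , drop = FALSE]
  dup <- unlist(tapply(df$pos_mb, factor(df$chrom, levels = unique(df$chrom)),
                       function(p) c(FALSE, diff(p) <= 0), simplify = FALSE))
  if (any(dup))
    stop("marker positions must be strictly increasing within a chromosome")
  al <- as.matrix(df[, LETTERS[1:8]])
  n0 <- rowSums(al == 0L, na.rm = TRUE)
  n1 <- rowSums(al == 1L, na.rm = TRUE)
  df$informative <- n0 > 0L & n1 > 0L
  rownames(df) <- NULL
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>", nrow(x), "markers on",
      length(unique(x$chrom)), "chromosomes;",
      sum(x$informative), "informative\n")
  invisible(x)
}

#' Read / write a founder allele table
#'
#' CSV dialect: header `marker,chrom,pos_mb,A,B,C,D,E,F,G,H`, alleles in
#' \{0, 1, N\}.
#'
#' @param path file path.
#' @return `read_founder_panel` returns a [marker_panel()].
#' @export
read_founder_panel <- function(path) {
  if (!file.exists(path)) stop("founder panel file not found: ", path)
  marker_panel(utils::read.csv(path, colClasses = "character"))
}

#' @rdname read_founder_panel
#' @param panel a [marker_panel()].
#' @export
write_founder_panel <- function(panel, path) {
  out <- as.data.frame(panel)[, c("marker", "chrom", "pos_mb", LETTERS[1:8])]
  for (f in LETTERS[1:8]) {
    v <- as.character(out[[f]]); v[is.na(v)] <- "N"; out[[f]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a genotype call table
#'
#' CSV dialect: first column `marker`, one column per animal, calls in
#' \{0, 1, 2, N\} counting B-alleles.  In memory, calls are an integer
#' matrix (markers x animals, NA for no-call) whose rows are aligned to a
#' [marker_panel()] by marker id.
#'
#' @param path file path.
#' @param panel optional [marker_panel()] to align rows against (fatal if
#'   the marker sets differ).
#' @return integer matrix with rownames = marker ids, colnames = animal ids.
#' @export
read_genotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (names(df)[1] != "marker") stop("first genotype column must be 'marker'")
  g <- as.matrix(df[, -1, drop = FALSE])
  g[g == "N"] <- NA
  mode(g) <- "integer"
  rownames(g) <- df$marker
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    stop("genotype calls must be 0, 1, 2 or N")
  if (!is.null(panel)) g <- align_genotypes(g, panel)
  g
}

#' @rdname read_genotypes
#' @param geno genotype matrix as returned by `read_genotypes`.
#' @export
write_genotypes <- function(geno, path) {
  out <- as.data.frame(geno)
  for (j in seq_along(out)) {
    v <- as.character(out[[j]]); v[is.na(v)] <- "N"; out[[j]] <- v
  }
  out <- cbind(marker = rownames(geno), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

align_genotypes <- function(geno, panel) {
  i <- match(panel$marker, rownames(geno))
  if (anyNA(i))
    stop("genotype table does not cover the marker panel (",
         sum(is.na(i)), " markers missing)")
  geno[i, , drop = FALSE]
}
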