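# Line-level merge of the obligate ancestors' mosaics: segregating regions
# within and between ancestors, the "consistently inconsistent" fixed
# override, maximum residual heterozygosity, and line classification.

empty_regions <- function() {
  data.frame(chrom = character(0), start_mb = numeric(0),
             end_mb = numeric(0), founders = character(0),
             stringsAsFactors = FALSE)
}

# merge overlapping/touching regions per chromosome, unioning founder sets
merge_regions <- function(regions) {
  if (nrow(regions) == 0L) return(empty_regions())
  out <- lapply(split(regions, regions$chrom), function(r) {
    m <- merge_intervals(data.frame(start = r$start_mb, end = r$end_mb,
                                    founders = r$founders,
                                    stringsAsFactors = FALSE))
    data.frame(chrom = r$chrom[1L], start_mb = m$start, end_mb = m$end,
               founders = m$founders, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(match(res$chrom, unique(regions$chrom)), res$start_mb), ,
      drop = FALSE]
}

check_estimated <- function(m) {
  if (!isTRUE(attr(m, "breakpoints_estimated")))
    stop("mosaic must first go through estimate_breakpoints()")
}

# expected genotype of a mosaic at given markers (NA where a founder is
# untyped; male X segments give 2 x the single founder's allele)
predicted_genotype <- function(m, panel, idx) {
  pred <- rep(NA_integer_, length(idx))
  pos <- panel$pos_mb[idx]
  chroms <- panel$chrom[idx]
  al <- as.matrix(as.data.frame(panel)[, LETTERS[1:8]])
  for (chrom in unique(chroms)) {
    sel <- chroms == chrom
    seg <- m[m$chrom == chrom, , drop = FALSE]
    if (nrow(seg) == 0L) next
    si <- findInterval(pos[sel], seg$start_mb)
    si[si < 1L] <- 1L
    f1 <- seg$founder1[si]; f2 <- seg$founder2[si]
    i_mark <- idx[sel]
    a1 <- al[cbind(i_mark, match(f1, LETTERS[1:8]))]
    if (all(is.na(f2))) pred[sel] <- 2L * a1
    else pred[sel] <- a1 + al[cbind(i_mark, match(f2, LETTERS[1:8]))]
  }
  pred
}

#' Segregating regions within one ancestor
#'
#' Every heterozygous-state segment of the mosaic becomes a candidate
#' segregating region whose boundaries are tightened to the outermost
#' heterozygous genotype calls inside it (ambiguous heterozygous regions
#' within an ancestor begin and end at the closest heterozygous call).  A
#' heterozygous segment containing no heterozygous call is dropped with a
#' warning (the reconstruction and the genotypes disagree); a single call
#' gives a zero-length region, which is also dropped.
#'
#' @param m a `cc_mosaic` with estimated breakpoints.
#' @param calls genotype vector for the same animal, aligned to `panel`.
#' @param panel a [marker_panel()].
#' @return region data.frame `chrom`, `start_mb`, `end_mb`, `founders`.
#' @export
within_ancestor_segregating <- function(m, calls, panel) {
  check_estimated(m)
  if (length(calls) != nrow(panel))
    stop("genotype vector and marker panel have different lengths")
  het <- which(!is.na(m$founder1) & !is.na(m$founder2) &
                 m$founder1 != m$founder2)
  out <- empty_regions()
  for (i in het) {
    sel <- panel$chrom == m$chrom[i] &
      panel$pos_mb >= m$start_mb[i] & panel$pos_mb < m$end_mb[i] &
      !is.na(calls) & calls == 1L
    pos <- panel$pos_mb[sel]
    if (length(pos) == 0L) {
      warning("heterozygous segment ", m$chrom[i], ":", m$start_mb[i], "-",
              m$end_mb[i], " contains no heterozygous call; dropped")
      next
    }
    if (max(pos) <= min(pos)) next
    out <- rbind(out, data.frame(
      chrom = m$chrom[i], start_mb = min(pos), end_mb = max(pos),
      founders = founder_union(m$founder1[i], m$founder2[i]),
      stringsAsFactors = FALSE))
  }
  merge_regions(out)
}

#' Segregating regions between ancestors
#'
#' Overlays two or more mosaics (for the most recent obligate ancestor
#' pair: four autosomal haplotypes, three X haplotypes -- the dam's two
#' plus the sire's one).  Any interval where the pooled haplotypes carry
#' two or more distinct founders becomes a segregating region; boundaries
#' are snapped outward to the nearest informative marker flanking the
#' discordance (ambiguous heterozygous regions between ancestors begin and
#' end at the nearest informative genotype), or to the chromosome end if
#' none exists.  Overlapping or touching regions are merged with founder
#' sets unioned.
#'
#' @param mosaics list of `cc_mosaic` objects on a common panel, with
#'   estimated breakpoints.
#' @param panel the shared [marker_panel()].
#' @return region data.frame `chrom`, `start_mb`, `end_mb`, `founders`.
#' @export
between_ancestor_segregating <- function(mosaics, panel) {
  stopifnot(length(mosaics) >= 2L)
  fp <- panel_fingerprint(panel)
  for (m in mosaics) {
    check_estimated(m)
    if (!identical(attr(m, "panel_fingerprint"), fp))
      stop("mosaics were reconstructed on a different marker panel")
  }
  cl <- attr(mosaics[[1L]], "chrom_lengths")
  out <- empty_regions()
  for (chrom in unique(panel$chrom)) {
    segs <- lapply(mosaics, function(m) m[m$chrom == chrom, , drop = FALSE])
    if (any(vapply(segs, nrow, 0L) == 0L)) next
    breaks <- sort(unique(c(0, unlist(lapply(segs, `[[`, "end_mb")))))
    iv <- atomic_intervals(breaks)
    mid <- (iv$start + iv$end) / 2
    fset <- vector("list", nrow(iv))
    for (s in segs) {
      si <- findInterval(mid, s$start_mb); si[si < 1L] <- 1L
      fset <- Map(c, fset, s$founder1[si], s$founder2[si])
    }
    nfound <- vapply(fset, function(x) length(unique(x[!is.na(x)])), 0L)
    disc <- nfound >= 2L
    if (!any(disc)) next
    r <- rle(disc)
    e <- cumsum(r$lengths); s0 <- c(1L, e[-length(e)] + 1L)
    info_pos <- panel$pos_mb[panel$chrom == chrom & panel$informative]
    len <- chrom_len(cl, chrom)
    for (k in which(r$values)) {
      a <- iv$start[s0[k]]; b <- iv$end[e[k]]
      left <- info_pos[info_pos <= a]
      right <- info_pos[info_pos >= b]
      a2 <- if (length(left)) max(left) else 0
      b2 <- if (length(right)) min(right) else len
      founders <- sort(unique(unlist(fset[s0[k]:e[k]])))
      founders <- founders[!is.na(founders)]
      out <- rbind(out, data.frame(
        chrom = chrom, start_mb = a2, end_mb = b2,
        founders = paste(founders, collapse = ""), stringsAsFactors = FALSE))
    }
  }
  merge_regions(out)
}

#' Reclassify consistently inconsistent regions as fixed
#'
#' When the observed genotype calls disagree with the founder-table
#' prediction of the assigned haplotype in the same way, at `k` or more
#' consecutive informative markers, in every genotyped ancestor (identical
#' calls across the animals throughout the run), the discordance is taken
#' to be a feature of the line's haplotype -- a private variant relative
#' to the founder reference -- rather than residual segregation, and the
#' region is treated as fixed.
#'
#' @param regions candidate segregating regions.
#' @param geno genotype matrix whose columns are the genotyped ancestors.
#' @param panel a [marker_panel()].
#' @param mosaics named list of the ancestors' `cc_mosaic`s (names matching
#'   `geno` columns) used for the founder-table prediction.
#' @param k minimum run length of identical-discordance informative
#'   markers (default 3; runs shorter than this are indistinguishable from
#'   genotyping error).
#' @return list with `segregating` (regions kept) and `overridden`
#'   (regions reclassified as fixed).
#' @export
apply_fixed_override <- function(regions, geno, panel, mosaics, k = 3L) {
  stopifnot(k >= 2L)
  geno <- align_genotypes(geno, panel)
  anc <- colnames(geno)
  stopifnot(all(anc %in% names(mosaics)))
  if (nrow(regions) == 0L)
    return(list(segregating = regions, overridden = empty_regions()))
  drop <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    idx <- which(panel$chrom == regions$chrom[i] &
                   panel$pos_mb >= regions$start_mb[i] &
                   panel$pos_mb < regions$end_mb[i] & panel$informative)
    if (length(idx) < k) next
    obs <- geno[idx, anc, drop = FALSE]
    qual <- rep(TRUE, length(idx))
    # identical non-missing calls across all ancestors
    qual <- qual & apply(obs, 1L, function(x)
      !anyNA(x) && length(unique(x)) == 1L)
    for (a in anc) {
      pred <- predicted_genotype(mosaics[[a]], panel, idx)
      qual <- qual & !is.na(pred) & !is.na(obs[, a]) & obs[, a] != pred
    }
    r <- rle(qual)
    if (any(r$values & r$lengths >= k)) drop[i] <- TRUE
  }
  list(segregating = regions[!drop, , drop = FALSE],
       overridden = regions[drop, , drop = FALSE])
}

#' Maximum residual heterozygosity of a line
#'
#' The genomic length of all segregating regions divided by the full
#' tracked genome length (19 autosomes + X by default), as a percentage.
#' Overlapping regions are unioned first.
#'
#' @param regions region data.frame (`chrom`, `start_mb`, `end_mb`).
#' @param chrom_lengths chromosome-length table; its total is the
#'   denominator.
#' @return percentage in [0, 100].
#' @export
residual_heterozygosity <- function(regions, chrom_lengths) {
  chrom_lengths <- validate_chrom_lengths(chrom_lengths)
  if (nrow(regions) == 0L) return(0)
  bad <- !(regions$chrom %in% chrom_lengths$chrom)
  if (any(bad))
    stop("region on untracked chromosome: ",
         paste(unique(regions$chrom[bad]), collapse = ", "))
  lens <- chrom_len(chrom_lengths, regions$chrom)
  if (any(regions$start_mb < 0) || any(regions$end_mb > lens + 1e-9))
    stop("region outside chromosome bounds")
  merged <- merge_regions(regions)
  seg_mb <- sum(merged$end_mb - merged$start_mb)
  100 * seg_mb / sum(chrom_lengths$length_mb)
}

#' Classify a line from its residual heterozygosity
#'
#' Lines are declared complete at >= 98% homozygosity and distributable at
#' >= 90% homozygosity (boundaries inclusive: "reached").
#'
#' @param het_percent residual heterozygosity in [0, 100].
#' @return "complete", "distributable" or "in_progress".
#' @export
classify_line <- function(het_percent) {
  if (!is.finite(het_percent) || het_percent < 0 || het_percent > 100)
    stop("het_percent must lie in [0, 100]")
  homozygosity <- 100 - het_percent
  if (homozygosity >= 98) "complete"
  else if (homozygosity >= 90) "distributable"
  else "in_progress"
}

#' Build the line-genome tiling of fixed and segregating regions
#'
#' Combines the ancestors' mosaics with the final segregating regions into
#' the line haplotype: fixed segments carry the single founder letter all
#' haplotypes agree on; segregating regions carry the set of founders
#' still segregating; regions removed by the fixed override are emitted as
#' fixed with the lexicographically smallest founder of their set as
#' representative (the calls there match none of the founder predictions
#' exactly).  Together the segments tile every tracked chromosome.
#'
#' @param mosaics list of the ancestors' `cc_mosaic`s (breakpoints
#'   estimated).
#' @param regions final segregating regions.
#' @param chrom_lengths chromosome-length table.
#' @param overridden regions reclassified as fixed by
#'   [apply_fixed_override()] (optional).
#' @return object of class `cc_line_genome`: data.frame `chrom`,
#'   `start_mb`, `end_mb`, `status` ("fixed"/"segregating"), `founders`.
#' @export
build_line_genome <- function(mosaics, regions, chrom_lengths,
                              overridden = NULL) {
  chrom_lengths <- validate_chrom_lengths(chrom_lengths)
  for (m in mosaics) check_estimated(m)
  if (is.null(overridden)) overridden <- empty_regions()
  regions <- merge_regions(regions)
  rows <- list()
  for (ci in seq_len(nrow(chrom_lengths))) {
    chrom <- chrom_lengths$chrom[ci]
    len <- chrom_lengths$length_mb[ci]
    seg_c <- regions[regions$chrom == chrom, , drop = FALSE]
    ovr_c <- overridden[overridden$chrom == chrom, , drop = FALSE]
    if (nrow(seg_c) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start_mb = seg_c$start_mb, end_mb = seg_c$end_mb,
        status = "segregating", founders = seg_c$founders,
        stringsAsFactors = FALSE)
    if (nrow(ovr_c) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start_mb = ovr_c$start_mb, end_mb = ovr_c$end_mb,
        status = "fixed",
        founders = substr(ovr_c$founders, 1L, 1L),
        stringsAsFactors = FALSE)
    taken <- rbind(seg_c[, c("start_mb", "end_mb")],
                   ovr_c[, c("start_mb", "end_mb")])
    fixed_iv <- complement_intervals(
      data.frame(start = taken$start_mb, end = taken$end_mb), len)
    if (nrow(fixed_iv) == 0L) next
    segs <- lapply(mosaics, function(m) m[m$chrom == chrom, , drop = FALSE])
    segs <- segs[vapply(segs, nrow, 0L) > 0L]
    for (fi in seq_len(nrow(fixed_iv))) {
      a <- fixed_iv$start[fi]; bnd <- fixed_iv$end[fi]
      cuts <- sort(unique(c(a, bnd,
                            unlist(lapply(segs, function(s)
                              s$end_mb[s$end_mb > a & s$end_mb < bnd])))))
      iv <- atomic_intervals(cuts)
      mid <- (iv$start + iv$end) / 2
      lab <- rep(NA_character_, nrow(iv))
      for (s in segs) {
        si <- findInterval(mid, s$start_mb); si[si < 1L] <- 1L
        f <- cbind(s$founder1[si], s$founder2[si])
        piece <- apply(f, 1L, function(x) {
          u <- unique(x[!is.na(x)])
          if (length(u) > 1L) "!" else if (length(u) == 1L) u else NA
        })
        conflict <- !is.na(lab) & !is.na(piece) & lab != piece
        if (any(piece == "!", na.rm = TRUE) || any(conflict))
          stop("ancestors fixed for different founders outside any ",
               "segregating region on chromosome ", chrom,
               " (upstream inconsistency)")
        lab[is.na(lab)] <- piece[is.na(lab)]
      }
      r <- rle(lab)
      e <- cumsum(r$lengths); s0 <- c(1L, e[-length(e)] + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start_mb = iv$start[s0], end_mb = iv$end[e],
        status = "fixed", founders = r$values, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(match(out$chrom, chrom_lengths$chrom), out$start_mb), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cc_line_genome", "data.frame")
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

#' Write a line genome as the distributable-line haplotype text file
#'
#' TSV with columns `chrom`, `start_mb`, `end_mb`, `status`
#' (fixed/segregating) and `founders` (one letter, or the sorted
#' concatenation of the founders still segregating, e.g. "DG").
#'
#' @param lg a `cc_line_genome`.
#' @param path output file.
#' @export
write_line_genome <- function(lg, path) {
  utils::write.table(as.data.frame(lg), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Line status report
#'
#' @param line_id line name.
#' @param het_percent maximum residual heterozygosity (percent).
#' @param ancestors data.frame row with `sire`, `dam`, `generation`.
#' @param chrom_lengths chromosome-length table used.
#' @param n_regions number of segregating regions.
#' @param segregating_mb total segregating length in Mb.
#' @return object of class `cc_line_status` (named list) with fields
#'   `line_id`, `het_percent`, `homozygosity_percent`, `status`,
#'   `ancestors`, `genome_length_mb`, `segregating_mb`, `n_regions`.
#' @export
line_status_report <- function(line_id, het_percent, ancestors,
                               chrom_lengths, n_regions, segregating_mb) {
  structure(list(
    line_id = line_id,
    het_percent = het_percent,
    homozygosity_percent = 100 - het_percent,
    status = classify_line(het_percent),
    ancestors = ancestors,
    genome_length_mb = sum(chrom_lengths$length_mb),
    segregating_mb = segregating_mb,
    n_regions = n_regions
  ), class = "cc_line_status")
}

#' @export
print.cc_line_status <- function(x, ...) {
  cat(sprintf("<line %s> %s: homozygosity %.2f%% (residual het %.2f%%), %d segregating region(s), %.1f Mb\n",
              x$line_id, x$status, x$homozygosity_percent, x$het_percent,
              x$n_regions, x$segregating_mb))
  cat("  most recent obligate ancestors:", x$ancestors$sire, "x",
      x$ancestors$dam, "(generation", paste0(x$ancestors$generation, ")\n"))
  invisible(x)
}
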