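# Diplotype hidden Markov model over the eight founder haplotypes.
#
# Autosomes (and the female X) are decoded over the 36 unordered founder
# pairs (8 homozygous + 28 heterozygous states); the male X over the 8
# haploid founder states.  Emissions model a per-allele miscall rate eps;
# transitions charge each haplotype switch between adjacent markers a
# probability q/7 where q = 1 - exp(-r * d) for inter-marker distance d Mb
# and per-haplotype switch rate r per Mb.  Decoding is Viterbi with ties
# broken toward the lexicographically smaller state, so results are
# deterministic.

autosomal_states <- function() {
  out <- character(0)
  for (i in 1:8) for (j in i:8)
    out <- c(out, paste0(LETTERS[i], LETTERS[j]))
  out
}

state_founders <- function(states) {
  cbind(substr(states, 1L, 1L), substr(states, nchar(states), nchar(states)))
}

# number of haplotype switches (0/1/2) between unordered founder pairs
switch_count_matrix <- function(states) {
  sf <- state_founders(states)
  n <- length(states)
  K <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- sf[i, ]; b <- sf[j, ]
    shared <- sum(pmin(table(factor(a, LETTERS[1:8])),
                       table(factor(b, LETTERS[1:8]))))
    K[i, j] <- length(a) - shared
  }
  K
}

.hmm_cache <- new.env(parent = emptyenv())

get_state_space <- function(haploid = FALSE) {
  key <- if (haploid) "hap" else "dip"
  if (is.null(.hmm_cache[[key]])) {
    states <- if (haploid) LETTERS[1:8] else autosomal_states()
    sf <- if (haploid) cbind(states, states) else state_founders(states)
    K <- if (haploid) outer(states, states, `!=`) * 1L
    else switch_count_matrix(states)
    .hmm_cache[[key]] <- list(states = states, sf = sf, K = K,
                              ploidy = if (haploid) 1L else 2L)
  }
  .hmm_cache[[key]]
}

#' HMM parameters for haplotype reconstruction
#'
#' @param eps per-allele genotyping error rate (0 < eps < 0.5);
#'   default 0.002.
#' @param r per-haplotype switch rate per Mb (default 0.005, i.e. tens of
#'   expected recombinations genome-wide accumulated over funnel breeding
#'   and inbreeding).
#' @return named list of class `hmm_params`.
#' @export
hmm_params <- function(eps = 0.002, r = 0.005) {
  stopifnot(eps > 0, eps < 0.5, r > 0)
  structure(list(eps = eps, r = r), class = "hmm_params")
}

# P(observed call | true genotype): rows true 0/1/2, cols obs 0/1/2
call_error_table <- function(eps) {
  rbind(c((1 - eps)^2, 2 * eps * (1 - eps), eps^2),
        c(eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps)),
        c(eps^2, 2 * eps * (1 - eps), (1 - eps)^2))
}

#' Emission probability of one genotype call
#'
#' Probability of observing `call` at a marker given a diplotype state,
#' under independent per-allele miscalls at rate `eps`.  A missing call
#' (`NA`/"N") emits probability 1; a state involving a founder with no
#' allele call at the marker is uninformative there and also emits 1.  On
#' the male X the state is a single founder letter and heterozygous calls
#' are treated as missing.
#'
#' @param call genotype call: 0, 1 or 2 B-alleles, or NA.
#' @param state two founder letters, e.g. "AH" (order irrelevant), or one
#'   letter for the male X.
#' @param marker one row of a [marker_panel()].
#' @param eps per-allele error rate in (0, 0.5).
#' @return numeric probability.
#' @export
#' @examples
#' pan <- marker_panel(data.frame(marker = "m1", chrom = "1", pos_mb = 1,
#'   A = 0, B = 1, C = 0, D = 1, E = 0, F = 1, G = 0, H = 1))
#' emission_probability(0, "AA", pan[1, ], eps = 0.01)  # (1 - 0.01)^2
emission_probability <- function(call, state, marker, eps) {
  stopifnot(eps > 0, eps < 0.5)
  if (is.character(call) && call == "N") call <- NA
  if (is.na(call)) return(1)
  call <- as.integer(call)
  stopifnot(call %in% 0:2)
  f <- strsplit(state, "")[[1L]]
  stopifnot(all(f %in% LETTERS[1:8]), length(f) %in% 1:2)
  al <- vapply(f, function(x) as.integer(marker[[x]]), integer(1))
  if (anyNA(al)) return(1)
  if (length(f) == 1L) {  # male X, hemizygous
    if (call == 1L) return(1)
    obs <- call %/% 2L
    return(if (obs == al) 1 - eps else eps)
  }
  call_error_table(eps)[sum(al) + 1L, call + 1L]
}

# log-emission matrix (markers x states) for one chromosome
emission_logmat <- function(calls, alleles, sp, eps) {
  n <- length(calls)
  S <- length(sp$states)
  if (sp$ploidy == 2L) {
    a1 <- alleles[, match(sp$sf[, 1L], LETTERS[1:8]), drop = FALSE]
    a2 <- alleles[, match(sp$sf[, 2L], LETTERS[1:8]), drop = FALSE]
    implied <- a1 + a2                       # n x S, NA if founder untyped
    et <- log(call_error_table(eps))
    E <- matrix(0, n, S)
    obs_ok <- !is.na(calls)
    for (s in seq_len(S)) {
      use <- obs_ok & !is.na(implied[, s])
      E[use, s] <- et[cbind(implied[use, s] + 1L, calls[use] + 1L)]
    }
  } else {
    implied <- alleles[, match(sp$states, LETTERS[1:8]), drop = FALSE]
    calls_x <- calls
    calls_x[!is.na(calls_x) & calls_x == 1L] <- NA  # het call on male X
    obs <- calls_x %/% 2L
    E <- matrix(0, n, S)
    obs_ok <- !is.na(obs)
    for (s in seq_len(S)) {
      use <- obs_ok & !is.na(implied[, s])
      E[use, s] <- ifelse(obs[use] == implied[use, s], log(1 - eps), log(eps))
    }
  }
  list(E = E, implied = implied)
}

# Viterbi over one chromosome.  E: n x S log emissions; K: S x S switch
# counts; q: per-gap switch probabilities (length n-1).  Ties go to the
# smallest state index (states are ordered lexicographically).
viterbi_path <- function(E, K, q, ploidy) {
  n <- nrow(E); S <- ncol(E)
  if (n == 1L) return(which.max(E[1L, ]))
  back <- matrix(0L, n, S)
  V <- E[1L, ]
  sS <- seq_len(S)
  for (i in 2:n) {
    a <- log(q[i - 1L] / 7)
    b <- log1p(-q[i - 1L])
    # K is symmetric, so work row-wise directly: cand[t, s] = V[s] + trans
    cand <- matrix(V, S, S, byrow = TRUE) + (a - b) * K
    idx <- max.col(cand, ties.method = "first")
    V <- cand[cbind(sS, idx)] + b * ploidy + E[i, ]
    back[i, ] <- idx
  }
  path <- integer(n)
  path[n] <- which.max(V)
  for (i in n:2) path[i - 1L] <- back[i, path[i]]
  path
}

#' Reconstruct one animal's founder-haplotype mosaic
#'
#' Runs the diplotype HMM chromosome by chromosome on one animal's
#' genotype calls and collapses the maximum-a-posteriori (Viterbi) state
#' path into segments.  The male X is decoded over the 8 haploid founder
#' states.  Segment coordinates initially span the first to last marker of
#' each Viterbi run; use [estimate_breakpoints()] to place boundaries at
#' midpoints of the flanking informative markers and to extend the first
#' and last segments to the chromosome ends.
#'
#' @param calls integer vector of genotype calls (0/1/2/NA B-allele counts)
#'   aligned to `panel` rows, or a 1-column matrix with marker rownames.
#' @param panel a [marker_panel()].
#' @param sex "male" or "female" (controls X decoding).
#' @param params an [hmm_params()].
#' @param chrom_lengths chromosome-length table covering the panel's
#'   chromosomes (default [m37_chrom_lengths()] restricted to them).
#' @return object of class `cc_mosaic`: data.frame `chrom`, `start_mb`,
#'   `end_mb`, `founder1`, `founder2` (NA on male X), `support` (number of
#'   informative non-missing calls in the segment), `flag` ("" or
#'   "low_confidence"/"no_data"); attribute `boundaries` records, for each
#'   internal segment boundary, the flanking informative marker positions.
#' @export
reconstruct_mosaic <- function(calls, panel, sex = "female",
                               params = hmm_params(),
                               chrom_lengths = NULL) {
  stopifnot(inherits(panel, "marker_panel"), sex %in% c("male", "female"))
  animal <- NULL
  if (is.matrix(calls)) {
    stopifnot(ncol(calls) == 1L)
    animal <- colnames(calls)
    calls <- align_genotypes(calls, panel)[, 1L]
  }
  if (length(calls) != nrow(panel))
    stop("genotype vector and marker panel have different lengths")
  if (is.null(chrom_lengths))
    chrom_lengths <- m37_chrom_lengths(unique(panel$chrom))
  chrom_lengths <- validate_chrom_lengths(chrom_lengths)

  allele_mat <- as.matrix(as.data.frame(panel)[, LETTERS[1:8]])
  segs <- list(); bounds <- list()
  for (chrom in unique(panel$chrom)) {
    idx <- which(panel$chrom == chrom)
    haploid <- chrom == "X" && sex == "male"
    sp <- get_state_space(haploid)
    cc <- calls[idx]
    em <- emission_logmat(cc, allele_mat[idx, , drop = FALSE], sp, params$eps)
    pos <- panel$pos_mb[idx]
    usable <- !is.na(cc) & panel$informative[idx]
    if (!any(usable)) {
      segs[[chrom]] <- data.frame(
        chrom = chrom, start_mb = pos[1L], end_mb = pos[length(pos)],
        founder1 = NA_character_, founder2 = NA_character_,
        support = 0L, flag = "no_data", stringsAsFactors = FALSE)
      next
    }
    q <- 1 - exp(-params$r * diff(pos))
    path <- viterbi_path(em$E, sp$K, q, sp$ploidy)
    r <- rle(path)
    seg_end <- cumsum(r$lengths)
    seg_start <- c(1L, seg_end[-length(seg_end)] + 1L)
    st <- sp$states[r$values]
    flag <- if (sum(usable) < 2L) "low_confidence" else ""
    f1 <- substr(st, 1L, 1L)
    f2 <- if (haploid) NA_character_ else substr(st, 2L, 2L)
    support <- vapply(seq_along(st), function(k)
      sum(usable[seg_start[k]:seg_end[k]]), integer(1))
    segs[[chrom]] <- data.frame(
      chrom = chrom, start_mb = pos[seg_start], end_mb = pos[seg_end],
      founder1 = f1, founder2 = f2, support = support, flag = flag,
      stringsAsFactors = FALSE)
    if (length(st) > 1L) {
      bl <- lapply(seq_len(length(st) - 1L), function(k) {
        s1 <- r$values[k]; s2 <- r$values[k + 1L]
        disting <- !is.na(em$implied[, s1]) & !is.na(em$implied[, s2]) &
          em$implied[, s1] != em$implied[, s2] & !is.na(cc)
        li <- which(disting[seq_len(seg_end[k])])
        ri <- which(disting) ; ri <- ri[ri >= seg_start[k + 1L]]
        data.frame(
          chrom = chrom, after_segment = k,
          left_pos = if (length(li)) pos[max(li)] else NA_real_,
          right_pos = if (length(ri)) pos[min(ri)] else NA_real_,
          stringsAsFactors = FALSE)
      })
      bounds[[chrom]] <- do.call(rbind, bl)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out,
            boundaries = if (length(bounds)) do.call(rbind, c(bounds, list(make.row.names = FALSE))) else NULL,
            chrom_lengths = chrom_lengths,
            panel_fingerprint = panel_fingerprint(panel),
            animal = animal, sex = sex, breakpoints_estimated = FALSE,
            class = c("cc_mosaic", "data.frame"))
}

panel_fingerprint <- function(panel) {
  paste(nrow(panel), panel$marker[1L], panel$marker[nrow(panel)],
        signif(sum(panel$pos_mb), 12), sep = ":")
}

#' Place recombination breakpoints at midpoints of ambiguous intervals
#'
#' Each boundary between two Viterbi segments is ambiguous between the last
#' marker informative for the flanking state pair on the left and the first
#' such marker on the right; the breakpoint is placed at the arithmetic
#' midpoint of those two positions.  An ambiguous interval that runs off a
#' chromosome end puts the boundary at the chromosome end.  First and last
#' segments are extended to 0 and to the configured chromosome length.
#'
#' @param m a `cc_mosaic` from [reconstruct_mosaic()].
#' @return the mosaic with segment coordinates tiling each chromosome
#'   exactly; attribute `boundaries` gains a `breakpoint` column.
#' @export
estimate_breakpoints <- function(m) {
  stopifnot(inherits(m, "cc_mosaic"))
  cl <- attr(m, "chrom_lengths")
  b <- attr(m, "boundaries")
  if (!is.null(b)) {
    b$breakpoint <- (b$left_pos + b$right_pos) / 2
    b$breakpoint[is.na(b$left_pos)] <- 0
    b$breakpoint[is.na(b$right_pos)] <-
      chrom_len(cl, b$chrom[is.na(b$right_pos)])
  }
  out <- list()
  for (chrom in unique(m$chrom)) {
    seg <- m[m$chrom == chrom, , drop = FALSE]
    len <- chrom_len(cl, chrom)
    n <- nrow(seg)
    if (n > 1L) {
      bp <- b$breakpoint[b$chrom == chrom]
      bp <- cummax(pmin(pmax(bp, 0), len))   # enforce monotone boundaries
      seg$start_mb <- c(0, bp)
      seg$end_mb <- c(bp, len)
    } else {
      seg$start_mb <- 0
      seg$end_mb <- len
    }
    seg <- seg[seg$end_mb > seg$start_mb, , drop = FALSE]
    # squash any adjacent same-state segments left by dropped slivers
    if (nrow(seg) > 1L) {
      key <- paste(seg$founder1, seg$founder2)
      r <- rle(key)
      e <- cumsum(r$lengths); s <- c(1L, e[-length(e)] + 1L)
      seg2 <- seg[s, , drop = FALSE]
      seg2$end_mb <- seg$end_mb[e]
      seg2$support <- vapply(seq_along(s), function(k)
        sum(seg$support[s[k]:e[k]]), integer(1))
      seg <- seg2
    }
    out[[chrom]] <- seg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attributes(res)[c("boundaries", "chrom_lengths", "panel_fingerprint",
                    "animal", "sex")] <-
    attributes(m)[c("boundaries", "chrom_lengths", "panel_fingerprint",
                    "animal", "sex")]
  attr(res, "boundaries") <- b
  attr(res, "breakpoints_estimated") <- TRUE
  class(res) <- c("cc_mosaic", "data.frame")
  res
}

#' Reconstruct mosaics for a set of animals
#'
#' Convenience wrapper running [reconstruct_mosaic()] +
#' [estimate_breakpoints()] per animal.
#'
#' @param geno genotype matrix (markers x animals; see [read_genotypes()]).
#' @param panel a [marker_panel()].
#' @param sex_map named character vector id -> "male"/"female".
#' @inheritParams reconstruct_mosaic
#' @param ids animals to reconstruct (default: all columns of `geno`).
#' @return named list of `cc_mosaic` objects.
#' @export
reconstruct_animals <- function(geno, panel, sex_map, params = hmm_params(),
                                chrom_lengths = NULL, ids = colnames(geno)) {
  geno <- align_genotypes(geno, panel)
  out <- list()
  for (id in ids) {
    if (!id %in% colnames(geno)) stop("no genotypes for animal ", id)
    if (!id %in% names(sex_map)) stop("no sex recorded for animal ", id)
    m <- reconstruct_mosaic(geno[, id], panel, sex_map[[id]], params,
                            chrom_lengths)
    attr(m, "animal") <- id
    out[[id]] <- estimate_breakpoints(m)
  }
  out
}

#' Write a mosaic as BED-like TSV
#'
#' Columns `chrom`, `start_mb`, `end_mb`, `founder1`, `founder2`,
#' `support` (founder2 empty on the male X).
#'
#' @param m a `cc_mosaic`.
#' @param path output file.
#' @export
write_mosaic <- function(m, path) {
  out <- as.data.frame(m)[, c("chrom", "start_mb", "end_mb",
                              "founder1", "founder2", "support")]
  out$founder2[is.na(out$founder2)] <- ""
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
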