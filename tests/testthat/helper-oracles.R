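# Independent oracles and fixture builders used across the suite.

# ---- pedigree oracles -----------------------------------------------------

# transitive closure by repeated edge expansion (descendants oracle)
oracle_descendants <- function(ped, ids) {
  tab <- ped$tab
  reach <- ids
  repeat {
    kids <- tab$id[(tab$sire %in% reach) | (tab$dam %in% reach)]
    new <- setdiff(kids, reach)
    if (length(new) == 0L) break
    reach <- c(reach, new)
  }
  sort(setdiff(reach, ids))
}

# brute force over all matings, reachability tested with igraph on the
# parent->child DAG with the pair's offspring deleted
oracle_obligate_igraph <- function(ped, extant) {
  tab <- ped$tab
  edges <- rbind(cbind(tab$sire, tab$id), cbind(tab$dam, tab$id))
  edges <- edges[!is.na(edges[, 1L]), , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  founders <- tab$id[is.na(tab$sire)]
  desc_of <- function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = "out")), v)
  cand <- unique(tab[!is.na(tab$sire), c("sire", "dam")])
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$sire[i]; d <- cand$dam[i]
    if (s %in% founders || d %in% founders) next
    ds <- desc_of(s); dd <- desc_of(d)
    if (!all(extant %in% ds) || !all(extant %in% dd)) next
    off <- tab$id[!is.na(tab$sire) & tab$sire == s & tab$dam == d]
    g2 <- igraph::delete_vertices(g, off)
    src <- setdiff(extant, off)
    ok <- TRUE
    for (e in src) {
      up <- names(igraph::subcomponent(g2, e, mode = "in"))
      if (any(founders %in% up)) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  out$generation <- pmax(tab$generation[match(out$sire, tab$id)],
                         tab$generation[match(out$dam, tab$id)])
  out <- out[order(out$generation, out$sire, out$dam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# literal exhaustive enumeration of every ancestry path (small pedigrees)
enumerate_paths <- function(ped, id) {
  tab <- ped$tab
  i <- match(id, tab$id)
  if (is.na(tab$sire[i])) return(list(id))
  paths <- c(enumerate_paths(ped, tab$sire[i]),
             enumerate_paths(ped, tab$dam[i]))
  lapply(paths, function(p) c(id, p))
}

oracle_obligate_paths <- function(ped, extant) {
  tab <- ped$tab
  founders <- tab$id[is.na(tab$sire)]
  all_paths <- unlist(lapply(extant, enumerate_paths, ped = ped),
                      recursive = FALSE)
  cand <- unique(tab[!is.na(tab$sire), c("sire", "dam")])
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$sire[i]; d <- cand$dam[i]
    if (s %in% founders || d %in% founders) next
    off <- tab$id[!is.na(tab$sire) & tab$sire == s & tab$dam == d]
    through_s <- vapply(all_paths, function(p) s %in% p, logical(1))
    through_d <- vapply(all_paths, function(p) d %in% p, logical(1))
    through_off <- vapply(all_paths, function(p) any(off %in% p), logical(1))
    origin <- vapply(all_paths, `[[`, "", 1L)
    # every extant animal descends from both members ...
    desc_ok <- all(vapply(extant, function(e) {
      any(through_s[origin == e]) && any(through_d[origin == e]) &&
        !e %in% c(s, d)
    }, logical(1)))
    # ... and every path is blocked by the pair's offspring
    keep[i] <- desc_ok && all(through_off)
  }
  out <- cand[keep, , drop = FALSE]
  out$generation <- pmax(tab$generation[match(out$sire, tab$id)],
                         tab$generation[match(out$dam, tab$id)])
  out <- out[order(out$generation, out$sire, out$dam), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- heterozygosity oracles ----------------------------------------------

# per-position brute force on a grid (cell midpoints)
grid_het <- function(regions, chrom_lengths, step = 0.1) {
  tot <- 0L; het <- 0L
  for (i in seq_len(nrow(chrom_lengths))) {
    chrom <- chrom_lengths$chrom[i]
    n <- round(chrom_lengths$length_mb[i] / step)
    pos <- (seq_len(n) - 0.5) * step
    tot <- tot + n
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    if (nrow(r) == 0L) next
    inside <- vapply(pos, function(p)
      any(p >= r$start_mb & p < r$end_mb), logical(1))
    het <- het + sum(inside)
  }
  100 * het / tot
}

# sib-mating recurrence H_t = H_{t-1}/2 + H_{t-2}/4, iterated numerically;
# sib generation 0 is the eight-way F1 sibship (H = 1, and H_{-1} = 1)
sib_recurrence <- function(t_max) {
  H <- numeric(t_max + 1L)
  H[1L] <- 1
  if (t_max >= 1L) H[2L] <- 3 / 4
  if (t_max >= 2L) for (t in 2:t_max)
    H[t + 1L] <- H[t] / 2 + H[t - 1L] / 4
  H
}

# ---- fixture builders -----------------------------------------------------

small_chroms <- function(lens = c(60, 50, 40), x = TRUE) {
  chrom <- c(as.character(seq_len(length(lens) - as.integer(x))),
             if (x) "X")
  data.frame(chrom = chrom, length_mb = lens, stringsAsFactors = FALSE)
}

quick_cfg <- function(seed, n_sib = 6L, lens = c(60, 50, 40), x = TRUE,
                      spacing = 0.5, ...) {
  sim_config(n_sib_generations = n_sib,
             chrom_lengths = small_chroms(lens, x),
             marker_spacing_mb = spacing, seed = seed, ...)
}

# hand-built cc_mosaic (already "breakpoint-estimated") for linegenome tests
manual_mosaic <- function(df, chrom_lengths, fingerprint = "manual",
                          sex = "female") {
  df <- as.data.frame(df)
  if (is.null(df$support)) df$support <- 10L
  if (is.null(df$flag)) df$flag <- ""
  structure(df, chrom_lengths = chrom_lengths,
            panel_fingerprint = fingerprint, sex = sex,
            breakpoints_estimated = TRUE, boundaries = NULL,
            class = c("cc_mosaic", "data.frame"))
}

# panel with all eight founders distinct enough to be informative anywhere:
# alternate split patterns so every founder pair is distinguished somewhere
manual_panel <- function(chrom, positions, pattern = NULL) {
  n <- length(positions)
  base <- rbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  al <- base[rep(1:3, length.out = n), , drop = FALSE]
  if (!is.null(pattern)) al <- matrix(pattern, n, 8, byrow = TRUE)
  colnames(al) <- LETTERS[1:8]
  marker_panel(data.frame(marker = sprintf("m%04d", seq_len(n)),
                          chrom = chrom, pos_mb = positions,
                          as.data.frame(al)))
}

# fraction of genome length where a reconstructed mosaic matches the true
# diplotype (unordered founder pairs; haploid male X compared on founder1)
mosaic_match_fraction <- function(m, truth, chrom_lengths) {
  tot <- 0; match_len <- 0
  for (chrom in chrom_lengths$chrom) {
    len <- chrom_lengths$length_mb[chrom_lengths$chrom == chrom]
    a <- m[m$chrom == chrom, , drop = FALSE]
    b <- truth[truth$chrom == chrom, , drop = FALSE]
    cuts <- sort(unique(c(0, len, a$end_mb, b$end_mb)))
    cuts <- cuts[cuts <= len]
    iv <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
    mid <- (iv$start + iv$end) / 2
    ai <- findInterval(mid, a$start_mb); ai[ai < 1L] <- 1L
    bi <- findInterval(mid, b$start_mb); bi[bi < 1L] <- 1L
    key <- function(f1, f2) {
      ifelse(is.na(f2), f1,
             paste0(pmin(f1, f2), pmax(f1, f2)))
    }
    same <- !is.na(a$founder1[ai]) &
      key(a$founder1[ai], a$founder2[ai]) == key(b$founder1[bi], b$founder2[bi])
    tot <- tot + len
    match_len <- match_len + sum((iv$end - iv$start)[same])
  }
  match_len / tot
}

# founder pair of a truth mosaic at each marker of a panel
track_at_test <- function(truth, panel) {
  f1 <- character(nrow(panel)); f2 <- character(nrow(panel))
  for (chrom in unique(panel$chrom)) {
    sel <- panel$chrom == chrom
    tr <- truth[truth$chrom == chrom, , drop = FALSE]
    i <- findInterval(panel$pos_mb[sel], tr$start_mb); i[i < 1L] <- 1L
    f1[sel] <- tr$founder1[i]; f2[sel] <- tr$founder2[i]
  }
  data.frame(founder1 = f1, founder2 = f2, stringsAsFactors = FALSE)
}

# number of maximal intervals where the pooled haplotypes of `ids` carry
# >= 2 distinct founders (truth-side, for marker-resolution slack)
joint_tract_count <- function(sim, ids) {
  cl <- sim$config$chrom_lengths
  n <- 0L
  for (chrom in cl$chrom) {
    haps <- unlist(lapply(ids, function(a) sim$animals[[a]]$haplos[[chrom]]),
                   recursive = FALSE)
    breaks <- sort(unique(c(0, unlist(lapply(haps, function(h) h$end)))))
    if (length(breaks) < 2L) next
    mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
    lab <- vapply(haps, function(h)
      h$founder[pmax(findInterval(mid, h$start), 1L)], character(length(mid)))
    if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1L)
    disc <- apply(lab, 1L, function(x) length(unique(x)) >= 2L)
    r <- rle(disc)
    n <- n + sum(r$values)
  }
  n
}
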