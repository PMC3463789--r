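#' Configuration for the funnel-breeding simulator
#'
#' Describes one simulated recombinant inbred line bred on the eight-way
#' funnel design: four pairwise founder crosses (G1), two four-way crosses
#' (G2), one eight-way cross producing the first sibship, then
#' `n_sib_generations` of brother-sister matings (one breeding pair and a
#' sibship of two per generation).  Meioses place crossovers as a Poisson
#' process along each chromosome (no interference) at
#' `recomb_rate_per_mb`; the X chromosome follows sex-specific
#' transmission (sires pass their X intact to daughters only).
#' Chromosome Y and the mitochondrial genome are not simulated.
#'
#' @param n_sib_generations integer >= 0, number of sib-mating generations.
#' @param founder_order permutation of LETTERS[1:8]: founder letters at
#'   funnel positions 1..8 (odd positions are dams, even positions sires).
#' @param recomb_rate_per_mb expected crossovers per Mb per meiosis
#'   (default 0.005, i.e. ~0.5 cM/Mb).
#' @param genotyping_error per-allele miscall probability (default 0.002).
#' @param missing_rate per-call no-call probability (default 0.02).
#' @param marker_spacing_mb spacing of the simulated marker panel
#'   (default 0.35 Mb, giving a MUGA-scale panel on the full genome).
#' @param chrom_lengths chromosome-length table (default [m37_chrom_lengths()]).
#' @param n_arms 1 for a pure chain, 2 to split the line into two parallel
#'   breeding arms at `split_generation`.
#' @param split_generation sib generation at which a 2-arm line splits
#'   (default: halfway).
#' @param line_id line name used in pedigree rows and animal ids.
#' @param seed integer seed; all randomness in the simulator derives from it.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_sib_generations = 10L,
                       founder_order = LETTERS[1:8],
                       recomb_rate_per_mb = 0.005,
                       genotyping_error = 0.002,
                       missing_rate = 0.02,
                       marker_spacing_mb = 0.35,
                       chrom_lengths = m37_chrom_lengths(),
                       n_arms = 1L,
                       split_generation = NULL,
                       line_id = "SIM001",
                       seed = 1L) {
  stopifnot(n_sib_generations >= 0,
            setequal(founder_order, LETTERS[1:8]),
            recomb_rate_per_mb >= 0,
            genotyping_error >= 0, genotyping_error < 1,
            missing_rate >= 0, missing_rate < 1,
            marker_spacing_mb > 0,
            n_arms %in% c(1L, 2L))
  chrom_lengths <- validate_chrom_lengths(chrom_lengths)
  if (is.null(split_generation))
    split_generation <- max(1L, ceiling(n_sib_generations / 2))
  structure(list(
    n_sib_generations = as.integer(n_sib_generations),
    founder_order = founder_order,
    recomb_rate_per_mb = recomb_rate_per_mb,
    genotyping_error = genotyping_error,
    missing_rate = missing_rate,
    marker_spacing_mb = marker_spacing_mb,
    chrom_lengths = chrom_lengths,
    n_arms = as.integer(n_arms),
    split_generation = as.integer(split_generation),
    line_id = line_id,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# ---- haplotypes -----------------------------------------------------------
# A haplotype is a data.frame(start, end, founder) tiling [0, L) in Mb.

single_founder_hap <- function(founder, len) {
  data.frame(start = 0, end = len, founder = founder,
             stringsAsFactors = FALSE)
}

clip_hap <- function(h, a, b) {
  keep <- h$end > a & h$start < b
  h <- h[keep, , drop = FALSE]
  h$start <- pmax(h$start, a)
  h$end <- pmin(h$end, b)
  h
}

squash_hap <- function(h) {
  if (nrow(h) <= 1L) { rownames(h) <- NULL; return(h) }
  r <- rle(h$founder)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- data.frame(start = h$start[starts], end = h$end[ends],
                    founder = r$values, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# One meiotic product of the two parental haplotypes on one chromosome.
make_gamete <- function(h1, h2, len, rate) {
  n_xo <- stats::rpois(1L, rate * len)
  xo <- sort(stats::runif(n_xo, 0, len))
  cur <- sample.int(2L, 1L)
  bounds <- c(0, xo, len)
  pieces <- vector("list", length(bounds) - 1L)
  haps <- list(h1, h2)
  for (i in seq_along(pieces)) {
    pieces[[i]] <- clip_hap(haps[[cur]], bounds[i], bounds[i + 1L])
    cur <- 3L - cur
  }
  squash_hap(do.call(rbind, pieces))
}

# Founder label of a haplotype at positions `pos`.
hap_founder_at <- function(h, pos) track_at(h, pos, "founder")

# ---- the simulator --------------------------------------------------------

#' Simulate a funnel-bred recombinant inbred line
#'
#' Produces the full pedigree, the true founder-haplotype mosaic of every
#' animal, a marker panel, and noisy genotype calls for all animals, so the
#' reconstruction and line-classification machinery can be validated
#' against known truth.  Identical seeds give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return object of class `cc_funnel_sim`: list with elements `config`,
#'   `panel` ([marker_panel()]), `pedigree` ([cc_pedigree()]), `animals`
#'   (named list; each has `id`, `sex`, `generation` and `haplos`, a
#'   per-chromosome list of 1 or 2 haplotype data.frames), `genotypes`
#'   (marker x animal integer matrix) and `extant` (ids of the final
#'   sibship(s)).
#' @export
simulate_funnel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- make_marker_panel(cfg)
  set.seed(cfg$seed)

  cl <- cfg$chrom_lengths
  autosomes <- cl$chrom[cl$chrom != "X"]
  has_x <- "X" %in% cl$chrom
  rate <- cfg$recomb_rate_per_mb
  animals <- list()
  ped_rows <- list()

  add_animal <- function(id, sire, dam, sex, generation, haplos) {
    animals[[id]] <<- list(id = id, sex = sex, generation = generation,
                           haplos = haplos)
    ped_rows[[length(ped_rows) + 1L]] <<- data.frame(
      id = id, sire = ifelse(is.null(sire), "", sire),
      dam = ifelse(is.null(dam), "", dam), sex = sex,
      generation = generation, line = cfg$line_id,
      stringsAsFactors = FALSE)
  }

  founder_hap <- function(letter) {
    h <- lapply(seq_len(nrow(cl)), function(i)
      list(single_founder_hap(letter, cl$length_mb[i])))
    names(h) <- cl$chrom
    h
  }

  # G0: eight founders at funnel positions; odd positions dams, even sires
  founder_ids <- paste0(cfg$line_id, "_F", seq_len(8L))
  for (i in seq_len(8L)) {
    letter <- cfg$founder_order[i]
    sex <- if (i %% 2L == 1L) "female" else "male"
    haplos <- founder_hap(letter)
    for (chrom in cl$chrom) {
      if (chrom == "X" && sex == "male") next
      haplos[[chrom]] <- c(haplos[[chrom]], haplos[[chrom]][1L])
    }
    add_animal(founder_ids[i], NULL, NULL, sex, 0L, haplos)
  }

  make_child <- function(id, sire_id, dam_id, sex, generation) {
    sire <- animals[[sire_id]]; dam <- animals[[dam_id]]
    haplos <- stats::setNames(vector("list", nrow(cl)), cl$chrom)
    for (chrom in autosomes) {
      len <- chrom_len(cl, chrom)
      hd <- make_gamete(dam$haplos[[chrom]][[1L]], dam$haplos[[chrom]][[2L]],
                        len, rate)
      hs <- make_gamete(sire$haplos[[chrom]][[1L]], sire$haplos[[chrom]][[2L]],
                        len, rate)
      haplos[[chrom]] <- list(hd, hs)
    }
    if (has_x) {
      len <- chrom_len(cl, "X")
      hx <- if (length(dam$haplos[["X"]]) == 2L)
        make_gamete(dam$haplos[["X"]][[1L]], dam$haplos[["X"]][[2L]], len, rate)
      else dam$haplos[["X"]][[1L]]
      haplos[["X"]] <- if (sex == "female")
        list(hx, sire$haplos[["X"]][[1L]])   # sire's X passed intact
      else list(hx)
    }
    add_animal(id, sire_id, dam_id, sex, generation, haplos)
    id
  }

  pfx <- function(...) paste0(cfg$line_id, "_", ...)
  # G1: four pairwise crosses; G2: two four-way crosses
  g1 <- character(4)
  g1_sex <- c("female", "male", "female", "male")
  for (k in seq_len(4L))
    g1[k] <- make_child(pfx("G1_", k), founder_ids[2L * k],
                        founder_ids[2L * k - 1L], g1_sex[k], 1L)
  g2_a <- make_child(pfx("G2_a"), g1[2L], g1[1L], "female", 2L)
  g2_b <- make_child(pfx("G2_b"), g1[4L], g1[3L], "male", 2L)

  # eight-way cross: first sibship (generation 3), then sib mating
  sibship <- c(make_child(pfx("G3_1"), g2_b, g2_a, "female", 3L),
               make_child(pfx("G3_2"), g2_b, g2_a, "male", 3L))
  arms <- list(main = sibship)
  for (t in seq_len(cfg$n_sib_generations)) {
    gen <- 3L + t
    split_now <- cfg$n_arms == 2L && t == cfg$split_generation &&
      length(arms) == 1L
    new_arms <- list()
    for (arm in names(arms)) {
      sib <- arms[[arm]]
      dam_id <- sib[1L]; sire_id <- sib[2L]
      n_kids <- if (split_now) 4L else 2L
      kids <- character(n_kids)
      for (k in seq_len(n_kids)) {
        sex <- if (k %% 2L == 1L) "female" else "male"
        kids[k] <- make_child(pfx("G", gen, "_", arm, k), sire_id, dam_id,
                              sex, gen)
      }
      if (split_now) {
        new_arms[["a"]] <- kids[1:2]
        new_arms[["b"]] <- kids[3:4]
      } else {
        new_arms[[arm]] <- kids
      }
    }
    arms <- new_arms
  }
  extant <- unlist(arms, use.names = FALSE)

  ped <- cc_pedigree(do.call(rbind, ped_rows))
  geno <- simulate_genotypes(animals, panel, cfg)
  structure(list(config = cfg, panel = panel, pedigree = ped,
                 animals = animals, genotypes = geno, extant = extant),
            class = "cc_funnel_sim")
}

#' @export
print.cc_funnel_sim <- function(x, ...) {
  cat("<cc_funnel_sim>", x$config$line_id, "-", length(x$animals),
      "animals,", x$config$n_sib_generations, "sib generations,",
      nrow(x$panel), "markers\n")
  invisible(x)
}

#' Build the simulated marker panel
#'
#' Markers are evenly spaced (`marker_spacing_mb`) along every tracked
#' chromosome, at positions (k - 1/2) x spacing; founder alleles are drawn
#' at random subject to every marker splitting the eight founders into two
#' non-empty groups, so every marker is informative.  Deterministic under
#' `cfg$seed`; the panel draw does not perturb the breeding random stream.
#'
#' @param cfg a [sim_config()].
#' @return a [marker_panel()].
#' @export
make_marker_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$seed %% 1000000007L) + 104729L)
  cl <- cfg$chrom_lengths
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    n <- max(1L, floor(cl$length_mb[i] / cfg$marker_spacing_mb))
    pos <- (seq_len(n) - 0.5) * cfg$marker_spacing_mb
    data.frame(chrom = cl$chrom[i], pos_mb = pos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  m <- nrow(df)
  al <- matrix(sample(c(0L, 1L), m * 8L, replace = TRUE), nrow = m)
  mono <- rowSums(al) %in% c(0L, 8L)
  if (any(mono)) {
    j <- sample.int(8L, sum(mono), replace = TRUE)
    al[cbind(which(mono), j)] <- 1L - al[cbind(which(mono), j)]
  }
  colnames(al) <- LETTERS[1:8]
  df <- cbind(marker = sprintf("S%05d", seq_len(m)), df,
              as.data.frame(al), stringsAsFactors = FALSE)
  marker_panel(df, chrom_order = cl$chrom)
}

# Noisy genotype calls for every animal on the panel.
simulate_genotypes <- function(animals, panel, cfg) {
  alleles <- as.matrix(as.data.frame(panel)[, LETTERS[1:8]])
  rownames(alleles) <- NULL
  m <- nrow(panel)
  ids <- names(animals)
  geno <- matrix(NA_integer_, nrow = m, ncol = length(ids),
                 dimnames = list(panel$marker, ids))
  by_chrom <- split(seq_len(m), factor(panel$chrom, unique(panel$chrom)))
  eps <- cfg$genotyping_error
  for (a in ids) {
    an <- animals[[a]]
    calls <- integer(m)
    for (chrom in names(by_chrom)) {
      idx <- by_chrom[[chrom]]
      pos <- panel$pos_mb[idx]
      haps <- an$haplos[[chrom]]
      f <- lapply(haps, hap_founder_at, pos = pos)
      a1 <- alleles[cbind(idx, match(f[[1L]], LETTERS[1:8]))]
      if (length(haps) == 2L) {
        a2 <- alleles[cbind(idx, match(f[[2L]], LETTERS[1:8]))]
        if (eps > 0) {
          flip1 <- stats::runif(length(idx)) < eps
          flip2 <- stats::runif(length(idx)) < eps
          a1 <- ifelse(flip1, 1L - a1, a1)
          a2 <- ifelse(flip2, 1L - a2, a2)
        }
        calls[idx] <- a1 + a2
      } else {
        # hemizygous X: the single allele is reported as a homozygous call
        if (eps > 0) {
          flip1 <- stats::runif(length(idx)) < eps
          a1 <- ifelse(flip1, 1L - a1, a1)
        }
        calls[idx] <- 2L * a1
      }
    }
    if (cfg$missing_rate > 0)
      calls[stats::runif(m) < cfg$missing_rate] <- NA_integer_
    geno[, a] <- calls
  }
  geno
}

# ---- truth oracles --------------------------------------------------------

#' True heterozygosity of simulated animals
#'
#' Exact, length-weighted percentage of the tracked genome at which the
#' relevant haplotype multiset carries two or more distinct founders.  For
#' a single animal that multiset is its own two haplotypes per autosome
#' (one on the male X, which therefore never counts as heterozygous); for a
#' male + female pair it is the joint four autosomal haplotypes and the
#' three X haplotypes (dam's two plus sire's one), i.e. the quantity the
#' line-status pipeline is trying to bound from genotypes.
#'
#' @param sim a `cc_funnel_sim`.
#' @param ids one animal id, or a vector of ids (a male+female pair or any
#'   larger set; all haplotypes are pooled).
#' @param chroms optional subset of chromosomes (default: all tracked).
#' @return percentage in [0, 100].
#' @export
true_heterozygosity <- function(sim, ids, chroms = NULL) {
  cl <- sim$config$chrom_lengths
  if (!is.null(chroms)) cl <- cl[cl$chrom %in% chroms, , drop = FALSE]
  het_mb <- 0
  for (i in seq_len(nrow(cl))) {
    chrom <- cl$chrom[i]
    haps <- unlist(lapply(ids, function(a) sim$animals[[a]]$haplos[[chrom]]),
                   recursive = FALSE)
    het_mb <- het_mb + hap_discord_length(haps)
  }
  100 * het_mb / sum(cl$length_mb)
}

# Total length over which >= 2 distinct founders occur among haplotypes.
hap_discord_length <- function(haps) {
  if (length(haps) < 2L) return(0)
  breaks <- sort(unique(c(0, unlist(lapply(haps, function(h) h$end)))))
  iv <- atomic_intervals(breaks)
  if (nrow(iv) == 0L) return(0)
  mid <- (iv$start + iv$end) / 2
  lab <- vapply(haps, hap_founder_at, character(nrow(iv)), pos = mid)
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1L)
  n_distinct <- apply(lab, 1L, function(x) length(unique(x)))
  sum((iv$end - iv$start)[n_distinct >= 2L])
}

#' True diplotype mosaic of one simulated animal
#'
#' Collapses the animal's two haplotypes (one on the male X) into the same
#' segment representation the reconstruction produces: unordered founder
#' pairs per interval.
#'
#' @param sim a `cc_funnel_sim`.
#' @param id animal id.
#' @return data.frame `chrom`, `start_mb`, `end_mb`, `founder1`, `founder2`
#'   (`founder2` is NA on the male X).
#' @export
true_diplotype <- function(sim, id) {
  an <- sim$animals[[id]]
  if (is.null(an)) stop("unknown animal id: ", id)
  cl <- sim$config$chrom_lengths
  out <- list()
  for (chrom in cl$chrom) {
    haps <- an$haplos[[chrom]]
    breaks <- sort(unique(c(0, unlist(lapply(haps, function(h) h$end)))))
    iv <- atomic_intervals(breaks)
    mid <- (iv$start + iv$end) / 2
    if (length(haps) == 2L) {
      f1 <- hap_founder_at(haps[[1L]], mid)
      f2 <- hap_founder_at(haps[[2L]], mid)
      lo <- pmin(f1, f2); hi <- pmax(f1, f2)
    } else {
      lo <- hap_founder_at(haps[[1L]], mid); hi <- NA_character_
    }
    df <- data.frame(chrom = chrom, start_mb = iv$start, end_mb = iv$end,
                     founder1 = lo, founder2 = hi, stringsAsFactors = FALSE)
    # merge runs with identical state
    key <- paste(df$founder1, df$founder2)
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- c(1L, ends[-length(ends)] + 1L)
    df <- data.frame(chrom = chrom, start_mb = df$start_mb[starts],
                     end_mb = df$end_mb[ends], founder1 = df$founder1[starts],
                     founder2 = df$founder2[starts], stringsAsFactors = FALSE)
    out[[chrom]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write simulator output to a directory
#'
#' Emits `pedigree.csv`, `panel.csv`, `genotypes.csv` and one
#' `truth_<animal>.tsv` mosaic file per animal, in the package's standard
#' text dialects.
#'
#' @param sim a `cc_funnel_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_founder_panel(sim$panel, file.path(dir, "panel.csv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.csv"))
  for (id in names(sim$animals)) {
    td <- true_diplotype(sim, id)
    utils::write.table(td, file.path(dir, paste0("truth_", id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
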