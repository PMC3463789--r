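# End-to-end orchestration: pedigree -> obligate ancestors -> haplotype
# reconstruction -> segregating-region merge -> override -> residual
# heterozygosity -> classification -> line haplotype file + JSON report.

#' Configuration for a pipeline run
#'
#' Inputs may be given as file paths (pedigree CSV, founder-panel CSV,
#' genotype CSV) or as the corresponding in-memory objects.
#'
#' @param pedigree path or [cc_pedigree()].
#' @param panel path or [marker_panel()].
#' @param geno path or genotype matrix (see [read_genotypes()]).
#' @param extant character vector of extant animal ids.
#' @param eps,r HMM parameters (see [hmm_params()]).
#' @param k fixed-override run length (see [apply_fixed_override()]).
#' @param chrom_lengths chromosome-length table; default
#'   [m37_chrom_lengths()] restricted to the panel's chromosomes.
#' @param denominator "chrom_lengths" (default) divides segregating length
#'   by the configured genome length; "marker_span" divides by the length
#'   spanned by the panel's outermost markers per chromosome.
#' @param out_dir output directory, or NULL to skip writing files.
#' @param line_id optional line name (default: taken from the pedigree).
#' @return object of class `cc_run_config`.
#' @export
run_config <- function(pedigree, panel, geno, extant,
                       eps = 0.002, r = 0.005, k = 3L,
                       chrom_lengths = NULL,
                       denominator = c("chrom_lengths", "marker_span"),
                       out_dir = NULL, line_id = NULL) {
  denominator <- match.arg(denominator)
  for (x in list(pedigree, panel, geno))
    if (is.character(x) && !file.exists(x))
      stop("input file not found: ", x)
  stopifnot(length(extant) >= 1L, eps > 0, eps < 0.5, r > 0, k >= 2L)
  structure(list(pedigree = pedigree, panel = panel, geno = geno,
                 extant = extant, eps = eps, r = r, k = as.integer(k),
                 chrom_lengths = chrom_lengths, denominator = denominator,
                 out_dir = out_dir, line_id = line_id),
            class = "cc_run_config")
}

cc_log <- function(stage, fmt, ...) {
  message(sprintf("[ccstatus %s] %s: %s",
                  format(Sys.time(), "%H:%M:%S"), stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  cc_log(stage, "done in %.2fs", proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full line-status pipeline
#'
#' Executes every stage for one line and, when `out_dir` is set, writes
#' `line_<id>.tsv` (the line haplotype file) and `report_<id>.json`.
#' Partial outputs are removed if a stage fails.  Given identical inputs
#' the outputs are byte-identical: nothing downstream of the (seeded)
#' simulator draws random numbers.
#'
#' @param cfg a [run_config()].
#' @return list with `report` (a `cc_line_status`), `line_genome`,
#'   `regions`, `overridden`, `mosaics`, `ancestors`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "cc_run_config"))
  ped <- run_stage("pedigree", {
    if (is.character(cfg$pedigree)) read_pedigree(cfg$pedigree)
    else cfg$pedigree
  })
  panel <- run_stage("panel", {
    if (is.character(cfg$panel)) read_founder_panel(cfg$panel)
    else cfg$panel
  })
  geno <- run_stage("genotypes", {
    g <- if (is.character(cfg$geno)) read_genotypes(cfg$geno) else cfg$geno
    align_genotypes(g, panel)
  })
  chrom_lengths <- if (is.null(cfg$chrom_lengths))
    m37_chrom_lengths(unique(panel$chrom)) else
      validate_chrom_lengths(cfg$chrom_lengths)

  mrca <- run_stage("ancestors", most_recent_obligate_ancestors(ped, cfg$extant))
  anc_ids <- c(mrca$sire, mrca$dam)
  cc_log("ancestors", "most recent obligate pair: %s x %s (generation %d)",
         mrca$sire, mrca$dam, mrca$generation)

  sex_map <- stats::setNames(ped$tab$sex, ped$tab$id)
  params <- hmm_params(eps = cfg$eps, r = cfg$r)
  mosaics <- run_stage("reconstruct",
    reconstruct_animals(geno, panel, sex_map, params, chrom_lengths,
                        ids = anc_ids))

  regions <- run_stage("segregating", {
    within <- lapply(anc_ids, function(a)
      within_ancestor_segregating(mosaics[[a]], geno[, a], panel))
    between <- between_ancestor_segregating(mosaics, panel)
    merge_regions(do.call(rbind, c(within, list(between))))
  })
  ovr <- run_stage("override",
    apply_fixed_override(regions, geno[, anc_ids, drop = FALSE], panel,
                         mosaics, k = cfg$k))

  denom <- if (cfg$denominator == "chrom_lengths") chrom_lengths else {
    spans <- tapply(panel$pos_mb, factor(panel$chrom, unique(panel$chrom)),
                    function(p) max(p) - min(p))
    data.frame(chrom = names(spans), length_mb = as.numeric(spans))
  }
  het <- run_stage("heterozygosity",
    residual_heterozygosity(ovr$segregating, denom))
  lg <- run_stage("line_genome",
    build_line_genome(mosaics, ovr$segregating, chrom_lengths,
                      ovr$overridden))

  line_id <- if (!is.null(cfg$line_id)) cfg$line_id else ped$line_id
  merged <- merge_regions(ovr$segregating)
  report <- line_status_report(
    line_id = line_id, het_percent = het, ancestors = mrca,
    chrom_lengths = denom, n_regions = nrow(merged),
    segregating_mb = if (nrow(merged)) sum(merged$end_mb - merged$start_mb) else 0)

  if (!is.null(cfg$out_dir)) {
    ok <- FALSE
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(cfg$out_dir, paste0("line_", line_id, ".tsv"))
    js <- file.path(cfg$out_dir, paste0("report_", line_id, ".json"))
    on.exit(if (!ok) unlink(c(tsv, js)), add = TRUE)
    write_line_genome(lg, tsv)
    write_status_json(report, js, n_markers = nrow(panel))
    ok <- TRUE
    cc_log("output", "wrote %s and %s", tsv, js)
  }
  list(report = report, line_genome = lg, regions = ovr$segregating,
       overridden = ovr$overridden, mosaics = mosaics, ancestors = mrca)
}

write_status_json <- function(report, path, n_markers = NULL) {
  x <- list(line_id = report$line_id,
            het_percent = report$het_percent,
            homozygosity_percent = report$homozygosity_percent,
            status = report$status,
            ancestors = list(sire = report$ancestors$sire,
                             dam = report$ancestors$dam,
                             generation = report$ancestors$generation),
            genome_length_mb = report$genome_length_mb,
            segregating_mb = report$segregating_mb,
            n_segregating_regions = report$n_regions)
  if (!is.null(n_markers)) x$n_markers <- n_markers
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Status table for a batch of lines
#'
#' Runs [run_pipeline()] per configuration and assembles the
#' "available lines"-style table: one row per line with homozygosity,
#' status, segregating Mb and region count, sorted by homozygosity
#' descending.  Per-line failures land in the `error` column and do not
#' stop the batch.
#'
#' @param cfgs nonempty list of [run_config()] objects.
#' @return data.frame `line_id`, `homozygosity_percent`, `status`,
#'   `segregating_mb`, `n_regions`, `error`.
#' @export
batch_report <- function(cfgs) {
  if (length(cfgs) == 0L) stop("empty configuration list")
  rows <- lapply(cfgs, function(cfg) {
    res <- tryCatch(run_pipeline(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      id <- if (!is.null(cfg$line_id)) cfg$line_id else NA_character_
      data.frame(line_id = id, homozygosity_percent = NA_real_,
                 status = NA_character_, segregating_mb = NA_real_,
                 n_regions = NA_integer_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      r <- res$report
      data.frame(line_id = r$line_id,
                 homozygosity_percent = r$homozygosity_percent,
                 status = r$status, segregating_mb = r$segregating_mb,
                 n_regions = r$n_regions, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-xtfrm(out$homozygosity_percent), out$line_id), , drop = FALSE]
}
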