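cl1 <- data.frame(chrom = "1", length_mb = 100)

test_that("within-ancestor regions are tightened to het calls", {
  pan <- manual_panel("1", c(5, 15, 22.1, 30, 37.9, 45, 55))
  m <- manual_mosaic(data.frame(
    chrom = "1", start_mb = c(0, 20, 40), end_mb = c(20, 40, 100),
    founder1 = c("B", "F", "B"), founder2 = c("B", "H", "B")),
    cl1, fingerprint = ccstatus:::panel_fingerprint(pan))
  calls <- c(0L, 0L, 1L, 0L, 1L, 0L, 0L)
  r <- within_ancestor_segregating(m, calls, pan)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_mb, 22.1)
  expect_equal(r$end_mb, 37.9)
  expect_equal(r$founders, "FH")

  # fully homozygous animal: no regions
  m0 <- manual_mosaic(data.frame(chrom = "1", start_mb = 0, end_mb = 100,
                                 founder1 = "B", founder2 = "B"), cl1)
  expect_equal(nrow(within_ancestor_segregating(m0, calls, pan)), 0L)

  # heterozygous segment without a single het call is dropped with warning
  expect_warning(
    r2 <- within_ancestor_segregating(m, rep(0L, 7), pan),
    "no heterozygous call")
  expect_equal(nrow(r2), 0L)
})

test_that("between-ancestor regions capture discordant haplotypes", {
  pan <- manual_panel("1", seq(10, 90, by = 10))
  fp <- ccstatus:::panel_fingerprint(pan)
  anc1 <- manual_mosaic(data.frame(chrom = "1", start_mb = 0, end_mb = 100,
                                   founder1 = "D", founder2 = "D"), cl1, fp)
  anc2 <- manual_mosaic(data.frame(
    chrom = "1", start_mb = c(0, 60, 80), end_mb = c(60, 80, 100),
    founder1 = c("D", "G", "D"), founder2 = c("D", "G", "D")), cl1, fp)
  r <- between_ancestor_segregating(list(anc1, anc2), pan)
  expect_equal(nrow(r), 1L)
  expect_equal(r$founders, "DG")
  # boundaries snapped to the nearest informative genotypes (60 and 80
  # are themselves marker positions here)
  expect_equal(r$start_mb, 60)
  expect_equal(r$end_mb, 80)

  # one ancestor homozygous, the other segregating
  anc3 <- manual_mosaic(data.frame(
    chrom = "1", start_mb = c(0, 30, 50), end_mb = c(30, 50, 100),
    founder1 = c("B", "B", "B"), founder2 = c("B", "E", "B")), cl1, fp)
  anc4 <- manual_mosaic(data.frame(chrom = "1", start_mb = 0, end_mb = 100,
                                   founder1 = "B", founder2 = "B"), cl1, fp)
  r2 <- between_ancestor_segregating(list(anc4, anc3), pan)
  expect_equal(r2$founders, "BE")
  expect_equal(r2$start_mb, 30)
  expect_equal(r2$end_mb, 50)

  # identical fully homozygous mosaics: nothing segregates
  expect_equal(nrow(between_ancestor_segregating(list(anc1, anc1), pan)), 0L)

  # boundaries between marker positions snap outward
  anc5 <- manual_mosaic(data.frame(
    chrom = "1", start_mb = c(0, 55), end_mb = c(55, 100),
    founder1 = c("D", "G"), founder2 = c("D", "G")), cl1, fp)
  r3 <- between_ancestor_segregating(list(anc1, anc5), pan)
  expect_equal(r3$start_mb, 50)
  expect_equal(r3$end_mb, 100)  # runs to the chromosome end

  # mismatched panels are fatal
  pan2 <- manual_panel("1", seq(5, 95, by = 10))
  expect_error(between_ancestor_segregating(list(anc1, anc2), pan2),
               "different marker panel")
})

test_that("X regions pool the dam's two haplotypes with the sire's one", {
  clx <- data.frame(chrom = "X", length_mb = 100)
  pan <- manual_panel("X", seq(10, 90, by = 10))
  fp <- ccstatus:::panel_fingerprint(pan)
  dam <- manual_mosaic(data.frame(chrom = "X", start_mb = 0, end_mb = 100,
                                  founder1 = "C", founder2 = "C"), clx, fp)
  sire <- manual_mosaic(data.frame(
    chrom = "X", start_mb = c(0, 40), end_mb = c(40, 100),
    founder1 = c("C", "E"), founder2 = NA_character_), clx, fp,
    sex = "male")
  r <- between_ancestor_segregating(list(dam, sire), pan)
  expect_equal(r$founders, "CE")
  expect_equal(r$start_mb, 40)
  # all three X haplotypes sharing one founder = fixed
  sire2 <- manual_mosaic(data.frame(chrom = "X", start_mb = 0, end_mb = 100,
                                    founder1 = "C", founder2 = NA_character_),
                         clx, fp, sex = "male")
  expect_equal(nrow(between_ancestor_segregating(list(dam, sire2), pan)), 0L)
})

test_that("consistently inconsistent regions are reclassified as fixed", {
  # markers every 2 Mb; D and G split 0/1 at every marker
  pos <- seq(2, 98, by = 2)
  pan <- manual_panel("1", pos, pattern = c(0, 1, 0, 1, 0, 1, 0, 1))
  fp <- ccstatus:::panel_fingerprint(pan)
  anc1 <- manual_mosaic(data.frame(chrom = "1", start_mb = 0, end_mb = 100,
                                   founder1 = "B", founder2 = "B"), cl1, fp)
  anc2 <- manual_mosaic(data.frame(
    chrom = "1", start_mb = c(0, 60, 80), end_mb = c(60, 80, 100),
    founder1 = c("B", "D", "B"), founder2 = c("B", "D", "B")), cl1, fp)
  regions <- data.frame(chrom = "1", start_mb = 60, end_mb = 80,
                        founders = "BD", stringsAsFactors = FALSE)
  # predictions in [60, 80): anc1 (B,B) -> 0; anc2 (D,D) -> 2.
  # identical call 1 in both ancestors at >= 5 consecutive markers
  # disagrees with both predictions -> a private variant of the line.
  g <- matrix(0L, nrow(pan), 2, dimnames = list(pan$marker, c("a1", "a2")))
  in_reg <- pos >= 60 & pos < 80
  g[in_reg, ] <- 1L
  ovr <- apply_fixed_override(regions, g, pan,
                              list(a1 = anc1, a2 = anc2), k = 3)
  expect_equal(nrow(ovr$segregating), 0L)
  expect_equal(nrow(ovr$overridden), 1L)

  # discordance in only one ancestor is not "consistent"
  g2 <- g; g2[in_reg, 1] <- 0L
  ovr2 <- apply_fixed_override(regions, g2, pan,
                               list(a1 = anc1, a2 = anc2), k = 3)
  expect_equal(nrow(ovr2$segregating), 1L)
  expect_equal(nrow(ovr2$overridden), 0L)

  # k larger than any run length: no-op
  ovr3 <- apply_fixed_override(regions, g, pan,
                               list(a1 = anc1, a2 = anc2), k = 50)
  expect_equal(ovr3$segregating, regions)
})

test_that("residual heterozygosity is the segregating fraction", {
  cl <- data.frame(chrom = as.character(1:25), length_mb = rep(100, 25))
  expect_equal(residual_heterozygosity(ccstatus:::empty_regions(), cl), 0)
  one <- data.frame(chrom = "1", start_mb = 0, end_mb = 100, founders = "AB")
  expect_equal(residual_heterozygosity(one, cl), 4.0)
  # overlapping regions are unioned first
  two <- rbind(one, data.frame(chrom = "1", start_mb = 50, end_mb = 100,
                               founders = "AC"))
  expect_equal(residual_heterozygosity(two, cl), 4.0)
  expect_error(residual_heterozygosity(
    data.frame(chrom = "1", start_mb = 50, end_mb = 150, founders = "AB"), cl),
    "outside chromosome bounds")
  expect_error(residual_heterozygosity(
    data.frame(chrom = "Z", start_mb = 0, end_mb = 1, founders = "AB"), cl),
    "untracked chromosome")

  # monotone: adding a region never lowers the estimate
  set.seed(99)
  regions <- ccstatus:::empty_regions()
  last <- 0
  for (i in 1:20) {
    chrom <- sample(cl$chrom, 1)
    a <- runif(1, 0, 90)
    regions <- rbind(regions, data.frame(chrom = chrom, start_mb = a,
                                         end_mb = a + runif(1, 0, 10),
                                         founders = "AB"))
    now <- residual_heterozygosity(regions, cl)
    expect_gte(now, last)
    last <- now
  }

  # grid brute force agrees exactly when boundaries sit on the 0.1 grid
  set.seed(100)
  regions <- data.frame(chrom = sample(cl$chrom, 30, replace = TRUE),
                        start_mb = round(runif(30, 0, 60), 1))
  regions$end_mb <- regions$start_mb + round(runif(30, 0.5, 30), 1)
  regions$founders <- "DG"
  expect_equal(residual_heterozygosity(regions, cl),
               grid_het(regions, cl), tolerance = 1e-12)
})

test_that("classification thresholds are inclusive at 90 and 98", {
  expect_equal(classify_line(2.0), "complete")
  expect_equal(classify_line(10.0), "distributable")
  expect_equal(classify_line(0.0), "complete")
  expect_equal(classify_line(10.0 + 1e-9), "in_progress")
  expect_equal(classify_line(100), "in_progress")
  expect_error(classify_line(-0.1), "\\[0, 100\\]")
  expect_error(classify_line(100.5), "\\[0, 100\\]")
})

test_that("the line genome tiles the chromosomes and flags contradictions", {
  pan <- manual_panel("1", seq(10, 90, by = 10))
  fp <- ccstatus:::panel_fingerprint(pan)
  # Fig-2a-like chromosome: two segregating regions, remainder fixed
  anc1 <- manual_mosaic(data.frame(
    chrom = "1", start_mb = c(0, 20, 30, 70, 80),
    end_mb = c(20, 30, 70, 80, 100),
    founder1 = c("B", "B", "B", "B", "B"),
    founder2 = c("B", "E", "B", "H", "B")), cl1, fp)
  anc2 <- manual_mosaic(data.frame(chrom = "1", start_mb = 0, end_mb = 100,
                                   founder1 = "B", founder2 = "B"), cl1, fp)
  regions <- between_ancestor_segregating(list(anc1, anc2), pan)
  expect_equal(nrow(regions), 2L)
  lg <- build_line_genome(list(anc1, anc2), regions, cl1)
  expect_s3_class(lg, "cc_line_genome")
  expect_equal(sum(lg$end_mb - lg$start_mb), 100)
  expect_equal(sort(unique(lg$status)), c("fixed", "segregating"))
  expect_equal(lg$founders[lg$status == "fixed"], rep("B", 3))
  expect_equal(sum(lg$status == "segregating"), 2L)
  # overridden regions come back as fixed with a representative founder
  ovr <- data.frame(chrom = "1", start_mb = 20, end_mb = 30, founders = "BE")
  lg2 <- build_line_genome(list(anc1, anc2), regions[2, ], cl1,
                           overridden = ovr)
  expect_equal(lg2$founders[lg2$start_mb == 20], "B")
  expect_equal(lg2$status[lg2$start_mb == 20], "fixed")

  # ancestors fixed for different founders with no segregating region: bug
  anc3 <- manual_mosaic(data.frame(chrom = "1", start_mb = 0, end_mb = 100,
                                   founder1 = "A", founder2 = "A"), cl1, fp)
  expect_error(build_line_genome(list(anc2, anc3),
                                 ccstatus:::empty_regions(), cl1),
               "different founders")
})

test_that("line genome matches truth on a simulated fixed line", {
  sim <- simulate_funnel(quick_cfg(31, n_sib = 25, genotyping_error = 0,
                                   missing_rate = 0))
  cl <- sim$config$chrom_lengths
  sex <- setNames(sim$pedigree$tab$sex, sim$pedigree$tab$id)
  mrca <- most_recent_obligate_ancestors(sim$pedigree, sim$extant)
  anc <- c(mrca$sire, mrca$dam)
  mos <- reconstruct_animals(sim$genotypes, sim$panel, sex,
                             chrom_lengths = cl, ids = anc)
  betw <- between_ancestor_segregating(mos, sim$panel)
  with1 <- within_ancestor_segregating(mos[[1]], sim$genotypes[, anc[1]],
                                       sim$panel)
  with2 <- within_ancestor_segregating(mos[[2]], sim$genotypes[, anc[2]],
                                       sim$panel)
  regions <- ccstatus:::merge_regions(rbind(betw, with1, with2))
  lg <- build_line_genome(mos, regions, cl)
  # tiling: fixed + segregating lengths = genome length exactly
  expect_equal(sum(lg$end_mb - lg$start_mb), sum(cl$length_mb))
  # after 25 generations the line is essentially fixed; where it is, the
  # assigned founder must match the simulated truth
  truth <- true_diplotype(sim, sim$extant[1])
  fixed <- lg[lg$status == "fixed", ]
  agree <- 0; tot <- 0
  for (i in seq_len(nrow(fixed))) {
    tr <- truth[truth$chrom == fixed$chrom[i], ]
    mid <- (fixed$start_mb[i] + fixed$end_mb[i]) / 2
    j <- findInterval(mid, tr$start_mb); j <- max(j, 1)
    tot <- tot + 1
    if (!is.na(fixed$founders[i]) && tr$founder1[j] == fixed$founders[i])
      agree <- agree + 1
  }
  expect_gt(agree / tot, 0.95)
})
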