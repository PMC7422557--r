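test_that("TADs are the in-arm complement of boundary regions", {
  layout <- genome_layout("chr1p", "chr1", 0, 1e6)
  b <- data.frame(chrom = "chr1", start = 400000, end = 450000)
  tads <- tads_from_boundaries(b, layout)
  expect_equal(tads$start, c(0, 450000))
  expect_equal(tads$end, c(400000, 1e6))

  # a boundary covering the whole arm leaves no TADs
  b2 <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  expect_equal(nrow(tads_from_boundaries(b2, layout)), 0)

  # two boundaries give three intervals; overlapping ones are merged
  b3 <- data.frame(chrom = "chr1", start = c(200000, 240000, 700000),
                   end = c(250000, 260000, 710000))
  tads3 <- tads_from_boundaries(b3, layout)
  expect_equal(nrow(tads3), 3)
  # union of TADs, boundaries (merged) and gaps covers the arm exactly
  covered <- sum(tads3$end - tads3$start) + (260000 - 200000) + 10000
  expect_equal(covered, 1e6)

  # gap intervals are excluded too
  gaps <- data.frame(chrom = "chr1", start = 0, end = 100000)
  tads4 <- tads_from_boundaries(b, layout, gaps = gaps)
  expect_equal(tads4$start[1], 100000)
})

test_that("DI sign inversions are located at run changes, zeros skipped", {
  di <- data.frame(chrom = "chr1", start = c(0, 25000, 50000, 75000),
                   end = c(25000, 50000, 75000, 100000),
                   value = c(1, 1, -1, -1))
  inv <- find_negative_inversions(di)
  expect_equal(inv$pos, 50000)

  # (-,+) is a positive inversion (a boundary), not a negative one
  di2 <- data.frame(chrom = "chr1", start = c(0, 25000),
                    end = c(25000, 50000), value = c(-1, 1))
  expect_equal(nrow(find_negative_inversions(di2)), 0)
  expect_equal(find_inversions(di2, "positive")$pos, 25000)

  # zero bins do not break a run; the coordinate is the run-gap midpoint
  di3 <- data.frame(chrom = "chr1", start = c(0, 25000, 50000),
                    end = c(25000, 50000, 75000), value = c(1, 0, -1))
  expect_equal(find_negative_inversions(di3)$pos, 37500)

  # all-zero track yields nothing
  di4 <- transform(di, value = 0)
  expect_equal(nrow(find_negative_inversions(di4)), 0)
})

test_that("negative and positive inversions alternate along a track", {
  set.seed(21)
  di <- data.frame(chrom = "chr1",
                   start = seq(0, 99) * 25000,
                   end = seq(1, 100) * 25000,
                   value = rnorm(100))
  neg <- find_negative_inversions(di)
  pos <- find_inversions(di, "positive")
  both <- rbind(data.frame(pos = neg$pos, kind = "n"),
                data.frame(pos = pos$pos, kind = "p"))
  both <- both[order(both$pos), ]
  expect_true(all(both$kind[-1] != both$kind[-nrow(both)]))
})

test_that("TADs split at the negative inversion into DI sections", {
  tad <- data.frame(chrom = "chr1", start = 0, end = 100000)
  di <- data.frame(chrom = "chr1", start = 0:3 * 25000, end = 1:4 * 25000,
                   value = c(1, 1, 1, -1))
  sec <- split_sections(tad, di)
  expect_equal(sec$kind, c("positive_DI", "negative_DI"))
  expect_equal(sec$end[1] - sec$start[1], 75000)
  expect_equal(sec$end[2] - sec$start[2], 25000)

  # symmetric DI -> equal halves
  di2 <- data.frame(chrom = "chr1", start = 0:3 * 25000, end = 1:4 * 25000,
                    value = c(1, 1, -1, -1))
  sec2 <- split_sections(tad, di2)
  expect_equal(sec2$end[1] - sec2$start[1], sec2$end[2] - sec2$start[2])

  # no interior inversion: a single unsplit section, with a message
  di3 <- data.frame(chrom = "chr1", start = 0:3 * 25000, end = 1:4 * 25000,
                    value = c(1, 1, 1, 1))
  expect_message(sec3 <- split_sections(tad, di3), "unsplit")
  expect_equal(sec3$kind, "unsplit")
})

test_that("anchored profiles average item counts per fixed-width bin", {
  anchors <- data.frame(chrom = "chr1", pos = c(1e6, 2e6, 3e6))
  items <- data.frame(chrom = "chr1", pos = c(1e6, 2e6, 3e6))
  prof <- anchored_density_profile(anchors, items, flank = 50000, bin = 10000)
  expect_equal(sum(prof$profile), 1)          # total mass 1
  expect_equal(unname(prof$profile[6, "all"]), 1)  # all in the central bin
  # no items within the flank: all-zero profile
  far <- data.frame(chrom = "chr1", pos = 9e6)
  prof2 <- anchored_density_profile(anchors, far, flank = 50000, bin = 10000)
  expect_true(all(prof2$profile == 0))
  # minus-strand anchors flip the axis
  anchors2 <- data.frame(chrom = "chr1", pos = 1e6, strand = "-")
  items2 <- data.frame(chrom = "chr1", pos = 1e6 + 15000)
  prof3 <- anchored_density_profile(anchors2, items2, flank = 50000,
                                    bin = 10000)
  expect_equal(which(prof3$profile > 0), 4)   # offset -15 kb after flip
  expect_error(anchored_density_profile(anchors[0, ], items, 50000, 10000),
               "no anchors")
})

test_that("meta-domain profiles bin on the relative 0..1 axis", {
  dom <- data.frame(chrom = "chr1", start = 0, end = 100000)
  item <- data.frame(chrom = "chr1", pos = 30000)  # 30% into the domain
  mp <- meta_domain_profile(dom, item, n_bins = 100)
  expect_equal(which(mp[, "all"] > 0), 31)  # bin covering [30%, 31%)
  expect_equal(sum(mp), 1)

  # forward sites only in the left half -> forward cline left, zero right
  doms <- data.frame(chrom = "chr1", start = 0:9 * 1e6, end = 1:10 * 1e6)
  set.seed(4)
  left <- data.frame(chrom = "chr1",
                     pos = rep(doms$start, each = 20) +
                       runif(200, 0, 5e5), orientation = ">")
  right <- data.frame(chrom = "chr1",
                      pos = rep(doms$start, each = 20) +
                        runif(200, 5e5, 1e6), orientation = "<")
  mp2 <- meta_domain_profile(doms, rbind(left, right), n_bins = 10,
                             stratify = "orientation")
  expect_true(all(mp2[6:10, ">"] == 0))
  expect_true(all(mp2[1:5, "<"] == 0))
  expect_true(sum(mp2[1:5, ">"]) > 0)

  expect_warning(
    meta_domain_profile(rbind(dom, data.frame(chrom = "chr1", start = 5,
                                              end = 5)), item, 10),
    "zero-length")
})

test_that("section stacks render per-section binned presence", {
  sec <- data.frame(tad_id = 1, chrom = "chr1", start = 0, end = 100000,
                    kind = "negative_DI", inversion_pos = 100000)
  # one forward site 12 kb left of the inversion point
  items <- data.frame(chrom = "chr1", pos = 88000, orientation = ">")
  st <- section_stack_profile(sec, items, window = 1e6, bin = 5000,
                              stratify = "orientation")
  fwd <- st[[">"]]
  expect_equal(sum(fwd, na.rm = TRUE), 1)
  expect_equal(which(fwd[1, ] == 1), 98)  # bin [-15, -10) kb of 200
  # bins outside the section are NA
  expect_true(is.na(fwd[1, 1]))
  # empty item set: all-zero (or NA) matrix
  st2 <- section_stack_profile(sec, items[0, ], window = 1e6, bin = 5000)
  expect_equal(sum(st2$all, na.rm = TRUE), 0)
})

test_that("insulation span profiles count straddling interactions", {
  b <- data.frame(chrom = "chr1", centre = 1e6, score = 3)
  none <- data.frame(chrom1 = character(), start1 = numeric(),
                     end1 = numeric(), chrom2 = character(),
                     start2 = numeric(), end2 = numeric())
  expect_true(all(insulation_span_profile(b, none) == 0))

  one <- data.frame(chrom1 = "chr1", start1 = 0.9e6, end1 = 0.905e6,
                    chrom2 = "chr1", start2 = 1.1e6, end2 = 1.105e6)
  prof <- insulation_span_profile(b, one, shifts = c(-3e5, 0, 3e5))
  expect_equal(unname(prof["0", "3"]), 1)
  expect_equal(unname(prof["-3e+05", "3"]), 0)
})

test_that("boundary CTCF census counts sites in centred windows", {
  cons <- data.frame(chrom = "chr1", centre = c(1e6, 5e6), score = c(2, 7))
  sites <- data.frame(chrom = "chr1",
                      pos = c(1e6 - 20000, 1e6, 1e6 + 24000, 2e6))
  cen <- boundary_ctcf_census(cons, sites, flank = 25000)
  expect_equal(cen$counts$n_sites, c(3, 0))
  expect_equal(as.vector(cen$zero_fraction[c("2", "7")]), c(0, 1))
})
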