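test_that("generators are reproducible given the spec seed", {
  sp <- synthetic_spec(seed = 7, n_sites = 300)
  g1 <- make_layout_and_sites(sp)
  g2 <- make_layout_and_sites(sp)
  expect_identical(g1$sites, g2$sites)
  expect_identical(g1$layout, g2$layout)
  # a different seed moves the sites
  g3 <- make_layout_and_sites(synthetic_spec(seed = 8, n_sites = 300))
  expect_false(identical(g1$sites$midpoint, g3$sites$midpoint))
})

test_that("site sequences respect the layout and capacity limits", {
  sp <- synthetic_spec(seed = 1, n_sites = 200)
  g <- make_layout_and_sites(sp)
  expect_equal(nrow(g$sites), 200)
  # sites fall inside their arm and midpoints increase strictly per arm
  for (arm in split(g$sites, g$sites$arm_id)) {
    a <- g$layout[g$layout$arm_id == arm$arm_id[1], ]
    expect_true(all(arm$midpoint >= a$start & arm$midpoint < a$end))
    expect_true(all(diff(arm$midpoint) > 0))
  }
  expect_error(make_layout_and_sites(
    synthetic_spec(seed = 1, n_sites = 2000, arm_length = 1e4,
                   spacing = "uniform", min_spacing = 100)),
    "capacity")
})

test_that("iid orientations give near-theoretical tri-plet classes", {
  g <- make_layout_and_sites(synthetic_spec(seed = 1, n_sites = 20000,
                                            orientation = "iid"))
  cc <- count_classes(g$sites, 3)
  f <- cc$counts / cc$total
  se <- sqrt(0.25 * 0.75 / cc$total)
  expect_true(all(abs(f - 0.25) < 3 * se))
})

test_that("the grammar model plants divergent sites at domain edges", {
  g <- make_layout_and_sites(synthetic_spec(seed = 5, n_sites = 2000,
                                            orientation = "grammar",
                                            domain_size = 1e6,
                                            spacing = "uniform"))
  s <- assign_triplet_classes(g$sites)
  # the two sites flanking each domain edge form divergent tri-plets
  # (last reverse site of one domain, first forward site of the next)
  flank_classes <- character(0)
  for (arm in split(s, s$arm_id)) {
    phase <- (arm$midpoint - arm$midpoint %% 1e6)
    edges <- unique(phase)[-1]
    for (ed in edges) {
      before <- which(arm$midpoint < ed)
      after <- which(arm$midpoint >= ed)
      if (length(before) && length(after)) {
        flank_classes <- c(flank_classes,
                           as.character(arm$triplet_class[max(before)]),
                           as.character(arm$triplet_class[min(after)]))
      }
    }
  }
  flank_classes <- flank_classes[!is.na(flank_classes)]
  expect_gt(mean(flank_classes == "Div"), 0.6)
})

test_that("position shuffling preserves counts, orientations and scores", {
  g <- make_layout_and_sites(synthetic_spec(seed = 2, n_sites = 400))
  sh <- shuffle_positions(g$sites, g$layout, seed = 11)
  expect_equal(table(sh$arm_id), table(g$sites$arm_id))
  expect_equal(sort(sh$orientation), sort(g$sites$orientation))
  expect_equal(sort(sh$motif_score), sort(g$sites$motif_score))
  expect_false(identical(sh$midpoint, g$sites$midpoint))
  # clustered real spacing has a short-gap excess over the shuffled null
  gaps_real <- inter_site_distances(g$sites)$gap_bp
  gaps_null <- inter_site_distances(sh)$gap_bp
  expect_gt(mean(gaps_real < 5000), 2 * mean(gaps_null < 5000))
})

test_that("boundary plants are recovered with planted conservation", {
  sim <- simulate_boundary_datasets(n_celltypes = 7, n_shared = 20,
                                    n_private = 5, jitter = 10000, seed = 6)
  expect_length(sim$datasets, 7)
  cons <- consensus_boundaries(sim$datasets, w = 25000, seed = 1)
  expect_equal(sum(cons$score == 7), 20)
  expect_equal(sum(cons$score == 1), 35)

  # zero jitter: consensus regions collapse onto the plant positions
  sim0 <- simulate_boundary_datasets(n_celltypes = 3, n_shared = 5,
                                     n_private = 0, jitter = 0,
                                     boundary_width = 1000, seed = 2)
  cons0 <- consensus_boundaries(sim0$datasets, w = 25000)
  expect_equal(cons0$end - cons0$start, rep(1000, 5))
  expect_setequal(cons0$start, sim0$truth$pos)

  # a single dataset gives conservation score 1 everywhere
  sim1 <- simulate_boundary_datasets(n_celltypes = 1, n_shared = 0,
                                     n_private = 10, seed = 3)
  cons1 <- consensus_boundaries(sim1$datasets, w = 25000)
  expect_true(all(cons1$score == 1))

  expect_error(simulate_boundary_datasets(n_shared = 1e5,
                                          chrom_length = 1e6),
               "collide")
})

test_that("DI tracks carry the planted asymmetry", {
  tads <- data.frame(chrom = "chr1", start = c(0, 2e6), end = c(2e6, 4e6))
  di <- simulate_di_track(tads, asymmetry = 0.5, noise = 0)
  inv <- find_negative_inversions(di)
  expect_equal(inv$pos, c(1e6, 3e6))  # exactly at TAD midpoints
  expect_equal(nrow(simulate_di_track(tads[0, ], 0.5, 0)), 0)
  expect_warning(simulate_di_track(tads, 0.5, noise = 2, seed = 1),
                 "flipped")
  expect_error(simulate_di_track(
    data.frame(chrom = "chr1", start = 3, end = 2e6), 0.5, 0),
    "divide")
})

test_that("interaction pairs respect the cross-boundary fraction", {
  tads <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  within <- simulate_interactions(tads, n_per_tad = 30, cross_fraction = 0,
                                  seed = 4)
  b <- data.frame(chrom = "chr1", centre = 1e6, score = 1)
  expect_equal(unname(insulation_span_profile(b, within,
                                              shifts = 0)["0", "1"]), 0)
  crossed <- simulate_interactions(tads, n_per_tad = 30,
                                   cross_fraction = 1, seed = 4)
  # the first TAD's pairs all straddle the 1 Mb boundary; the last TAD
  # has no right neighbour so its pairs stay within
  n_straddle <- sum(crossed$start1 < 1e6 & crossed$start2 >= 1e6)
  expect_equal(n_straddle, 30)
  expect_equal(unname(insulation_span_profile(b, crossed,
                                              shifts = 0)["0", "1"]), 30)
})
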