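#' Specification for synthetic CTCF-site genomes
#'
#' Bundles the parameters of the synthetic genome generator. Defaults
#' describe a small multi-arm genome whose statistics echo real CTCF site
#' tables: a clustered spacing mixture producing a short-gap excess over
#' uniform spacing, independent equiprobable orientations, and
#' motif/ChIP-seq scores drawn with latent correlation 0.43.
#'
#' @param seed RNG seed.
#' @param n_arms number of chromosome arms (two arms per chromosome).
#' @param arm_length arm length in bp.
#' @param n_sites total number of sites across arms.
#' @param spacing `"uniform"` (positions iid uniform per arm) or
#'   `"clustered"` (two-component exponential gap mixture).
#' @param short_gap,long_gap,short_frac clustered-spacing mixture: mean of
#'   the short and long gap components (bp) and the short-component
#'   weight.
#' @param orientation `"iid"` (each site forward with `forward_prob`) or
#'   `"grammar"` (planted TAD grammar: domains of `domain_size` with
#'   forward sites in their left half and reverse sites in their right
#'   half, giving divergent patterns at domain edges and convergent ones
#'   at domain centres).
#' @param forward_prob probability of `>` under `"iid"`.
#' @param domain_size planted domain size in bp under `"grammar"`.
#' @param flip_prob per-site orientation noise under `"grammar"`.
#' @param score_cor latent correlation between motif and ChIP-seq scores.
#' @param site_width motif interval width in bp.
#' @param min_spacing minimal distance between site midpoints in bp.
#' @return a validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_arms = 4, arm_length = 3e7,
                           n_sites = 4000,
                           spacing = c("clustered", "uniform"),
                           short_gap = 5000, long_gap = 200000,
                           short_frac = 0.6,
                           orientation = c("iid", "grammar"),
                           forward_prob = 0.5, domain_size = 1e6,
                           flip_prob = 0, score_cor = 0.43,
                           site_width = 20, min_spacing = 100) {
  spec <- list(seed = seed, n_arms = n_arms, arm_length = arm_length,
               n_sites = n_sites, spacing = match.arg(spacing),
               short_gap = short_gap, long_gap = long_gap,
               short_frac = short_frac,
               orientation = match.arg(orientation),
               forward_prob = forward_prob, domain_size = domain_size,
               flip_prob = flip_prob, score_cor = score_cor,
               site_width = site_width, min_spacing = min_spacing)
  .assert(n_arms >= 1 && n_sites >= 0, "counts must be non-negative")
  .assert(forward_prob >= 0 && forward_prob <= 1, "forward_prob in [0,1]")
  class(spec) <- "synthetic_spec"
  spec
}

# Internal: distinct site midpoints for one arm under the spacing model.
.arm_positions <- function(spec, n) {
  if (spec$spacing == "uniform") {
    .assert(n * spec$min_spacing <= spec$arm_length,
            "site count exceeds arm capacity at min spacing")
    repeat {
      pos <- sort(floor(runif(n, 0, spec$arm_length)))
      if (n < 2 || min(diff(pos)) >= spec$min_spacing) return(pos)
    }
  }
  gaps <- ifelse(runif(n - 1) < spec$short_frac,
                 stats::rexp(n - 1, 1 / spec$short_gap),
                 stats::rexp(n - 1, 1 / spec$long_gap))
  gaps <- pmax(gaps, spec$min_spacing)
  pos <- floor(cumsum(c(runif(1, 0, spec$long_gap), gaps)))
  pos
}

#' Generate a synthetic genome layout and site table
#'
#' Draws a reproducible multi-arm genome of oriented CTCF sites under the
#' spacing, orientation and score models of a [synthetic_spec()]. Under
#' independent equiprobable orientations, k-plet class frequencies
#' converge to the theoretical proportions; under the `"grammar"` model,
#' divergent patterns are planted at domain edges.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `layout` (from [genome_layout()]) and `sites` (a
#'   sites `data.frame` with `arm_id`, `orientation`, `motif_score`,
#'   `chipseq_score`, `midpoint`).
#' @export
make_layout_and_sites <- function(spec) {
  .assert(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  .assert(spec$n_sites >= 1, "need at least one site")
  set.seed(spec$seed)
  per_arm <- diff(floor(seq(0, spec$n_sites, length.out = spec$n_arms + 1)))
  chroms <- paste0("chr", ceiling(seq_len(spec$n_arms) / 2))
  arm_of <- ifelse(seq_len(spec$n_arms) %% 2 == 1, "p", "q")
  arm_ids <- paste0(chroms, arm_of)
  sites <- NULL
  arm_end <- numeric(spec$n_arms)
  arm_start <- numeric(spec$n_arms)
  for (i in seq_len(spec$n_arms)) {
    n <- per_arm[i]
    pos <- if (n > 0) .arm_positions(spec, n) else numeric(0)
    # q arms sit beyond the p arm plus a centromere gap
    offset <- if (arm_of[i] == "q") {
      prev <- arm_end[i - 1]
      prev + 3e6
    } else 0
    arm_start[i] <- offset
    arm_end[i] <- offset + max(spec$arm_length, if (n) max(pos) + spec$long_gap else 0)
    pos <- pos + offset
    ori <- .draw_orientations(spec, pos, arm_start[i])
    if (n > 0) {
      sites <- rbind(sites, data.frame(
        chrom = chroms[i],
        start = pos - spec$site_width %/% 2,
        end = pos + (spec$site_width - spec$site_width %/% 2),
        orientation = ori, arm_id = arm_ids[i],
        stringsAsFactors = FALSE))
    }
  }
  layout <- genome_layout(arm_ids, chroms, arm_start, arm_end)
  sites$midpoint <- .midpoint(sites$start, sites$end)
  # correlated latent scores: motif normal-like, ChIP-seq skewed
  n <- nrow(sites)
  z1 <- rnorm(n)
  z2 <- spec$score_cor * z1 + sqrt(1 - spec$score_cor^2) * rnorm(n)
  sites$motif_score <- 12 + 2 * z1
  sites$chipseq_score <- exp(1 + z2)
  sites <- sites[order(match(sites$arm_id, arm_ids), sites$midpoint), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  list(layout = layout, sites = sites)
}

.draw_orientations <- function(spec, pos, arm_start) {
  n <- length(pos)
  if (n == 0) return(character(0))
  if (spec$orientation == "iid") {
    return(c("<", ">")[1L + (runif(n) < spec$forward_prob)])
  }
  # planted grammar: forward in the left half of each domain, reverse in
  # the right half -> divergent at domain edges, convergent at centres
  rel <- ((pos - arm_start) %% spec$domain_size) / spec$domain_size
  ori <- ifelse(rel < 0.5, ">", "<")
  flip <- runif(n) < spec$flip_prob
  ori[flip] <- ifelse(ori[flip] == ">", "<", ">")
  ori
}

#' Randomize site positions, keeping orientations and scores
#'
#' Redraws every site's position uniformly within its arm (preserving the
#' per-arm site count and the orientation sequence), the spatial null used
#' to contrast the observed inter-CTCF distance distribution.
#'
#' @param sites sites `data.frame` with `arm_id`.
#' @param layout layout `data.frame`.
#' @param seed RNG seed.
#' @return sites with redrawn positions, sorted per arm.
#' @export
shuffle_positions <- function(sites, layout, seed = 1) {
  set.seed(seed)
  arms <- .by_arm(sites)
  out <- lapply(arms, function(a) {
    arm <- layout[layout$arm_id == a$arm_id[1], ]
    .assert(nrow(arm) == 1, "arm %s missing from layout", a$arm_id[1])
    w <- a$end - a$start
    mid <- sort(floor(runif(nrow(a), arm$start, arm$end)))
    a$start <- mid - w %/% 2
    a$end <- a$start + w
    a$midpoint <- .midpoint(a$start, a$end)
    a
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate boundary datasets with a planted consensus
#'
#' Builds `n_celltypes` boundary datasets sharing `n_shared` planted
#' boundaries (each appearing in every dataset with positional jitter)
#' plus `n_private` boundaries unique to each dataset. All plants are
#' separated by more than `3 * w` so consensus clustering is
#' unambiguous; an error is raised when the chromosome cannot hold them.
#'
#' @param n_celltypes number of datasets.
#' @param n_shared planted boundaries present in all datasets.
#' @param n_private boundaries private to each dataset.
#' @param jitter maximal absolute positional jitter in bp (must stay below
#'   the detection window for recoverable plants).
#' @param boundary_width width of each boundary region in bp; keep below
#'   `w - 2 * jitter` so that a plant's positions always form one clique.
#' @param w detection window the consensus will use (spacing safety
#'   margin).
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return list with `datasets` (named list of boundary `data.frame`s) and
#'   `truth` (`data.frame` of planted positions: `pos`, `type`,
#'   `cell_type`).
#' @export
simulate_boundary_datasets <- function(n_celltypes = 7, n_shared = 50,
                                       n_private = 20, jitter = 10000,
                                       boundary_width = 5000, w = 25000,
                                       chrom_length = 2.4e8,
                                       chrom = "chr1", seed = 1) {
  .assert(jitter >= 0, "jitter must be >= 0")
  set.seed(seed)
  n_slots <- n_shared + n_celltypes * n_private
  step <- 3 * w + 2 * (jitter + boundary_width) + w
  .assert(n_slots * step <= chrom_length,
          "planted boundaries collide: chromosome too short for %d slots",
          n_slots)
  slots <- sample(seq(step, n_slots * step, by = step))
  shared <- slots[seq_len(n_shared)]
  private <- matrix(slots[n_shared + seq_len(n_celltypes * n_private)],
                    nrow = n_celltypes)
  jit <- function(n) if (jitter > 0) floor(runif(n, -jitter, jitter)) else 0
  datasets <- lapply(seq_len(n_celltypes), function(ct) {
    pos <- c(shared + jit(n_shared), private[ct, ] + jit(n_private))
    b <- data.frame(chrom = chrom, start = pos,
                    end = pos + boundary_width, stringsAsFactors = FALSE)
    b[order(b$start), , drop = FALSE]
  })
  names(datasets) <- paste0("celltype", seq_len(n_celltypes))
  truth <- rbind(
    if (n_shared > 0)
      data.frame(pos = shared, type = "shared",
                 cell_type = NA_character_),
    if (n_private > 0)
      data.frame(pos = as.vector(t(private)), type = "private",
                 cell_type = rep(names(datasets), each = n_private))
  )
  list(datasets = datasets, truth = truth)
}

#' Simulate a directionality-index track over TADs
#'
#' Each TAD receives a positive-DI run followed by a negative-DI run, the
#' split placed at `asymmetry` of the TAD length (0.5 = midpoint), with
#' optional additive Gaussian noise. Noise large enough to flip signs
#' triggers a warning.
#'
#' @param tads `data.frame` of TAD intervals whose coordinates are
#'   multiples of `bin`.
#' @param asymmetry positive-section fraction of each TAD (scalar or one
#'   value per TAD).
#' @param noise standard deviation of additive noise (signal is +/- 1).
#' @param bin DI bin size in bp (25 kb at the reference resolution).
#' @param seed RNG seed.
#' @return DI track `data.frame` (`chrom`, `start`, `end`, `value`).
#' @export
simulate_di_track <- function(tads, asymmetry = 0.5, noise = 0,
                              bin = 25000, seed = 1) {
  if (nrow(tads) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  .assert(all(tads$start %% bin == 0) && all(tads$end %% bin == 0),
          "bin size must divide TAD coordinates")
  asymmetry <- rep(asymmetry, length.out = nrow(tads))
  set.seed(seed)
  out <- lapply(seq_len(nrow(tads)), function(i) {
    nb <- (tads$end[i] - tads$start[i]) %/% bin
    n_pos <- max(1L, min(nb - 1L, round(nb * asymmetry[i])))
    clean <- c(rep(1, n_pos), rep(-1, nb - n_pos))
    data.frame(chrom = tads$chrom[i],
               start = tads$start[i] + bin * (seq_len(nb) - 1L),
               end = tads$start[i] + bin * seq_len(nb),
               clean = clean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$value <- out$clean + rnorm(nrow(out), 0, noise)
  if (any(sign(out$value) != sign(out$clean))) {
    warning("noise flipped the sign of some DI bins", call. = FALSE)
  }
  out$clean <- NULL
  rownames(out) <- NULL
  out
}

#' Simulate promoter-genome interaction pairs over TADs
#'
#' Draws `n_per_tad` interaction pairs per TAD: a fraction
#' `1 - cross_fraction` lies entirely within one TAD; `cross_fraction`
#' straddles the boundary between a TAD and its right neighbour (ends in
#' the two flanking TADs).
#'
#' @param tads `data.frame` of TAD intervals, sorted per chromosome.
#' @param n_per_tad interactions per TAD.
#' @param cross_fraction fraction of boundary-straddling pairs in [0, 1].
#' @param anchor_width width of each interaction end in bp.
#' @param seed RNG seed.
#' @return BEDPE-style `data.frame` with a `score` column.
#' @export
simulate_interactions <- function(tads, n_per_tad = 10, cross_fraction = 0,
                                  anchor_width = 5000, seed = 1) {
  .assert(cross_fraction >= 0 && cross_fraction <= 1,
          "cross_fraction must be in [0, 1]")
  set.seed(seed)
  mk_pair <- function(chrom, a, b) {
    data.frame(chrom1 = chrom, start1 = a, end1 = a + anchor_width,
               chrom2 = chrom, start2 = b, end2 = b + anchor_width,
               score = 10, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(tads)), function(i) {
    t <- tads[i, ]
    n_cross <- rbinom(1, n_per_tad, cross_fraction)
    pairs <- NULL
    nxt <- if (i < nrow(tads) && tads$chrom[i + 1] == t$chrom) tads[i + 1, ] else NULL
    if (is.null(nxt)) n_cross <- 0
    n_within <- n_per_tad - n_cross
    if (n_within > 0) {
      p <- matrix(floor(runif(2 * n_within, t$start, t$end - anchor_width)),
                  ncol = 2)
      pairs <- mk_pair(t$chrom, pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
    }
    if (n_cross > 0) {
      a <- floor(runif(n_cross, t$start, t$end - anchor_width))
      b <- floor(runif(n_cross, nxt$start, nxt$end - anchor_width))
      pairs <- rbind(pairs, mk_pair(t$chrom, a, b))
    }
    pairs
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
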