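# Internal: coerce an interval/position table to (chrom, pos) midpoints.
.as_positions <- function(x) {
  if (!is.null(x$pos)) return(data.frame(chrom = x$chrom, pos = x$pos))
  if (!is.null(x$midpoint)) return(data.frame(chrom = x$chrom, pos = x$midpoint))
  data.frame(chrom = x$chrom, pos = .midpoint(x$start, x$end))
}

#' Derive TAD intervals from consensus boundaries
#'
#' TADs are the complement of the (merged) boundary regions within each
#' chromosome arm, minus any assembly gap intervals. Overlapping boundary
#' regions are merged first.
#'
#' @param boundaries boundary `data.frame` (`chrom`, `start`, `end`),
#'   typically consensus boundaries conserved in >= 2 cell types.
#' @param layout arm layout from [genome_layout()].
#' @param gaps optional `data.frame` of gap intervals to exclude.
#' @return `data.frame` of TAD intervals (`chrom`, `start`, `end`),
#'   0-based half-open, sorted.
#' @export
tads_from_boundaries <- function(boundaries, layout, gaps = NULL) {
  arm_gr <- .sites_gr(layout)
  excl <- boundaries[, c("chrom", "start", "end")]
  if (!is.null(gaps)) excl <- rbind(excl, gaps[, c("chrom", "start", "end")])
  # zero-length boundary regions (degenerate consensus) exclude nothing
  excl <- excl[excl$end > excl$start, , drop = FALSE]
  tad_gr <- if (nrow(excl)) {
    GenomicRanges::setdiff(arm_gr, GenomicRanges::reduce(.sites_gr(excl)))
  } else {
    GenomicRanges::reduce(arm_gr)
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(tad_gr)),
                    start = GenomicRanges::start(tad_gr) - 1L,
                    end = GenomicRanges::end(tad_gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: split item positions by a stratification column.
.strata_of <- function(items, stratify) {
  if (is.null(stratify)) return(factor(rep("all", nrow(items))))
  .assert(stratify %in% names(items), "no column '%s' in items", stratify)
  x <- items[[stratify]]
  if (is.factor(x)) x else factor(x)  # keep declared levels
}

#' Meta-domain (relative-position) density profile
#'
#' Divides every domain into `n_bins` equal bins (bin size varies with the
#' domain), counts the items falling in each bin, and averages the
#' per-domain bin vectors, giving mean item counts on a normalized 0..1
#' axis across domains.
#'
#' @param domains `data.frame` of domain intervals (`chrom`, `start`,
#'   `end`); zero-length domains are skipped with a warning.
#' @param items `data.frame` of positioned items (sites); position is the
#'   interval midpoint.
#' @param n_bins number of relative bins (default 100).
#' @param stratify optional items column to stratify by (e.g.
#'   `"orientation"` or `"triplet_class"`).
#' @return numeric matrix, `n_bins` rows x strata columns, of mean counts
#'   per bin; attribute `n_domains`.
#' @export
meta_domain_profile <- function(domains, items, n_bins = 100,
                                stratify = NULL) {
  degen <- domains$end <= domains$start
  if (any(degen)) {
    warning(sprintf("skipping %d zero-length domain(s)", sum(degen)),
            call. = FALSE)
    domains <- domains[!degen, , drop = FALSE]
  }
  .assert(nrow(domains) > 0, "no non-degenerate domains")
  pos <- .as_positions(items)
  strat <- .strata_of(items, stratify)
  levs <- levels(strat)
  acc <- matrix(0, nrow = n_bins, ncol = length(levs),
                dimnames = list(NULL, levs))
  for (i in seq_len(nrow(domains))) {
    inside <- pos$chrom == domains$chrom[i] &
      pos$pos >= domains$start[i] & pos$pos < domains$end[i]
    if (!any(inside)) next
    rel <- (pos$pos[inside] - domains$start[i]) /
      (domains$end[i] - domains$start[i])
    b <- pmin(floor(rel * n_bins) + 1L, n_bins)
    for (l in levs) {
      sel <- strat[inside] == l
      if (any(sel)) {
        tb <- tabulate(b[sel], nbins = n_bins)
        acc[, l] <- acc[, l] + tb
      }
    }
  }
  out <- acc / nrow(domains)
  attr(out, "n_domains") <- nrow(domains)
  out
}

#' Find directionality-index sign inversions
#'
#' Scans a binned DI track for sign changes. A negative inversion is a
#' (+) to (-) change — the smoother switch towards the middle of TADs; a
#' positive inversion is a (-) to (+) change — the abrupt switch that marks
#' a TAD boundary. Zero-valued bins are skipped and do not break a run.
#' The reported coordinate is the midpoint between the end of the last bin
#' of one sign and the start of the first bin of the other (their shared
#' edge when the bins are adjacent).
#'
#' @param di `data.frame` with `chrom`, `start`, `end`, `value` (binned
#'   signed DI), bins sorted and non-overlapping per chromosome.
#' @param direction `"negative"` for (+)->(-), `"positive"` for (-)->(+).
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
find_inversions <- function(di, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  from <- if (direction == "negative") 1 else -1
  out <- lapply(split(di, di$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    d <- d[d$value != 0, , drop = FALSE]  # zero bins do not break runs
    if (nrow(d) < 2) return(NULL)
    s <- sign(d$value)
    flip <- which(s[-nrow(d)] == from & s[-1] == -from)
    if (!length(flip)) return(NULL)
    data.frame(chrom = d$chrom[1],
               pos = .midpoint(d$end[flip], d$start[flip + 1L]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), pos = numeric())
  rownames(out) <- NULL
  out
}

#' @rdname find_inversions
#' @export
find_negative_inversions <- function(di) find_inversions(di, "negative")

#' Split TADs into positive- and negative-DI sections
#'
#' A TAD decomposes at its interior negative DI inversion into a
#' positive-DI section (from the TAD start, i.e. the upstream positive
#' inversion, to the negative inversion) and a negative-DI section (from
#' the negative inversion to the TAD end). The two sections need not have
#' equal lengths. When several negative inversions fall inside one TAD the
#' one nearest the TAD midpoint is used; TADs with none are emitted as a
#' single unsplit section.
#'
#' @param tads `data.frame` of TAD intervals.
#' @param di binned DI track (see [find_inversions()]).
#' @return `data.frame` with columns `tad_id`, `chrom`, `start`, `end`,
#'   `kind` (`positive_DI`, `negative_DI` or `unsplit`), `inversion_pos`.
#' @export
split_sections <- function(tads, di) {
  inv <- find_inversions(di, "negative")
  out <- lapply(seq_len(nrow(tads)), function(i) {
    t <- tads[i, ]
    cand <- inv$pos[inv$chrom == t$chrom & inv$pos > t$start &
                      inv$pos < t$end]
    if (!length(cand)) {
      return(data.frame(tad_id = i, chrom = t$chrom, start = t$start,
                        end = t$end, kind = "unsplit",
                        inversion_pos = NA_real_))
    }
    mid <- .midpoint(t$start, t$end)
    p <- cand[which.min(abs(cand - mid))]
    data.frame(tad_id = i, chrom = t$chrom,
               start = c(t$start, p), end = c(p, t$end),
               kind = c("positive_DI", "negative_DI"),
               inversion_pos = p)
  })
  n_unsplit <- sum(vapply(out, function(x) x$kind[1] == "unsplit", logical(1)))
  if (n_unsplit > 0) {
    message(sprintf("%d TAD(s) without an interior negative inversion left unsplit",
                    n_unsplit))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Anchored density profile
#'
#' Average item density in fixed-width bins around a set of anchors
#' (boundary centres, DI inversion points, TSS, ...). For every anchor the
#' offsets of nearby item midpoints are binned over `[-flank, +flank)`;
#' profiles are means across anchors, optionally stratified by an item
#' column. Anchors with a `strand` column have their axis flipped for
#' `-` strand.
#'
#' @param anchors `data.frame` with `chrom` and `pos` (or an interval whose
#'   midpoint is used), optional `strand`.
#' @param items positioned items `data.frame`.
#' @param flank half-window in bp.
#' @param bin bin width in bp; must divide `flank`.
#' @param stratify optional items column name.
#' @param values optional items column name: per-bin means of this value
#'   (pooled over items) are returned instead of counts.
#' @return list with `offset` (bin centre offsets in bp), `profile`
#'   (bins x strata matrix of mean counts per anchor, or mean values) and
#'   `n_anchors`.
#' @export
anchored_density_profile <- function(anchors, items, flank = 250000,
                                     bin = 5000, stratify = NULL,
                                     values = NULL) {
  .assert(nrow(anchors) > 0, "no anchors")
  .assert(flank %% bin == 0, "bin must divide flank")
  apos <- .as_positions(anchors)
  flip <- if (!is.null(anchors$strand)) anchors$strand == "-" else
    rep(FALSE, nrow(anchors))
  ipos <- .as_positions(items)
  strat <- .strata_of(items, stratify)
  levs <- levels(strat)
  nb <- as.integer(2 * flank / bin)
  counts <- matrix(0, nrow = nb, ncol = length(levs),
                   dimnames = list(NULL, levs))
  vsum <- counts
  val <- if (!is.null(values)) items[[values]] else NULL
  for (i in seq_len(nrow(apos))) {
    off <- ipos$pos - apos$pos[i]
    if (flip[i]) off <- -off
    sel <- ipos$chrom == apos$chrom[i] & off >= -flank & off < flank
    if (!any(sel)) next
    b <- floor((off[sel] + flank) / bin) + 1L
    for (l in levs) {
      ls <- strat[sel] == l
      if (any(ls)) {
        counts[, l] <- counts[, l] + tabulate(b[ls], nbins = nb)
        if (!is.null(val)) {
          vs <- tapply(val[sel][ls], factor(b[ls], levels = seq_len(nb)), sum)
          vs[is.na(vs)] <- 0
          vsum[, l] <- vsum[, l] + vs
        }
      }
    }
  }
  profile <- if (is.null(val)) counts / nrow(apos) else {
    p <- vsum / counts
    p[counts == 0] <- NA
    p
  }
  list(offset = seq(-flank + bin / 2, flank - bin / 2, by = bin),
       profile = profile, n_anchors = nrow(apos))
}

#' Stacked per-section binned item density
#'
#' Renders item density for every DI section in fixed bins over a window
#' centred on the section's negative inversion point, with sections
#' (rows) ordered by size. Bins lying entirely outside a section are `NA`;
#' bins inside hold item counts, optionally stratified.
#'
#' @param sections `data.frame` from [split_sections()] (rows with
#'   `inversion_pos` available).
#' @param items positioned items `data.frame`.
#' @param window total window width in bp centred on the inversion point.
#' @param bin bin width in bp.
#' @param stratify optional items column name.
#' @return named list of matrices (one per stratum), rows = sections in
#'   decreasing size order, columns = bins; plus attribute `order` with
#'   the section row indices used.
#' @export
section_stack_profile <- function(sections, items, window = 1e6, bin = 5000,
                                  stratify = NULL) {
  sections <- sections[!is.na(sections$inversion_pos), , drop = FALSE]
  .assert(window %% (2 * bin) == 0, "bin must divide window/2")
  ord <- order(sections$end - sections$start, decreasing = TRUE)
  sections <- sections[ord, , drop = FALSE]
  ipos <- .as_positions(items)
  strat <- .strata_of(items, stratify)
  levs <- levels(strat)
  nb <- as.integer(window / bin)
  half <- window / 2
  mats <- lapply(levs, function(l) {
    matrix(NA_real_, nrow = nrow(sections), ncol = nb)
  })
  names(mats) <- levs
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    edges <- seq(s$inversion_pos - half, s$inversion_pos + half, by = bin)
    inside_bin <- edges[-length(edges)] < s$end & edges[-1] > s$start
    for (l in levs) {
      sel <- strat == l & ipos$chrom == s$chrom &
        ipos$pos >= pmax(s$start, s$inversion_pos - half) &
        ipos$pos < pmin(s$end, s$inversion_pos + half)
      b <- floor((ipos$pos[sel] - (s$inversion_pos - half)) / bin) + 1L
      row <- rep(NA_real_, nb)
      row[inside_bin] <- 0
      if (length(b)) {
        tb <- tabulate(b, nbins = nb)
        row[inside_bin] <- tb[inside_bin]
      }
      mats[[l]][i, ] <- row
    }
  }
  attr(mats, "order") <- ord
  mats
}

#' Boundary insulation profile from paired interactions
#'
#' Counts promoter-genome interaction pairs that span each boundary
#' centre (their two ends on opposite sides of the centre), then shifts
#' every boundary in 10-kb steps up to +/- 400 kb and recomputes the mean
#' spanning count, modelling the local background. Stratified by boundary
#' conservation score. Insulating boundaries show a dip at shift 0.
#'
#' @param boundaries consensus `data.frame` with `chrom`, `centre`,
#'   `score`.
#' @param interactions BEDPE-style `data.frame` of interaction pairs (ends
#'   are taken at interval midpoints); filter upstream by confidence
#'   score.
#' @param shifts numeric vector of shift offsets in bp.
#' @return matrix of mean spanning counts, rows = shifts, columns =
#'   conservation scores.
#' @export
insulation_span_profile <- function(boundaries, interactions,
                                    shifts = seq(-400000, 400000, 10000)) {
  e1 <- .midpoint(interactions$start1, interactions$end1)
  e2 <- .midpoint(interactions$start2, interactions$end2)
  same <- interactions$chrom1 == interactions$chrom2
  lo <- pmin(e1, e2)[same]
  hi <- pmax(e1, e2)[same]
  ich <- interactions$chrom1[same]
  scores <- sort(unique(boundaries$score))
  out <- matrix(0, nrow = length(shifts), ncol = length(scores),
                dimnames = list(as.character(shifts), as.character(scores)))
  for (sc in scores) {
    b <- boundaries[boundaries$score == sc, , drop = FALSE]
    tot <- numeric(length(shifts))
    for (i in seq_len(nrow(b))) {
      onchr <- ich == b$chrom[i]
      if (!any(onchr)) next
      l <- lo[onchr]; h <- hi[onchr]
      tot <- tot + vapply(shifts, function(s) {
        c0 <- b$centre[i] + s
        sum(l < c0 & h > c0)
      }, numeric(1))
    }
    out[, as.character(sc)] <- tot / max(1, nrow(b))
  }
  out
}

#' CTCF site census of consensus boundaries
#'
#' Counts the CTCF sites within `centre +/- flank` of every consensus
#' boundary and summarises the counts per conservation score, including
#' the fraction of CTCF-free boundaries.
#'
#' @param consensus consensus `data.frame` with `chrom`, `centre`,
#'   `score`.
#' @param sites sites `data.frame`.
#' @param flank half-window in bp.
#' @return list with `counts` (per-boundary `data.frame`: `score`,
#'   `n_sites`), `histogram` (score x site-count table) and
#'   `zero_fraction` (named vector per score).
#' @export
boundary_ctcf_census <- function(consensus, sites, flank = 25000) {
  spos <- .as_positions(sites)
  n_sites <- vapply(seq_len(nrow(consensus)), function(i) {
    sum(spos$chrom == consensus$chrom[i] &
          abs(spos$pos - consensus$centre[i]) <= flank)
  }, numeric(1))
  counts <- data.frame(score = consensus$score, n_sites = n_sites)
  hist <- table(score = counts$score, n_sites = counts$n_sites)
  zf <- tapply(counts$n_sites == 0, counts$score, mean)
  list(counts = counts, histogram = hist, zero_fraction = zf)
}
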