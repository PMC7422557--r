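#' Permeability scores for extrusion anchoring
#'
#' Permeability `v` is the probability that the extrusion complex ignores a
#' correctly oriented CTCF site. The `full_stop` model sets `v = 0`
#' everywhere (every correctly oriented site anchors); the score-driven
#' models set `v = 1 - (s - min s) / (max s - min s)` so that the
#' strongest-scoring site is impermeable (`v = 0`) and the weakest fully
#' permeable (`v = 1`).
#'
#' @param scores numeric vector of per-site scores (ignored for
#'   `full_stop`).
#' @param model one of `"full_stop"`, `"chipseq"`, `"motif"`, `"rank"`.
#'   The three score-driven models share the min-max formula and differ
#'   only in which score vector is supplied.
#' @return numeric vector of permeabilities in `[0, 1]`.
#' @export
permeability_scores <- function(scores,
                                model = c("full_stop", "chipseq", "motif",
                                          "rank")) {
  model <- match.arg(model)
  if (model == "full_stop") return(rep(0, length(scores)))
  .assert(length(scores) >= 2, "min-max normalisation needs >= 2 sites")
  rng <- range(scores)
  .assert(rng[1] < rng[2],
          "constant scores: min-max permeability undefined")
  1 - (scores - rng[1]) / (rng[2] - rng[1])
}

# Internal: scan outward from a loading gap on one side.
# cands: candidate site indices in scan order; v: their permeabilities.
# Returns the anchoring index or NA if the arm end is reached.
.scan_side <- function(cands, v, literal = FALSE) {
  if (!length(cands)) return(NA_integer_)
  u <- runif(length(cands))
  hit <- if (literal) which(u < v) else which(u >= v)
  if (!length(hit)) NA_integer_ else cands[hit[1]]
}

#' Simulate permeability-based loop extrusion
#'
#' In each epoch one extrusion event is loaded between every pair of
#' adjacent CTCF sites on every arm (so the simulation is independent of
#' local site density). Each event pulls DNA left and right independently:
#' the left side may anchor only at forward (`>`) sites, the right side
#' only at reverse (`<`) sites — the convergent configuration — and at
#' each correctly oriented candidate the side stops with probability
#' `1 - v` (permeability `v` = probability to ignore the site). A loop is
#' recorded only when both sides anchor before reaching the arm end; the
#' same loop can recur within and across epochs. Extrusion never crosses
#' an arm boundary.
#'
#' @param sites sites `data.frame` with `arm_id`, `orientation`,
#'   `midpoint`.
#' @param permeability numeric vector aligned with `sites` rows, from
#'   [permeability_scores()].
#' @param epochs number of simulation epochs (default 100).
#' @param seed RNG seed; epoch-level substreams are derived from it so the
#'   catalog is reproducible.
#' @param stop_rule `"consistent"` (default) stops a side at a correctly
#'   oriented site with probability `1 - v`, matching the definition of
#'   permeability as the probability to ignore the site (so `v = 0`
#'   always stops, as the full-stop model requires). `"literal"` stops
#'   when a uniform draw is below `v`, the inverted reading; it is kept
#'   only for comparison and makes the full-stop model anchor nowhere.
#' @return A loop catalog `data.frame` with columns `arm_id`,
#'   `left_index`, `right_index` (row numbers in `sites`), `left_mid`,
#'   `right_mid` and `count`, with attribute `epochs`.
#' @export
simulate_extrusion <- function(sites, permeability, epochs = 100, seed = 1,
                               stop_rule = c("consistent", "literal")) {
  literal <- match.arg(stop_rule) == "literal"
  .assert(epochs >= 1, "epochs must be >= 1")
  .assert(length(permeability) == nrow(sites),
          "permeability must align with sites")
  if (nrow(sites) == 0) {
    out <- data.frame(arm_id = character(), left_index = integer(),
                      right_index = integer(), left_mid = numeric(),
                      right_mid = numeric(), count = integer())
    attr(out, "epochs") <- epochs
    return(out)
  }
  arms <- .by_arm(cbind(sites, .row = seq_len(nrow(sites))))
  set.seed(seed)
  epoch_seeds <- sample.int(.Machine$integer.max, epochs)
  chunks <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    set.seed(epoch_seeds[e])
    arm_chunks <- lapply(arms, function(a) {
      M <- nrow(a)
      if (M < 2) return(NULL)
      fwd <- which(a$orientation == ">")
      rev_ <- which(a$orientation == "<")
      v <- permeability[a$.row]
      L <- rep(NA_integer_, M - 1L)
      R <- rep(NA_integer_, M - 1L)
      for (i in seq_len(M - 1L)) {
        lc <- rev(fwd[fwd <= i])
        l <- .scan_side(lc, v[lc], literal)
        if (is.na(l)) next
        rc <- rev_[rev_ >= i + 1L]
        r <- .scan_side(rc, v[rc], literal)
        if (is.na(r)) next
        L[i] <- a$.row[l]
        R[i] <- a$.row[r]
      }
      ok <- !is.na(L)
      cbind(L[ok], R[ok])
    })
    chunks[[e]] <- do.call(rbind, arm_chunks)
  }
  rec <- do.call(rbind, chunks)
  lefts <- if (is.null(rec)) integer(0) else rec[, 1]
  rights <- if (is.null(rec)) integer(0) else rec[, 2]
  if (!length(lefts)) {
    out <- data.frame(arm_id = character(), left_index = integer(),
                      right_index = integer(), left_mid = numeric(),
                      right_mid = numeric(), count = integer())
    attr(out, "epochs") <- epochs
    return(out)
  }
  key <- paste(lefts, rights)
  tb <- table(key)
  li <- as.integer(sub(" .*", "", names(tb)))
  ri <- as.integer(sub(".* ", "", names(tb)))
  out <- data.frame(arm_id = sites$arm_id[li], left_index = li,
                    right_index = ri, left_mid = sites$midpoint[li],
                    right_mid = sites$midpoint[ri],
                    count = as.integer(tb), stringsAsFactors = FALSE)
  stopifnot(all(sites$orientation[out$left_index] == ">"),
            all(sites$orientation[out$right_index] == "<"),
            all(out$left_mid < out$right_mid))
  out <- out[order(out$left_index, out$right_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "epochs") <- epochs
  out
}

# Internal: map one set of loop anchors (BEDPE rows) to site row indices.
# An anchor maps to the nearest site of the required orientation whose
# interval it overlaps; NA if none.
.map_anchor <- function(anchor, sites, orientation) {
  gr_a <- GenomicRanges::GRanges(anchor$chrom,
                                 IRanges::IRanges(anchor$start + 1L,
                                                  anchor$end))
  ok <- sites$orientation == orientation
  gr_s <- .sites_gr(sites[ok, , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(gr_a, gr_s)
  out <- rep(NA_integer_, nrow(anchor))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- which(ok)[S4Vectors::subjectHits(hits)]
    amid <- .midpoint(anchor$start, anchor$end)[q]
    d <- abs(sites$midpoint[s] - amid)
    o <- order(q, d)
    first <- !duplicated(q[o])
    out[q[o][first]] <- s[o][first]
  }
  out
}

#' Evaluate a simulated loop catalog against reference loops
#'
#' Reference loop anchor pairs (e.g. HiCCUPS calls) are first filtered to
#' those with a convergent CTCF configuration: the upstream anchor must
#' overlap a forward (`>`) site and the downstream anchor a reverse (`<`)
#' site. For every occurrence threshold `t`, recall is the fraction of
#' filtered reference loops recovered by the catalog with `count >= t`,
#' and precision the fraction of catalog loops with `count >= t` present
#' in the reference.
#'
#' @param catalog loop catalog from [simulate_extrusion()].
#' @param reference BEDPE-style `data.frame`
#'   (`chrom1,start1,end1,chrom2,start2,end2`).
#' @param sites the sites `data.frame` the catalog indexes into.
#' @param thresholds occurrence thresholds; defaults to
#'   `1..max(catalog$count)`.
#' @return list with `curve` (`data.frame` of `threshold`, `recall`,
#'   `precision`, `n_called`) and `n_reference` (size of the filtered
#'   reference).
#' @export
evaluate_against_reference <- function(catalog, reference, sites,
                                       thresholds = NULL) {
  a1 <- data.frame(chrom = reference$chrom1, start = reference$start1,
                   end = reference$end1)
  a2 <- data.frame(chrom = reference$chrom2, start = reference$start2,
                   end = reference$end2)
  l <- .map_anchor(a1, sites, ">")
  r <- .map_anchor(a2, sites, "<")
  keep <- !is.na(l) & !is.na(r) & sites$midpoint[l] < sites$midpoint[r]
  .assert(any(keep), "no reference loop has convergent CTCF anchors")
  ref_keys <- unique(paste(l[keep], r[keep]))
  if (is.null(thresholds)) {
    thresholds <- seq_len(max(catalog$count, 1))
  }
  cat_keys <- paste(catalog$left_index, catalog$right_index)
  curve <- do.call(rbind, lapply(thresholds, function(t) {
    called <- cat_keys[catalog$count >= t]
    data.frame(threshold = t,
               recall = mean(ref_keys %in% called),
               precision = if (length(called))
                 mean(called %in% ref_keys) else NA_real_,
               n_called = length(called))
  }))
  list(curve = curve, n_reference = length(ref_keys))
}
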