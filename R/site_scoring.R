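#' Map ChIP-seq peak signals onto sites
#'
#' For every site and every track, takes the maximum `signal` of the peaks
#' overlapping the site interval, or 0 when no peak overlaps (absence of
#' binding evidence).
#'
#' @param sites sites `data.frame` (`chrom`, `start`, `end`).
#' @param tracks named list of peak `data.frame`s (`chrom`, `start`, `end`,
#'   `signal`), e.g. from [read_intervals()] with the `narrowpeak` dialect.
#' @return numeric matrix, sites x tracks.
#' @export
map_site_signals <- function(sites, tracks) {
  .assert(length(tracks) >= 1, "need at least one track")
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  site_gr <- .sites_gr(sites)
  vals <- matrix(0, nrow = nrow(sites), ncol = length(tracks),
                 dimnames = list(NULL, names(tracks)))
  for (t in names(tracks)) {
    tr <- tracks[[t]]
    .assert(all(c("chrom", "start", "end", "signal") %in% names(tr)),
            "track %s lacks chrom/start/end/signal columns", t)
    hits <- GenomicRanges::findOverlaps(site_gr, .sites_gr(tr))
    if (length(hits)) {
      mx <- tapply(tr$signal[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
      vals[as.integer(names(mx)), t] <- as.numeric(mx)
    }
  }
  vals
}

#' Quantile-normalize per-site signal columns across tracks
#'
#' Makes the value distribution of every track identical: each column's
#' sorted values are replaced by the across-track mean of sorted values
#' (the standard quantile-normalization reference), preserving within-track
#' rank order. Delegated to `limma::normalizeQuantiles`.
#'
#' @param values sites x tracks numeric matrix.
#' @return matrix of the same shape.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(10, 20, 30)))
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  .assert(all(is.finite(values)), "signals must be finite")
  if (ncol(values) == 1) {
    warning("single track: quantile normalization is a no-op", call. = FALSE)
    return(values)
  }
  if (nrow(values) == 1) {
    # one observation per track: the common reference is the mean
    return(matrix(mean(values), 1, ncol(values),
                  dimnames = dimnames(values)))
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' ChIP-seq score per site
#'
#' Per-site per-track maxima of overlapping peak signals
#' ([map_site_signals()]) are quantile-normalized across tracks and then
#' summed over tracks, yielding one conservation-weighted binding score per
#' site.
#'
#' @inheritParams map_site_signals
#' @return numeric vector of scores, one per site.
#' @export
chipseq_score <- function(sites, tracks) {
  vals <- map_site_signals(sites, tracks)
  if (ncol(vals) > 1) vals <- quantile_normalize(vals)
  rowSums(vals)
}

#' Rank-aggregate score and quartile stratification
#'
#' Motif and ChIP-seq scores live on incomparable scales (normal-like vs
#' Poisson-like), so they are combined multiplicatively on the rank scale:
#' `rank_score = rank(motif) * rank(chipseq)` with higher score = higher
#' rank and average ranks on ties. Sites are then cut into four
#' equally-populated quartiles of the rank score, Q1 holding the strongest
#' sites and Q4 the weakest; quartile sizes differ by at most 1.
#'
#' @param motif_scores,chipseq_scores numeric vectors of equal length
#'   (>= 4).
#' @return `data.frame` with columns `motif_score`, `chipseq_score`,
#'   `motif_rank`, `chipseq_rank`, `rank_score`, `quartile`.
#' @export
aggregate_rank_score <- function(motif_scores, chipseq_scores) {
  n <- length(motif_scores)
  .assert(n == length(chipseq_scores), "score vectors differ in length")
  .assert(n >= 4, "need at least 4 sites to form quartiles")
  if (length(unique(motif_scores)) == 1 ||
      length(unique(chipseq_scores)) == 1) {
    warning("a score vector is constant; its ranks are all tied",
            call. = FALSE)
  }
  rm_ <- rank(motif_scores, ties.method = "average")
  rc_ <- rank(chipseq_scores, ties.method = "average")
  rs <- rm_ * rc_
  # Q1 = top quarter by rank score; sizes differ by <= 1 by construction
  ord_rank <- rank(-rs, ties.method = "first")
  quart <- paste0("Q", ceiling(ord_rank * 4 / n))
  data.frame(motif_score = motif_scores, chipseq_score = chipseq_scores,
             motif_rank = rm_, chipseq_rank = rc_, rank_score = rs,
             quartile = factor(quart, levels = paste0("Q", 1:4)),
             stringsAsFactors = FALSE)
}

#' Score sites end to end
#'
#' Convenience wrapper: computes the ChIP-seq score from peak tracks,
#' combines it with the motif score into the rank-aggregate score, and
#' attaches `chipseq_score`, `rank_score` and `quartile` columns to the
#' site table.
#'
#' @param sites sites `data.frame` with a `motif_score` column.
#' @param tracks named list of peak tracks (see [map_site_signals()]).
#' @return `sites` with score columns added.
#' @export
score_sites <- function(sites, tracks) {
  .assert(!is.null(sites$motif_score), "sites lack motif_score")
  cs <- chipseq_score(sites, tracks)
  st <- aggregate_rank_score(sites$motif_score, cs)
  sites$chipseq_score <- cs
  sites$rank_score <- st$rank_score
  sites$quartile <- st$quartile
  sites
}
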