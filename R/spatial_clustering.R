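#' Inter-CTCF distances
#'
#' Gaps between adjacent site midpoints along each chromosome-arm sequence
#' (`M - 1` gaps per arm of M sites).
#'
#' @param sites sites `data.frame` with `arm_id`.
#' @return `data.frame` with columns `arm_id` and `gap_bp`.
#' @export
inter_site_distances <- function(sites) {
  arms <- .by_arm(sites)
  out <- lapply(names(arms), function(arm) {
    m <- arms[[arm]]$midpoint
    if (length(m) < 2) return(NULL)
    data.frame(arm_id = arm, gap_bp = diff(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(arm_id = character(), gap_bp = numeric())
  out
}

#' Maximum-gap clustering of CTCF sites
#'
#' Single-linkage clustering of adjacent sites: two neighbouring sites join
#' the same cluster when their gap is at most `d` bp. Clusters partition
#' each arm; `d = 1` gives one cluster per site (at > 1 bp midpoint
#' spacing), and `d` beyond the arm length gives one cluster per arm.
#'
#' @param sites sites `data.frame` with `arm_id`.
#' @param d clustering window in bp (>= 1).
#' @param gap_mode `"midpoint"` measures gaps midpoint-to-midpoint;
#'   `"interval"` measures the gap between the end of one motif interval
#'   and the start of the next (BED-style interval gap). Immaterial at kb
#'   scales.
#' @return `sites` with an added `cluster_id` column (unique across arms).
#' @export
cluster_by_distance <- function(sites, d, gap_mode = c("midpoint", "interval")) {
  .assert(d >= 1, "clustering window d must be >= 1")
  gap_mode <- match.arg(gap_mode)
  arms <- .by_arm(sites)
  offset <- 0L
  out <- lapply(arms, function(a) {
    M <- nrow(a)
    gaps <- if (gap_mode == "midpoint") diff(a$midpoint) else
      a$start[-1] - a$end[-M]
    new_cluster <- c(TRUE, gaps > d)
    ids <- cumsum(new_cluster) + offset
    offset <<- ids[M]
    a$cluster_id <- ids
    a
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Internal: per-pattern k-plet counts restricted to clusters at window d.
# Returns a named count vector over all 2^K patterns for each K in K_set.
.pattern_counts_in_clusters <- function(clustered, K_set) {
  counts <- lapply(K_set, function(K) {
    pats <- enumerate_patterns(K)$pattern
    setNames(numeric(length(pats)), pats)
  })
  names(counts) <- as.character(K_set)
  for (cl in split(clustered$orientation,
                   clustered$cluster_id)) {
    M <- length(cl)
    s <- paste(cl, collapse = "")
    for (K in K_set) {
      if (M < K) next
      n <- M - K + 1L
      windows <- substring(s, seq_len(n), seq_len(n) + K - 1L)
      tb <- table(windows)
      k <- as.character(K)
      counts[[k]][names(tb)] <- counts[[k]][names(tb)] + as.numeric(tb)
    }
  }
  counts
}

#' Pattern enrichment across clustering windows
#'
#' For each clustering window `d`, sites are clustered with
#' [cluster_by_distance()] and k-plets are extracted only inside clusters
#' (a k-plet spanning two clusters is not counted). Observed per-pattern
#' counts are compared to a uniform expectation over the `2^K` patterns of
#' the same size (`1/4` per di-plet, `1/8` per tri-plet, `1/16` per
#' tetra-plet of the total at that window), yielding a matrix of
#' `log10(observed / expected)`. Per-window Pearson chi-square p-values
#' against the uniform per-pattern expectation are also returned. As
#' `d` grows past the arm length, pattern counts converge to the
#' genome-wide [count_classes()] totals.
#'
#' @param sites sites `data.frame` with `arm_id`.
#' @param windows ascending numeric vector of clustering windows in bp.
#' @param K_set k-plet sizes to tabulate (subset of 2:4).
#' @param gap_mode see [cluster_by_distance()].
#' @return list with `log_enrichment` (rows = patterns ordered by K then
#'   class as in the pattern table, columns = windows), `observed` (same
#'   shape, raw counts), `totals` (per K per window) and `chisq_p`
#'   (per K per window). Windows with no k-plet of some K get `NA`.
#' @export
enrichment_by_window <- function(sites, windows, K_set = 2:4,
                                 gap_mode = c("midpoint", "interval")) {
  .assert(all(diff(windows) > 0), "windows must be sorted ascending")
  .assert(all(K_set %in% 2:4), "K_set must be within 2..4")
  gap_mode <- match.arg(gap_mode)
  pat_tab <- do.call(rbind, lapply(K_set, function(K) {
    cbind(enumerate_patterns(K), K = K)
  }))
  nw <- length(windows)
  obs <- matrix(0, nrow = nrow(pat_tab), ncol = nw,
                dimnames = list(pat_tab$pattern, as.character(windows)))
  totals <- matrix(0, nrow = length(K_set), ncol = nw,
                   dimnames = list(as.character(K_set), as.character(windows)))
  chisq_p <- totals * NA
  for (j in seq_len(nw)) {
    clustered <- cluster_by_distance(sites, windows[j], gap_mode)
    cnts <- .pattern_counts_in_clusters(clustered, K_set)
    for (K in K_set) {
      k <- as.character(K)
      v <- cnts[[k]]
      obs[names(v), j] <- v
      totals[k, j] <- sum(v)
      if (sum(v) > 0) {
        E <- rep(sum(v) / 2^K, 2^K)
        stat <- sum((v - E)^2 / E)
        chisq_p[k, j] <- pchisq(stat, 2^K - 1, lower.tail = FALSE)
      }
    }
  }
  expected <- obs * NA
  for (i in seq_len(nrow(pat_tab))) {
    K <- pat_tab$K[i]
    expected[i, ] <- totals[as.character(K), ] / 2^K
  }
  log_enr <- log10(obs / expected)
  log_enr[!is.finite(log_enr)] <- NA
  list(patterns = pat_tab, log_enrichment = log_enr, observed = obs,
       totals = totals, chisq_p = chisq_p, windows = windows)
}

#' Span distributions of k-plets by class
#'
#' Groups k-plet spans (distance from the most upstream to the most
#' downstream member site) by orientation class and compares classes
#' pairwise with Bonferroni-corrected two-sample t tests.
#'
#' @param kplets output of [extract_kplets()] with `span_bp` available.
#' @return list with `spans` (data.frame class/span_bp), `medians` and
#'   `pairwise_p` (matrix from [stats::pairwise.t.test()]).
#' @export
pattern_span <- function(kplets) {
  .assert(nrow(kplets) > 0 && !all(is.na(kplets$span_bp)),
          "k-plets carry no spans")
  .assert(!anyNA(kplets$class), "k-plets must be classified (K >= 2)")
  spans <- data.frame(class = kplets$class, span_bp = kplets$span_bp)
  med <- tapply(spans$span_bp, spans$class, median)
  pw <- if (nlevels(droplevels(spans$class)) >= 2) {
    stats::pairwise.t.test(spans$span_bp, spans$class,
                           p.adjust.method = "bonferroni")$p.value
  } else NULL
  list(spans = spans, medians = med, pairwise_p = pw)
}

#' Enrichment robustness under quartile removal
#'
#' Recomputes [enrichment_by_window()] on subsets of sites obtained by
#' dropping score quartiles (e.g. the strongest 25%), probing whether the
#' spatial orientation patterns depend on strong sites only.
#'
#' @param sites sites `data.frame` with `arm_id` and a `quartile` column
#'   (Q1 = strongest, see [aggregate_rank_score()]).
#' @param windows clustering windows in bp.
#' @param drop list of character vectors; each element names the quartiles
#'   to remove for one subset run.
#' @param K_set k-plet sizes.
#' @return named list of [enrichment_by_window()] results, one per subset
#'   (names like `"drop:Q1"`), plus `"full"` for the complete set.
#' @export
quartile_robustness <- function(sites, windows,
                                drop = list("Q1", "Q4", c("Q3", "Q4")),
                                K_set = 2:4) {
  .assert(!is.null(sites$quartile), "sites lack quartile assignments")
  out <- list(full = enrichment_by_window(sites, windows, K_set))
  for (dq in drop) {
    keep <- !(sites$quartile %in% dq)
    .assert(any(keep), "dropping %s empties the site set",
            paste(dq, collapse = "+"))
    out[[paste0("drop:", paste(dq, collapse = "+"))]] <-
      enrichment_by_window(sites[keep, , drop = FALSE], windows, K_set)
  }
  out
}
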