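#' Extract boundary positions from boundary datasets
#'
#' Every TAD boundary region of every cell type contributes two boundary
#' positions: its start and its stop coordinate.
#'
#' @param datasets named list of boundary `data.frame`s (`chrom`, `start`,
#'   `end`), one per cell type.
#' @return `data.frame` with columns `chrom`, `pos`, `cell_type`,
#'   `origin` (`"start"`/`"stop"`), sorted by (`chrom`, `pos`).
#' @export
boundary_positions <- function(datasets) {
  .assert(length(datasets) >= 1, "need at least one boundary dataset")
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("celltype", seq_along(datasets))
  }
  out <- do.call(rbind, lapply(names(datasets), function(ct) {
    b <- datasets[[ct]]
    data.frame(chrom = rep(b$chrom, 2),
               pos = c(b$start, b$end),
               cell_type = ct,
               origin = rep(c("start", "stop"), each = nrow(b)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the boundary-position proximity graph
#'
#' Nodes are boundary positions; an undirected, unweighted edge connects
#' two positions on the same chromosome whose distance is at most the
#' detection window `w` (no self edges). This is the graph on which
#' communities of nearby boundary positions are detected.
#'
#' @param positions `data.frame` from [boundary_positions()].
#' @param w detection window in bp (25 kb at the reference Hi-C
#'   resolution).
#' @return an `igraph` graph whose vertices carry `chrom`, `pos`,
#'   `cell_type` attributes; vertex order is canonical (sorted by
#'   chromosome then position).
#' @export
build_position_graph <- function(positions, w = 25000) {
  .assert(w > 0, "detection window w must be > 0")
  .assert(nrow(positions) > 0, "no boundary positions")
  positions <- positions[order(positions$chrom, positions$pos), , drop = FALSE]
  n <- nrow(positions)
  edges <- vector("list", n)
  # positions are sorted: for node i, scan forward while within w
  for (i in seq_len(n)) {
    j <- i + 1L
    hits <- integer(0)
    while (j <= n && positions$chrom[j] == positions$chrom[i] &&
           positions$pos[j] - positions$pos[i] <= w) {
      hits <- c(hits, j)
      j <- j + 1L
    }
    if (length(hits)) edges[[i]] <- rbind(i, hits)
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(em)) g <- igraph::add_edges(g, as.vector(em))
  igraph::V(g)$chrom <- positions$chrom
  igraph::V(g)$pos <- positions$pos
  igraph::V(g)$cell_type <- positions$cell_type
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Detect communities of boundary positions
#'
#' Louvain modularity maximisation on the position graph. Unlike connected
#' components, modularity optimisation can split a chain of loosely linked
#' positions into dense communities. The heuristic is stochastic, so it is
#' restarted `n_restarts` times from the given seed and the
#' highest-modularity partition is kept; the whole procedure is
#' deterministic given the seed.
#'
#' @param graph graph from [build_position_graph()].
#' @param seed RNG seed for the heuristic.
#' @param n_restarts independent restarts to take the best of.
#' @return integer membership vector over the graph's vertices.
#' @export
detect_communities <- function(graph, seed = 1, n_restarts = 10) {
  set.seed(seed)
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    comm <- igraph::cluster_louvain(graph)
    q <- igraph::modularity(comm)
    if (q > best_q) {
      best_q <- q
      best <- comm
    }
  }
  igraph::membership(best)
}

#' Derive consensus boundaries from position communities
#'
#' Each community of boundary positions yields one consensus boundary: the
#' region from its most upstream to its most downstream position (a
#' zero-length region for singleton communities), a centre halfway, and a
#' conservation score equal to the number of distinct cell types
#' contributing positions.
#'
#' @param positions `data.frame` as passed to [build_position_graph()]
#'   (same sorted order as the graph's vertices).
#' @param membership membership vector from [detect_communities()].
#' @return `data.frame` with columns `chrom`, `start`, `end`, `centre`,
#'   `score`, `n_positions`, sorted by coordinate.
#' @export
derive_consensus <- function(positions, membership) {
  positions <- positions[order(positions$chrom, positions$pos), , drop = FALSE]
  .assert(length(membership) == nrow(positions),
          "membership does not match positions")
  out <- do.call(rbind, lapply(split(seq_len(nrow(positions)), membership),
    function(idx) {
      p <- positions[idx, , drop = FALSE]
      data.frame(chrom = p$chrom[1],
                 start = min(p$pos), end = max(p$pos),
                 centre = .midpoint(min(p$pos), max(p$pos)),
                 score = length(unique(p$cell_type)),
                 n_positions = nrow(p),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus TAD boundaries across cell types
#'
#' End-to-end boundary consensus: extract start/stop positions from every
#' cell type's boundary set, link positions within the detection window
#' `w`, detect Louvain communities, and emit one consensus boundary per
#' community with its conservation score (1 = cell-type specific, up to
#' the number of input datasets).
#'
#' @inheritParams boundary_positions
#' @param w detection window in bp.
#' @param seed RNG seed for community detection.
#' @return consensus `data.frame`, see [derive_consensus()].
#' @examples
#' ds <- list(a = data.frame(chrom = "chr1", start = 1e6, end = 1.01e6),
#'            b = data.frame(chrom = "chr1", start = 1.005e6, end = 1.015e6))
#' consensus_boundaries(ds, w = 25000)
#' @export
consensus_boundaries <- function(datasets, w = 25000, seed = 1) {
  pos <- boundary_positions(datasets)
  g <- build_position_graph(pos, w)
  memb <- detect_communities(g, seed)
  derive_consensus(pos, memb)
}

#' Overlap of consensus boundaries with a reference boundary set
#'
#' To avoid length biases (consensus regions shrink as conservation
#' grows), every consensus boundary is replaced by its centre extended
#' `flank` bp both ways before intersecting with the reference set. The
#' intersect fraction is reported per conservation score.
#'
#' @param consensus consensus `data.frame` from [consensus_boundaries()].
#' @param reference `data.frame` of reference boundary intervals
#'   (`chrom`, `start`, `end`).
#' @param flank half-width of the centred window in bp.
#' @return `data.frame` with columns `score`, `n`, `n_overlap`,
#'   `fraction`.
#' @export
score_overlap_with_reference <- function(consensus, reference,
                                         flank = 25000) {
  .assert(nrow(reference) > 0, "empty reference boundary set")
  win <- data.frame(chrom = consensus$chrom,
                    start = pmax(0, consensus$centre - flank),
                    end = consensus$centre + flank)
  hits <- GenomicRanges::findOverlaps(.sites_gr(win), .sites_gr(reference))
  has <- seq_len(nrow(consensus)) %in% S4Vectors::queryHits(hits)
  agg <- lapply(split(has, consensus$score), function(h) {
    c(n = length(h), n_overlap = sum(h), fraction = mean(h))
  })
  out <- data.frame(score = as.integer(names(agg)),
                    do.call(rbind, agg), row.names = NULL)
  out[order(out$score), , drop = FALSE]
}
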