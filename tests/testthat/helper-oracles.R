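# Fixture builders and independent brute-force oracles. Oracles are kept
# deliberately naive and separate from the package implementation.

# Build a sites data.frame from orientation strings, one string per arm.
# Midpoints default to 1 kb spacing starting at 10 kb.
sites_from_orientations <- function(..., midpoints = NULL, chrom = NULL,
                                    spacing = 1000) {
  strings <- list(...)
  if (length(strings) == 1 && is.list(strings[[1]])) strings <- strings[[1]]
  out <- lapply(seq_along(strings), function(i) {
    o <- strsplit(strings[[i]], "")[[1]]
    m <- if (is.null(midpoints)) 10000 + spacing * seq_along(o) else
      midpoints[[i]]
    ch <- if (is.null(chrom)) paste0("chr", i) else chrom[[i]]
    data.frame(chrom = ch, start = m - 10, end = m + 10,
               orientation = o, midpoint = m,
               arm_id = paste0("arm", i), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Hand-frozen class table for every di-, tri- and tetra-plet pattern
# (the tabulated classification, independent of the adjacency-scan rule).
ORACLE_CLASSES <- c(
  ">>" = "Same", "<<" = "Same", "><" = "Conv", "<>" = "Div",
  ">>>" = "Same", "<<<" = "Same",
  ">><" = "Conv", "><<" = "Conv",
  "<>>" = "Div", "<<>" = "Div",
  "><>" = "ConvDiv", "<><" = "ConvDiv",
  ">>>>" = "Same", "<<<<" = "Same",
  ">>><" = "Conv", ">><<" = "Conv", "><<<" = "Conv",
  "<>>>" = "Div", "<<>>" = "Div", "<<<>" = "Div",
  ">><>" = "ConvDiv", "><>>" = "ConvDiv", "><><" = "ConvDiv",
  "><<>" = "ConvDiv", "<>><" = "ConvDiv", "<><>" = "ConvDiv",
  "<><<" = "ConvDiv", "<<><" = "ConvDiv"
)

# Naive class counting: substring every window, look the class up.
oracle_count_classes <- function(ori, K) {
  counts <- c(Same = 0, Conv = 0, Div = 0, ConvDiv = 0)
  M <- length(ori)
  if (M < K) return(counts)
  s <- paste(ori, collapse = "")
  for (i in seq_len(M - K + 1)) {
    cls <- ORACLE_CLASSES[[substr(s, i, i + K - 1)]]
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# Brute-force full-stop extrusion: for every loading gap, the nearest
# forward site to the left and nearest reverse site to the right anchor.
oracle_full_stop <- function(ori) {
  loops <- list()
  M <- length(ori)
  for (i in seq_len(M - 1)) {
    left <- rev(which(ori[seq_len(i)] == ">"))
    right <- i + which(ori[(i + 1):M] == "<")
    if (length(left) && length(right)) {
      loops[[length(loops) + 1]] <- c(left[1], right[1])
    }
  }
  unique(do.call(rbind, loops))
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, next_max) {
    k <- length(memb) + 1
    if (k > n) {
      out[[length(out) + 1]] <<- memb
      return()
    }
    for (g in seq_len(next_max)) {
      rec(c(memb, g), max(next_max, g + 1))
    }
  }
  rec(integer(0), 1)
  out
}

# Newman modularity of a membership vector on an undirected graph.
oracle_modularity <- function(adj, memb) {
  m2 <- sum(adj)  # 2m
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  B <- adj - outer(deg, deg) / m2
  same <- outer(memb, memb, "==")
  sum(B[same]) / m2
}

# Best modularity over every partition (exhaustive; n <= 10).
oracle_best_modularity <- function(adj) {
  max(vapply(all_partitions(nrow(adj)), function(p)
    oracle_modularity(adj, p), numeric(1)))
}
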