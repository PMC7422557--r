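#' Classify an orientation pattern
#'
#' A k-plet of adjacent CTCF sites is summarised by its orientation string
#' over `{>, <}` and classified by which adjacency types it contains:
#' \describe{
#'   \item{Same}{no `><` and no `<>` adjacency (e.g. `>>>`)}
#'   \item{Conv}{convergent `><` adjacencies only (e.g. `>><`, `><<`)}
#'   \item{Div}{divergent `<>` adjacencies only (e.g. `<>>`, `<<>`)}
#'   \item{ConvDiv}{both kinds present (e.g. `><>`, `<><`)}
#' }
#' The adjacency-scan rule coincides with the tabulated classes for di- to
#' tetra-plets and extends to any pattern length >= 2.
#'
#' @param pattern character vector of orientation strings over `{>, <}`,
#'   each of length >= 2.
#' @return factor with levels `Same`, `Conv`, `Div`, `ConvDiv`.
#' @examples
#' classify_pattern(c(">><", "<>>", "><>", ">>>"))
#' @export
classify_pattern <- function(pattern) {
  .assert(all(grepl("^[><]+$", pattern)),
          "patterns may contain only '>' and '<'")
  .assert(all(nchar(pattern) >= 2), "patterns must have length >= 2")
  has_conv <- grepl("><", pattern, fixed = TRUE)
  has_div <- grepl("<>", pattern, fixed = TRUE)
  cls <- ifelse(has_conv & has_div, "ConvDiv",
         ifelse(has_conv, "Conv",
         ifelse(has_div, "Div", "Same")))
  factor(cls, levels = .CLASS_LEVELS)
}

#' Enumerate all orientation patterns of length K
#'
#' Lists the `2^K` distinct orientation strings and their classes, ordered
#' by class (Same, Conv, Div, ConvDiv). For K = 1 the two patterns carry no
#' class (classification needs an adjacency).
#'
#' @param K pattern length, 1 to 4.
#' @return `data.frame` with columns `pattern` and `class`.
#' @examples
#' enumerate_patterns(3)   # 8 patterns, 2 per class
#' @export
enumerate_patterns <- function(K) {
  .assert(length(K) == 1 && K %in% 1:4, "K must be an integer in 1..4")
  pats <- do.call(paste0, expand.grid(rep(list(c(">", "<")), K),
                                      stringsAsFactors = FALSE))
  if (K == 1) {
    return(data.frame(pattern = sort(pats, decreasing = TRUE),
                      class = factor(NA, levels = .CLASS_LEVELS),
                      stringsAsFactors = FALSE))
  }
  cls <- classify_pattern(pats)
  ord <- order(as.integer(cls), pats, method = "radix", decreasing = c(FALSE, TRUE))
  data.frame(pattern = pats[ord], class = cls[ord], stringsAsFactors = FALSE)
}

#' Theoretical class proportions under random orientations
#'
#' Expected class frequencies of k-plets when every site's orientation is
#' drawn independently and equiprobably, obtained by brute force over all
#' `2^K` equiprobable patterns: di-plets (1/2, 1/4, 1/4, 0), tri-plets 1/4
#' each, tetra-plets (2/16, 3/16, 3/16, 8/16).
#'
#' @param K pattern length, 2 to 4.
#' @return named numeric vector over the four classes, summing to 1.
#' @export
theoretical_class_proportions <- function(K) {
  .assert(length(K) == 1 && K %in% 2:4, "K must be 2, 3 or 4")
  tab <- table(enumerate_patterns(K)$class)
  p <- setNames(as.numeric(tab) / 2^K, names(tab))
  p[p > 0]  # di-plets have no ConvDiv class
}

# Internal: pull per-arm orientation vectors out of a sites data.frame.
# Accepts a plain character vector (one arm) for convenience.
.orientation_list <- function(x) {
  if (is.character(x)) {
    if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
    return(list(arm = x))
  }
  lapply(.by_arm(x), function(a) a$orientation)
}

#' Extract all k-plets from site sequences
#'
#' Slides a window of K adjacent sites along each chromosome-arm sequence
#' (stride 1), yielding `M - K + 1` k-plets per arm of M sites. The span of
#' a k-plet is the distance from its most upstream to its most downstream
#' site midpoint.
#'
#' @param sites sites `data.frame` carrying `arm_id` (see [split_by_arm()]),
#'   or a character vector of orientations for a single sequence.
#' @param K k-plet size (>= 1).
#' @return `data.frame` with columns `arm_id`, `index` (window start within
#'   the arm), `pattern`, `class` (NA for K = 1) and `span_bp` (NA when
#'   positions are unavailable).
#' @export
extract_kplets <- function(sites, K) {
  .assert(length(K) == 1 && K >= 1, "K must be >= 1")
  oris <- .orientation_list(sites)
  mids <- if (is.data.frame(sites)) {
    lapply(.by_arm(sites), function(a) a$midpoint)
  } else NULL
  out <- lapply(names(oris), function(arm) {
    o <- oris[[arm]]
    M <- length(o)
    if (M < K) return(NULL)
    n <- M - K + 1L
    s <- paste(o, collapse = "")
    pats <- substring(s, seq_len(n), seq_len(n) + K - 1L)
    span <- if (!is.null(mids)) {
      m <- mids[[arm]]
      m[seq_len(n) + K - 1L] - m[seq_len(n)]
    } else NA_real_
    data.frame(arm_id = arm, index = seq_len(n), pattern = pats,
               span_bp = span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning("no sequence has >= K sites; returning empty k-plet list",
            call. = FALSE)
    out <- data.frame(arm_id = character(), index = integer(),
                      pattern = character(), span_bp = numeric())
  }
  out$class <- if (K >= 2 && nrow(out)) classify_pattern(out$pattern) else
    factor(rep(NA_character_, nrow(out)), levels = .CLASS_LEVELS)
  out[, c("arm_id", "index", "pattern", "class", "span_bp")]
}

# Internal fast path: class counts of K-plets for a list of per-arm
# orientation vectors, via cumulative sums over adjacency indicators.
.count_classes_fast <- function(oris, K) {
  tot <- setNames(numeric(4), .CLASS_LEVELS)
  for (o in oris) {
    M <- length(o)
    if (M < K) next
    g <- o == ">"
    if (K == 1) next
    conv <- g[-M] & !g[-1]
    div <- !g[-M] & g[-1]
    n <- M - K + 1L
    i <- seq_len(n)
    Cc <- c(0, cumsum(conv))
    Cd <- c(0, cumsum(div))
    nc <- Cc[i + K - 1L] - Cc[i]
    nd <- Cd[i + K - 1L] - Cd[i]
    tot["Same"] <- tot["Same"] + sum(nc == 0 & nd == 0)
    tot["Conv"] <- tot["Conv"] + sum(nc > 0 & nd == 0)
    tot["Div"] <- tot["Div"] + sum(nc == 0 & nd > 0)
    tot["ConvDiv"] <- tot["ConvDiv"] + sum(nc > 0 & nd > 0)
  }
  tot
}

#' Count k-plet classes genome wide
#'
#' Tallies the Same / Conv / Div / ConvDiv classes of all k-plets across
#' chromosome-arm sequences. The total is `sum over arms of (M - K + 1)`.
#'
#' @inheritParams extract_kplets
#' @param K k-plet size, >= 2.
#' @return list with elements `K`, `counts` (named vector over the four
#'   classes) and `total`.
#' @export
count_classes <- function(sites, K) {
  .assert(length(K) == 1 && K >= 2, "K must be >= 2")
  counts <- .count_classes_fast(.orientation_list(sites), K)
  list(K = K, counts = counts, total = sum(counts))
}

#' Annotate sites with their tri-plet class
#'
#' Each interior site of an arm is assigned the class of the tri-plet
#' centred on it (a function of its own orientation and that of its two
#' neighbours). The first and last site of each arm get `NA`.
#'
#' @param sites sites `data.frame` with `arm_id`.
#' @return `sites` with a `triplet_class` factor column added.
#' @export
assign_triplet_classes <- function(sites) {
  arms <- .by_arm(sites)
  cls <- lapply(arms, function(a) {
    M <- nrow(a)
    out <- factor(rep(NA_character_, M), levels = .CLASS_LEVELS)
    if (M >= 3) {
      s <- paste(a$orientation, collapse = "")
      pats <- substring(s, seq_len(M - 2L), seq_len(M - 2L) + 2L)
      out[2:(M - 1L)] <- classify_pattern(pats)
    }
    out
  })
  sites$triplet_class <- unlist(cls, use.names = FALSE)
  sites$triplet_class <- factor(sites$triplet_class, levels = .CLASS_LEVELS)
  sites
}

#' Pearson chi-square test of class counts against fixed proportions
#'
#' Computes the Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' `E = total * prop` and `df = number of classes - 1`; the proportions are
#' fixed a priori (not estimated from the data).
#'
#' @param counts named numeric vector of observed class counts.
#' @param expected_props named numeric proportions over the same classes,
#'   summing to 1.
#' @return list with `statistic`, `df` and `p_value`.
#' @examples
#' class_chisq_test(c(Same = 10, Conv = 30), c(Same = 0.5, Conv = 0.5))
#' @export
class_chisq_test <- function(counts, expected_props) {
  .assert(length(counts) == length(expected_props),
          "counts and expected_props differ in length")
  if (!is.null(names(counts)) && !is.null(names(expected_props))) {
    expected_props <- expected_props[names(counts)]
  }
  .assert(abs(sum(expected_props) - 1) < 1e-8, "expected_props must sum to 1")
  E <- sum(counts) * expected_props
  .assert(all(E > 0), "zero expected count")
  stat <- sum((counts - E)^2 / E)
  df <- length(counts) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Internal: chi-square-style distance between class frequencies and the
# theoretical proportions: sum_c (f_c - p_c)^2 / p_c.
.class_distance <- function(counts, props) {
  counts <- counts[names(props)]
  f <- counts / sum(counts)
  sum((f - props)^2 / props)
}

#' Orientation randomization test of class abundances
#'
#' Measures how far the observed k-plet class frequencies lie from the
#' theoretical proportions under random orientations, and calibrates that
#' distance against a null distribution obtained by redrawing every site's
#' orientation independently and equiprobably (positions fixed) `n_reps`
#' times. The distance statistic is `sum_c (f_c - p_c)^2 / p_c` over the
#' class frequencies.
#'
#' @inheritParams count_classes
#' @param n_reps number of randomizations (the reference analysis used
#'   10,000).
#' @param seed RNG seed.
#' @return list with `observed_distance`, `null_distances`, `p_raw` (plain
#'   fraction of null distances >= observed; can be 0 when the observed
#'   distance exceeds every replicate) and `p_adjusted` (`(r + 1)/(n + 1)`).
#' @export
randomization_test <- function(sites, K, n_reps = 10000, seed = 1) {
  .assert(n_reps >= 1, "n_reps must be >= 1")
  oris <- .orientation_list(sites)
  props <- theoretical_class_proportions(K)
  obs <- .class_distance(.count_classes_fast(oris, K), props)
  lens <- vapply(oris, length, integer(1))
  set.seed(seed)
  null <- vapply(seq_len(n_reps), function(r) {
    rand <- lapply(lens, function(M) {
      c("<", ">")[1L + (runif(M) < 0.5)]
    })
    .class_distance(.count_classes_fast(rand, K), props)
  }, numeric(1))
  r <- sum(null >= obs)
  list(observed_distance = obs, null_distances = null,
       p_raw = r / n_reps, p_adjusted = (r + 1) / (n_reps + 1))
}

#' Maximal genome-wide convergent/divergent skew
#'
#' On any single sequence, convergent (`><`) and divergent (`<>`)
#' adjacencies must alternate, so the per-sequence count difference
#' `|#Conv - #Div|` of k-plets is bounded (1 for di-plets, 2 for
#' tri-plets, 3 for tetra-plets). The bound is established here by brute
#' force over every orientation sequence up to `max_len` sites and then
#' multiplied by the number of independent arm sequences.
#'
#' @param K k-plet size (2 to 4).
#' @param n_arms number of chromosome-arm sequences (42 for the human
#'   autosomes minus acrocentric p-arms).
#' @param max_len exhaustive search depth in sites.
#' @return list with `per_sequence_bound`, `genome_wide_bound`
#'   (`per_sequence_bound * n_arms`) and `attaining_sequence`, an explicit
#'   worst-case orientation string.
#' @export
max_class_skew <- function(K, n_arms = 42, max_len = 9) {
  .assert(K %in% 2:4, "K must be 2, 3 or 4")
  best <- 0
  best_seq <- ""
  for (M in K:max_len) {
    grid <- expand.grid(rep(list(c(">", "<")), M), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      o <- as.character(grid[i, ])
      cnt <- .count_classes_fast(list(o), K)
      skew <- abs(cnt["Conv"] - cnt["Div"])
      if (skew > best) {
        best <- skew
        best_seq <- paste(o, collapse = "")
      }
    }
  }
  list(per_sequence_bound = as.numeric(best),
       genome_wide_bound = as.numeric(best) * n_arms,
       attaining_sequence = best_seq)
}
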