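#' Define a chromosome-arm layout
#'
#' A genome layout partitions each chromosome into arms (typically p and q,
#' split at the centromere). Arms are the unit within which CTCF sites form
#' ordered sequences: k-plets, clusters and extrusion events never cross an
#' arm boundary or the centromere gap.
#'
#' @param arm_id character vector of unique arm identifiers.
#' @param chrom chromosome of each arm.
#' @param start,end 0-based half-open arm interval in bp.
#' @return A `data.frame` with columns `arm_id`, `chrom`, `start`, `end`.
#' @examples
#' genome_layout(c("chr1p", "chr1q"), "chr1", c(0, 130e6), c(120e6, 240e6))
#' @export
genome_layout <- function(arm_id, chrom, start, end) {
  layout <- data.frame(
    arm_id = as.character(arm_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  .assert(nrow(layout) > 0, "layout must contain at least one arm")
  .assert(!anyDuplicated(layout$arm_id), "arm_ids must be unique")
  .assert(all(layout$start < layout$end), "arm start must be < end")
  for (ch in unique(layout$chrom)) {
    a <- layout[layout$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1) {
      .assert(all(a$end[-nrow(a)] <= a$start[-1]),
              "arms overlap on chromosome %s", ch)
    }
  }
  layout[order(layout$chrom, layout$start), , drop = FALSE]
}

#' Read an arm/centromere layout from a BED file
#'
#' The BED name column (column 4) provides the arm identifier; when absent,
#' identifiers `chrom:start-end` are fabricated.
#'
#' @param path BED3/BED4 file (gzip transparent).
#' @return A layout `data.frame` as from [genome_layout()].
#' @export
read_layout <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name) else
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  genome_layout(ids, as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Read a CTCF site table
#'
#' Reads a tab-separated site table with header columns `chrom`, `start`,
#' `end`, `orientation` and any number of additional score columns
#' (`motif_score`, `chipseq_score`, ...). Orientation is `>` for a motif on
#' the forward strand and `<` for the reverse strand; `+`/`-` are accepted
#' and converted. Rows without an orientation call (empty, `NA` or `.`) are
#' dropped with a warning reporting the count, matching the upstream
#' exclusion of binding sites lacking a motif match.
#'
#' @param path tab-separated file, gzip transparent, with a header line.
#' @param one_based set `TRUE` if the table's coordinates are 1-based
#'   inclusive; they are converted to the internal 0-based half-open
#'   convention at read time.
#' @return A `data.frame` of sites sorted by (`chrom`, `start`) with a
#'   `midpoint` column (`floor((start + end) / 2)`).
#' @export
read_sites <- function(path, one_based = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, comment.char = "")
  need <- c("chrom", "start", "end", "orientation")
  .assert(all(need %in% names(df)),
          "site table must have columns: %s", paste(need, collapse = ", "))
  if (one_based) df$start <- df$start - 1L
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("malformed coordinates (start >= end) at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  ori <- as.character(df$orientation)
  ori[ori == "+"] <- ">"
  ori[ori == "-"] <- "<"
  keep <- !is.na(ori) & ori %in% c(">", "<")
  if (any(!keep)) {
    warning(sprintf("dropped %d site(s) without orientation", sum(!keep)),
            call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  df$orientation <- ori[keep]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$midpoint <- .midpoint(df$start, df$end)
  rownames(df) <- NULL
  df
}

#' Write a CTCF site table
#'
#' Inverse of [read_sites()]; coordinates are written 0-based half-open.
#'
#' @param sites sites `data.frame`.
#' @param path output path.
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic interval records in a declared dialect
#'
#' Thin wrapper over the standard track importers, returning plain 0-based
#' half-open data.frames. Dialects:
#' \describe{
#'   \item{bed}{BED3-6; optional `name`, `score`, `strand`.}
#'   \item{narrowpeak}{ENCODE narrowPeak (10 columns); the per-peak
#'     enrichment (`signalValue`, column 7) is returned as `signal`.}
#'   \item{bedgraph}{4 columns; the track value is returned as `value`.}
#'   \item{bedpe}{paired intervals, >= 6 columns, optional `name`/`score`.}
#' }
#' A file whose column count does not match the declared dialect raises a
#' format error.
#'
#' @param path input file (gzip transparent).
#' @param dialect one of `"bed"`, `"narrowpeak"`, `"bedgraph"`, `"bedpe"`.
#' @return A `data.frame`; for `bedpe`, columns `chrom1,start1,end1,
#'   chrom2,start2,end2` plus optional `name` and `score`.
#' @export
read_intervals <- function(path,
                           dialect = c("bed", "narrowpeak", "bedgraph",
                                       "bedpe")) {
  dialect <- match.arg(dialect)
  nfield <- .peek_fields(path)
  ok <- switch(dialect,
    bed = nfield >= 3 && nfield <= 6,
    narrowpeak = nfield == 10,
    bedgraph = nfield == 4,
    bedpe = nfield >= 6
  )
  .assert(ok, "file %s has %d columns; not valid %s", path, nfield, dialect)
  if (dialect == "bedpe") return(.read_bedpe(path))
  fmt <- c(bed = "bed", narrowpeak = "narrowPeak", bedgraph = "bedGraph")
  gr <- rtracklayer::import(path, format = fmt[[dialect]])
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (dialect == "bed") {
    if (!is.null(gr$name)) out$name <- gr$name
    if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
    st <- as.character(GenomicRanges::strand(gr))
    if (any(st != "*")) out$strand <- st
  } else if (dialect == "narrowpeak") {
    out$name <- gr$name
    out$signal <- gr$signalValue
    out$pvalue <- gr$pValue
    out$qvalue <- gr$qValue
    out$peak <- gr$peak
  } else {
    out$value <- as.numeric(gr$score)
  }
  out
}

.peek_fields <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  n <- count.fields(con, sep = "\t", comment.char = "#", quote = "")
  .assert(length(n) > 0, "file %s is empty", path)
  .assert(length(unique(n)) == 1,
          "file %s has a ragged column count", path)
  n[1]
}

.read_bedpe <- function(path) {
  df <- read.table(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   comment.char = "#")
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(df) >= 7) names(df)[7] <- "name"
  if (ncol(df) >= 8) names(df)[8] <- "score"
  df
}

#' Write paired intervals as BEDPE
#'
#' @param pairs `data.frame` with `chrom1,start1,end1,chrom2,start2,end2`
#'   and optional `name`, `score` columns.
#' @param path output path.
#' @export
write_bedpe <- function(pairs, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  .assert(all(cols %in% names(pairs)), "pairs lacks BEDPE columns")
  extra <- intersect(c("name", "score"), names(pairs))
  write.table(pairs[, c(cols, extra), drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Partition sites into chromosome-arm sequences
#'
#' Assigns every site to the arm containing its midpoint. Sites falling
#' outside all arms (e.g. inside a centromere gap) are dropped with a
#' warning reporting the count. Within each arm, sites are sorted by
#' midpoint, forming the ordered site sequences on which all k-plet and
#' clustering operations act.
#'
#' @param sites sites `data.frame` (needs `chrom`, `start`, `end`; a
#'   `midpoint` column is computed if absent).
#' @param layout layout `data.frame` from [genome_layout()].
#' @return The retained sites with an `arm_id` column, sorted by
#'   (`arm_id`, `midpoint`).
#' @export
split_by_arm <- function(sites, layout) {
  .assert(is.data.frame(layout) && nrow(layout) > 0, "empty layout")
  if (is.null(sites$midpoint)) sites$midpoint <- .midpoint(sites$start, sites$end)
  arm <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(layout))) {
    hit <- sites$chrom == layout$chrom[i] &
      sites$midpoint >= layout$start[i] & sites$midpoint < layout$end[i]
    arm[hit] <- layout$arm_id[i]
  }
  dropped <- sum(is.na(arm))
  if (dropped > 0) {
    warning(sprintf("dropped %d site(s) outside all arms", dropped),
            call. = FALSE)
  }
  out <- sites[!is.na(arm), , drop = FALSE]
  out$arm_id <- arm[!is.na(arm)]
  out <- out[order(match(out$arm_id, layout$arm_id), out$midpoint), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: split a sites data.frame (with arm_id) into an ordered list of
# per-arm data.frames; arms keep their first-appearance order.
.by_arm <- function(sites) {
  .assert(!is.null(sites$arm_id), "sites must carry arm_id (run split_by_arm)")
  split(sites, factor(sites$arm_id, levels = unique(sites$arm_id)))
}
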