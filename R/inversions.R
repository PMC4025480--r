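# Detection of recombination-suppressed blocks (putative inversions):
# long runs of physically dispersed markers collapsing to one map position.

#' Detect recombination-suppressed marker blocks
#'
#' Finds maximal runs of consecutive map markers whose total map span is at
#' most `eps_cM`, keeping runs with at least `min_markers` markers and a
#' physical span of at least `min_bp`. The physical span is the sum of each
#' involved scaffold's marker extent (inter-scaffold gaps are unknown, so the
#' span is an "at least" figure). Returned calls are non-overlapping, sorted
#' by linkage group and position. Defaults are calibrated to the smallest
#' block such suppression is expected to produce in a dense RIL map
#' (tens of markers over several Mb).
#'
#' @param map A `genetic_map`.
#' @param eps_cM Maximum map span of a block (default 1.0).
#' @param min_markers Minimum markers per block (default 20).
#' @param min_bp Minimum summed physical span (default 2e6).
#' @return data.frame of calls: group, first/last marker, marker count,
#'   physical and map spans, involved scaffolds.
#' @export
detect_blocks <- function(map, eps_cM = 1.0, min_markers = 20, min_bp = 2e6) {
  stopifnot(inherits(map, "genetic_map"))
  calls <- list()
  for (g in names(map$groups)) {
    df <- map$groups[[g]]
    pos <- df$pos_cM
    m <- length(pos)
    if (m < min_markers) next
    reach <- findInterval(pos + eps_cM + 1e-9, pos)
    i <- 1L
    while (i <= m) {
      j <- reach[i]
      maximal <- i == 1L || reach[i - 1L] < j
      ok <- FALSE
      if (maximal && j - i + 1L >= min_markers) {
        rows <- df[i:j, ]
        span_bp <- sum(vapply(split(rows, rows$scaffold_id), function(s) {
          max(s$end_bp) - min(s$start_bp)
        }, numeric(1)))
        if (span_bp >= min_bp) {
          calls[[length(calls) + 1L]] <- data.frame(
            group = as.integer(g),
            first_marker = rows$marker_id[1L],
            last_marker = rows$marker_id[nrow(rows)],
            first_index = i, last_index = j,
            n_markers = j - i + 1L,
            physical_span_bp = span_bp,
            map_span_cM = pos[j] - pos[i],
            start_cM = pos[i],
            scaffolds = paste(unique(rows$scaffold_id), collapse = ","))
          ok <- TRUE
        }
      }
      i <- if (ok) j + 1L else i + 1L
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(group = integer(), first_marker = character(),
               last_marker = character(), first_index = integer(),
               last_index = integer(), n_markers = integer(),
               physical_span_bp = numeric(), map_span_cM = numeric(),
               start_cM = numeric(), scaffolds = character())
  out <- out[order(out$group, out$start_cM), ]
  rownames(out) <- NULL
  out
}

#' Summarise detected suppression blocks
#'
#' Adds the map-gap signature: the cM gap between each block and its
#' flanking markers (large flanking gaps are typical of inversions in RIL
#' maps) plus the chromosome's median adjacent gap for reference.
#'
#' @param calls Output of [detect_blocks()].
#' @param map The `genetic_map` the calls came from.
#' @return The calls with `flank_gap_lo_cM`, `flank_gap_hi_cM` (`NA` at
#'   chromosome ends) and `chrom_median_gap_cM`; per-block marker lists in
#'   `attr(, "markers")`.
#' @export
block_report <- function(calls, map) {
  stopifnot(inherits(map, "genetic_map"))
  if (nrow(calls) == 0L) {
    calls$flank_gap_lo_cM <- numeric(0)
    calls$flank_gap_hi_cM <- numeric(0)
    calls$chrom_median_gap_cM <- numeric(0)
    attr(calls, "markers") <- list()
    return(calls)
  }
  mk <- vector("list", nrow(calls))
  lo <- hi <- med <- numeric(nrow(calls))
  for (r in seq_len(nrow(calls))) {
    df <- map$groups[[as.character(calls$group[r])]]
    i <- calls$first_index[r]
    j <- calls$last_index[r]
    lo[r] <- if (i > 1L) df$pos_cM[i] - df$pos_cM[i - 1L] else NA_real_
    hi[r] <- if (j < nrow(df)) df$pos_cM[j + 1L] - df$pos_cM[j] else NA_real_
    med[r] <- stats::median(diff(df$pos_cM))
    mk[[r]] <- df$marker_id[i:j]
  }
  calls$flank_gap_lo_cM <- lo
  calls$flank_gap_hi_cM <- hi
  calls$chrom_median_gap_cM <- med
  attr(calls, "markers") <- mk
  calls
}

#' Write inversion calls as TSV and BED
#'
#' @param calls Output of [detect_blocks()] (optionally [block_report()]).
#' @param map The source `genetic_map`.
#' @param tsv,bed Output paths (`NULL` to skip either).
#' @return Invisibly, the calls.
#' @export
write_inversion_calls <- function(calls, map, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    rows <- list()
    for (r in seq_len(nrow(calls))) {
      df <- map$groups[[as.character(calls$group[r])]]
      w <- df[calls$first_index[r]:calls$last_index[r], ]
      rows[[r]] <- data.frame(chrom = w$scaffold_id, start = w$start_bp,
                              end = w$end_bp,
                              name = sprintf("block_%d", r))
    }
    utils::write.table(do.call(rbind, rows), bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(calls)
}
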