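# SNP filter cascade and 50-kb window genotype caller.

new_snp_data <- function(snps, im_reads, alt_reads, ril_ids, true_geno = NULL) {
  stopifnot(nrow(snps) == nrow(im_reads), nrow(snps) == nrow(alt_reads),
            ncol(im_reads) == length(ril_ids))
  structure(list(snps = snps, im_reads = im_reads, alt_reads = alt_reads,
                 ril_ids = ril_ids, true_geno = true_geno),
            class = "snp_data")
}

#' @export
print.snp_data <- function(x, ...) {
  cat(sprintf("snp_data: %d SNPs x %d RILs, median total depth %g\n",
              nrow(x$snps), length(x$ril_ids),
              stats::median(rowSums(x$im_reads) + rowSums(x$alt_reads))))
  invisible(x)
}

.subset_snp_data <- function(x, keep) {
  new_snp_data(x$snps[keep, , drop = FALSE],
               x$im_reads[keep, , drop = FALSE],
               x$alt_reads[keep, , drop = FALSE],
               x$ril_ids,
               true_geno = if (!is.null(x$true_geno)) x$true_geno[keep, , drop = FALSE])
}

#' Filter SNPs by the five-criterion cascade
#'
#' Retains SNPs that (1) are biallelic, (2) have an unambiguous IM-parent
#' (IM767) base call, (3) have total read depth across all RILs between
#' `depth_min` and `depth_max` (inclusive), (4) have an alternative-base
#' frequency across RILs between `freq_min` and `freq_max` (inclusive), and
#' (5) have a fraction of RILs called heterozygous below `het_max` (strict).
#' Criteria are evaluated in this order; each rejected SNP is charged to the
#' first criterion it fails and per-criterion counts are attached as
#' `attr(, "rejection_log")`.
#'
#' @param snp_data A `snp_data` object (see [simulate_reads()],
#'   [read_snp_tsv()], [read_snp_vcf()]).
#' @param depth_min,depth_max Total-depth bounds (defaults 50 and 1000).
#' @param freq_min,freq_max Alternative-base frequency bounds (defaults 0.2
#'   and 0.8).
#' @param het_max Maximum fraction of called RILs heterozygous (default 0.25).
#' @param freq_weighting `"read"` (default) pools reads across RILs for
#'   criterion 4; `"ril"` averages per-RIL alternative-base frequencies.
#' @param p_hi,p_lo Per-RIL genotype thresholds used by criterion 5 (passed
#'   to [call_snp_genotypes()]).
#' @return A filtered `snp_data` with a `rejection_log` attribute.
#' @export
filter_snps <- function(snp_data, depth_min = 50, depth_max = 1000,
                        freq_min = 0.2, freq_max = 0.8, het_max = 0.25,
                        freq_weighting = c("read", "ril"),
                        p_hi = 0.9, p_lo = 0.1) {
  stopifnot(inherits(snp_data, "snp_data"))
  freq_weighting <- match.arg(freq_weighting)
  n <- nrow(snp_data$snps)
  log <- data.frame(criterion = c("biallelic", "im767_unambiguous",
                                  "total_depth", "alt_base_frequency",
                                  "het_fraction"),
                    n_rejected = 0L)
  if (n == 0L) {
    out <- snp_data
    attr(out, "rejection_log") <- log
    return(out)
  }
  alive <- rep(TRUE, n)
  charge <- function(pass, i) {
    rej <- alive & !pass
    log$n_rejected[i] <<- sum(rej)
    alive <<- alive & pass
  }
  s <- snp_data$snps
  charge(!is.na(s$im_base) & !is.na(s$alt_base) & s$im_base != s$alt_base, 1L)
  charge(s$im767_call != "AMBIGUOUS", 2L)
  tot <- rowSums(snp_data$im_reads) + rowSums(snp_data$alt_reads)
  charge(tot >= depth_min & tot <= depth_max, 3L)
  if (freq_weighting == "read") {
    af <- rowSums(snp_data$alt_reads) / pmax(tot, 1L)
  } else {
    d <- snp_data$im_reads + snp_data$alt_reads
    f <- snp_data$alt_reads / ifelse(d > 0, d, NA)
    af <- rowMeans(f, na.rm = TRUE)
  }
  charge(tot > 0 & af >= freq_min & af <= freq_max, 4L)
  calls <- call_snp_genotypes(snp_data, p_hi = p_hi, p_lo = p_lo)
  called <- rowSums(calls$geno != GENO_MISSING)
  hetfrac <- rowSums(calls$geno == GENO_HET) / pmax(called, 1L)
  charge(hetfrac < het_max, 5L)
  out <- .subset_snp_data(snp_data, alive)
  attr(out, "rejection_log") <- log
  out
}

#' Per-SNP, per-RIL genotype calls from allele depths
#'
#' A RIL's genotype at a SNP is IM/IM when the sample frequency of the IM
#' base among its reads exceeds `p_hi`, PR/PR when below `p_lo`, and IM/PR
#' (heterozygous) otherwise; RILs with zero reads are MISSING.
#'
#' @param snp_data A `snp_data` object.
#' @param p_hi,p_lo Frequency thresholds (defaults 0.9 and 0.1, strict).
#' @return A `snp_calls` object: SNP metadata, integer genotype matrix (see
#'   [geno_codes()]) and the per-cell IM-base frequency.
#' @export
call_snp_genotypes <- function(snp_data, p_hi = 0.9, p_lo = 0.1) {
  stopifnot(inherits(snp_data, "snp_data"))
  d <- snp_data$im_reads + snp_data$alt_reads
  f <- snp_data$im_reads / ifelse(d > 0, d, NA)
  geno <- matrix(GENO_HET, nrow(f), ncol(f), dimnames = dimnames(f))
  geno[!is.na(f) & f > p_hi] <- GENO_IM
  geno[!is.na(f) & f < p_lo] <- GENO_PR
  geno[is.na(f)] <- GENO_MISSING
  structure(list(snps = snp_data$snps, geno = geno, im_freq = f,
                 ril_ids = snp_data$ril_ids),
            class = "snp_calls")
}

#' @export
print.snp_calls <- function(x, ...) {
  cat(sprintf("snp_calls: %d SNPs x %d RILs (%.1f%% called)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(x$geno != GENO_MISSING)))
  invisible(x)
}

#' Neighbor-consistency filter for spurious SNPs
#'
#' A SNP is excluded when, aggregated over RILs, its genotype calls disagree
#' with the calls at other SNPs within `radius_bp` on the same scaffold more
#' than half the time. Comparisons where either call is MISSING or HET are
#' skipped; SNPs with no neighbor in range are retained. All SNPs are judged
#' against the original (unfiltered) call set.
#'
#' @param calls A `snp_calls` object.
#' @param radius_bp Neighborhood radius (default 50000).
#' @param max_disagreement Exclusion threshold on the disagreement fraction
#'   (default 0.5, strict).
#' @return A filtered `snp_calls`; excluded SNP indices in
#'   `attr(, "excluded")`.
#' @export
consistency_filter <- function(calls, radius_bp = 50000,
                               max_disagreement = 0.5) {
  stopifnot(inherits(calls, "snp_calls"))
  n <- nrow(calls$geno)
  keep <- rep(TRUE, n)
  for (sc in unique(calls$snps$scaffold_id)) {
    rows <- which(calls$snps$scaffold_id == sc)
    pos <- calls$snps$pos[rows]
    o <- order(pos)
    rows <- rows[o]
    pos <- pos[o]
    G <- calls$geno[rows, , drop = FALSE]
    A <- (G == GENO_IM) + 0
    B <- (G == GENO_PR) + 0
    CA <- apply(A, 2L, cumsum)
    CB <- apply(B, 2L, cumsum)
    if (length(rows) == 1L) next
    CA <- rbind(0, matrix(CA, ncol = ncol(A)))
    CB <- rbind(0, matrix(CB, ncol = ncol(B)))
    lo <- findInterval(pos - radius_bp, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + radius_bp, pos)
    WA <- CA[hi + 1L, , drop = FALSE] - CA[lo, , drop = FALSE] - A
    WB <- CB[hi + 1L, , drop = FALSE] - CB[lo, , drop = FALSE] - B
    disagree <- rowSums(A * WB + B * WA)
    agree <- rowSums(A * WA + B * WB)
    tot <- agree + disagree
    bad <- tot > 0 & disagree / pmax(tot, 1) > max_disagreement
    keep[rows[bad]] <- FALSE
  }
  out <- structure(list(snps = calls$snps[keep, , drop = FALSE],
                        geno = calls$geno[keep, , drop = FALSE],
                        im_freq = calls$im_freq[keep, , drop = FALSE],
                        ril_ids = calls$ril_ids),
                   class = "snp_calls")
  attr(out, "excluded") <- which(!keep)
  out
}

new_geno_matrix <- function(markers, geno, ril_ids, p = NULL,
                            truth_markers = NULL) {
  stopifnot(nrow(markers) == nrow(geno), ncol(geno) == length(ril_ids))
  rownames(markers) <- NULL
  structure(list(markers = markers, geno = geno, p = p, ril_ids = ril_ids,
                 truth_markers = truth_markers),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d RILs (%.1f%% called, %.2f%% HET)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(x$geno != GENO_MISSING),
              100 * mean(x$geno == GENO_HET)))
  invisible(x)
}

#' Window-based marker genotype calls
#'
#' Aggregates per-SNP calls within contiguous `window_bp` tiles of each
#' scaffold (tiling from scaffold coordinate 0; the final partial window is
#' kept as a marker). Within a window and RIL, `p` is the IM-allele
#' frequency among called SNPs, counting a HET SNP call as half an IM
#' allele: `p = (n_IM + 0.5 n_HET) / n_called`. The marker is called IM/IM
#' if `p > p_hi`, PR/PR if `p < p_lo`, IM/PR if `het_lo < p < het_hi`, and
#' MISSING otherwise (including windows with no called SNP).
#'
#' @param calls A `snp_calls` object (usually after [consistency_filter()]).
#' @param window_bp Window size (default 50000; a 5-Mb scaffold yields 100
#'   contiguous markers).
#' @param p_hi,p_lo,het_lo,het_hi Call thresholds (defaults 0.9, 0.1, 0.4,
#'   0.6, all strict).
#' @param scaffold_lengths Optional named vector of scaffold lengths used to
#'   emit trailing empty windows and cap the final window end.
#' @return A `geno_matrix`: marker metadata (`marker_id`, `scaffold_id`,
#'   `window_index`, `start_bp`, `end_bp`), integer genotype matrix, and the
#'   per-cell `p`.
#' @export
call_windows <- function(calls, window_bp = 50000, p_hi = 0.9, p_lo = 0.1,
                         het_lo = 0.4, het_hi = 0.6,
                         scaffold_lengths = NULL) {
  stopifnot(inherits(calls, "snp_calls"))
  win <- floor(calls$snps$pos / window_bp)
  key <- paste0(calls$snps$scaffold_id, ":", win)
  scafs <- unique(calls$snps$scaffold_id)
  mk <- list()
  for (sc in scafs) {
    len <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths)) {
      scaffold_lengths[[sc]]
    } else {
      (max(win[calls$snps$scaffold_id == sc]) + 1L) * window_bp
    }
    idx <- 0L:max(0L, ceiling(len / window_bp) - 1L)
    mk[[sc]] <- data.frame(scaffold_id = sc, window_index = idx,
                           start_bp = idx * window_bp,
                           end_bp = pmin((idx + 1L) * window_bp, len))
  }
  markers <- do.call(rbind, mk)
  markers$marker_id <- sprintf("%s:%d", markers$scaffold_id, markers$window_index)
  rownames(markers) <- NULL
  mkey <- markers$marker_id
  nIM <- rowsum((calls$geno == GENO_IM) + 0, key)
  nPR <- rowsum((calls$geno == GENO_PR) + 0, key)
  nHET <- rowsum((calls$geno == GENO_HET) + 0, key)
  # align aggregated windows onto the full marker list
  idx <- match(mkey, rownames(nIM))
  z <- matrix(0, length(mkey), ncol(calls$geno))
  get <- function(m) {
    out <- z
    out[!is.na(idx), ] <- m[idx[!is.na(idx)], , drop = FALSE]
    out
  }
  nIM <- get(nIM); nPR <- get(nPR); nHET <- get(nHET)
  ncall <- nIM + nPR + nHET
  p <- (nIM + 0.5 * nHET) / ifelse(ncall > 0, ncall, NA)
  geno <- matrix(GENO_MISSING, length(mkey), ncol(calls$geno),
                 dimnames = list(mkey, calls$ril_ids))
  geno[!is.na(p) & p > p_hi] <- GENO_IM
  geno[!is.na(p) & p < p_lo] <- GENO_PR
  geno[!is.na(p) & p > het_lo & p < het_hi] <- GENO_HET
  new_geno_matrix(markers[, c("marker_id", "scaffold_id", "window_index",
                              "start_bp", "end_bp")],
                  geno, calls$ril_ids, p = p)
}

#' Select the mapping subset of RILs and markers
#'
#' Keeps the `n_rils` RILs with the most complete genotyping (fewest MISSING
#' cells; ties broken by RIL id order), then restricts to markers called in
#' at least `completeness` of the kept RILs.
#'
#' @param gm A `geno_matrix`.
#' @param n_rils Number of RILs to keep (default 100).
#' @param completeness Minimum called fraction per marker (default 0.75).
#' @return A `geno_matrix` restricted to the mapping set.
#' @export
select_mapping_set <- function(gm, n_rils = 100, completeness = 0.75) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_rils <- .assert_count(n_rils, "n_rils")
  if (n_rils > ncol(gm$geno)) {
    warning("n_rils exceeds panel size; keeping all RILs")
    n_rils <- ncol(gm$geno)
  }
  miss <- colSums(gm$geno == GENO_MISSING)
  keep_ril <- sort(.order_by(miss, seq_along(miss))[seq_len(n_rils)])
  geno <- gm$geno[, keep_ril, drop = FALSE]
  called <- rowMeans(geno != GENO_MISSING)
  keep_mk <- called >= completeness
  new_geno_matrix(gm$markers[keep_mk, , drop = FALSE],
                  geno[keep_mk, , drop = FALSE],
                  gm$ril_ids[keep_ril],
                  p = if (!is.null(gm$p)) gm$p[keep_mk, keep_ril, drop = FALSE],
                  truth_markers = if (!is.null(gm$truth_markers))
                    gm$truth_markers[keep_mk, , drop = FALSE])
}

#' Per-marker segregation and heterozygosity summary
#'
#' IM allele frequency is allele-weighted: `(n_IM + 0.5 n_HET) / n_called`.
#' Markers with all cells MISSING are flagged and get `NA` frequencies.
#'
#' @param gm A `geno_matrix`.
#' @return data.frame with per-marker IM allele frequency, HET fraction
#'   (of called cells), MISSING fraction and an `undefined` flag.
#' @export
summarize_segregation <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  nIM <- rowSums(gm$geno == GENO_IM)
  nPR <- rowSums(gm$geno == GENO_PR)
  nHET <- rowSums(gm$geno == GENO_HET)
  ncall <- nIM + nPR + nHET
  data.frame(marker_id = gm$markers$marker_id,
             scaffold_id = gm$markers$scaffold_id,
             im_allele_freq = ifelse(ncall > 0, (nIM + 0.5 * nHET) / ncall, NA),
             het_fraction = ifelse(ncall > 0, nHET / ncall, NA),
             missing_fraction = 1 - ncall / ncol(gm$geno),
             undefined = ncall == 0)
}
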