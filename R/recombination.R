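# Recombination-rate estimation (cM/Mb) and geometric block-bootstrap CIs.

#' Per-scaffold recombination rates
#'
#' For every unbroken scaffold carrying at least 2 mapped markers, the map
#' span (cM of last minus first marker) divided by the physical span (end of
#' last window minus start of first window, in Mb) gives a cM/Mb point
#' estimate. Scaffolds split across linkage groups or with a single marker
#' are skipped and logged.
#'
#' @param map A `genetic_map`.
#' @return data.frame (`scaffold_id`, `group`, `n_markers`,
#'   `map_length_cM`, `physical_length_bp`, `rate_cM_per_Mb`) in genome
#'   (map) order, with skipped scaffolds in `attr(, "skipped")`.
#' @export
scaffold_rates <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  broken <- unique(map$breaks$scaffold_id)
  out <- list()
  skipped <- list()
  for (g in names(map$groups)) {
    df <- map$groups[[g]]
    for (sc in unique(df$scaffold_id)) {
      rows <- df[df$scaffold_id == sc, ]
      if (sc %in% broken) {
        skipped[[length(skipped) + 1L]] <- data.frame(scaffold_id = sc,
                                                      reason = "broken")
        next
      }
      if (nrow(rows) < 2L) {
        skipped[[length(skipped) + 1L]] <- data.frame(scaffold_id = sc,
                                                      reason = "single_marker")
        next
      }
      cM <- max(rows$pos_cM) - min(rows$pos_cM)
      # physical span between the outermost windows, in scaffold coordinates
      bp <- max(rows$end_bp) - min(rows$start_bp)
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = sc, group = as.integer(g), n_markers = nrow(rows),
        map_length_cM = cM, physical_length_bp = bp,
        rate_cM_per_Mb = cM / (bp / 1e6),
        first_pos_cM = min(rows$pos_cM))
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold_id = character(), group = integer(),
               n_markers = integer(), map_length_cM = numeric(),
               physical_length_bp = numeric(), rate_cM_per_Mb = numeric(),
               first_pos_cM = numeric())
  out <- out[order(out$group, out$first_pos_cM), ]
  out$first_pos_cM <- NULL
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(scaffold_id = character(), reason = character())
  out
}

#' Global, mapped and unmapped recombination rates
#'
#' `mapped_rate = mapped_cM / mapped_Mb`;
#' `unmapped_rate = (total_map_cM - mapped_cM) / (genome_Mb - mapped_Mb)`;
#' `genomewide_rate = total_map_cM / genome_Mb`.
#'
#' @param total_map_cM Total map length in cM.
#' @param mapped_cM Map length within unbroken scaffolds.
#' @param mapped_bp Physical length within those scaffolds.
#' @param genome_bp Haploid genome size.
#' @return List with `mapped_rate`, `unmapped_rate`, `genomewide_rate`
#'   (cM/Mb). The unmapped rate is `NA` in the degenerate 0/0 case.
#' @examples
#' g <- global_rates(1750, 1200, 185e6, 450e6)
#' round(g$genomewide_rate, 1)  # 3.9
#' round(g$unmapped_rate, 1)    # 2.1
#' @export
global_rates <- function(total_map_cM, mapped_cM = total_map_cM,
                         mapped_bp = NULL, genome_bp) {
  if (is.null(mapped_bp)) mapped_bp <- genome_bp
  if (mapped_cM > total_map_cM) stop("mapped_cM exceeds total_map_cM")
  if (mapped_bp > genome_bp) stop("mapped_bp exceeds genome_bp")
  rest_cM <- total_map_cM - mapped_cM
  rest_bp <- genome_bp - mapped_bp
  if (rest_bp <= 0 && rest_cM > 0) {
    stop("leftover cM with no unmapped sequence to host it")
  }
  unmapped <- if (rest_bp == 0 && rest_cM == 0) NA_real_ else
    rest_cM / (rest_bp / 1e6)
  list(mapped_rate = mapped_cM / (mapped_bp / 1e6),
       unmapped_rate = unmapped,
       genomewide_rate = total_map_cM / (genome_bp / 1e6))
}

#' @describeIn global_rates Compute the same summary from a built map and its
#'   per-scaffold rates (aggregation-consistent: `mapped_rate` equals the
#'   ratio of sums over scaffolds).
#' @param map A `genetic_map`.
#' @param rates Output of [scaffold_rates()].
#' @export
global_rates_from_map <- function(map, rates, genome_bp) {
  total <- sum(vapply(map$groups, function(g) max(g$pos_cM), numeric(1)))
  global_rates(total, sum(rates$map_length_cM),
               sum(rates$physical_length_bp), genome_bp)
}

#' Geometric block sizes for the bootstrap
#'
#' Block lengths are geometric on support 1, 2, ... with success probability
#' `1 / mean_block` (mean `mean_block`); the zero-support variant would allow
#' empty blocks.
#'
#' @param n Number of draws.
#' @param mean_block Mean block length (default 3).
#' @return Integer vector of block sizes.
#' @export
rgeom_block_sizes <- function(n, mean_block = 3) {
  stats::rgeom(n, 1 / mean_block) + 1L
}

.boot_rates <- function(cM, Mb, n_boot, mean_block) {
  n <- length(cM)
  out <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- integer(0)
    while (length(idx) < n) {
      k <- ceiling((n - length(idx)) / mean_block) + 2L
      starts <- sample.int(n, k, replace = TRUE)
      lens <- rgeom_block_sizes(k, mean_block)
      idx <- c(idx, (rep(starts - 1L, lens) + sequence(lens) - 1L) %% n + 1L)
    }
    idx <- idx[seq_len(n)]
    out[b] <- sum(cM[idx]) / sum(Mb[idx])
  }
  out
}

#' Block-bootstrap confidence intervals for recombination rates
#'
#' Per chromosome (and globally), scaffolds are resampled in blocks of
#' consecutive scaffolds whose lengths are geometric with mean `mean_block`
#' (wrapping circularly so every scaffold has equal inclusion probability);
#' each replicate concatenates blocks until the original scaffold count is
#' reached, truncates, and records the length-weighted rate
#' `sum(cM) / sum(Mb)`. The CI is the central percentile interval of the
#' replicate rates; the point estimate is the ratio of sums on the original
#' data. Blocked resampling accommodates non-independence of rates among
#' adjacent scaffolds.
#'
#' @param rates Output of [scaffold_rates()] (genome order).
#' @param mean_block Mean geometric block size (default 3).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param alpha 1 - confidence level (default 0.05).
#' @param seed Integer seed (required).
#' @param sides `"central"` (default) for the (alpha/2, 1-alpha/2) interval;
#'   `"lower"`/`"upper"` for one-sided bounds.
#' @return data.frame with one row per chromosome plus a `global` row:
#'   point estimate, `ci_lo`, `ci_hi`, scaffold count, and a flag when the
#'   percentile CI fails to cover the ratio point estimate.
#' @export
block_bootstrap_ci <- function(rates, mean_block = 3, n_boot = 10000,
                               alpha = 0.05, seed,
                               sides = c("central", "lower", "upper")) {
  seed <- .assert_seed(seed)
  sides <- match.arg(sides)
  n_boot <- .assert_count(n_boot, "n_boot")
  set.seed(seed)
  one <- function(df, label) {
    cM <- df$map_length_cM
    Mb <- df$physical_length_bp / 1e6
    point <- sum(cM) / sum(Mb)
    if (nrow(df) == 1L) {
      warning("chromosome ", label, " has a single scaffold; CI collapses to the point")
      return(data.frame(chromosome = label, n_scaffolds = 1L,
                        rate_cM_per_Mb = point, ci_lo = point, ci_hi = point,
                        ci_excludes_point = FALSE))
    }
    reps <- .boot_rates(cM, Mb, n_boot, mean_block)
    q <- switch(sides,
                central = stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                          names = FALSE),
                lower = c(stats::quantile(reps, alpha, names = FALSE), Inf),
                upper = c(-Inf, stats::quantile(reps, 1 - alpha, names = FALSE)))
    data.frame(chromosome = label, n_scaffolds = nrow(df),
               rate_cM_per_Mb = point, ci_lo = q[1L], ci_hi = q[2L],
               ci_excludes_point = point < q[1L] | point > q[2L])
  }
  groups <- sort(unique(rates$group))
  out <- lapply(groups, function(g) {
    one(rates[rates$group == g, , drop = FALSE], as.character(g))
  })
  out[[length(out) + 1L]] <- one(rates, "global")
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation of recombination rate with gene density
#'
#' Pearson correlation between per-scaffold cM/Mb and a per-scaffold density
#' covariate (e.g. genes/Mb), restricted to scaffolds with physical length
#' above `min_bp`.
#'
#' @param rates Output of [scaffold_rates()].
#' @param density Numeric vector aligned with `rates` rows.
#' @param min_bp Minimum scaffold physical span (default 500000).
#' @return List with `estimate`, `p_value`, `n`; `undefined = TRUE` when
#'   fewer than 3 scaffolds qualify or a variable is constant.
#' @export
rate_density_correlation <- function(rates, density, min_bp = 500000) {
  stopifnot(nrow(rates) == length(density))
  keep <- rates$physical_length_bp > min_bp & !is.na(density)
  x <- rates$rate_cM_per_Mb[keep]
  y <- density[keep]
  if (sum(keep) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_, n = sum(keep),
                undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       undefined = FALSE)
}
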