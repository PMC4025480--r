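# Linkage grouping, scaffold-constrained marker ordering and cM estimation
# for selfed-RIL panels.

# genotype codes -> +1 (IM), -1 (PR), 0 (HET or MISSING; HET cells carry
# almost no pairwise information at <1% residual heterozygosity)
.code_matrix <- function(gm) {
  S <- matrix(0, nrow(gm$geno), ncol(gm$geno), dimnames = dimnames(gm$geno))
  S[gm$geno == GENO_IM] <- 1
  S[gm$geno == GENO_PR] <- -1
  S
}

.lod_binomial <- function(k, n, R) {
  # LOD of R_hat vs the free-recombination null R = 0.5
  t1 <- ifelse(k > 0, k * log10(R), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log10(1 - R), 0)
  t1 + t2 + n * log10(2)
}

#' Pairwise recombination fraction and LOD between two markers
#'
#' The RIL recombination fraction is estimated as `R_hat = k / n`, where `k`
#' counts discordant (IM,PR)/(PR,IM) genotype pairs among the `n` RILs with
#' homozygous non-missing calls at both markers (HET cells are excluded),
#' truncated at 0.5. The LOD tests the null of free recombination (R = 0.5):
#' `lod = k log10(R_hat) + (n-k) log10(1-R_hat) + n log10(2)`.
#'
#' @param gm A `geno_matrix`.
#' @param i,j Marker indices or `marker_id`s.
#' @return List with `R_hat`, `lod`, `n_informative`, `k_discordant`.
#'   Pairs with fewer than 2 informative RILs are flagged `undefined`.
#' @export
pairwise_linkage <- function(gm, i, j) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.character(i)) i <- match(i, gm$markers$marker_id)
  if (is.character(j)) j <- match(j, gm$markers$marker_id)
  a <- gm$geno[i, ]
  b <- gm$geno[j, ]
  inf <- a %in% c(GENO_IM, GENO_PR) & b %in% c(GENO_IM, GENO_PR)
  n <- sum(inf)
  if (n < 2L) {
    return(list(R_hat = NA_real_, lod = NA_real_, n_informative = n,
                k_discordant = NA_integer_, undefined = TRUE))
  }
  k <- sum(a[inf] != b[inf])
  R <- min(k / n, 0.5)
  list(R_hat = R, lod = .lod_binomial(k, n, R), n_informative = n,
       k_discordant = k, undefined = FALSE)
}

#' All-pairs recombination fractions and LODs
#'
#' Vectorised computation of the matrices behind [pairwise_linkage()] for
#' every marker pair; the substrate for grouping and heatmaps.
#'
#' @param gm A `geno_matrix`.
#' @param min_informative Pairs with fewer informative RILs get `NA`
#'   (default 2).
#' @return List of square matrices `R_hat`, `lod`, `n_informative` in marker
#'   order (class `pairwise_linkage_matrix`).
#' @export
pairwise_linkage_matrix <- function(gm, min_informative = 2) {
  stopifnot(inherits(gm, "geno_matrix"))
  S <- .code_matrix(gm)
  A <- abs(S)
  n <- tcrossprod(A)            # informative RILs per pair
  conc <- tcrossprod(S)         # concordant - discordant
  k <- (n - conc) / 2
  R <- pmin(k / ifelse(n > 0, n, NA), 0.5)
  lod <- .lod_binomial(k, n, R)
  bad <- n < min_informative
  R[bad] <- NA
  lod[bad] <- NA
  diag(R) <- 0
  diag(lod) <- .lod_binomial(0, diag(n), 0)
  dimnames(R) <- dimnames(lod) <- dimnames(n) <-
    list(gm$markers$marker_id, gm$markers$marker_id)
  structure(list(R_hat = R, lod = lod, n_informative = n),
            class = "pairwise_linkage_matrix")
}

#' Group markers into linkage groups by single linkage
#'
#' Markers i and j land in one group iff they are connected by a chain of
#' pairs with `R_hat <= r_threshold` (nearest-neighbour grouping with
#' recombination as the criterion). Groups are numbered by descending size,
#' ties by smallest marker index.
#'
#' @param pl A `pairwise_linkage_matrix`.
#' @param r_threshold Linking threshold on `R_hat` (default 0.15).
#' @return Integer vector of group labels, one per marker.
#' @export
group_markers <- function(pl, r_threshold = 0.15) {
  stopifnot(inherits(pl, "pairwise_linkage_matrix"))
  R <- pl$R_hat
  m <- nrow(R)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(!is.na(R) & R <= r_threshold & upper.tri(R), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1L])
    rj <- find(edges[e, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(m), find, integer(1))
  sizes <- table(root)
  first <- tapply(seq_len(m), root, min)
  ord <- .order_by(-as.vector(sizes), as.vector(first))
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  relabel[match(root, as.integer(names(sizes)))]
}

#' Break chimeric scaffolds across linkage groups
#'
#' A scaffold whose markers fall into more than one linkage group is split
#' into maximal runs of consecutive windows sharing a group; each run becomes
#' a fragment with a derived id (`scaffold.1`, `scaffold.2`, ...). Fragments
#' are the units whose internal marker order is frozen during ordering.
#'
#' @param gm A `geno_matrix`.
#' @param groups Integer group labels from [group_markers()].
#' @return List: `markers` (metadata with `group` and `fragment_id`) and
#'   `breaks` (one row per fragment of each split scaffold).
#' @export
break_scaffolds <- function(gm, groups) {
  mk <- gm$markers
  mk$group <- groups
  mk$fragment_id <- mk$scaffold_id
  breaks <- list()
  for (sc in unique(mk$scaffold_id)) {
    rows <- which(mk$scaffold_id == sc)
    rows <- rows[order(mk$window_index[rows])]
    g <- mk$group[rows]
    if (length(unique(g)) <= 1L) next
    run <- cumsum(c(TRUE, g[-1L] != g[-length(g)]))
    mk$fragment_id[rows] <- sprintf("%s.%d", sc, run)
    for (r in unique(run)) {
      idx <- rows[run == r]
      breaks[[length(breaks) + 1L]] <- data.frame(
        scaffold_id = sc, fragment_id = sprintf("%s.%d", sc, r),
        group = mk$group[idx[1L]],
        first_window = min(mk$window_index[idx]),
        last_window = max(mk$window_index[idx]),
        n_markers = length(idx))
    }
  }
  breaks <- if (length(breaks)) do.call(rbind, breaks) else
    data.frame(scaffold_id = character(), fragment_id = character(),
               group = integer(), first_window = integer(),
               last_window = integer(), n_markers = integer())
  list(markers = mk, breaks = breaks)
}

# junction cost table for a signed block sequence; blocks is a list of
# marker-index vectors already in physical order
.block_ends <- function(blocks) {
  list(head = vapply(blocks, function(b) b[1L], numeric(1)),
       tail = vapply(blocks, function(b) b[length(b)], numeric(1)))
}

.seq_sarf <- function(ordseq, flip, blocks, R, within) {
  ends <- .block_ends(blocks)
  tailm <- ifelse(flip, ends$head[ordseq], ends$tail[ordseq])
  headm <- ifelse(flip, ends$tail[ordseq], ends$head[ordseq])
  B <- length(ordseq)
  jc <- 0
  if (B > 1L) {
    idx <- cbind(tailm[-B], headm[-1L])
    r <- R[idx]
    r[is.na(r)] <- 0.5
    jc <- sum(r)
  }
  jc + sum(within[ordseq])
}

#' Order markers within a linkage group
#'
#' Markers on one scaffold fragment are frozen in physical (window) order and
#' treated as rigid blocks; the block order and block orientations are chosen
#' to minimise the sum of adjacent recombination fractions (SARF) by greedy
#' nearest-neighbour construction from `n_restarts` random starts, each
#' refined by 2-opt reversal moves until no move improves. Pairs with
#' undefined `R_hat` cost 0.5 (free recombination). The final order is
#' deterministic given `seed`; the whole-group direction is canonicalised so
#' the first marker index precedes the last.
#'
#' @param gm A `geno_matrix`.
#' @param marker_idx Indices (into `gm$markers`) of the group's markers.
#' @param fragment_id Fragment labels aligned with `marker_idx` (from
#'   [break_scaffolds()]); `NULL` treats every marker as a free block.
#' @param pl Optional precomputed [pairwise_linkage_matrix()].
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed (required).
#' @return List: `order` (marker indices in map order) and `sarf`.
#' @export
order_markers <- function(gm, marker_idx, fragment_id = NULL, pl = NULL,
                          n_restarts = 20, seed) {
  seed <- .assert_seed(seed)
  n_restarts <- .assert_count(n_restarts, "n_restarts")
  if (length(marker_idx) == 1L) {
    return(list(order = marker_idx, sarf = 0))
  }
  if (is.null(pl)) {
    sub <- new_geno_matrix(gm$markers[marker_idx, , drop = FALSE],
                           gm$geno[marker_idx, , drop = FALSE], gm$ril_ids)
    R <- pairwise_linkage_matrix(sub)$R_hat
    loc <- seq_along(marker_idx)
  } else {
    R <- pl$R_hat[marker_idx, marker_idx, drop = FALSE]
    loc <- seq_along(marker_idx)
  }
  if (is.null(fragment_id)) fragment_id <- as.character(marker_idx)
  win <- gm$markers$window_index[marker_idx]
  blocks <- lapply(split(loc, fragment_id), function(ix) ix[order(win[ix])])
  names(blocks) <- NULL
  B <- length(blocks)
  within <- vapply(blocks, function(b) {
    if (length(b) < 2L) return(0)
    r <- R[cbind(b[-length(b)], b[-1L])]
    r[is.na(r)] <- 0.5
    sum(r)
  }, numeric(1))
  ends <- .block_ends(blocks)
  # junction cost lookup: cost[e1, e2] with ends coded tail-of / head-of
  Rj <- R
  Rj[is.na(Rj)] <- 0.5
  if (B == 1L) {
    ord <- blocks[[1L]]
    return(list(order = marker_idx[ord], sarf = within[1L]))
  }
  set.seed(seed)
  best <- NULL
  best_s <- Inf
  for (rs in seq_len(n_restarts)) {
    start <- if (rs == 1L) 1L else sample.int(B, 1L)
    ordseq <- start
    flip <- FALSE
    left <- setdiff(seq_len(B), start)
    while (length(left)) {
      tl <- if (flip[length(flip)]) ends$head[ordseq[length(ordseq)]]
            else ends$tail[ordseq[length(ordseq)]]
      cost_f <- Rj[tl, ends$head[left]]
      cost_r <- Rj[tl, ends$tail[left]]
      pick <- which.min(pmin(cost_f, cost_r))
      ordseq <- c(ordseq, left[pick])
      flip <- c(flip, cost_r[pick] < cost_f[pick])
      left <- left[-pick]
    }
    # 2-opt refinement: reversing positions i..j flips those blocks, so the
    # left junction becomes (tail of i-1 -> old tail of j) and the right
    # junction (old head of i -> head of j+1); sweep with best improvement
    repeat {
      H <- ifelse(flip, ends$tail[ordseq], ends$head[ordseq])
      Tl <- ifelse(flip, ends$head[ordseq], ends$tail[ordseq])
      bestd <- -1e-12
      besti <- 0L
      bestj <- 0L
      for (i in seq_len(B)) {
        js <- i:B
        if (i == 1L) js <- js[js < B]      # full reversal changes nothing
        if (!length(js)) next
        leftold <- if (i > 1L) Rj[Tl[i - 1L], H[i]] else 0
        rightold <- rightnew <- numeric(length(js))
        sel <- js < B
        rightold[sel] <- Rj[cbind(Tl[js[sel]], H[js[sel] + 1L])]
        rightnew[sel] <- Rj[cbind(rep(H[i], sum(sel)), H[js[sel] + 1L])]
        leftnew <- if (i > 1L) Rj[Tl[i - 1L], Tl[js]] else numeric(length(js))
        delta <- leftnew + rightnew - leftold - rightold
        k <- which.min(delta)
        if (delta[k] < bestd) {
          bestd <- delta[k]
          besti <- i
          bestj <- js[k]
        }
      }
      if (besti == 0L) break
      seg <- besti:bestj
      ordseq[seg] <- rev(ordseq[seg])
      flip[seg] <- !rev(flip[seg])
    }
    s <- .seq_sarf(ordseq, flip, blocks, Rj, within)
    if (s < best_s - 1e-12) {
      best_s <- s
      best <- list(ordseq = ordseq, flip = flip)
    }
  }
  out <- unlist(lapply(seq_along(best$ordseq), function(i) {
    b <- blocks[[best$ordseq[i]]]
    if (best$flip[i]) rev(b) else b
  }))
  if (out[1L] > out[length(out)]) out <- rev(out)
  list(order = marker_idx[out], sarf = best_s)
}

#' Map positions from adjacent recombination fractions
#'
#' For each adjacent ordered pair, the RIL discordance `R_hat` is converted
#' to the meiotic recombination fraction by the selfed-RIL inverse
#' `r = R / (2 (1 - R))` (Haldane-Waddington), then to map distance by the
#' Haldane function `d = -50 ln(1 - 2r)` cM; `r` is capped at 0.49 to keep
#' distances finite. Positions are cumulative from 0.
#'
#' @param gm A `geno_matrix`.
#' @param ordered_idx Marker indices in map order.
#' @return data.frame of the ordered markers with `pos_cM`.
#' @export
estimate_positions <- function(gm, ordered_idx) {
  stopifnot(inherits(gm, "geno_matrix"))
  m <- length(ordered_idx)
  d <- numeric(max(m - 1L, 0L))
  if (m > 1L) {
    S <- .code_matrix(gm)[ordered_idx, , drop = FALSE]
    a <- S[-m, , drop = FALSE]
    b <- S[-1L, , drop = FALSE]
    inf <- (a != 0) & (b != 0)
    n <- rowSums(inf)
    k <- rowSums((a != b) & inf)
    R <- pmin(ifelse(n > 0, k / n, 0.5), 0.5)
    r <- pmin(R / (2 * (1 - R)), 0.49)
    d <- -50 * log(1 - 2 * r)
  }
  out <- gm$markers[ordered_idx, , drop = FALSE]
  out$pos_cM <- cumsum(c(0, d))
  rownames(out) <- NULL
  out
}

#' Build a genetic map from a genotype matrix
#'
#' Full map construction: all-pairs linkage, single-linkage grouping at
#' `r_threshold`, chimeric-scaffold breaking, scaffold-constrained ordering
#' per group and Haldane/selfed-RIL cM positions.
#'
#' @param gm A `geno_matrix` (typically from [select_mapping_set()]).
#' @param r_threshold Grouping threshold (default 0.15).
#' @param n_restarts Ordering restarts (default 20).
#' @param seed Integer seed (required).
#' @param min_group_size Groups smaller than this go to the unplaced list
#'   (default 2).
#' @param keep_pairwise Keep per-group `R_hat`/LOD submatrices for heatmap
#'   export (default TRUE).
#' @return A `genetic_map`: `groups` (list of ordered marker data.frames with
#'   `pos_cM` and `fragment_id`), `breaks`, `unplaced`, and per-group
#'   summaries.
#' @export
build_genetic_map <- function(gm, r_threshold = 0.15, n_restarts = 20, seed,
                              min_group_size = 2, keep_pairwise = TRUE) {
  seed <- .assert_seed(seed)
  pl <- pairwise_linkage_matrix(gm)
  groups <- group_markers(pl, r_threshold = r_threshold)
  brk <- break_scaffolds(gm, groups)
  keep_groups <- as.integer(names(which(table(groups) >= min_group_size)))
  out <- list()
  pw <- list()
  for (g in sort(keep_groups)) {
    idx <- which(groups == g)
    om <- order_markers(gm, idx, fragment_id = brk$markers$fragment_id[idx],
                        pl = pl, n_restarts = n_restarts,
                        seed = seed + g)
    df <- estimate_positions(gm, om$order)
    df$fragment_id <- brk$markers$fragment_id[om$order]
    df$group <- g
    attr(df, "sarf") <- om$sarf
    out[[as.character(g)]] <- df
    if (keep_pairwise) {
      pw[[as.character(g)]] <- list(R_hat = pl$R_hat[om$order, om$order],
                                    lod = pl$lod[om$order, om$order])
    }
  }
  unplaced <- gm$markers[!(groups %in% keep_groups), , drop = FALSE]
  structure(list(groups = out, breaks = brk$breaks, unplaced = unplaced,
                 group_of = groups, ril_ids = gm$ril_ids,
                 pairwise = if (keep_pairwise) pw,
                 r_threshold = r_threshold, seed = seed),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- vapply(x$groups, function(g) max(g$pos_cM), numeric(1))
  nm <- vapply(x$groups, nrow, integer(1))
  cat(sprintf("genetic_map: %d linkage groups, %d markers, total %.0f cM (%d unplaced)\n",
              length(x$groups), sum(nm), sum(len), nrow(x$unplaced)))
  invisible(x)
}

#' Linkage-group summary table
#'
#' @param map A `genetic_map`.
#' @return data.frame with per-group marker count, map length, mean and
#'   maximum adjacent spacing.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  do.call(rbind, lapply(names(map$groups), function(g) {
    pos <- map$groups[[g]]$pos_cM
    gaps <- diff(pos)
    data.frame(group = as.integer(g), n_markers = length(pos),
               length_cM = max(pos),
               mean_spacing_cM = if (length(gaps)) mean(gaps) else NA_real_,
               max_spacing_cM = if (length(gaps)) max(gaps) else NA_real_)
  }))
}

#' Mean adjacent marker spacing of a map
#'
#' With `n_markers` on `n_groups` linkage groups there are
#' `n_markers - n_groups` adjacent intervals, so the mean spacing is
#' `total_cM / (n_markers - n_groups)`.
#'
#' @param total_cM Total map length.
#' @param n_markers Total marker count.
#' @param n_groups Number of linkage groups.
#' @return Mean spacing in cM.
#' @export
mean_marker_spacing <- function(total_cM, n_markers, n_groups) {
  stopifnot(n_markers > n_groups)
  total_cM / (n_markers - n_groups)
}

#' Export pairwise heatmap matrices for one linkage group
#'
#' Writes the square `R_hat` and LOD matrices in map order (the conventional
#' display puts recombination fractions below the diagonal and LODs above).
#'
#' @param map A `genetic_map` built with `keep_pairwise = TRUE`.
#' @param group Group number.
#' @param dir Output directory; files `<prefix>_rhat.tsv` and
#'   `<prefix>_lod.tsv` with `prefix = group<group>`.
#' @return Invisibly, list of the two matrices.
#' @export
linkage_heatmap_export <- function(map, group, dir = ".") {
  stopifnot(inherits(map, "genetic_map"), !is.null(map$pairwise))
  pw <- map$pairwise[[as.character(group)]]
  if (is.null(pw)) stop("no such group: ", group)
  fr <- file.path(dir, sprintf("group%s_rhat.tsv", group))
  fl <- file.path(dir, sprintf("group%s_lod.tsv", group))
  utils::write.table(pw$R_hat, fr, sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(pw$lod, fl, sep = "\t", quote = FALSE, col.names = NA)
  invisible(pw)
}
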