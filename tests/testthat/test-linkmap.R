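# pairwise linkage, grouping, ordering and cM estimation

# tiny geno_matrix straight from a coded matrix (+1 IM, -1 PR, 0 missing)
gm_from_codes <- function(S) {
  geno <- matrix(0L, nrow(S), ncol(S))
  geno[S == 1] <- 1L
  geno[S == -1] <- 2L
  mk <- data.frame(marker_id = sprintf("s%d:0", seq_len(nrow(S))),
                   scaffold_id = sprintf("s%d", seq_len(nrow(S))),
                   window_index = 0L, start_bp = 0, end_bp = 5e4)
  rilmap:::new_geno_matrix(mk, geno, sprintf("R%03d", seq_len(ncol(S))))
}

test_that("pairwise LOD matches the binomial closed form and a grid oracle", {
  # n = 100, k = 0: lod = 100 log10 2
  a <- rep(1, 100)
  gm <- gm_from_codes(rbind(a, a))
  pl <- pairwise_linkage(gm, 1, 2)
  expect_equal(pl$R_hat, 0)
  expect_equal(pl$lod, 100 * log10(2), tolerance = 1e-12)
  # n = 100, k = 50: free recombination, lod = 0
  b <- a; b[1:50] <- -1
  pl2 <- pairwise_linkage(gm_from_codes(rbind(a, b)), 1, 2)
  expect_equal(pl2$R_hat, 0.5)
  expect_equal(pl2$lod, 0)
  # n = 100, k = 25: compare with brute-force likelihood-ratio over an R grid
  c25 <- a; c25[1:25] <- -1
  pl3 <- pairwise_linkage(gm_from_codes(rbind(a, c25)), 1, 2)
  expect_equal(pl3$R_hat, 0.25)
  grid <- seq(1e-4, 0.5, by = 1e-4)
  loglik <- 25 * log10(grid) + 75 * log10(1 - grid)
  oracle <- max(loglik) - (25 * log10(0.5) + 75 * log10(0.5))
  expect_equal(pl3$lod, oracle, tolerance = 1e-6)
  # HET and MISSING cells are excluded from the informative count
  d <- a; d[1:10] <- 0
  pl4 <- pairwise_linkage(gm_from_codes(rbind(a, d)), 1, 2)
  expect_equal(pl4$n_informative, 90)
  # fewer than 2 informative RILs -> undefined
  e <- rep(0, 100); e[1] <- 1
  expect_true(pairwise_linkage(gm_from_codes(rbind(a, e)), 1, 2)$undefined)
})

test_that("matrix form agrees with the scalar form", {
  f <- fx_inv()
  sub <- rilmap:::new_geno_matrix(f$gm$markers[1:40, ], f$gm$geno[1:40, ],
                                  f$gm$ril_ids)
  pl <- pairwise_linkage_matrix(sub)
  for (pair in list(c(1, 2), c(3, 17), c(5, 40))) {
    one <- pairwise_linkage(sub, pair[1], pair[2])
    expect_equal(pl$R_hat[pair[1], pair[2]], one$R_hat)
    expect_equal(pl$lod[pair[1], pair[2]], one$lod)
    expect_equal(pl$n_informative[pair[1], pair[2]], one$n_informative)
  }
  expect_equal(unname(diag(pl$R_hat)), rep(0, 40))
})

test_that("single-linkage grouping is transitive and size-ordered", {
  # chain a-b (0.1), b-c (0.1), a-c (0.3): one group by transitivity
  R <- matrix(0.5, 4, 4)
  diag(R) <- 0
  R[1, 2] <- R[2, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- 0.1
  R[1, 3] <- R[3, 1] <- 0.3
  pl <- structure(list(R_hat = R, lod = R * 0,
                       n_informative = matrix(100, 4, 4)),
                  class = "pairwise_linkage_matrix")
  g <- group_markers(pl, r_threshold = 0.15)
  expect_equal(g, c(1L, 1L, 1L, 2L))
  # two markers at R = 0.5 only: two singleton groups
  R2 <- matrix(0.5, 2, 2); diag(R2) <- 0
  pl2 <- structure(list(R_hat = R2, lod = R2,
                        n_informative = matrix(100, 2, 2)),
                   class = "pairwise_linkage_matrix")
  expect_equal(sort(group_markers(pl2, 0.15)), c(1L, 2L))
})

test_that("grouping recovers simulated chromosomes", {
  f <- fx_inv()
  pl <- pairwise_linkage_matrix(f$gm)
  g <- group_markers(pl, 0.15)
  expect_equal(length(unique(g)), 3L)
  truth <- f$gm$truth_markers$chromosome_id
  acc <- max(table(g, truth)) / max(table(truth))
  conf <- table(g, truth)
  purity <- sum(apply(conf, 1, max)) / length(g)
  expect_gte(purity, 0.99)
})

test_that("chimeric scaffolds break into runs at the group change", {
  f <- fx_inv()
  mk <- f$gm$markers[1:20, ]
  mk$scaffold_id <- "chimera"
  mk$window_index <- 0:19
  gm <- rilmap:::new_geno_matrix(mk, f$gm$geno[1:20, ], f$gm$ril_ids)
  groups <- rep(c(1L, 2L), each = 10)
  br <- break_scaffolds(gm, groups)
  expect_equal(nrow(br$breaks), 2L)
  expect_equal(br$breaks$first_window, c(0L, 10L))
  expect_equal(br$breaks$last_window, c(9L, 19L))
  expect_equal(unique(br$markers$fragment_id), c("chimera.1", "chimera.2"))
  # single-group scaffold stays unsplit
  br2 <- break_scaffolds(gm, rep(1L, 20))
  expect_equal(nrow(br2$breaks), 0L)
  expect_equal(unique(br2$markers$fragment_id), "chimera")
  # alternating labels split exactly as labeled
  br3 <- break_scaffolds(gm, rep(c(1L, 2L), 10))
  expect_equal(nrow(br3$breaks), 20L)
})

test_that("ordering minimises SARF: 3 free markers and exhaustive oracle", {
  # R(a,b) = 0.05, R(b,c) = 0.05, R(a,c) = 0.10 -> order a-b-c, SARF 0.10
  n <- 200
  a <- rep(c(1, -1), each = n / 2)
  b <- a; b[seq(1, n, by = 20)] <- -b[seq(1, n, by = 20)]       # R = 0.05
  c_ <- b; c_[seq(2, n, by = 20)] <- -c_[seq(2, n, by = 20)]    # R(b,c) = 0.05
  gm <- gm_from_codes(rbind(a, c_, b))   # scrambled input order
  om <- order_markers(gm, 1:3, seed = 1)
  expect_equal(om$sarf, 0.10, tolerance = 1e-12)
  expect_equal(om$order[2], 3L)          # b sits in the middle
  # random instances: greedy+2-opt equals exhaustive search (<= 6 free blocks)
  set.seed(42)
  for (rep in 1:5) {
    m <- sample(4:6, 1)
    S <- matrix(sample(c(1, -1), m * 50, replace = TRUE), m, 50)
    gmr <- gm_from_codes(S)
    R <- pairwise_linkage_matrix(gmr)$R_hat
    om <- order_markers(gmr, seq_len(m), seed = rep)
    oracle <- exhaustive_sarf(as.list(seq_len(m)), R)
    expect_equal(om$sarf, oracle, tolerance = 1e-9)
  }
})

test_that("scaffold order constraint freezes within-fragment marker order", {
  f <- fx_inv()
  df <- f$map$groups[[1]]
  for (fr in unique(df$fragment_id)) {
    w <- df$window_index[df$fragment_id == fr]
    expect_true(all(diff(w) == 1) || all(diff(w) == -1) || length(w) == 1)
  }
  # a single-scaffold group comes back in physical order
  idx <- which(f$gm$markers$scaffold_id == f$gm$markers$scaffold_id[1])
  om <- order_markers(f$gm, idx,
                      fragment_id = rep("one", length(idx)), seed = 5)
  expect_equal(om$order, idx)
})

test_that("selfed-RIL inverse and Haldane give correct distances", {
  # R = 0 -> d = 0 (co-locating markers)
  a <- rep(1, 50)
  gm0 <- gm_from_codes(rbind(a, a))
  expect_equal(estimate_positions(gm0, 1:2)$pos_cM, c(0, 0))
  # R = 1/3 -> r = 0.25 -> d = -50 ln(0.5)
  n <- 300
  x <- rep(1, n)
  y <- x; y[seq_len(n / 3)] <- -1
  d <- estimate_positions(gm_from_codes(rbind(x, y)), 1:2)$pos_cM[2]
  expect_equal(d, -50 * log(0.5), tolerance = 1e-9)
})

test_that("RIL discordance matches the Haldane-Waddington series (oracle)", {
  for (r in c(0.05, 0.1, 0.25, 0.4)) {
    obs <- two_locus_selfing_oracle(r, n = 5000, gens = 16, seed = 100 + r * 100)
    expected <- 2 * r / (1 + 2 * r)
    se <- sqrt(expected * (1 - expected) / 5000)
    expect_lt(abs(obs - expected), 3 * se)
  }
})

test_that("map distances are additive for ordered loci without interference", {
  f <- fx_inv()
  df <- f$map$groups[[1]]
  m <- nrow(df)
  i <- round(m * 0.2); j <- round(m * 0.4); k <- round(m * 0.6)
  ord <- match(df$marker_id, f$gm$markers$marker_id)
  dij <- estimate_positions(f$gm, ord[c(i, j)])$pos_cM[2]
  djk <- estimate_positions(f$gm, ord[c(j, k)])$pos_cM[2]
  dik <- estimate_positions(f$gm, ord[c(i, k)])$pos_cM[2]
  # simulation error grows with distance; allow a generous band
  expect_lt(abs(dik - (dij + djk)), 0.25 * dik + 2)
})

test_that("full map construction recovers chromosome lengths and order", {
  f <- fx_inv()
  sm <- map_summary(f$map)
  expect_equal(nrow(sm), 3L)
  # suppressed intervals shrink the realized map; compare against the
  # crossover-derived expectation instead of the nominal 100 cM
  for (g in names(f$map$groups)) {
    df <- f$map$groups[[g]]
    truth <- f$gm$truth_markers[match(df$marker_id,
                                      f$gm$truth_markers$marker_id), ]
    expect_equal(length(unique(truth$chromosome_id)), 1L)
    # order within a suppressed inversion is unresolvable (all R_hat = 0):
    # judge order recovery outside the true inversion intervals
    inv <- f$lay$inversions[f$lay$inversions$chromosome_id ==
                              truth$chromosome_id[1], ]
    free <- rep(TRUE, nrow(truth))
    for (r in seq_len(nrow(inv))) {
      free <- free & !(truth$chrom_mid_bp >= inv$start_bp[r] &
                         truth$chrom_mid_bp < inv$end_bp[r])
    }
    tau <- cor(seq_len(sum(free)), order(truth$chrom_mid_bp[free]),
               method = "kendall")
    expect_gte(abs(tau), 0.95)
  }
})

test_that("ordering never beats the truth-order SARF on error-free data", {
  f <- fx_inv()
  df <- f$map$groups[[2]]
  idx <- match(df$marker_id, f$gm$markers$marker_id)
  truth <- f$gm$truth_markers[idx, ]
  true_order <- idx[order(truth$chrom_mid_bp)]
  S <- rilmap:::.code_matrix(f$gm)
  sarf_of <- function(ord) {
    a <- S[ord[-length(ord)], , drop = FALSE]
    b <- S[ord[-1], , drop = FALSE]
    inf <- a != 0 & b != 0
    n <- rowSums(inf)
    k <- rowSums((a != b) & inf)
    sum(pmin(k / n, 0.5))
  }
  expect_lte(attr(df, "sarf"), sarf_of(true_order) + 1e-9)
})

test_that("heatmap export writes square matrices in map order", {
  f <- fx_inv()
  dir <- withr::local_tempdir()
  pw <- linkage_heatmap_export(f$map, 1, dir)
  m <- nrow(f$map$groups[[1]])
  expect_equal(dim(pw$R_hat), c(m, m))
  got <- as.matrix(read.delim(file.path(dir, "group1_rhat.tsv"),
                              row.names = 1, check.names = FALSE))
  expect_equal(unname(got), unname(pw$R_hat), tolerance = 1e-6)
  expect_equal(unname(diag(pw$R_hat)), rep(0, m))
  # recombination fraction grows with map separation on average
  sep <- abs(outer(seq_len(m), seq_len(m), "-"))
  ut <- upper.tri(pw$R_hat)
  expect_gt(cor(sep[ut], pw$R_hat[ut], use = "complete.obs"), 0.3)
})

test_that("mean marker spacing reproduces the printed arithmetic", {
  expect_equal(round(mean_marker_spacing(1750, 3073, 14), 1), 0.6)
})
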