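# phenotype preprocessing, imputation, scanning, thresholds and effects

test_that("log(x+1) transform is exact and reduces right skew", {
  expect_equal(transform_trait(0), 0)
  expect_equal(transform_trait(exp(1) - 1), 1)
  expect_error(transform_trait(c(1, -2)), "-1")
  f <- fx_qtl()
  sk <- function(x) mean(scale(x)^3)
  expect_lt(sk(f$ph$t1l), sk(f$ph$t1))
})

test_that("variance components: degenerate layouts behave as documented", {
  # zero noise, RIL effects only: V_error ~ 0
  d <- expand.grid(ril_id = sprintf("R%02d", 1:30), replicate = 1:3)
  d$growup <- "GU1"
  d$method <- "HPLC"
  ril_eff <- rnorm(30)
  d$y <- ril_eff[match(d$ril_id, sprintf("R%02d", 1:30))]
  # a perfect fit makes anova() warn about F-tests; only mean squares are used
  vc <- suppressWarnings(variance_components(d, "y"))
  expect_lt(vc$V_error, 1e-20)
  expect_gt(vc$V_ril, 0.1)
  # pure noise: V_ril truncated at zero often; never negative
  set.seed(5)
  reps <- replicate(10, {
    d$y <- rnorm(nrow(d))
    variance_components(d, "y")$V_ril
  })
  expect_true(all(reps >= 0))
  # single replicate everywhere: within-RIL variance inestimable
  d1 <- d[d$replicate == 1, ]
  d1$y <- rnorm(nrow(d1))
  vc1 <- suppressWarnings(variance_components(d1, "y"))  # saturated fit warns
  expect_true(vc1$inestimable)
  expect_true(is.na(vc1$V_error))
})

test_that("MoM components match REML on a balanced design (lme4 oracle)", {
  skip_if_not_installed("lme4")
  set.seed(8)
  d <- expand.grid(ril_id = sprintf("R%03d", 1:120), replicate = 1:4)
  d$growup <- paste0("GU", (match(d$ril_id, unique(d$ril_id)) - 1) %% 3 + 1)
  d$method <- ifelse(d$replicate %% 2 == 0, "UHPLC", "HPLC")
  ril_eff <- rnorm(120, 0, sqrt(2))
  d$y <- 1 + ril_eff[match(d$ril_id, sprintf("R%03d", 1:120))] +
    0.5 * (d$method == "UHPLC") + 0.3 * (d$growup == "GU2") + rnorm(nrow(d))
  vc <- variance_components(d, "y")
  lf <- lme4::lmer(y ~ growup + method + (1 | ril_id), data = d, REML = TRUE)
  vcl <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(vc$V_ril, vcl$vcov[vcl$grp == "ril_id"], tolerance = 0.02)
  expect_equal(vc$V_error, vcl$vcov[vcl$grp == "Residual"], tolerance = 0.02)
})

test_that("RIL means are residuals robust to batch offsets", {
  f <- fx_qtl()
  ph2 <- f$ph
  shift <- ph2$growup == "GU2"
  ph2$t1l <- ph2$t1l + ifelse(shift, 1.5, 0)
  vc2 <- variance_components(ph2, "t1l")
  m1 <- ril_means(f$ph, "t1l", f$vc)
  m2 <- ril_means(ph2, "t1l", vc2)
  expect_equal(unname(m1), unname(m2), tolerance = 1e-8)
  # single-replicate RIL: its mean is its one residual
  one <- f$ph[f$ph$ril_id == f$ph$ril_id[1] & f$ph$replicate == 1, ]
  sub <- rbind(one, f$ph[f$ph$ril_id != f$ph$ril_id[1], ])
  vcs <- variance_components(sub, "t1l")
  ms <- ril_means(sub, "t1l", vcs)
  res1 <- sub$t1l[1] - predict(vcs$fixed_fit, newdata = data.frame(
    growup = factor(sub$growup[1]), method = factor(sub$method[1])))
  expect_equal(unname(ms[one$ril_id]), unname(res1))
})

test_that("trait correlations: self, shared-QTL and null behaviour", {
  f <- fx_qtl()
  m <- f$means
  tc <- trait_correlations(list(a = m, b = m))
  expect_equal(tc$estimate["a", "b"], 1)
  # traits sharing polygenic structure correlate positively
  ph <- simulate_phenotypes(fx_qtl()$tr, seed = 501)
  for (t in attr(ph, "pheno_truth")$traits) ph[[t]] <- transform_trait(ph[[t]])
  ms <- lapply(attr(ph, "pheno_truth")$traits, function(t) {
    vc <- variance_components(ph, t)
    ril_means(ph, t, vc)
  })
  names(ms) <- attr(ph, "pheno_truth")$traits
  tc2 <- trait_correlations(ms)
  off <- tc2$estimate[upper.tri(tc2$estimate)]
  expect_true(all(off > 0.1))
  expect_true(all(tc2$p_value[upper.tri(tc2$p_value)] < 0.01))
  # degenerate: constant trait flagged as NA
  tc3 <- trait_correlations(list(a = m, const = setNames(rep(1, length(m)),
                                                         names(m))))
  expect_true(is.na(tc3$estimate["a", "const"]))
})

test_that("imputation reproduces two-flank conditional probabilities", {
  f <- fx_qtl()
  map <- f$map
  gm <- f$gm
  # force one interior marker missing for every RIL on group 1
  df <- map$groups[[1]]
  mid <- df$marker_id[5]
  g2 <- gm
  row <- match(mid, gm$markers$marker_id)
  left <- match(df$marker_id[4], gm$markers$marker_id)
  right <- match(df$marker_id[6], gm$markers$marker_id)
  g2$geno[row, ] <- 0L
  # RILs with IM flanks on both sides: P(IM) from the chain formula
  q1 <- rilmap:::.d_to_R(df$pos_cM[5] - df$pos_cM[4])
  q2 <- rilmap:::.d_to_R(df$pos_cM[6] - df$pos_cM[5])
  p_exp <- (1 - q1) * (1 - q2) / ((1 - q1) * (1 - q2) + q1 * q2)
  imp <- impute_genotypes(g2, map, n_imputations = 400, seed = 9)
  im_flanks <- which(g2$geno[left, ] == 1L & g2$geno[right, ] == 1L)
  draws <- vapply(imp$imputations, function(M) M[mid, im_flanks],
                  integer(length(im_flanks)))
  p_obs <- mean(draws == 1L)
  n_draw <- length(draws)
  expect_gt(p_exp, 0.99)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n_draw) + 1e-4)
  # equidistant opposite flanks: symmetric coin
  q <- 0.05
  mk <- data.frame(marker_id = c("a", "b", "c"), scaffold_id = "s",
                   window_index = 0:2, start_bp = 0:2, end_bp = 1:3)
  r_meiotic <- q / (2 * (1 - q))
  d_cM <- -50 * log(1 - 2 * r_meiotic)               # invert R -> d
  geno <- matrix(c(1L, 0L, 2L), 3, 600)
  colnames(geno) <- sprintf("R%03d", 1:600)
  gm3 <- rilmap:::new_geno_matrix(mk, geno, colnames(geno))
  map3 <- list(groups = list(`1` = cbind(mk, pos_cM = c(0, d_cM, 2 * d_cM),
                                         fragment_id = "s", group = 1L)),
               breaks = data.frame(), unplaced = mk[0, ], ril_ids = colnames(geno))
  class(map3) <- "genetic_map"
  imp3 <- impute_genotypes(gm3, map3, n_imputations = 50, seed = 10)
  p_im <- mean(vapply(imp3$imputations, function(M) M["b", ], integer(600)) == 1L)
  expect_lt(abs(p_im - 0.5), 3 * sqrt(0.25 / (600 * 50)))
  # no missing data: every imputation equals the input
  imp0 <- impute_genotypes(f$gm, map, n_imputations = 3, seed = 11)
  ref <- f$gm$geno[match(imp0$index$marker_id, f$gm$markers$marker_id), ]
  for (M in imp0$imputations) {
    expect_true(all(M[ref %in% 1:2] == ref[ref %in% 1:2]))
  }
})

test_that("with complete homozygous genotypes the combined LOD is the single fit", {
  f <- fx_qtl()
  gm <- f$gm
  gm$geno[gm$geno == 3L] <- 1L
  expect_true(all(gm$geno %in% 1:2))
  map <- f$map
  imp <- impute_genotypes(gm, map, n_imputations = 16, seed = 21)
  y <- f$means
  sc <- scan_qtl(imp, y)
  shared <- intersect(names(y), gm$ril_ids)
  ys <- y[shared]
  n <- length(ys)
  RSS0 <- sum((ys - mean(ys))^2)
  direct <- vapply(sc$marker_id, function(mk) {
    x <- ifelse(gm$geno[match(mk, gm$markers$marker_id),
                        match(shared, gm$ril_ids)] == 1L, 1, -1)
    if (length(unique(x)) == 1L) return(0)
    (n / 2) * log10(RSS0 / sum(resid(lm(ys ~ x))^2))
  }, numeric(1))
  expect_lt(max(abs(sc$lod - direct)), 1e-10)
})

test_that("LOD is invariant to affine phenotype transforms and nonnegative", {
  f <- fx_qtl()
  imp <- impute_genotypes(f$gm, f$map, n_imputations = 4, seed = 31)
  a <- scan_qtl(imp, f$means)
  b <- scan_qtl(imp, 3 - 2 * f$means)
  expect_equal(a$lod, b$lod, tolerance = 1e-9)
  expect_true(all(a$lod >= 0))
  expect_error(scan_qtl(imp, f$means[1:5]), "fewer than 10")
})

test_that("a perfect signal peaks at its marker with capped LOD", {
  f <- fx_qtl()
  imp <- impute_genotypes(f$gm, f$map, n_imputations = 4, seed = 41)
  target <- imp$index$marker_id[40]
  x <- imp$imputations[[1]][target, ]
  y <- setNames(ifelse(x == 1L, 1, -1), imp$ril_ids)
  sc <- scan_qtl(imp, y)
  expect_equal(sc$marker_id[which.max(sc$lod)], target)
  expect_true(is.finite(max(sc$lod)))
  expect_gt(max(sc$lod), 100)
})

test_that("scan recovers the simulated QTL and its effect size", {
  f <- fx_qtl()
  imp <- impute_genotypes(f$gm, f$map, n_imputations = 8, seed = 51)
  sc <- scan_qtl(imp, f$means)
  pk <- which.max(sc$lod)
  truth <- f$gm$truth_markers
  pk_meta <- truth[match(sc$marker_id[pk], truth$marker_id), ]
  expect_equal(pk_meta$chromosome_id, f$qs$chromosome_id)
  expect_lt(abs(pk_meta$chrom_mid_bp - f$qs$pos_bp), 4e6)
  # effect: IM/IM - PR/PR difference is 2a within-RIL SDs
  ef <- qtl_effects(imp, f$means, sc$marker_id[pk], f$vc)
  expect_lt(abs(ef$effect_sd - 2 * f$qs$effect_sd) / (2 * f$qs$effect_sd), 0.3)
  expect_true(ef$pct_variance > 2 && ef$pct_variance < 50)
  # trait equal to the genotype code: pct variance = 100
  yg <- setNames(ifelse(imp$imputations[[1]][40, ] == 1L, 1, -1), imp$ril_ids)
  ef2 <- qtl_effects(imp, yg, imp$index$marker_id[40])
  expect_equal(ef2$pct_variance, 100, tolerance = 1e-8)
})

test_that("permutation thresholds are ordered, stable and calibrated", {
  f <- fx_qtl()
  imp <- impute_genotypes(f$gm, f$map, n_imputations = 4, seed = 61)
  set.seed(62)
  y <- setNames(rnorm(length(imp$ril_ids)), imp$ril_ids)
  th <- permutation_thresholds(imp, y, n_perm = 300, seed = 63)
  expect_lte(th[["10%"]], th[["5%"]])
  th2 <- permutation_thresholds(imp, y, n_perm = 600, seed = 64)
  expect_lt(abs(th2[["5%"]] - th[["5%"]]), 0.2)
  expect_warning(permutation_thresholds(imp, y, n_perm = 50, seed = 65),
                 "permutations")
})

test_that("conditional scans control a known QTL and find a second one", {
  lay <- sim_layout(n_chromosomes = 3, chrom_cM = 100, chrom_bp = 15e6,
                    mean_scaffold_bp = 2e6, scaffold_coverage = 0.95,
                    inversions = NULL, seed = 71)
  qs <- data.frame(trait = "t", chromosome_id = c("chr1", "chr2"),
                   pos_bp = c(7e6, 8e6), effect_sd = c(0.9, 0.6))
  tr <- simulate_pedigree(lay, n_rils = 250, seed = 72, qtl_spec = qs)
  gm <- true_genotype_matrix(tr, window_bp = 5e5)
  map <- build_genetic_map(gm, seed = 73)
  ph <- simulate_phenotypes(tr, skew_transform = FALSE, seed = 74)
  vc <- variance_components(ph, "t")
  y <- ril_means(ph, "t", vc)
  imp <- impute_genotypes(gm, map, n_imputations = 4, seed = 75)
  truth <- gm$truth_markers
  chrom_of <- function(mk) truth$chromosome_id[match(mk, truth$marker_id)]
  sc1 <- scan_qtl(imp, y)
  pk1 <- sc1$marker_id[which.max(sc1$lod)]
  expect_equal(chrom_of(pk1), "chr1")
  # after controlling the chr1 QTL the genome-wide peak moves to chr2
  sc2 <- add_qtl(imp, y, pk1)
  pk2 <- sc2$marker_id[which.max(sc2$lod)]
  expect_equal(chrom_of(pk2), "chr2")
  # conditioning on a marker from the QTL-free chr3 leaves the chr1 LOD alone
  g1 <- sc1$group[which.max(sc1$lod)]
  null_mk <- sc1$marker_id[chrom_of(sc1$marker_id) == "chr3"][1]
  sc3 <- add_qtl(imp, y, null_mk)
  expect_lt(abs(max(sc3$lod[sc3$group == g1]) - max(sc1$lod[sc1$group == g1])),
            0.4)
  # full forward model finds both simulated QTL and only those chromosomes
  mod <- build_qtl_model(imp, y, n_perm = 300, seed = 76, decomposition = vc)
  expect_equal(nrow(mod), 2L)
  expect_setequal(chrom_of(mod$marker_id), c("chr1", "chr2"))
})

test_that("LOD intervals follow the drop geometry", {
  # triangle profile with slope 0.1 LOD/cM: 1.8 drop spans 18 cM per side
  pos <- seq(0, 100, by = 1)
  lod <- pmax(0, 5 - 0.1 * abs(pos - 50))
  sc <- data.frame(marker_id = sprintf("m%d", seq_along(pos)), group = 1L,
                   pos_cM = pos, lod = lod)
  class(sc) <- c("qtl_scan", "data.frame")
  iv <- lod_interval(sc, 1, drop = 1.8)
  expect_equal(iv$lo_cM, 32)
  expect_equal(iv$hi_cM, 68)
  expect_equal(iv$pct_chromosome, 36)
  expect_false(iv$flat)
  # peak at the chromosome end clips at the boundary
  lod2 <- pmax(0, 5 - 0.1 * pos)
  sc2 <- sc
  sc2$lod <- lod2
  iv2 <- lod_interval(sc2, 1, drop = 1.8)
  expect_equal(iv2$lo_cM, 0)
  expect_equal(iv2$hi_cM, 18)
  # flat profile flags the whole chromosome
  sc3 <- sc
  sc3$lod <- rep(1, length(pos))
  expect_true(lod_interval(sc3, 1)$flat)
})
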