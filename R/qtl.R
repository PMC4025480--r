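# Phenotype preprocessing and QTL detection by multiple-imputation interval
# mapping with permutation-based genome-wide LOD thresholds.

#' Log(x + 1) trait transform
#'
#' Raw secondary-metabolite concentrations (mg/g dry weight) are
#' right-skewed; analysis proceeds on the natural log of (concentration + 1).
#' Measured concentrations are nonnegative, but any value above -1 (where
#' the transform is defined) is accepted so that exactly skew-simulated
#' panels round-trip.
#'
#' @param values Numeric vector, each element > -1.
#' @return Transformed values.
#' @export
transform_trait <- function(values) {
  if (any(values <= -1, na.rm = TRUE)) {
    stop("trait values must be > -1 for the log(x + 1) transform")
  }
  log1p(values)
}

#' Nested-ANOVA variance components for a replicated trait
#'
#' Fits the layout the phenotyping design implies: grow-up and
#' quantification method as fixed factors, RIL random and nested within
#' grow-up. Among- and within-RIL variance components come from the expected
#' mean squares of the sequential ANOVA (method of moments) with the
#' unbalanced-design coefficient
#' `k = (N - sum_g sum_i n_gi^2 / n_g) / df_ril`; a negative among-RIL
#' estimate is truncated to 0 and flagged. The within-RIL SD (used for QTL
#' effect sizes) is `sqrt(V_error)`.
#'
#' @param pheno data.frame with `ril_id`, `growup`, `method` columns.
#' @param trait Name of the (already transformed) trait column.
#' @return A `variance_decomposition`: `V_ril`, `V_error`, `within_ril_sd`,
#'   the fixed-effect fit (`y ~ growup + method`) used for residuals, mean
#'   squares, and flags.
#' @export
variance_components <- function(pheno, trait) {
  y <- pheno[[trait]]
  stopifnot(!is.null(y))
  d <- data.frame(y = y, growup = factor(pheno$growup),
                  method = factor(pheno$method), ril = factor(pheno$ril_id))
  # constant fixed factors (single grow-up or method) drop out of the model
  fixed_terms <- c(if (nlevels(d$growup) > 1L) "growup",
                   if (nlevels(d$method) > 1L) "method")
  full <- stats::lm(stats::reformulate(c(fixed_terms, "ril"), "y"), data = d)
  an <- stats::anova(full)
  ms_err <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  ms_ril <- an["ril", "Mean Sq"]
  df_ril <- an["ril", "Df"]
  inestimable <- df_err == 0L
  if (inestimable) ms_err <- NA_real_
  # unbalanced nested EMS coefficient (replicates per RIL, adjusted)
  tab <- table(d$growup, d$ril)
  n_g <- rowSums(tab)
  k <- (sum(n_g) - sum(rowSums(tab^2) / n_g)) / df_ril
  v_ril_raw <- (ms_ril - ms_err) / k
  truncated <- !is.na(v_ril_raw) && v_ril_raw < 0
  v_ril <- if (is.na(v_ril_raw)) NA_real_ else max(v_ril_raw, 0)
  fixed_fit <- stats::lm(stats::reformulate(c(fixed_terms, "1"), "y"), data = d)
  structure(list(V_ril = v_ril, V_error = ms_err,
                 within_ril_sd = sqrt(ms_err),
                 fixed_fit = fixed_fit,
                 mean_squares = c(ril = ms_ril, error = ms_err),
                 k_coefficient = k,
                 truncated = truncated, inestimable = inestimable),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("variance_decomposition: V_ril = %.4g, V_error = %.4g (within-RIL SD %.4g)%s\n",
              x$V_ril, x$V_error, x$within_ril_sd,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Per-RIL mean residual phenotypes
#'
#' RIL means are averages of residual values after correcting for the fixed
#' grow-up and quantification-method effects.
#'
#' @param pheno data.frame with `ril_id`, `growup`, `method`.
#' @param trait Transformed trait column name.
#' @param decomposition A [variance_components()] result for this trait.
#' @return Named numeric vector of RIL means (RILs with no observations are
#'   absent).
#' @export
ril_means <- function(pheno, trait, decomposition) {
  stopifnot(inherits(decomposition, "variance_decomposition"))
  res <- pheno[[trait]] - stats::predict(decomposition$fixed_fit,
                                         newdata = data.frame(
                                           growup = factor(pheno$growup),
                                           method = factor(pheno$method)))
  out <- tapply(res, pheno$ril_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Pairwise Pearson correlations between trait RIL means
#'
#' @param means Named list of RIL-mean vectors (one per trait), names = RIL
#'   ids.
#' @return List of matrices: `estimate`, `p_value`, `n` (shared RILs). Pairs
#'   with fewer than 3 shared RILs or zero variance are `NA`.
#' @export
trait_correlations <- function(means) {
  tn <- names(means)
  m <- length(means)
  est <- p <- nn <- matrix(NA_real_, m, m, dimnames = list(tn, tn))
  diag(est) <- 1
  diag(p) <- 0
  for (i in seq_len(m)) {
    nn[i, i] <- length(means[[i]])
    for (j in seq_len(m)) {
      if (j <= i) next
      shared <- intersect(names(means[[i]]), names(means[[j]]))
      nn[i, j] <- nn[j, i] <- length(shared)
      if (length(shared) < 3L) next
      x <- means[[i]][shared]
      y <- means[[j]][shared]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      est[i, j] <- est[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(estimate = est, p_value = p, n = nn)
}

# ---- multiple imputation -------------------------------------------------

# map distance (cM) -> meiotic r (inverse Haldane) -> RIL discordance R
.d_to_R <- function(d) {
  r <- (1 - exp(-d / 50)) / 2
  2 * r / (1 + 2 * r)
}

#' Impute missing genotypes along the map
#'
#' Missing (and HET, treated as missing: the scan uses a two-genotype model)
#' calls are drawn from the conditional distribution of a two-state IM/PR
#' Markov chain along each linkage group. The transition probability between
#' adjacent markers is the selfed-RIL discordance derived from the map
#' distance (`d` to meiotic `r` by the inverse Haldane function, then
#' `R = 2r/(1+2r)`). Sampling conditions on the nearest non-missing flanking
#' markers on both sides (one side at chromosome ends); RILs with no
#' observed genotype in a group get chain draws with a uniform start and are
#' flagged. Each imputation is a complete matrix; with no missing data all
#' imputations equal the input.
#'
#' @param gm A `geno_matrix` (the mapping set).
#' @param map A `genetic_map` built from it.
#' @param n_imputations Number of imputations (default 32).
#' @param seed Integer seed (required).
#' @return A `qtl_imputations` object: marker index (map order), RIL ids and
#'   a list of complete genotype matrices coded 1 = IM, 2 = PR.
#' @export
impute_genotypes <- function(gm, map, n_imputations = 32, seed) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(map, "genetic_map"))
  n_imputations <- .assert_count(n_imputations, "n_imputations")
  seed <- .assert_seed(seed)
  set.seed(seed)
  n_ril <- length(gm$ril_ids)
  index <- do.call(rbind, lapply(names(map$groups), function(g) {
    data.frame(marker_id = map$groups[[g]]$marker_id, group = as.integer(g),
               pos_cM = map$groups[[g]]$pos_cM)
  }))
  m_tot <- nrow(index)
  imps <- replicate(n_imputations,
                    matrix(NA_integer_, m_tot, n_ril,
                           dimnames = list(index$marker_id, gm$ril_ids)),
                    simplify = FALSE)
  flagged <- character(0)
  row0 <- 0L
  for (g in names(map$groups)) {
    df <- map$groups[[g]]
    m <- nrow(df)
    rows <- row0 + seq_len(m)
    obs <- gm$geno[match(df$marker_id, gm$markers$marker_id), , drop = FALSE]
    obs[obs == GENO_HET | obs == GENO_MISSING] <- NA_integer_
    q <- .d_to_R(diff(df$pos_cM))          # adjacent flip probabilities
    # two-state symmetric chain: 1 - 2Q(t,u) = prod (1 - 2 q_s)
    pre <- c(1, cumprod(1 - 2 * q))        # pre[t] = prod_{s<t}
    Qto <- function(t, u) 0.5 * (1 - pre[u] / pre[t])
    for (ril in seq_len(n_ril)) {
      o <- which(!is.na(obs[, ril]))
      if (length(o) == 0L) {
        flagged <- c(flagged, gm$ril_ids[ril])
        # no data: chain draws, uniform start (uniform marginals throughout)
        for (k in seq_len(n_imputations)) {
          s <- integer(m)
          s[1L] <- sample(c(GENO_IM, GENO_PR), 1L)
          if (m > 1L) for (t in 2:m) {
            s[t] <- if (stats::runif(1) < q[t - 1L]) 3L - s[t - 1L] else s[t - 1L]
          }
          imps[[k]][rows, ril] <- s
        }
        next
      }
      base <- obs[, ril]
      S <- matrix(rep(base, n_imputations), m, n_imputations)
      # interior runs between consecutive observed markers
      bounds <- cbind(o[-length(o)], o[-1L])
      for (b in seq_len(nrow(bounds))) {
        L <- bounds[b, 1L]; U <- bounds[b, 2L]
        if (U - L < 2L) next
        xu <- base[U]
        for (t in (L + 1L):(U - 1L)) {
          qs <- q[t - 1L]                     # step from t-1
          Qu <- Qto(t, U)                     # composite flip to U
          prev <- S[t - 1L, ]
          # P(x_t = prev | prev, x_U) via step x forward-composite weights
          a_same <- 1 - qs
          a_diff <- qs
          b_same <- ifelse(prev == xu, 1 - Qu, Qu)       # x_t = prev
          b_diff <- ifelse(prev == xu, Qu, 1 - Qu)       # x_t = flip(prev)
          p_same <- a_same * b_same / (a_same * b_same + a_diff * b_diff)
          flip <- stats::runif(n_imputations) >= p_same
          S[t, ] <- ifelse(flip, 3L - prev, prev)
        }
      }
      # left tail: backward from first observed marker
      if (o[1L] > 1L) {
        for (t in (o[1L] - 1L):1L) {
          qs <- q[t]
          flip <- stats::runif(n_imputations) < qs
          S[t, ] <- ifelse(flip, 3L - S[t + 1L, ], S[t + 1L, ])
        }
      }
      # right tail: forward from last observed marker
      if (o[length(o)] < m) {
        for (t in (o[length(o)] + 1L):m) {
          qs <- q[t - 1L]
          flip <- stats::runif(n_imputations) < qs
          S[t, ] <- ifelse(flip, 3L - S[t - 1L, ], S[t - 1L, ])
        }
      }
      for (k in seq_len(n_imputations)) imps[[k]][rows, ril] <- S[, k]
    }
    row0 <- row0 + m
  }
  structure(list(index = index, imputations = imps, ril_ids = gm$ril_ids,
                 n_imputations = n_imputations, seed = seed,
                 flagged_rils = unique(flagged)),
            class = "qtl_imputations")
}

#' @export
print.qtl_imputations <- function(x, ...) {
  cat(sprintf("qtl_imputations: %d markers x %d RILs, %d imputations\n",
              nrow(x$index), length(x$ril_ids), x$n_imputations))
  invisible(x)
}

# LOD vector for one imputation: coded genotypes X (m x n, +1/-1), Y (n x P)
# regression LOD = (n/2) log10(RSS0 / RSS1), Haley-Knott form
.lod_one <- function(X, Y) {
  n <- nrow(Y)
  Sy <- colSums(Y)
  SSy <- colSums(Y^2) - Sy^2 / n            # RSS0 per phenotype column
  Sx <- rowSums(X)
  varx <- n - Sx^2 / n                      # X entries are +/-1
  Sxy <- X %*% Y                            # m x P
  ct <- Sxy - outer(Sx, Sy) / n
  gain <- ct^2 / ifelse(varx > 1e-12, varx, Inf)
  RSS1 <- sweep(-gain, 2L, SSy, "+")
  RSS1 <- pmax(RSS1, matrix(SSy, nrow(X), length(SSy), byrow = TRUE) *
                 .Machine$double.eps)
  lod <- (n / 2) * (log10(matrix(SSy, nrow(X), length(SSy), byrow = TRUE)) -
                      log10(RSS1))
  pmax(lod, 0)
}

# residualize columns of M (n x k) on covariates [1, Z]
.resid_on <- function(M, qrZ) qr.resid(qrZ, M)

.lod_one_cov <- function(X, Y, qrZ) {
  n <- nrow(Y)
  Yt <- .resid_on(Y, qrZ)
  Gt <- .resid_on(t(X), qrZ)                # n x m
  RSS0 <- colSums(Yt^2)                     # per phenotype
  vx <- colSums(Gt^2)
  ct <- crossprod(Gt, Yt)                   # m x P
  gain <- ct^2 / ifelse(vx > 1e-12, vx, Inf)
  RSS1 <- sweep(-gain, 2L, RSS0, "+")
  RSS1 <- pmax(RSS1, matrix(RSS0, nrow(X), length(RSS0), byrow = TRUE) *
                 .Machine$double.eps)
  lod <- (n / 2) * (log10(matrix(RSS0, nrow(X), length(RSS0), byrow = TRUE)) -
                      log10(RSS1))
  pmax(lod, 0)
}

# combine per-imputation LOD matrices: log10 of the mean of 10^LOD
.combine_lods <- function(lods) {
  M <- Reduce(pmax, lods)
  S <- Reduce(`+`, lapply(lods, function(L) 10^(L - M)))
  M + log10(S / length(lods))
}

.coded_imp <- function(imp, k, ril_sel) {
  G <- imp$imputations[[k]][, ril_sel, drop = FALSE]
  X <- matrix(-1, nrow(G), ncol(G))
  X[G == GENO_IM] <- 1
  X
}

.covariate_qr <- function(imp, k, ril_sel, covariate_markers) {
  if (is.null(covariate_markers) || length(covariate_markers) == 0L) return(NULL)
  rows <- match(covariate_markers, imp$index$marker_id)
  Z <- t(.coded_imp(imp, k, ril_sel)[rows, , drop = FALSE])
  M <- cbind(1, Z)
  qz <- qr(M)
  if (qz$rank < ncol(M)) {
    warning("collinear covariate marker(s) dropped")
    keep <- qz$pivot[seq_len(qz$rank)]
    qz <- qr(M[, keep, drop = FALSE])
  }
  qz
}

#' Multiple-imputation interval-mapping scan
#'
#' At each marker and imputation, the LOD is `(n/2) log10(RSS0/RSS1)` from
#' regressing the trait on the genotype code (IM = +1, PR = -1), optionally
#' with model-QTL covariates in both the null and alternative regressions.
#' Imputation LODs are combined as the log10 of the arithmetic mean of
#' `10^LOD` across imputations. With complete genotypes this reduces exactly
#' to the single-regression LOD.
#'
#' @param imp A [impute_genotypes()] result.
#' @param phen Named numeric vector of RIL mean phenotypes (names = RIL ids;
#'   the intersection with genotyped RILs is scanned).
#' @param covariate_markers Optional marker ids whose (imputed) genotypes are
#'   regression covariates — the conditional scan of [add_qtl()].
#' @return A `qtl_scan` data.frame: `marker_id`, `group`, `pos_cM`, `lod`.
#' @export
scan_qtl <- function(imp, phen, covariate_markers = NULL) {
  stopifnot(inherits(imp, "qtl_imputations"))
  shared <- intersect(names(phen), imp$ril_ids)
  if (length(shared) < 10L) stop("fewer than 10 phenotyped, genotyped RILs")
  ril_sel <- match(shared, imp$ril_ids)
  y <- matrix(phen[shared], ncol = 1L)
  lods <- lapply(seq_len(imp$n_imputations), function(k) {
    X <- .coded_imp(imp, k, ril_sel)
    qz <- .covariate_qr(imp, k, ril_sel, covariate_markers)
    if (is.null(qz)) .lod_one(X, y) else .lod_one_cov(X, y, qz)
  })
  lod <- .combine_lods(lods)[, 1L]
  out <- cbind(imp$index, lod = lod)
  attr(out, "n") <- length(shared)
  attr(out, "n_imputations") <- imp$n_imputations
  attr(out, "covariates") <- covariate_markers
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Conditional scan for additional QTL
#'
#' Rescans the genome with the genotypes of the QTL already in the model
#' included as covariates in both null and alternative regressions.
#'
#' @param imp A [impute_genotypes()] result.
#' @param phen Named phenotype vector.
#' @param model_markers Marker ids of the QTL already in the model.
#' @return A `qtl_scan`.
#' @export
add_qtl <- function(imp, phen, model_markers) {
  if (length(model_markers) == 0L) stop("model is empty")
  scan_qtl(imp, phen, covariate_markers = model_markers)
}

#' Permutation-based genome-wide LOD thresholds
#'
#' Permutes the RIL mean phenotypes against intact genotype rows, records the
#' genome-wide maximum combined LOD per permutation, and returns the
#' `1 - alpha` quantiles.
#'
#' @param imp A [impute_genotypes()] result.
#' @param phen Named phenotype vector.
#' @param n_perm Number of permutations (default 1000; fewer than 100 warns).
#' @param alphas Significance levels (default 0.05 and 0.10).
#' @param seed Integer seed (required).
#' @param covariate_markers Optional covariates, as in [scan_qtl()].
#' @return Named vector of thresholds, with the per-permutation maxima in
#'   `attr(, "max_lods")`.
#' @export
permutation_thresholds <- function(imp, phen, n_perm = 1000,
                                   alphas = c(0.05, 0.10), seed,
                                   covariate_markers = NULL) {
  stopifnot(inherits(imp, "qtl_imputations"))
  n_perm <- .assert_count(n_perm, "n_perm")
  if (n_perm < 100L) warning("fewer than 100 permutations: thresholds are noisy")
  seed <- .assert_seed(seed)
  shared <- intersect(names(phen), imp$ril_ids)
  ril_sel <- match(shared, imp$ril_ids)
  y <- phen[shared]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  M <- NULL
  S <- NULL
  for (k in seq_len(imp$n_imputations)) {
    X <- .coded_imp(imp, k, ril_sel)
    qz <- .covariate_qr(imp, k, ril_sel, covariate_markers)
    L <- if (is.null(qz)) .lod_one(X, Y) else .lod_one_cov(X, Y, qz)
    if (is.null(M)) {
      M <- L
      S <- matrix(1, nrow(L), ncol(L))
    } else {
      Mn <- pmax(M, L)
      S <- S * 10^(M - Mn) + 10^(L - Mn)
      M <- Mn
    }
  }
  comb <- M + log10(S / imp$n_imputations)
  max_lods <- apply(comb, 2L, max)
  th <- stats::quantile(max_lods, 1 - alphas, names = FALSE)
  names(th) <- paste0(format(100 * alphas, trim = TRUE), "%")
  attr(th, "max_lods") <- max_lods
  th
}

#' LOD support interval around a peak
#'
#' The interval runs from the outermost map positions flanking the peak where
#' the LOD stays within `drop` of the peak LOD; also reports the percentage
#' of the chromosome the interval covers.
#'
#' @param scan A `qtl_scan`.
#' @param group Linkage group of the peak.
#' @param drop LOD drop (default 1.8).
#' @return List: `lo_cM`, `hi_cM`, `peak_cM`, `peak_lod`, `pct_chromosome`,
#'   and `flat` when the whole chromosome is within the drop.
#' @export
lod_interval <- function(scan, group, drop = 1.8) {
  df <- scan[scan$group == group, , drop = FALSE]
  if (nrow(df) == 0L) stop("no markers on group ", group)
  pk <- which.max(df$lod)
  th <- df$lod[pk] - drop
  ok <- which(df$lod >= th)
  lo <- df$pos_cM[min(ok)]
  hi <- df$pos_cM[max(ok)]
  len <- max(df$pos_cM)
  list(lo_cM = lo, hi_cM = hi, peak_cM = df$pos_cM[pk],
       peak_lod = df$lod[pk],
       pct_chromosome = if (len > 0) 100 * (hi - lo) / len else NA_real_,
       flat = all(df$lod >= th))
}

#' QTL effect sizes and explained variance
#'
#' The effect of each model QTL is the difference between the IM/IM and
#' PR/PR class means of the RIL phenotype, in units of the within-RIL SD
#' (`sqrt(V_error)` from the nested ANOVA), averaged over imputations. The
#' percentage of variance explained uses sums of squares from the linear
#' model with the QTL genotype codes as predictors.
#'
#' @param imp A [impute_genotypes()] result.
#' @param phen Named phenotype vector.
#' @param model_markers Marker ids of the QTL in the model.
#' @param decomposition The trait's [variance_components()] (for the
#'   within-RIL SD); `NULL` uses the phenotype SD instead.
#' @return data.frame per QTL: `marker_id`, `effect_sd`, `pct_variance`,
#'   and a flag for imputations lacking a genotype class.
#' @export
qtl_effects <- function(imp, phen, model_markers, decomposition = NULL) {
  stopifnot(inherits(imp, "qtl_imputations"), length(model_markers) >= 1L)
  shared <- intersect(names(phen), imp$ril_ids)
  ril_sel <- match(shared, imp$ril_ids)
  y <- phen[shared]
  sdw <- if (!is.null(decomposition)) decomposition$within_ril_sd else
    stats::sd(y)
  rows <- match(model_markers, imp$index$marker_id)
  if (anyNA(rows)) stop("unknown model marker")
  eff <- matrix(NA_real_, length(rows), imp$n_imputations)
  ssq <- matrix(NA_real_, length(rows), imp$n_imputations)
  flagged <- rep(FALSE, length(rows))
  for (k in seq_len(imp$n_imputations)) {
    X <- .coded_imp(imp, k, ril_sel)[rows, , drop = FALSE]
    for (qi in seq_along(rows)) {
      im <- X[qi, ] > 0
      if (all(im) || !any(im)) {
        flagged[qi] <- TRUE
        next
      }
      eff[qi, k] <- mean(y[im]) - mean(y[!im])
      fit <- stats::lm(y ~ t(X)[, qi])
      ss_total <- sum((y - mean(y))^2)
      ss_model <- ss_total - sum(stats::resid(fit)^2)
      ssq[qi, k] <- 100 * ss_model / ss_total
    }
  }
  data.frame(marker_id = model_markers,
             effect_sd = rowMeans(eff, na.rm = TRUE) / sdw,
             pct_variance = rowMeans(ssq, na.rm = TRUE),
             class_missing_flag = flagged)
}

#' Fit a full QTL model by forward search
#'
#' Initial scan, permutation thresholds, then repeated conditional scans
#' ([add_qtl()]) adding the genome-wide peak while it exceeds the 5%
#' threshold. Reports, per QTL: peak, LOD, permutation p-value (fraction of
#' permutation maxima at or above the observed LOD), 1.8-LOD interval and
#' chromosome percentage, effect in within-RIL SD units, and percent
#' variance explained.
#'
#' @param imp A [impute_genotypes()] result.
#' @param phen Named phenotype vector.
#' @param n_perm Permutations for thresholds (default 1000).
#' @param alpha Entry threshold level (default 0.05).
#' @param drop LOD-interval drop (default 1.8).
#' @param seed Integer seed (required).
#' @param decomposition Optional [variance_components()] for effect scaling.
#' @param max_qtl Safety cap on model size (default 5).
#' @return A `qtl_model` data.frame (possibly empty), with the thresholds in
#'   `attr(, "thresholds")` and the initial scan in `attr(, "scan")`.
#' @export
build_qtl_model <- function(imp, phen, n_perm = 1000, alpha = 0.05,
                            drop = 1.8, seed, decomposition = NULL,
                            max_qtl = 5) {
  seed <- .assert_seed(seed)
  th <- permutation_thresholds(imp, phen, n_perm = n_perm,
                               alphas = c(alpha, 0.10), seed = seed)
  max_lods <- attr(th, "max_lods")
  model <- character(0)
  records <- list()
  scan0 <- scan_qtl(imp, phen)
  current <- scan0
  repeat {
    pk <- which.max(current$lod)
    if (current$lod[pk] <= th[1L] || length(model) >= max_qtl) break
    mk <- current$marker_id[pk]
    iv <- lod_interval(current, current$group[pk], drop = drop)
    records[[length(records) + 1L]] <- data.frame(
      marker_id = mk, group = current$group[pk],
      pos_cM = current$pos_cM[pk], lod = current$lod[pk],
      p_value = mean(max_lods >= current$lod[pk]),
      interval_lo_cM = iv$lo_cM, interval_hi_cM = iv$hi_cM,
      pct_chromosome = iv$pct_chromosome)
    model <- c(model, mk)
    current <- add_qtl(imp, phen, model)
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(marker_id = character(), group = integer(), pos_cM = numeric(),
               lod = numeric(), p_value = numeric(),
               interval_lo_cM = numeric(), interval_hi_cM = numeric(),
               pct_chromosome = numeric())
  if (nrow(out)) {
    ef <- qtl_effects(imp, phen, out$marker_id, decomposition)
    out$effect_sd <- ef$effect_sd
    out$pct_variance <- ef$pct_variance
  } else {
    out$effect_sd <- numeric(0)
    out$pct_variance <- numeric(0)
  }
  attr(out, "thresholds") <- th
  attr(out, "scan") <- scan0
  class(out) <- c("qtl_model", "data.frame")
  out
}
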