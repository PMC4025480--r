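# Selfed-RIL panel simulator with full ground truth.
#
# Haplotypes are run-length segment lists: `list(ends, par)` where `ends`
# is a strictly increasing vector of segment end coordinates (half-open,
# last end = chromosome length) and `par` the parental origin per segment
# (1 = IM, 2 = PR).

.hap_const <- function(L, par) list(ends = L, par = as.integer(par))

.hap_at <- function(hap, pos) {
  hap$par[findInterval(pos, hap$ends) + 1L]
}

# extract+splice gamete pieces between crossover cuts, alternating haplotypes
.meiosis_gamete <- function(h1, h2, xo, L, start_hap) {
  if (length(xo) == 0L && start_hap == 1L) return(h1)
  if (length(xo) == 0L) return(h2)
  cuts <- c(0, xo, L)
  haps <- list(h1, h2)
  cur <- start_hap
  ends <- vector("list", length(cuts) - 1L)
  par <- vector("list", length(cuts) - 1L)
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]
    b <- cuts[i + 1L]
    h <- haps[[cur]]
    i1 <- findInterval(a, h$ends) + 1L
    i2 <- findInterval(b, h$ends, left.open = TRUE) + 1L
    ends[[i]] <- pmin(h$ends[i1:i2], b)
    par[[i]] <- h$par[i1:i2]
    cur <- 3L - cur
  }
  ends <- unlist(ends)
  par <- unlist(par)
  n <- length(ends)
  if (n > 1L) {
    keep <- c(par[-n] != par[-1L], TRUE)
    ends <- ends[keep]
    par <- par[keep]
  }
  list(ends = ends, par = par)
}

# TRUE when the two haplotypes carry different parents at every point of [s, e)
.het_across <- function(h1, h2, s, e) {
  cuts <- c(s, h1$ends[h1$ends > s & h1$ends < e],
            h2$ends[h2$ends > s & h2$ends < e], e)
  cuts <- sort(unique(cuts))
  mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
  all(.hap_at(h1, mids) != .hap_at(h2, mids))
}

# total bp where the two haplotypes disagree
.het_length <- function(h1, h2) {
  cuts <- sort(unique(c(0, h1$ends, h2$ends)))
  mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
  sum((diff(cuts))[.hap_at(h1, mids) != .hap_at(h2, mids)])
}

#' Simulate a selfed-RIL pedigree with crossover ground truth
#'
#' Each RIL descends from one IM x PR F1 by `n_selfing_generations` rounds
#' of self-fertilisation with single-seed descent (F8 corresponds to 7).
#' Per meiosis, crossovers form a Poisson process along each chromosome with
#' `genetic_length_cM / 100` expected events (no interference, consistent
#' with the Haldane map function used downstream). Inside an inversion
#' interval, a meiosis in an individual heterozygous IM/PR across the whole
#' interval yields no crossovers (suppression is absolute by default; set
#' `inversion_leak` > 0 to let each suppressed crossover survive with that
#' probability). All realized crossover positions are logged.
#'
#' @param layout A [genome_layout()].
#' @param n_rils Number of RILs to derive.
#' @param n_selfing_generations Selfing rounds after the F1 (default 7, an
#'   F8 panel).
#' @param seed Integer seed (required; identical seeds give identical output).
#' @param qtl_spec Optional data.frame (`trait`, `chromosome_id`, `pos_bp`,
#'   `effect_sd`) of true QTL carried as ground truth for
#'   [simulate_phenotypes()]; `effect_sd` is the additive effect in
#'   within-RIL SD units (+a for IM/IM, -a for PR/PR).
#' @param variance_components Named numeric vector `V_ril`, `V_growup`,
#'   `V_error` on the transformed (log) trait scale.
#' @param inversion_leak Probability a crossover inside a heterozygous
#'   inversion is retained (default 0 = absolute suppression).
#' @return A `sim_truth` object: per-RIL two-haplotype segment lists per
#'   chromosome, the crossover log, and the phenotype ground truth.
#' @examples
#' lay <- sim_layout(n_chromosomes = 1, chrom_cM = 100, chrom_bp = 1e6,
#'                   inversions = NULL, seed = 1)
#' tr <- simulate_pedigree(lay, n_rils = 5, seed = 2)
#' true_genotype(tr, 1, "chr1", c(0, 5e5))
#' @export
simulate_pedigree <- function(layout, n_rils,
                              n_selfing_generations = 7,
                              seed,
                              qtl_spec = NULL,
                              variance_components = c(V_ril = 1, V_growup = 0.04,
                                                      V_error = 1),
                              inversion_leak = 0) {
  stopifnot(inherits(layout, "genome_layout"))
  n_rils <- .assert_count(n_rils, "n_rils")
  n_selfing_generations <- .assert_count(n_selfing_generations,
                                         "n_selfing_generations")
  seed <- .assert_seed(seed)
  if (any(variance_components < 0)) stop("variance components must be >= 0")
  set.seed(seed)
  chroms <- layout$chromosomes
  n_chr <- nrow(chroms)
  inv_by_chr <- split(layout$inversions, factor(layout$inversions$chromosome_id,
                                                levels = chroms$id))
  log_ril <- list(); log_gen <- list(); log_chr <- list(); log_pos <- list()
  nlog <- 0L

  rils <- vector("list", n_rils)
  for (ril in seq_len(n_rils)) {
    # F1: one IM haplotype, one PR haplotype on every chromosome
    ind <- lapply(seq_len(n_chr), function(i) {
      L <- chroms$physical_length_bp[i]
      list(.hap_const(L, 1L), .hap_const(L, 2L))
    })
    for (gen in seq_len(n_selfing_generations)) {
      offspring <- vector("list", n_chr)
      for (ci in seq_len(n_chr)) {
        L_bp <- chroms$physical_length_bp[ci]
        L_cM <- chroms$genetic_length_cM[ci]
        invs <- inv_by_chr[[ci]]
        pair <- ind[[ci]]
        gam <- vector("list", 2L)
        for (g in 1:2) {
          n_xo <- rpois(1L, L_cM / 100)
          xo <- if (n_xo > 0L) sort(runif(n_xo, 0, L_bp)) else numeric(0)
          if (length(xo) && nrow(invs)) {
            for (r in seq_len(nrow(invs))) {
              inside <- xo >= invs$start_bp[r] & xo < invs$end_bp[r]
              if (any(inside) &&
                  .het_across(pair[[1L]], pair[[2L]],
                              invs$start_bp[r], invs$end_bp[r])) {
                drop <- inside
                if (inversion_leak > 0) {
                  drop <- inside & runif(length(xo)) >= inversion_leak
                }
                xo <- xo[!drop]
              }
            }
          }
          if (length(xo)) {
            nlog <- nlog + 1L
            log_ril[[nlog]] <- rep.int(ril, length(xo))
            log_gen[[nlog]] <- rep.int(gen, length(xo))
            log_chr[[nlog]] <- rep.int(ci, length(xo))
            log_pos[[nlog]] <- xo
          }
          start <- sample.int(2L, 1L)
          gam[[g]] <- .meiosis_gamete(pair[[1L]], pair[[2L]], xo, L_bp, start)
        }
        offspring[[ci]] <- gam
      }
      ind <- offspring
    }
    rils[[ril]] <- ind
  }
  crossover_log <- data.frame(
    ril = unlist(log_ril, use.names = FALSE),
    generation = unlist(log_gen, use.names = FALSE),
    chromosome_id = chroms$id[unlist(log_chr, use.names = FALSE)],
    pos_bp = unlist(log_pos, use.names = FALSE)
  )
  structure(list(layout = layout,
                 ril_ids = sprintf("RIL_%04d", seq_len(n_rils)),
                 haplotypes = rils,
                 n_selfing_generations = n_selfing_generations,
                 qtl_spec = qtl_spec,
                 variance_components = variance_components,
                 crossover_log = crossover_log,
                 seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d RILs (F%d), %d chromosomes, %d logged crossovers\n",
              length(x$ril_ids), x$n_selfing_generations + 1L,
              nrow(x$layout$chromosomes), nrow(x$crossover_log)))
  invisible(x)
}

#' True genotype of a RIL at physical positions
#'
#' @param truth A `sim_truth` object.
#' @param ril RIL index (integer) or id.
#' @param chromosome_id Chromosome id.
#' @param bp Vector of 0-based positions.
#' @return Integer genotype codes (see [geno_codes()]).
#' @export
true_genotype <- function(truth, ril, chromosome_id, bp) {
  if (is.character(ril)) ril <- match(ril, truth$ril_ids)
  ci <- match(chromosome_id, truth$layout$chromosomes$id)
  pair <- truth$haplotypes[[ril]][[ci]]
  a <- .hap_at(pair[[1L]], bp)
  b <- .hap_at(pair[[2L]], bp)
  ifelse(a == b, a, GENO_HET)
}

#' Residual heterozygosity per RIL
#'
#' Fraction of the genome (bp-weighted) where a RIL's two haplotypes carry
#' different parental alleles. Under selfing this halves per generation:
#' expectation (1/2)^g after g selfing generations.
#'
#' @param truth A `sim_truth` object.
#' @return Numeric vector, one fraction per RIL.
#' @export
ril_heterozygosity <- function(truth) {
  tot <- sum(truth$layout$chromosomes$physical_length_bp)
  vapply(truth$haplotypes, function(ind) {
    sum(vapply(ind, function(pair) .het_length(pair[[1L]], pair[[2L]]),
               numeric(1))) / tot
  }, numeric(1))
}

#' Error-free window genotype matrix from simulation truth
#'
#' Tiles every scaffold into `window_bp` windows (from scaffold coordinate 0;
#' the final partial window is kept) and reports the true genotype at each
#' window midpoint — the idealised output of the window caller, used for
#' recovery tests that isolate mapping from genotyping noise.
#'
#' @param truth A `sim_truth` object.
#' @param window_bp Window size in bp (default 50000).
#' @return A `geno_matrix` (see [call_windows()]).
#' @export
true_genotype_matrix <- function(truth, window_bp = 50000) {
  layout <- truth$layout
  sc <- layout$scaffolds
  mk <- list()
  for (i in seq_len(nrow(sc))) {
    starts <- seq(0, sc$length_bp[i] - 1e-9, by = window_bp)
    ends <- pmin(starts + window_bp, sc$length_bp[i])
    mk[[i]] <- data.frame(scaffold_id = sc$scaffold_id[i],
                          window_index = seq_along(starts) - 1L,
                          start_bp = starts, end_bp = ends,
                          chromosome_id = sc$chromosome_id[i],
                          anchored = sc$anchored[i],
                          chrom_mid_bp = sc$start_bp[i] + (starts + ends) / 2)
  }
  mk <- do.call(rbind, mk)
  mk$marker_id <- sprintf("%s:%d", mk$scaffold_id, mk$window_index)
  n_ril <- length(truth$ril_ids)
  geno <- matrix(GENO_MISSING, nrow(mk), n_ril,
                 dimnames = list(mk$marker_id, truth$ril_ids))
  for (ch in unique(mk$chromosome_id)) {
    rows <- which(mk$chromosome_id == ch)
    pos <- mk$chrom_mid_bp[rows]
    for (r in seq_len(n_ril)) {
      geno[rows, r] <- true_genotype(truth, r, ch, pos)
    }
  }
  new_geno_matrix(mk[, c("marker_id", "scaffold_id", "window_index",
                         "start_bp", "end_bp")],
                  geno, truth$ril_ids,
                  truth_markers = mk)
}

#' Error-free point-locus genotype matrix
#'
#' Places markers as point loci (1-bp windows) evenly along each scaffold,
#' always including both scaffold ends, and reports the true genotype at
#' each locus. Unlike [true_genotype_matrix()], whose 50-kb windows lose
#' half a window of genetic span at each scaffold end relative to the
#' physical span, point loci at the ends make a scaffold's genetic and
#' physical spans commensurate — the placement of choice when studying
#' per-scaffold recombination rates in isolation from the window caller.
#'
#' @param truth A `sim_truth` object.
#' @param spacing_bp Approximate spacing between loci (default 150000).
#' @return A `geno_matrix` with 1-bp marker windows.
#' @export
point_genotype_matrix <- function(truth, spacing_bp = 150000) {
  layout <- truth$layout
  sc <- layout$scaffolds
  mk <- list()
  for (i in seq_len(nrow(sc))) {
    L <- sc$length_bp[i]
    k <- max(2L, ceiling(L / spacing_bp) + 1L)
    pos <- seq(0, L - 1, length.out = k)
    mk[[i]] <- data.frame(scaffold_id = sc$scaffold_id[i],
                          window_index = seq_along(pos) - 1L,
                          start_bp = pos, end_bp = pos + 1,
                          chromosome_id = sc$chromosome_id[i],
                          anchored = sc$anchored[i],
                          chrom_mid_bp = sc$start_bp[i] + pos + 0.5)
  }
  mk <- do.call(rbind, mk)
  mk$marker_id <- sprintf("%s:%d", mk$scaffold_id, mk$window_index)
  n_ril <- length(truth$ril_ids)
  geno <- matrix(GENO_MISSING, nrow(mk), n_ril,
                 dimnames = list(mk$marker_id, truth$ril_ids))
  for (ch in unique(mk$chromosome_id)) {
    rows <- which(mk$chromosome_id == ch)
    pos <- mk$chrom_mid_bp[rows]
    for (r in seq_len(n_ril)) {
      geno[rows, r] <- true_genotype(truth, r, ch, pos)
    }
  }
  new_geno_matrix(mk[, c("marker_id", "scaffold_id", "window_index",
                         "start_bp", "end_bp")],
                  geno, truth$ril_ids, truth_markers = mk)
}

#' Simulate low-coverage SNP read counts
#'
#' Places SNPs uniformly within scaffolds at `snp_density_per_kb` (Poisson
#' number per scaffold), then draws per-RIL read depth ~ Poisson(`mean_depth`)
#' at every SNP. Each read reports the allele of one of the RIL's two
#' haplotypes chosen uniformly, flipped with probability `base_error`. The
#' IM-parent base is recorded per SNP, emulating variant-caller output from
#' restriction-fragment sequencing: very many informative SNPs at low depth
#' per line.
#'
#' @param truth A `sim_truth` object.
#' @param snp_density_per_kb Expected SNPs per kb of scaffold sequence.
#' @param mean_depth Mean reads per RIL per SNP.
#' @param base_error Per-read allele error probability, in `[0, 0.5)`.
#' @param seed Integer seed (required).
#' @param im767_ambiguous_frac Fraction of SNPs whose IM-parent base call is
#'   ambiguous (flagged, to exercise filter criterion 2).
#' @return A `snp_data` object: `snps` metadata data.frame (scaffold, 0-based
#'   position, IM/alt base, IM767 call) plus SNP x RIL integer matrices
#'   `im_reads` and `alt_reads`.
#' @export
simulate_reads <- function(truth, snp_density_per_kb = 1,
                           mean_depth = 0.7, base_error = 0.002,
                           seed, im767_ambiguous_frac = 0) {
  stopifnot(inherits(truth, "sim_truth"))
  if (base_error < 0 || base_error >= 0.5) stop("`base_error` must be in [0, 0.5)")
  if (mean_depth <= 0) stop("`mean_depth` must be > 0")
  seed <- .assert_seed(seed)
  set.seed(seed)
  layout <- truth$layout
  sc <- layout$scaffolds
  bases <- c("A", "C", "G", "T")
  snp <- list()
  for (i in seq_len(nrow(sc))) {
    n <- rpois(1L, sc$length_bp[i] / 1000 * snp_density_per_kb)
    if (n == 0L) next
    pos <- sort(runif(n, 0, sc$length_bp[i]))
    im <- sample(bases, n, replace = TRUE)
    alt <- vapply(im, function(b) sample(setdiff(bases, b), 1L), character(1))
    snp[[length(snp) + 1L]] <- data.frame(
      scaffold_id = sc$scaffold_id[i], pos = floor(pos),
      im_base = im, alt_base = unname(alt),
      chromosome_id = sc$chromosome_id[i],
      chrom_pos = sc$start_bp[i] + pos,
      im767_call = "IM")
  }
  snps <- do.call(rbind, snp)
  if (im767_ambiguous_frac > 0) {
    amb <- runif(nrow(snps)) < im767_ambiguous_frac
    snps$im767_call[amb] <- "AMBIGUOUS"
  }
  n_snp <- nrow(snps)
  n_ril <- length(truth$ril_ids)
  G <- matrix(GENO_MISSING, n_snp, n_ril)
  for (ch in unique(snps$chromosome_id)) {
    rows <- which(snps$chromosome_id == ch)
    pos <- snps$chrom_pos[rows]
    for (r in seq_len(n_ril)) {
      G[rows, r] <- true_genotype(truth, r, ch, pos)
    }
  }
  depth <- matrix(rpois(n_snp * n_ril, mean_depth), n_snp, n_ril)
  p_true <- matrix(c(1, 0, 0.5)[G], n_snp, n_ril)   # P(read carries IM base)
  p_im <- p_true * (1 - base_error) + (1 - p_true) * base_error
  im_reads <- matrix(rbinom(n_snp * n_ril, depth, p_im), n_snp, n_ril,
                     dimnames = list(NULL, truth$ril_ids))
  alt_reads <- depth - im_reads
  dimnames(alt_reads) <- dimnames(im_reads)
  new_snp_data(snps, im_reads, alt_reads, truth$ril_ids,
               true_geno = G)
}

#' Default QTL specification for simulated phenotype panels
#'
#' Three modest-effect QTL, one per trait, on distinct chromosomes —
#' the architecture the mapping stage is meant to recover.
#'
#' @param layout A [genome_layout()].
#' @param traits Trait names.
#' @param effects Additive effects in within-RIL SD units.
#' @param chromosomes Host chromosome indices (recycled into range).
#' @return data.frame usable as `qtl_spec` in [simulate_pedigree()].
#' @export
default_qtl_spec <- function(layout, traits = c("conandroside", "ppg5", "ppg7"),
                             effects = c(0.45, 0.5, 0.55),
                             chromosomes = c(3L, 6L, 13L)) {
  n_chr <- nrow(layout$chromosomes)
  chromosomes <- ((chromosomes - 1L) %% n_chr) + 1L
  data.frame(trait = traits,
             chromosome_id = layout$chromosomes$id[chromosomes],
             pos_bp = round(layout$chromosomes$physical_length_bp[chromosomes] * 0.5),
             effect_sd = effects)
}

#' Simulate replicated phenotypes with batch structure
#'
#' Replicate values follow the linear model the downstream ANOVA assumes:
#' grand mean + summed QTL effects (+a for IM/IM, -a for PR/PR, 0 for HET,
#' scaled by sqrt(V_error) so effects are in within-RIL SD units) + a RIL
#' random deviate (variance `V_ril`, correlated `ril_cor` across traits via a
#' shared polygenic factor) + fixed grow-up and quantification-method offsets
#' + residual error (variance `V_error`). RILs are assigned to grow-ups in
#' rotation (each RIL nested in one grow-up); quantification method
#' alternates across replicates. With `skew_transform` the linear value `v`
#' is emitted as `exp(v) - 1`, giving the right-skewed raw concentrations
#' whose `log(x + 1)` transform recovers the linear scale; all emitted values
#' then exceed -1.
#'
#' @param truth A `sim_truth` (supplies `qtl_spec` and `variance_components`).
#' @param n_growups Number of grow-up batches.
#' @param n_reps Replicates per RIL.
#' @param skew_transform Emit `exp(v) - 1` (default TRUE).
#' @param seed Integer seed (required).
#' @param grand_mean Grand mean on the linear scale.
#' @param method_offset Fixed offset of the second quantification method.
#' @param ril_cor Cross-trait correlation of RIL random deviates.
#' @param effect_unit Trait-scale value of one within-RIL SD used to scale
#'   QTL effects; defaults to `sqrt(V_error)`. Supply explicitly when
#'   simulating noise-free panels.
#' @return data.frame (`ril_id`, `growup`, `method`, `replicate`, one column
#'   per trait) with the generating truth in `attr(, "pheno_truth")`.
#' @export
simulate_phenotypes <- function(truth, n_growups = 3, n_reps = 3,
                                skew_transform = TRUE, seed,
                                grand_mean = 1, method_offset = 0.2,
                                ril_cor = 0.4, effect_unit = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  seed <- .assert_seed(seed)
  n_growups <- .assert_count(n_growups, "n_growups")
  n_reps <- .assert_count(n_reps, "n_reps")
  vc <- truth$variance_components
  if (any(vc < 0)) stop("variance components must be nonnegative")
  set.seed(seed)
  qtl <- truth$qtl_spec
  traits <- if (is.null(qtl) || nrow(qtl) == 0) "trait1" else unique(qtl$trait)
  n_ril <- length(truth$ril_ids)
  growup_offsets <- rnorm(n_growups, 0, sqrt(vc[["V_growup"]]))
  growup_of <- rep_len(seq_len(n_growups), n_ril)
  # correlated RIL random deviates: shared factor + trait-specific part
  common <- rnorm(n_ril)
  dev <- sapply(traits, function(t) {
    sqrt(vc[["V_ril"]]) *
      (sqrt(ril_cor) * common + sqrt(1 - ril_cor) * rnorm(n_ril))
  })
  dev <- matrix(dev, n_ril, length(traits),
                dimnames = list(NULL, traits))
  # QTL genotype contributions per RIL per trait (SD units -> linear scale)
  qtl_contrib <- matrix(0, n_ril, length(traits),
                        dimnames = list(NULL, traits))
  if (!is.null(qtl) && nrow(qtl)) {
    for (k in seq_len(nrow(qtl))) {
      g <- vapply(seq_len(n_ril), function(r) {
        true_genotype(truth, r, qtl$chromosome_id[k], qtl$pos_bp[k])
      }, integer(1))
      code <- c(1, -1, 0)[g]   # IM=+1, PR=-1, HET=0
      unit <- if (is.null(effect_unit)) sqrt(vc[["V_error"]]) else effect_unit
      qtl_contrib[, qtl$trait[k]] <- qtl_contrib[, qtl$trait[k]] +
        code * qtl$effect_sd[k] * unit
    }
  }
  rows <- expand.grid(replicate = seq_len(n_reps), ril = seq_len(n_ril))
  out <- data.frame(ril_id = truth$ril_ids[rows$ril],
                    growup = paste0("GU", growup_of[rows$ril]),
                    method = c("HPLC", "UHPLC")[(rows$replicate - 1L) %% 2L + 1L],
                    replicate = rows$replicate)
  m_off <- ifelse(out$method == "UHPLC", method_offset, 0)
  for (t in traits) {
    v <- grand_mean + qtl_contrib[rows$ril, t] + dev[rows$ril, t] +
      growup_offsets[growup_of[rows$ril]] + m_off +
      rnorm(nrow(rows), 0, sqrt(vc[["V_error"]]))
    out[[t]] <- if (skew_transform) exp(v) - 1 else v
  }
  attr(out, "pheno_truth") <- list(qtl_spec = qtl,
                                   variance_components = vc,
                                   growup_offsets = growup_offsets,
                                   method_offset = method_offset,
                                   grand_mean = grand_mean,
                                   traits = traits,
                                   skew_transform = skew_transform)
  out
}

#' Write simulation ground truth as JSON
#'
#' Serialises haplotype segment lists, the crossover log, QTL spec and
#' variance components so that external tools can audit recovery.
#'
#' @param truth A `sim_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    ril_ids = truth$ril_ids,
    n_selfing_generations = truth$n_selfing_generations,
    chromosomes = truth$layout$chromosomes,
    inversions = truth$layout$inversions,
    qtl_spec = truth$qtl_spec,
    variance_components = as.list(truth$variance_components),
    crossover_log = truth$crossover_log,
    haplotypes = lapply(truth$haplotypes, function(ind) {
      lapply(ind, function(pair) {
        list(h1 = pair[[1L]], h2 = pair[[2L]])
      })
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
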