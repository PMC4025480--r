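# Shared fixtures (memoised: built once per test run) and independent
# oracles used across test files.

.fix <- new.env()

# 3 chromosomes, ~6.7 cM/Mb, three large inversions, 100 RILs
fx_inv <- function() {
  if (is.null(.fix$inv)) {
    lay <- sim_layout(n_chromosomes = 3, chrom_cM = 100, chrom_bp = 15e6,
                      mean_scaffold_bp = 1.2e6,
                      inversions = data.frame(
                        chromosome_id = c("chr1", "chr2", "chr3"),
                        start_bp = c(9e6, 1e6, 6e6),
                        end_bp = c(9e6, 1e6, 6e6) + c(3.75e6, 2.95e6, 4.1e6)),
                      seed = 101)
    tr <- simulate_pedigree(lay, n_rils = 100, seed = 102)
    gm <- true_genotype_matrix(tr)
    map <- build_genetic_map(gm, seed = 103)
    .fix$inv <- list(lay = lay, tr = tr, gm = gm, map = map)
  }
  .fix$inv
}

# plain panel without suppression, one QTL, replicated phenotypes
fx_qtl <- function() {
  if (is.null(.fix$qtl)) {
    lay <- sim_layout(n_chromosomes = 3, chrom_cM = 100, chrom_bp = 15e6,
                      mean_scaffold_bp = 2e6, inversions = NULL, seed = 201)
    qs <- default_qtl_spec(lay, traits = "t1", effects = 0.8, chromosomes = 2L)
    tr <- simulate_pedigree(lay, n_rils = 169, seed = 202, qtl_spec = qs)
    gm <- true_genotype_matrix(tr, window_bp = 5e5)
    map <- build_genetic_map(gm, seed = 203)
    ph <- simulate_phenotypes(tr, seed = 204)
    ph$t1l <- transform_trait(ph$t1)
    vc <- variance_components(ph, "t1l")
    rm_ <- ril_means(ph, "t1l", vc)
    .fix$qtl <- list(lay = lay, qs = qs, tr = tr, gm = gm, map = map,
                     ph = ph, vc = vc, means = rm_)
  }
  .fix$qtl
}

# hand-built snp_data: counts matrices with explicit per-RIL reads
make_snp_data <- function(scaffold, pos, im, alt, im_base = "A",
                          alt_base = "C", im767 = "IM") {
  n_snp <- length(pos)
  snps <- data.frame(scaffold_id = rep_len(scaffold, n_snp), pos = pos,
                     im_base = rep_len(im_base, n_snp),
                     alt_base = rep_len(alt_base, n_snp),
                     im767_call = rep_len(im767, n_snp))
  if (is.null(colnames(im))) {
    colnames(im) <- colnames(alt) <- sprintf("R%02d", seq_len(ncol(im)))
  }
  rilmap:::new_snp_data(snps, im, alt, colnames(im))
}

# direct two-locus selfing simulator: independent oracle for the
# Haldane-Waddington RIL discordance R = 2r / (1 + 2r)
two_locus_selfing_oracle <- function(r, n, gens, seed) {
  set.seed(seed)
  # haplotypes per line: columns h1l1, h1l2, h2l1, h2l2 (0 = IM, 1 = PR)
  H <- cbind(0L, 0L, 1L, 1L)[rep(1, n), , drop = FALSE]
  gamete <- function(H) {
    s1 <- sample(c(0L, 1L), n, replace = TRUE)
    s2 <- ifelse(runif(n) < r, 1L - s1, s1)
    cbind(ifelse(s1 == 0L, H[, 1L], H[, 3L]),
          ifelse(s2 == 0L, H[, 2L], H[, 4L]))
  }
  for (g in seq_len(gens)) {
    g1 <- gamete(H)
    g2 <- gamete(H)
    H <- cbind(g1, g2)
  }
  hom <- H[, 1L] == H[, 3L] & H[, 2L] == H[, 4L]
  mean(H[hom, 1L] != H[hom, 2L])
}

# exhaustive SARF optimum over all block orders and orientations
exhaustive_sarf <- function(blocks, R) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  orients <- expand.grid(rep(list(c(FALSE, TRUE)), length(blocks)))
  for (p in perms(seq_along(blocks))) {
    for (oi in seq_len(nrow(orients))) {
      seqm <- unlist(lapply(seq_along(p), function(i) {
        b <- blocks[[p[i]]]
        if (orients[oi, i]) rev(b) else b
      }))
      s <- sum(R[cbind(seqm[-length(seqm)], seqm[-1L])])
      best <- min(best, s)
    }
  }
  best
}
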