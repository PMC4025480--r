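#' Construct a genome layout
#'
#' A genome layout describes the simulated (or assumed) genome: chromosomes
#' with genetic and physical lengths, scaffolds placed on chromosomes, and
#' inversion intervals within which crossovers are suppressed in IM/PR
#' heterozygotes. All coordinates are 0-based, half-open `[start, end)`;
#' 1-based coordinates appear only at VCF boundaries.
#'
#' @param chromosomes data.frame with columns `id` (character),
#'   `genetic_length_cM` (> 0) and `physical_length_bp` (> 0).
#' @param scaffolds data.frame with columns `scaffold_id`, `chromosome_id`,
#'   `start_bp`, `length_bp`, and logical `anchored`. Unanchored scaffolds
#'   (`anchored = FALSE`) carry no chromosome assignment in emitted data,
#'   though the layout retains their true location.
#' @param inversions data.frame with columns `chromosome_id`, `start_bp`,
#'   `end_bp`, or `NULL` for none.
#' @return An object of class `genome_layout`.
#' @seealso [sim_layout()] for a parameterised generator.
#' @export
genome_layout <- function(chromosomes, scaffolds, inversions = NULL) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(scaffolds))
  chromosomes$id <- as.character(chromosomes$id)
  if (any(chromosomes$genetic_length_cM <= 0)) {
    stop("chromosome genetic lengths must be > 0")
  }
  if (any(chromosomes$physical_length_bp <= 0)) {
    stop("chromosome physical lengths must be > 0")
  }
  if (anyDuplicated(chromosomes$id)) stop("duplicate chromosome ids")
  scaffolds$scaffold_id <- as.character(scaffolds$scaffold_id)
  scaffolds$chromosome_id <- as.character(scaffolds$chromosome_id)
  if (is.null(scaffolds$anchored)) scaffolds$anchored <- TRUE
  if (anyDuplicated(scaffolds$scaffold_id)) stop("duplicate scaffold ids")
  if (!all(scaffolds$chromosome_id %in% chromosomes$id)) {
    stop("scaffold refers to unknown chromosome")
  }
  # scaffold intervals on one chromosome must be disjoint and in range
  for (ch in unique(scaffolds$chromosome_id)) {
    s <- scaffolds[scaffolds$chromosome_id == ch, ]
    s <- s[order(s$start_bp), ]
    ends <- s$start_bp + s$length_bp
    L <- chromosomes$physical_length_bp[chromosomes$id == ch]
    if (any(s$start_bp < 0) || any(ends > L)) {
      stop("scaffold interval outside chromosome: ", ch)
    }
    if (nrow(s) > 1L && any(s$start_bp[-1L] < ends[-nrow(s)])) {
      stop("overlapping scaffolds on chromosome ", ch)
    }
  }
  if (is.null(inversions)) {
    inversions <- data.frame(chromosome_id = character(), start_bp = numeric(),
                             end_bp = numeric())
  }
  inversions$chromosome_id <- as.character(inversions$chromosome_id)
  if (nrow(inversions)) {
    if (!all(inversions$chromosome_id %in% chromosomes$id)) {
      stop("inversion refers to unknown chromosome")
    }
    L <- chromosomes$physical_length_bp[match(inversions$chromosome_id, chromosomes$id)]
    if (any(inversions$start_bp < 0) || any(inversions$end_bp > L) ||
        any(inversions$end_bp <= inversions$start_bp)) {
      stop("inversion interval outside its chromosome")
    }
  }
  structure(list(chromosomes = chromosomes, scaffolds = scaffolds,
                 inversions = inversions),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %d scaffolds (%d unanchored), %d inversions\n",
              nrow(x$chromosomes), nrow(x$scaffolds),
              sum(!x$scaffolds$anchored), nrow(x$inversions)))
  cat(sprintf("  total physical size %.1f Mb, total map length %.0f cM\n",
              sum(x$chromosomes$physical_length_bp) / 1e6,
              sum(x$chromosomes$genetic_length_cM)))
  invisible(x)
}

#' Simulate a genome layout
#'
#' Generates a layout emulating a draft plant genome build: a modest number
#' of chromosomes covered by scaffolds of heterogeneous size (log-normal,
#' capped), an optional fraction of scaffolds left unanchored, and large
#' recombination-suppressed intervals (inversions) on a subset of
#' chromosomes. Defaults follow a yellow monkeyflower-like genome scaled to
#' 14 chromosomes of ~125 cM and three 3-4 Mb inversions.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_cM Genetic length per chromosome (recycled).
#' @param chrom_bp Physical length per chromosome (recycled).
#' @param mean_scaffold_bp Mean scaffold size; sizes are log-normal with
#'   `sd_log` on the log scale, truncated to `[min_scaffold_bp, max_scaffold_bp]`.
#' @param sd_log Log-scale standard deviation of scaffold sizes.
#' @param min_scaffold_bp,max_scaffold_bp Scaffold size bounds (the reference
#'   build tops out at 4.9 Mb).
#' @param scaffold_coverage Fraction of each chromosome covered by
#'   scaffolds; the remainder forms inter-scaffold gaps (unassembled
#'   sequence), mirroring draft builds where much of the genome lies between
#'   mapped scaffolds.
#' @param unanchored_frac Fraction of scaffolds emitted without a chromosome
#'   assignment.
#' @param inversions data.frame (`chromosome_id`, `start_bp`, `end_bp`), or
#'   `NULL` for none, or `"default"` to place three 3-4 Mb inversions on
#'   chromosomes 5, 8 and 10 (wrapping if fewer chromosomes).
#' @param seed Integer seed (required).
#' @return A [genome_layout()].
#' @export
sim_layout <- function(n_chromosomes = 14,
                       chrom_cM = 125,
                       chrom_bp = 32e6,
                       mean_scaffold_bp = 1.2e6,
                       sd_log = 0.8,
                       min_scaffold_bp = 5e4,
                       max_scaffold_bp = 4.9e6,
                       scaffold_coverage = 0.8,
                       unanchored_frac = 0,
                       inversions = "default",
                       seed) {
  seed <- .assert_seed(seed)
  n_chromosomes <- .assert_count(n_chromosomes, "n_chromosomes")
  set.seed(seed)
  chrom_cM <- rep_len(chrom_cM, n_chromosomes)
  chrom_bp <- rep_len(chrom_bp, n_chromosomes)
  chromosomes <- data.frame(id = paste0("chr", seq_len(n_chromosomes)),
                            genetic_length_cM = chrom_cM,
                            physical_length_bp = chrom_bp)
  .assert_fraction(scaffold_coverage, "scaffold_coverage", lo = 1e-6, hi = 1)
  gap_mean <- mean_scaffold_bp * (1 - scaffold_coverage) / scaffold_coverage
  sc <- list()
  k <- 0L
  for (i in seq_len(n_chromosomes)) {
    pos <- 0
    L <- chrom_bp[i]
    while (pos < L) {
      len <- exp(rnorm(1, log(mean_scaffold_bp) - sd_log^2 / 2, sd_log))
      len <- min(max(len, min_scaffold_bp), max_scaffold_bp, L - pos)
      k <- k + 1L
      sc[[k]] <- data.frame(scaffold_id = sprintf("scaffold_%d", k),
                            chromosome_id = chromosomes$id[i],
                            start_bp = pos, length_bp = len)
      pos <- pos + len
      if (gap_mean > 0) pos <- pos + rexp(1, 1 / gap_mean)
    }
  }
  scaffolds <- do.call(rbind, sc)
  scaffolds$anchored <- TRUE
  if (unanchored_frac > 0) {
    n_un <- round(unanchored_frac * nrow(scaffolds))
    if (n_un > 0) {
      scaffolds$anchored[sample.int(nrow(scaffolds), n_un)] <- FALSE
    }
  }
  if (identical(inversions, "default")) {
    host <- c(5L, 8L, 10L)
    host <- ((host - 1L) %% n_chromosomes) + 1L
    size <- c(3.75e6, 2.95e6, 4.1e6)
    start <- pmax(0, pmin(chrom_bp[host] * c(0.7, 0.05, 0.45), chrom_bp[host] - size))
    inversions <- data.frame(chromosome_id = chromosomes$id[host],
                             start_bp = start, end_bp = start + size)
  }
  genome_layout(chromosomes, scaffolds, inversions)
}

#' Write / read a layout as BED-like TSV
#'
#' Scaffold rows are written as 0-based half-open intervals
#' (`chromosome_id`, `start_bp`, `end_bp`, `scaffold_id`, `anchored`);
#' chromosome sizes and inversions go to companion tables in the same file,
#' separated by section headers understood by [read_layout_tsv()].
#'
#' @param layout A [genome_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#section\tchromosomes", con)
  utils::write.table(layout$chromosomes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("#section\tscaffolds", con)
  sc <- layout$scaffolds
  bed <- data.frame(chromosome_id = ifelse(sc$anchored, sc$chromosome_id, "UNANCHORED"),
                    start_bp = sc$start_bp,
                    end_bp = sc$start_bp + sc$length_bp,
                    scaffold_id = sc$scaffold_id,
                    anchored = sc$anchored,
                    true_chromosome_id = sc$chromosome_id)
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("#section\tinversions", con)
  utils::write.table(layout$inversions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_tsv
#' @note Reading requires the truth-retaining layout written by
#'   [write_layout_tsv()]; `UNANCHORED` rows are only readable when the
#'   `anchored` column is present (truth retains the location).
#' @export
read_layout_tsv <- function(path) {
  lines <- readLines(path)
  sec <- grep("^#section\t", lines)
  names(sec) <- sub("^#section\t", "", lines[sec])
  read_sec <- function(name) {
    i <- sec[[name]]
    j <- c(sec, length(lines) + 1L)[which(names(sec) == name) + 1L] - 1L
    block <- lines[(i + 1L):j]
    utils::read.table(text = block, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  chromosomes <- read_sec("chromosomes")
  bed <- read_sec("scaffolds")
  inv <- read_sec("inversions")
  sc <- data.frame(scaffold_id = bed$scaffold_id,
                   chromosome_id = if (!is.null(bed$true_chromosome_id))
                     bed$true_chromosome_id else bed$chromosome_id,
                   start_bp = bed$start_bp,
                   length_bp = bed$end_bp - bed$start_bp,
                   anchored = bed$anchored)
  if (nrow(inv) == 0) inv <- NULL
  genome_layout(chromosomes, sc, inv)
}

#' Read a simulation configuration from YAML
#'
#' Convenience loader for simulation parameters. The file must provide an
#' explicit `seed`; all other entries are returned as-is for passing to
#' [sim_layout()], [simulate_pedigree()], [simulate_reads()] and
#' [simulate_phenotypes()].
#'
#' @param path Path to a YAML file.
#' @return Named list of parameters.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("simulation config must state an explicit `seed`")
  cfg
}
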