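# Internal helpers shared across modules.

# Genotype codes used throughout: integer matrices keep the marker x RIL
# substrate compact. 0 must stay MISSING so that `geno != 0` selects calls.
GENO_MISSING <- 0L
GENO_IM <- 1L
GENO_PR <- 2L
GENO_HET <- 3L

#' Genotype integer codes
#'
#' Genotype matrices in rilmap are integer matrices using a fixed coding:
#' 0 = MISSING, 1 = IM (Iron Mountain homozygote), 2 = PR (Point Reyes
#' homozygote), 3 = HET (IM/PR heterozygote).
#'
#' @return Named integer vector mapping labels to codes.
#' @examples
#' geno_codes()
#' @export
geno_codes <- function() {
  c(MISSING = GENO_MISSING, IM = GENO_IM, PR = GENO_PR, HET = GENO_HET)
}

#' Convert genotype codes to labels
#'
#' @param x Integer vector or matrix of genotype codes.
#' @return Character vector/matrix with labels "MISSING", "IM", "PR", "HET".
#' @export
geno_labels <- function(x) {
  lab <- c("MISSING", "IM", "PR", "HET")[as.integer(x) + 1L]
  if (is.matrix(x)) {
    lab <- matrix(lab, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  lab
}

.assert_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    stop("a single integer `seed` is required for reproducibility", call. = FALSE)
  }
  as.integer(seed)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a number in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  as.numeric(x)
}

# cheap stable tie-break ordering: order by primary, ties by id
.order_by <- function(primary, id, decreasing = FALSE) {
  order(if (decreasing) -primary else primary, id)
}
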