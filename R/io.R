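# Plain-text interchange: minimal VCF and TSV for SNP allele depths,
# genotype matrices, maps and phenotypes.

#' Write SNP allele depths as minimal VCF
#'
#' One line per SNP with `CHROM` = scaffold, 1-based `POS`, `REF` = IM-parent
#' base, `ALT` = alternative base, an `IM767` INFO tag carrying the IM767
#' call, and per-sample `AD` (IM reads, alt reads).
#'
#' @param snp_data A `snp_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snp_data, path) {
  stopifnot(inherits(snp_data, "snp_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=IM767,Number=1,Type=String,Description=\"IM767 parent call\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (IM base first)\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", snp_data$ril_ids), collapse = "\t"), con)
  s <- snp_data$snps
  ad <- matrix(paste(snp_data$im_reads, snp_data$alt_reads, sep = ","),
               nrow(s), length(snp_data$ril_ids))
  lines <- paste(s$scaffold_id, s$pos + 1L, ".", s$im_base, s$alt_base, ".",
                 "PASS", paste0("IM767=", s$im767_call), "AD",
                 apply(ad, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read SNP allele depths from a minimal VCF
#'
#' Expects per-sample `AD` fields with the IM-parent base as `REF` (as
#' written by [write_snp_vcf()]); the `IM767` INFO tag is honoured when
#' present. Uses the vcfR parser when installed, otherwise a plain-text
#' reader for the same layout.
#'
#' @param path VCF path (uncompressed).
#' @return A `snp_data` object.
#' @export
read_snp_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    ad <- vcfR::extract.gt(v, element = "AD")
    info <- fix[, "INFO"]
    im767 <- ifelse(grepl("IM767=AMBIGUOUS", info), "AMBIGUOUS", "IM")
    snps <- data.frame(scaffold_id = fix[, "CHROM"],
                       pos = as.numeric(fix[, "POS"]) - 1,
                       im_base = fix[, "REF"], alt_base = fix[, "ALT"],
                       im767_call = im767)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    cols <- strsplit(lines[hdr], "\t")[[1L]]
    body <- lines[-seq_len(hdr)]
    f <- strsplit(body, "\t")
    fix <- t(vapply(f, function(x) x[1:8], character(8)))
    ad <- t(vapply(f, function(x) x[-(1:9)], character(length(cols) - 9L)))
    colnames(ad) <- cols[-(1:9)]
    snps <- data.frame(scaffold_id = fix[, 1L],
                       pos = as.numeric(fix[, 2L]) - 1,
                       im_base = fix[, 4L], alt_base = fix[, 5L],
                       im767_call = ifelse(grepl("IM767=AMBIGUOUS", fix[, 8L]),
                                           "AMBIGUOUS", "IM"))
  }
  split2 <- function(i) {
    m <- matrix(as.integer(unlist(strsplit(ad, ","))), ncol = 2L, byrow = TRUE)
    matrix(m[, i], nrow(ad), ncol(ad), dimnames = dimnames(ad))
  }
  new_snp_data(snps, split2(1L), split2(2L), colnames(ad))
}

#' Write / read SNP allele depths as long TSV
#'
#' One row per (SNP, RIL) cell with nonzero depth; zero-depth cells are
#' implied MISSING. A `#rils` header line preserves the full sample list.
#'
#' @param snp_data A `snp_data` object.
#' @param path File path.
#' @return `path` (write) or a `snp_data` (read).
#' @export
write_snp_tsv <- function(snp_data, path) {
  stopifnot(inherits(snp_data, "snp_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#rils\t", paste(snp_data$ril_ids, collapse = ",")), con)
  nz <- which(snp_data$im_reads + snp_data$alt_reads > 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]   # stable SNP order
  s <- snp_data$snps[nz[, 1L], ]
  df <- data.frame(snp_index = nz[, 1L],
                   scaffold_id = s$scaffold_id, pos = s$pos,
                   im_base = s$im_base, alt_base = s$alt_base,
                   im767_call = s$im767_call,
                   ril_id = snp_data$ril_ids[nz[, 2L]],
                   im_reads = snp_data$im_reads[nz],
                   alt_reads = snp_data$alt_reads[nz])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_tsv
#' @export
read_snp_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  rils <- strsplit(sub("^#rils\t", "", first), ",")[[1L]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  df <- df[order(df$snp_index), ]
  uk <- !duplicated(df$snp_index)
  snps <- data.frame(scaffold_id = df$scaffold_id[uk], pos = df$pos[uk],
                     im_base = df$im_base[uk], alt_base = df$alt_base[uk],
                     im767_call = df$im767_call[uk])
  si <- match(df$snp_index, df$snp_index[uk])
  ri <- match(df$ril_id, rils)
  im <- alt <- matrix(0L, sum(uk), length(rils),
                      dimnames = list(NULL, rils))
  im[cbind(si, ri)] <- df$im_reads
  alt[cbind(si, ri)] <- df$alt_reads
  new_snp_data(snps, im, alt, rils)
}

#' Write a genotype matrix as wide and long TSV
#'
#' The wide layout mirrors a map-plus-genotypes table: header rows give the
#' linkage group and cM position (when a map is supplied) and the marker id
#' (`scaffold:window`), followed by one row per RIL with genotype labels.
#'
#' @param gm A `geno_matrix`.
#' @param path Output path for the wide table.
#' @param map Optional `genetic_map` to prepend group/position rows and order
#'   columns in map order.
#' @param long_path Optional path for a long-format table
#'   (`marker_id`, `ril_id`, `genotype`, `p`).
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(gm, path, map = NULL, long_path = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  idx <- seq_len(nrow(gm$markers))
  grp <- pos <- NULL
  if (!is.null(map)) {
    flat <- do.call(rbind, lapply(names(map$groups), function(g) {
      data.frame(marker_id = map$groups[[g]]$marker_id,
                 group = as.integer(g), pos_cM = map$groups[[g]]$pos_cM)
    }))
    idx <- match(flat$marker_id, gm$markers$marker_id)
    keep <- !is.na(idx)
    flat <- flat[keep, ]
    idx <- idx[keep]
    grp <- flat$group
    pos <- flat$pos_cM
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(grp)) {
    writeLines(paste(c("linkage_group", grp), collapse = "\t"), con)
    writeLines(paste(c("pos_cM", format(pos, trim = TRUE)), collapse = "\t"), con)
  }
  writeLines(paste(c("marker", gm$markers$marker_id[idx]), collapse = "\t"), con)
  lab <- geno_labels(gm$geno[idx, , drop = FALSE])
  for (r in seq_along(gm$ril_ids)) {
    writeLines(paste(c(gm$ril_ids[r], lab[, r]), collapse = "\t"), con)
  }
  if (!is.null(long_path)) {
    long <- data.frame(marker_id = rep(gm$markers$marker_id, ncol(gm$geno)),
                       ril_id = rep(gm$ril_ids, each = nrow(gm$geno)),
                       genotype = as.vector(geno_labels(gm$geno)),
                       p = if (!is.null(gm$p)) as.vector(gm$p) else NA)
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a genetic map as TSV
#'
#' One row per mapped marker: linkage group, cM position, marker id,
#' scaffold, fragment and window interval.
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  flat <- do.call(rbind, lapply(names(map$groups), function(g) {
    df <- map$groups[[g]]
    data.frame(group = as.integer(g), pos_cM = df$pos_cM,
               marker_id = df$marker_id, scaffold_id = df$scaffold_id,
               fragment_id = df$fragment_id, window_index = df$window_index,
               start_bp = df$start_bp, end_bp = df$end_bp)
  }))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Expects columns `ril_id`, `growup`, `method`, `replicate` and one column
#' per trait (raw concentrations, mg/g dry weight).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("ril_id", "growup", "method", "replicate")
  if (!all(need %in% names(df))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
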