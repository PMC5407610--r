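# File interfaces: phased VCF in/out for haplotype panels, population
# maps, archaic/outgroup allele tracks, and window tables as report TSV
# (1-based inclusive) or BED (0-based half-open).

#' Write a haplotype panel as phased VCF
#'
#' Minimal VCF 4.2 with phased GT fields; REF is the ancestral allele (A)
#' and ALT the derived allele (T) by convention, with the true ancestral
#' state recorded in the INFO AA tag.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param provenance optional named character vector written as
#'   `##<name>=<value>` header lines.
#' @export
write_panel_vcf <- function(panel, path, provenance = NULL) {
  inds <- unique(panel$individuals)
  hap_of <- split(seq_along(panel$individuals), panel$individuals)
  gt <- vapply(inds, function(id) {
    rows <- hap_of[[id]]
    a <- panel$alleles[rows, , drop = FALSE]
    g <- apply(a, 2, function(x)
      paste(ifelse(is.na(x), ".", x), collapse = "|"))
    g
  }, character(length(panel$positions)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=sweepintro-", utils::packageVersion("sweepintro")),
           if (!is.null(provenance))
             paste0("##", names(provenance), "=", provenance),
           paste0("##contig=<ID=", panel$chrom, ">"),
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", inds), collapse = "\t"))
  body <- paste(panel$chrom, format(panel$positions, scientific = FALSE,
                                    trim = TRUE),
                ".", "A", "T", ".", "PASS", "AA=A", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Biallelic phased records only; the derived allele is ALT unless an AA
#' INFO tag marks ALT as ancestral, in which case the site is flipped.
#'
#' @param path VCF path (plain or gzipped).
#' @param populations named character vector individual -> population, or
#'   path to a two-column (sample, population) TSV.
#' @export
read_panel_vcf <- function(path, populations) {
  if (is.character(populations) && length(populations) == 1 &&
      file.exists(populations)) {
    pm <- read.table(populations, header = FALSE, stringsAsFactors = FALSE)
    populations <- setNames(pm[[2]], pm[[1]])
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  biall <- !grepl(",", fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biall, , drop = FALSE]
  fix <- fix[biall, , drop = FALSE]
  inds <- colnames(gt)
  split_gt <- function(g) {
    out <- strsplit(g, "[|/]")
    vapply(out, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (length(x) == 1) x <- c(x, NA_integer_)
      x[seq_len(2)]
    }, integer(2))
  }
  allele_rows <- matrix(NA_integer_, 2 * length(inds), nrow(gt))
  for (j in seq_along(inds)) {
    sp <- split_gt(gt[, j])
    allele_rows[2 * j - 1, ] <- sp[1, ]
    allele_rows[2 * j, ] <- sp[2, ]
  }
  # polarity: flip sites whose AA tag equals ALT
  aa <- sub(".*AA=([^;]+).*", "\\1", fix[, "INFO"])
  flip <- !is.na(aa) & aa == fix[, "ALT"] & grepl("AA=", fix[, "INFO"])
  allele_rows[, flip] <- 1L - allele_rows[, flip]
  ord <- order(as.numeric(fix[, "POS"]))
  haplotype_panel(fix[1, "CHROM"], as.numeric(fix[ord, "POS"]),
                  allele_rows[, ord, drop = FALSE],
                  rep(inds, each = 2), populations)
}

#' Read an allele track (chrom, pos, allele) TSV
#'
#' Returns per-site alleles aligned with `positions`; absent positions are
#' NA.
#'
#' @param path tab-delimited file with columns chrom, pos, allele.
#' @param positions site positions to align to.
#' @export
read_allele_track <- function(path, positions) {
  tr <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- rep(NA_integer_, length(positions))
  m <- match(positions, tr[[2]])
  out[!is.na(m)] <- as.integer(tr[[3]][m[!is.na(m)]])
  out
}

#' Write an allele track TSV
#' @param chrom chromosome label.
#' @param positions site positions.
#' @param alleles 0/1/NA alleles.
#' @param path output path.
#' @export
write_allele_track <- function(chrom, positions, alleles, path) {
  write.table(data.frame(chrom, positions, alleles), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a window table
#'
#' `format = "tsv"` writes the reported 1-based inclusive coordinates with
#' all score columns; `format = "bed"` writes BED (0-based half-open,
#' first three columns plus an optional score).
#'
#' @param wtab window table.
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @param score column name used as the BED score.
#' @export
write_window_table <- function(wtab, path, format = c("tsv", "bed"),
                               score = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(wtab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = wtab$chrom, start = wtab$start - 1,
                      end = wtab$end)
    if (!is.null(score)) bed$score <- wtab[[score]]
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
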