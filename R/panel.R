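#' Construct a phased haplotype panel
#'
#' A panel holds the phased allele matrix over haplotypes x variants
#' (entries 0 = reference allele, 1 = alternate allele) together with the
#' variant table and population/panel labels. Two haplotype rows per
#' diploid sample.
#'
#' @param alleles Integer/numeric matrix of 0/1 with one row per haplotype
#'   and one column per variant.
#' @param variants Variant tibble as from [variant_table()]; one row per
#'   matrix column.
#' @param population_label Population name, e.g. "CEU".
#' @param panel_label Panel name, e.g. "1000G" or "HapMap3".
#' @return Object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, variants, population_label = "CEU",
                            panel_label = "panel") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != nrow(variants)) {
    stop("allele matrix has ", ncol(alleles), " columns but ",
         nrow(variants), " variants")
  }
  if (nrow(alleles) < 2) stop("a panel needs at least 2 haplotypes")
  if (!all(alleles %in% c(0L, 1L))) {
    stop("allele matrix entries must be 0 or 1 (biallelic, phased)")
  }
  validate_variants(variants)
  structure(
    list(alleles = alleles, variants = as_tibble(variants),
         population_label = population_label, panel_label = panel_label,
         monomorphic = apply(alleles, 2, function(x) length(unique(x)) == 1L)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes x ",
      ncol(x$alleles), " variants (", x$panel_label, "/",
      x$population_label, "); ", sum(x$monomorphic),
      " monomorphic\n", sep = "")
  invisible(x)
}

#' Number of haplotypes / variants in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer count.
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname n_haplotypes
#' @export
n_variants <- function(panel) ncol(panel$alleles)

#' Read a phased haplotype panel from a VCF file
#'
#' Consumes phased GT fields only. Biallelic SNP records with fully phased
#' genotypes become panel columns; multiallelic, unphased, or
#' missing-genotype records are skipped and counted (reported via a
#' message and the `n_skipped` attribute).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param region Optional list with `chrom` and optionally `start`, `end`
#'   (1-based, inclusive) restricting the records used.
#' @param population_label,panel_label Labels stored on the panel.
#' @return A [haplotype_panel()] with 2N haplotypes for N samples and an
#'   `n_skipped` attribute.
#' @export
read_vcf_panel <- function(path, region = NULL, population_label = "CEU",
                           panel_label = "panel") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (nrow(fix) == 0) stop("no records in VCF ", path)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    keep <- keep & fix$CHROM == region$chrom
    if (!is.null(region$start)) keep <- keep & as.integer(fix$POS) >= region$start
    if (!is.null(region$end)) keep <- keep & as.integer(fix$POS) <= region$end
  }
  # biallelic SNPs only
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  gt_fields <- sub(":.*", "", gt[, -1, drop = FALSE])
  phased <- apply(gt_fields, 1, function(g) all(grepl("^[01]\\|[01]$", g)))
  ok <- keep & biallelic & phased
  n_skipped <- sum(keep & !ok)
  if (n_skipped > 0) {
    message("read_vcf_panel: skipped ", n_skipped,
            " non-biallelic/unphased/missing record(s)")
  }
  if (!any(ok)) stop("no phased biallelic records in region of ", path)
  gt_ok <- gt_fields[ok, , drop = FALSE]
  # each sample contributes two haplotype rows
  left <- apply(gt_ok, c(1, 2), function(g) as.integer(substr(g, 1, 1)))
  right <- apply(gt_ok, c(1, 2), function(g) as.integer(substr(g, 3, 3)))
  n_samp <- ncol(gt_ok)
  alleles <- matrix(0L, nrow = 2L * n_samp, ncol = nrow(gt_ok))
  alleles[seq(1, 2 * n_samp, by = 2), ] <- t(left)
  alleles[seq(2, 2 * n_samp, by = 2), ] <- t(right)
  ids <- fix$ID[ok]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[ok], ":", fix$POS[ok])[
    is.na(ids) | ids == "."]
  variants <- tibble(
    rsid = ids, chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
    ref_allele = fix$REF[ok], alt_allele = fix$ALT[ok],
    locus_label = NA_character_, region_class = "unknown"
  )
  panel <- haplotype_panel(alleles, variants, population_label, panel_label)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 with one diploid sample per haplotype pair and
#' phased GT fields, so that [read_vcf_panel()] round-trips the allele
#' matrix exactly. Panels with an odd number of haplotypes are rejected.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  m <- panel$alleles
  if (nrow(m) %% 2 != 0) stop("VCF output needs an even number of haplotypes")
  n_samp <- nrow(m) / 2
  v <- panel$variants
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("SAMPLE", seq_len(n_samp))), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(m)), function(j) {
    gts <- paste0(m[seq(1, nrow(m), by = 2), j], "|",
                  m[seq(2, nrow(m), by = 2), j])
    paste(c(v$chrom[j], v$pos[j], v$rsid[j], v$ref_allele[j],
            v$alt_allele[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  ord <- order(v$chrom, v$pos)
  writeLines(c(header, body[ord]), path)
  invisible(path)
}
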