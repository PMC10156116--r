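#' Construct a SNP panel
#'
#' A SNP panel is the common currency of all analyses in hybridscan: a set
#' of biallelic sites with genomic coordinates, a dosage matrix (count of
#' alternate alleles per genotype), and a sample-to-population map.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt`.  Positions must be strictly increasing within a
#'   scaffold.
#' @param geno integer matrix, sites x samples, entries in `0..ploidy` or
#'   `NA` for missing genotypes.
#' @param pop_map named character vector mapping sample id -> population
#'   label; must cover every column of `geno`.
#' @param ploidy integer ploidy (default 2).
#' @return An object of class `snp_panel`.
#' @export
snp_panel <- function(sites, geno, pop_map, ploidy = 2L) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites))
  samples <- colnames(geno)
  if (is.null(samples)) stop("genotype matrix must have sample column names")
  missing_samples <- setdiff(samples, names(pop_map))
  if (length(missing_samples) > 0)
    stop("sample(s) absent from population map: ",
         paste(missing_samples, collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (any(bad < 0 | bad > ploidy))
    stop("dosages must lie in 0..ploidy")
  ord_ok <- tapply(sites$pos, sites$scaffold, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok)))
    stop("positions must be strictly increasing within each scaffold")
  structure(list(sites = sites, geno = geno, samples = samples,
                 pop_map = pop_map[samples], ploidy = as.integer(ploidy)),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (ploidy ", x$ploidy, ")\n", sep = "")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(x$pop_map)), table(x$pop_map)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Populations of a SNP panel or frequency table
#' @param x a `snp_panel` or `freq_table`
#' @return character vector of population labels
#' @export
populations <- function(x) {
  if (inherits(x, "snp_panel")) unique(unname(x$pop_map))
  else if (inherits(x, "freq_table")) colnames(x$freq)
  else stop("no populations for this object")
}

#' Read a SNP panel from a VCF file and a population map
#'
#' Consumes a minimal VCF dialect: CHROM, POS, REF, ALT and the GT subfield
#' of the genotype columns.  Phased (`|`) and unphased (`/`) separators are
#' treated identically; every other field is ignored.  Only biallelic SNP
#' records are retained, and sites whose fraction of missing genotypes
#' exceeds `max_missing_fraction` are dropped.  Counts of excluded records
#' are reported via [message()].
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param popmap_path path to a two-column whitespace-separated file
#'   (sample id, population label).
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   genotypes per site.  Use `0` for whole-genome-style panels (complete
#'   information only) and about `0.3` for reduced-representation panels.
#' @return A [snp_panel()].
#' @export
read_vcf <- function(path, popmap_path, max_missing_fraction = 0) {
  pm <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  unknown <- setdiff(samples, names(pm))
  if (length(unknown) > 0)
    stop("sample(s) present in VCF but absent from popmap: ",
         paste(unknown, collapse = ", "))
  n_meta <- length(v@meta) + 1L  # meta lines plus the #CHROM header line

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L & alt != "." & alt != ""
  n_drop_allelic <- sum(!biallelic)
  if (n_drop_allelic > 0)
    hs_log("dropped %d non-biallelic-SNP record(s)", n_drop_allelic)

  gt_field <- gt_raw[, -1, drop = FALSE]
  fmt <- gt_raw[, 1]
  # GT is required to be the first FORMAT subfield by the VCF standard
  gt <- sub(":.*$", "", gt_field)
  dos <- gt_dosage(gt)
  bad <- which(is.na(dos) & !is.na(gt) & gt != "./." & gt != ".|." & gt != ".")
  if (length(bad) > 0) {
    rec <- ((bad[1] - 1L) %% nrow(gt)) + 1L
    stop(sprintf("malformed genotype field '%s' at line %d of %s",
                 gt[bad[1]], n_meta + rec, path))
  }

  keep <- biallelic
  dos <- dos[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  miss_frac <- rowMeans(is.na(dos))
  keep2 <- miss_frac <= max_missing_fraction + 1e-12
  if (any(!keep2))
    hs_log("dropped %d site(s) exceeding missing fraction %.2f",
           sum(!keep2), max_missing_fraction)
  dos <- dos[keep2, , drop = FALSE]
  fix <- fix[keep2, , drop = FALSE]

  sites <- data.frame(scaffold = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  colnames(dos) <- samples
  snp_panel(sites, dos, pm)
}

# GT string -> diploid alternate-allele dosage (NA for missing);
# returns NA for anything that is not a 0/1 diploid genotype
gt_dosage <- function(gt) {
  lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
           "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L,
           "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
  out <- lut[gt]
  dim(out) <- dim(gt)
  out
}

#' Read a two-column population map
#' @param path whitespace-separated file: sample id, population label.
#' @return named character vector (sample -> population)
#' @export
read_popmap <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("popmap must have two columns: sample, population")
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write a SNP panel as a minimal VCF plus popmap
#'
#' Writes the subset of VCF that [read_vcf()] consumes, so that a
#' write-then-read round trip reproduces dosages, coordinates and the
#' population map exactly.
#'
#' @param panel a [snp_panel()]
#' @param path output VCF path
#' @param popmap_path optional output path for the popmap
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, popmap_path = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  gt <- matrix("./.", nrow = nrow(panel$geno), ncol = ncol(panel$geno))
  gt[panel$geno == 0L] <- "0/0"
  gt[panel$geno == 1L] <- "0/1"
  gt[panel$geno == 2L] <- "1/1"
  body <- cbind(panel$sites$scaffold, panel$sites$pos, ".",
                panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hybridscan",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", panel$samples),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  if (!is.null(popmap_path))
    write.table(data.frame(names(panel$pop_map), unname(panel$pop_map)),
                popmap_path, quote = FALSE, row.names = FALSE,
                col.names = FALSE, sep = "\t")
  invisible(path)
}

# internal constructor for per-population frequency tables
new_freq_table <- function(sites, freq, count, polarized, derived_is_alt) {
  structure(list(sites = sites, freq = freq, count = count,
                 polarized = polarized, derived_is_alt = derived_is_alt),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("<freq_table> ", nrow(x$freq), " sites x ", ncol(x$freq),
      " populations", if (x$polarized) " (polarized)", "\n", sep = "")
  invisible(x)
}

#' Per-population alternate-allele frequencies
#'
#' Computes, for every site and population, the alternate-allele frequency
#' `dosage sum / (ploidy x non-missing samples)`.  Frequencies are
#' unpolarized; f3/f4 and FST are invariant to the choice of reference
#' allele, so this table can feed them directly.
#'
#' @param panel a [snp_panel()]
#' @return A `freq_table` with matrices `freq` and `count` (alleles used),
#'   sites x populations.  Cells with no non-missing genotypes are `NA`.
#' @export
compute_freqs <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  pops <- populations(panel)
  ns <- nrow(panel$sites)
  freq <- matrix(NA_real_, ns, length(pops), dimnames = list(NULL, pops))
  count <- matrix(0L, ns, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- which(panel$pop_map == p)
    g <- panel$geno[, cols, drop = FALSE]
    nm <- rowSums(!is.na(g))
    cnt <- panel$ploidy * nm
    s <- rowSums(g, na.rm = TRUE)
    freq[, p] <- ifelse(cnt > 0, s / cnt, NA_real_)
    count[, p] <- cnt
  }
  new_freq_table(panel$sites, freq, count, polarized = FALSE,
                 derived_is_alt = NULL)
}

#' Polarize allele frequencies against an outgroup
#'
#' Sites where the outgroup population is missing or polymorphic are
#' dropped (the ancestral state is undefined there).  At retained sites the
#' derived allele is the one absent from the outgroup, and all frequencies
#' are expressed as derived-allele frequencies; the outgroup column is kept
#' (always 0 by construction) so that D-statistic pattern products can use
#' it directly.
#'
#' @param panel a [snp_panel()]
#' @param outgroup population label of the outgroup
#' @return A polarized `freq_table`.
#' @export
polarize_by_outgroup <- function(panel, outgroup) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!outgroup %in% populations(panel))
    stop("unknown outgroup population: ", outgroup)
  ft <- compute_freqs(panel)
  of <- ft$freq[, outgroup]
  keep <- !is.na(of) & (of == 0 | of == 1)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    hs_log("dropped %d site(s) with missing or polymorphic outgroup", n_drop)
  derived_is_alt <- of[keep] == 0
  freq <- ft$freq[keep, , drop = FALSE]
  flip <- !derived_is_alt
  freq[flip, ] <- 1 - freq[flip, ]
  new_freq_table(ft$sites[keep, , drop = FALSE], freq,
                 ft$count[keep, , drop = FALSE],
                 polarized = TRUE, derived_is_alt = derived_is_alt)
}

#' Partition sites into equal-size jackknife blocks
#'
#' Blocks are contiguous runs of `block_size` sites in genome order;
#' trailing remainder sites are excluded.  Blocks defined by SNP count (not
#' physical length) match the usage of genome-wide f-statistic scans where
#' e.g. 13,316,418 SNPs at 10,000 SNPs per block give 1331 blocks.
#'
#' @param n_sites number of sites
#' @param block_size sites per block (default 10000)
#' @return A `block_index`: list with `starts`, `ends` (inclusive site
#'   indices) and `block_size`.
#' @export
partition_blocks <- function(n_sites, block_size = 10000L) {
  if (block_size <= 0) stop("block_size must be >= 1")
  n_blocks <- floor(n_sites / block_size)
  if (n_blocks == 0)
    warning("fewer sites than block_size: no complete blocks")
  starts <- (seq_len(n_blocks) - 1L) * block_size + 1L
  structure(list(starts = as.integer(starts),
                 ends = as.integer(starts + block_size - 1L),
                 block_size = as.integer(block_size),
                 n_blocks = as.integer(n_blocks)),
            class = "block_index")
}

#' @export
print.block_index <- function(x, ...) {
  cat("<block_index> ", x$n_blocks, " blocks of ", x$block_size,
      " sites\n", sep = "")
  invisible(x)
}

#' Write a frequency table as TSV
#' @param freqs a `freq_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_freq_table <- function(freqs, path) {
  out <- data.frame(scaffold = freqs$sites$scaffold, position = freqs$sites$pos,
                    freqs$freq, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
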