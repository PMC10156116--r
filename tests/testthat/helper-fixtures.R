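# shared fixtures, all built in code

# a small VCF + popmap written to a temp dir; returns the two paths
write_toy_vcf <- function(records, samples = c("s1", "s2", "s3"),
                          pops = c("A", "A", "B")) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  vcf <- file.path(dir, "toy.vcf")
  pm <- file.path(dir, "toy.popmap")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), vcf)
  writeLines(paste(samples, pops, sep = "\t"), pm)
  list(vcf = vcf, popmap = pm)
}

# panel with explicit dosages: geno is a sites x samples matrix
make_panel <- function(geno, pops, positions = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  if (is.null(positions)) positions <- seq_len(nrow(geno)) * 100L
  snp_panel(
    sites = data.frame(scaffold = "sc1", pos = positions,
                       ref = "A", alt = "T"),
    geno = geno,
    pop_map = stats::setNames(pops, colnames(geno)))
}

# a two-population split scenario (times in generations)
two_pop_scenario <- function(t_split, ne = 10000, n_diploid = 2) {
  demographic_scenario(
    populations = data.frame(name = c("P1", "P2"),
                             n_diploid = n_diploid, ne = ne),
    splits = data.frame(time = t_split, derived = "P2",
                        ancestral = "P1"))
}

# a strictly bifurcating four-population scenario with no admixture:
# (((P1,P2),P3),P4)
four_pop_scenario <- function(t1 = 5000, t2 = 20000, t3 = 60000,
                              ne = 10000, n_diploid = 2) {
  demographic_scenario(
    populations = data.frame(name = paste0("P", 1:4),
                             n_diploid = n_diploid, ne = ne),
    splits = data.frame(time = c(t1, t2, t3),
                        derived = c("P2", "P3", "P4"),
                        ancestral = c("P1", "P1", "P1")))
}

# random ingroup frequency table for algebraic property checks
random_freq_table <- function(n_sites, pops, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n_sites * length(pops)), n_sites, length(pops),
              dimnames = list(NULL, pops))
  freq_table(f)
}
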