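#' Allele-balance histogram at heterozygous sites
#'
#' Bins the alternate-allele read fraction `alt / (ref + alt)` of sites
#' whose total coverage lies within `[min_cov, max_cov]`.  The expected
#' internal modes of the histogram sit at `k/p` for ploidy `p` (0.5 for a
#' diploid; 0.33 and 0.66 for a triploid; 0.25, 0.5, 0.75 for a
#' tetraploid), which makes the histogram a ploidy diagnostic.
#'
#' @param counts a `site_read_counts` data.frame (columns `ref`, `alt`)
#' @param min_cov,max_cov inclusive coverage bounds (defaults 10 and 100)
#' @param bin_width histogram bin width in `(0, 0.5]` (default 0.02)
#' @return An `ab_histogram`: list with `breaks`, `mids`, `mass`
#'   (normalized), `n_sites`, `cov_bounds`.
#' @export
allele_balance_histogram <- function(counts, min_cov = 10, max_cov = 100,
                                     bin_width = 0.02) {
  stopifnot(min_cov <= max_cov, bin_width > 0, bin_width <= 0.5)
  cov <- counts$ref + counts$alt
  keep <- cov >= min_cov & cov <= max_cov
  if (!any(keep)) stop("no sites pass the coverage filter")
  x <- counts$alt[keep] / cov[keep]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(breaks = breaks, mids = h$mids,
                 mass = h$counts / sum(h$counts),
                 n_sites = sum(keep), cov_bounds = c(min_cov, max_cov)),
            class = "ab_histogram")
}

#' @export
print.ab_histogram <- function(x, ...) {
  cat("<ab_histogram> ", x$n_sites, " sites, ", length(x$mids),
      " bins, coverage ", x$cov_bounds[1], "-", x$cov_bounds[2], "\n",
      sep = "")
  invisible(x)
}

# local modes of the kernel-smoothed allele-balance density above a
# height threshold (relative to the uniform density of 1), restricted to
# the open interval (0.1, 0.9); modes closer than `min_sep` are merged.
# Kernel smoothing of the binned mass is needed because read-count
# lattices (alt/coverage takes few distinct values) make the raw
# histogram saw-toothed, and because at moderate coverage a tetraploid's
# modes are broad and low.
detect_peaks <- function(hist, height_factor = 1.3, min_sep = 0.08) {
  de <- stats::density(hist$mids, weights = hist$mass,
                       bw = max(0.02, hist$breaks[2] - hist$breaks[1]),
                       from = 0, to = 1, n = 512)
  y <- de$y
  n <- length(y)
  win <- 15L  # ~0.06 on the allele-fraction axis
  peaks <- numeric(0)
  for (i in seq_len(n)) {
    lo <- max(1, i - win); hi <- min(n, i + win)
    if (y[i] >= max(y[lo:hi]) && y[i] > height_factor &&
        de$x[i] > 0.1 && de$x[i] < 0.9)
      peaks <- c(peaks, de$x[i])
  }
  if (length(peaks) > 1) {
    grp <- cumsum(c(1, diff(peaks) > min_sep))
    peaks <- as.numeric(tapply(peaks, grp, mean))
  }
  peaks
}

#' Classify ploidy from an allele-balance histogram
#'
#' Kernel-smooths the binned allele-balance mass, detects internal modes
#' above 1.3 times the uniform-density level, and scores each candidate
#' ploidy `p` by the summed distance of the expected internal peak set
#' `{k/p : 0 < k < p}` to the nearest detected peak.  The minimizer is
#' called; the call is `undetermined` when the best score exceeds the
#' tolerance or the detected peak count does not match the called ploidy.
#'
#' @param hist an `ab_histogram`
#' @param candidates candidate ploidies (default 2:4)
#' @param tolerance maximum summed peak distance for a call (default 0.08)
#' @return A `ploidy_call`: list with `ploidy` (integer or `NA` for
#'   undetermined), `scores` per candidate, and detected `peaks`.
#' @export
classify_ploidy <- function(hist, candidates = 2:4, tolerance = 0.08) {
  stopifnot(inherits(hist, "ab_histogram"))
  peaks <- detect_peaks(hist)
  scores <- vapply(candidates, function(p) {
    expected <- (1:(p - 1)) / p
    if (length(peaks) == 0) return(Inf)
    sum(vapply(peaks, function(pk) min(abs(pk - expected)), numeric(1)))
  }, numeric(1))
  names(scores) <- paste0("ploidy_", candidates)
  best <- candidates[which.min(scores)]
  undet <- length(peaks) == 0 || min(scores) > tolerance ||
    length(peaks) != best - 1
  structure(list(ploidy = if (undet) NA_integer_ else as.integer(best),
                 scores = scores, peaks = peaks,
                 tolerance = tolerance),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("<ploidy_call> ",
      if (is.na(x$ploidy)) "undetermined" else paste0("ploidy ", x$ploidy),
      "; peaks at ", paste(sprintf("%.2f", x$peaks), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Screen scaffolds for aneuploidy via coverage deviation
#'
#' Selects the `top_n` largest scaffolds, computes the length-weighted
#' genome mean coverage over them, and reports each scaffold's percent
#' deviation `100 * (scaffold - genome) / genome`; scaffolds whose
#' absolute deviation exceeds the threshold are flagged as candidate
#' aneuploidies.
#'
#' @param cov_table data.frame with columns `scaffold`, `length`,
#'   `coverage` (mean depth)
#' @param top_n number of largest scaffolds to use (default 100)
#' @param flag_threshold_pct absolute percent deviation that triggers a
#'   flag (default 25)
#' @return An `aneuploidy_report` data.frame: scaffold, length, coverage,
#'   `deviation_pct`, `flag`; `attr(, "genome_mean")`.
#' @export
scaffold_coverage_deviation <- function(cov_table, top_n = 100,
                                        flag_threshold_pct = 25) {
  stopifnot(all(c("scaffold", "length", "coverage") %in% names(cov_table)))
  if (top_n > nrow(cov_table))
    stop("top_n exceeds the number of scaffolds")
  ord <- order(cov_table$length, decreasing = TRUE)
  sel <- cov_table[ord[seq_len(top_n)], ]
  gm <- weighted.mean(sel$coverage, sel$length)
  if (gm == 0) stop("zero genome mean coverage")
  dev <- 100 * (sel$coverage - gm) / gm
  out <- data.frame(scaffold = sel$scaffold, length = sel$length,
                    coverage = sel$coverage, deviation_pct = dev,
                    flag = abs(dev) > flag_threshold_pct)
  attr(out, "genome_mean") <- gm
  class(out) <- c("aneuploidy_report", "data.frame")
  out
}
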