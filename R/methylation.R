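# Per-CpG methylation frequency, change classification between two
# conditions, family aggregation and dip-region detection.

#' Per-site methylation frequency
#'
#' The frequency of a CpG site is the percentage of reads where the site is
#' called methylated among reads with any valid call (methylated or
#' unmethylated); reads with no call do not enter the denominator.
#'
#' @param n_meth reads called methylated.
#' @param n_valid reads with any valid call.
#' @return Percentage in `[0, 100]`; `NA` when `n_valid` is 0.
#' @export
site_frequency <- function(n_meth, n_valid) {
  if (any(n_valid < 0)) stop("n_valid must be >= 0")
  if (any(n_meth > n_valid)) stop("n_meth cannot exceed n_valid")
  if (any(n_meth < 0)) stop("n_meth must be >= 0")
  ifelse(n_valid > 0, 100 * n_meth / n_valid, NA_real_)
}

#' Read a per-site methylation call table
#'
#' Tab-separated with header columns `chrom`, `pos` (0-based), `n_valid`,
#' `n_meth`. A `freq` column (percent) is added.
#'
#' @param path TSV file.
#' @return data.frame of class `meth_sites`.
#' @export
read_meth_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "n_valid", "n_meth")
  if (!all(req %in% names(df)))
    stop("methylation table must have header columns: ", paste(req, collapse = ", "))
  meth_sites(df$chrom, df$pos, df$n_valid, df$n_meth)
}

#' Construct a per-site methylation table
#'
#' @param chrom,pos site coordinates (`pos` 0-based).
#' @param n_valid,n_meth call counts, `0 <= n_meth <= n_valid`.
#' @return data.frame of class `meth_sites` with added `freq` (percent).
#' @export
meth_sites <- function(chrom, pos, n_valid, n_meth) {
  freq <- site_frequency(n_meth, n_valid)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   n_valid = as.numeric(n_valid), n_meth = as.numeric(n_meth),
                   freq = freq, stringsAsFactors = FALSE)
  class(df) <- c("meth_sites", "data.frame")
  df
}

#' Write a methylation table as TSV
#' @param sites `meth_sites` data.frame.
#' @param path output file.
#' @export
write_meth_table <- function(sites, path) {
  write.table(sites[, c("chrom", "pos", "n_valid", "n_meth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify per-CpG methylation changes between two conditions
#'
#' Sites are joined on `(chrom, pos)`; only sites called in both samples are
#' considered. A joined site is `excluded` when its WT frequency is not
#' strictly above `min_wt_freq` or its coverage is not strictly above
#' `min_cov` in both samples. Otherwise, with `delta_` the KO-minus-WT
#' frequency difference in percentage points: `increased` when
#' `delta_ > delta`, `decreased` when `delta_ < -delta`, else `unchanged`
#' (boundary values are unchanged — all thresholds are strict, as in the
#' conventional donut-chart rule: WT frequency > 40%, coverage > 10,
#' difference beyond +/-10 points).
#'
#' @param wt,ko `meth_sites` tables (wild-type / reference first).
#' @param min_wt_freq WT-frequency inclusion floor in percent (strict).
#' @param min_cov coverage floor for both samples (strict).
#' @param delta unchanged band half-width in percentage points.
#' @return List of class `meth_change`: `sites` (joined table with
#'   `wt_freq`, `ko_freq`, `delta`, `class`), `summary` (counts and the
#'   proportions of increased/decreased/unchanged among non-excluded
#'   sites), `n_joined`.
#' @export
classify_changes <- function(wt, ko, min_wt_freq = 40, min_cov = 10, delta = 10) {
  key_wt <- paste(wt$chrom, wt$pos)
  key_ko <- paste(ko$chrom, ko$pos)
  m <- match(key_wt, key_ko)
  keep <- !is.na(m) & wt$n_valid > 0 & ko$n_valid[m] > 0
  j <- data.frame(chrom = wt$chrom[keep], pos = wt$pos[keep],
                  wt_valid = wt$n_valid[keep], ko_valid = ko$n_valid[m[keep]],
                  wt_freq = wt$freq[keep], ko_freq = ko$freq[m[keep]],
                  stringsAsFactors = FALSE)
  j$delta <- j$ko_freq - j$wt_freq
  excluded <- !(j$wt_freq > min_wt_freq & j$wt_valid > min_cov & j$ko_valid > min_cov)
  cls <- ifelse(excluded, "excluded",
                ifelse(j$delta > delta, "increased",
                       ifelse(j$delta < -delta, "decreased", "unchanged")))
  j$class <- factor(cls, levels = c("increased", "decreased", "unchanged", "excluded"))
  counts <- table(j$class)
  nonexc <- sum(counts[c("increased", "decreased", "unchanged")])
  props <- if (nonexc > 0)
    as.numeric(counts[c("increased", "decreased", "unchanged")]) / nonexc
  else rep(NA_real_, 3)
  summary <- data.frame(
    class = c("increased", "decreased", "unchanged", "excluded"),
    count = as.integer(counts[c("increased", "decreased", "unchanged", "excluded")]),
    proportion = c(props, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(sites = j, summary = summary, n_joined = nrow(j)),
            class = "meth_change")
}

#' @export
print.meth_change <- function(x, ...) {
  cat(sprintf("<meth_change> %d joined sites\n", x$n_joined))
  print(x$summary)
  invisible(x)
}

#' Mean methylation frequency per repeat family
#'
#' Sites are assigned to families by position lookup in the labeled region
#' set; sites outside every labeled region are reported under `"other"`.
#' Means are unweighted over sites; rows ordered with `"overall"` first.
#'
#' @param sites `meth_sites` table (sites with `n_valid` 0 are dropped).
#' @param regions `GRanges` with `label` column.
#' @return data.frame: `family`, `n_sites`, `mean_freq`.
#' @export
aggregate_by_family <- function(sites, regions) {
  sites <- sites[sites$n_valid > 0, , drop = FALSE]
  fam <- site_family(sites, regions)
  keep_levels <- unique(fam)
  out <- data.frame(
    family = c("overall", keep_levels),
    n_sites = c(nrow(sites), vapply(keep_levels, function(f) sum(fam == f), 0L)),
    mean_freq = c(mean(sites$freq),
                  vapply(keep_levels, function(f) mean(sites$freq[fam == f]), 0)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

site_family <- function(sites, regions) {
  if (!nrow(sites)) return(character())
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos + 1, width = 1))
  fam <- rep("other", nrow(sites))
  if (length(regions)) {
    hits <- GenomicRanges::findOverlaps(q, regions, select = "first")
    ok <- !is.na(hits)
    fam[ok] <- regions$label[hits[ok]]
  }
  fam
}

#' Detect locally hypomethylated dip regions in a frequency track
#'
#' Slides windows of `window_bp` (stepped by a quarter window) over one
#' array's per-site frequency track, flags windows whose mean frequency is
#' below `low_threshold`, merges consecutive low windows into candidate
#' dips, and keeps dips at least `min_len_bp` long whose nearest informative
#' flanking windows on both sides are at or above the threshold (so a
#' uniformly low array yields no dips). Windows without sites are
#' uninformative and ignored.
#'
#' @param positions site positions (bp, 0-based) on one array.
#' @param freqs site methylation frequencies (percent).
#' @param window_bp sliding window width in bp.
#' @param low_threshold mean-frequency threshold in percent.
#' @param min_len_bp minimum dip length in bp.
#' @return data.frame: `start`, `end` (bp, 0-based half-open), `mean_freq`.
#' @export
find_dip_regions <- function(positions, freqs, window_bp = 10000,
                             low_threshold = 50, min_len_bp = 20000) {
  stopifnot(length(positions) == length(freqs), window_bp > 0)
  if (!length(positions))
    return(data.frame(start = numeric(), end = numeric(), mean_freq = numeric()))
  ord <- order(positions)
  positions <- positions[ord]; freqs <- freqs[ord]
  step <- max(1, window_bp / 4)
  starts <- seq(min(positions), max(positions), by = step)
  wmean <- vapply(starts, function(s) {
    inw <- positions >= s & positions < s + window_bp
    if (!any(inw)) NA_real_ else mean(freqs[inw])
  }, 0)
  informative <- which(!is.na(wmean))
  if (!length(informative))
    return(data.frame(start = numeric(), end = numeric(), mean_freq = numeric()))
  low <- wmean < low_threshold
  out <- list()
  i <- 1
  while (i <= length(informative)) {
    wi <- informative[i]
    if (!low[wi]) { i <- i + 1; next }
    j <- i
    while (j < length(informative) && low[informative[j + 1]]) j <- j + 1
    wi_last <- informative[j]
    d_start <- starts[wi]; d_end <- starts[wi_last] + window_bp
    flank_lo <- if (i > 1) !low[informative[i - 1]] else FALSE
    flank_hi <- if (j < length(informative)) !low[informative[j + 1]] else FALSE
    if (d_end - d_start >= min_len_bp && flank_lo && flank_hi) {
      ins <- positions >= d_start & positions < d_end
      out[[length(out) + 1L]] <- data.frame(start = d_start, end = d_end,
                                            mean_freq = mean(freqs[ins]))
    }
    i <- j + 1
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(), mean_freq = numeric()))
  do.call(rbind, out)
}
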