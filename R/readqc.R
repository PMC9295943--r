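# Sequencing-based enrichment quantification: k-mer read classification,
# binned log2 enrichment profiles, enrichment domains, uncut sites,
# length-proxy comparison and coverage threshold tables.

#' Build a canonical k-mer set
#'
#' K-mers are canonicalized to the lexicographic minimum of the k-mer and
#' its reverse complement, so read orientation never matters. Can be built
#' from an explicit k-mer vector, a plain-text file (one k-mer per line,
#' e.g. a published satellite 18-mer list), or de novo from monomer
#' sequences (all overlapping windows of the doubled monomer, covering the
#' tandem junction).
#'
#' @param kmers character vector of ACGT k-mers, or `NULL`.
#' @param path optional text file with one k-mer per line.
#' @param monomers optional `DNAStringSet`/character of monomer sequences
#'   to derive k-mers from.
#' @param k k-mer length (default 18, the alpha-satellite convention).
#' @return Object of class `kmer_set`: list with `k` and sorted canonical
#'   `kmers`.
#' @export
kmer_set <- function(kmers = NULL, path = NULL, monomers = NULL, k = 18) {
  if (!is.null(path)) {
    kmers <- c(kmers, toupper(trimws(readLines(path))))
    kmers <- kmers[nzchar(kmers)]
  }
  if (!is.null(monomers)) {
    monomers <- as.character(monomers)
    for (m in monomers) {
      mm <- toupper(paste0(m, m))  # doubled: windows across the junction
      if (nchar(m) < k) stop("monomer shorter than k")
      kmers <- c(kmers, substring(mm, 1:nchar(m), k:(nchar(m) + k - 1)))
    }
  }
  if (is.null(kmers) || !length(kmers)) stop("no k-mers supplied")
  kmers <- toupper(kmers)
  if (any(nchar(kmers) != k)) stop("all k-mers must have length k = ", k)
  if (any(grepl("[^ACGT]", kmers))) stop("k-mers must be ACGT only")
  structure(list(k = as.integer(k), kmers = sort(unique(canonical_kmer(kmers)))),
            class = "kmer_set")
}

canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Count reads positive for a satellite k-mer set
#'
#' A read is positive when at least `min_hits` of its k-mer windows
#' (canonicalized) belong to the set; a repeated matching k-mer counts once
#' per window unless `distinct = TRUE`, which requires `min_hits` distinct
#' set members. Windows containing `N` never match; reads shorter than `k`
#' are counted in the total but can never be positive.
#'
#' @param reads `DNAStringSet`, or path to FASTA/FASTQ(.gz).
#' @param kmerset a [kmer_set()].
#' @param min_hits minimum matching windows (default 2, the alpha-satellite
#'   read-classification rule).
#' @param distinct require distinct set k-mers rather than windows.
#' @return List with `n_positive`, `n_total`, `fraction`.
#' @export
count_kmer_positive_reads <- function(reads, kmerset, min_hits = 2, distinct = FALSE) {
  stopifnot(inherits(kmerset, "kmer_set"), min_hits >= 1)
  reads <- as_reads(reads)
  k <- kmerset$k
  # membership set contains both orientations so windows need no revcomp
  members <- unique(c(kmerset$kmers,
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAStringSet(kmerset$kmers)))))
  lookup <- new.env(hash = TRUE, parent = emptyenv(), size = length(members) * 2L)
  for (m in members) assign(m, TRUE, envir = lookup)
  seqs <- toupper(as.character(reads))
  n_positive <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    win <- substring(s, 1:(L - k + 1L), k:L)
    hit <- vapply(win, function(w) exists(w, envir = lookup, inherits = FALSE),
                  TRUE, USE.NAMES = FALSE)
    nh <- if (distinct) length(unique(canonical_kmer(win[hit]))) else sum(hit)
    if (nh >= min_hits) n_positive <- n_positive + 1L
  }
  n_total <- length(seqs)
  list(n_positive = n_positive, n_total = n_total,
       fraction = if (n_total > 0) n_positive / n_total else NA_real_)
}

as_reads <- function(reads) {
  if (is(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    return(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  if (is.character(reads)) return(Biostrings::DNAStringSet(toupper(reads)))
  stop("cannot interpret 'reads'")
}

#' Read binned counts from bedGraph or 3-column TSV
#'
#' Accepts `chrom, bin_start, count` (TSV) or `chrom, start, end, value`
#' (bedGraph). Bin starts must be multiples of `bin_width`.
#'
#' @param path input file.
#' @param bin_width bin width in bp (default 2000).
#' @return data.frame of class `binned_counts`: `chrom`, `bin_start`,
#'   `count`; attribute `bin_width`.
#' @export
read_binned_counts <- function(path, bin_width = 2000) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) == 4L) df <- df[, c(1, 2, 4)]
  if (ncol(df) != 3L) stop("expected 3 (TSV) or 4 (bedGraph) columns")
  names(df) <- c("chrom", "bin_start", "count")
  binned_counts(df$chrom, df$bin_start, df$count, bin_width)
}

#' Construct binned counts
#'
#' @param chrom,bin_start,count vectors; `bin_start` must be multiples of
#'   `bin_width` and counts non-negative.
#' @param bin_width bin width in bp.
#' @return data.frame of class `binned_counts`.
#' @export
binned_counts <- function(chrom, bin_start, count, bin_width = 2000) {
  stopifnot(all(count >= 0), all(bin_start %% bin_width == 0))
  df <- data.frame(chrom = as.character(chrom), bin_start = as.numeric(bin_start),
                   count = as.numeric(count), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$bin_start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "bin_width") <- bin_width
  class(df) <- c("binned_counts", "data.frame")
  df
}

#' Per-bin log2 enrichment profile of a sample over a reference
#'
#' Both samples are scaled to a common total count (the mean of the two
#' totals), then `log2((s_i + p) / (r_i + p))` is computed on the scaled
#' counts with pseudocount `p`. Bins present in only one input are treated
#' as zero in the other; bins that are zero in both get log2 ratio 0 (the
#' pseudocount cancels).
#'
#' @param sample,reference `binned_counts` with equal `bin_width`.
#' @param pseudocount positive pseudocount on the scaled-count scale.
#' @return data.frame of class `enrichment_profile`: `chrom`, `bin_start`,
#'   `log2_ratio`, `fold`; attribute `bin_width`.
#' @export
binned_log2_profile <- function(sample, reference, pseudocount = 1) {
  stopifnot(inherits(sample, "binned_counts"), inherits(reference, "binned_counts"),
            pseudocount > 0)
  bw_s <- attr(sample, "bin_width"); bw_r <- attr(reference, "bin_width")
  if (!identical(bw_s, bw_r)) stop("bin_width mismatch: ", bw_s, " vs ", bw_r)
  key_s <- paste(sample$chrom, sample$bin_start)
  key_r <- paste(reference$chrom, reference$bin_start)
  keys <- union(key_s, key_r)
  s <- setNames(rep(0, length(keys)), keys); s[key_s] <- sample$count
  r <- setNames(rep(0, length(keys)), keys); r[key_r] <- reference$count
  tot_s <- sum(s); tot_r <- sum(r)
  target_total <- (tot_s + tot_r) / 2
  s_sc <- if (tot_s > 0) s * target_total / tot_s else s
  r_sc <- if (tot_r > 0) r * target_total / tot_r else r
  lr <- log2((s_sc + pseudocount) / (r_sc + pseudocount))
  parts <- strsplit(keys, " ", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                    bin_start = as.numeric(vapply(parts, `[[`, "", 2L)),
                    log2_ratio = unname(lr),
                    fold = unname(2^lr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bw_s
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Call enrichment domains from a binned profile
#'
#' Domains are maximal runs of bins whose fold enrichment exceeds
#' `min_fold` (strictly), optionally bridging gaps of up to `max_gap_bins`
#' sub-threshold or missing bins; runs of fewer than `min_bins`
#' above-threshold bins are dropped.
#'
#' @param profile an `enrichment_profile` (or any data.frame with `chrom`,
#'   `bin_start`, `fold` and a `bin_width` attribute).
#' @param min_fold fold threshold (default 5: a bin belongs to a domain
#'   when its fold over the whole-genome reference exceeds 5).
#' @param max_gap_bins bridge up to this many consecutive failing bins.
#' @param min_bins minimum passing bins per domain.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open bp),
#'   `n_bins` (passing bins), `mean_fold` (over passing bins).
#' @export
call_domains <- function(profile, min_fold = 5, max_gap_bins = 0, min_bins = 1) {
  stopifnot(min_fold > 0)
  bw <- attr(profile, "bin_width")
  if (is.null(bw)) stop("profile lacks a bin_width attribute")
  out <- list()
  for (chr in unique(profile$chrom)) {
    p <- profile[profile$chrom == chr, , drop = FALSE]
    p <- p[order(p$bin_start), , drop = FALSE]
    idx <- p$bin_start / bw
    pass_idx <- idx[p$fold > min_fold]
    if (!length(pass_idx)) next
    # group passing bins: same domain while index gap <= max_gap_bins + 1
    grp <- cumsum(c(1, diff(pass_idx) > max_gap_bins + 1))
    for (g in unique(grp)) {
      bins <- pass_idx[grp == g]
      if (length(bins) < min_bins) next
      folds <- p$fold[match(bins, idx)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = min(bins) * bw, end = (max(bins) + 1) * bw,
        n_bins = length(bins), mean_fold = mean(folds),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), mean_fold = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Coverage of labeled regions by enrichment domains
#'
#' For each region with the requested label, the base pairs overlapped by
#' any domain and the covered proportion of the region.
#'
#' @param domains data.frame from [call_domains()].
#' @param regions `GRanges` with `label` column.
#' @param label family label to report (default all labels).
#' @return data.frame: `chrom`, `start`, `end`, `label`, `region_bp`,
#'   `covered_bp`, `proportion`.
#' @export
domain_region_coverage <- function(domains, regions, label = NULL) {
  if (!is.null(label)) regions <- regions[regions$label %in% label]
  dom <- if (nrow(domains))
    region_set(domains$chrom, domains$start, domains$end, label = "domain")
  else GenomicRanges::GRanges(label = character())
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = BiocGenerics::start(regions) - 1L,
    end = BiocGenerics::end(regions),
    label = regions$label,
    region_bp = BiocGenerics::width(regions),
    covered_bp = vapply(seq_along(regions), function(i)
      overlap_length(as.character(GenomicRanges::seqnames(regions))[i],
                     BiocGenerics::start(regions)[i] - 1L,
                     BiocGenerics::end(regions)[i], dom), 0),
    stringsAsFactors = FALSE
  ) -> df
  df$proportion <- ifelse(df$region_bp > 0, df$covered_bp / df$region_bp, NA_real_)
  df
}

#' Fraction of uncut restriction sites in sample reads
#'
#' Counts recognition-site occurrences inside reads (overlapping windows
#' allowed — reads are observations, not digestion substrates; both
#' orientations for non-palindromic enzymes; windows with `N` never match)
#' and reports sample occurrences as a percentage of reference occurrences,
#' per enzyme and pooled. Callers are expected to have normalized the two
#' read sets to equal total base counts (downsampling).
#'
#' @param sample_reads,reference_reads `DNAStringSet` or FASTA/FASTQ path.
#' @param enzymes an `enzyme_panel`, enzyme-name character vector, or list
#'   of [enzyme()].
#' @return data.frame: `enzyme` (names plus `"pooled"`), `n_sample`,
#'   `n_reference`, `pct_of_reference` (`NA` when the reference count is 0).
#' @export
uncut_site_fraction <- function(sample_reads, reference_reads, enzymes) {
  panel <- as_enzyme_panel(enzymes)
  if (!nrow(panel)) stop("need at least one enzyme")
  s <- as_reads(sample_reads); r <- as_reads(reference_reads)
  count_all <- function(reads, recognition) {
    hits <- sum(vapply(seq_along(reads), function(i)
      nrow(compile_pattern_hits(recognition, reads[[i]])), 0L))
    hits
  }
  n_s <- vapply(panel$recognition, count_all, 0L, reads = s, USE.NAMES = FALSE)
  n_r <- vapply(panel$recognition, count_all, 0L, reads = r, USE.NAMES = FALSE)
  df <- data.frame(enzyme = c(panel$name, "pooled"),
                   n_sample = c(n_s, sum(n_s)),
                   n_reference = c(n_r, sum(n_r)),
                   stringsAsFactors = FALSE)
  df$pct_of_reference <- ifelse(df$n_reference > 0,
                                100 * df$n_sample / df$n_reference, NA_real_)
  df
}

#' Per-region percent variation in read counts (length proxy)
#'
#' For depth-normalized read counts per region, the percentage variation of
#' condition A over condition B, `(A/B - 1) * 100` — a proxy for relative
#' satellite array length between cell lines or conditions.
#'
#' @param counts_a,counts_b named numeric vectors of per-region counts
#'   (names are region ids; the intersection is compared).
#' @return data.frame: `region`, `count_a`, `count_b`, `pct_change` (`NA`
#'   where the B count is zero).
#' @export
length_change <- function(counts_a, counts_b) {
  regions <- intersect(names(counts_a), names(counts_b))
  if (!length(regions)) stop("no shared region names")
  a <- counts_a[regions]; b <- counts_b[regions]
  data.frame(region = regions, count_a = unname(a), count_b = unname(b),
             pct_change = ifelse(b > 0, (a / b - 1) * 100, NA_real_),
             stringsAsFactors = FALSE)
}

#' Percentage of bins at or above coverage thresholds
#'
#' @param bin_coverages numeric vector of per-bin mean coverages.
#' @param thresholds ascending coverage thresholds.
#' @return data.frame: `threshold`, `pct_bins` (non-increasing in the
#'   threshold).
#' @export
coverage_threshold_table <- function(bin_coverages, thresholds) {
  stopifnot(length(bin_coverages) > 0, !is.unsorted(thresholds))
  pct <- vapply(thresholds, function(t)
    100 * mean(bin_coverages >= t), 0)
  data.frame(threshold = thresholds, pct_bins = pct)
}
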