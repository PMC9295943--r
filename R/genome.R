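# Genome and region I/O plus the interval arithmetic shared by all modules.
# Internal convention: 0-based half-open (BED); GRanges (1-based closed) is
# used as the interval engine and converted at the boundary.

#' Load a genome from FASTA (optionally gzip-compressed)
#'
#' Sequences are uppercased; record order is preserved.
#'
#' @param path FASTA or FASTA.gz file.
#' @return A named `DNAStringSet`.
#' @export
load_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequences in FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path)
  toupper_set(seqs)
}

toupper_set <- function(seqs) {
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- names(seqs)
  out
}

#' Load labeled genomic regions from BED
#'
#' Column 4, when present, is the repeat-family label (e.g. `cen_region`,
#' `HOR`, `HSat2`); absent labels default to `"cen_region"`. Intervals
#' shorter than `min_length` are dropped (satellite arrays below a length
#' floor are conventionally excluded from digestion analyses), remaining
#' intervals are sorted, and overlapping intervals with the same label are
#' merged.
#'
#' @param path BED3/BED4/BED6 file.
#' @param min_length minimum interval length in bp (default 0 = keep all).
#' @param default_label label assigned when column 4 is missing.
#' @return A `GRanges` with metadata column `label`.
#' @export
load_regions <- function(path, min_length = 0, default_label = "cen_region") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(GenomicRanges::GRanges(label = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3L) stop("BED file needs at least 3 columns: ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad))
    stop("invalid BED record (start >= end or non-numeric) at line ", bad[1L],
         ": ", lines[bad[1L]])
  label <- if (ncol >= 4L) vapply(fields, `[[`, "", 4L) else rep(default_label, length(chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), label = label)
  regions_normalize(gr, min_length)
}

regions_normalize <- function(gr, min_length = 0) {
  gr <- gr[BiocGenerics::width(gr) >= max(min_length, 1)]
  if (!length(gr)) return(gr)
  out <- lapply(split(gr, gr$label), function(g) {
    m <- GenomicRanges::reduce(g)
    m$label <- rep(unique(g$label), length(m))
    m
  })
  out <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  BiocGenerics::sort(out)
}

#' Construct a labeled region set from vectors (0-based half-open)
#'
#' @param chrom,start,end interval coordinates, `start` 0-based, `end`
#'   exclusive.
#' @param label family labels (recycled).
#' @param min_length length floor in bp.
#' @return A `GRanges` with metadata column `label`.
#' @export
region_set <- function(chrom, start, end, label = "cen_region", min_length = 0) {
  stopifnot(all(start < end))
  n <- max(length(chrom), length(start))
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
                               IRanges::IRanges(rep_len(start, n) + 1,
                                                rep_len(end, n)),
                               label = rep_len(label, n))
  regions_normalize(gr, min_length)
}

#' Write a labeled region set as BED4 (0-based half-open)
#'
#' @param regions `GRanges` with a `label` metadata column.
#' @param path output file.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(regions)),
                   BiocGenerics::start(regions) - 1L,
                   BiocGenerics::end(regions),
                   regions$label)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the sequences of labeled regions from a genome
#'
#' @param genome named `DNAStringSet` from [load_genome()].
#' @param regions `GRanges` with `label` column.
#' @return A list with one element per region: `chrom`, `start`, `end`,
#'   `label`, `sequence` (`DNAString`).
#' @export
region_sequences <- function(genome, regions) {
  chroms <- as.character(GenomicRanges::seqnames(regions))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("region chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  lapply(seq_along(regions), function(i) {
    L <- length(genome[[chroms[i]]])
    s0 <- BiocGenerics::start(regions)[i] - 1L
    e0 <- BiocGenerics::end(regions)[i]
    if (s0 < 0L || e0 > L)
      stop(sprintf("region %s:%d-%d out of bounds (chrom length %d)",
                   chroms[i], s0, e0, L))
    list(chrom = chroms[i], start = s0, end = e0,
         label = regions$label[i],
         sequence = Biostrings::subseq(genome[[chroms[i]]], s0 + 1L, e0))
  })
}

#' Complement of a region set over the chromosomes of a genome
#'
#' Returns the unannotated gaps between regions (per chromosome) as a
#' `GRanges` labeled `"unlabeled"`.
#'
#' @param genome named `DNAStringSet`.
#' @param regions `GRanges`.
#' @return `GRanges` with `label` column.
#' @export
region_complement <- function(genome, regions) {
  lens <- setNames(BiocGenerics::width(genome), names(genome))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(regions),
                               IRanges::ranges(regions))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- lens
  comp <- GenomicRanges::gaps(gr)
  comp <- comp[GenomicRanges::strand(comp) == "*"]
  comp$label <- rep("unlabeled", length(comp))
  comp
}

#' Overlap in base pairs between one interval and a region set
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param regions `GRanges` with `label` column.
#' @param label optional family label; when given only regions with that
#'   label are counted.
#' @return Total overlapped bp (numeric scalar).
#' @examples
#' rs <- region_set("chr1", 15, 30)
#' overlap_length("chr1", 10, 20, rs)  # 5
#' @export
overlap_length <- function(chrom, start, end, regions, label = NULL) {
  if (!is.null(label)) regions <- regions[regions$label %in% label]
  regions <- regions[as.character(GenomicRanges::seqnames(regions)) == chrom]
  if (!length(regions)) return(0)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  hits <- GenomicRanges::findOverlaps(q, regions)
  if (!length(hits)) return(0)
  ov <- GenomicRanges::pintersect(
    rep(q, length(hits)),
    GenomicRanges::GRanges(GenomicRanges::seqnames(regions),
                           IRanges::ranges(regions))[S4Vectors::subjectHits(hits)])
  sum(BiocGenerics::width(ov))
}
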