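# In silico digestion: IUPAC site matching, greedy site resolution,
# fragment generation. Coordinates are 0-based half-open throughout.

#' Find all candidate matches of one recognition sequence in one sequence
#'
#' Scans the forward strand; for non-palindromic recognition sequences the
#' reverse-complement orientation is scanned too and hits reported in
#' forward coordinates (deduplicated). Windows containing any non-ACGT base
#' (assembly `N`s) never match. Overlapping matches are all reported.
#'
#' @param recognition IUPAC recognition sequence.
#' @param seq a `DNAString`, or a character scalar (uppercased internally).
#' @return data.frame with 0-based `start`, exclusive `end`.
#' @export
compile_pattern_hits <- function(recognition, seq) {
  check_iupac(recognition)
  subject <- as_dnastring(seq)
  pat <- Biostrings::DNAString(recognition)
  hits <- site_starts(pat, subject)
  if (!is_palindromic(recognition)) {
    hits <- sort(unique(c(hits, site_starts(Biostrings::reverseComplement(pat), subject))))
  }
  data.frame(start = hits, end = hits + nchar(recognition))
}

# 0-based match starts of `pat` in `subject`, N-containing windows excluded
site_starts <- function(pat, subject) {
  m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  if (!length(m)) return(integer())
  # drop windows overlapping non-ACGT letters: Biostrings would let a
  # pattern N match a subject N, but gaps are not DNA
  keep <- !grepl("[^ACGT]", as.character(m))
  BiocGenerics::start(m)[keep] - 1L
}

as_dnastring <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  Biostrings::DNAString(toupper(as.character(seq)))
}

#' Find retained restriction sites in a sequence under a digestion plan
#'
#' Pools candidate matches of every enzyme in the plan (both orientations
#' for non-palindromic enzymes), then resolves them to a sorted,
#' non-overlapping set by greedy leftmost selection. Ties at equal start are
#' broken by longer recognition sequence first, then by enzyme-name order.
#' Runs of `N` at least as long as the shortest recognition sequence in the
#' plan act as hard fragment breaks (assembly gaps are not contiguous DNA).
#'
#' @param seq a `DNAString` or character scalar.
#' @param plan a [digestion_plan()].
#' @return data.frame with columns `start` (0-based), `end` (exclusive),
#'   `enzyme` (name, or `"gap"` for an N-run break), sorted, non-overlapping.
#' @export
find_sites <- function(seq, plan) {
  stopifnot(inherits(plan, "digestion_plan"))
  subject <- as_dnastring(seq)
  panel <- plan$enzymes
  cand <- lapply(seq_len(nrow(panel)), function(i) {
    h <- compile_pattern_hits(panel$recognition[i], subject)
    if (nrow(h)) h$enzyme <- panel$name[i]
    h
  })
  cand <- cand[vapply(cand, nrow, 0L) > 0L]
  gaps <- gap_runs(subject, min_len = if (nrow(panel)) min(nchar(panel$recognition)) else Inf)
  all <- c(cand, if (nrow(gaps)) list(gaps))
  if (!length(all))
    return(data.frame(start = integer(), end = integer(), enzyme = character()))
  hits <- do.call(rbind, all)
  resolve_greedy(hits)
}

# runs of non-ACGT letters of length >= min_len, as pseudo-hits
gap_runs <- function(subject, min_len) {
  if (!is.finite(min_len))
    return(data.frame(start = integer(), end = integer(), enzyme = character()))
  chars <- strsplit(as.character(subject), "")[[1]]
  isn <- !(chars %in% c("A", "C", "G", "T"))
  if (!any(isn))
    return(data.frame(start = integer(), end = integer(), enzyme = character()))
  r <- rle(isn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # 0-based
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             enzyme = rep("gap", sum(keep)))
}

# greedy leftmost non-overlapping; ties: longer site first, then name order
resolve_greedy <- function(hits) {
  ord <- order(hits$start, -(hits$end - hits$start), hits$enzyme)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest one sequence into fragments
#'
#' In `site_removal` mode the fragments are the maximal runs between
#' retained sites with the site bases excluded (the recognition sequence is
#' replaced by a break), and zero-length fragments from adjacent sites are
#' discarded. In `site_retained` mode a cut is placed at each retained
#' site's start so that every base is conserved in some fragment (N-run
#' gap breaks are still excluded in both modes).
#'
#' @param seq a `DNAString` or character scalar.
#' @param plan a [digestion_plan()].
#' @param seq_id sequence identifier recorded in the output.
#' @param source_label origin label recorded in the output.
#' @return data.frame with columns `seq_id`, `start` (0-based), `end`
#'   (exclusive), `length`, `source_label`.
#' @examples
#' digest_sequence("AAACCAGGTTT", digestion_plan("ScrFI"))  # lengths 3, 3
#' @export
digest_sequence <- function(seq, plan, seq_id = "seq", source_label = "unlabeled") {
  subject <- as_dnastring(seq)
  L <- length(subject)
  sites <- find_sites(subject, plan)
  if (plan$mode == "site_removal") {
    starts <- c(0L, sites$end)
    ends <- c(sites$start, L)
  } else {
    gap <- sites$enzyme == "gap"
    cutpts <- sort(unique(c(sites$start[!gap], sites$start[gap], sites$end[gap])))
    # gap runs excluded even in site_retained mode
    starts <- c(0L, cutpts)
    ends <- c(cutpts, L)
    if (any(gap)) {
      frag <- data.frame(start = starts, end = ends)
      inside_gap <- vapply(seq_len(nrow(frag)), function(i)
        any(frag$start[i] >= sites$start[gap] & frag$end[i] <= sites$end[gap]), TRUE)
      starts <- frag$start[!inside_gap]
      ends <- frag$end[!inside_gap]
    }
  }
  keep <- ends > starts
  data.frame(seq_id = rep(seq_id, sum(keep)),
             start = starts[keep], end = ends[keep],
             length = ends[keep] - starts[keep],
             source_label = rep(source_label, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Digest a genome (or any set of labeled sequences)
#'
#' @param seqs a named `DNAStringSet` (names become `seq_id`).
#' @param plan a [digestion_plan()].
#' @param source_labels optional character vector (recycled) of origin
#'   labels, one per sequence.
#' @return data.frame of fragments (see [digest_sequence()]).
#' @export
digest_set <- function(seqs, plan, source_labels = "unlabeled") {
  stopifnot(is(seqs, "DNAStringSet"))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  labels <- rep_len(source_labels, length(seqs))
  out <- lapply(seq_along(seqs), function(i)
    digest_sequence(seqs[[i]], plan, seq_id = ids[i], source_label = labels[i]))
  do.call(rbind, out)
}

#' Write fragments as BED6
#'
#' Columns: chrom, start, end, source_label, length (score), strand ".".
#'
#' @param fragments fragment data.frame from [digest_sequence()]/[digest_set()].
#' @param path output file path.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$seq_id, fragments$start, fragments$end,
                    fragments$source_label, fragments$length, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract fragment sequences from a genome
#'
#' @param genome named `DNAStringSet` containing every `seq_id` in
#'   `fragments`.
#' @param fragments fragment data.frame with chromosome-scale coordinates.
#' @return A `DNAStringSet` named `seq_id:start-end`, one per fragment,
#'   with the fragment's `source_label` kept in `attr(, "source_label")`.
#' @export
fragment_sequences <- function(genome, fragments) {
  missing <- setdiff(unique(fragments$seq_id), names(genome))
  if (length(missing))
    stop("fragment seq_id(s) not in genome: ", paste(missing, collapse = ", "))
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(fragments)), function(i)
    as.character(Biostrings::subseq(genome[[fragments$seq_id[i]]],
                                    fragments$start[i] + 1L, fragments$end[i])),
    ""))
  names(out) <- sprintf("%s:%d-%d", fragments$seq_id,
                        fragments$start, fragments$end)
  attr(out, "source_label") <- fragments$source_label
  out
}
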