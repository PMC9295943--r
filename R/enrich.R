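# Size-selection enrichment prediction and enzyme-combination screening.

#' Fragment-length binning
#'
#' Bins are half-open `[lo, hi)`; the final bin is open-ended. The default
#' (5-kb steps up to 55 kb, then `>= 55 kb`) brackets the usual
#' high-molecular-weight landmarks of restriction-plus-size-selection
#' protocols (>15-20 kb selected, intact satellite fragments >55 kb).
#'
#' @param edges strictly increasing internal bin boundaries in bp.
#' @return An object of class `size_binning` with elements `lo`, `hi`,
#'   `label`.
#' @export
size_binning <- function(edges = seq(5000, 55000, by = 5000)) {
  edges <- as.numeric(edges)
  if (!length(edges) || any(diff(edges) <= 0) || any(edges <= 0))
    stop("edges must be a non-empty strictly increasing positive vector")
  lo <- c(0, edges)
  hi <- c(edges, Inf)
  label <- ifelse(is.finite(hi),
                  sprintf("[%g,%g)", lo, hi),
                  sprintf(">=%g", lo))
  structure(list(lo = lo, hi = hi, label = label), class = "size_binning")
}

bin_index <- function(lengths, binning) {
  findInterval(lengths, c(binning$lo, Inf), rightmost.closed = FALSE)
}

#' Genome-wide base-pair fraction of the target regions
#'
#' The baseline against which fold enrichment is expressed: the proportion
#' of the (undigested) genome lying inside target-labeled regions. For the
#' human T2T reference and its annotated centromeric regions this is the
#' ~2.8% expected centromeric content of a non-enriched sample.
#'
#' @param genome named `DNAStringSet`.
#' @param regions `GRanges` with `label` column.
#' @param target_labels labels counted as target (default `"cen_region"`).
#' @return Fraction in `[0, 1]`.
#' @export
baseline_fraction <- function(genome, regions, target_labels = "cen_region") {
  total <- sum(as.numeric(BiocGenerics::width(genome)))
  if (total == 0) stop("empty genome")
  tgt <- regions[regions$label %in% target_labels]
  if (!length(tgt)) return(0)
  sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(tgt)))) / total
}

#' Predict size-selection enrichment from an in silico digestion
#'
#' Digests the target partition (regions carrying a target label) and the
#' non-target partition (everything else) separately, bins all fragments by
#' length, and reports per bin the fragment- and base-pair-percentage of
#' target origin plus the fold enrichment in target bp over the undigested
#' baseline.
#'
#' In `partition = "by_region"` mode (default) each target region and each
#' inter-region gap is digested as its own sequence, so fragments never
#' straddle a target boundary. In `partition = "whole_chromosome"` mode
#' whole chromosomes are digested and each fragment is classified as target
#' when at least half of its length overlaps target regions.
#'
#' @param genome named `DNAStringSet`.
#' @param regions `GRanges` with `label` column.
#' @param plan a [digestion_plan()].
#' @param binning a [size_binning()].
#' @param target_labels labels treated as target origin.
#' @param partition digestion mode, see Details.
#' @return data.frame of class `enrichment_table` with one row per bin and
#'   columns `bin`, `bin_lo`, `bin_hi`, `n_frag_target`, `n_frag_total`,
#'   `bp_target`, `bp_total`, `pct_frag_target`, `pct_bp_target`,
#'   `fold_bp`; attribute `baseline_pct` holds the genome-wide target
#'   percentage. `fold_bp` is `NA` when the baseline is zero.
#' @export
predict_enrichment <- function(genome, regions, plan,
                               binning = size_binning(),
                               target_labels = "cen_region",
                               partition = c("by_region", "whole_chromosome")) {
  partition <- match.arg(partition)
  stopifnot(is(genome, "DNAStringSet"))
  if (!length(genome)) stop("empty genome")
  frags <- if (partition == "by_region") {
    digest_partitioned(genome, regions, plan, target_labels)
  } else {
    digest_majority(genome, regions, plan, target_labels)
  }
  baseline_pct <- 100 * baseline_fraction(genome, regions, target_labels)
  enrichment_table(frags, binning, baseline_pct)
}

digest_partitioned <- function(genome, regions, plan, target_labels) {
  tgt <- regions[regions$label %in% target_labels]
  nontgt_ann <- regions[!(regions$label %in% target_labels)]
  comp <- region_complement(genome, regions)
  parts <- c(region_sequences(genome, tgt),
             region_sequences(genome, nontgt_ann),
             region_sequences(genome, comp))
  out <- lapply(parts, function(p) {
    f <- digest_sequence(p$sequence, plan,
                         seq_id = p$chrom,
                         source_label = if (p$label %in% target_labels) "target" else "non_target")
    if (nrow(f)) {
      f$start <- f$start + p$start
      f$end <- f$end + p$start
    }
    f
  })
  do.call(rbind, out)
}

digest_majority <- function(genome, regions, plan, target_labels) {
  frags <- digest_set(genome, plan)
  if (!nrow(frags)) return(frags)
  tgt <- regions[regions$label %in% target_labels]
  ov <- vapply(seq_len(nrow(frags)), function(i)
    overlap_length(frags$seq_id[i], frags$start[i], frags$end[i], tgt), 0)
  frags$source_label <- ifelse(ov >= frags$length / 2, "target", "non_target")
  frags
}

enrichment_table <- function(frags, binning, baseline_pct) {
  nb <- length(binning$lo)
  if (nrow(frags)) {
    idx <- bin_index(frags$length, binning)
    is_t <- frags$source_label == "target"
    n_frag_total <- tabulate(idx, nb)
    n_frag_target <- tabulate(idx[is_t], nb)
    bp_total <- vapply(seq_len(nb), function(b) sum(frags$length[idx == b]), 0)
    bp_target <- vapply(seq_len(nb), function(b) sum(frags$length[idx == b & is_t]), 0)
  } else {
    n_frag_total <- n_frag_target <- bp_total <- bp_target <- numeric(nb)
  }
  pct_frag_target <- ifelse(n_frag_total > 0, 100 * n_frag_target / n_frag_total, NA_real_)
  pct_bp_target <- ifelse(bp_total > 0, 100 * bp_target / bp_total, NA_real_)
  fold_bp <- if (baseline_pct > 0) pct_bp_target / baseline_pct else rep(NA_real_, nb)
  out <- data.frame(bin = binning$label, bin_lo = binning$lo, bin_hi = binning$hi,
                    n_frag_target = n_frag_target, n_frag_total = n_frag_total,
                    bp_target = bp_target, bp_total = bp_total,
                    pct_frag_target = pct_frag_target,
                    pct_bp_target = pct_bp_target,
                    fold_bp = fold_bp,
                    stringsAsFactors = FALSE)
  attr(out, "baseline_pct") <- baseline_pct
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Pooled enrichment above a fragment-length cutoff
#'
#' Aggregates an [predict_enrichment()] table over all bins whose lower
#' edge is at least `min_length`, mimicking a size-selection step that
#' keeps fragments above a cutoff.
#'
#' @param table an `enrichment_table`.
#' @param min_length size-selection cutoff in bp (must coincide with a bin
#'   edge).
#' @return A list with `pct_bp_target`, `pct_frag_target`, `fold_bp`,
#'   `bp_total` for the pooled selected fraction (`NA`s when the selection
#'   is empty).
#' @export
enrichment_above <- function(table, min_length = 20000) {
  stopifnot(inherits(table, "enrichment_table"))
  sel <- table$bin_lo >= min_length
  if (!any(sel)) stop("min_length exceeds all bin edges")
  bp_total <- sum(table$bp_total[sel])
  bp_target <- sum(table$bp_target[sel])
  n_total <- sum(table$n_frag_total[sel])
  n_target <- sum(table$n_frag_target[sel])
  baseline <- attr(table, "baseline_pct")
  pct_bp <- if (bp_total > 0) 100 * bp_target / bp_total else NA_real_
  list(pct_bp_target = pct_bp,
       pct_frag_target = if (n_total > 0) 100 * n_target / n_total else NA_real_,
       fold_bp = if (!is.na(pct_bp) && baseline > 0) pct_bp / baseline else NA_real_,
       bp_total = bp_total)
}

#' Write an enrichment table as TSV
#'
#' @param table `enrichment_table`.
#' @param path output file; the baseline percentage is recorded in a
#'   comment line.
#' @export
write_enrichment_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# baseline_pct=%.10g", attr(table, "baseline_pct")), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default screening objective: maximum fold enrichment above a size cutoff
#'
#' @param min_edge bins with lower edge below this are ignored.
#' @return A function of an `enrichment_table` returning a numeric score.
#' @export
objective_max_fold <- function(min_edge = 15000) {
  force(min_edge)
  function(table) {
    v <- table$fold_bp[table$bin_lo >= min_edge]
    v <- v[!is.na(v)]
    if (!length(v)) return(-Inf)
    max(v)
  }
}

#' Screen enzyme combinations for predicted enrichment
#'
#' Evaluates every combination of up to `max_size` enzymes from a panel,
#' scoring each with `objective` applied to its [predict_enrichment()]
#' table. Candidate site positions are computed once per enzyme and reused
#' across combinations. Results are sorted by score (descending), ties
#' broken toward the smaller combination, then lexicographic names.
#'
#' @param genome named `DNAStringSet`.
#' @param regions `GRanges` with `label` column.
#' @param panel an `enzyme_panel`.
#' @param max_size largest combination size (>= 1).
#' @param objective function of an `enrichment_table` -> numeric score.
#' @param binning a [size_binning()].
#' @param mode digestion mode passed to [digestion_plan()].
#' @param target_labels labels treated as target origin.
#' @param min_solo_target_pct optional pruning floor: enzymes whose solo
#'   digestion leaves the selected-bin target bp percentage below this are
#'   dropped before combining (default `NULL` = no pruning).
#' @return data.frame of class `combo_screen`: `combination` (comma-joined
#'   names), `size`, `score`, sorted best-first; the per-combination tables
#'   are in `attr(, "tables")` keyed by combination string.
#' @export
screen_combinations <- function(genome, regions, panel,
                                max_size = 3,
                                objective = objective_max_fold(),
                                binning = size_binning(),
                                mode = "site_removal",
                                target_labels = "cen_region",
                                min_solo_target_pct = NULL) {
  panel <- as_enzyme_panel(panel)
  if (!nrow(panel)) stop("panel must be non-empty")
  if (max_size < 1) stop("max_size must be >= 1")
  max_size <- min(max_size, nrow(panel))

  # partition sequences once; per-enzyme candidate hits once per sequence
  parts <- partition_sequences(genome, regions, target_labels)
  cand <- lapply(parts, function(p) {
    lapply(seq_len(nrow(panel)), function(i) {
      h <- compile_pattern_hits(panel$recognition[i], p$sequence)
      if (nrow(h)) h$enzyme <- panel$name[i] else h$enzyme <- character()
      h
    })
  })
  gapruns <- lapply(parts, function(p)
    gap_runs(as_dnastring(p$sequence), min_len = min(nchar(panel$recognition))))
  baseline_pct <- 100 * baseline_fraction(genome, regions, target_labels)

  keep_idx <- seq_len(nrow(panel))
  if (!is.null(min_solo_target_pct)) {
    solo <- vapply(keep_idx, function(i) {
      tbl <- combo_table(i, parts, cand, gapruns, panel, mode, binning, baseline_pct)
      s <- enrichment_above(tbl, min_length = environment(objective)$min_edge %||% 15000)
      if (is.na(s$pct_bp_target)) 100 else s$pct_bp_target
    }, 0)
    keep_idx <- keep_idx[solo >= min_solo_target_pct]
    if (!length(keep_idx)) stop("pruning removed every enzyme; lower min_solo_target_pct")
  }

  combos <- unlist(lapply(seq_len(max_size), function(k)
    combn(keep_idx, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(ix) {
    tbl <- combo_table(ix, parts, cand, gapruns, panel, mode, binning, baseline_pct)
    list(combination = paste(sort(panel$name[ix]), collapse = ","),
         size = length(ix), score = objective(tbl), table = tbl)
  })
  df <- data.frame(combination = vapply(rows, `[[`, "", "combination"),
                   size = vapply(rows, `[[`, 0L, "size"),
                   score = vapply(rows, `[[`, 0, "score"),
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, df$size, df$combination)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "tables") <- setNames(lapply(rows[ord], `[[`, "table"), df$combination)
  class(df) <- c("combo_screen", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

partition_sequences <- function(genome, regions, target_labels) {
  tgt <- regions[regions$label %in% target_labels]
  nontgt_ann <- regions[!(regions$label %in% target_labels)]
  comp <- region_complement(genome, regions)
  parts <- c(region_sequences(genome, tgt),
             region_sequences(genome, nontgt_ann),
             region_sequences(genome, comp))
  lapply(parts, function(p) {
    p$source_label <- if (p$label %in% target_labels) "target" else "non_target"
    p
  })
}

# build an enrichment table for one enzyme-index combination from cached hits
combo_table <- function(ix, parts, cand, gapruns, panel, mode, binning, baseline_pct) {
  frag_list <- lapply(seq_along(parts), function(pi) {
    hits <- do.call(rbind, c(cand[[pi]][ix],
                             if (nrow(gapruns[[pi]])) list(gapruns[[pi]])))
    L <- length(as_dnastring(parts[[pi]]$sequence))
    lens <- fragment_lengths_from_hits(hits, L, mode)
    if (!length(lens)) return(NULL)
    data.frame(length = lens, source_label = parts[[pi]]$source_label,
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, frag_list)
  if (is.null(frags))
    frags <- data.frame(length = numeric(), source_label = character())
  enrichment_table(frags, binning, baseline_pct)
}

fragment_lengths_from_hits <- function(hits, L, mode) {
  if (is.null(hits) || !nrow(hits)) return(L)
  sites <- resolve_greedy(hits)
  if (mode == "site_removal") {
    lens <- c(sites$start, L) - c(0L, sites$end)
  } else {
    gap <- sites$enzyme == "gap"
    cutpts <- sort(unique(c(sites$start[!gap], sites$start[gap], sites$end[gap])))
    starts <- c(0L, cutpts); ends <- c(cutpts, L)
    if (any(gap)) {
      inside <- vapply(seq_along(starts), function(i)
        any(starts[i] >= sites$start[gap] & ends[i] <= sites$end[gap]), TRUE)
      starts <- starts[!inside]; ends <- ends[!inside]
    }
    lens <- ends - starts
  }
  lens[lens > 0]
}
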