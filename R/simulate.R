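# Synthetic data with known ground truth: tandem-repeat toy genomes,
# size-selected read pools, and paired WT/KO methylation call tables.

#' Generate a satellite-like monomer free of chosen recognition sites
#'
#' Rejection-samples an AT-rich monomer until neither the monomer nor its
#' tandem doubling (which exposes every junction-spanning window) contains
#' a recognition site of any forbidden enzyme. Deterministic for a fixed
#' seed.
#'
#' @param length monomer length in bp (default 171, the alpha-satellite
#'   monomer size).
#' @param gc GC content of the sampled bases (default 0.38, AT-rich).
#' @param forbidden_enzymes `enzyme_panel`/names whose sites must be absent.
#' @param seed integer RNG seed.
#' @param max_attempts rejection-sampling cap.
#' @return Character scalar of length `length`.
#' @export
make_monomer <- function(length = 171, gc = 0.38,
                         forbidden_enzymes = c("ScrFI", "NlaIV", "EcoO109I"),
                         seed = 1, max_attempts = 1000) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  panel <- as_enzyme_panel(forbidden_enzymes)
  plan <- digestion_plan(panel)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (attempt in seq_len(max_attempts)) {
    mono <- paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
    if (nrow(panel) == 0L ||
        nrow(find_sites(paste0(mono, mono), plan)) == 0L)
      return(mono)
  }
  stop("could not sample a site-free monomer in ", max_attempts,
       " attempts; loosen constraints (shorter recognition sites or monomer)")
}

#' Specification of a synthetic tandem-repeat toy genome
#'
#' @param monomer_length monomer length in bp (171 default).
#' @param hor_unit monomers per higher-order-repeat unit.
#' @param array_copies HOR units per array.
#' @param n_arrays number of satellite arrays on the chromosome.
#' @param background_length total background (non-array) bp.
#' @param background_site_spacing target spacing of injected recognition
#'   sites in the background, in bp.
#' @param forbidden_enzymes enzymes whose sites the arrays must lack and
#'   which are injected in the background.
#' @param divergence_rate per-base substitution probability applied to
#'   monomer copies (0 = perfectly homogeneous array).
#' @param seed integer RNG seed.
#' @return List of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(monomer_length = 171, hor_unit = 4, array_copies = 50,
                            n_arrays = 1, background_length = 307800,
                            background_site_spacing = 500,
                            forbidden_enzymes = c("ScrFI", "NlaIV", "EcoO109I"),
                            divergence_rate = 0, seed = 1) {
  stopifnot(monomer_length > 0, hor_unit > 0, array_copies > 0, n_arrays > 0,
            background_length > 0, background_site_spacing > 0,
            divergence_rate >= 0, divergence_rate <= 1)
  structure(list(monomer_length = monomer_length, hor_unit = hor_unit,
                 array_copies = array_copies, n_arrays = n_arrays,
                 background_length = background_length,
                 background_site_spacing = background_site_spacing,
                 forbidden_enzymes = forbidden_enzymes,
                 divergence_rate = divergence_rate, seed = seed),
            class = "toy_genome_spec")
}

#' Build a toy genome with satellite arrays and known ground truth
#'
#' Lays out one chromosome as alternating background segments and tandem
#' satellite arrays (background | array | ... | background). Arrays are
#' verified site-free for the forbidden enzymes (divergent copies are
#' re-checked and the whole genome build retried if divergence created a
#' site). Background segments carry exact recognition-site instances
#' injected at the requested spacing, jittered uniformly by +/-20%.
#'
#' @param spec a [toy_genome_spec()].
#' @return List: `genome` (named `DNAStringSet`, one chromosome `chrT`),
#'   `regions` (`GRanges`, arrays labeled `cen_region`), `truth` (list with
#'   `target_fraction`, `target_bp`, `genome_bp`, `array_starts`,
#'   `array_ends`, `seed`).
#' @export
make_toy_genome <- function(spec = toy_genome_spec()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  panel <- as_enzyme_panel(spec$forbidden_enzymes)
  plan <- digestion_plan(panel)
  array_len <- spec$monomer_length * spec$hor_unit * spec$array_copies
  n_seg <- spec$n_arrays + 1L
  seg_len <- floor(spec$background_length / n_seg)
  seg_lens <- rep(seg_len, n_seg)
  seg_lens[n_seg] <- spec$background_length - seg_len * (n_seg - 1L)

  for (retry in 0:4) {
    set.seed(spec$seed + retry)
    mono <- make_monomer(spec$monomer_length, forbidden_enzymes = panel,
                         seed = spec$seed + retry)
    arrays <- vapply(seq_len(spec$n_arrays), function(i)
      build_array(mono, spec$hor_unit * spec$array_copies, spec$divergence_rate),
      "")
    ok <- all(vapply(arrays, function(a)
      nrow(find_sites(a, plan)) == 0L, TRUE))
    if (ok) break
    if (retry == 4) stop("divergence kept introducing recognition sites; lower divergence_rate")
  }
  bgs <- vapply(seg_lens, function(L)
    build_background(L, panel, spec$background_site_spacing), "")

  pieces <- character(0); starts <- numeric(0); ends <- numeric(0); at <- 0
  for (i in seq_len(spec$n_arrays)) {
    pieces <- c(pieces, bgs[i]); at <- at + seg_lens[i]
    pieces <- c(pieces, arrays[i])
    starts <- c(starts, at); ends <- c(ends, at + array_len)
    at <- at + array_len
  }
  pieces <- c(pieces, bgs[n_seg])
  chrom <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chrT"
  regions <- region_set(rep("chrT", spec$n_arrays), starts, ends,
                        label = "cen_region")
  total <- nchar(chrom)
  truth <- list(target_fraction = spec$n_arrays * array_len / total,
                target_bp = spec$n_arrays * array_len, genome_bp = total,
                array_starts = starts, array_ends = ends, seed = spec$seed)
  list(genome = genome, regions = regions, truth = truth)
}

build_array <- function(monomer, n_copies, divergence_rate) {
  if (divergence_rate == 0)
    return(paste(rep(monomer, n_copies), collapse = ""))
  bases <- c("A", "C", "G", "T")
  copies <- vapply(seq_len(n_copies), function(i) {
    ch <- strsplit(monomer, "")[[1]]
    mut <- runif(length(ch)) < divergence_rate
    if (any(mut))
      ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(bases, b), 1L), "")
    paste(ch, collapse = "")
  }, "")
  paste(copies, collapse = "")
}

# random background with exact recognition-site instances injected at
# jittered spacing; accidental extra sites are allowed (they only shorten
# background fragments further)
build_background <- function(length, panel, spacing) {
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, length, replace = TRUE)
  if (nrow(panel) == 0L) return(paste(seq, collapse = ""))
  pos <- 1
  enz_i <- 1L
  while (TRUE) {
    gap <- round(spacing * runif(1, 0.8, 1.2))
    pos <- pos + gap
    site <- concrete_site(panel$recognition[enz_i])
    enz_i <- enz_i %% nrow(panel) + 1L
    if (pos + nchar(site) - 1 > length) break
    seq[pos:(pos + nchar(site) - 1)] <- strsplit(site, "")[[1]]
    pos <- pos + nchar(site)
  }
  paste(seq, collapse = "")
}

# resolve an IUPAC recognition sequence to one concrete instance
concrete_site <- function(recognition) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(recognition, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Simulate size-selected reads from a fragment pool
#'
#' Keeps fragments at least `min_length` long (the size-selection step),
#' then draws error-free reads with source fragments chosen with
#' probability proportional to fragment length (uniform by base) and start
#' offsets uniform over valid positions. Read names record the source
#' fragment's label (`source=<label>`). Deterministic for a fixed seed.
#'
#' @param fragments named `DNAStringSet` of fragment sequences, or a list
#'   with elements `sequence` and `label` per fragment; labels default to
#'   names or `"unlabeled"`.
#' @param min_length size-selection cutoff in bp.
#' @param n_reads number of reads.
#' @param read_length read length in bp (fragments shorter than this are
#'   also excluded).
#' @param seed integer RNG seed.
#' @param error_rate optional uniform substitution-error probability per
#'   base (default 0, error-free).
#' @param labels optional character vector of per-fragment labels.
#' @return A `DNAStringSet` of reads named
#'   `read<i> source=<label>`; attribute `source_label` carries the
#'   per-read truth labels.
#' @export
simulate_size_selected_reads <- function(fragments, min_length, n_reads,
                                         read_length, seed = 1,
                                         error_rate = 0, labels = NULL) {
  stopifnot(n_reads > 0, read_length > 0)
  if (is.list(fragments) && !is(fragments, "DNAStringSet")) {
    labels <- vapply(fragments, function(f) f$label %||% "unlabeled", "")
    fragments <- Biostrings::DNAStringSet(vapply(fragments, function(f)
      as.character(f$sequence), ""))
  }
  fragments <- as_reads(fragments)
  if (is.null(labels)) labels <- names(fragments) %||% rep("unlabeled", length(fragments))
  keep <- Biostrings::width(fragments) >= max(min_length, read_length)
  if (!any(keep))
    stop("no fragment passes the size selection (min_length = ", min_length, ")")
  fragments <- fragments[keep]; labels <- labels[keep]
  set.seed(seed)
  w <- as.numeric(Biostrings::width(fragments))
  src <- sample.int(length(fragments), n_reads, replace = TRUE, prob = w)
  starts <- vapply(src, function(i)
    sample.int(w[i] - read_length + 1L, 1L), 0L)
  reads <- Biostrings::subseq(fragments[src], start = starts,
                              width = read_length)
  if (error_rate > 0) reads <- add_errors(reads, error_rate)
  names(reads) <- sprintf("read%d source=%s", seq_len(n_reads), labels[src])
  attr(reads, "source_label") <- labels[src]
  reads
}

add_errors <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  out <- vapply(as.character(reads), function(s) {
    ch <- strsplit(s, "")[[1]]
    mut <- runif(length(ch)) < error_rate
    if (any(mut))
      ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(bases, b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(reads)
  res
}

#' Write simulated reads as FASTQ (constant base quality)
#'
#' @param reads `DNAStringSet` from [simulate_size_selected_reads()].
#' @param path output FASTQ path.
#' @param quality_char constant Phred symbol (default `"I"`, Q40).
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  for (i in seq_along(reads)) {
    s <- as.character(reads[[i]])
    writeLines(c(paste0("@", ids[i]), s, "+",
                 strrep(quality_char, nchar(s))), con)
  }
  invisible(path)
}

#' Simulate paired WT/KO methylation call tables with family effects
#'
#' Sites are placed uniformly within the labeled regions (proportionally to
#' region length). Each site draws a WT methylation probability from a beta
#' distribution around its family mean (concentration `dispersion`); the KO
#' probability is the WT probability scaled by `1 - relative_drop` for the
#' site's family. Valid-call counts are Poisson with the given mean
#' coverage (floored at 1), methylated counts binomial. Deterministic for
#' a fixed seed.
#'
#' Default family effects mirror the observed behaviour of DNMT1/DNMT3B
#' double-knockout cells: a large relative methylation loss at
#' pericentromeric HSATII (~73% of the WT level) versus a minor one at
#' alpha-satellite (~9.8%).
#'
#' @param regions `GRanges` with `label` column naming the families.
#' @param family_params named list (by family label) of lists with
#'   `mean_wt` (percent), `relative_drop` (fraction of WT level lost in
#'   KO), `dispersion` (beta concentration, larger = tighter site spread).
#' @param coverage mean per-site valid-call coverage (Poisson).
#' @param n_sites total number of CpG sites to place.
#' @param seed integer RNG seed.
#' @return List: `wt`, `ko` (`meth_sites` tables), `truth` (per-family
#'   `mean_wt`, `relative_drop`, site counts, `seed`).
#' @export
simulate_methylation <- function(regions,
                                 family_params = default_family_params(),
                                 coverage = 30, n_sites = 5000, seed = 1) {
  stopifnot(length(regions) > 0, n_sites > 0, coverage > 0)
  fams <- unique(regions$label)
  missing <- setdiff(fams, names(family_params))
  if (length(missing))
    stop("family_params missing for label(s): ", paste(missing, collapse = ", "))
  set.seed(seed)
  w <- as.numeric(BiocGenerics::width(regions))
  reg_i <- sample.int(length(regions), n_sites, replace = TRUE, prob = w)
  pos <- BiocGenerics::start(regions)[reg_i] - 1L +
    vapply(reg_i, function(i) sample.int(BiocGenerics::width(regions)[i], 1L) - 1L, 0L)
  chrom <- as.character(GenomicRanges::seqnames(regions))[reg_i]
  fam <- regions$label[reg_i]
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; fam <- fam[ord]
  # drop coincident positions so (chrom, pos) keys stay unique
  dup <- duplicated(paste(chrom, pos))
  chrom <- chrom[!dup]; pos <- pos[!dup]; fam <- fam[!dup]
  n <- length(pos)

  p_wt <- numeric(n); p_ko <- numeric(n)
  for (f in unique(fam)) {
    pars <- family_params[[f]]
    m <- pars$mean_wt / 100
    kappa <- pars$dispersion %||% 50
    idx <- which(fam == f)
    p <- rbeta(length(idx), m * kappa, (1 - m) * kappa)
    p_wt[idx] <- p
    p_ko[idx] <- p * (1 - pars$relative_drop)
  }
  cov_wt <- pmax(1L, rpois(n, coverage))
  cov_ko <- pmax(1L, rpois(n, coverage))
  wt <- meth_sites(chrom, pos, cov_wt, rbinom(n, cov_wt, p_wt))
  ko <- meth_sites(chrom, pos, cov_ko, rbinom(n, cov_ko, p_ko))
  truth <- list(
    families = lapply(family_params[intersect(names(family_params), unique(fam))],
                      function(p) p[c("mean_wt", "relative_drop")]),
    n_sites = n, site_family = fam, coverage = coverage, seed = seed)
  list(wt = wt, ko = ko, truth = truth)
}

#' Default synthetic methylation family parameters
#'
#' High-methylation satellite families (so the >40% WT inclusion filter
#' retains most sites) with knockout relative drops of 73% (HSATII) and
#' 9.8% (alpha-satellite).
#'
#' @return Named list usable as `family_params` in
#'   [simulate_methylation()].
#' @export
default_family_params <- function() {
  list(
    alpha_sat = list(mean_wt = 65, relative_drop = 0.098, dispersion = 50),
    HSATII = list(mean_wt = 75, relative_drop = 0.73, dispersion = 50)
  )
}
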