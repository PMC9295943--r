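# Independent naive oracle for IUPAC site matching and digestion, written
# window-by-window against the plain IUPAC table; used to cross-check the
# package's Biostrings-backed scanner.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

complement_code <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                     S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                     D = "H", H = "D", N = "N")

naive_revcomp_pattern <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  paste(complement_code[chars], collapse = "")
}

# all 0-based starts where `pattern` matches `seq` on the given string;
# genome letters outside ACGT never match
naive_scan_one <- function(seq, pattern) {
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(pattern), "")[[1]]
  m <- length(pc); n <- length(sc)
  if (n < m) return(integer())
  hits <- integer()
  for (s in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(sc[s + j] %in% iupac_sets[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# candidate hits of one pattern, both orientations, forward coordinates
naive_pattern_hits <- function(seq, pattern) {
  hits <- naive_scan_one(seq, pattern)
  rc <- naive_revcomp_pattern(pattern)
  if (rc != toupper(pattern)) hits <- sort(unique(c(hits, naive_scan_one(seq, rc))))
  data.frame(start = hits, end = hits + nchar(pattern))
}

# full naive find_sites: pool enzymes, greedy leftmost, ties longer site
# first then name order (independent re-implementation of the policy)
naive_find_sites <- function(seq, panel) {
  cand <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    h <- naive_pattern_hits(seq, panel$recognition[i])
    if (nrow(h)) h$enzyme <- panel$name[i] else h$enzyme <- character()
    h
  }))
  if (is.null(cand) || !nrow(cand))
    return(data.frame(start = integer(), end = integer(), enzyme = character()))
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$enzyme), , drop = FALSE]
  keep <- rep(FALSE, nrow(cand)); last <- 0
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last) { keep[i] <- TRUE; last <- cand$end[i] }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

naive_fragment_lengths <- function(seq, panel, mode = "site_removal") {
  L <- nchar(seq)
  sites <- naive_find_sites(seq, panel)
  if (mode == "site_removal") {
    lens <- c(sites$start, L) - c(0, sites$end)
  } else {
    cuts <- sites$start
    lens <- diff(c(0, cuts, L))
  }
  lens[lens > 0]
}

random_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

random_iupac_pattern <- function(min_len = 4, max_len = 7) {
  len <- sample(min_len:max_len, 1)
  # bias toward concrete bases so matches actually occur
  alph <- c(rep(c("A", "C", "G", "T"), 4), "R", "Y", "S", "W", "K", "M", "N")
  paste(sample(alph, len, replace = TRUE), collapse = "")
}
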