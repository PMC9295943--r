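#' Restriction enzymes with degenerate recognition sites
#'
#' An enzyme is a short name plus an IUPAC recognition sequence
#' (alphabet `ACGTRYSWKMBDHVN`). A recognition sequence is *palindromic*
#' when its IUPAC reverse complement describes exactly the same set of
#' concrete DNA sequences; for such enzymes a single-strand scan of the
#' genome already finds every double-strand site.
#'
#' @param name short enzyme name (e.g. `"ScrFI"`).
#' @param recognition IUPAC recognition sequence (e.g. `"CCNGG"`).
#' @return An object of class `enzyme`: a list with elements `name`,
#'   `recognition` and `palindromic`.
#' @examples
#' enzyme("ScrFI", "CCNGG")
#' @export
enzyme <- function(name, recognition) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(as.character(recognition))
  check_iupac(recognition)
  structure(
    list(name = name, recognition = recognition,
         palindromic = is_palindromic(recognition)),
    class = "enzyme"
  )
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s%s\n", x$name, x$recognition,
              if (x$palindromic) "  (palindromic)" else ""))
  invisible(x)
}

iupac_alphabet <- function() names(Biostrings::IUPAC_CODE_MAP)

check_iupac <- function(recognition) {
  if (!nzchar(recognition))
    stop("recognition sequence must be non-empty")
  chars <- strsplit(recognition, "")[[1]]
  bad <- setdiff(chars, iupac_alphabet())
  if (length(bad))
    stop("invalid IUPAC symbol(s) in recognition sequence: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Test whether an IUPAC recognition sequence is palindromic
#'
#' Because the IUPAC reverse complement maps each ambiguity code onto the
#' code describing exactly the complementary base set, the concrete-sequence
#' sets of `x` and its reverse complement coincide if and only if the two
#' IUPAC strings are identical.
#'
#' @param recognition IUPAC string.
#' @return `TRUE` or `FALSE`.
#' @export
is_palindromic <- function(recognition) {
  check_iupac(recognition)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
  identical(toupper(recognition), rc)
}

#' Read an enzyme panel from a REBASE-style TSV file
#'
#' Expects two tab-separated columns, `name` and `recognition`; a header
#' line is optional and detected by the literal column names.
#'
#' @param path path to a TSV file.
#' @return A data.frame of class `enzyme_panel` with columns `name`,
#'   `recognition`, `palindromic`.
#' @export
read_enzyme_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty enzyme panel file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("enzyme panel lines must have two tab-separated columns")
  df <- data.frame(
    name = vapply(fields, `[[`, "", 1L),
    recognition = toupper(vapply(fields, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  if (tolower(df$name[1L]) == "name") df <- df[-1L, , drop = FALSE]
  enzyme_panel(df$name, df$recognition)
}

#' Construct an enzyme panel
#'
#' @param name character vector of enzyme names (must be unique).
#' @param recognition character vector of IUPAC recognition sequences.
#' @return A data.frame of class `enzyme_panel`.
#' @export
enzyme_panel <- function(name, recognition) {
  stopifnot(length(name) == length(recognition), length(name) > 0L)
  if (anyDuplicated(name)) stop("enzyme names must be unique")
  recognition <- toupper(recognition)
  invisible(lapply(recognition, check_iupac))
  df <- data.frame(name = as.character(name),
                   recognition = recognition,
                   palindromic = vapply(recognition, is_palindromic, TRUE,
                                        USE.NAMES = FALSE),
                   stringsAsFactors = FALSE)
  class(df) <- c("enzyme_panel", "data.frame")
  df
}

#' The default six-enzyme panel
#'
#' The two triple combinations validated for centromere enrichment
#' (ScrFI + NlaIV + EcoO109I and ScrFI + EcoO109I + BstUI) plus the
#' alternative MscI + AseI pair. All six recognition sequences are
#' palindromic.
#'
#' @return An `enzyme_panel` data.frame with six rows.
#' @export
default_enzyme_panel <- function() {
  enzyme_panel(
    name = c("ScrFI", "NlaIV", "EcoO109I", "BstUI", "MscI", "AseI"),
    recognition = c("CCNGG", "GGNNCC", "RGGNCCY", "CGCG", "TGGCCA", "ATTAAT")
  )
}

#' A digestion plan: enzymes plus digestion semantics
#'
#' @param enzymes an `enzyme_panel`, a list of [enzyme()] objects, or a
#'   character vector of names drawn from [default_enzyme_panel()]. May be
#'   empty, in which case digestion leaves every sequence intact.
#' @param mode `"site_removal"` (recognition-site bases are deleted from the
#'   fragments, mimicking replacement of each site by a break) or
#'   `"site_retained"` (cut placed at site start; all bases conserved).
#' @return An object of class `digestion_plan`.
#' @export
digestion_plan <- function(enzymes = default_enzyme_panel(),
                           mode = c("site_removal", "site_retained")) {
  mode <- match.arg(mode)
  panel <- as_enzyme_panel(enzymes)
  structure(
    list(enzymes = panel, mode = mode,
         match_policy = "greedy_leftmost_nonoverlapping"),
    class = "digestion_plan"
  )
}

as_enzyme_panel <- function(enzymes) {
  if (inherits(enzymes, "enzyme_panel")) return(enzymes)
  if (is.character(enzymes)) {
    if (!length(enzymes)) return(empty_panel())
    dflt <- default_enzyme_panel()
    missing <- setdiff(enzymes, dflt$name)
    if (length(missing))
      stop("unknown enzyme name(s): ", paste(missing, collapse = ", "),
           " (not in the default panel; supply recognition sequences)")
    out <- dflt[match(enzymes, dflt$name), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("enzyme_panel", "data.frame")
    return(out)
  }
  if (is.list(enzymes)) {
    if (!length(enzymes)) return(empty_panel())
    if (all(vapply(enzymes, inherits, TRUE, "enzyme")))
      return(enzyme_panel(vapply(enzymes, `[[`, "", "name"),
                          vapply(enzymes, `[[`, "", "recognition")))
    if (is.data.frame(enzymes) && all(c("name", "recognition") %in% names(enzymes)))
      return(enzyme_panel(enzymes$name, enzymes$recognition))
  }
  stop("cannot interpret 'enzymes' as an enzyme panel")
}

empty_panel <- function() {
  df <- data.frame(name = character(), recognition = character(),
                   palindromic = logical(), stringsAsFactors = FALSE)
  class(df) <- c("enzyme_panel", "data.frame")
  df
}

#' @export
print.digestion_plan <- function(x, ...) {
  cat(sprintf("<digestion_plan> mode=%s, %d enzyme(s): %s\n",
              x$mode, nrow(x$enzymes),
              paste(x$enzymes$name, collapse = ", ")))
  invisible(x)
}
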