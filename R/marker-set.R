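ALPHABETS <- list(
  protein    = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
  nucleotide = c("A", "C", "G", "T")
)

# characters tolerated on input beyond the evolving alphabet
EXTRA_CHARS <- list(protein = c("X", "B", "Z", "U", "*"),
                    nucleotide = c("N", "U"))

DOMAIN_LEVELS <- c("Bacteria", "Archaea", "Eukaryota", "Viral", "unknown")
SOURCE_LEVELS <- c("reference", "environmental")

#' Create a set of marker sequences
#'
#' A marker set is the package's container for the sequences entering the
#' screen: a data frame with one row per sequence carrying the residues plus
#' the metadata the screen consumes -- whether a sequence is a curated
#' reference or an environmental (metagenomic) read, which domain of life a
#' reference belongs to, and simulation ground truth when available.
#'
#' Environmental sequences by definition have no trusted taxonomy, so their
#' `domain_label` must be `"unknown"`; the constructor enforces this.
#'
#' @param id unique sequence identifiers.
#' @param residues residue strings (uppercased on input).
#' @param alphabet `"protein"` or `"nucleotide"` (recycled).
#' @param source `"reference"` or `"environmental"` (recycled).
#' @param domain_label one of `"Bacteria"`, `"Archaea"`, `"Eukaryota"`,
#'   `"Viral"`, `"unknown"` (recycled; must be `"unknown"` for environmental
#'   sequences).
#' @param true_subfamily optional simulation ground truth label.
#' @param is_fragment logical, whether the sequence is a known fragment.
#' @return a data frame of class `marker_set`.
#' @export
#' @examples
#' marker_set(c("s1", "s2"), c("MKV", "MKI"), "protein")
marker_set <- function(id, residues, alphabet,
                       source = "reference",
                       domain_label = "unknown",
                       true_subfamily = NA_character_,
                       is_fragment = FALSE) {
  n <- length(id)
  ms <- data.frame(
    id = as.character(id),
    residues = toupper(as.character(residues)),
    alphabet = rep_len(as.character(alphabet), n),
    source = rep_len(as.character(source), n),
    domain_label = rep_len(as.character(domain_label), n),
    true_subfamily = rep_len(as.character(true_subfamily), n),
    is_fragment = rep_len(as.logical(is_fragment), n),
    stringsAsFactors = FALSE
  )
  class(ms) <- c("marker_set", "data.frame")
  validate_marker_set(ms)
  ms
}

validate_marker_set <- function(ms) {
  if (anyDuplicated(ms$id))
    stop("sequence ids must be unique within a marker set: ",
         paste(unique(ms$id[duplicated(ms$id)]), collapse = ", "))
  if (any(!nzchar(ms$residues)))
    stop("residues must be non-empty (offending id: ",
         ms$id[!nzchar(ms$residues)][1L], ")")
  if (!all(ms$alphabet %in% names(ALPHABETS)))
    stop("alphabet must be 'protein' or 'nucleotide'")
  if (!all(ms$source %in% SOURCE_LEVELS))
    stop("source must be one of: ", paste(SOURCE_LEVELS, collapse = ", "))
  if (!all(ms$domain_label %in% DOMAIN_LEVELS))
    stop("domain_label must be one of: ", paste(DOMAIN_LEVELS, collapse = ", "))
  bad <- ms$source == "environmental" & ms$domain_label != "unknown"
  if (any(bad))
    stop("environmental sequences must have domain_label 'unknown' (id: ",
         ms$id[bad][1L], ")")
  for (a in unique(ms$alphabet)) {
    ok <- c(ALPHABETS[[a]], EXTRA_CHARS[[a]], "-", ".")
    chars <- unique(strsplit(paste(ms$residues[ms$alphabet == a],
                                   collapse = ""), "")[[1L]])
    ill <- setdiff(chars, ok)
    if (length(ill))
      stop("illegal ", a, " characters: ", paste(ill, collapse = " "))
  }
  invisible(ms)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker set: %d sequence(s), alphabet(s): %s\n", nrow(x),
              paste(unique(x$alphabet), collapse = ", ")))
  cat(sprintf("  sources: %s\n",
              paste(sprintf("%s=%d", names(table(x$source)), table(x$source)),
                    collapse = ", ")))
  lens <- nchar(x$residues)
  cat(sprintf("  lengths: %d-%d (median %g)\n",
              min(lens), max(lens), stats::median(lens)))
  invisible(x)
}

# named residue vector from a marker set
marker_residues <- function(ms) setNames(ms$residues, ms$id)
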