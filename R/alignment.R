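GAP_CHARS <- c("-", ".")

# substitution scoring matrix for internal alignments: BLOSUM62 for proteins,
# +5/-4 for nucleotides
substitution_matrix <- function(alphabet) {
  if (alphabet == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m[ALPHABETS$protein, ALPHABETS$protein]
  } else {
    m <- matrix(-4, 4L, 4L, dimnames = list(ALPHABETS$nucleotide,
                                            ALPHABETS$nucleotide))
    diag(m) <- 5
    m
  }
}

#' Construct a reference alignment
#'
#' A reference alignment is a character matrix of aligned rows (residues plus
#' the gap symbol `-`), keyed by sequence id, with an optional domain label
#' per row.  Every row must have the same number of columns.
#'
#' @param rows named character vector of aligned rows (equal lengths), or a
#'   character matrix with rownames.
#' @param domain_label optional named vector of per-row domains.
#' @param alphabet `"protein"` or `"nucleotide"` (guessed from the residues
#'   when missing).
#' @return a list of class `ref_alignment` with elements `mat` (character
#'   matrix), `domain` (named vector or `NULL`), `alphabet`.
#' @export
ref_alignment <- function(rows, domain_label = NULL, alphabet = NULL) {
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    if (is.null(names(rows))) stop("rows must be named by sequence id")
    if (length(unique(nchar(rows))) != 1L)
      stop("all aligned rows must have equal length")
    mat <- do.call(rbind, strsplit(toupper(rows), ""))
    rownames(mat) <- names(rows)
  }
  mat[mat %in% GAP_CHARS] <- "-"
  if (is.null(rownames(mat))) stop("alignment rows must be named")
  if (is.null(alphabet)) {
    res <- setdiff(unique(as.vector(mat)), "-")
    alphabet <- if (all(res %in% c(ALPHABETS$nucleotide,
                                   EXTRA_CHARS$nucleotide)))
      "nucleotide" else "protein"
  }
  if (!is.null(domain_label)) {
    domain_label <- domain_label[rownames(mat)]
    names(domain_label) <- rownames(mat)
  }
  structure(list(mat = mat, domain = domain_label, alphabet = alphabet),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat(sprintf("reference alignment: %d row(s) x %d column(s) [%s]\n",
              nrow(x$mat), ncol(x$mat), x$alphabet))
  if (!is.null(x$domain)) print(table(x$domain))
  invisible(x)
}

#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction is strictly greater than `max_gap_fraction` are
#' removed (a column at exactly the threshold is retained).  This reproduces
#' the curation applied to reference rRNA alignments, where columns with more
#' than 90% gaps carry almost no positional-homology signal.
#'
#' @param aln a [ref_alignment()].
#' @param max_gap_fraction retention threshold (default 0.90).
#' @return the filtered `ref_alignment`, with an integer attribute
#'   `kept_columns` giving the surviving original column indices.
#' @export
filter_alignment_columns <- function(aln, max_gap_fraction = 0.90) {
  stopifnot(inherits(aln, "ref_alignment"))
  gap_frac <- colMeans(aln$mat == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (!length(keep))
    stop("column filtering removed every column of the alignment")
  out <- ref_alignment(aln$mat[, keep, drop = FALSE],
                       domain_label = aln$domain, alphabet = aln$alphabet)
  attr(out, "kept_columns") <- keep
  out
}

#' Align a query into a reference alignment profile
#'
#' Aligns a query sequence against the per-column residue-frequency profile
#' of a reference alignment with affine gap penalties.  The alignment is
#' semi-global: every query residue is consumed (internal and terminal
#' insertions are penalized), while unmatched reference columns before and
#' after the query's span are free, which is the natural convention for
#' placing fragmentary reads into a full-length reference.  Query residues
#' not matched to reference columns are recorded as insertions and do not
#' create new columns.
#'
#' The returned statistics drive the downstream quality screen:
#' `aligned_span` is the number of reference columns between the first and
#' last query-occupied column (inclusive), `match_columns` the number of
#' query residues placed in reference columns, and `gap_fraction` the
#' fraction of query residues left unplaced.
#'
#' @param query a one-row [marker_set()], or a single named character string.
#' @param ref_aln a [ref_alignment()] of the same alphabet.
#' @param config a [screen_config()] (gap penalties).
#' @return a list of class `aligned_query`: `id`, `score`, `columns`
#'   (per-residue reference column or `NA`), `aligned_row` (the query written
#'   in reference coordinates), `aligned_span`, `match_columns`,
#'   `gap_fraction`.
#' @export
profile_align <- function(query, ref_aln, config = screen_config()) {
  stopifnot(inherits(ref_aln, "ref_alignment"))
  if (inherits(query, "marker_set") || is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    qid <- query$id
    qseq <- query$residues
  } else {
    if (is.null(names(query))) stop("query string must be named")
    qid <- names(query)
    qseq <- unname(query)
  }
  if (!nzchar(qseq)) stop("empty query sequence")
  alpha <- ALPHABETS[[ref_aln$alphabet]]
  q <- strsplit(toupper(qseq), "")[[1L]]
  m <- length(q)
  n <- ncol(ref_aln$mat)
  S <- substitution_matrix(ref_aln$alphabet)

  # per-column profile scores: freq-weighted substitution score per residue
  counts <- apply(ref_aln$mat, 2L, function(col) {
    col <- col[col %in% alpha]
    tabulate(match(col, alpha), nbins = length(alpha))
  })                                           # |alphabet| x n
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
  colscore <- S %*% freq                        # |alphabet| x n
  # residues outside the evolving alphabet (X, N, ...) score 0 everywhere
  qi <- match(q, alpha)
  score_rows <- matrix(0, m, n)
  ok <- !is.na(qi)
  score_rows[ok, ] <- colscore[qi[ok], , drop = FALSE]
  score_rows[, tot == 0L] <- 0                  # all-gap columns are neutral

  open <- config$profile_gap_open
  ext <- config$profile_gap_extend
  NEG <- -1e18
  # DP over (query prefix i-1) x (reference prefix j-1); M = residue placed
  # in column, X = reference column skipped (deletion), Y = query residue
  # inserted.  Leading/trailing reference columns are free via row 1 of X
  # and the final maximization.
  M <- matrix(NEG, m + 1L, n + 1L)
  X <- matrix(NEG, m + 1L, n + 1L)
  Y <- matrix(NEG, m + 1L, n + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) X[1L, 2L:(n + 1L)] <- 0          # free leading reference gap
  if (m >= 1L) Y[2L:(m + 1L), 1L] <- -(open + (seq_len(m) - 1L) * ext)
  jj <- 2L:(n + 1L)
  for (i in 2L:(m + 1L)) {
    prev_best <- pmax(M[i - 1L, ], X[i - 1L, ], Y[i - 1L, ])
    M[i, jj] <- score_rows[i - 1L, ] + prev_best[jj - 1L]
    Y[i, jj] <- pmax(M[i - 1L, jj] - open, Y[i - 1L, jj] - ext)
    # X[i, j] = max(M[i, j-1] - open, X[i, j-1] - ext); since X cannot start
    # a row, this unrolls to max over t <= j-1 of M[i, t] - open -
    # (j-1-t) * ext, a running maximum of M[i, t] + t * ext
    W <- cummax(c(NEG, M[i, jj - 1L] + (jj - 1L) * ext))
    X[i, jj] <- W[jj] - open - (jj - 1L) * ext
  }
  end_best <- pmax(M[m + 1L, ], Y[m + 1L, ])
  j <- which.max(end_best)
  state <- if (M[m + 1L, j] >= Y[m + 1L, j]) "M" else "Y"
  score <- end_best[j]

  # traceback
  columns <- rep(NA_integer_, m)
  i <- m + 1L
  eps <- 1e-9
  while (i > 1L) {
    if (state == "M") {
      columns[i - 1L] <- j - 1L
      prevs <- c(M = M[i - 1L, j - 1L], X = X[i - 1L, j - 1L],
                 Y = Y[i - 1L, j - 1L])
      tgt <- M[i, j] - score_rows[i - 1L, j - 1L]
      state <- names(prevs)[which(prevs >= tgt - eps)][1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Y") {
      state <- if (M[i - 1L, j] - open >= Y[i, j] - eps) "M" else "Y"
      i <- i - 1L
    } else {                                    # X: reference column skipped
      state <- if (M[i, j - 1L] - open >= X[i, j] - eps) "M" else "X"
      j <- j - 1L
    }
  }

  occupied <- columns[!is.na(columns)]
  aligned_row <- rep("-", n)
  if (length(occupied))
    aligned_row[columns[!is.na(columns)]] <- q[!is.na(columns)]
  out <- list(
    id = qid,
    score = score,
    columns = columns,
    aligned_row = paste(aligned_row, collapse = ""),
    aligned_span = if (length(occupied))
      as.integer(max(occupied) - min(occupied) + 1L) else 0L,
    match_columns = length(occupied),
    gap_fraction = 1 - length(occupied) / m
  )
  class(out) <- "aligned_query"
  out
}

#' @export
print.aligned_query <- function(x, ...) {
  cat(sprintf("aligned query %s: span %d, matched %d, gap fraction %.3f\n",
              x$id, x$aligned_span, x$match_columns, x$gap_fraction))
  invisible(x)
}

#' Screen the quality of a profile alignment
#'
#' Rejects placements too unreliable to support deep phylogenetic inference:
#' queries aligning over fewer than `min_aligned_span` reference columns are
#' rejected as `short_span` (short local similarities routinely mimic deep
#' branches), and queries with more than `max_query_gap_fraction` of their
#' residues unplaced are rejected as `gappy`.
#'
#' @param aq an [profile_align()] result.
#' @param config a [screen_config()].
#' @return a list with `accept` (logical) and `reason`
#'   (`NA`, `"short_span"` or `"gappy"`).
#' @export
screen_alignment_quality <- function(aq, config = screen_config()) {
  if (aq$aligned_span < config$min_aligned_span)
    return(list(accept = FALSE, reason = "short_span"))
  if (aq$gap_fraction > config$max_query_gap_fraction)
    return(list(accept = FALSE, reason = "gappy"))
  list(accept = TRUE, reason = NA_character_)
}

#' Progressive profile alignment of unaligned sequences
#'
#' Builds a multiple alignment by seeding with the longest sequence and
#' profile-aligning each remaining sequence, in decreasing length order
#' (ties by id), into the growing alignment.  Because [profile_align()] never
#' creates new reference columns, residues of later sequences falling between
#' seed columns are dropped; this is adequate for the package's
#' substitution-dominated markers, and an externally computed alignment can
#' be supplied wherever a [ref_alignment()] is accepted.
#'
#' @param ms a [marker_set()] (single alphabet).
#' @param config a [screen_config()].
#' @return a [ref_alignment()] over all sequences.
#' @export
align_progressive <- function(ms, config = screen_config()) {
  stopifnot(nrow(ms) >= 1L)
  if (length(unique(ms$alphabet)) != 1L)
    stop("all sequences must share one alphabet")
  ord <- order(-nchar(ms$residues), ms$id)
  ms <- ms[ord, , drop = FALSE]
  aln <- ref_alignment(setNames(ms$residues[1L], ms$id[1L]),
                       alphabet = ms$alphabet[1L])
  for (i in seq_len(nrow(ms))[-1L]) {
    aq <- profile_align(setNames(ms$residues[i], ms$id[i]), aln, config)
    mat <- rbind(aln$mat, strsplit(aq$aligned_row, "")[[1L]])
    rownames(mat)[nrow(mat)] <- ms$id[i]
    aln <- ref_alignment(mat, alphabet = ms$alphabet[1L])
  }
  aln
}

#' Add an aligned query as a row of a reference alignment
#'
#' @param aln a [ref_alignment()].
#' @param aq an [profile_align()] result against `aln`.
#' @return a `ref_alignment` with one additional row (domain `"unknown"`).
#' @export
bind_aligned_query <- function(aln, aq) {
  mat <- rbind(aln$mat, strsplit(aq$aligned_row, "")[[1L]])
  rownames(mat)[nrow(mat)] <- aq$id
  dom <- aln$domain
  if (!is.null(dom)) dom <- c(dom, setNames("unknown", aq$id))
  ref_alignment(mat, domain_label = dom, alphabet = aln$alphabet)
}
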