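# Karlin-Altschul parameters used to convert raw local-alignment scores to
# bit scores.  The protein values are the standard gapped BLOSUM62 (open 11,
# extend 1) estimates; the nucleotide values are an approximation for the
# +5/-4 scoring scheme and only matter for the rarely used nucleotide path.
karlin_params <- function(alphabet) {
  if (alphabet == "protein") list(lambda = 0.267, K = 0.041)
  else list(lambda = 0.28, K = 0.046)
}

#' Construct a similarity graph
#'
#' Canonicalizes an edge list (drops self-hits, merges reciprocal duplicates
#' keeping the minimum E-value and maximum bit score) and restricts it to
#' edges at or below the E-value cutoff.
#'
#' @param nodes character vector of sequence ids.
#' @param edges data frame with columns `id_a`, `id_b`, `bit_score`,
#'   `expect`.
#' @param evalue_cutoff maximum expectation value for a retained edge.
#' @return a list of class `similarity_graph` with elements `nodes`, `edges`,
#'   `evalue_cutoff`.
#' @export
similarity_graph <- function(nodes, edges, evalue_cutoff) {
  edges <- dedup_edges(edges)
  unknown <- setdiff(unique(c(edges$id_a, edges$id_b)), nodes)
  if (length(unknown))
    stop("edges reference unknown sequence ids: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  edges <- edges[edges$expect <= evalue_cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = as.character(nodes), edges = edges,
                 evalue_cutoff = evalue_cutoff),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity graph: %d node(s), %d edge(s) at E <= %g\n",
              length(x$nodes), nrow(x$edges), x$evalue_cutoff))
  invisible(x)
}

#' All-versus-all pairwise similarity
#'
#' Computes a local (Smith-Waterman) alignment score for every sequence pair
#' (BLOSUM62 with affine gaps for proteins), converts it to a bit score via
#' the standard Karlin-Altschul transformation, and derives the expectation
#' value as `E = m * n * 2^(-bits)` with `m`, `n` the pair's lengths.  Pairs
#' with `E <= evalue_cutoff` become edges of the similarity graph.
#'
#' This internal engine stands in for an external BLASTP search; searches run
#' outside the package can be ingested instead via
#' [read_similarity_table()] and [similarity_graph()].
#'
#' By default a word-based prefilter (the same idea as BLAST seeding) skips
#' the quadratic alignment for pairs sharing no length-`word_size` word.
#' Pairs similar enough to matter for clustering share many words, so the
#' prefilter almost never drops a significant edge -- at worst a handful of
#' borderline pairs, which the density-based Lek clustering tolerates.  Set
#' `prefilter = FALSE` to force the exhaustive scan.
#'
#' @param ms a [marker_set()]; all sequences must share one alphabet.
#' @param config a [screen_config()] (E-value cutoff, gap penalties).
#' @param prefilter logical; use the shared-word prefilter.
#' @param word_size prefilter word length (default 5 for protein, 11 for
#'   nucleotide).
#' @return a [similarity_graph()].
#' @export
all_vs_all_similarity <- function(ms, config = screen_config(),
                                  prefilter = TRUE, word_size = NULL) {
  if (length(unique(ms$alphabet)) != 1L)
    stop("all sequences must share one alphabet")
  alphabet <- ms$alphabet[1L]
  n <- nrow(ms)
  ids <- ms$id
  if (n < 2L)
    return(similarity_graph(ids, data.frame(id_a = character(),
                                            id_b = character(),
                                            bit_score = numeric(),
                                            expect = numeric()),
                            config$evalue_cutoff))
  if (is.null(word_size))
    word_size <- if (alphabet == "protein") 5L else 11L

  todo <- matrix(TRUE, n, n)
  if (prefilter) {
    todo <- shared_word_pairs(ms$residues, word_size)
  }
  todo[lower.tri(todo, diag = TRUE)] <- FALSE

  xset <- if (alphabet == "protein") Biostrings::AAStringSet(ms$residues)
          else Biostrings::DNAStringSet(gsub("U", "T", ms$residues))
  names(xset) <- ids
  submat <- substitution_matrix_full(alphabet)
  kp <- karlin_params(alphabet)
  lens <- nchar(ms$residues)

  ia <- integer(); ib <- integer(); raw <- numeric()
  for (i in seq_len(n - 1L)) {
    js <- which(todo[i, ])
    if (!length(js)) next
    sc <- Biostrings::pairwiseAlignment(
      xset[js], xset[[i]], type = "local",
      substitutionMatrix = submat,
      gapOpening = config$gap_open, gapExtension = config$gap_extend,
      scoreOnly = TRUE)
    ia <- c(ia, rep.int(i, length(js)))
    ib <- c(ib, js)
    raw <- c(raw, sc)
  }
  bits <- (kp$lambda * raw - log(kp$K)) / log(2)
  expect <- exp(log(lens[ia]) + log(lens[ib]) - bits * log(2))
  edges <- data.frame(id_a = ids[ia], id_b = ids[ib],
                      bit_score = bits, expect = expect,
                      stringsAsFactors = FALSE)
  similarity_graph(ids, edges, config$evalue_cutoff)
}

# substitution matrix including ambiguity characters, for the Biostrings
# engine (scores 0 against extras so fragments with X/N still align)
substitution_matrix_full <- function(alphabet) {
  core <- substitution_matrix(alphabet)
  extra <- setdiff(EXTRA_CHARS[[alphabet]], "U")
  all <- c(rownames(core), extra)
  m <- matrix(0, length(all), length(all), dimnames = list(all, all))
  m[rownames(core), colnames(core)] <- core
  m
}

# logical n x n matrix: do sequences i and j share at least one word?
shared_word_pairs <- function(seqs, word_size) {
  n <- length(seqs)
  words <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < word_size) return(s)
    unique(substring(s, seq_len(L - word_size + 1L),
                     word_size:L))
  })
  idx <- rep(seq_len(n), lengths(words))
  by_word <- split(idx, unlist(words))
  share <- diag(n) > 0
  for (grp in by_word) {
    if (length(grp) > 1L) share[grp, grp] <- TRUE
  }
  share
}

#' Lek clustering of a similarity graph
#'
#' Agglomerative partitioning of a protein superfamily into subfamilies.
#' Starting from singletons, the pair of clusters `(A, B)` maximizing the
#' Lek score
#' \deqn{L(A, B) = \frac{\#\{\text{graph edges between } A \text{ and } B\}}
#'   {|A| \cdot |B|}}
#' is merged repeatedly until the maximum score falls below `score_cutoff`.
#' `L` is the density of significant pairwise similarities between two
#' clusters, so it lies in `[0, 1]`: 1 when every cross pair is significant,
#' 0 when none is.  Ties are broken deterministically by the lexicographically
#' smallest pair of minimum member ids, making the partition invariant to
#' input order.
#'
#' @param graph a [similarity_graph()].
#' @param score_cutoff merge threshold in `(0, 1]` (0.10 for the RecA screen,
#'   0.60 for the stricter RpoB screen).
#' @return a data frame of class `lek_clusters` with columns `cluster_id`
#'   (integer; 1 = largest cluster) and `member_id`; singletons are size-1
#'   clusters, so the rows partition the node set.
#' @export
lek_cluster <- function(graph, score_cutoff) {
  if (!is.numeric(score_cutoff) || score_cutoff <= 0 || score_cutoff > 1)
    stop("score_cutoff must lie in (0, 1]")
  ids <- sort(graph$nodes)
  n <- length(ids)
  members <- as.list(ids)
  minid <- ids
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  B <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    ia <- match(graph$edges$id_a, ids)
    ib <- match(graph$edges$id_b, ids)
    B[cbind(ia, ib)] <- 1
    B[cbind(ib, ia)] <- 1
  }
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    L <- B[act, act, drop = FALSE] / outer(sizes[act], sizes[act])
    L[lower.tri(L, diag = TRUE)] <- -Inf
    mx <- max(L)
    if (mx < score_cutoff) break
    cand <- which(L >= mx - 1e-12, arr.ind = TRUE)
    key_a <- pmin(minid[act[cand[, 1L]]], minid[act[cand[, 2L]]])
    key_b <- pmax(minid[act[cand[, 1L]]], minid[act[cand[, 2L]]])
    pick <- order(key_a, key_b)[1L]
    i <- act[cand[pick, 1L]]
    j <- act[cand[pick, 2L]]
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    minid[i] <- min(minid[i], minid[j])
    B[i, ] <- B[i, ] + B[j, ]
    B[, i] <- B[, i] + B[, j]
    B[i, i] <- 0
    active[j] <- FALSE
  }
  act <- which(active)
  ord <- act[order(-sizes[act], minid[act])]
  out <- data.frame(
    cluster_id = rep(seq_along(ord), times = sizes[ord]),
    member_id = unlist(lapply(ord, function(i) sort(members[[i]]))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("lek_clusters", "data.frame")
  out
}

#' Apply size and fragment filters to clusters
#'
#' Reproduces the screen's exclusion rules: clusters with fewer than
#' `min_cluster_members` members are too small to distinguish a novel
#' subfamily from a spurious singleton or chimera (`excluded_small`), and
#' clusters dominated by fragments -- every member flagged as a fragment, or
#' a median member length below `min_peptide_length` when that is set -- are
#' likely artifacts of partial peptides (`excluded_fragment`).  All other
#' clusters are `retained`.  The `environmental_only` flag (every member an
#' environmental read) is the primary novelty signal downstream.
#'
#' @param clusters a [lek_cluster()] result.
#' @param ms the [marker_set()] resolving every member id.
#' @param config a [screen_config()].
#' @return a list of class `cluster_set`: `members` (the input data frame)
#'   and `clusters` (one row per cluster: `cluster_id`, `n_members`,
#'   `n_full_length`, `environmental_only`, `fragment_dominated`, `status`).
#' @export
filter_clusters <- function(clusters, ms, config = screen_config()) {
  missing <- setdiff(clusters$member_id, ms$id)
  if (length(missing))
    stop("cluster members missing from the marker set: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  row <- match(clusters$member_id, ms$id)
  per <- split(seq_len(nrow(clusters)), clusters$cluster_id)
  info <- do.call(rbind, lapply(names(per), function(cid) {
    idx <- row[per[[cid]]]
    lens <- nchar(ms$residues[idx])
    frag_dom <- all(ms$is_fragment[idx]) ||
      (!is.null(config$min_peptide_length) &&
         stats::median(lens) < config$min_peptide_length)
    full <- !ms$is_fragment[idx] &
      (is.null(config$min_peptide_length) |
         lens >= (config$min_peptide_length %||% 0))
    status <- if (length(idx) < config$min_cluster_members) "excluded_small"
              else if (frag_dom) "excluded_fragment"
              else "retained"
    data.frame(cluster_id = as.integer(cid),
               n_members = length(idx),
               n_full_length = sum(full),
               environmental_only = all(ms$source[idx] == "environmental"),
               fragment_dominated = frag_dom,
               status = status,
               stringsAsFactors = FALSE)
  }))
  info <- info[order(info$cluster_id), ]
  rownames(info) <- NULL
  structure(list(members = clusters, clusters = info), class = "cluster_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d cluster(s) over %d sequence(s)\n",
              nrow(x$clusters), nrow(x$members)))
  print(table(x$clusters$status))
  invisible(x)
}

#' Select representative members of a cluster
#'
#' Deterministic stand-in for manual representative picking: for `k = 1` the
#' medoid (the member with maximal average bit-score similarity to the rest)
#' is returned; for `k > 1` the longest member is always included and the
#' remaining slots are filled by k-medoids under the graph's bit-score
#' similarity, maximizing the average similarity of each member to its
#' closest selected representative.  Exact search over subsets is used for
#' small clusters, greedy forward selection otherwise; all ties are broken
#' by lexicographic id, so repeated invocation is reproducible.
#'
#' @param member_ids character vector of cluster member ids.
#' @param graph a [similarity_graph()] providing bit scores.
#' @param k number of representatives.
#' @param ms the [marker_set()] (for member lengths).
#' @param exact_limit maximum number of candidate subsets for exact search.
#' @return a character vector of at most `k` ids (all members when
#'   `|cluster| <= k`).
#' @export
select_representatives <- function(member_ids, graph, k, ms,
                                   exact_limit = 20000) {
  member_ids <- sort(member_ids)
  nm <- length(member_ids)
  if (nm <= k) return(member_ids)
  S <- matrix(0, nm, nm, dimnames = list(member_ids, member_ids))
  e <- graph$edges
  e <- e[e$id_a %in% member_ids & e$id_b %in% member_ids, , drop = FALSE]
  S[cbind(e$id_a, e$id_b)] <- e$bit_score
  S[cbind(e$id_b, e$id_a)] <- e$bit_score
  diag(S) <- max(S) + 1           # every member is most similar to itself
  objective <- function(sel) mean(apply(S[, sel, drop = FALSE], 1L, max))
  if (k == 1L) {
    avg <- rowMeans(S)
    return(member_ids[order(-avg, member_ids)][1L])
  }
  lens <- nchar(ms$residues[match(member_ids, ms$id)])
  forced <- member_ids[order(-lens, member_ids)][1L]
  rest <- setdiff(member_ids, forced)
  pick_n <- k - 1L
  if (choose(length(rest), pick_n) <= exact_limit) {
    combos <- utils::combn(rest, pick_n, simplify = FALSE)
    scores <- vapply(combos, function(cc) objective(c(forced, cc)), 0)
    best <- which(scores >= max(scores) - 1e-12)
    keys <- vapply(combos[best], paste, "", collapse = "|")
    sel <- c(forced, combos[best][order(keys)][[1L]])
  } else {
    sel <- forced
    while (length(sel) < k) {
      cand <- setdiff(rest, sel)
      gain <- vapply(cand, function(cc) objective(c(sel, cc)), 0)
      sel <- c(sel, cand[order(-gain, cand)][1L])
    }
  }
  sort(sel)
}
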