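#' Screen environmental rRNA reads for deep branching
#'
#' The rRNA arm of the screen, one query at a time: (1) the read is aligned
#' into the column-curated reference alignment as a profile; (2) placements
#' spanning fewer than `min_aligned_span` reference columns or leaving too
#' many residues unplaced are rejected -- short or gappy alignments routinely
#' fake deep branches; (3) a neighbor-joining tree of the references plus the
#' query is built from Jukes-Cantor distances; (4) the query is a deep-branch
#' candidate when it attaches within `deep_branch_max_nodes` internal nodes
#' of the domain-separation node.
#'
#' @param queries a nucleotide [marker_set()] of environmental reads.
#' @param ref_aln a domain-labelled [ref_alignment()], already column-filtered
#'   (see [filter_alignment_columns()]).
#' @param config a [screen_config()].
#' @return a data frame with one row per query: `query_id`, `verdict`
#'   (`candidate`, `rejected_alignment`, `rejected_shallow`, `unresolvable`),
#'   `score`, `aligned_span`, `gap_fraction`, `reason`.
#' @export
screen_rrna <- function(queries, ref_aln, config = screen_config()) {
  stopifnot(inherits(ref_aln, "ref_alignment"))
  if (!nrow(ref_aln$mat)) stop("empty reference alignment")
  if (is.null(ref_aln$domain))
    stop("reference alignment must carry domain labels")
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    aq <- profile_align(queries[i, , drop = FALSE], ref_aln, config)
    qual <- screen_alignment_quality(aq, config)
    base <- data.frame(query_id = queries$id[i], verdict = NA_character_,
                       score = NA_integer_,
                       aligned_span = aq$aligned_span,
                       gap_fraction = aq$gap_fraction,
                       reason = qual$reason, stringsAsFactors = FALSE)
    if (!qual$accept) {
      base$verdict <- "rejected_alignment"
      return(base)
    }
    joint <- bind_aligned_query(ref_aln, aq)
    phy <- nj_tree(distance_matrix(joint, "jc_nucleotide",
                                   on_undefined = "d_max"))
    sep <- find_domain_separation_nodes(phy, ref_aln$domain,
                                        ignore_leaves = queries$id[i])
    if (!length(sep)) {
      base$verdict <- "unresolvable"
      return(base)
    }
    db <- deep_branch_score(phy, queries$id[i], sep,
                            max_nodes = config$deep_branch_max_nodes)
    base$score <- db$score
    base$verdict <- if (db$is_deep) "candidate" else "rejected_shallow"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call novel subfamilies from filtered clusters
#'
#' The protein arm's verdict stage.  Representatives of every retained
#' cluster are selected, aligned progressively, and placed in a single
#' neighbor-joining tree with bootstrap supports.  A cluster is called
#' `novel` when all its members are environmental, it passed the size and
#' fragment filters, and its representatives form a monophyletic group in
#' the representative tree; clusters containing any reference sequence are
#' `known`, and environmental-only clusters whose representatives scatter
#' across the tree are flagged `non_monophyletic` (clustering and phylogeny
#' disagree, so no novelty claim is made).  Excluded clusters keep their
#' filter status as the verdict.
#'
#' @param cs a [filter_clusters()] result.
#' @param ms the [marker_set()].
#' @param graph the [similarity_graph()] used for clustering.
#' @param config a [screen_config()].
#' @param representative_aln optional externally built [ref_alignment()] of
#'   representatives, overriding the internal progressive alignment.
#' @return a list with `calls` (data frame: `cluster_id`, `verdict`,
#'   `environmental_only`, `member_count`, `full_length_count`,
#'   `monophyletic_in_representative_tree`), `tree` (the representative
#'   `phylo` with supports, or `NULL`), `representatives` (data frame
#'   `cluster_id`, `member_id`).
#' @export
call_novel_subfamilies <- function(cs, ms, graph, config = screen_config()) {
  stopifnot(inherits(cs, "cluster_set"))
  info <- cs$clusters
  retained <- info$cluster_id[info$status == "retained"]
  if (length(retained) < 3L)
    warning("fewer than 3 retained clusters; representative tree may be ",
            "uninformative")
  reps <- do.call(rbind, lapply(retained, function(cid) {
    mem <- cs$members$member_id[cs$members$cluster_id == cid]
    data.frame(cluster_id = cid,
               member_id = select_representatives(
                 mem, graph, config$representatives_per_cluster, ms),
               stringsAsFactors = FALSE)
  }))
  tree <- NULL
  mono <- setNames(rep(NA, length(retained)), retained)
  if (!is.null(reps) && length(unique(reps$member_id)) >= 3L) {
    rep_ms <- ms[match(reps$member_id, ms$id), , drop = FALSE]
    aln <- align_progressive(rep_ms, config)
    corr <- if (rep_ms$alphabet[1L] == "protein") "poisson"
            else "jc_nucleotide"
    tree <- bootstrap_support(aln, config$bootstrap_replicates,
                              seed = derive_seed(config$rng_seed,
                                                 "bootstrap"),
                              correction = corr, on_undefined = "d_max")
    for (cid in retained)
      mono[as.character(cid)] <- is_monophyletic(
        tree, reps$member_id[reps$cluster_id == cid])
  } else if (length(retained)) {
    # too few representatives for a tree: a single retained cluster is
    # trivially congruent with (absent) tree structure
    mono[] <- TRUE
  }
  calls <- data.frame(
    cluster_id = info$cluster_id,
    verdict = NA_character_,
    environmental_only = info$environmental_only,
    member_count = info$n_members,
    full_length_count = info$n_full_length,
    monophyletic_in_representative_tree = NA,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(calls))) {
    cid <- calls$cluster_id[r]
    st <- info$status[r]
    if (st != "retained") {
      calls$verdict[r] <- st
      next
    }
    m <- mono[as.character(cid)]
    calls$monophyletic_in_representative_tree[r] <- m
    calls$verdict[r] <- if (!calls$environmental_only[r]) "known"
                        else if (isTRUE(m)) "novel"
                        else "non_monophyletic"
  }
  list(calls = calls, tree = tree, representatives = reps)
}

#' Majority-vote domain attribution for an assembly
#'
#' Tallies the domain assignments of the genes neighbouring a focal marker on
#' an assembly and reports the strict majority (plurality) domain;
#' `unassigned` neighbours do not vote, and any tie for the top count --
#' including an empty neighborhood -- yields `"ambiguous"`.
#'
#' @param neighborhood an [assembly_neighborhood()].
#' @return a list of class `domain_vote`: `assembly_id`, `counts` (named
#'   integer vector over the voting domains), `majority`.
#' @export
vote_assembly_domain <- function(neighborhood) {
  stopifnot(inherits(neighborhood, "assembly_neighborhood"))
  voters <- setdiff(ASSEMBLY_DOMAINS, "unassigned")
  da <- neighborhood$neighbors$domain_assignment
  counts <- setNames(vapply(voters, function(d) sum(da == d), 0L), voters)
  top <- max(counts, 0L)
  winners <- names(counts)[counts == top]
  majority <- if (top > 0L && length(winners) == 1L) winners else "ambiguous"
  structure(list(assembly_id = neighborhood$assembly_id, counts = counts,
                 majority = majority),
            class = "domain_vote")
}

#' @export
print.domain_vote <- function(x, ...) {
  cat(sprintf("assembly %s: majority = %s (%s)\n", x$assembly_id, x$majority,
              paste(sprintf("%s %d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Run the full protein screening pipeline
#'
#' Orchestrates simulate (optional) -> all-vs-all similarity -> Lek
#' clustering -> size/fragment filtering -> novelty calling -> per-assembly
#' domain voting, and returns a structured report.  Inputs may come from a
#' [simulation_spec()] (the synthetic path) or from a [marker_set()] plus an
#' optional pre-computed similarity edge table (the external-data path).
#'
#' @param config a [screen_config()].
#' @param sim_spec a [simulation_spec()], or `NULL` when `sequences` given.
#' @param sequences a [marker_set()], ignored when `sim_spec` is given.
#' @param similarity_edges optional edge data frame (e.g. from
#'   [read_similarity_table()]); when `NULL` the internal engine is used.
#' @param neighborhoods optional list of [assembly_neighborhood()] to vote on.
#' @return a list of class `screen_report`: `cluster_table`, `calls`,
#'   `votes`, `tree_newick`, `truth` (synthetic path only), and `manifest`
#'   (inputs, seed and every threshold used).
#' @export
run_pipeline <- function(config = screen_config(), sim_spec = NULL,
                         sequences = NULL, similarity_edges = NULL,
                         neighborhoods = NULL) {
  truth <- NULL
  if (!is.null(sim_spec)) {
    sim <- simulate_screen_inputs(sim_spec)
    sequences <- sim$sequences
    truth <- sim$truth
  }
  if (is.null(sequences))
    stop("configuration error: no input sequences (give sim_spec or ",
         "sequences)")
  graph <- if (!is.null(similarity_edges)) {
    similarity_graph(sequences$id, similarity_edges, config$evalue_cutoff)
  } else {
    all_vs_all_similarity(sequences, config)
  }
  clusters <- lek_cluster(graph, config$lek_score_cutoff)
  cs <- filter_clusters(clusters, sequences, config)
  nv <- call_novel_subfamilies(cs, sequences, graph, config)
  cluster_table <- merge(nv$calls,
                         cs$members,
                         by = "cluster_id")
  cluster_table <- cluster_table[order(cluster_table$cluster_id,
                                       cluster_table$member_id), ]
  rownames(cluster_table) <- NULL
  votes <- NULL
  if (!is.null(neighborhoods)) {
    votes <- do.call(rbind, lapply(neighborhoods, function(nb) {
      v <- vote_assembly_domain(nb)
      data.frame(assembly_id = v$assembly_id,
                 t(v$counts), majority = v$majority,
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    rownames(votes) <- NULL
  }
  manifest <- list(
    seed = config$rng_seed,
    thresholds = unclass(config),
    n_sequences = nrow(sequences),
    n_edges = nrow(graph$edges),
    simulated = !is.null(sim_spec)
  )
  structure(list(cluster_table = cluster_table, calls = nv$calls,
                 votes = votes,
                 tree_newick = if (!is.null(nv$tree))
                   ape::write.tree(nv$tree) else NA_character_,
                 truth = truth, manifest = manifest),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen report\n")
  cat(sprintf("  sequences: %d, similarity edges: %d\n",
              x$manifest$n_sequences, x$manifest$n_edges))
  cat("  verdicts:\n")
  print(table(x$calls$verdict))
  if (!is.null(x$votes)) {
    cat("  assembly votes:\n")
    print(x$votes)
  }
  invisible(x)
}

#' Write a screen report to TSV files
#'
#' Writes `clusters.tsv` (per-member cluster table), `calls.tsv` (per-cluster
#' verdicts), `votes.tsv` (when present), `tree.nwk` (when present) and a
#' YAML `manifest.yaml` recording the seed and every threshold.  Output is a
#' pure function of the report, so identical runs produce byte-identical
#' files.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$cluster_table, "clusters.tsv")
  tsv(report$calls, "calls.tsv")
  if (!is.null(report$votes)) tsv(report$votes, "votes.tsv")
  if (!is.na(report$tree_newick))
    writeLines(report$tree_newick, file.path(dir, "tree.nwk"))
  manifest <- report$manifest
  manifest$thresholds <- lapply(manifest$thresholds, function(v)
    if (is.null(v)) "unset" else v)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
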