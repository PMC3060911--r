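# Unrooted adjacency list of a phylo: for each node, the neighbouring node
# ids and the connecting branch lengths.
tree_adjacency <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- replicate(nn, list(node = integer(), len = numeric()),
                   simplify = FALSE)
  len <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge))
         else phy$edge.length
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    adj[[a]]$node <- c(adj[[a]]$node, b)
    adj[[a]]$len <- c(adj[[a]]$len, len[e])
    adj[[b]]$node <- c(adj[[b]]$node, a)
    adj[[b]]$len <- c(adj[[b]]$len, len[e])
  }
  adj
}

# leaves reachable from `start` without passing through `blocked`
component_leaves <- function(adj, ntip, start, blocked) {
  seen <- rep(FALSE, length(adj))
  seen[blocked] <- TRUE
  seen[start] <- TRUE
  queue <- start
  leaves <- integer()
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v <= ntip) leaves <- c(leaves, v)
    nxt <- adj[[v]]$node
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  leaves
}

#' Find the domain-separation nodes of a labelled tree
#'
#' A domain-separation node is an internal node whose removal splits the
#' leaves into components that are each pure for a single domain of life,
#' with at least three domains represented across the components -- the
#' junction of Bacteria, Archaea and Eukaryota in a three-domain tree.
#' Query leaves (environmental reads placed into the tree) are ignored
#' during the purity test, as are leaves labelled `"unknown"` or absent
#' from `domain_map`.
#'
#' @param phy an unrooted `phylo` (a rooted binary representation is treated
#'   as unrooted).
#' @param domain_map named character vector mapping leaf ids to domains.
#' @param ignore_leaves leaf ids excluded from the purity test.
#' @return integer vector of internal node ids (empty when no node
#'   qualifies, e.g. when a domain is not monophyletic).
#' @export
find_domain_separation_nodes <- function(phy, domain_map,
                                         ignore_leaves = character()) {
  ntip <- length(phy$tip.label)
  adj <- tree_adjacency(phy)
  lab <- domain_map[phy$tip.label]
  lab[phy$tip.label %in% ignore_leaves] <- NA
  lab[!is.na(lab) & lab == "unknown"] <- NA
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  keep <- integer()
  for (v in internal) {
    doms_per_comp <- lapply(adj[[v]]$node, function(u) {
      lv <- component_leaves(adj, ntip, u, v)
      unique(lab[lv][!is.na(lab[lv])])
    })
    sizes <- lengths(doms_per_comp)
    if (all(sizes <= 1L) &&
        length(unique(unlist(doms_per_comp))) >= 3L)
      keep <- c(keep, v)
  }
  keep
}

#' Topological depth of a query's attachment point
#'
#' Counts the internal nodes strictly between the attachment node of a query
#' leaf (the node it hangs from) and the nearest domain-separation node.
#' Attachment directly at a separation node scores 0; a query is
#' deep-branching when its score is at most `max_nodes` -- by default 2,
#' i.e. the attachment is "one or two nodes away" from (or at) the junction
#' of the three domains.
#'
#' @param phy a `phylo` containing `query_leaf`.
#' @param query_leaf the query's tip label.
#' @param sep_nodes internal node ids from [find_domain_separation_nodes()];
#'   must be non-empty (an empty set means the tree could not resolve three
#'   pure domains, and the query cannot be scored).
#' @param max_nodes deep-branch threshold (inclusive).
#' @return a list with integer `score` and logical `is_deep`.
#' @export
deep_branch_score <- function(phy, query_leaf, sep_nodes, max_nodes = 2L) {
  if (!length(sep_nodes))
    stop("undefined deep-branch score: no domain-separation node")
  tipno <- match(query_leaf, phy$tip.label)
  if (is.na(tipno)) stop("query leaf not in tree: ", query_leaf)
  adj <- tree_adjacency(phy)
  attach_node <- adj[[tipno]]$node[1L]
  # BFS from the attachment node counting intervening internal nodes
  ntip <- length(phy$tip.label)
  dist <- rep(NA_integer_, length(adj))
  dist[attach_node] <- 0L
  queue <- attach_node
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]$node) {
      if (u > ntip && is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  d <- dist[sep_nodes]
  score <- min(d, na.rm = TRUE) - 1L          # nodes strictly between
  score <- max(score, 0L)                      # attachment at the node itself
  list(score = as.integer(score), is_deep = score <= max_nodes)
}

#' Test whether a leaf set is monophyletic on an unrooted tree
#'
#' True when some edge's bipartition isolates exactly the given leaves;
#' singletons, sets of all leaves, and their complements of size one are
#' trivially monophyletic.
#'
#' @param phy a `phylo`.
#' @param leaf_set character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(phy, leaf_set) {
  tips <- phy$tip.label
  unknown <- setdiff(leaf_set, tips)
  if (length(unknown))
    stop("unknown leaf id(s): ", paste(unknown, collapse = ", "))
  leaf_set <- unique(leaf_set)
  k <- length(leaf_set)
  n <- length(tips)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  out <- setdiff(tips, leaf_set)[1L]
  rt <- ape::root(phy, outgroup = out, resolve.root = TRUE)
  m <- ape::getMRCA(rt, leaf_set)
  clade <- ape::extract.clade(rt, m)$tip.label
  setequal(clade, leaf_set)
}

#' Nearest labelled neighbour of a query leaf
#'
#' Assigns the query the label of the labelled leaf at minimum patristic
#' (branch-length) distance; exact ties across distinct labels return
#' `"ambiguous"`.
#'
#' @param phy a `phylo` with branch lengths.
#' @param query_leaf tip label of the query.
#' @param label_map named character vector of labels for (some) non-query
#'   leaves; leaves missing from the map or labelled `"unknown"`/`NA` do not
#'   vote.
#' @param tol distances within `tol` of the minimum count as ties.
#' @return a single label, or `"ambiguous"`.
#' @export
nearest_neighbor_label <- function(phy, query_leaf, label_map, tol = 1e-10) {
  if (!query_leaf %in% phy$tip.label)
    stop("query leaf not in tree: ", query_leaf)
  lm <- label_map[!is.na(label_map) & label_map != "unknown"]
  lm <- lm[names(lm) %in% setdiff(phy$tip.label, query_leaf)]
  if (!length(lm)) stop("no labelled leaves to assign from")
  d <- patristic_to_leaf(phy, query_leaf)[names(lm)]
  md <- min(d)
  labs <- unique(lm[d <= md + tol])
  if (length(labs) == 1L) unname(labs) else "ambiguous"
}

# patristic distance from one leaf to all leaves, by Dijkstra-free BFS
# (paths are unique on a tree)
patristic_to_leaf <- function(phy, leaf) {
  adj <- tree_adjacency(phy)
  ntip <- length(phy$tip.label)
  src <- match(leaf, phy$tip.label)
  dist <- rep(NA_real_, length(adj))
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    for (j in seq_along(nb$node)) {
      u <- nb$node[j]
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + nb$len[j]
        queue <- c(queue, u)
      }
    }
  }
  setNames(dist[seq_len(ntip)], phy$tip.label)
}

#' Bipartitions induced by the internal edges of a tree
#'
#' Each internal edge splits the leaves in two; the bipartition is encoded
#' canonically as the sorted leaf ids of the side not containing the
#' alphabetically first leaf, joined with `"|"`.  Used for bootstrap support
#' counting and topology comparison.
#'
#' @param phy a `phylo`.
#' @return a data frame with columns `node` (the edge's child node id) and
#'   `key` (canonical bipartition string); trivial (pendant) edges excluded.
#' @export
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1L]
  below <- clade_tip_cache(phy)
  child <- phy$edge[, 2L]
  internal <- child[child > ntip]
  keys <- vapply(internal, function(v) {
    side <- below[[v]]
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
  ok <- !is.na(keys)
  data.frame(node = internal[ok], key = keys[ok], stringsAsFactors = FALSE)
}
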