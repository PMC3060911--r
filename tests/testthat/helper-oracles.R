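# Independent brute-force oracles used to validate the package's tree
# queries.  These are deliberately naive re-derivations from the raw edge
# matrix, sharing no code with the implementation.

# leaves on the child side of every edge, by following edges away from the
# child; returns a list of character vectors indexed by edge number
oracle_edge_sides <- function(phy) {
  ntip <- length(phy$tip.label)
  lapply(seq_len(nrow(phy$edge)), function(e) {
    child <- phy$edge[e, 2L]
    got <- child
    repeat {
      more <- phy$edge[phy$edge[, 1L] %in% got, 2L]
      new <- setdiff(more, got)
      if (!length(new)) break
      got <- c(got, new)
    }
    phy$tip.label[got[got <= ntip]]
  })
}

oracle_monophyletic <- function(phy, set) {
  tips <- phy$tip.label
  if (length(set) <= 1L || length(set) >= length(tips) - 1L) return(TRUE)
  sides <- oracle_edge_sides(phy)
  any(vapply(sides, function(s) setequal(s, set) ||
               setequal(setdiff(tips, s), set), TRUE))
}

# exhaustive separation-node scan: for every internal node, collect the leaf
# sets of the components left by its removal and apply the purity rule
oracle_sep_nodes <- function(phy, dmap, ignore = character()) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  # symmetric neighbor lists straight from the edge matrix
  nbr <- lapply(seq_len(nn), function(v)
    c(phy$edge[phy$edge[, 1L] == v, 2L], phy$edge[phy$edge[, 2L] == v, 1L]))
  lab <- dmap[phy$tip.label]
  lab[phy$tip.label %in% ignore | lab == "unknown"] <- NA
  found <- integer()
  for (v in (ntip + 1L):nn) {
    comps <- lapply(nbr[[v]], function(start) {
      seen <- c(v, start)
      frontier <- start
      while (length(frontier)) {
        nxt <- setdiff(unlist(nbr[frontier]), seen)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
      doms <- lab[phy$tip.label[intersect(seen, seq_len(ntip))]]
      unique(doms[!is.na(doms)])
    })
    if (all(lengths(comps) <= 1L) &&
        length(unique(unlist(comps))) >= 3L)
      found <- c(found, v)
  }
  found
}

# a random unrooted-looking binary tree with positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.05, 1)
  phy
}

rand_protein <- function(n, len) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  vapply(seq_len(n), function(i) paste(sample(aa, len, TRUE), collapse = ""),
         "")
}

# majority true subfamily of each cluster, for sensitivity bookkeeping
cluster_truth_label <- function(members, truth) {
  tab <- table(truth$true_subfamily[match(members, truth$id)])
  names(tab)[which.max(tab)]
}
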