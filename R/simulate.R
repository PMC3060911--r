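#' Simulation specification
#'
#' Parameters of the synthetic study system: a three-domain phylogeny with
#' optional planted divergent lineages and ancient paralogous families, over
#' which marker sequences are evolved.  Defaults describe the standard
#' protein-marker scenario used throughout the package's validation: eight
#' taxa per domain, five paralogous families arising from ancient
#' whole-superfamily duplications, and one planted environmental-only
#' five-member lineage attached at the domain-separation node with a long
#' (1.8 substitutions/site) stem, on a 500-residue marker.
#'
#' Branch-length units are expected substitutions per site throughout.
#' `domain_stem_length` is the stem joining each domain clade to the
#' separation node; `within_domain_depth` is the mean root-to-tip path inside
#' a domain clade; `paralog_stem_length` is the stem from the duplication
#' root to each family copy, so two families are separated by at least twice
#' that value.
#'
#' @param taxa_per_domain leaves per domain clade (>= 2).
#' @param domain_stem_length stem length from separation node to each domain.
#' @param within_domain_depth mean root-to-tip depth inside a domain clade.
#' @param novel_lineages list of planted lineages, each a list with fields
#'   `n_taxa`, `stem_length`, `attach_policy` (`"at_separation_node"` or
#'   `"within_domain"`), and for the latter `domain` and `min_depth`.
#' @param n_paralog_families number of paralogous copies of the three-domain
#'   tree under a common duplication root (1 = no paralogy).
#' @param paralog_stem_length stem length per family copy.
#' @param root_sequence_length marker length in residues.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param environmental_fraction fraction of non-planted sequences relabelled
#'   as environmental (their domain becomes `"unknown"`).
#' @param fragment_fraction fraction of environmental sequences truncated to
#'   a fragment (0 disables).
#' @param fragment_length_range integer range of fragment lengths.
#' @param rng_seed master seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(taxa_per_domain = 8L,
                            domain_stem_length = 0.15,
                            within_domain_depth = 0.25,
                            novel_lineages = list(list(
                              n_taxa = 5L, stem_length = 1.8,
                              attach_policy = "at_separation_node")),
                            n_paralog_families = 5L,
                            paralog_stem_length = 1.25,
                            root_sequence_length = 500L,
                            alphabet = "protein",
                            environmental_fraction = 0.3,
                            fragment_fraction = 0,
                            fragment_length_range = c(200L, 400L),
                            rng_seed = 1L) {
  spec <- list(taxa_per_domain = as.integer(taxa_per_domain),
               domain_stem_length = domain_stem_length,
               within_domain_depth = within_domain_depth,
               novel_lineages = novel_lineages,
               n_paralog_families = as.integer(n_paralog_families),
               paralog_stem_length = paralog_stem_length,
               root_sequence_length = as.integer(root_sequence_length),
               alphabet = match.arg(alphabet, names(ALPHABETS)),
               environmental_fraction = environmental_fraction,
               fragment_fraction = fragment_fraction,
               fragment_length_range = as.integer(fragment_length_range),
               rng_seed = as.integer(rng_seed))
  class(spec) <- "simulation_spec"
  if (spec$taxa_per_domain < 2L)
    stop("taxa_per_domain must be at least 2")
  if (spec$root_sequence_length < 1L)
    stop("root_sequence_length must be positive")
  if (spec$environmental_fraction < 0 || spec$environmental_fraction > 1)
    stop("environmental_fraction must lie in [0, 1]")
  if (spec$fragment_fraction < 0 || spec$fragment_fraction > 1)
    stop("fragment_fraction must lie in [0, 1]")
  if (any(c(spec$domain_stem_length, spec$within_domain_depth,
            spec$paralog_stem_length) < 0))
    stop("branch-length parameters must be non-negative")
  spec
}

DOMAINS3 <- c("Bacteria", "Archaea", "Eukaryota")

# random rooted clade topology with exponential branch lengths rescaled so the
# mean root-to-tip path equals `depth` (uses the current RNG stream)
rand_clade <- function(n, depth, labels) {
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  phy$tip.label <- labels
  phy$edge.length <- stats::rexp(nrow(phy$edge))
  d <- mean(ape::node.depth.edgelength(phy)[seq_len(n)])
  if (d > 0) phy$edge.length <- phy$edge.length * depth / d
  phy
}

# strip the trailing ";" so a written tree can be used as a subtree string
as_subtree <- function(phy) sub(";$", "", ape::write.tree(phy, digits = 10))

#' Leaf metadata table for simulated trees
#'
#' @param id leaf ids.
#' @param domain_label,source,true_subfamily per-leaf metadata (recycled).
#' @return a data frame with one row per leaf.
#' @keywords internal
leaf_data <- function(id, domain_label, source = "reference",
                      true_subfamily = NA_character_) {
  data.frame(id = id,
             domain_label = rep_len(domain_label, length(id)),
             source = rep_len(source, length(id)),
             true_subfamily = rep_len(true_subfamily, length(id)),
             stringsAsFactors = FALSE)
}

#' A tree with per-leaf domain and source labels
#'
#' @param phy a `phylo`.
#' @param leaves a data frame as built by `leaf_data()` covering every tip.
#' @return a list of class `labeled_tree` with elements `phy` and `leaves`.
#' @export
labeled_tree <- function(phy, leaves) {
  stopifnot(inherits(phy, "phylo"))
  if (!setequal(phy$tip.label, leaves$id))
    stop("leaf metadata must cover exactly the tree's tips")
  leaves <- leaves[match(phy$tip.label, leaves$id), , drop = FALSE]
  rownames(leaves) <- NULL
  structure(list(phy = phy, leaves = leaves), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("labeled tree: %d tips\n", length(x$phy$tip.label)))
  print(table(x$leaves$domain_label))
  invisible(x)
}

# named domain vector for tree queries
domain_map <- function(lt) setNames(lt$leaves$domain_label, lt$leaves$id)

#' Simulate a three-domain phylogeny
#'
#' Builds an unrooted tree of three domain-pure clades (Bacteria, Archaea,
#' Eukaryota) joined at a single internal node -- the domain-separation node.
#' Within-clade topologies are random; branch lengths are exponential,
#' rescaled so the mean root-to-tip depth of each clade equals
#' `within_domain_depth`.
#'
#' @param taxa_per_domain leaves per domain (>= 2).
#' @param domain_stem_length stem length from the separation node to each
#'   domain clade.
#' @param within_domain_depth mean root-to-tip depth within clades.
#' @param seed integer seed.
#' @param tip_prefix optional prefix for the tip labels.
#' @return a [labeled_tree()] whose tips are named
#'   `<prefix><Domain>_<i>`.
#' @export
#' @examples
#' lt <- simulate_domain_tree(4, seed = 7)
#' find_domain_separation_nodes(lt$phy, domain_map = setNames(
#'   lt$leaves$domain_label, lt$leaves$id))
simulate_domain_tree <- function(taxa_per_domain,
                                 domain_stem_length = 0.15,
                                 within_domain_depth = 0.25,
                                 seed = 1L,
                                 tip_prefix = "") {
  if (taxa_per_domain < 2L)
    stop("taxa_per_domain must be at least 2")
  with_seed(seed, {
    clades <- lapply(DOMAINS3, function(d) {
      rand_clade(taxa_per_domain, within_domain_depth,
                 paste0(tip_prefix, d, "_", seq_len(taxa_per_domain)))
    })
    nwk <- paste0("(", paste0(vapply(clades, as_subtree, ""), ":",
                              format(domain_stem_length, digits = 10),
                              collapse = ","), ");")
    phy <- ape::read.tree(text = nwk)
    lv <- leaf_data(phy$tip.label,
                    domain_label = rep(DOMAINS3,
                                       each = taxa_per_domain)[
                      match(phy$tip.label,
                            unlist(lapply(clades, `[[`, "tip.label")))])
    labeled_tree(phy, lv)
  })
}

# number of internal nodes on the path from `from` (excluded) to each node,
# counting the node itself; computed by BFS on the unrooted adjacency
node_depths_from <- function(phy, from) {
  adj <- tree_adjacency(phy)
  n_node <- length(adj)
  depth <- rep(NA_integer_, n_node)
  depth[from] <- 0L
  queue <- from
  ntip <- length(phy$tip.label)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]$node) {
      if (is.na(depth[u])) {
        depth[u] <- depth[v] + if (u > ntip) 1L else 0L
        queue <- c(queue, u)
      }
    }
  }
  depth
}

#' Plant a divergent lineage on a three-domain tree
#'
#' Attaches a clade of `n_taxa` environmental leaves by a stem of
#' `stem_length` either directly at the domain-separation node
#' (`"at_separation_node"` -- the deeply branching, "fourth domain" scenario)
#' or inside a named domain clade at a topological depth of at least
#' `min_depth` internal nodes from the separation node (`"within_domain"` --
#' the divergent-but-classifiable control).
#'
#' @param lt a [labeled_tree()] from [simulate_domain_tree()].
#' @param n_taxa number of planted leaves (>= 1).
#' @param stem_length stem branch length.
#' @param attach_policy `"at_separation_node"` or `"within_domain"`.
#' @param domain domain clade name for `"within_domain"`.
#' @param min_depth minimum internal-node depth of the attachment point
#'   (only for `"within_domain"`).
#' @param clade_depth mean root-to-tip depth of the planted clade.
#' @param seed integer seed.
#' @param label_prefix prefix for the planted tip labels; also their
#'   `true_subfamily`.
#' @param ignore_leaves leaf ids excluded from the separation-node purity
#'   test (used when the tree carries several paralogous families).
#' @return a [labeled_tree()] with the planted leaves labelled
#'   `source = "environmental"`, `domain_label = "unknown"`.
#' @export
plant_novel_lineage <- function(lt, n_taxa, stem_length,
                                attach_policy = c("at_separation_node",
                                                  "within_domain"),
                                domain = NULL, min_depth = 3L,
                                clade_depth = 0.15, seed = 1L,
                                label_prefix = "novel1",
                                ignore_leaves = character()) {
  attach_policy <- match.arg(attach_policy)
  phy <- lt$phy
  dm <- domain_map(lt)
  sep <- find_domain_separation_nodes(phy, dm, ignore_leaves = ignore_leaves)
  if (!length(sep))
    stop("tree has no domain-separation node; cannot plant a lineage")
  sep <- sep[1L]
  labels <- paste0(label_prefix, "_", seq_len(n_taxa))
  with_seed(seed, {
    if (n_taxa >= 2L) {
      clade <- rand_clade(n_taxa, clade_depth, labels)
    } else {
      # single tip: bind a zero-length cherry, then drop the placeholder so
      # the surviving pendant edge has exactly the stem length
      clade <- ape::read.tree(text = paste0("(", labels, ":0,..drop..:0);"))
    }
    clade$root.edge <- stem_length
    if (attach_policy == "at_separation_node") {
      out <- ape::bind.tree(phy, clade, where = sep, position = 0)
    } else {
      if (is.null(domain) || !domain %in% lt$leaves$domain_label)
        stop("attach_policy 'within_domain' needs a domain present in the ",
             "tree")
      depth <- node_depths_from(phy, sep)
      ntip <- length(phy$tip.label)
      dom_leaves <- setdiff(lt$leaves$id[lt$leaves$domain_label == domain],
                            ignore_leaves)
      # candidate edges (parent, child) inside the domain clade whose parent
      # already has >= min_depth internal nodes between it and the separation
      # node; attaching mid-edge then guarantees a deep-branch score of at
      # least min_depth for the planted leaves
      below <- clade_tip_cache(phy)
      cand <- which(vapply(seq_len(nrow(phy$edge)), function(e) {
        p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
        tips_below <- below[[ch]]
        p != sep && depth[p] >= min_depth &&
          all(tips_below %in% dom_leaves)
      }, TRUE))
      if (!length(cand))
        stop("domain clade too shallow to plant at min_depth = ", min_depth)
      e <- if (length(cand) == 1L) cand else sample(cand, 1L)
      out <- ape::bind.tree(phy, clade, where = phy$edge[e, 2L],
                            position = phy$edge.length[e] / 2)
    }
    if (n_taxa == 1L) out <- ape::drop.tip(out, "..drop..")
    lv <- rbind(lt$leaves,
                leaf_data(labels, domain_label = "unknown",
                          source = "environmental",
                          true_subfamily = label_prefix))
    labeled_tree(out, lv)
  })
}

# tips below each node of a rooted phylo (list indexed by node id)
clade_tip_cache <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Evolve sequences along a tree
#'
#' A Jukes-Cantor-type equal-rates substitution process on the 4-letter
#' nucleotide or 20-letter amino-acid alphabet: the root sequence is uniform
#' over the alphabet, and along each branch of length `b` every site is
#' replaced, with probability `1 - exp(-b * k/(k-1))` (`k` = alphabet size),
#' by a state drawn uniformly from the other `k - 1` states.  This
#' parameterization makes the expected fraction of differing sites between a
#' parent and child exactly `1 - exp(-b * k/(k-1))`, giving the simulator a
#' closed form to be validated against.
#'
#' @param phy a `phylo` with non-negative branch lengths in expected
#'   substitutions/site.
#' @param root_length sequence length in residues.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param seed integer seed.
#' @return a named character vector of tip sequences.
#' @export
evolve_sequences <- function(phy, root_length,
                             alphabet = c("protein", "nucleotide"),
                             seed = 1L) {
  alphabet <- match.arg(alphabet)
  if (any(phy$edge.length < 0))
    stop("negative branch length in tree")
  chars <- ALPHABETS[[alphabet]]
  k <- length(chars)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  L <- as.integer(root_length)
  with_seed(seed, {
    states <- matrix(NA_integer_, nn, L)
    root <- ntip + 1L
    states[root, ] <- sample.int(k, L, replace = TRUE)
    cw <- ape::reorder.phylo(phy, "cladewise")  # parents precede children
    for (e in seq_len(nrow(cw$edge))) {
      par <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]
      b <- cw$edge.length[e]
      s <- states[par, ]
      p_sub <- 1 - exp(-b * k / (k - 1))
      hit <- stats::runif(L) < p_sub
      if (any(hit)) {
        shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% k) + 1L
      }
      states[ch, ] <- s
    }
    seqs <- vapply(seq_len(ntip),
                   function(i) paste(chars[states[i, ]], collapse = ""), "")
    setNames(seqs, phy$tip.label)
  })
}

#' Truncate environmental sequences to fragments
#'
#' Replaces a fraction of the environmental sequences by one contiguous
#' substring whose length is uniform over `range`, with a uniform start
#' position, and flags them with `is_fragment`.  This emulates the short
#' fragmentary peptides that dominate some metagenomic clusters.
#'
#' @param ms a [marker_set()].
#' @param range integer `(min, max)` fragment length; `max` must not exceed
#'   the shortest environmental sequence.
#' @param fraction fraction of environmental sequences to truncate.
#' @param seed integer seed.
#' @return the marker set with truncated residues and `is_fragment` set.
#' @export
fragment_sequences <- function(ms, range, fraction, seed = 1L) {
  range <- as.integer(range)
  if (length(range) != 2L || range[1L] > range[2L] || range[1L] < 1L)
    stop("range must be an increasing pair of positive lengths")
  env <- which(ms$source == "environmental")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!length(env) || fraction == 0) return(ms)
  if (range[2L] > min(nchar(ms$residues[env])))
    stop("fragment range exceeds the shortest environmental sequence")
  n_sel <- round(fraction * length(env))
  if (n_sel == 0) return(ms)
  with_seed(seed, {
    sel <- if (n_sel == length(env)) env else sort(sample(env, n_sel))
    lens <- if (range[1L] == range[2L]) rep(range[1L], length(sel))
            else sample(seq(range[1L], range[2L]), length(sel),
                        replace = TRUE)
    for (j in seq_along(sel)) {
      i <- sel[j]
      full <- nchar(ms$residues[i])
      start <- sample.int(full - lens[j] + 1L, 1L)
      ms$residues[i] <- substr(ms$residues[i], start, start + lens[j] - 1L)
      ms$is_fragment[i] <- TRUE
    }
    ms
  })
}

#' Simulate an assembly neighborhood with known domain composition
#'
#' Lays out the requested numbers of neighbouring genes on non-overlapping
#' intervals around a focal marker gene, each carrying the requested
#' domain assignment -- the input expected by [vote_assembly_domain()].
#'
#' @param focal_id id of the focal marker gene.
#' @param neighbor_domain_counts named integer vector, e.g.
#'   `c(Archaea = 3, Bacteria = 1)`; names must be valid domain assignments.
#' @param seed integer seed (strands are random).
#' @param assembly_id assembly identifier.
#' @param gene_length,spacer layout parameters in bp.
#' @return an [assembly_neighborhood()].
#' @export
simulate_assembly <- function(focal_id, neighbor_domain_counts, seed = 1L,
                              assembly_id = paste0("asm_", focal_id),
                              gene_length = 900L, spacer = 100L) {
  counts <- neighbor_domain_counts
  if (any(counts < 0)) stop("neighbor counts must be non-negative")
  if (!all(names(counts) %in% ASSEMBLY_DOMAINS))
    stop("unknown domain assignment in counts: ",
         paste(setdiff(names(counts), ASSEMBLY_DOMAINS), collapse = ", "))
  doms <- rep(names(counts), times = counts)
  n <- length(doms)
  step <- gene_length + spacer
  # focal gene sits first; neighbors follow downstream
  starts <- 1L + step * seq_len(n)
  with_seed(seed, {
    nb <- data.frame(
      gene_id = if (n) paste0(assembly_id, "_g", seq_len(n)) else character(),
      start = starts,
      end = starts + gene_length - 1L,
      strand = if (n) sample(c("+", "-"), n, replace = TRUE) else character(),
      description = if (n) paste0(doms, "-like protein ", seq_len(n))
                    else character(),
      domain_assignment = doms,
      stringsAsFactors = FALSE
    )
    assembly_neighborhood(assembly_id, focal_id, nb)
  })
}

#' Simulate a full protein-screen input set
#'
#' Generates the complete synthetic study system described by a
#' [simulation_spec()]: one three-domain tree duplicated into
#' `n_paralog_families` paralogous copies under a common root (emulating
#' ancient gene duplications), planted novel lineages attached to the first
#' family's separation node or within one of its domains, sequences evolved
#' over the joint tree, a random subset of non-planted leaves relabelled as
#' environmental reads, and optional fragmentation.
#'
#' @param spec a [simulation_spec()].
#' @return a list with elements `sequences` (a [marker_set()]; environmental
#'   rows have `domain_label = "unknown"`), `truth` (data frame `id`,
#'   `domain`, `true_subfamily`, `planted`), and `tree` (a [labeled_tree()]
#'   over all sequences).
#' @export
#' @examples
#' sim <- simulate_screen_inputs(simulation_spec(taxa_per_domain = 3,
#'   n_paralog_families = 2, root_sequence_length = 120, rng_seed = 42))
#' table(sim$truth$true_subfamily)
simulate_screen_inputs <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  seed <- spec$rng_seed
  base <- simulate_domain_tree(spec$taxa_per_domain,
                               spec$domain_stem_length,
                               spec$within_domain_depth,
                               seed = derive_seed(seed, "base_topology"))
  nfam <- spec$n_paralog_families
  fam_ids <- paste0("family", seq_len(nfam))
  copies <- lapply(seq_len(nfam), function(f) {
    cp <- base$phy
    cp$tip.label <- paste0(fam_ids[f], "_", cp$tip.label)
    cp
  })
  if (nfam > 1L) {
    nwk <- paste0("(", paste0(vapply(copies, as_subtree, ""), ":",
                              format(spec$paralog_stem_length, digits = 10),
                              collapse = ","), ");")
    phy <- ape::read.tree(text = nwk)
  } else {
    phy <- copies[[1L]]
  }
  lv <- do.call(rbind, lapply(seq_len(nfam), function(f) {
    leaf_data(paste0(fam_ids[f], "_", base$leaves$id),
              domain_label = base$leaves$domain_label,
              true_subfamily = fam_ids[f])
  }))
  lt <- labeled_tree(phy, lv)
  # planted lineages attach relative to family 1's separation node; leaves of
  # the other families are ignored during the purity test
  for (j in seq_along(spec$novel_lineages)) {
    nl <- spec$novel_lineages[[j]]
    fam1 <- startsWith(lt$leaves$id, paste0(fam_ids[1L], "_"))
    planted <- is.na(lt$leaves$true_subfamily) |
      !lt$leaves$true_subfamily %in% fam_ids
    ignore <- lt$leaves$id[(!fam1) | planted]
    lt <- plant_novel_lineage(
      lt, n_taxa = nl$n_taxa, stem_length = nl$stem_length,
      attach_policy = nl$attach_policy,
      domain = nl$domain,
      min_depth = if (!is.null(nl$min_depth)) nl$min_depth else 3L,
      seed = derive_seed(seed, paste0("plant", j)),
      label_prefix = paste0("novel", j),
      ignore_leaves = ignore)
  }
  seqs <- evolve_sequences(lt$phy, spec$root_sequence_length,
                           alphabet = spec$alphabet,
                           seed = derive_seed(seed, "evolve"))
  lv <- lt$leaves
  # environmental relabelling of non-planted leaves
  n_known <- sum(lv$source == "reference")
  n_env <- round(spec$environmental_fraction * n_known)
  if (n_env > 0) {
    idx <- which(lv$source == "reference")
    sel <- with_seed(derive_seed(seed, "env"), sort(sample(idx, n_env)))
    lv$source[sel] <- "environmental"
  }
  truth <- data.frame(id = lv$id,
                      domain = lv$domain_label,
                      true_subfamily = lv$true_subfamily,
                      planted = !lv$true_subfamily %in% fam_ids,
                      stringsAsFactors = FALSE)
  ms <- marker_set(lv$id, seqs[lv$id], spec$alphabet,
                   source = lv$source,
                   domain_label = ifelse(lv$source == "environmental",
                                         "unknown", lv$domain_label),
                   true_subfamily = lv$true_subfamily,
                   is_fragment = FALSE)
  if (spec$fragment_fraction > 0)
    ms <- fragment_sequences(ms, spec$fragment_length_range,
                             spec$fragment_fraction,
                             seed = derive_seed(seed, "fragment"))
  list(sequences = ms, truth = truth, tree = lt)
}

#' Simulate a labelled rRNA reference alignment
#'
#' Builds a three-domain nucleotide phylogeny, evolves full-length sequences
#' over it, and returns them as a gap-free reference alignment with per-row
#' domain labels -- the synthetic stand-in for a curated set of
#' representative small-subunit rRNA sequences.  Because the simulator is
#' substitution-only, homologous sites stay in register and the raw
#' sequences already form a valid alignment.
#'
#' @param taxa_per_domain leaves per domain.
#' @param domain_stem_length,within_domain_depth tree shape parameters
#'   (see [simulate_domain_tree()]).
#' @param root_length alignment length in bases.
#' @param seed integer seed.
#' @return a list with `aln` (a [ref_alignment()]), `tree` (a
#'   [labeled_tree()]).
#' @export
simulate_rrna_reference <- function(taxa_per_domain = 8L,
                                    domain_stem_length = 0.30,
                                    within_domain_depth = 0.25,
                                    root_length = 1200L,
                                    seed = 1L) {
  lt <- simulate_domain_tree(taxa_per_domain, domain_stem_length,
                             within_domain_depth,
                             seed = derive_seed(seed, "rrna_tree"))
  seqs <- evolve_sequences(lt$phy, root_length, alphabet = "nucleotide",
                           seed = derive_seed(seed, "rrna_evolve"))
  aln <- ref_alignment(seqs, domain_label = domain_map(lt))
  list(aln = aln, tree = lt)
}

#' Simulate an rRNA screening case with a planted query
#'
#' Plants a single environmental query on a three-domain rRNA tree (either at
#' the separation node or inside a domain at a given depth), evolves
#' sequences over the joint tree, and returns the reference alignment
#' (query excluded) together with the query read, optionally truncated to a
#' fragment.
#'
#' @inheritParams simulate_rrna_reference
#' @param attach_policy,domain,min_depth,query_stem placement of the planted
#'   query (see [plant_novel_lineage()]).
#' @param fragment_length if non-`NULL`, the query is truncated to this many
#'   bases.
#' @param seed integer seed.
#' @return a list with `aln` (reference [ref_alignment()]), `query`
#'   (a one-row [marker_set()]), and `tree` (the true [labeled_tree()]).
#' @export
simulate_rrna_case <- function(taxa_per_domain = 8L,
                               domain_stem_length = 0.30,
                               within_domain_depth = 0.25,
                               root_length = 1200L,
                               attach_policy = "at_separation_node",
                               domain = NULL, min_depth = 3L,
                               query_stem = 0.8,
                               fragment_length = NULL,
                               seed = 1L) {
  lt <- simulate_domain_tree(taxa_per_domain, domain_stem_length,
                             within_domain_depth,
                             seed = derive_seed(seed, "rrna_tree"))
  lt <- plant_novel_lineage(lt, n_taxa = 1L, stem_length = query_stem,
                            attach_policy = attach_policy, domain = domain,
                            min_depth = min_depth,
                            seed = derive_seed(seed, "rrna_plant"),
                            label_prefix = "query")
  seqs <- evolve_sequences(lt$phy, root_length, alphabet = "nucleotide",
                           seed = derive_seed(seed, "rrna_evolve"))
  qid <- "query_1"
  ref_ids <- setdiff(names(seqs), qid)
  dm <- domain_map(lt)[ref_ids]
  aln <- ref_alignment(seqs[ref_ids], domain_label = dm)
  query <- marker_set(qid, seqs[qid], "nucleotide", source = "environmental")
  if (!is.null(fragment_length))
    query <- fragment_sequences(query, c(fragment_length, fragment_length),
                                fraction = 1,
                                seed = derive_seed(seed, "rrna_fragment"))
  list(aln = aln, query = query, tree = lt)
}
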