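graph_from_pairs <- function(nodes, pairs) {
  edges <- data.frame(id_a = vapply(pairs, `[`, "", 1L),
                      id_b = vapply(pairs, `[`, "", 2L),
                      bit_score = rep(100, length(pairs)),
                      expect = rep(1e-50, length(pairs)),
                      stringsAsFactors = FALSE)
  similarity_graph(nodes, edges, 1e-40)
}

clique_pairs <- function(ids) {
  cc <- utils::combn(ids, 2)
  lapply(seq_len(ncol(cc)), function(i) cc[, i])
}

# exhaustive agglomeration oracle: explore every legal merge sequence and
# collect all terminal partitions
all_terminal_partitions <- function(adj, cutoff) {
  results <- list()
  recurse <- function(clusters) {
    n <- length(clusters)
    legal <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cross <- sum(adj[clusters[[i]], clusters[[j]]])
      if (cross / (length(clusters[[i]]) * length(clusters[[j]])) >=
            cutoff)
        legal <- c(legal, list(c(i, j)))
    }
    if (!length(legal)) {
      key <- paste(sort(vapply(clusters,
                               function(cl) paste(sort(cl), collapse = ","),
                               "")), collapse = ";")
      results[[key]] <<- TRUE
      return()
    }
    for (p in legal) {
      merged <- clusters
      merged[[p[1]]] <- c(merged[[p[1]]], merged[[p[2]]])
      merged[[p[2]]] <- NULL
      recurse(merged)
    }
  }
  recurse(as.list(rownames(adj)))
  names(results)
}

test_that("cliques merge into one cluster and edgeless graphs stay
           singletons", {
  g <- graph_from_pairs(letters[1:5], clique_pairs(letters[1:5]))
  cl <- lek_cluster(g, 0.10)
  expect_equal(max(cl$cluster_id), 1L)
  expect_setequal(cl$member_id, letters[1:5])

  g0 <- graph_from_pairs(letters[1:4], list())
  cl0 <- lek_cluster(g0, 0.10)
  expect_equal(max(cl0$cluster_id), 4L)
})

test_that("two 3-cliques joined by one edge merge at cutoff 0.10 but not at
           0.60, in agreement with exhaustive agglomeration", {
  nodes <- letters[1:6]
  pairs <- c(clique_pairs(letters[1:3]), clique_pairs(letters[4:6]),
             list(c("c", "d")))
  g <- graph_from_pairs(nodes, pairs)
  # L between the cliques = 1/9 ~ 0.111
  lo <- lek_cluster(g, 0.10)
  expect_equal(max(lo$cluster_id), 1L)
  hi <- lek_cluster(g, 0.60)
  expect_equal(max(hi$cluster_id), 2L)
  expect_setequal(hi$member_id[hi$cluster_id == 1], letters[1:3])
  expect_setequal(hi$member_id[hi$cluster_id == 2], letters[4:6])

  adj <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  for (p in pairs) adj[p[1], p[2]] <- adj[p[2], p[1]] <- 1
  # the greedy best-merge partition is a valid terminal state of
  # unconstrained agglomeration (some merge orders stall before completing
  # the cliques, which is why the implementation merges best-first)
  terminals <- all_terminal_partitions(adj, 0.60)
  expect_true("a,b,c;d,e,f" %in% terminals)
  # at the permissive cutoff every merge order reaches the single cluster
  expect_equal(all_terminal_partitions(adj, 0.10), "a,b,c,d,e,f")
})

test_that("clustering is invariant to node order and monotone in the
           cutoff", {
  for (s in 1:5) {
    set.seed(s)
    nodes <- paste0("n", sample(20))
    cc <- utils::combn(sort(nodes), 2)
    on <- sample(ncol(cc), 60)
    pairs <- lapply(on, function(i) cc[, i])
    g1 <- graph_from_pairs(sort(nodes), pairs)
    g2 <- graph_from_pairs(nodes, rev(pairs))
    c1 <- lek_cluster(g1, 0.25)
    c2 <- lek_cluster(g2, 0.25)
    expect_equal(c1, c2)
    # coarse clusters are unions of fine clusters
    fine <- lek_cluster(g1, 0.60)
    co <- c1$cluster_id[match(fine$member_id, c1$member_id)]
    expect_true(all(tapply(co, fine$cluster_id,
                           function(v) length(unique(v))) == 1L))
  }
})

test_that("cluster filters reproduce the size and fragment exclusion
           rules", {
  ms <- marker_set(
    c("a1", "a2", "b1", "b2", "b3", "b4", "c1", "c2", "c3"),
    c(strrep("M", 450), strrep("K", 450),
      strrep("A", 350), strrep("C", 350), strrep("D", 350), strrep("E", 450),
      strrep("F", 500), strrep("G", 500), strrep("H", 500)),
    "protein",
    source = c("environmental", "environmental",
               "environmental", "environmental", "environmental",
               "environmental",
               "reference", "environmental", "environmental"))
  clusters <- data.frame(
    cluster_id = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
    member_id = ms$id)
  class(clusters) <- c("lek_clusters", "data.frame")

  cs <- filter_clusters(clusters, ms, screen_config(min_peptide_length = 400))
  info <- cs$clusters
  expect_equal(info$status, c("excluded_small", "excluded_fragment",
                              "retained"))
  # median of cluster 2 lengths (350,350,350,450) = 350 < 400
  expect_true(info$fragment_dominated[2])
  expect_equal(info$environmental_only, c(TRUE, TRUE, FALSE))

  # all-fragment clusters are excluded even without a length threshold
  ms$is_fragment[3:6] <- TRUE
  cs2 <- filter_clusters(clusters, ms, screen_config())
  expect_equal(cs2$clusters$status[2], "excluded_fragment")
})

test_that("representative selection is deterministic and matches a
           brute-force medoid scan", {
  # 3-member path graph: b is the middle member
  epath <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                      bit_score = c(50, 50), expect = 1e-50)
  g <- similarity_graph(c("a", "b", "c"), epath, 1e-40)
  ms <- marker_set(c("a", "b", "c"), rep(strrep("M", 100), 3), "protein")
  expect_equal(select_representatives(c("a", "b", "c"), g, 1, ms), "b")

  # |cluster| <= k returns everything
  expect_equal(select_representatives(c("a", "b"), g, 3, ms), c("a", "b"))

  # randomized instances vs exhaustive search over all k-subsets
  for (s in 1:5) {
    set.seed(s)
    ids <- paste0("m", 1:7)
    cc <- utils::combn(ids, 2)
    e <- data.frame(id_a = cc[1, ], id_b = cc[2, ],
                    bit_score = round(runif(ncol(cc), 10, 90)),
                    expect = 1e-50)
    gg <- similarity_graph(ids, e, 1e-40)
    lens <- sample(200:400, 7)
    mm <- marker_set(ids, vapply(lens, function(l) strrep("M", l), ""),
                     "protein")
    k <- 3
    sel <- select_representatives(ids, gg, k, mm)
    expect_length(sel, k)
    forced <- ids[order(-lens, ids)][1]
    expect_true(forced %in% sel)
    # brute force over subsets containing the forced member
    S <- matrix(0, 7, 7, dimnames = list(ids, ids))
    S[cbind(e$id_a, e$id_b)] <- e$bit_score
    S[cbind(e$id_b, e$id_a)] <- e$bit_score
    diag(S) <- max(S) + 1
    obj <- function(sub) mean(apply(S[, sub, drop = FALSE], 1, max))
    subs <- utils::combn(setdiff(ids, forced), k - 1, simplify = FALSE)
    best <- max(vapply(subs, function(x) obj(c(forced, x)), 0))
    expect_equal(obj(sel), best)
    expect_identical(sel, select_representatives(ids, gg, k, mm))
  }
})
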