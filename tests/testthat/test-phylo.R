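toy_aln <- function(rows, domains = NULL) {
  ref_alignment(rows, domain_label = domains)
}

test_that("column filtering removes exactly the columns above the gap
           threshold", {
  # 10 rows; column 1: 9 gaps (0.9, retained); column 2: 10 gaps (removed);
  # column 3: gap-free
  m <- matrix("A", 10, 3)
  m[1:9, 1] <- "-"
  m[, 2] <- "-"
  rownames(m) <- paste0("r", 1:10)
  aln <- ref_alignment(m)
  out <- filter_alignment_columns(aln, 0.90)
  expect_equal(ncol(out$mat), 2L)
  expect_equal(attr(out, "kept_columns"), c(1L, 3L))
  # gap-free alignment unchanged
  clean <- ref_alignment(matrix("A", 4, 5,
                                dimnames = list(paste0("s", 1:4), NULL)))
  expect_equal(filter_alignment_columns(clean)$mat, clean$mat)
  allgap <- ref_alignment(matrix("-", 4, 2,
                                 dimnames = list(paste0("s", 1:4), NULL)))
  expect_error(filter_alignment_columns(allgap), "every column")
})

test_that("a query equal to a reference row is placed in exactly that row's
           columns", {
  ref <- simulate_rrna_reference(taxa_per_domain = 3, root_length = 400,
                                 seed = 2)$aln
  q <- gsub("-", "", paste(ref$mat[2, ], collapse = ""))
  aq <- profile_align(setNames(q, "probe"), ref, screen_config())
  expect_equal(aq$gap_fraction, 0)
  expect_equal(aq$aligned_span, 400L)
  expect_equal(aq$match_columns, 400L)
  expect_equal(strsplit(aq$aligned_row, "")[[1]], unname(ref$mat[2, ]))
})

test_that("an internal deletion reduces match_columns but not the aligned
           span", {
  ref <- simulate_rrna_reference(taxa_per_domain = 3, root_length = 400,
                                 seed = 2)$aln
  full <- paste(ref$mat[2, ], collapse = "")
  gapped <- paste0(substr(full, 1, 195), substr(full, 206, 400))
  aq <- profile_align(setNames(gapped, "probe"), ref, screen_config())
  expect_equal(aq$aligned_span, 400L)
  expect_equal(aq$match_columns, 390L)
  expect_equal(aq$gap_fraction, 0)
})

test_that("any query yields an aligned_query; quality gates decide
           rejection", {
  ref <- simulate_rrna_reference(taxa_per_domain = 3, root_length = 350,
                                 seed = 4)$aln
  set.seed(7)
  junk <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  aq <- profile_align(setNames(junk, "junk"), ref, screen_config())
  expect_s3_class(aq, "aligned_query")
  expect_gte(aq$aligned_span, aq$match_columns)
  expect_error(profile_align(setNames("", "x"), ref, screen_config()),
               "empty")
})

test_that("alignment quality screening applies the span and gap rules at
           their boundaries", {
  cfg <- screen_config()
  mk <- function(span, gapf) structure(
    list(id = "q", aligned_span = span, gap_fraction = gapf),
    class = "aligned_query")
  expect_equal(screen_alignment_quality(mk(299L, 0), cfg)$reason,
               "short_span")
  expect_true(screen_alignment_quality(mk(300L, 0.1), cfg)$accept)
  expect_equal(screen_alignment_quality(mk(800L, 0.6), cfg)$reason, "gappy")
  expect_true(screen_alignment_quality(mk(800L, 0.5), cfg)$accept)
})

test_that("distances follow the closed-form corrections and their caps", {
  m <- rbind(a = strsplit(strrep("A", 10), "")[[1]],
             b = c(rep("A", 9), "C"),
             c = rep("C", 10))
  # protein: p = 0.1 between a and b
  D <- distance_matrix(m, "poisson")
  expect_equal(D["a", "b"], -log(0.9))
  expect_equal(D["a", "a"], 0)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0))
  # nucleotide saturation: p = 0.75 caps at d_max
  m2 <- rbind(a = c("A", "C", "G", "T"), b = c("C", "A", "G", "T"),
              c = c("C", "G", "T", "A"))
  D2 <- distance_matrix(m2, "jc_nucleotide")
  expect_equal(D2["a", "c"], 5.0)
  # pair with no shared ungapped columns
  m3 <- rbind(a = c("A", "-"), b = c("-", "C"), c = c("A", "C"))
  expect_error(distance_matrix(m3, "poisson"), "a / b")
  D3 <- distance_matrix(m3, "poisson", on_undefined = "d_max")
  expect_equal(D3["a", "b"], 5.0)
})

test_that("neighbor joining solves the 3-taxon case exactly and is total on
           tied matrices", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(D)
  cp <- ape::cophenetic.phylo(phy)
  expect_equal(cp[rownames(D), colnames(D)], D)
  # the three pendant lengths solve the pairwise equations
  expect_equal(sort(phy$edge.length), c(1, 2, 3))

  Dt <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Dt) <- 0
  t1 <- nj_tree(Dt)
  expect_s3_class(t1, "phylo")
  expect_identical(ape::write.tree(t1), ape::write.tree(nj_tree(Dt)))
  expect_true(all(t1$edge.length >= 0))
  expect_error(nj_tree(Dt[1:2, 1:2]), "at least 3")
  Dt2 <- Dt; Dt2[1, 2] <- 2
  expect_error(nj_tree(Dt2), "symmetric")
})

test_that("neighbor joining recovers the generating topology from additive
           distances", {
  skip_if_not_installed("phangorn")
  for (s in 1:20) {
    phy <- random_tree(8, seed = 1000 + s)
    D <- ape::cophenetic.phylo(phy)
    rec <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(rec), ape::unroot(phy)), 0)
  }
})

test_that("bootstrap supports saturate for a perfectly supported split and
           are reproducible", {
  # every column separates {a,b} from {c,d,e}
  m <- rbind(a = rep("A", 40), b = rep("A", 40),
             c = rep("C", 40), d = rep("C", 40), e = rep("C", 40))
  # add distinguishing noise so tips are not identical
  m[1, 1:3] <- c("G", "G", "G"); m[3, 4:6] <- c("T", "T", "T")
  aln <- ref_alignment(m)
  phy <- bootstrap_support(aln, n_replicates = 50, seed = 3,
                           correction = "jc_nucleotide")
  sup <- node_supports(phy)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  bip <- tree_bipartitions(phy)
  ab <- bip$node[vapply(strsplit(bip$key, "|", fixed = TRUE),
                        function(k) setequal(k, c("a", "b")) ||
                          setequal(k, c("c", "d", "e")), TRUE)]
  expect_equal(as.integer(phy$node.label[ab - 5L]), 100L)
  phy2 <- bootstrap_support(aln, n_replicates = 50, seed = 3,
                            correction = "jc_nucleotide")
  expect_identical(phy$node.label, phy2$node.label)
})

test_that("separation-node detection matches exhaustive enumeration and
           returns the central node of a symmetric three-clade tree", {
  phy <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1,(C1:1,C2:1):1);")
  dm <- setNames(rep(c("Bacteria", "Archaea", "Eukaryota"), each = 2),
                 c("A1", "A2", "B1", "B2", "C1", "C2"))
  sep <- find_domain_separation_nodes(phy, dm)
  expect_length(sep, 1L)
  expect_equal(sep, 7L)  # the central node joins the three cherries
  # shuffled labels: no domain is monophyletic
  dm2 <- setNames(c("Bacteria", "Archaea", "Bacteria", "Eukaryota",
                    "Archaea", "Eukaryota"), names(dm))
  expect_length(find_domain_separation_nodes(phy, dm2), 0L)
  # random labelled trees vs the brute-force oracle
  doms <- c("Bacteria", "Archaea", "Eukaryota")
  for (s in 1:30) {
    tr <- random_tree(sample(6:12, 1), seed = 3000 + s)
    dmr <- setNames(sample(doms, length(tr$tip.label), TRUE), tr$tip.label)
    expect_equal(sort(find_domain_separation_nodes(tr, dmr)),
                 sort(oracle_sep_nodes(tr, dmr)),
                 info = paste("seed", s))
  }
})

test_that("deep-branch scores count intervening internal nodes from the
           attachment point", {
  # caterpillar inside the Bacteria clade gives known node counts
  phy <- ape::read.tree(text = paste0(
    "(((((q:1,B1:1):1,B2:1):1,B3:1):1,B4:1):1,",
    "(A1:1,A2:1):1,(E1:1,E2:1):1);"))
  dm <- setNames(c("Bacteria", "Bacteria", "Bacteria", "Bacteria",
                   "Archaea", "Archaea", "Eukaryota", "Eukaryota"),
                 c("B1", "B2", "B3", "B4", "A1", "A2", "E1", "E2"))
  sep <- find_domain_separation_nodes(phy, dm, ignore_leaves = "q")
  expect_length(sep, 1L)
  db <- deep_branch_score(phy, "q", sep)
  expect_equal(db$score, 3L)   # three internal nodes between q's cherry and
  expect_false(db$is_deep)     # the separation node
  # query directly pendant at the separation node
  phy0 <- ape::read.tree(text =
    "((B1:1,B2:1):1,(A1:1,A2:1):1,(E1:1,E2:1):1,q:1);")
  sep0 <- find_domain_separation_nodes(phy0, dm, ignore_leaves = "q")
  db0 <- deep_branch_score(phy0, "q", sep0)
  expect_equal(db0$score, 0L)
  expect_true(db0$is_deep)
  # score exactly 2 is still deep (inclusive threshold)
  phy2 <- ape::read.tree(text = paste0(
    "((((q:1,B1:1):1,B2:1):1,B3:1):1,(A1:1,A2:1):1,(E1:1,E2:1):1);"))
  sep2 <- find_domain_separation_nodes(phy2, dm, ignore_leaves = "q")
  db2 <- deep_branch_score(phy2, "q", sep2)
  expect_equal(db2$score, 2L)
  expect_true(db2$is_deep)
  expect_error(deep_branch_score(phy2, "q", integer()), "undefined")
})

test_that("monophyly agrees with exhaustive edge enumeration", {
  quart <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_false(is_monophyletic(quart, c("A1", "B1")))
  expect_true(is_monophyletic(quart, "A1"))
  expect_true(is_monophyletic(quart, c("A1", "A2")))
  expect_error(is_monophyletic(quart, "nope"), "unknown")
  for (s in 1:50) {
    tr <- random_tree(sample(5:16, 1), seed = 500 + s)
    set.seed(s)
    sub <- sample(tr$tip.label, sample(2:(length(tr$tip.label) - 1), 1))
    expect_equal(is_monophyletic(tr, sub), oracle_monophyletic(tr, sub),
                 info = paste("seed", s))
  }
})

test_that("nearest-neighbour labelling follows patristic distance with tie
           handling", {
  phy <- ape::read.tree(text = "((q:0,a:0):1,(b:1,c:2):1);")
  lm <- c(a = "Archaea", b = "Bacteria", c = "Bacteria")
  expect_equal(nearest_neighbor_label(phy, "q", lm), "Archaea")
  phyt <- ape::read.tree(text = "((q:1,a:1):1,(b:1,x:1):1);")
  expect_equal(nearest_neighbor_label(
    phyt, "q", c(a = "Archaea", b = "Bacteria", x = "Bacteria")), "Archaea")
  tie <- ape::read.tree(text = "(q:1,a:2,b:2);")
  expect_equal(nearest_neighbor_label(
    tie, "q", c(a = "Archaea", b = "Bacteria")), "ambiguous")
  expect_error(nearest_neighbor_label(tie, "q", c(zz = "Archaea")),
               "labelled")
  # oracle comparison on random trees using ape's cophenetic distances
  for (s in 1:30) {
    tr <- random_tree(sample(5:12, 1), seed = 700 + s)
    set.seed(s)
    q <- sample(tr$tip.label, 1)
    others <- setdiff(tr$tip.label, q)
    lmr <- setNames(sample(c("Bacteria", "Archaea", "Eukaryota"),
                           length(others), TRUE), others)
    cp <- ape::cophenetic.phylo(tr)[q, others]
    best <- names(cp)[cp <= min(cp) + 1e-10]
    expected <- if (length(unique(lmr[best])) == 1L) unique(lmr[best])
                else "ambiguous"
    expect_equal(nearest_neighbor_label(tr, q, lmr), unname(expected),
                 info = paste("seed", s))
  }
})
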