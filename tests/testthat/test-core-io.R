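test_that("FASTA parsing matches an independent parser and handles wrapping", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  set.seed(42)
  s <- tolower(paste(sample(c("A","C","D","E","F","G"), 120, TRUE),
                     collapse = ""))
  writeLines(c(">seq1 some description",
               substring(s, c(1, 61), c(60, 120)),
               ">seq2",
               "MKVL"), tmp)
  ms <- read_fasta(tmp, "protein")
  expect_s3_class(ms, "marker_set")
  expect_equal(ms$id, c("seq1", "seq2"))
  expect_equal(nchar(ms$residues), c(120L, 4L))
  # independent parser
  bs <- Biostrings::readAAStringSet(tmp)
  expect_equal(unname(as.character(bs[[1]])), ms$residues[1])
  expect_equal(unname(as.character(bs[[2]])), ms$residues[2])
})

test_that("FASTA reader returns an empty set for an empty file and reports
           malformed input with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  file.create(tmp)
  expect_equal(nrow(read_fasta(tmp, "protein")), 0L)
  writeLines(c(">ok", "MKV", ">bad", "MK1L"), tmp)
  expect_error(read_fasta(tmp, "protein"), "line 4")
  writeLines(c("ACGT", ">late"), tmp)
  expect_error(read_fasta(tmp, "nucleotide"), "line 1")
})

test_that("FASTA round-trips through write_fasta", {
  ms <- marker_set(c("a", "b"), c(strrep("MKVL", 40), "ACDEF"), "protein")
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ms, tmp, width = 37L)
  back <- read_fasta(tmp, "protein")
  expect_equal(back$id, ms$id)
  expect_equal(back$residues, ms$residues)
})

test_that("BLAST tabular ingestion drops self-hits and merges reciprocal
           rows keeping the best statistics", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("a\tb\t90\t100\t5\t0\t1\t100\t1\t100\t1e-50\t200",
            "a\ta\t100\t100\t0\t0\t1\t100\t1\t100\t0\t300",
            "b\ta\t90\t100\t5\t0\t1\t100\t1\t100\t1e-60\t190")
  writeLines(rows, tmp)
  edges <- read_similarity_table(tmp)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$id_a, "a")
  expect_equal(edges$id_b, "b")
  expect_equal(edges$expect, 1e-60)   # minimum E kept
  expect_equal(edges$bit_score, 200)  # maximum bit score kept
  # order independence
  writeLines(rev(rows), tmp)
  expect_equal(read_similarity_table(tmp), edges)
  # wrong column count
  writeLines("a\tb\t1e-50\t200", tmp)
  expect_error(read_similarity_table(tmp), "12")
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,c:2);", tmp)
  phy <- read_newick(tmp)
  expect_equal(sort(phy$tip.label), c("a", "b", "c"))
  write_newick(phy, tmp)
  phy2 <- read_newick(tmp)
  expect_equal(phy2$edge.length[order(phy2$edge[, 2])],
               phy$edge.length[order(phy$edge[, 2])])

  writeLines("((a:1,b:1)95:1,(c:1,d:1)80:1);", tmp)
  phys <- read_newick(tmp)
  expect_true(95L %in% node_supports(phys))
  write_newick(phys, tmp)
  expect_true(95L %in% node_supports(read_newick(tmp)))

  # write-then-read is identity on the bipartition set of a random tree
  phy20 <- random_tree(20, seed = 99)
  write_newick(phy20, tmp)
  back <- read_newick(tmp)
  expect_setequal(tree_bipartitions(back)$key, tree_bipartitions(phy20)$key)
})

test_that("unbalanced Newick input is a parse error", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1:1,c:2);", tmp)
  expect_error(read_newick(tmp))
})

test_that("assembly tables group rows into neighborhoods around the focal
           gene", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("assembly_id", "gene_id", "start", "end", "strand",
                 "description", "domain_assignment", "is_focal"),
               collapse = "\t")
  writeLines(c(hdr,
               "asm1\tg1\t1\t900\t+\tmarker\tunassigned\t1",
               "asm2\th1\t1\t900\t-\tmarker\tunassigned\t1",
               "asm1\tg2\t1001\t1900\t-\thelicase\tArchaea\t0",
               "asm2\th2\t1001\t1900\t+\tpolymerase\tBacteria\t0",
               "asm1\tg3\t2001\t2900\t+\tprimase\tArchaea\t0"), tmp)
  nbs <- read_assembly_table(tmp)
  expect_named(nbs, c("asm1", "asm2"))
  expect_equal(nbs$asm1$focal_gene_id, "g1")
  expect_equal(nrow(nbs$asm1$neighbors), 2L)
  expect_equal(nrow(nbs$asm2$neighbors), 1L)
  # coordinate error
  writeLines(c(hdr, "asm1\tg1\t900\t1\t+\tmarker\tunassigned\t1"), tmp)
  expect_error(read_assembly_table(tmp), "coordinate")
})

test_that("the bundled neighbor-gene table parses with the published row
           counts", {
  path <- system.file("extdata", "gos_novel_reca_neighbors.tsv",
                      package = "lekscreen")
  nbs <- read_assembly_table(path)
  expect_length(nbs, 12L)
  expect_equal(nrow(nbs[["1096627390330"]]$neighbors), 32L)
  expect_equal(sum(vapply(nbs, function(x) nrow(x$neighbors), 0L)), 55L)
})

test_that("marker sets enforce their invariants", {
  expect_error(marker_set(c("a", "a"), c("MK", "ML"), "protein"), "unique")
  expect_error(marker_set("a", "", "protein"), "non-empty")
  expect_error(marker_set("a", "MKV", "protein", source = "environmental",
                          domain_label = "Bacteria"), "unknown")
  ok <- marker_set("a", "mkv", "protein")
  expect_equal(ok$residues, "MKV")
})

test_that("screen configuration validates thresholds and reads YAML", {
  expect_error(screen_config(lek_score_cutoff = 1.2), "0, 1")
  expect_error(screen_config(evalue_cutoff = -1), "positive")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("evalue_cutoff: 1.0e-70", "lek_score_cutoff: 0.60",
               "min_peptide_length: 400"), tmp)
  cfg <- read_screen_config(tmp)
  expect_equal(cfg$evalue_cutoff, 1e-70)
  expect_equal(cfg$lek_score_cutoff, 0.60)
  expect_equal(cfg$min_peptide_length, 400)
  writeLines("no_such_field: 1", tmp)
  expect_error(read_screen_config(tmp), "unknown config fields")
})
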