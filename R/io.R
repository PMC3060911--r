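#' Read sequences from a FASTA file
#'
#' A small strict FASTA reader: it reports malformed input with the offending
#' line number, which matters when ingesting hand-assembled marker sets.
#' Residues are uppercased and line wrapping is ignored.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param source,domain_label metadata applied to every record
#'   (see [marker_set()]).
#' @return a [marker_set()] with one row per record.
#' @export
read_fasta <- function(path, alphabet, source = "reference",
                       domain_label = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # drop trailing whitespace; keep track of original line numbers
  lines <- sub("[ \t\r]+$", "", lines)
  nonempty <- which(nzchar(lines))
  if (!length(nonempty))
    return(marker_set(character(), character(), alphabet)[0, ])
  ids <- character()
  seqs <- character()
  cur <- NULL
  buf <- character()
  flush <- function() {
    if (is.null(cur)) return()
    ids <<- c(ids, cur)
    seqs <<- c(seqs, paste(buf, collapse = ""))
  }
  ok_chars <- c(ALPHABETS[[alphabet]], EXTRA_CHARS[[alphabet]], "-", ".")
  for (i in nonempty) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      cur <- sub("^>\\s*", "", ln)
      cur <- sub("\\s.*$", "", cur)  # id = first whitespace-delimited token
      if (!nzchar(cur)) stop("FASTA parse error at line ", i, ": empty header")
      buf <- character()
    } else {
      if (is.null(cur))
        stop("FASTA parse error at line ", i, ": sequence before any header")
      up <- toupper(gsub("[ \t]", "", ln))
      ill <- setdiff(unique(strsplit(up, "")[[1L]]), ok_chars)
      if (length(ill))
        stop("FASTA parse error at line ", i, ": illegal ", alphabet,
             " character(s): ", paste(ill, collapse = " "))
      buf <- c(buf, up)
    }
  }
  flush()
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA parse error: record '", ids[empty][1L], "' has no residues")
  marker_set(ids, seqs, alphabet, source = source, domain_label = domain_label)
}

#' Write a marker set to a FASTA file
#'
#' @param ms a [marker_set()].
#' @param path output path.
#' @param width residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ms, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ms))) {
    writeLines(paste0(">", ms$id[i]), con)
    s <- ms$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read pairwise similarities from BLAST tabular output
#'
#' Ingests 12-column tab-separated BLAST tabular (outfmt 6) so that searches
#' run with an external BLASTP can replace the internal alignment engine.
#' Only the query id, subject id, E-value and bit score columns are used.
#' Self-hits are dropped; reciprocal and repeated hits for the same pair are
#' merged keeping the minimum E-value and the maximum bit score.
#'
#' @param path path to a tab-separated 12-column file.
#' @return a data frame of edges with columns `id_a`, `id_b` (with
#'   `id_a < id_b`), `bit_score`, `expect`.
#' @export
read_similarity_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 12L)
    stop("similarity table format error: expected 12 tab-separated columns, ",
         "found ", ncol(tab))
  edges <- data.frame(id_a = tab[[1L]], id_b = tab[[2L]],
                      bit_score = as.numeric(tab[[12L]]),
                      expect = as.numeric(tab[[11L]]),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$bit_score) || anyNA(edges$expect))
    stop("similarity table format error: non-numeric E-value or bit score")
  dedup_edges(edges)
}

# canonicalize (id_a < id_b), drop self hits, merge duplicates keeping the
# minimum E-value and maximum bit score
dedup_edges <- function(edges) {
  if (any(edges$expect < 0)) stop("expectation values must be non-negative")
  edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
  if (!nrow(edges)) {
    out <- edges[, c("id_a", "id_b", "bit_score", "expect")]
    rownames(out) <- NULL
    return(out)
  }
  a <- pmin(edges$id_a, edges$id_b)
  b <- pmax(edges$id_a, edges$id_b)
  key <- paste(a, b, sep = "\r")
  bit <- tapply(edges$bit_score, key, max)
  exp_ <- tapply(edges$expect, key, min)
  parts <- strsplit(names(bit), "\r", fixed = TRUE)
  out <- data.frame(id_a = vapply(parts, `[`, "", 1L),
                    id_b = vapply(parts, `[`, "", 2L),
                    bit_score = as.numeric(bit),
                    expect = as.numeric(exp_),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that keep the
#' package's tree interchange in one place.  Node labels, when integer-like,
#' are interpreted as bootstrap supports in `[0, 100]`.
#'
#' @param path a file path; for `read_newick` the file must contain a single
#'   Newick tree.
#' @param phy an object of class `phylo`.
#' @param digits significant digits for branch lengths on output.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree found in ", path)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single Newick tree in ", path)
    phy <- phy[[1L]]
  }
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf ids in tree")
  phy
}

#' @rdname read_newick
#' @export
write_newick <- function(phy, path, digits = 6L) {
  stopifnot(inherits(phy, "phylo"))
  txt <- ape::write.tree(phy, digits = digits)
  writeLines(txt, path)
  invisible(path)
}

#' Integer branch supports of a tree
#'
#' @param phy a `phylo` whose node labels carry bootstrap percentages.
#' @return an integer vector (NA where a node is unlabelled).
#' @export
node_supports <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_integer_, phy$Nnode))
  suppressWarnings(as.integer(phy$node.label))
}

ASSEMBLY_DOMAINS <- c("Bacteria", "Archaea", "Eukaryota", "Viruses/Phages",
                      "unassigned")

#' Construct an assembly gene neighborhood
#'
#' The genes co-located with a focal marker gene on a metagenomic assembly,
#' with a domain-of-life assignment per neighbour (typically from the nearest
#' labelled neighbour in a per-gene phylogenetic tree).  Coordinates are
#' 1-based and inclusive.
#'
#' @param assembly_id assembly identifier.
#' @param focal_gene_id id of the focal marker gene (not listed among
#'   neighbours).
#' @param neighbors data frame with columns `gene_id`, `start`, `end`,
#'   `strand`, `description`, `domain_assignment`.
#' @return a list of class `assembly_neighborhood`.
#' @export
assembly_neighborhood <- function(assembly_id, focal_gene_id, neighbors) {
  need <- c("gene_id", "start", "end", "strand", "description",
            "domain_assignment")
  if (!all(need %in% names(neighbors)))
    stop("neighbors must have columns: ", paste(need, collapse = ", "))
  neighbors$start <- as.integer(neighbors$start)
  neighbors$end <- as.integer(neighbors$end)
  bad <- neighbors$start > neighbors$end | neighbors$start < 1L
  if (any(bad))
    stop("coordinate error: start > end or start < 1 for gene ",
         neighbors$gene_id[bad][1L])
  if (focal_gene_id %in% neighbors$gene_id)
    stop("focal gene must not be counted among its own neighbors")
  if (!all(neighbors$domain_assignment %in% ASSEMBLY_DOMAINS))
    stop("domain_assignment must be one of: ",
         paste(ASSEMBLY_DOMAINS, collapse = ", "))
  structure(list(assembly_id = as.character(assembly_id),
                 focal_gene_id = as.character(focal_gene_id),
                 neighbors = neighbors),
            class = "assembly_neighborhood")
}

#' @export
print.assembly_neighborhood <- function(x, ...) {
  cat(sprintf("assembly %s: focal gene %s, %d neighbor(s)\n",
              x$assembly_id, x$focal_gene_id, nrow(x$neighbors)))
  print(table(x$neighbors$domain_assignment))
  invisible(x)
}

#' Read assembly gene-neighborhood tables
#'
#' Reads a tab-separated annotation table with header columns `assembly_id`,
#' `gene_id`, `start`, `end`, `strand`, `description`, `domain_assignment`,
#' `is_focal` and groups rows into one [assembly_neighborhood()] per assembly.
#' Exactly one row per assembly must be flagged focal (`is_focal` = 1).
#'
#' @param path path to the TSV file.
#' @return a named list of `assembly_neighborhood` objects.
#' @export
read_assembly_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("assembly_id", "gene_id", "start", "end", "strand",
            "description", "domain_assignment", "is_focal")
  if (!all(need %in% names(tab)))
    stop("assembly table must have columns: ", paste(need, collapse = ", "))
  bad <- as.integer(tab$start) > as.integer(tab$end) |
    as.integer(tab$start) < 1L
  if (any(bad))
    stop("coordinate error: start > end or start < 1 for gene ",
         tab$gene_id[bad][1L])
  out <- lapply(split(tab, tab$assembly_id), function(grp) {
    focal <- grp[as.logical(as.integer(grp$is_focal)), , drop = FALSE]
    if (nrow(focal) != 1L)
      stop("assembly ", grp$assembly_id[1L], ": expected exactly one focal ",
           "gene, found ", nrow(focal))
    nb <- grp[!as.logical(as.integer(grp$is_focal)), , drop = FALSE]
    assembly_neighborhood(grp$assembly_id[1L], focal$gene_id,
                          nb[, c("gene_id", "start", "end", "strand",
                                 "description", "domain_assignment")])
  })
  out[order(names(out))]
}
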