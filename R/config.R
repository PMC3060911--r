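#' Screen configuration
#'
#' Collects every tunable threshold used by the screen in one validated list.
#' The defaults are the values used for the RecA protein screen; the RpoB
#' screen tightens the clustering (`evalue_cutoff = 1e-70`,
#' `lek_score_cutoff = 0.60`) and adds a minimum peptide length of 400
#' residues, reflecting the multi-domain architecture of RNA polymerase
#' subunits, whose fragments otherwise cluster apart from full-length genes.
#'
#' @param evalue_cutoff maximum pairwise expectation value for an edge in the
#'   similarity graph (RecA: `1e-40`; RpoB: `1e-70`).
#' @param lek_score_cutoff minimum between-cluster Lek score for a merge,
#'   in `(0, 1]` (RecA: `0.10`; RpoB: `0.60`).
#' @param min_cluster_members clusters with fewer members are excluded from
#'   novelty calling (default 3).
#' @param min_peptide_length clusters whose median member is shorter are
#'   treated as fragment clusters (`NULL` disables; 400 for RpoB).
#' @param max_column_gap_fraction reference-alignment columns with a strictly
#'   greater gap fraction are removed (default 0.90).
#' @param min_aligned_span queries whose placement spans fewer reference
#'   columns (in bp / residues) are rejected as unalignable (default 300).
#' @param max_query_gap_fraction queries with a larger fraction of unplaced
#'   residues are rejected as too gappy (default 0.5).
#' @param deep_branch_max_nodes a query is deep-branching when at most this
#'   many internal nodes separate its attachment point from a
#'   domain-separation node (default 2, i.e. "one or two nodes away").
#' @param bootstrap_replicates column-resampling replicates for branch
#'   support (default 100).
#' @param representatives_per_cluster representatives selected per retained
#'   cluster for the superfamily tree (default 3).
#' @param neighbor_evalue_cutoff E-value cutoff for accepting database hits
#'   of neighbouring genes (default 1e-5).
#' @param neighbor_hit_count number of top hits used to build each
#'   neighbouring gene's tree (default 50).
#' @param gap_open,gap_extend affine gap penalties for the internal local
#'   (Smith-Waterman) engine (defaults 11 and 1, matching the bit-score
#'   calibration).
#' @param profile_gap_open,profile_gap_extend affine gap penalties for
#'   profile (placement) alignment (defaults 11 and 2; the heavier extension
#'   keeps divergent-but-homologous queries aligned through mismatch runs
#'   instead of shredding them into gaps).
#' @param rng_seed master seed from which all stage seeds are derived.
#' @return a list of class `screen_config`.
#' @export
#' @examples
#' cfg <- screen_config()
#' rpob <- screen_config(evalue_cutoff = 1e-70, lek_score_cutoff = 0.60,
#'                       min_peptide_length = 400)
screen_config <- function(evalue_cutoff = 1e-40,
                          lek_score_cutoff = 0.10,
                          min_cluster_members = 3L,
                          min_peptide_length = NULL,
                          max_column_gap_fraction = 0.90,
                          min_aligned_span = 300L,
                          max_query_gap_fraction = 0.5,
                          deep_branch_max_nodes = 2L,
                          bootstrap_replicates = 100L,
                          representatives_per_cluster = 3L,
                          neighbor_evalue_cutoff = 1e-5,
                          neighbor_hit_count = 50L,
                          gap_open = 11,
                          gap_extend = 1,
                          profile_gap_open = 11,
                          profile_gap_extend = 2,
                          rng_seed = 1L) {
  cfg <- list(
    evalue_cutoff = evalue_cutoff,
    lek_score_cutoff = lek_score_cutoff,
    min_cluster_members = as.integer(min_cluster_members),
    min_peptide_length = if (is.null(min_peptide_length)) NULL
                         else as.numeric(min_peptide_length),
    max_column_gap_fraction = max_column_gap_fraction,
    min_aligned_span = as.integer(min_aligned_span),
    max_query_gap_fraction = max_query_gap_fraction,
    deep_branch_max_nodes = as.integer(deep_branch_max_nodes),
    bootstrap_replicates = as.integer(bootstrap_replicates),
    representatives_per_cluster = as.integer(representatives_per_cluster),
    neighbor_evalue_cutoff = neighbor_evalue_cutoff,
    neighbor_hit_count = as.integer(neighbor_hit_count),
    gap_open = gap_open,
    gap_extend = gap_extend,
    profile_gap_open = profile_gap_open,
    profile_gap_extend = profile_gap_extend,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  pos <- c("evalue_cutoff", "lek_score_cutoff", "min_cluster_members",
           "min_aligned_span", "deep_branch_max_nodes", "bootstrap_replicates",
           "neighbor_evalue_cutoff", "neighbor_hit_count", "gap_open",
           "profile_gap_open", "representatives_per_cluster")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a single positive number")
  if (!is.null(cfg$min_peptide_length) && cfg$min_peptide_length <= 0)
    stop("config field 'min_peptide_length' must be positive or NULL")
  if (cfg$lek_score_cutoff > 1)
    stop("lek_score_cutoff must lie in (0, 1]")
  if (cfg$max_column_gap_fraction < 0 || cfg$max_column_gap_fraction > 1)
    stop("max_column_gap_fraction must lie in [0, 1]")
  if (cfg$gap_extend < 0 || cfg$profile_gap_extend < 0)
    stop("gap extension penalties must be non-negative")
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen configuration:\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-28s %s\n", f,
                if (is.null(v)) "(unset)" else format(v)))
  }
  invisible(x)
}

#' Read a screen configuration from a YAML file
#'
#' The file holds a flat mapping whose keys mirror the [screen_config()]
#' argument names; absent keys keep their defaults and unknown keys are an
#' error, so a config file cannot silently misspell a threshold.
#'
#' @param path path to a YAML file.
#' @return a `screen_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(screen_config, vals)
}
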