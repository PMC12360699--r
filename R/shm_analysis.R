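#' Competition rank of a probability within a 20-vector
#'
#' Rank in descending order with competition ranking for ties: the rank
#' of entry `j` is 1 plus the number of entries strictly greater than it,
#' so the argmax always has rank 1.
#'
#' @param column Numeric vector of 20 probabilities.
#' @param j Index (1-20) of the entry to rank.
#' @return Integer rank in `[1, 20]`.
#' @export
competition_rank <- function(column, j) {
  stopifnot(length(column) == 20L, j >= 1L, j <= 20L)
  1L + sum(column > column[j])
}

#' Substitutions along the edges of a lineage tree, ranked by the model
#'
#' For every tree edge whose endpoint sequences have equal length and
#' differ at one or more positions, the per-residue probability matrix
#' is computed for the parent sequence (the sequence before the edge),
#' and at each differential position the child's residue is ranked
#' within the parent's probability column in descending order
#' (competition ranking; 1 = the model's most likely residue). The
#' parent's own residue rank and its probability are recorded alongside.
#' An edge with several differential positions gets an edge-level
#' substitution rank equal to the arithmetic mean of its per-position
#' child ranks. Edges with unequal-length endpoints (indels) are skipped
#' and counted. Germline-to-child edges are scored by default (the
#' germline is a valid parent sequence); set
#' `include_germline_edges = FALSE` to restrict to edges between
#' observed sequences.
#'
#' @param tree A [build_tree()] result.
#' @param provider A [likelihood_provider()].
#' @param include_germline_edges Score edges whose parent is the
#'   germline root (default `TRUE`).
#' @return Data frame with one row per (edge, differential position):
#'   `clone_id, parent_id, child_id, position` (0-based), `from_aa,
#'   to_aa, rank_child, rank_parent, rl_parent_residue, edge_rank`
#'   (repeated across an edge's rows). The number of skipped
#'   unequal-length edges is kept in the `skipped_unequal_length`
#'   attribute.
#' @export
edge_substitutions <- function(tree, provider, include_germline_edges = TRUE) {
  stopifnot(inherits(tree, "lineage_tree"),
            inherits(provider, "likelihood_provider"))
  register_tree_germlines(provider, tree)
  seq_of <- stats::setNames(tree$nodes$sequence_aa, tree$nodes$node_id)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(tree$edges))) {
    pid <- tree$edges$parent[i]; cid <- tree$edges$child[i]
    if (!include_germline_edges && pid == "germline") next
    ps <- seq_of[[pid]]; cs <- seq_of[[cid]]
    if (nchar(ps) != nchar(cs)) { skipped <- skipped + 1L; next }
    pc <- aa_split(ps); cc <- aa_split(cs)
    pos <- which(pc != cc)
    if (length(pos) == 0L) next
    pm <- residue_probabilities(provider, ps)
    rank_child <- integer(length(pos)); rank_parent <- integer(length(pos))
    rl_parent <- numeric(length(pos))
    for (k in seq_along(pos)) {
      p <- pos[k]
      col <- pm[p, ]
      rank_child[k] <- competition_rank(col, aa_index(cc[p]))
      rank_parent[k] <- competition_rank(col, aa_index(pc[p]))
      rl_parent[k] <- col[aa_index(pc[p])]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = tree$clone_id, parent_id = pid, child_id = cid,
      position = pos - 1L, from_aa = pc[pos], to_aa = cc[pos],
      rank_child = rank_child, rank_parent = rank_parent,
      rl_parent_residue = rl_parent, edge_rank = mean(rank_child),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clone_id = character(), parent_id = character(),
               child_id = character(), position = integer(),
               from_aa = character(), to_aa = character(),
               rank_child = integer(), rank_parent = integer(),
               rl_parent_residue = numeric(), edge_rank = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "skipped_unequal_length") <- skipped
  out
}

#' Parent-residue likelihood at mutating versus conserved positions
#'
#' For every qualifying edge (equal-length endpoints, >= 1 differential
#' position) of a tree, the mean parent-residue probability is computed
#' separately over the differential (mutating) and the identical
#' (conserved) positions of the parent sequence, and the two paired sets
#' are compared with a paired t-test. Lower likelihood at mutating
#' positions indicates that the model anticipates where hypermutation
#' strikes.
#'
#' @param tree A [build_tree()] result (or a `lineage_forest`, pooled
#'   over trees).
#' @param provider A [likelihood_provider()].
#' @param include_germline_edges As in [edge_substitutions()].
#' @return List with `pairs` (data frame `clone_id, parent_id, child_id,
#'   rl_mutating, rl_conserved`), pooled `mean_rl_mutating` and
#'   `mean_rl_conserved`, and `p_value` of the paired t-test (`NA` with
#'   fewer than 2 complete pairs or zero variance of differences).
#' @export
conserved_vs_mutating <- function(tree, provider, include_germline_edges = TRUE) {
  trees <- if (inherits(tree, "lineage_forest")) tree else list(tree)
  pairs <- list()
  for (tr in trees) {
    register_tree_germlines(provider, tr)
    seq_of <- stats::setNames(tr$nodes$sequence_aa, tr$nodes$node_id)
    for (i in seq_len(nrow(tr$edges))) {
      pid <- tr$edges$parent[i]; cid <- tr$edges$child[i]
      if (!include_germline_edges && pid == "germline") next
      ps <- seq_of[[pid]]; cs <- seq_of[[cid]]
      if (nchar(ps) != nchar(cs)) next
      pc <- aa_split(ps); cc <- aa_split(cs)
      diff_pos <- which(pc != cc)
      if (length(diff_pos) == 0L) next
      same_pos <- which(pc == cc)
      pm <- residue_probabilities(provider, ps)
      rl <- pm[cbind(seq_along(pc), aa_index(pc))]
      pairs[[length(pairs) + 1L]] <- data.frame(
        clone_id = tr$clone_id, parent_id = pid, child_id = cid,
        rl_mutating = mean(rl[diff_pos]),
        rl_conserved = if (length(same_pos)) mean(rl[same_pos]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(clone_id = character(), parent_id = character(),
               child_id = character(), rl_mutating = numeric(),
               rl_conserved = numeric(), stringsAsFactors = FALSE)
  complete <- stats::complete.cases(pairs[, c("rl_mutating", "rl_conserved")])
  p_value <- NA_real_
  if (sum(complete) >= 2L) {
    dif <- pairs$rl_mutating[complete] - pairs$rl_conserved[complete]
    if (stats::sd(dif) > 0) {
      p_value <- stats::t.test(pairs$rl_mutating[complete],
                               pairs$rl_conserved[complete],
                               paired = TRUE)$p.value
    }
  }
  list(pairs = pairs,
       mean_rl_mutating = mean(pairs$rl_mutating[complete]),
       mean_rl_conserved = mean(pairs$rl_conserved[complete]),
       p_value = p_value)
}

#' Shannon evenness of a residue probability column
#'
#' Shannon entropy of the 20-way distribution divided by its maximum
#' `log(20)`, with the convention `0 * log(0) = 0`. 1 means the model is
#' maximally uncertain (uniform), 0 means deterministic (one-hot).
#'
#' @param column Numeric vector of 20 non-negative probabilities summing
#'   to 1 within `1e-6`.
#' @return Evenness in `[0, 1]`.
#' @export
#' @examples
#' shannon_evenness(rep(0.05, 20))           # 1
#' shannon_evenness(c(1, rep(0, 19)))        # 0
shannon_evenness <- function(column) {
  if (any(column < 0)) stop("probabilities must be non-negative")
  if (abs(sum(column) - 1) > 1e-6) stop("column must sum to 1")
  p <- column[column > 0]
  h <- -sum(p * log(p))
  h / log(20)
}

#' Per-position Shannon evenness of a probability matrix
#'
#' @param pm A [probability_matrix()].
#' @return Numeric vector, one evenness value per position.
#' @export
matrix_evenness <- function(pm) {
  stopifnot(inherits(pm, "probability_matrix"))
  apply(unclass(pm), 1L, shannon_evenness)
}

#' Mean substitution rank per sample and across samples
#'
#' Aggregates edge-level substitution ranks: the per-sample statistic is
#' the mean `edge_rank` over that sample's edges, and the grand mean is
#' the unweighted mean of the per-sample means (samples, not cells, are
#' the units).
#'
#' @param records Edge-substitution rows from [edge_substitutions()],
#'   carrying a `sample_id` column.
#' @return List with `per_sample` (data frame `sample_id, mean_rank,
#'   n_edges`) and `grand_mean`.
#' @export
mean_substitution_rank <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample1"
  # one row per edge: edge_rank is constant within an edge
  edges <- unique(records[, c("sample_id", "clone_id", "parent_id",
                              "child_id", "edge_rank")])
  agg <- stats::aggregate(edge_rank ~ sample_id, data = edges, FUN = mean)
  n <- stats::aggregate(edge_rank ~ sample_id, data = edges, FUN = length)
  per_sample <- data.frame(sample_id = agg$sample_id, mean_rank = agg$edge_rank,
                           n_edges = n$edge_rank, stringsAsFactors = FALSE)
  list(per_sample = per_sample, grand_mean = mean(per_sample$mean_rank))
}

# germline-anchored providers need a germline per scored sequence; within a
# tree every equal-length node sequence descends from the root germline
register_tree_germlines <- function(provider, tree) {
  if (!inherits(provider, "germline_anchored_provider")) return(invisible(NULL))
  g <- tree$nodes$sequence_aa[tree$nodes$is_germline]
  s <- tree$nodes$sequence_aa[nchar(tree$nodes$sequence_aa) == nchar(g)]
  register_germlines(provider, s, rep(g, length(s)))
  invisible(NULL)
}

#' Edge substitutions across a whole forest
#'
#' Convenience wrapper running [edge_substitutions()] on every tree of a
#' forest and stacking the rows, with each tree's `sample_id` attached.
#'
#' @param forest A [build_forest()] result.
#' @param provider A [likelihood_provider()].
#' @param include_germline_edges As in [edge_substitutions()].
#' @return Stacked data frame of edge-substitution rows.
#' @export
forest_edge_substitutions <- function(forest, provider,
                                      include_germline_edges = TRUE) {
  stopifnot(inherits(forest, "lineage_forest"))
  out <- lapply(forest, function(tr) {
    df <- edge_substitutions(tr, provider, include_germline_edges)
    if (nrow(df)) df$sample_id <- if (is.null(tr$sample_id)) "sample1" else tr$sample_id
    df
  })
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0L])
  if (is.null(res)) {
    res <- edge_substitutions(forest[[1L]], provider, include_germline_edges)[0, ]
    res$sample_id <- character(0)
  }
  rownames(res) <- NULL
  res
}
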