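#' Correlation with two-sided test, as a tidy row
#'
#' Wraps [stats::cor.test()] (Pearson product-moment or Spearman rank)
#' and returns the estimate, two-sided p-value and sample size as a
#' one-row data frame. Pairs with missing values are dropped. If either
#' vector has zero variance the estimate is undefined: the row is
#' returned with `estimate = NA` and `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @param analysis Optional analysis label carried on the row.
#' @return One-row data frame: `analysis, statistic, estimate, p_value,
#'   n, degenerate`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      analysis = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlation requires at least 3 complete pairs (got ", n, ")")
  stat_name <- if (method == "pearson") "pearson_r" else "spearman_rho"
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(analysis = analysis, statistic = stat_name,
                      estimate = NA_real_, p_value = NA_real_, n = n,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(analysis = analysis, statistic = stat_name,
             estimate = unname(ct$estimate), p_value = ct$p.value, n = n,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Per-cell feature table joining SP scores to repertoire features
#'
#' Builds the long table behind the repertoire-level association
#' analyses: one row per scored record (cell x locus-or-paired x
#' source), annotated with the cell's isotype, heavy V-gene family,
#' heavy-chain SHM (Hamming distance to germline; `NA` for
#' indel-excluded cells), normalized clonal expansion of its clone, and
#' — when a forest is supplied — the Levenshtein root-path length of
#' the cell's node in its clonal tree. Cells missing a feature keep
#' `NA` there and remain available to the other analyses.
#'
#' @param scored Output of [score_repertoire()].
#' @param rep The scored [bcr_repertoire].
#' @param forest Optional [build_forest()] result (heavy trees for
#'   heavy-locus rows).
#' @return Data frame: `cell_id, locus, provider, source, sp,
#'   n_positions, sample_id, isotype, v_family, hamming_shm,
#'   normalized_expansion, clone_id, root_path_length`.
#' @export
sp_feature_table <- function(scored, rep, forest = NULL) {
  stopifnot(is.data.frame(scored), inherits(rep, "bcr_repertoire"))
  cells <- rep$cells
  hv <- rep$chains[rep$chains$locus == "heavy", ]
  shm <- stats::setNames(hamming_shm(hv$sequence_aa, hv$germline_aa), hv$cell_id)
  vfam <- stats::setNames(v_family(hv$v_call), hv$cell_id)
  expansion <- normalized_expansion(rep)
  out <- scored
  idx <- match(out$cell_id, cells$cell_id)
  out$isotype <- cells$isotype[idx]
  out$v_family <- unname(vfam[out$cell_id])
  out$hamming_shm <- unname(shm[out$cell_id])
  out$clone_id <- cells$clone_id[idx]
  out$normalized_expansion <- unname(expansion[out$clone_id])
  out$root_path_length <- NA_integer_
  if (!is.null(forest)) {
    rpl <- stats::setNames(numeric(0), character(0))
    for (tr in forest) {
      na <- node_attributes(tr)
      depth <- stats::setNames(na$root_path_length, na$node_id)
      rpl <- c(rpl, stats::setNames(unname(depth[tr$node_cells$node_id]),
                                    tr$node_cells$cell_id))
    }
    out$root_path_length <- unname(rpl[out$cell_id])
  }
  out
}

#' Pairwise Welch group comparisons with multiplicity adjustment
#'
#' Welch two-sample t-tests on `value` between requested pairs of
#' groups, with the p-values adjusted over the family of pairs (Holm by
#' default). Pairs where either group has fewer than 2 observations are
#' skipped.
#'
#' @param table Data frame (e.g. from [sp_feature_table()]).
#' @param value Name of the numeric column to compare (default `"sp"`).
#' @param group Name of the grouping column (default `"isotype"`).
#' @param pairs List of length-2 character vectors; `NULL` compares all
#'   group pairs.
#' @param adjust Adjustment method: `"holm"`, `"bonferroni"` or `"BH"`.
#' @return Data frame: `group1, group2, mean1, mean2, estimate`
#'   (mean1 - mean2), `t, p_value, adjusted_p, n1, n2`.
#' @export
group_compare <- function(table, value = "sp", group = "isotype", pairs = NULL,
                          adjust = c("holm", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(value %in% names(table), group %in% names(table))
  v <- table[[value]]; g <- as.character(table[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  if (is.null(pairs)) {
    lv <- sort(unique(g))
    pairs <- if (length(lv) >= 2L) utils::combn(lv, 2L, simplify = FALSE) else list()
  }
  rows <- list()
  for (pr in pairs) {
    a <- v[g == pr[1L]]; b <- v[g == pr[2L]]
    if (length(a) < 2L || length(b) < 2L) next
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)  # both groups constant
    if (is.null(tt)) {
      tstat <- 0; p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
    } else {
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = pr[1L], group2 = pr[2L], mean1 = mean(a), mean2 = mean(b),
      estimate = mean(a) - mean(b), t = tstat, p_value = p,
      n1 = length(a), n2 = length(b), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group1 = character(), group2 = character(), mean1 = numeric(),
               mean2 = numeric(), estimate = numeric(), t = numeric(),
               p_value = numeric(), n1 = integer(), n2 = integer(),
               stringsAsFactors = FALSE)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Correlation of group mean SP with external group frequencies
#'
#' Pearson correlation between the mean SP per group (V-gene family or
#' isotype) and that group's frequency in an external table (e.g. the
#' percentage of unique sequences per group in a sequence database).
#' Groups present in only one of the two tables are dropped with a
#' warning; at least 3 shared groups are required.
#'
#' @param mean_sp_by_group Data frame with columns `group` and
#'   `mean_sp`.
#' @param frequency_table Data frame with columns `group` and `percent`.
#' @return One-row data frame as from [correlate()].
#' @export
frequency_association <- function(mean_sp_by_group, frequency_table) {
  stopifnot(all(c("group", "mean_sp") %in% names(mean_sp_by_group)),
            all(c("group", "percent") %in% names(frequency_table)))
  m <- merge(mean_sp_by_group, frequency_table, by = "group")
  lost <- setdiff(union(mean_sp_by_group$group, frequency_table$group), m$group)
  if (length(lost)) {
    warning("unmatched group(s) dropped: ", paste(lost, collapse = ", "))
  }
  correlate(m$mean_sp, m$percent, method = "pearson",
            analysis = "frequency_association")
}

#' Pairwise SP correlations across providers or sources
#'
#' Pearson correlation between the SPs of every pair of scored tables,
#' per input source, over the cells (cell x locus) the pair shares.
#' Pairs sharing fewer than 3 cells for a source are flagged and
#' returned with `NA`.
#'
#' @param scored_list Named list of [score_repertoire()] outputs (names
#'   default to each table's provider).
#' @return Data frame: `provider1, provider2, source, estimate, p_value,
#'   n, degenerate`.
#' @export
cross_model_correlation <- function(scored_list) {
  stopifnot(is.list(scored_list), length(scored_list) >= 2L)
  if (is.null(names(scored_list))) {
    names(scored_list) <- vapply(scored_list, function(s) s$provider[1L], "")
  }
  nm <- names(scored_list)
  rows <- list()
  for (i in seq_along(scored_list)) for (j in seq_along(scored_list)) {
    if (j <= i) next
    a <- scored_list[[i]]; b <- scored_list[[j]]
    for (src in intersect(unique(a$source), unique(b$source))) {
      ai <- a[a$source == src, ]; bi <- b[b$source == src, ]
      m <- merge(ai[, c("cell_id", "locus", "sp")],
                 bi[, c("cell_id", "locus", "sp")],
                 by = c("cell_id", "locus"))
      row <- if (nrow(m) < 3L) {
        data.frame(analysis = NA_character_, statistic = "pearson_r",
                   estimate = NA_real_, p_value = NA_real_, n = nrow(m),
                   degenerate = TRUE, stringsAsFactors = FALSE)
      } else {
        correlate(m$sp.x, m$sp.y, method = "pearson")
      }
      row$provider1 <- nm[i]; row$provider2 <- nm[j]; row$source <- src
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("provider1", "provider2", "source", "estimate", "p_value", "n",
          "degenerate")]
}

#' Association between SP and binding affinity
#'
#' Spearman correlation between SP and the dissociation constant Kd over
#' matched cells. `scope = "intraclonal"` restricts the analysis to the
#' members of one clone (the within-tree analysis); `"polyclonal"` uses
#' every matched cell.
#'
#' @param scored A [score_repertoire()] output (typically filtered to
#'   one locus and source).
#' @param affinity_table Data frame with columns `sequence_id` (matching
#'   `cell_id`) and `kd` (> 0), and `clone_id` when intraclonal scope is
#'   requested.
#' @param scope `"polyclonal"` or `"intraclonal"`.
#' @param clone Clone id for intraclonal scope.
#' @return One-row data frame as from [correlate()], with an
#'   `n_unmatched` attribute counting dropped ids.
#' @export
affinity_association <- function(scored, affinity_table,
                                 scope = c("polyclonal", "intraclonal"),
                                 clone = NULL) {
  scope <- match.arg(scope)
  stopifnot(all(c("sequence_id", "kd") %in% names(affinity_table)))
  if (any(affinity_table$kd <= 0)) stop("kd must be strictly positive")
  tab <- affinity_table
  if (scope == "intraclonal") {
    if (is.null(clone) || !"clone_id" %in% names(tab)) {
      stop("intraclonal scope requires a clone id and a clone_id column")
    }
    tab <- tab[tab$clone_id == clone, ]
  }
  m <- merge(scored[, c("cell_id", "sp")], tab,
             by.x = "cell_id", by.y = "sequence_id")
  if (nrow(m) == 0L) stop("no overlap between scored cells and affinity table")
  res <- correlate(m$sp, m$kd, method = "spearman",
                   analysis = paste0("affinity_", scope))
  attr(res, "n_unmatched") <- nrow(tab) - nrow(m)
  res
}

#' Mean SP per group
#'
#' Small helper aggregating a feature table to per-group mean SP, the
#' form [frequency_association()] consumes.
#'
#' @param table A [sp_feature_table()] output (or any data frame with an
#'   `sp` column).
#' @param group Name of the grouping column.
#' @return Data frame `group, mean_sp, n`.
#' @export
mean_sp_by <- function(table, group) {
  stopifnot("sp" %in% names(table), group %in% names(table))
  ok <- is.finite(table$sp) & !is.na(table[[group]])
  agg <- stats::aggregate(table$sp[ok], by = list(group = table[[group]][ok]),
                          FUN = mean)
  n <- stats::aggregate(table$sp[ok], by = list(group = table[[group]][ok]),
                        FUN = length)
  data.frame(group = agg$group, mean_sp = agg$x, n = n$x,
             stringsAsFactors = FALSE)
}
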