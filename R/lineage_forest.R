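#' Levenshtein edit distance between two amino-acid strings
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion),
#' delegated to [utils::adist()].
#'
#' @param a,b Strings.
#' @return Non-negative integer.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Build a germline-rooted lineage tree for one clone
#'
#' Grows a tree over the unique sequences of a clone by iterative
#' minimum-distance attachment: starting from the germline root, the
#' unattached sequence whose minimum Levenshtein distance to any
#' attached node is smallest is attached as a child of that nearest
#' node, until all sequences are placed. This Prim-style growth yields a
#' minimum spanning tree of the complete Levenshtein graph over the
#' germline and the unique sequences. Ties are resolved
#' deterministically: prefer the candidate parent with the larger cell
#' count (expanded intermediates are the more plausible ancestors), then
#' the lexicographically smaller child sequence, then the earlier
#' attached parent.
#'
#' @param clone_sequences Named integer vector: names are the unique
#'   (non-germline-labelled) sequences of the clone, values their cell
#'   counts (>= 1). Duplicate names are an error — merge counts first.
#' @param germline The clone's germline sequence (root; cell count 0).
#' @param clone_id Optional clone label carried on the tree.
#' @return A `lineage_tree`: list with `clone_id`, `nodes` (data frame
#'   `node_id, sequence_aa, cell_count, is_germline`), and `edges` (data
#'   frame `parent, child, weight`).
#' @export
build_tree <- function(clone_sequences, germline, clone_id = NA_character_) {
  seqs <- names(clone_sequences)
  counts <- as.integer(clone_sequences)
  if (is.null(seqs) || length(seqs) == 0L) stop("clone_sequences must be a named vector")
  if (anyDuplicated(seqs)) stop("duplicate sequences must be pre-merged")
  if (!is.character(germline) || !nzchar(germline)) stop("germline must be non-empty")
  if (any(counts < 1L)) stop("cell counts must be >= 1")

  all_seq <- c(germline, seqs)
  d <- utils::adist(all_seq)               # (n+1) x (n+1), row/col 1 = germline
  n <- length(seqs)
  node_id <- c("germline", paste0("node", seq_len(n)))
  cell_count <- c(0L, counts)
  attached <- c(TRUE, rep(FALSE, n))
  parent_of <- rep(NA_integer_, n + 1L)
  order_attached <- integer(0)

  for (step in seq_len(n)) {
    att <- which(attached); un <- which(!attached)
    sub <- d[att, un, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    parents <- att[cand[, 1L]]
    children <- un[cand[, 2L]]
    # tie rules: larger parent cell_count, then smaller child sequence,
    # then earlier parent index
    ord <- order(-cell_count[parents], all_seq[children], parents)
    pick <- ord[1L]
    parent_of[children[pick]] <- parents[pick]
    attached[children[pick]] <- TRUE
    order_attached <- c(order_attached, children[pick])
  }
  edges <- data.frame(
    parent = node_id[parent_of[order_attached]],
    child = node_id[order_attached],
    weight = d[cbind(parent_of[order_attached], order_attached)],
    stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = node_id, sequence_aa = all_seq,
                      cell_count = cell_count,
                      is_germline = c(TRUE, rep(FALSE, n)),
                      stringsAsFactors = FALSE)
  structure(list(clone_id = clone_id, nodes = nodes, edges = edges),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree '%s': %d nodes, %d edges, total weight %d\n",
              x$clone_id, nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Total edge length from the germline root to a node
#'
#' @param tree A [build_tree()] result.
#' @param node_id A node identifier in the tree.
#' @return Sum of Levenshtein edge weights on the unique root-to-node
#'   path (0 for the root).
#' @export
root_path_length <- function(tree, node_id) {
  stopifnot(inherits(tree, "lineage_tree"))
  if (!node_id %in% tree$nodes$node_id) stop("unknown node: ", node_id)
  total <- 0L
  cur <- node_id
  while (cur != "germline") {
    e <- tree$edges[tree$edges$child == cur, ]
    if (nrow(e) != 1L) stop("broken tree at node ", cur)
    total <- total + e$weight
    cur <- e$parent
  }
  total
}

#' Build the lineage forest of a repertoire
#'
#' One germline-rooted tree per clone, over the unique heavy-chain
#' sequences (default) or the concatenated heavy+light sequences. The
#' clone's germline is the most frequent heavy (or heavy+light) germline
#' among its member cells. Each tree also carries `node_cells`, the
#' mapping from nodes to the cell barcodes they contain, and per-node
#' isotype counts.
#'
#' @param rep A [bcr_repertoire].
#' @param chains `"heavy"` or `"paired"` (heavy+light concatenation).
#' @return A `lineage_forest`: named list of `lineage_tree`s keyed by
#'   clone id.
#' @export
build_forest <- function(rep, chains = c("heavy", "paired")) {
  stopifnot(inherits(rep, "bcr_repertoire"))
  chains <- match.arg(chains)
  cells <- rep$cells
  ch <- rep$chains
  hv <- ch[ch$locus == "heavy", ]
  lt <- ch[ch$locus == "light", ]
  hseq <- stats::setNames(hv$sequence_aa, hv$cell_id)
  hger <- stats::setNames(hv$germline_aa, hv$cell_id)
  lseq <- stats::setNames(lt$sequence_aa, lt$cell_id)
  lger <- stats::setNames(lt$germline_aa, lt$cell_id)
  seq_of <- function(ids) {
    if (chains == "heavy") unname(hseq[ids])
    else paste0(unname(hseq[ids]), unname(lseq[ids]))
  }
  germ_of <- function(ids) {
    if (chains == "heavy") unname(hger[ids])
    else paste0(unname(hger[ids]), unname(lger[ids]))
  }
  forest <- list()
  for (cl in unique(cells$clone_id)) {
    ids <- cells$cell_id[cells$clone_id == cl]
    s <- seq_of(ids)
    g <- germ_of(ids)
    germline <- names(sort(table(g), decreasing = TRUE))[1L]
    counts <- table(s)
    tree <- build_tree(stats::setNames(as.integer(counts), names(counts)),
                       germline, clone_id = cl)
    node_of_seq <- stats::setNames(tree$nodes$node_id[!tree$nodes$is_germline],
                                   tree$nodes$sequence_aa[!tree$nodes$is_germline])
    # a sequence identical to the germline maps to its own node only if present;
    # unique sequences always have a node, so the lookup below is total
    tree$node_cells <- data.frame(node_id = unname(node_of_seq[s]),
                                  cell_id = ids, stringsAsFactors = FALSE)
    iso <- cells$isotype[match(ids, cells$cell_id)]
    tree$node_isotypes <- table(tree$node_cells$node_id, iso)
    tree$sample_id <- cells$sample_id[match(ids[1L], cells$cell_id)]
    forest[[cl]] <- tree
  }
  structure(forest, class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("lineage_forest: %d clonal trees, %d nodes total\n",
              length(x), sum(vapply(x, function(t) nrow(t$nodes), 0L))))
  invisible(x)
}

#' Newick serialization of a lineage tree
#'
#' Writes the tree with node identifiers as labels and Levenshtein edge
#' weights as branch lengths. Lineage trees have labelled internal nodes
#' and unary chains (an observed sequence can have a single descendant),
#' which the `phylo` tip/internal representation cannot carry, so the
#' serializer works on the tree structure directly.
#'
#' @param tree A [build_tree()] result.
#' @return A single Newick string, terminated by `;`.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  children <- split(tree$edges$child, tree$edges$parent)
  weight <- stats::setNames(tree$edges$weight, tree$edges$child)
  rec <- function(id) {
    kids <- children[[id]]
    lab <- if (id == "germline") id else sprintf("%s:%d", id, weight[[id]])
    if (is.null(kids)) return(lab)
    sprintf("(%s)%s", paste(vapply(sort(kids), rec, ""), collapse = ","), lab)
  }
  paste0(rec("germline"), ";")
}

#' Node attribute table of a tree
#'
#' @param tree A [build_tree()] result.
#' @return Data frame `node_id, sequence_aa, cell_count,
#'   root_path_length`.
#' @export
node_attributes <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  data.frame(node_id = tree$nodes$node_id,
             sequence_aa = tree$nodes$sequence_aa,
             cell_count = tree$nodes$cell_count,
             root_path_length = vapply(tree$nodes$node_id,
                                       function(id) as.numeric(root_path_length(tree, id)),
                                       numeric(1)),
             stringsAsFactors = FALSE)
}
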