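# Shared fixtures and independent oracles for the test suite.

# random row-stochastic L x 20 matrix for a random sequence
rand_pm <- function(L) {
  seq_aa <- paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  m <- matrix(stats::runif(L * 20), nrow = L)
  probability_matrix(seq_aa, m / rowSums(m))
}

# independent SP oracle: explicit per-position loop, no shared code with
# compute_sp (indexes via which() on the alphabet, accumulates a sum)
sp_oracle <- function(pm, positions = NULL) {
  s <- attr(pm, "sequence_aa")
  if (is.null(positions)) positions <- seq_len(nchar(s))
  total <- 0
  for (i in positions) {
    letter <- substr(s, i, i)
    j <- which(aa_alphabet() == letter)
    total <- total + log(unname(pm[i, j]))
  }
  total / length(positions)
}

# independent MST oracle: Kruskal with union-find on a symmetric distance
# matrix (build_tree grows Prim-style, a different algorithm)
kruskal_mst_weight <- function(d) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- which(upper.tri(d), arr.ind = TRUE)
  edges <- edges[order(d[edges]), , drop = FALSE]
  total <- 0
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + d[edges[k, 1], edges[k, 2]]
    }
  }
  total
}

# one chain-record row in the raw layout filter_cells() accepts
chain_row <- function(cell_id, locus, seq = "ACDEFGHIKL", germ = seq,
                      v_call = if (locus == "heavy") "IGHV1-1*01" else "IGKV1-1*01",
                      c_call = if (locus == "heavy") "IGHM" else "IGKC",
                      cdr3_start = 2L, cdr3_end = 6L, sample_id = "s1") {
  data.frame(cell_id = cell_id, locus = locus, sequence_aa = seq,
             germline_aa = germ, v_call = v_call, c_call = c_call,
             cdr3_aa = substr(seq, cdr3_start + 1L, cdr3_end),
             cdr3_start = cdr3_start, cdr3_end = cdr3_end,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# complete well-formed cell: one heavy + one light row
good_cell <- function(cell_id, seq_h = "ACDEFGHIKL", germ_h = seq_h,
                      c_call = "IGHM", sample_id = "s1") {
  rbind(chain_row(cell_id, "heavy", seq_h, germ_h, c_call = c_call,
                  sample_id = sample_id),
        chain_row(cell_id, "light", sample_id = sample_id))
}

# 12-cell fixture exercising every filter rule: 6 clean cells,
# 1 double-heavy, 1 heavy-only, 1 missing germline, 1 missing heavy
# C-gene, and one barcode present in two samples (both copies removed),
# giving 12 cell units total, 6 retained and 6 removed.
filter_fixture <- function() {
  rows <- rbind(
    good_cell("c01"), good_cell("c02"), good_cell("c03"),
    good_cell("c04", c_call = "IGHG1"), good_cell("c05", c_call = "IGHA1"),
    good_cell("c06"),
    # rule 1: two heavy transcripts
    rbind(chain_row("c08", "heavy"), chain_row("c08", "heavy"),
          chain_row("c08", "light")),
    # rule 2: heavy-only cell
    chain_row("c09", "heavy"),
    # rule 3: heavy chain with no germline annotation
    rbind(chain_row("c10", "heavy", germ = ""), chain_row("c10", "light")),
    # rule 4: heavy chain with no C-gene call
    rbind(chain_row("c11", "heavy", c_call = ""), chain_row("c11", "light")),
    # rule 5: same barcode in two samples (counts as 2 removed cells)
    good_cell("c12", sample_id = "s1"))
  rbind(rows, good_cell("c12", sample_id = "s2"))
}

# small simulated repertoire ready for scoring/tree analyses
quick_sim <- function(n_cells = 60, seed = 7, ...) {
  simulate_repertoire(sim_config(n_cells = n_cells, seed = seed, ...))
}
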