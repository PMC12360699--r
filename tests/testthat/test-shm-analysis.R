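test_that("competition rank matches the counting oracle on random columns", {
  set.seed(83)
  for (i in 1:500) {
    col <- stats::runif(20)
    col <- col / sum(col)
    if (i %% 7 == 0) col[sample(20, 2)] <- col[sample(20, 1)]  # force ties
    j <- sample(20, 1)
    expect_equal(competition_rank(col, j), 1L + sum(col > col[j]))
  }
  # argmax is always rank 1, even under ties
  col <- rep(0.05, 20)
  expect_equal(competition_rank(col, 7), 1L)
})

test_that("edge substitutions rank the child residue in the parent matrix", {
  # parent column: A 0.5, C 0.3, D 0.2; parent has A, child has C
  germ <- "AAAA"
  tree <- build_tree(c(CAAA = 1L), germ)
  mfn <- function(s) {
    m <- matrix(0, nchar(s), 20)
    m[, match("A", aa_alphabet())] <- 0.5
    m[, match("C", aa_alphabet())] <- 0.3
    m[, match("D", aa_alphabet())] <- 0.2
    probability_matrix(s, m)
  }
  p <- likelihood_provider("fixed", mfn)
  rec <- edge_substitutions(tree, p)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$position, 0L)
  expect_equal(rec$from_aa, "A")
  expect_equal(rec$to_aa, "C")
  expect_equal(rec$rank_child, 2L)
  expect_equal(rec$rank_parent, 1L)
  expect_equal(rec$rl_parent_residue, 0.5)
})

test_that("one-hot providers give rank 1 and multi-position edges average", {
  germ <- "AAAAAA"
  child <- "CCAAAA"  # two substitutions on one edge
  onehot_child <- likelihood_provider("oh", function(s) {
    m <- matrix(0, nchar(s), 20)
    m[cbind(seq_len(nchar(s)), aa_index(aa_split(child)))] <- 1
    probability_matrix(s, m)
  })
  tree <- build_tree(stats::setNames(1L, child), germ)
  rec <- edge_substitutions(tree, onehot_child)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$rank_child == 1L))
  expect_equal(unique(rec$edge_rank), 1)
  # explicit averaging rule: ranks 1 and 3 give edge_rank 2
  expect_equal(mean(c(1L, 3L)), 2)
  mixed <- likelihood_provider("mixed", function(s) {
    m <- matrix(1e-4, nchar(s), 20)
    m[1, match("C", aa_alphabet())] <- 1          # child residue top at pos 1
    m[2, match("W", aa_alphabet())] <- 0.6        # two residues above C at pos 2
    m[2, match("Y", aa_alphabet())] <- 0.3
    m[2, match("C", aa_alphabet())] <- 0.08
    probability_matrix(s, m / rowSums(m))
  })
  rec2 <- edge_substitutions(tree, mixed)
  expect_equal(sort(rec2$rank_child), c(1L, 3L))
  expect_equal(unique(rec2$edge_rank), 2)
})

test_that("unequal-length edges are skipped and counted", {
  tree <- build_tree(c(AAAT = 1L, AAATT = 1L), "AAAA")
  p <- uniform_provider()
  rec <- edge_substitutions(tree, p)
  expect_gte(attr(rec, "skipped_unequal_length"), 1L)
})

test_that("germline edges can be excluded from substitution scoring", {
  tree <- build_tree(c(AAAT = 1L, AATT = 1L), "AAAA")
  p <- uniform_provider()
  with_g <- edge_substitutions(tree, p, include_germline_edges = TRUE)
  without_g <- edge_substitutions(tree, p, include_germline_edges = FALSE)
  expect_true("germline" %in% with_g$parent_id)
  expect_false("germline" %in% without_g$parent_id)
  expect_lt(nrow(without_g), nrow(with_g))
})

test_that("conserved vs mutating likelihoods match closed forms", {
  # uniform provider: both means are exactly 1/20
  tree <- build_tree(c(CAAAAAAAAA = 1L), "AAAAAAAAAA")
  u <- conserved_vs_mutating(tree, uniform_provider())
  expect_equal(u$mean_rl_mutating, 0.05)
  expect_equal(u$mean_rl_conserved, 0.05)
  # germline-anchored q = 0.7, parent is the germline: parent residue IS the
  # germline residue at every position, so both means equal q
  g <- conserved_vs_mutating(tree, germline_anchored_provider(0.7))
  expect_equal(g$mean_rl_mutating, 0.7, tolerance = 1e-12)
  expect_equal(g$mean_rl_conserved, 0.7, tolerance = 1e-12)
})

test_that("provider-targeted simulations mutate low-likelihood positions", {
  # single-round lineages keep every mutating edge guided by exactly the
  # matrix of its tree parent, the cleanest read-out of position targeting
  prov <- positional_profile_provider(0.15, seed = 15)
  sim <- simulate_repertoire(sim_config(
    n_cells = 200, max_shm_rounds = 1, per_round_substitutions = 2, seed = 87,
    mutation_strategy = "provider", provider = prov))
  rep <- filter_cells(sim$chains, clonotype = "input_clone_id")
  forest <- build_forest(rep)
  cvm <- conserved_vs_mutating(forest, prov)
  expect_lt(cvm$mean_rl_mutating, cvm$mean_rl_conserved)
  expect_true(is.na(cvm$p_value) || (cvm$p_value >= 0 && cvm$p_value <= 1))
})

test_that("mutations placed at the model's least likely residues test significant", {
  # constructed scenario: every edge mutates the position where the parent
  # residue has the lowest likelihood under the provider
  prov <- positional_profile_provider(0.3, seed = 77)
  set.seed(78)
  germ <- paste(sample(aa_alphabet(), 40, replace = TRUE), collapse = "")
  pm <- residue_probabilities(prov, germ)
  rl_self <- unname(pm[cbind(1:40, aa_index(aa_split(germ)))])
  low_pos <- order(rl_self)[1:25]
  children <- vapply(low_pos, function(p) {
    s <- aa_split(germ)
    s[p] <- setdiff(aa_alphabet(), s[p])[1]
    paste(s, collapse = "")
  }, "")
  tree <- build_tree(stats::setNames(rep(1L, 25), children), germ)
  cvm <- conserved_vs_mutating(tree, prov)
  expect_lt(cvm$mean_rl_mutating, cvm$mean_rl_conserved)
  expect_lt(cvm$p_value, 0.01)
})

test_that("shannon evenness has the stated closed forms and bounds", {
  expect_equal(shannon_evenness(rep(0.05, 20)), 1)
  expect_equal(shannon_evenness(c(1, rep(0, 19))), 0)
  expect_equal(shannon_evenness(c(0.5, 0.5, rep(0, 18))), log(2) / log(20),
               tolerance = 1e-12)
  expect_error(shannon_evenness(c(-0.1, 1.1, rep(0, 18))), "non-negative")
  expect_error(shannon_evenness(rep(0.04, 20)), "sum to 1")
  set.seed(89)
  for (i in 1:100) {
    col <- stats::runif(20); col <- col / sum(col)
    ev <- shannon_evenness(col)
    expect_gte(ev, 0); expect_lte(ev, 1)
    expect_equal(shannon_evenness(sample(col)), ev, tolerance = 1e-12)
  }
  pm <- rand_pm(10)
  expect_length(matrix_evenness(pm), 10)
})

test_that("mean substitution rank averages samples, not cells", {
  rec <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    clone_id = c("a", "b", "c"), parent_id = c("p", "p", "p"),
    child_id = c("x", "y", "z"),
    edge_rank = c(1, 3, 4))
  ms <- mean_substitution_rank(rec)
  expect_equal(ms$per_sample$mean_rank[ms$per_sample$sample_id == "s1"], 2)
  expect_equal(ms$per_sample$mean_rank[ms$per_sample$sample_id == "s2"], 4)
  expect_equal(ms$grand_mean, 3)  # unweighted over samples
  all_one <- transform(rec, edge_rank = 1)
  expect_equal(mean_substitution_rank(all_one)$grand_mean, 1)
})
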