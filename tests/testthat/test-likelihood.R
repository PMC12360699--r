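test_that("probability_matrix validates its invariants", {
  m <- matrix(1 / 20, 2, 20)
  pm <- probability_matrix("AC", m)
  expect_s3_class(pm, "probability_matrix")
  expect_error(probability_matrix("AC", m[1, , drop = FALSE]), "L x 20")
  expect_error(probability_matrix("AX", m), "alphabet")
  bad <- m; bad[1, 1] <- 0.9
  expect_error(probability_matrix("AC", bad), "sum to 1")
  neg <- m; neg[1, 1] <- -0.05; neg[1, 2] <- 0.15
  expect_error(probability_matrix("AC", neg), "\\[0, 1\\]")
})

test_that("compute_sp matches analytic closed forms", {
  pm <- probability_matrix("ACDE", matrix(0.05, 4, 20))
  expect_equal(as.numeric(compute_sp(pm)), log(0.05), tolerance = 1e-12)
  # one-hot on the observed residues gives SP = 0
  oh <- matrix(0, 3, 20)
  oh[cbind(1:3, match(c("W", "A", "C"), aa_alphabet()))] <- 1
  expect_equal(as.numeric(compute_sp(probability_matrix("WAC", oh))), 0)
  # direct two-position arithmetic
  m <- matrix((1 - 0.5) / 19, 2, 20)
  m[1, match("A", aa_alphabet())] <- 0.5
  m[2, ] <- (1 - 0.25) / 19
  m[2, match("C", aa_alphabet())] <- 0.25
  pm2 <- probability_matrix("AC", m)
  expect_equal(as.numeric(compute_sp(pm2)), (log(0.5) + log(0.25)) / 2,
               tolerance = 1e-12)
})

test_that("compute_sp equals the independent per-position oracle", {
  set.seed(101)
  for (i in 1:50) {
    pm <- rand_pm(sample(3:40, 1))
    expect_equal(as.numeric(compute_sp(pm)), sp_oracle(pm), tolerance = 1e-12)
    k <- sample(nrow(pm), sample(nrow(pm), 1))
    expect_equal(as.numeric(compute_sp(pm, positions = k)), sp_oracle(pm, k),
                 tolerance = 1e-12)
  }
})

test_that("SP is invariant under matched permutation of positions and rows", {
  set.seed(102)
  pm <- rand_pm(12)
  perm <- sample(12)
  s2 <- paste(aa_split(attr(pm, "sequence_aa"))[perm], collapse = "")
  pm2 <- probability_matrix(s2, unclass(pm)[perm, ])
  expect_equal(as.numeric(compute_sp(pm)), as.numeric(compute_sp(pm2)),
               tolerance = 1e-12)
})

test_that("SP lies between the per-position log-probability extremes", {
  set.seed(103)
  pm <- rand_pm(20)
  lp <- observed <- log(unclass(pm)[cbind(1:20, aa_index(aa_split(attr(pm, "sequence_aa"))))])
  expect_gte(as.numeric(compute_sp(pm)), min(lp))
  expect_lte(as.numeric(compute_sp(pm)), max(lp))
})

test_that("compute_sp guards degenerate inputs", {
  pm <- probability_matrix("ACDE", matrix(0.05, 4, 20))
  expect_error(compute_sp(pm, positions = integer(0)), "non-empty")
  expect_error(compute_sp(pm, positions = 5), "out of range")
  # exact-zero observed probability is clamped to the floor and counted
  m <- matrix(0, 2, 20)
  m[1, ] <- 1 / 20
  m[2, match("C", aa_alphabet())] <- 0
  m[2, -match("C", aa_alphabet())] <- 1 / 19
  sp <- compute_sp(probability_matrix("AC", m), floor = 1e-10)
  expect_equal(attr(sp, "n_floored"), 1L)
  expect_equal(as.numeric(sp), (log(1 / 20) + log(1e-10)) / 2, tolerance = 1e-12)
})

test_that("germline-anchored provider has the stated closed form", {
  germ <- paste(rep("A", 100), collapse = "")
  p <- germline_anchored_provider(0.7, stats::setNames(germ, germ))
  expect_equal(as.numeric(compute_sp(residue_probabilities(p, germ))), log(0.7),
               tolerance = 1e-12)
  # k mismatches at q = 0.7, L = 100
  for (k in c(1, 5, 10)) {
    s <- paste(c(rep("C", k), rep("A", 100 - k)), collapse = "")
    register_germlines(p, s, germ)
    expect_equal(as.numeric(compute_sp(residue_probabilities(p, s))),
                 ((100 - k) * log(0.7) + k * log(0.3 / 19)) / 100,
                 tolerance = 1e-12)
  }
  expect_error(germline_anchored_provider(1 / 20), "strictly between")
  expect_error(germline_anchored_provider(1), "strictly between")
  expect_error(register_germlines(p, "ACD", "AC"), "length")
  expect_error(residue_probabilities(p, "WWWW"), "no germline registered")
})

test_that("uniform provider scores every sequence at log(1/20)", {
  p <- uniform_provider()
  expect_equal(as.numeric(compute_sp(residue_probabilities(p, "MKVL"))),
               log(1 / 20), tolerance = 1e-12)
})

test_that("profile provider is deterministic and row-stochastic", {
  p <- positional_profile_provider(0.25, seed = 9)
  a <- residue_probabilities(p, "ACDEFGHIKL")
  b <- residue_probabilities(p, "ACDEFGHIKL")
  expect_identical(unclass(a), unclass(b))
  expect_true(all(abs(rowSums(unclass(a)) - 1) < 1e-9))
  c2 <- residue_probabilities(p, "ACDEFGHIKM")
  expect_false(identical(unclass(a), unclass(c2)))
})

test_that("score_repertoire emits one record per cell, locus and source", {
  sim <- quick_sim(n_cells = 12)
  rep <- filter_cells(sim$chains)
  p <- germline_anchored_provider(0.7)
  sc <- score_repertoire(rep, p,
                         sources = c("full_vdj", "cdr3_from_vdj", "cdr3_only"))
  # 12 cells x 2 loci x 3 sources
  expect_equal(nrow(sc), 12 * 2 * 3)
  expect_true(all(sc$sp <= 0))
  expect_true(all(table(sc$source) == 24))
  # paired SP of a germline cell equals log(q)
  sc_p <- score_repertoire(rep, p, sources = "paired")
  expect_equal(nrow(sc_p), 12)
  tc <- sim$truth$cells
  germ_cells <- tc$cell_id[tc$rounds_total == 0]
  if (length(germ_cells)) {
    expect_equal(sc_p$sp[sc_p$cell_id == germ_cells[1]], log(0.7),
                 tolerance = 1e-12)
  }
})

test_that("cdr3_from_vdj and cdr3_only agree for position-independent providers", {
  sim <- quick_sim(n_cells = 6)
  rep <- filter_cells(sim$chains)
  p <- germline_anchored_provider(0.8)
  sc <- score_repertoire(rep, p, sources = c("cdr3_from_vdj", "cdr3_only"))
  a <- sc[sc$source == "cdr3_from_vdj", ]
  b <- sc[sc$source == "cdr3_only", ]
  m <- merge(a, b, by = c("cell_id", "locus"))
  # this provider's column at a position depends only on the germline residue
  expect_equal(m$sp.x, m$sp.y, tolerance = 1e-12)
})

test_that("paired scoring requires provider capability", {
  p <- likelihood_provider("h_only", function(s) {
    probability_matrix(s, matrix(1 / 20, nchar(s), 20))
  }, paired_scoring = FALSE)
  sim <- quick_sim(n_cells = 4)
  rep <- filter_cells(sim$chains)
  expect_error(score_repertoire(rep, p, sources = "paired"), "paired")
})
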