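#' Configuration for the synthetic repertoire generator
#'
#' Bundles and validates the parameters of [simulate_repertoire()]. The
#' defaults emulate a single-cell BCR sample after an immune challenge:
#' a few hundred to a few thousand cells, a heavy-tailed clone-size
#' distribution with expanded clones and many singletons, V(D)J
#' amino-acid sequences of ~110 residues with a CDR3 near the 3' end,
#' several rounds of somatic hypermutation accumulating down each
#' lineage, and isotype switching whose probability grows with mutation
#' load.
#'
#' @param n_cells Number of cells to simulate.
#' @param n_germlines Number of distinct germline V(D)J ancestors; each
#'   clone descends from one of them.
#' @param vdj_length Length (amino acids) of every simulated V(D)J
#'   sequence (no indels are simulated).
#' @param cdr3_span Integer pair, 0-based half-open CDR3 interval within
#'   `[0, vdj_length)`.
#' @param clone_size_alpha Exponent of the discrete power law
#'   `P(size = s) proportional to s^-alpha` (truncated at `n_cells`) from
#'   which clone sizes are drawn; ~2.5 gives the mix of expanded clones
#'   and singletons seen in real repertoires.
#' @param max_shm_rounds Maximum number of SHM rounds accumulated along
#'   any root-to-cell lineage path.
#' @param per_round_substitutions Point substitutions applied per SHM
#'   round (distinct positions within a round).
#' @param switch_coupling Probability, per SHM round, that an unswitched
#'   lineage switches IgM -> IgG/IgA; the switched state is inherited.
#' @param affinity_coupling Default slope linking log10(Kd) to SHM
#'   distance in [simulate_affinity_table()].
#' @param mutation_strategy `"uniform"` substitutes with one of the 19
#'   alternative residues uniformly; `"provider"` draws the replacement
#'   from `provider`'s probability column at the mutated position
#'   (renormalized over the alternatives), emulating hypermutation that
#'   follows the model's preferences.
#' @param provider A [likelihood_provider()], required when
#'   `mutation_strategy = "provider"`.
#' @param sample_id Sample label written on every simulated chain.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000L, n_germlines = 8L, vdj_length = 110L,
                       cdr3_span = c(95L, 107L), clone_size_alpha = 2.5,
                       max_shm_rounds = 8L, per_round_substitutions = 2L,
                       switch_coupling = 0.3, affinity_coupling = 0.2,
                       mutation_strategy = c("uniform", "provider"),
                       provider = NULL, sample_id = "sim1", seed = 1L) {
  mutation_strategy <- match.arg(mutation_strategy)
  cfg <- list(n_cells = as.integer(n_cells), n_germlines = as.integer(n_germlines),
              vdj_length = as.integer(vdj_length),
              cdr3_span = as.integer(cdr3_span),
              clone_size_alpha = clone_size_alpha,
              max_shm_rounds = as.integer(max_shm_rounds),
              per_round_substitutions = as.integer(per_round_substitutions),
              switch_coupling = switch_coupling,
              affinity_coupling = affinity_coupling,
              mutation_strategy = mutation_strategy, provider = provider,
              sample_id = sample_id, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cells >= 1L, n_germlines >= 1L, vdj_length >= 1L,
              length(cdr3_span) == 2L, max_shm_rounds >= 0L,
              per_round_substitutions >= 1L, clone_size_alpha > 0,
              switch_coupling >= 0, switch_coupling <= 1)
    if (cdr3_span[1] < 0L || cdr3_span[2] > vdj_length ||
        cdr3_span[1] >= cdr3_span[2]) {
      stop("cdr3_span must be a non-empty 0-based half-open interval inside the sequence")
    }
    if (per_round_substitutions * max_shm_rounds >= vdj_length) {
      stop("mutation saturation: per_round_substitutions * max_shm_rounds must be < vdj_length")
    }
  })
  if (mutation_strategy == "provider" && !inherits(provider, "likelihood_provider")) {
    stop("mutation_strategy = 'provider' requires a likelihood_provider")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired-chain single-cell BCR repertoire with known truth
#'
#' Generates a repertoire with the statistical structure the downstream
#' analyses assume: clone sizes from a truncated discrete power law,
#' germline-anchored lineages in which each cell derives from its
#' lineage parent by whole SHM rounds of point substitutions (no
#' indels), isotype switching coupled to mutation load, and a paired
#' light chain that mutates at half the heavy-chain rate (rounds halved,
#' rounded down, applied directly to the light germline). Every applied
#' substitution is recorded, so replaying a cell's truth log against its
#' germline reproduces its sequence exactly.
#'
#' @param config A [sim_config()].
#' @return A `simulated_repertoire`: list with
#'   \describe{
#'     \item{chains}{chain records (two rows per cell) in the layout
#'       [filter_cells()] accepts;}
#'     \item{truth}{`cells` data frame (`cell_id, clone_id, parent_id,
#'       rounds_extra, rounds_total, switched`) and `substitutions` data
#'       frame of every applied event (`cell_id, locus, event, position`
#'       (0-based), `from, to`) in application order, cumulative from the
#'       germline;}
#'     \item{germlines}{per-clone germline sequences and V-calls.}
#'   }
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed({
    set.seed(config$seed)
    simulate_repertoire_impl(config)
  })
}

simulate_repertoire_impl <- function(cfg) {
  aa <- aa_alphabet()
  L <- cfg$vdj_length
  rand_seq <- function() paste(sample(aa, L, replace = TRUE), collapse = "")
  germ <- data.frame(
    germline_id = seq_len(cfg$n_germlines),
    heavy = vapply(seq_len(cfg$n_germlines), function(i) rand_seq(), ""),
    light = vapply(seq_len(cfg$n_germlines), function(i) rand_seq(), ""),
    v_call_heavy = sprintf("IGHV%d-1*01", seq_len(cfg$n_germlines)),
    v_call_light = sprintf("IGKV%d-1*01", seq_len(cfg$n_germlines)),
    stringsAsFactors = FALSE)

  sizes <- draw_clone_sizes(cfg$n_cells, cfg$clone_size_alpha)
  n_clones <- length(sizes)
  clone_germ <- sample.int(cfg$n_germlines, n_clones, replace = TRUE)

  chains <- vector("list", 2L * cfg$n_cells)
  truth_cells <- vector("list", cfg$n_cells)
  subs <- vector("list", cfg$n_cells)
  cell_no <- 0L

  mutate_rounds <- function(seq_aa, n_rounds, history) {
    # returns list(seq, history): history is the cumulative event log
    for (r in seq_len(n_rounds)) {
      chars <- aa_split(seq_aa)
      if (cfg$mutation_strategy == "provider") {
        pm <- residue_probabilities(cfg$provider, seq_aa)
        # provider-guided targeting: hit positions where the model finds the
        # current residue unlikely, mirroring hypermutation predictability
        rl_self <- pm[cbind(seq_along(chars), aa_index(chars))]
        w <- 1 - rl_self
        if (sum(w) <= 0) w <- rep(1, length(chars))
        pos <- sample.int(nchar(seq_aa), cfg$per_round_substitutions, prob = w)
      } else {
        pos <- sample.int(nchar(seq_aa), cfg$per_round_substitutions)
      }
      for (p in pos) {
        from <- chars[p]
        alts <- setdiff(aa, from)
        if (cfg$mutation_strategy == "provider") {
          w <- pm[p, alts]
          to <- if (sum(w) > 0) sample(alts, 1L, prob = w) else sample(alts, 1L)
        } else {
          to <- sample(alts, 1L)
        }
        chars[p] <- to
        history[[length(history) + 1L]] <- list(position = p - 1L, from = from, to = to)
      }
      seq_aa <- paste(chars, collapse = "")
    }
    list(seq = seq_aa, history = history)
  }

  for (ci in seq_len(n_clones)) {
    g <- germ[clone_germ[ci], ]
    clone_id <- sprintf("sim_clone%d", ci)
    # per-clone lineage state: germline is element 0
    members <- list()  # each: list(cell_id, seq_h, hist_h, rounds_total, switched, iso)
    for (m in seq_len(sizes[ci])) {
      cell_no <- cell_no + 1L
      cell_id <- sprintf("cell%05d", cell_no)
      # total rounds drawn independently of clone size, so SHM load and
      # clonal expansion are decoupled by construction; the parent is any
      # earlier lineage member (or the germline) with fewer-or-equal rounds
      target <- sample.int(cfg$max_shm_rounds + 1L, 1L) - 1L
      germline_parent <- list(cell_id = "germline", seq_h = g$heavy,
                              hist_h = list(), rounds_total = 0L,
                              switched = FALSE, iso = "IGHM")
      cand <- c(list(germline_parent),
                Filter(function(m) m$rounds_total <= target, members))
      parent <- cand[[sample.int(length(cand), 1L)]]
      extra <- target - parent$rounds_total
      mh <- mutate_rounds(parent$seq_h, extra, parent$hist_h)
      switched <- parent$switched
      iso <- parent$iso
      if (!switched && extra > 0L && cfg$switch_coupling > 0) {
        if (any(stats::runif(extra) < cfg$switch_coupling)) {
          switched <- TRUE
          iso <- sample(c("IGHG1", "IGHA1"), 1L)
        }
      }
      rounds_total <- parent$rounds_total + extra
      # light chain: half the heavy rounds, applied directly to the light germline
      ml <- mutate_rounds(g$light, rounds_total %/% 2L, list())
      members[[length(members) + 1L]] <- list(
        cell_id = cell_id, seq_h = mh$seq, hist_h = mh$history,
        rounds_total = rounds_total, switched = switched, iso = iso)

      s0 <- cfg$cdr3_span[1]; s1 <- cfg$cdr3_span[2]
      chains[[2L * cell_no - 1L]] <- data.frame(
        cell_id = cell_id, locus = "heavy", sequence_aa = mh$seq,
        germline_aa = g$heavy, v_call = g$v_call_heavy, c_call = iso,
        cdr3_aa = substr(mh$seq, s0 + 1L, s1), cdr3_start = s0, cdr3_end = s1,
        clone_id = clone_id, sample_id = cfg$sample_id, stringsAsFactors = FALSE)
      chains[[2L * cell_no]] <- data.frame(
        cell_id = cell_id, locus = "light", sequence_aa = ml$seq,
        germline_aa = g$light, v_call = g$v_call_light, c_call = "IGKC",
        cdr3_aa = substr(ml$seq, s0 + 1L, s1), cdr3_start = s0, cdr3_end = s1,
        clone_id = clone_id, sample_id = cfg$sample_id, stringsAsFactors = FALSE)
      truth_cells[[cell_no]] <- data.frame(
        cell_id = cell_id, clone_id = clone_id, germline_id = g$germline_id,
        parent_id = parent$cell_id, rounds_extra = extra,
        rounds_total = rounds_total, switched = switched,
        stringsAsFactors = FALSE)
      subs[[cell_no]] <- event_df(cell_id, "heavy", mh$history) |>
        rbind(event_df(cell_id, "light", ml$history))
    }
  }
  structure(list(chains = do.call(rbind, chains),
                 truth = list(cells = do.call(rbind, truth_cells),
                              substitutions = do.call(rbind, subs)),
                 germlines = germ),
            class = "simulated_repertoire")
}

event_df <- function(cell_id, locus, history) {
  n <- length(history)
  if (n == 0L) {
    return(data.frame(cell_id = character(), locus = character(),
                      event = integer(), position = integer(),
                      from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(cell_id = cell_id, locus = locus, event = seq_len(n),
             position = vapply(history, function(e) e$position, 0L),
             from = vapply(history, function(e) e$from, ""),
             to = vapply(history, function(e) e$to, ""),
             stringsAsFactors = FALSE)
}

# clone sizes from P(s) ~ s^-alpha truncated at n_cells; last clone trimmed
draw_clone_sizes <- function(n_cells, alpha) {
  s <- seq_len(n_cells)
  w <- s^(-alpha)
  sizes <- integer(0)
  total <- 0L
  while (total < n_cells) {
    k <- sample.int(n_cells, 1L, prob = w)
    k <- min(k, n_cells - total)
    sizes <- c(sizes, k)
    total <- total + k
  }
  sizes
}

#' @export
print.simulated_repertoire <- function(x, ...) {
  cat(sprintf("simulated_repertoire: %d cells, %d clones, %d germlines\n",
              nrow(x$truth$cells), length(unique(x$truth$cells$clone_id)),
              nrow(x$germlines)))
  invisible(x)
}

#' Replay a cell's recorded substitutions against its germline
#'
#' Applies the truth event log of one cell and locus, in order, to the
#' clone germline. By construction the result equals the cell's emitted
#' sequence; this is the generator's own audit trail.
#'
#' @param sim A [simulate_repertoire()] result.
#' @param cell_id Cell to replay.
#' @param locus `"heavy"` or `"light"`.
#' @return The reconstructed amino-acid sequence.
#' @export
replay_truth <- function(sim, cell_id, locus = "heavy") {
  stopifnot(inherits(sim, "simulated_repertoire"))
  tc <- sim$truth$cells[sim$truth$cells$cell_id == cell_id, ]
  if (nrow(tc) != 1L) stop("unknown cell_id: ", cell_id)
  g <- sim$germlines[sim$germlines$germline_id == tc$germline_id, ]
  chars <- aa_split(if (locus == "heavy") g$heavy else g$light)
  ev <- sim$truth$substitutions
  ev <- ev[ev$cell_id == cell_id & ev$locus == locus, ]
  ev <- ev[order(ev$event), ]
  for (i in seq_len(nrow(ev))) {
    if (chars[ev$position[i] + 1L] != ev$from[i]) {
      stop("truth log inconsistent at event ", i)
    }
    chars[ev$position[i] + 1L] <- ev$to[i]
  }
  paste(chars, collapse = "")
}

#' Simulate a binding-affinity table coupled to SHM
#'
#' Emits one dissociation constant (Kd) per cell with
#' `log10(Kd) = intercept - coupling * SHM + noise`, where SHM is the
#' heavy-chain Hamming distance to the germline. Positive coupling makes
#' more-mutated cells bind more strongly (lower Kd), the signature of
#' affinity maturation.
#'
#' @param sim A [simulate_repertoire()] result.
#' @param coupling Slope on the SHM distance (log10 Kd units per
#'   substitution).
#' @param noise_sd Standard deviation of Gaussian noise on log10(Kd).
#' @param seed Integer seed.
#' @param intercept Baseline log10(Kd) of an unmutated cell (default -8,
#'   i.e. 10 nM).
#' @return Data frame `sequence_id, clone_id, shm, log10_kd, kd`.
#' @export
simulate_affinity_table <- function(sim, coupling, noise_sd = 0, seed = 1L,
                                    intercept = -8) {
  stopifnot(inherits(sim, "simulated_repertoire"))
  hv <- sim$chains[sim$chains$locus == "heavy", ]
  shm <- hamming_shm(hv$sequence_aa, hv$germline_aa)
  with_preserved_seed({
    set.seed(as.integer(seed))
    log10_kd <- intercept - coupling * shm + stats::rnorm(length(shm), 0, noise_sd)
  })
  data.frame(sequence_id = hv$cell_id,
             clone_id = sim$truth$cells$clone_id[match(hv$cell_id,
                                                       sim$truth$cells$cell_id)],
             shm = shm, log10_kd = log10_kd, kd = 10^log10_kd,
             stringsAsFactors = FALSE)
}

#' Frequency table of unique heavy-chain sequences per group
#'
#' Emulates a database-composition table: the percentage of unique
#' heavy-chain sequences falling in each V-gene family or isotype.
#'
#' @param rep A [simulate_repertoire()] result or a [bcr_repertoire].
#' @param group_by `"v_family"` or `"isotype"`.
#' @return Data frame `group, percent`; percentages sum to 100.
#' @export
simulate_frequency_table <- function(rep, group_by = c("v_family", "isotype")) {
  group_by <- match.arg(group_by)
  hv <- if (inherits(rep, "simulated_repertoire")) {
    rep$chains[rep$chains$locus == "heavy", ]
  } else if (inherits(rep, "bcr_repertoire")) {
    rep$chains[rep$chains$locus == "heavy", ]
  } else stop("rep must be a simulated_repertoire or bcr_repertoire")
  if (nrow(hv) == 0L) stop("empty repertoire")
  grp <- switch(group_by,
                v_family = v_family(hv$v_call),
                isotype = isotype_from_c_call(hv$c_call))
  uni <- unique(data.frame(group = grp, seq = hv$sequence_aa,
                           stringsAsFactors = FALSE))
  tab <- table(uni$group)
  data.frame(group = names(tab),
             percent = 100 * as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Write a simulated repertoire and its truth sidecar to disk
#'
#' Writes `repertoire.tsv` (AIRR-style dialect of [read_repertoire()])
#' and `truth.json` (lineage and substitution ground truth) into
#' `out_dir`.
#'
#' @param sim A [simulate_repertoire()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_simulated_repertoire <- function(sim, out_dir) {
  stopifnot(inherits(sim, "simulated_repertoire"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "repertoire.tsv")
  ch <- sim$chains
  out <- data.frame(cell_id = ch$cell_id, locus = ch$locus,
                    sequence_aa = ch$sequence_aa,
                    germline_alignment_aa = ch$germline_aa,
                    v_call = ch$v_call, c_call = ch$c_call, cdr3_aa = ch$cdr3_aa,
                    cdr3_start = ch$cdr3_start, cdr3_end = ch$cdr3_end,
                    clone_id = sim$truth$cells$clone_id[match(ch$cell_id,
                                                              sim$truth$cells$cell_id)],
                    sample_id = ch$sample_id, stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(cells = sim$truth$cells,
                            substitutions = sim$truth$substitutions),
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, truth))
}
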