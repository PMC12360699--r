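#' Per-residue probability matrix
#'
#' Container for the per-residue likelihoods (RL) of one amino-acid
#' sequence: an `L x 20` row-stochastic matrix whose row `i` holds the
#' model probabilities of each canonical residue at position `i` of
#' `sequence_aa`, with columns ordered as [aa_alphabet()].
#'
#' @param sequence_aa Amino-acid string of length `L` over the canonical
#'   alphabet.
#' @param probs Numeric `L x 20` matrix; every row must sum to 1 within
#'   `1e-6` and all entries must lie in `[0, 1]`.
#' @return A `probability_matrix` object (the matrix, carrying its
#'   sequence as an attribute).
#' @export
probability_matrix <- function(sequence_aa, probs) {
  stopifnot(is.character(sequence_aa), length(sequence_aa) == 1L)
  probs <- as.matrix(probs)
  if (!is_canonical_aa(sequence_aa)) {
    stop("sequence_aa must be a non-empty string over the 20-letter alphabet")
  }
  if (nrow(probs) != nchar(sequence_aa) || ncol(probs) != 20L) {
    stop("probs must be an L x 20 matrix matching nchar(sequence_aa)")
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("probability entries must lie in [0, 1]")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("every probability row must sum to 1 within 1e-6")
  }
  dimnames(probs) <- list(NULL, aa_alphabet())
  structure(probs, sequence_aa = sequence_aa, class = c("probability_matrix", "matrix"))
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat(sprintf("probability_matrix: %d positions x 20 residues for %s\n",
              nrow(x), shorten_seq(attr(x, "sequence_aa"))))
  invisible(x)
}

shorten_seq <- function(s, n = 24L) {
  if (nchar(s) > n) paste0(substr(s, 1L, n), "...") else s
}

#' Construct a likelihood provider
#'
#' A likelihood provider is the contract between sequence scoring and any
#' source of per-residue probabilities (a masked protein language model,
#' or the synthetic providers bundled here). It must return, for a given
#' amino-acid sequence, a [probability_matrix()] with one row per
#' position, deterministically for fixed input.
#'
#' @param name Provider name, used in output tables.
#' @param matrix_fn Function `(sequence_aa) -> probability_matrix`.
#' @param paired_scoring Logical; whether the provider supports joint
#'   heavy+light scoring (per-chain matrices are computed separately and
#'   the log-probabilities pooled).
#' @return A `likelihood_provider` object.
#' @seealso [germline_anchored_provider()], [uniform_provider()],
#'   [positional_profile_provider()]
#' @export
likelihood_provider <- function(name, matrix_fn, paired_scoring = FALSE) {
  stopifnot(is.character(name), is.function(matrix_fn))
  structure(list(name = name, matrix_fn = matrix_fn,
                 paired_scoring = isTRUE(paired_scoring)),
            class = "likelihood_provider")
}

#' @export
print.likelihood_provider <- function(x, ...) {
  cat(sprintf("likelihood_provider '%s' (paired_scoring = %s)\n",
              x$name, x$paired_scoring))
  invisible(x)
}

#' Per-residue probabilities for a sequence
#'
#' @param provider A [likelihood_provider()].
#' @param sequence_aa Amino-acid string to score.
#' @return A [probability_matrix()] aligned to `sequence_aa`.
#' @export
residue_probabilities <- function(provider, sequence_aa) {
  stopifnot(inherits(provider, "likelihood_provider"))
  pm <- provider$matrix_fn(sequence_aa)
  if (!inherits(pm, "probability_matrix")) {
    stop("provider returned an object that is not a probability_matrix")
  }
  if (!identical(attr(pm, "sequence_aa"), sequence_aa)) {
    stop("provider returned a matrix for a different sequence")
  }
  pm
}

#' Germline-anchored synthetic likelihood provider
#'
#' Emulates the germline bias of antibody language models: at every
#' position the probability mass `q` sits on the germline residue and the
#' remainder is spread uniformly over the 19 alternatives. The sequence
#' pseudolikelihood under this provider is a strictly decreasing function
#' of the number of germline mismatches, which makes it the reference
#' provider for the directional analyses on synthetic data.
#'
#' Germlines are registered per scored sequence (the provider must know
#' the equal-length germline of everything it scores);
#' [score_repertoire()] registers a repertoire's germlines, including the
#' CDR3 substrings used for CDR3-only scoring, automatically.
#'
#' @param q Probability on the germline residue; must lie strictly
#'   between 1/20 (the uniform boundary) and 1.
#' @param germlines Optional named character vector mapping sequence to
#'   its germline; more can be added with [register_germlines()].
#' @return A `likelihood_provider` with paired scoring enabled.
#' @export
#' @examples
#' p <- germline_anchored_provider(0.7, c(SEQW = "SEQW"))
#' compute_sp(residue_probabilities(p, "SEQW"))  # log(0.7)
germline_anchored_provider <- function(q, germlines = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q <= 1 / 20 || q >= 1) {
    stop("q must lie strictly between 1/20 and 1")
  }
  map <- new.env(parent = emptyenv())
  register <- function(sequences, germs) {
    stopifnot(length(sequences) == length(germs))
    for (i in seq_along(sequences)) {
      s <- sequences[[i]]; g <- germs[[i]]
      if (nchar(s) != nchar(g)) {
        stop("germline length must equal sequence length: ", shorten_seq(s))
      }
      assign(s, g, envir = map)
    }
    invisible(NULL)
  }
  if (!is.null(germlines)) register(names(germlines), unname(germlines))
  matrix_fn <- function(sequence_aa) {
    g <- get0(sequence_aa, envir = map, inherits = FALSE)
    if (is.null(g)) {
      stop("no germline registered for sequence ", shorten_seq(sequence_aa))
    }
    L <- nchar(sequence_aa)
    probs <- matrix((1 - q) / 19, nrow = L, ncol = 20L)
    probs[cbind(seq_len(L), aa_index(aa_split(g)))] <- q
    probability_matrix(sequence_aa, probs)
  }
  p <- likelihood_provider("germline_anchored", matrix_fn, paired_scoring = TRUE)
  p$q <- q
  p$register <- register
  class(p) <- c("germline_anchored_provider", class(p))
  p
}

#' Register sequence-to-germline pairs with a germline-anchored provider
#'
#' @param provider A [germline_anchored_provider()].
#' @param sequences Character vector of sequences that will be scored.
#' @param germlines Equal-length character vector of their germlines
#'   (each the same length as its sequence).
#' @return The provider, invisibly (registration mutates its map).
#' @export
register_germlines <- function(provider, sequences, germlines) {
  stopifnot(inherits(provider, "germline_anchored_provider"))
  provider$register(sequences, germlines)
  invisible(provider)
}

#' Uniform likelihood provider
#'
#' Assigns probability 1/20 to every residue at every position; the SP of
#' any sequence is `log(1/20)`. Useful as a null model.
#'
#' @return A `likelihood_provider` with paired scoring enabled.
#' @export
uniform_provider <- function() {
  matrix_fn <- function(sequence_aa) {
    L <- nchar(sequence_aa)
    probability_matrix(sequence_aa, matrix(1 / 20, nrow = L, ncol = 20L))
  }
  likelihood_provider("uniform", matrix_fn, paired_scoring = TRUE)
}

#' Deterministic skewed-profile likelihood provider
#'
#' A synthetic provider whose probability columns are skewed (low Shannon
#' evenness) but deterministic per input sequence: each column is a
#' Dirichlet draw from a generator seeded by a hash of the sequence, the
#' position and `seed`. Used to exercise rank statistics where the
#' germline-anchored provider is degenerate (its 19 alternative residues
#' are exchangeable).
#'
#' @param concentration Dirichlet concentration; smaller values give more
#'   peaked columns. Default 0.25.
#' @param seed Integer mixed into the per-sequence hash.
#' @return A `likelihood_provider`.
#' @export
positional_profile_provider <- function(concentration = 0.25, seed = 1L) {
  stopifnot(concentration > 0)
  matrix_fn <- function(sequence_aa) {
    L <- nchar(sequence_aa)
    probs <- with_preserved_seed({
      set.seed((sequence_hash(sequence_aa) + as.integer(seed)) %% .Machine$integer.max)
      g <- matrix(stats::rgamma(L * 20L, shape = concentration), nrow = L)
      g / rowSums(g)
    })
    probability_matrix(sequence_aa, probs)
  }
  likelihood_provider(sprintf("profile_c%g", concentration), matrix_fn,
                      paired_scoring = TRUE)
}

# deterministic 31-bit string hash (polynomial rolling)
sequence_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# run expr with the global RNG state saved and restored
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Sequence pseudolikelihood from a probability matrix
#'
#' The SP of a sequence is the mean, over the scored positions, of the
#' log probability the model assigns to the residue actually observed at
#' that position. With natural log (the default) an SP of 0 means every
#' observed residue had probability 1; `log(1/20) = -2.996` is the
#' uniform baseline.
#'
#' @param pm A [probability_matrix()].
#' @param positions Integer vector of 1-based positions to score;
#'   `NULL` (default) scores every position.
#' @param log_base Base of the logarithm; natural log by default.
#' @param floor Lower clamp applied to an observed-residue probability of
#'   exactly zero before taking the log (clamped positions are reported
#'   in the `n_floored` attribute).
#' @return The SP, a single non-positive number, with attributes
#'   `n_positions` and `n_floored`.
#' @export
#' @examples
#' pm <- probability_matrix("AC", rbind(c(0.5, rep(0.5 / 19, 19)),
#'                                      c(0.75 / 19, 0.25, rep(0.75 / 19, 18))))
#' compute_sp(pm)  # (log 0.5 + log 0.25) / 2
compute_sp <- function(pm, positions = NULL, log_base = exp(1), floor = 1e-10) {
  stopifnot(inherits(pm, "probability_matrix"))
  L <- nrow(pm)
  if (is.null(positions)) positions <- seq_len(L)
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("positions must be non-empty")
  if (any(positions < 1L) || any(positions > L)) {
    stop("positions out of range [1, ", L, "]")
  }
  obs <- aa_index(aa_split(attr(pm, "sequence_aa"))[positions])
  p <- pm[cbind(positions, obs)]
  floored <- p <= 0
  p[floored] <- floor
  sp <- mean(log(p, base = log_base))
  structure(sp, n_positions = length(positions), n_floored = sum(floored))
}

#' Score every cell of a repertoire under one or more input sources
#'
#' Computes sequence pseudolikelihoods for each retained cell of a
#' repertoire under the requested input sources:
#' \describe{
#'   \item{`full_vdj`}{the complete V(D)J amino-acid sequence is given to
#'     the provider and every position is scored;}
#'   \item{`cdr3_from_vdj`}{the full V(D)J sequence is given to the
#'     provider (full context) but only the CDR3 positions enter the SP;}
#'   \item{`cdr3_only`}{the bare CDR3 string is given to the provider and
#'     scored in full;}
#'   \item{`paired`}{heavy and light chains are scored jointly: the SP is
#'     the mean log-probability over all heavy plus light positions
#'     (requires a provider with `paired_scoring`).}
#' }
#' Heavy and light chains are scored separately for the three
#' single-chain sources. Cells lacking what a source needs (e.g. a CDR3
#' span) are skipped for that source and counted in the `skipped`
#' attribute. When the provider is germline-anchored, the repertoire's
#' germlines (and their CDR3 substrings) are registered automatically.
#'
#' @param rep A [bcr_repertoire] from [filter_cells()].
#' @param provider A [likelihood_provider()].
#' @param sources Character subset of
#'   `c("full_vdj", "cdr3_from_vdj", "cdr3_only", "paired")`.
#' @param log_base,floor Passed to [compute_sp()].
#' @return A data frame with one row per (cell, locus-or-paired, source):
#'   columns `cell_id`, `locus`, `provider`, `source`, `sp`,
#'   `n_positions`, `sample_id`.
#' @export
score_repertoire <- function(rep, provider,
                             sources = c("full_vdj", "cdr3_from_vdj", "cdr3_only"),
                             log_base = exp(1), floor = 1e-10) {
  stopifnot(inherits(rep, "bcr_repertoire"), inherits(provider, "likelihood_provider"))
  sources <- match.arg(sources, c("full_vdj", "cdr3_from_vdj", "cdr3_only", "paired"),
                       several.ok = TRUE)
  if ("paired" %in% sources && !provider$paired_scoring) {
    stop("provider '", provider$name, "' does not support paired scoring")
  }
  ch <- rep$chains
  if (inherits(provider, "germline_anchored_provider")) {
    ok <- !is.na(ch$germline_aa) & nchar(ch$germline_aa) == nchar(ch$sequence_aa)
    register_germlines(provider, ch$sequence_aa[ok], ch$germline_aa[ok])
    has_span <- ok & !is.na(ch$cdr3_start)
    if (any(has_span)) {
      s0 <- ch$cdr3_start[has_span]; s1 <- ch$cdr3_end[has_span]
      register_germlines(provider,
                         substr(ch$sequence_aa[has_span], s0 + 1L, s1),
                         substr(ch$germline_aa[has_span], s0 + 1L, s1))
    }
  }
  memo <- new.env(parent = emptyenv())
  get_pm <- function(s) {
    pm <- get0(s, envir = memo, inherits = FALSE)
    if (is.null(pm)) {
      pm <- residue_probabilities(provider, s)
      assign(s, pm, envir = memo)
    }
    pm
  }
  rows <- vector("list", 0L)
  skipped <- c(full_vdj = 0L, cdr3_from_vdj = 0L, cdr3_only = 0L, paired = 0L)
  add <- function(cell_id, locus, source, sp, sample_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_id = cell_id, locus = locus, provider = provider$name,
      source = source, sp = as.numeric(sp),
      n_positions = attr(sp, "n_positions"), sample_id = sample_id,
      stringsAsFactors = FALSE)
  }
  cells <- rep$cells
  for (i in seq_len(nrow(cells))) {
    cid <- cells$cell_id[i]
    sub <- ch[ch$cell_id == cid, , drop = FALSE]
    hv <- sub[sub$locus == "heavy", , drop = FALSE]
    lt <- sub[sub$locus == "light", , drop = FALSE]
    for (src in sources) {
      if (src == "paired") {
        res <- tryCatch({
          obs_p <- c(observed_logp(get_pm(hv$sequence_aa), log_base, floor),
                     observed_logp(get_pm(lt$sequence_aa), log_base, floor))
          structure(mean(obs_p), n_positions = length(obs_p))
        }, error = function(e) NULL)
        if (is.null(res)) skipped[["paired"]] <- skipped[["paired"]] + 1L
        else add(cid, "paired", src, res, cells$sample_id[i])
        next
      }
      for (k in seq_len(nrow(sub))) {
        row <- sub[k, ]
        res <- tryCatch({
          switch(src,
            full_vdj = compute_sp(get_pm(row$sequence_aa),
                                  log_base = log_base, floor = floor),
            cdr3_from_vdj = {
              if (is.na(row$cdr3_start)) stop("no cdr3 span")
              compute_sp(get_pm(row$sequence_aa),
                         positions = seq.int(row$cdr3_start + 1L, row$cdr3_end),
                         log_base = log_base, floor = floor)
            },
            cdr3_only = {
              if (is.na(row$cdr3_start)) stop("no cdr3 span")
              cdr3 <- substr(row$sequence_aa, row$cdr3_start + 1L, row$cdr3_end)
              compute_sp(get_pm(cdr3), log_base = log_base, floor = floor)
            })
        }, error = function(e) NULL)
        if (is.null(res)) skipped[[src]] <- skipped[[src]] + 1L
        else add(cid, row$locus, src, res, cells$sample_id[i])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), locus = character(), provider = character(),
               source = character(), sp = numeric(), n_positions = integer(),
               sample_id = character(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# vector of log-probabilities of the observed residues of a matrix
observed_logp <- function(pm, log_base = exp(1), floor = 1e-10) {
  obs <- aa_index(aa_split(attr(pm, "sequence_aa")))
  p <- pm[cbind(seq_len(nrow(pm)), obs)]
  p[p <= 0] <- floor
  log(p, base = log_base)
}
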