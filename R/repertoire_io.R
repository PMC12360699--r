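#' Read single-cell V(D)J contig annotations
#'
#' Reads an annotation table into one record per contig. Two dialects are
#' supported:
#' \describe{
#'   \item{`airr_tsv`}{tab-separated, AIRR-Rearrangement-style columns
#'     `cell_id, locus, sequence_aa, germline_alignment_aa, v_call,
#'     c_call, cdr3_aa, cdr3_start, cdr3_end` (amino-acid coordinates,
#'     0-based half-open), optional `sample_id` and `clone_id`.}
#'   \item{`contig_csv`}{comma-separated, CellRanger-filtered-contig
#'     style columns `barcode, chain, sequence_aa, germline_aa, v_gene,
#'     c_gene, cdr3, cdr3_start, cdr3_end` with 1-based inclusive
#'     coordinates, optional `sample_id`.}
#' }
#' Coordinates are normalized to 0-based half-open on read. Locus labels
#' `IGH` map to `heavy`, `IGK`/`IGL` to `light`. Rows whose sequence
#' contains non-canonical letters (`X`, `*`, gaps), or whose CDR3
#' coordinates disagree with the stated `cdr3_aa`, are skipped with a
#' warning; the counts are kept in the `dropped` attribute.
#'
#' @param path Path to the file.
#' @param dialect `"airr_tsv"` or `"contig_csv"`.
#' @return Data frame of chain records with columns `cell_id, locus,
#'   sequence_aa, germline_aa, v_call, c_call, cdr3_aa, cdr3_start,
#'   cdr3_end, sample_id` (0-based half-open spans; `NA` span when no
#'   CDR3 coordinates were given).
#' @export
read_repertoire <- function(path, dialect = c("airr_tsv", "contig_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "airr_tsv") {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    req <- c("cell_id", "locus", "sequence_aa", "germline_alignment_aa",
             "v_call", "c_call", "cdr3_aa")
    offset <- 0L  # already 0-based half-open
    cols <- list(cell_id = "cell_id", locus = "locus", sequence_aa = "sequence_aa",
                 germline_aa = "germline_alignment_aa", v_call = "v_call",
                 c_call = "c_call", cdr3_aa = "cdr3_aa")
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    req <- c("barcode", "chain", "sequence_aa", "germline_aa",
             "v_gene", "c_gene", "cdr3")
    offset <- 1L  # 1-based inclusive -> subtract 1 from start
    cols <- list(cell_id = "barcode", locus = "chain", sequence_aa = "sequence_aa",
                 germline_aa = "germline_aa", v_call = "v_gene",
                 c_call = "c_gene", cdr3_aa = "cdr3")
  }
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(
    cell_id = raw[[cols$cell_id]],
    locus = normalize_locus(raw[[cols$locus]]),
    sequence_aa = raw[[cols$sequence_aa]],
    germline_aa = raw[[cols$germline_aa]],
    v_call = raw[[cols$v_call]],
    c_call = raw[[cols$c_call]],
    cdr3_aa = raw[[cols$cdr3_aa]],
    cdr3_start = rep(NA_integer_, n),
    cdr3_end = rep(NA_integer_, n),
    sample_id = if ("sample_id" %in% names(raw)) raw[["sample_id"]] else
      rep("sample1", n),
    stringsAsFactors = FALSE)
  if ("clone_id" %in% names(raw)) out$clone_id <- raw[["clone_id"]]
  if ("cdr3_start" %in% names(raw) && "cdr3_end" %in% names(raw)) {
    out$cdr3_start <- suppressWarnings(as.integer(raw[["cdr3_start"]])) - offset
    out$cdr3_end <- suppressWarnings(as.integer(raw[["cdr3_end"]]))
  }
  dropped <- c(non_canonical = 0L, bad_locus = 0L, cdr3_mismatch = 0L)
  keep <- rep(TRUE, n)
  bad_seq <- !vapply(out$sequence_aa, is_canonical_aa, logical(1))
  dropped[["non_canonical"]] <- sum(bad_seq)
  keep[bad_seq] <- FALSE
  bad_locus <- is.na(out$locus)
  dropped[["bad_locus"]] <- sum(bad_locus & keep)
  keep[bad_locus] <- FALSE
  has_span <- keep & !is.na(out$cdr3_start) & !is.na(out$cdr3_end)
  span_ok <- has_span &
    out$cdr3_start >= 0L & out$cdr3_end <= nchar(out$sequence_aa) &
    out$cdr3_start < out$cdr3_end &
    substr(out$sequence_aa, out$cdr3_start + 1L, out$cdr3_end) == out$cdr3_aa
  bad_span <- has_span & !span_ok
  dropped[["cdr3_mismatch"]] <- sum(bad_span)
  keep[bad_span] <- FALSE
  if (any(!keep)) {
    warning(sum(!keep), " contig row(s) skipped (",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "), ")")
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

normalize_locus <- function(x) {
  lc <- tolower(x)
  res <- rep(NA_character_, length(x))
  res[lc %in% c("heavy", "igh")] <- "heavy"
  res[lc %in% c("light", "igk", "igl")] <- "light"
  res
}

#' Filter cells and assemble a repertoire
#'
#' Applies the standard quality rules to raw chain records, in order:
#' \enumerate{
#'   \item remove cells with more than one transcript for any locus;
#'   \item remove incomplete cells (missing a heavy or a light chain);
#'   \item remove cells whose heavy chain lacks an annotated germline;
#'   \item remove cells whose heavy chain lacks a C-gene call;
#'   \item remove every copy of a barcode that occurs in more than one
#'     sample (duplicated barcode).
#' }
#' Each cell is counted against the first rule it violates; the counts
#' are kept in `filter_log` and always reconcile with the input:
#' `sum(filter_log) + retained = input cells`. Surviving cells are
#' assigned clonotypes; with the default strategy, cells sharing heavy
#' and light V-gene families and identical heavy and light CDR3
#' amino-acid sequences form one clone. Note this strategy splits a
#' lineage as soon as hypermutation touches the CDR3, which couples
#' clone size to mutation load; `clonotype = "input_clone_id"` instead
#' trusts a `clone_id` column already present on the records (e.g.
#' upstream clonotyping, or simulation truth).
#'
#' @param records Chain records from [read_repertoire()] (or
#'   [simulate_repertoire()]'s `chains`).
#' @param clonotype `"vfam_cdr3"` (default) or `"input_clone_id"`.
#' @return A `bcr_repertoire`: list with `chains` (retained chain rows),
#'   `cells` (one row per cell: `cell_id, sample_id, isotype, clone_id`),
#'   and `filter_log` (named integer vector of per-rule removals plus
#'   `n_input` / `n_retained` attributes).
#' @export
filter_cells <- function(records, clonotype = c("vfam_cdr3", "input_clone_id")) {
  clonotype <- match.arg(clonotype)
  stopifnot(is.data.frame(records))
  need <- c("cell_id", "locus", "sequence_aa", "germline_aa", "v_call",
            "c_call", "cdr3_aa", "cdr3_start", "cdr3_end")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample1"
  key <- paste(records$sample_id, records$cell_id, sep = "\r")
  cells <- unique(data.frame(key = key, cell_id = records$cell_id,
                             sample_id = records$sample_id,
                             stringsAsFactors = FALSE))
  log <- c(multi_transcript = 0L, incomplete = 0L, no_germline = 0L,
           no_heavy_cgene = 0L, duplicated_barcode = 0L)
  n_input <- nrow(cells)
  alive <- rep(TRUE, n_input)
  heavy_row <- integer(n_input); light_row <- integer(n_input)
  for (i in seq_len(n_input)) {
    idx <- which(key == cells$key[i])
    loci <- records$locus[idx]
    if (any(table(loci) > 1L)) {
      alive[i] <- FALSE; log[["multi_transcript"]] <- log[["multi_transcript"]] + 1L
      next
    }
    h <- idx[loci == "heavy"]; l <- idx[loci == "light"]
    if (length(h) != 1L || length(l) != 1L) {
      alive[i] <- FALSE; log[["incomplete"]] <- log[["incomplete"]] + 1L
      next
    }
    if (is.na(records$germline_aa[h]) || !nzchar(records$germline_aa[h])) {
      alive[i] <- FALSE; log[["no_germline"]] <- log[["no_germline"]] + 1L
      next
    }
    if (is.na(records$c_call[h]) || !nzchar(records$c_call[h])) {
      alive[i] <- FALSE; log[["no_heavy_cgene"]] <- log[["no_heavy_cgene"]] + 1L
      next
    }
    heavy_row[i] <- h; light_row[i] <- l
  }
  dup_ids <- with(cells[alive, , drop = FALSE],
                  names(which(tapply(sample_id, cell_id,
                                     function(s) length(unique(s))) > 1L)))
  dup <- alive & cells$cell_id %in% dup_ids
  log[["duplicated_barcode"]] <- sum(dup)
  alive[dup] <- FALSE

  kept <- which(alive)
  chains <- records[c(heavy_row[kept], light_row[kept]), , drop = FALSE]
  rownames(chains) <- NULL
  cell_df <- data.frame(
    cell_id = cells$cell_id[kept],
    sample_id = cells$sample_id[kept],
    isotype = isotype_from_c_call(records$c_call[heavy_row[kept]]),
    stringsAsFactors = FALSE)
  cell_df$clone_id <- if (clonotype == "input_clone_id") {
    if (!"clone_id" %in% names(records)) {
      stop("clonotype = 'input_clone_id' requires a clone_id column")
    }
    records$clone_id[heavy_row[kept]]
  } else {
    assign_clonotypes(records, heavy_row[kept], light_row[kept])
  }
  rep <- structure(list(chains = chains, cells = cell_df, filter_log = log),
                   class = "bcr_repertoire")
  attr(rep$filter_log, "n_input") <- n_input
  attr(rep$filter_log, "n_retained") <- length(kept)
  rep
}

# clone = identical (heavy V family, light V family, heavy CDR3 aa, light CDR3 aa);
# ids ordered by clone size (largest first), ties by key for determinism
assign_clonotypes <- function(records, heavy_row, light_row) {
  if (!length(heavy_row)) return(character(0))
  keys <- paste(v_family(records$v_call[heavy_row]),
                v_family(records$v_call[light_row]),
                records$cdr3_aa[heavy_row],
                records$cdr3_aa[light_row], sep = "|")
  sizes <- sort(table(keys), decreasing = TRUE)
  ord <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  ids <- stats::setNames(paste0("clone", seq_along(ord)), ord)
  unname(ids[keys])
}

#' @export
print.bcr_repertoire <- function(x, ...) {
  cat(sprintf("bcr_repertoire: %d cells, %d clones, %d sample(s)\n",
              nrow(x$cells), length(unique(x$cells$clone_id)),
              length(unique(x$cells$sample_id))))
  cat("filter_log:", paste(sprintf("%s=%d", names(x$filter_log), x$filter_log),
                           collapse = " "), "\n")
  invisible(x)
}

#' Isotype from a heavy-chain C-gene call
#'
#' Collapses subclasses: `IGHM -> IgM`, `IGHD -> IgD`, `IGHG* -> IgG`,
#' `IGHA* -> IgA`, `IGHE -> IgE`; anything else is `NA`.
#'
#' @param c_call Character vector of C-gene calls.
#' @return Character vector of isotypes.
#' @export
isotype_from_c_call <- function(c_call) {
  map <- c(M = "IgM", D = "IgD", G = "IgG", A = "IgA", E = "IgE")
  cls <- sub("^IGH([MDGAE]).*$", "\\1", toupper(ifelse(is.na(c_call), "", c_call)))
  out <- unname(map[cls])
  out[!cls %in% names(map)] <- NA_character_
  out
}

#' Hamming distance between a sequence and its germline (SHM count)
#'
#' Somatic hypermutation is quantified as the number of differing
#' positions between a V(D)J sequence and its germline. Sequences whose
#' germline has a different length (indels) cannot be Hamming-compared
#' and are excluded: the function returns `NA` for them.
#'
#' @param sequence_aa,germline_aa Amino-acid strings (vectorized).
#' @return Integer vector of mismatch counts; `NA` where lengths differ.
#' @export
#' @examples
#' hamming_shm("ACDE", "ACDY")  # 1
#' hamming_shm("ACDE", "ACD")   # NA: excluded from SHM analyses
hamming_shm <- function(sequence_aa, germline_aa) {
  stopifnot(length(sequence_aa) == length(germline_aa))
  mapply(function(s, g) {
    if (is.na(s) || is.na(g) || nchar(s) != nchar(g)) return(NA_integer_)
    sum(aa_split(s) != aa_split(g))
  }, sequence_aa, germline_aa, USE.NAMES = FALSE)
}

#' V-gene family of a V-gene call
#'
#' Extracts the gene-family prefix, i.e. the locus plus family digits up
#' to the first allele/gene delimiter (`-`, `*`, or an `S` subgroup).
#' Calls not matching the immunoglobulin V-gene pattern give `"unknown"`.
#'
#' @param v_call Character vector, e.g. `"IGHV1-26*01"`.
#' @return Character vector of families, e.g. `"IGHV1"`.
#' @export
v_family <- function(v_call) {
  m <- regmatches(v_call, regexpr("^IG[HKL]V[0-9]+", v_call))
  out <- rep("unknown", length(v_call))
  hit <- grepl("^IG[HKL]V[0-9]+", v_call)
  out[hit] <- m
  out
}

#' Normalized clonal expansion
#'
#' Number of cells per clonotype divided by the total number of retained
#' cells in the repertoire; the values sum to 1 over clones.
#'
#' @param rep A [bcr_repertoire].
#' @return Named numeric vector, one entry per clone.
#' @export
normalized_expansion <- function(rep) {
  stopifnot(inherits(rep, "bcr_repertoire"))
  if (nrow(rep$cells) == 0L) stop("empty repertoire")
  tab <- table(rep$cells$clone_id)
  stats::setNames(as.numeric(tab) / nrow(rep$cells), names(tab))
}

#' Write a repertoire as AIRR-style TSV
#'
#' Writes the retained chains in the `airr_tsv` dialect of
#' [read_repertoire()] (0-based half-open CDR3 coordinates), including
#' `clone_id` and `sample_id`.
#'
#' @param rep A [bcr_repertoire].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "bcr_repertoire"))
  ch <- rep$chains
  clone <- stats::setNames(rep$cells$clone_id,
                           paste(rep$cells$sample_id, rep$cells$cell_id, sep = "\r"))
  out <- data.frame(
    cell_id = ch$cell_id, locus = ch$locus, sequence_aa = ch$sequence_aa,
    germline_alignment_aa = ch$germline_aa, v_call = ch$v_call,
    c_call = ch$c_call, cdr3_aa = ch$cdr3_aa, cdr3_start = ch$cdr3_start,
    cdr3_end = ch$cdr3_end,
    clone_id = unname(clone[paste(ch$sample_id, ch$cell_id, sep = "\r")]),
    sample_id = ch$sample_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the filtering report as JSON
#'
#' @param rep A [bcr_repertoire].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(rep, path) {
  stopifnot(inherits(rep, "bcr_repertoire"))
  jsonlite::write_json(
    list(n_input = attr(rep$filter_log, "n_input"),
         n_retained = attr(rep$filter_log, "n_retained"),
         removed = as.list(rep$filter_log)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
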