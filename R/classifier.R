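# Demultiplexing, quality filtering and classification of non-overlapping
# paired-end amplicon reads against an amplicon database.
#
# Read pairs travel as data frames with columns id, seq1, qual1, seq2, qual2
# and (after demultiplexing) sample. Qualities are Phred+33 strings.

default_align_params <- function() {
  list(k = 15L, band = 8L, floor_frac = 0.6, match = 2, mismatch = -3,
       gap_open = -5, gap_ext = -2, min_seed = 2L, cand_frac = 0.2,
       max_cand = 16L, q_scale = 1, q_cap = 42)
}

check_pairs <- function(pairs) {
  req <- c("id", "seq1", "qual1", "seq2", "qual2")
  if (!all(req %in% names(pairs)))
    stop("read pairs need columns ", paste(req, collapse = ", "))
  if (any(!nzchar(pairs$seq1)) || any(!nzchar(pairs$seq2)))
    stop("empty mate sequence")
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2)))
    stop("quality strings must match sequence lengths")
  invisible(pairs)
}

#' Demultiplex read pairs by exact barcode prefix
#'
#' A pair is assigned iff mate 1 begins with exactly one of the sheet's
#' barcodes; the barcode (and its quality) is then stripped. Matching is
#' exact (no mismatch tolerance): barcodes are short, and one error in a
#' short tag is more likely to produce a wrong sample than a rescue.
#'
#' @param pairs Read-pair data frame.
#' @param barcodes Data frame with columns `sample`, `barcode`; barcodes must
#'   be unique and equal length.
#' @return List with `assigned` (pairs plus `sample` column, barcodes
#'   stripped) and `unassigned`.
#' @export
demultiplex <- function(pairs, barcodes) {
  check_pairs(pairs)
  stopifnot(all(c("sample", "barcode") %in% names(barcodes)))
  bc <- toupper(barcodes$barcode)
  if (anyDuplicated(bc)) stop("duplicate barcodes in sheet")
  if (length(unique(nchar(bc))) != 1) stop("barcodes must be equal length")
  w <- nchar(bc[1])
  prefix <- toupper(substr(pairs$seq1, 1, w))
  hit <- match(prefix, bc)
  assigned <- pairs[!is.na(hit), , drop = FALSE]
  if (nrow(assigned)) {
    assigned$sample <- barcodes$sample[hit[!is.na(hit)]]
    assigned$seq1 <- substr(assigned$seq1, w + 1, nchar(assigned$seq1))
    assigned$qual1 <- substr(assigned$qual1, w + 1, nchar(assigned$qual1))
  } else assigned$sample <- character(0)
  list(assigned = assigned, unassigned = pairs[is.na(hit), , drop = FALSE])
}

phred_values <- function(qual) utf8ToInt(qual) - 33L

# 3' trim of one read: slide a window of `window` bases in from the 3' end,
# dropping the terminal base while the terminal window's mean quality is
# below `window_q`; then drop remaining trailing bases individually below
# `window_q`. Returns the kept length.
trim_length <- function(qual_int, window = 4L, window_q = 20) {
  e <- length(qual_int)
  while (e >= window && mean(qual_int[(e - window + 1):e]) < window_q) e <- e - 1L
  while (e >= 1 && qual_int[e] < window_q) e <- e - 1L
  e
}

#' Quality-filter read pairs by 3' sliding-window trimming
#'
#' Each mate is trimmed from the 3' end with a sliding window (window 4,
#' mean quality below `window_q` cut), then residual low-quality trailing
#' bases are removed; the pair is discarded if either trimmed mate is
#' shorter than `min_len`. These are the defaults of the common short-read
#' quality-trimming tool family; all are overridable.
#'
#' @param pairs Read-pair data frame.
#' @param min_len Minimum mate length after trimming (default 100).
#' @param window_q Mean-quality threshold of the sliding window (default 20).
#' @param window Window width (default 4).
#' @return List with `kept` (trimmed pairs) and `discarded`.
#' @export
quality_filter <- function(pairs, min_len = 100, window_q = 20, window = 4L) {
  check_pairs(pairs)
  n <- nrow(pairs)
  if (!n) return(list(kept = pairs, discarded = pairs))
  l1 <- vapply(pairs$qual1, function(q) trim_length(phred_values(q), window,
                                                    window_q), 0L,
               USE.NAMES = FALSE)
  l2 <- vapply(pairs$qual2, function(q) trim_length(phred_values(q), window,
                                                    window_q), 0L,
               USE.NAMES = FALSE)
  keep <- l1 >= min_len & l2 >= min_len
  kept <- pairs[keep, , drop = FALSE]
  if (nrow(kept)) {
    kept$seq1 <- substr(kept$seq1, 1, l1[keep])
    kept$qual1 <- substr(kept$qual1, 1, l1[keep])
    kept$seq2 <- substr(kept$seq2, 1, l2[keep])
    kept$qual2 <- substr(kept$qual2, 1, l2[keep])
  }
  list(kept = kept, discarded = pairs[!keep, , drop = FALSE])
}

db_sequences <- function(db) {
  if (inherits(db, "amplicon_db")) setNames(db$records$sequence, db$records$id)
  else db
}

#' Align one mate against the database
#'
#' Seed-anchored banded local alignment (match +2, mismatch -3, gap open -5,
#' gap extend -2) of the mate, in both orientations, against every reference;
#' hits scoring below `floor_frac` of the maximum attainable score are
#' dropped.
#'
#' @param mate DNA string.
#' @param db An `amplicon_db` or named character vector of references.
#' @param both_orientations Also align the reverse complement (default TRUE).
#' @param params Alignment parameter list; see `default_align_params()`
#'   entries `k`, `band`, `floor_frac`, `match`, `mismatch`, `gap_open`,
#'   `gap_ext`, `min_seed`.
#' @return Data frame `ref` (reference id), `score`, `start`, `end` (1-based
#'   inclusive reference coordinates), `strand`.
#' @export
align_mate <- function(mate, db, both_orientations = TRUE,
                       params = default_align_params()) {
  seqs <- db_sequences(db)
  h <- .cpp_align_mate(unname(seqs), toupper(mate), params$k, params$band,
                       params$floor_frac, params$match, params$mismatch,
                       params$gap_open, params$gap_ext, params$min_seed,
                       params$cand_frac, params$max_cand, both_orientations)
  data.frame(ref = names(seqs)[h$ref], score = h$score, start = h$start,
             end = h$end, strand = h$strand)
}

status_labels <- c("assigned", "discordant", "no_hit")

classify_engine <- function(pairs, db, params, frag_window) {
  seqs <- db_sequences(db)
  res <- .cpp_classify_pairs(unname(seqs), toupper(pairs$seq1),
                             toupper(pairs$seq2), params$k, params$band,
                             params$floor_frac, params$match, params$mismatch,
                             params$gap_open, params$gap_ext, params$min_seed,
                             params$cand_frac, params$max_cand,
                             params$q_scale, params$q_cap,
                             frag_window[1], frag_window[2])
  data.frame(id = pairs$id,
             sample = if ("sample" %in% names(pairs)) pairs$sample else NA,
             ref = ifelse(is.na(res$ref), NA, names(seqs)[res$ref]),
             q = res$q, score = res$score, fragment = res$fragment,
             status = status_labels[res$status])
}

#' Classify read pairs against an amplicon database
#'
#' Both mates are aligned in both orientations; a reference is concordant
#' when the two mates hit it in opposite orientations with a combined
#' footprint span inside `frag_window`. The uniqueness score
#' `Q = min(cap, S_best - S_second)` measures separation between the best
#' and second-best concordant reference in combined alignment-score units
#' (the floor standing in for a missing second hit); a pair is assigned to
#' the best reference's species iff `Q > q_threshold` (strict). Ties give
#' `Q = 0` and are left unassigned.
#'
#' @param pairs Read-pair data frame (see [demultiplex()] /
#'   [quality_filter()]).
#' @param db An `amplicon_db` (or named character vector of references, in
#'   which case species = reference id).
#' @param q_threshold Uniqueness threshold, exceeded strictly (default 10).
#' @param frag_window Length-2 numeric: accepted fragment span in nt
#'   (default `c(400, 1000)`, bracketing the 736-nt product).
#' @param params Alignment parameters, see [align_mate()].
#' @return Data frame with one row per pair: `id`, `sample`, `ref`,
#'   `species`, `q`, `score`, `fragment`, `status` in
#'   `assigned | ambiguous | discordant | no_hit`.
#' @export
classify_pairs <- function(pairs, db, q_threshold = 10,
                           frag_window = c(400, 1000),
                           params = default_align_params()) {
  check_pairs(pairs)
  if (!nrow(pairs))
    return(data.frame(id = character(), sample = character(),
                      ref = character(), species = character(), q = numeric(),
                      score = numeric(), fragment = numeric(),
                      status = character()))
  out <- classify_engine(pairs, db, params, frag_window)
  ambiguous <- out$status == "assigned" & !(out$q > q_threshold)
  out$status[ambiguous] <- "ambiguous"
  out$ref[out$status != "assigned"] <- NA
  out$species <- if (inherits(db, "amplicon_db"))
    db$records$species[match(out$ref, db$records$id)] else out$ref
  out[c("id", "sample", "ref", "species", "q", "score", "fragment", "status")]
}

#' Classify a single read pair
#'
#' Convenience wrapper around [classify_pairs()] for one pair.
#'
#' @param seq1,qual1,seq2,qual2 Mate sequences and Phred+33 qualities.
#' @inheritParams classify_pairs
#' @return One-row classification data frame (see [classify_pairs()]).
#' @export
classify_pair <- function(seq1, seq2, db, qual1 = NULL, qual2 = NULL,
                          q_threshold = 10, frag_window = c(400, 1000),
                          params = default_align_params()) {
  q1 <- qual1 %||% strrep("I", nchar(seq1))
  q2 <- qual2 %||% strrep("I", nchar(seq2))
  classify_pairs(data.frame(id = "pair1", seq1 = seq1, qual1 = q1,
                            seq2 = seq2, qual2 = q2),
                 db, q_threshold, frag_window, params)
}

#' Tabulate species assignments into an abundance table
#'
#' Counts assigned pairs per (sample, species); each pair contributes at most
#' one count. Unassigned pairs are reported separately so that
#' assigned + unassigned equals the number of classified pairs per sample.
#'
#' @param assignments Output of [classify_pairs()].
#' @param samples Optional character vector fixing the sample order (and
#'   including samples with zero assigned pairs).
#' @return An `abundance_table`: numeric matrix samples x species with
#'   attributes `normalization` (`"raw"`) and `unassigned` (named count
#'   vector per sample).
#' @export
tabulate_assignments <- function(assignments, samples = NULL) {
  a <- assignments
  if (all(is.na(a$sample))) a$sample <- "sample1"
  samples <- samples %||% sort(unique(a$sample))
  ok <- a$status == "assigned"
  species <- sort(unique(a$species[ok]))
  tab <- matrix(0, nrow = length(samples), ncol = length(species),
                dimnames = list(samples, species))
  if (any(ok)) {
    t0 <- table(factor(a$sample[ok], levels = samples),
                factor(a$species[ok], levels = species))
    tab[] <- as.numeric(t0)
  }
  unas <- table(factor(a$sample[!ok], levels = samples))
  abundance_table(tab, normalization = "raw",
                  unassigned = setNames(as.numeric(unas), samples))
}

#' Abundance table constructor
#'
#' @param counts Numeric matrix, samples as rows, species as columns;
#'   nonnegative.
#' @param normalization `"raw"` or `"normalized_to_depth"`.
#' @param depth Depth constant when normalized.
#' @param unassigned Optional per-sample unassigned counts.
#' @return An `abundance_table` matrix.
#' @export
abundance_table <- function(counts, normalization = c("raw",
                                                      "normalized_to_depth"),
                            depth = NULL, unassigned = NULL) {
  normalization <- match.arg(normalization)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(counts, class = c("abundance_table", class(counts)),
            normalization = normalization, depth = depth,
            unassigned = unassigned)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d species (%s%s)\n",
              nrow(x), ncol(x), attr(x, "normalization"),
              if (!is.null(attr(x, "depth")))
                sprintf(", depth %g", attr(x, "depth")) else ""))
  print(unclass(x)[, seq_len(min(ncol(x), 8)), drop = FALSE], ...)
  invisible(x)
}

#' Normalize an abundance table to a fixed per-sample depth
#'
#' Each sample row is scaled by `depth / rowsum` so that every row sums to
#' exactly `depth`; fractional values are allowed (this is scaling, not
#' rarefaction). Use [subsample_to_depth()] for a seeded subsampling
#' alternative.
#'
#' @param table An `abundance_table` (or plain matrix) of raw counts.
#' @param depth Target row sum (default 100000).
#' @return A normalized `abundance_table`.
#' @export
normalize_to_depth <- function(table, depth = 100000) {
  m <- as.matrix(table)
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "))
  out <- m * (depth / totals)
  abundance_table(out, "normalized_to_depth", depth = depth,
                  unassigned = attr(table, "unassigned"))
}

#' Seeded multinomial subsampling to a fixed depth
#'
#' Rarefaction-style alternative to [normalize_to_depth()]: draws `depth`
#' reads per sample without replacement proportionally to the observed
#' counts (multivariate hypergeometric via repeated sampling).
#'
#' @inheritParams normalize_to_depth
#' @param seed RNG seed (mandatory).
#' @return A subsampled `abundance_table` with integer counts.
#' @export
subsample_to_depth <- function(table, depth = 100000, seed) {
  stopifnot(!missing(seed))
  m <- as.matrix(table)
  totals <- rowSums(m)
  if (any(totals < depth))
    stop("sample(s) shallower than depth: ",
         paste(rownames(m)[totals < depth], collapse = ", "))
  out <- with_seed(seed, {
    t(apply(m, 1, function(row) {
      pool <- rep(seq_along(row), row)
      tabulate(sample(pool, depth), nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  abundance_table(out, "normalized_to_depth", depth = depth)
}
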