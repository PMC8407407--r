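# In-silico PCR with degenerate IUPAC primers.
#
# A primer site is accepted where the primer aligns with at most
# `max_mismatch` substitutions and at most `max_indel` single-base
# insertions/deletions, counted separately. IUPAC ambiguity codes in the
# primer match their base set; ambiguity codes in the template never match
# (a contig-gap N counts as a mismatch, not a free match).

#' Construct a PCR primer
#'
#' @param name Primer identifier.
#' @param sequence IUPAC DNA string (A, C, G, T plus ambiguity codes
#'   R, Y, S, W, K, M, B, D, H, V, N).
#' @param role `"forward"` or `"reverse"`.
#' @return An object of class `primer` with fields `name`, `sequence`, `role`
#'   and `degeneracy` (product of per-position code cardinalities).
#' @export
#' @examples
#' primer("PsEG30F", "ATYGAAATCGCCAARCG", "forward")
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("primer sequence must be non-empty")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' at position %d in primer '%s'",
                 chars[bad[1]], bad[1], name))
  structure(
    list(name = name, sequence = sequence, role = role,
         degeneracy = prod(lengths(IUPAC_SETS[chars]))),
    class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s) %s  [%d nt, degeneracy %d]\n",
              x$name, x$role, x$sequence, nchar(x$sequence), x$degeneracy))
  invisible(x)
}

#' rpoD and 16S primers used for Pseudomonas profiling
#'
#' The degenerate primers evaluated for genus-selective amplification of the
#' rpoD gene (PsEG30F/PsEG790R give the 736-nt product used throughout) and
#' the universal 16S V3-V4 pair.
#'
#' @return Named list of [primer] objects.
#' @export
#' @examples
#' rpod_primers()$PsEG30F
rpod_primers <- function() {
  list(
    PsEG30F  = primer("PsEG30F",  "ATYGAAATCGCCAARCG",    "forward"),
    PsEG790R = primer("PsEG790R", "CGGTTGATKTCCTTGA",     "reverse"),
    PsJL490R = primer("PsJL490R", "AGYTTGATYGGGATGAA",    "reverse"),
    PsJL628R = primer("PsJL628R", "GGGAACWKGCGCAGGAARTC", "reverse"),
    F341     = primer("341F",     "CCTACGGGNGGCWGCAG",    "forward"),
    R805     = primer("805R",     "GACTACHVGGGTATCTAATCC", "reverse")
  )
}

#' Expand an IUPAC string into all concrete DNA sequences
#'
#' @param sequence IUPAC DNA string.
#' @return Character vector of all concrete expansions; its length equals the
#'   product of per-position code cardinalities.
#' @export
#' @examples
#' expand_iupac("ATYG")   # 2 expansions
expand_iupac <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1]], bad[1]))
  if (!length(chars)) return("")
  grid <- expand.grid(IUPAC_SETS[chars], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; order is deterministic
  sort(do.call(paste0, grid))
}

as_primer <- function(x, role = "forward") {
  if (inherits(x, "primer")) x else primer(deparse(substitute(x)), x, role)
}

#' Test a primer for a site at a fixed template position
#'
#' Edit-style alignment of the primer against the local template window
#' starting at `position`, accepting at most `max_mismatch` substitutions and
#' `max_indel` single-base indels (counted separately).
#'
#' @param primer A [primer] object (or IUPAC string).
#' @param template DNA string.
#' @param position 1-based template position where the site starts.
#' @param max_mismatch,max_indel Edit budgets (each >= 0).
#' @return A one-row data frame (`start`, `end` 1-based inclusive, `strand`,
#'   `mismatches`, `indels`) or `NULL` when no within-budget alignment exists.
#' @export
iupac_match_at <- function(primer, template, position,
                           max_mismatch = 1, max_indel = 1) {
  if (is.character(primer)) primer <- primer("primer", primer, "forward")
  template <- toupper(template)
  stopifnot(position >= 1, position <= nchar(template),
            max_mismatch >= 0, max_indel >= 0)
  hits <- .cpp_scan_primer(template, primer$sequence, max_mismatch, max_indel,
                           FALSE)
  hits <- hits[hits$start == position - 1L, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  data.frame(start = hits$start + 1L, end = hits$end, strand = hits$strand,
             mismatches = hits$mismatches, indels = hits$indels)
}

#' Scan a template for degenerate primer sites on both strands
#'
#' Reverse-strand sites are matches of the primer against the reverse
#' complement, reported in forward-strand coordinates. Overlapping matches at
#' adjacent offsets (one physical site seen through several indel variants)
#' are deduplicated by keeping the lowest-edit, then leftmost, match.
#'
#' @inheritParams iupac_match_at
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @param dedupe Collapse overlapping same-strand matches (default `TRUE`).
#' @return Data frame of matches (`start`, `end` 1-based inclusive, `strand`,
#'   `mismatches`, `indels`), sorted by start.
#' @export
#' @examples
#' p <- primer("toy", "ATYG", "forward")
#' scan_template(p, "GGATCGGGATTGCC")
scan_template <- function(primer, template, max_mismatch = 1, max_indel = 1,
                          both_strands = TRUE, dedupe = TRUE) {
  if (is.character(primer)) primer <- primer("primer", primer, "forward")
  template <- toupper(template)
  empty <- data.frame(start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), indels = integer())
  if (!nzchar(template)) return(empty)
  hits <- .cpp_scan_primer(template, primer$sequence, max_mismatch, max_indel,
                           both_strands)
  if (!nrow(hits)) return(empty)
  hits$edits <- hits$mismatches + hits$indels
  if (dedupe) {
    keep <- logical(nrow(hits))
    for (s in unique(hits$strand)) {
      i_s <- which(hits$strand == s)
      ord <- i_s[order(hits$edits[i_s], hits$start[i_s])]
      taken <- matrix(numeric(0), ncol = 2)
      for (i in ord) {
        ov <- nrow(taken) > 0 &&
          any(hits$start[i] < taken[, 2] & hits$end[i] > taken[, 1])
        if (!ov) {
          keep[i] <- TRUE
          taken <- rbind(taken, c(hits$start[i], hits$end[i]))
        }
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  data.frame(start = hits$start + 1L, end = hits$end, strand = hits$strand,
             mismatches = hits$mismatches, indels = hits$indels,
             row.names = NULL)
}

#' In-silico amplification of a template by a primer pair
#'
#' Finds forward-primer sites paired with downstream reverse-complemented
#' reverse-primer sites (on either template orientation) and returns one
#' amplicon per forward site paired to the nearest compatible downstream
#' reverse site (PCR's dominant short product), or all compatible pairs with
#' `all_pairs = TRUE` for anomaly detection. Amplicon sequences include both
#' primer footprints and are reported 5'->3' relative to the forward primer.
#'
#' @param forward,reverse [primer] objects.
#' @param template DNA string.
#' @param max_mismatch,max_indel Per-site edit budgets.
#' @param max_len Maximum product length in nt (default 5000); bounds runaway
#'   products while still exposing anomalously long ones.
#' @param all_pairs Pair every forward site with every compatible reverse
#'   site instead of only the nearest.
#' @return Data frame with one row per amplicon: `start`, `end` (1-based
#'   inclusive, forward-strand coordinates), `length`, `orientation` (`"+"` if
#'   the forward primer sits on the forward strand), and `sequence`.
#' @export
amplify <- function(forward, reverse, template, max_mismatch = 1, max_indel = 1,
                    max_len = 5000, all_pairs = FALSE) {
  template <- toupper(template)
  stopifnot(max_len > nchar(forward$sequence) + nchar(reverse$sequence))
  fwd <- scan_template(forward, template, max_mismatch, max_indel)
  rev <- scan_template(reverse, template, max_mismatch, max_indel)
  out <- list()
  pair_sites <- function(plus, minus, orientation) {
    res <- list()
    if (!nrow(plus) || !nrow(minus)) return(res)
    for (i in seq_len(nrow(plus))) {
      down <- minus[minus$start > plus$end[i], , drop = FALSE]
      if (!nrow(down)) next
      down <- down[order(down$end), , drop = FALSE]
      down <- down[down$end - plus$start[i] + 1 <= max_len, , drop = FALSE]
      if (!nrow(down)) next
      if (!all_pairs) down <- down[1, , drop = FALSE]
      for (j in seq_len(nrow(down))) {
        seq <- substr(template, plus$start[i], down$end[j])
        if (orientation == "-") seq <- revcomp(seq)
        up_len <- plus$end[i] - plus$start[i] + 1L
        down_len <- down$end[j] - down$start[j] + 1L
        res[[length(res) + 1]] <- data.frame(
          start = plus$start[i], end = down$end[j],
          length = down$end[j] - plus$start[i] + 1L,
          orientation = orientation, sequence = seq,
          # primer footprint lengths at the 5' and 3' ends of `sequence`
          fwd_len = if (orientation == "+") up_len else down_len,
          rev_len = if (orientation == "+") down_len else up_len)
      }
    }
    res
  }
  # forward primer on + strand, reverse primer on - strand downstream
  out <- c(out, pair_sites(fwd[fwd$strand == "+", , drop = FALSE],
                           rev[rev$strand == "-", , drop = FALSE], "+"))
  # reverse primer on + strand, forward primer on - strand downstream
  out <- c(out, pair_sites(rev[rev$strand == "+", , drop = FALSE],
                           fwd[fwd$strand == "-", , drop = FALSE], "-"))
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      orientation = character(), sequence = character(),
                      fwd_len = integer(), rev_len = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Benchmark a primer pair over genome collections
#'
#' A template counts as amplified iff it yields at least one product;
#' products outside the expected length window are recorded as length
#' anomalies. The negative collection measures off-target amplification.
#'
#' @param forward,reverse [primer] objects.
#' @param targets Named character vector of target templates (e.g. from
#'   [read_fasta()]); must be non-empty.
#' @param negatives Optional named character vector of negative-control
#'   templates.
#' @param length_window Numeric length-2 vector: expected product length
#'   range in nt.
#' @param ... Passed to [amplify()] (budgets, `max_len`).
#' @return An object of class `primer_pair_metrics`: counts and fractions
#'   amplified for targets and negatives plus a `length_anomalies` data frame
#'   (`template_id`, `length`).
#' @export
evaluate_primer_pair <- function(forward, reverse, targets, negatives = NULL,
                                 length_window = c(600, 900), ...) {
  if (!length(targets)) stop("target collection must be non-empty")
  stopifnot(length(length_window) == 2, length_window[1] <= length_window[2])
  run <- function(coll) lapply(coll, function(tm)
    amplify(forward, reverse, tm, ...))
  amps <- run(targets)
  n_amp <- sum(vapply(amps, nrow, 0L) > 0)
  anom <- do.call(rbind, lapply(names(amps), function(id) {
    a <- amps[[id]]
    bad <- a$length < length_window[1] | a$length > length_window[2]
    if (any(bad)) data.frame(template_id = id, length = a$length[bad]) else NULL
  }))
  if (is.null(anom))
    anom <- data.frame(template_id = character(), length = integer())
  n_neg <- 0L
  if (!is.null(negatives) && length(negatives))
    n_neg <- sum(vapply(run(negatives), nrow, 0L) > 0)
  structure(list(
    n_templates = length(targets), n_amplified = n_amp,
    fraction_amplified = n_amp / length(targets),
    n_negative = length(negatives %||% character()),
    n_negative_amplified = n_neg,
    fraction_negative = if (length(negatives %||% character()))
      n_neg / length(negatives) else NA_real_,
    length_anomalies = anom,
    pair = paste(forward$name, reverse$name, sep = "/")),
    class = "primer_pair_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.primer_pair_metrics <- function(x, ...) {
  cat(sprintf("<primer_pair_metrics> %s\n", x$pair))
  cat(sprintf("  targets amplified : %d/%d (%.2f%%)\n",
              x$n_amplified, x$n_templates, 100 * x$fraction_amplified))
  if (x$n_negative > 0)
    cat(sprintf("  negatives amplified: %d/%d (%.2f%%)\n",
                x$n_negative_amplified, x$n_negative,
                100 * x$fraction_negative))
  cat(sprintf("  length anomalies  : %d\n", nrow(x$length_anomalies)))
  invisible(x)
}
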