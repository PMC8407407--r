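# Seeded generators for reference databases with controlled divergence,
# primer-bearing templates, and error-bearing non-overlapping paired reads.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults mirror the
#' study design this package re-embodies: a 166-entry reference database, a
#' 736-nt amplicon (primer footprints included), 2 x 300 nt non-overlapping
#' reads, and a 0.5% per-base substitution error rate.
#'
#' @param seed RNG seed (mandatory; every generator draw derives from it).
#' @param n_species Number of reference species (default 166).
#' @param divergence Target minimum pairwise divergence between any two
#'   references, as a fraction (default 0.03).
#' @param amplicon_length Full amplicon length in nt including both primer
#'   footprints (default 736).
#' @param read_length Mate length in nt (default 300).
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param quality Constant Phred quality assigned to simulated bases
#'   (default 37).
#' @param quality_decay Total linear quality drop toward the 3' end
#'   (default 0 = constant).
#' @param forward,reverse [primer] objects used when implanting sites; the
#'   amplicon interior length is `amplicon_length` minus both primer lengths.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_species = 166, divergence = 0.03,
                       amplicon_length = 736, read_length = 300,
                       error_rate = 0.005, quality = 37, quality_decay = 0,
                       forward = rpod_primers()$PsEG30F,
                       reverse = rpod_primers()$PsEG790R) {
  stopifnot(!missing(seed), n_species >= 1,
            divergence > 0, divergence < 1,
            read_length <= amplicon_length, error_rate >= 0, error_rate < 1)
  interior <- amplicon_length - nchar(forward$sequence) - nchar(reverse$sequence)
  stopifnot(interior >= read_length)
  structure(list(seed = seed, n_species = n_species, divergence = divergence,
                 amplicon_length = amplicon_length, interior_length = interior,
                 read_length = read_length, error_rate = error_rate,
                 quality = quality, quality_decay = quality_decay,
                 forward = forward, reverse = reverse),
            class = "sim_config")
}

min_pairwise_divergence <- function(seq_mat) {
  # seq_mat: n x L character matrix; divergence = hamming / L
  n <- nrow(seq_mat); L <- ncol(seq_mat)
  if (n < 2) return(NA_real_)
  match_counts <- matrix(0, n, n)
  for (b in BASES) {
    ind <- (seq_mat == b) * 1
    match_counts <- match_counts + tcrossprod(ind)
  }
  div <- 1 - match_counts / L
  min(div[upper.tri(div)])
}

#' Simulate a reference database with controlled divergence
#'
#' Evolves `n_species` sequences from a single random ancestor by independent
#' per-site substitution, at a per-lineage rate of 1.7 times the target
#' divergence (so the realised minimum pairwise divergence comfortably
#' exceeds the target even in the tail over all pairs), then verifies the
#' target; the rate escalates and finally errors if the target is
#' unreachable. Taxonomy labels with group/subgroup structure are
#' synthesised. Byte-identical output for identical `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_db`: an `amplicon_db` in `$db`, the `ancestor`
#'   sequence, and the realised `min_divergence`.
#' @export
simulate_reference_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_species; L <- config$interior_length
  with_seed(config$seed, {
    ancestor <- sample(BASES, L, replace = TRUE)
    rate <- min(0.75, 1.7 * config$divergence)
    for (attempt in 1:5) {
      seq_mat <- matrix(rep(ancestor, each = n), nrow = n)
      mut <- matrix(runif(n * L) < rate, nrow = n)
      n_mut <- sum(mut)
      if (n_mut) {
        # substitute with a uniformly chosen different base
        old <- seq_mat[mut]
        pick <- ceiling(runif(n_mut) * 3)
        alt <- t(vapply(old, function(b) setdiff(BASES, b), character(3)))
        seq_mat[mut] <- alt[cbind(seq_len(n_mut), pick)]
      }
      md <- min_pairwise_divergence(seq_mat)
      if (n == 1 || md >= config$divergence) break
      rate <- min(0.75, rate * 1.4)
      if (attempt == 5)
        stop(sprintf("divergence target %.3f unreachable (reached %.3f)",
                     config$divergence, md))
    }
    ids <- sprintf("ref%03d", seq_len(n))
    groups <- sprintf("group%02d", ((seq_len(n) - 1) %% 8) + 1)
    subgroups <- ifelse(seq_len(n) %% 2 == 0,
                        sprintf("%s.sub%d", groups, ((seq_len(n) - 1) %/% 8) %% 3 + 1),
                        NA_character_)
    records <- data.frame(
      id = ids, species = sprintf("species_%03d", seq_len(n)),
      group = groups, subgroup = subgroups,
      sequence = apply(seq_mat, 1, paste, collapse = ""), source_id = ids)
    db <- structure(list(records = records,
                         rejects = data.frame(id = character(),
                                              reason = character())),
                    class = "amplicon_db")
    structure(list(db = db, ancestor = paste(ancestor, collapse = ""),
                   min_divergence = if (n > 1) md else NA_real_,
                   config = config),
              class = "sim_db")
  })
}

#' Implant primer sites around a record to build a PCR template
#'
#' `template = 5' flank + forward site + record + revcomp(reverse site) +
#' 3' flank`, with concrete primer expansions drawn from the current RNG
#' stream; by construction [amplify()] recovers exactly the expected
#' amplicon.
#'
#' @param record DNA string (the amplicon interior).
#' @param forward,reverse [primer] objects.
#' @param flank Random flank length on each side (default 200 nt).
#' @param ablate_forward Omit the forward site (creates a template the pair
#'   cannot amplify, for negative fractions).
#' @return Template DNA string.
#' @export
implant_primer_sites <- function(record, forward = rpod_primers()$PsEG30F,
                                 reverse = rpod_primers()$PsEG790R,
                                 flank = 200, ablate_forward = FALSE) {
  stopifnot(nchar(record) >= nchar(forward$sequence),
            nchar(record) >= nchar(reverse$sequence))
  fwd_site <- sample(expand_iupac(forward$sequence), 1)
  rev_site <- sample(expand_iupac(reverse$sequence), 1)
  left <- if (flank > 0) paste(sample(BASES, flank, TRUE), collapse = "") else ""
  right <- if (flank > 0) paste(sample(BASES, flank, TRUE), collapse = "") else ""
  if (ablate_forward) fwd_site <- ""
  paste0(left, fwd_site, record, revcomp(rev_site), right)
}

quality_string <- function(len, quality, decay) {
  q <- round(quality - decay * (seq_len(len) - 1) / max(1, len - 1))
  intToUtf8(pmax(2, q) + 33)
}

add_substitutions <- function(mat, rate) {
  # mat: L x n character matrix of bases; i.i.d. substitutions at `rate`
  n_cells <- length(mat)
  nerr <- rbinom(1, n_cells, rate)
  if (nerr == 0) return(mat)
  idx <- sample.int(n_cells, nerr)
  mat[idx] <- vapply(mat[idx],
                     function(b) sample(setdiff(BASES, b), 1), character(1))
  mat
}

#' Simulate non-overlapping paired-end reads from database records
#'
#' Mate 1 is the first `read_length` nt of the source record, mate 2 the
#' reverse complement of the last `read_length` nt (the interior between the
#' mate footprints stays unsequenced, as for a 736-nt product on a 2x300
#' platform). Substitution errors are i.i.d. at the configured rate;
#' qualities are constant (with optional linear 3' decay). When `barcodes`
#' are given, each sample's barcode is prepended to mate 1.
#'
#' @param db A `sim_db`, `amplicon_db`, or named character vector of record
#'   sequences.
#' @param n_pairs Total number of pairs per sample.
#' @param proportions Named numeric vector (record id -> proportion, summing
#'   to 1) or `NULL` for equimolar across all records.
#' @param config A [sim_config()]; supplies read length, error rate,
#'   qualities and the seed.
#' @param samples Character vector of sample names (default one sample).
#' @param barcodes Optional named character vector sample -> barcode.
#' @param exact_counts Use exact proportional counts (largest remainder)
#'   instead of multinomial draws (default FALSE).
#' @return List of class `sim_reads`: `pairs` (read-pair data frame with
#'   `sample` column), `truth` (list with `proportions` per sample and
#'   `per_read` data frame of source ids).
#' @export
simulate_read_pairs <- function(db, config, n_pairs, proportions = NULL,
                                samples = "sample1", barcodes = NULL,
                                exact_counts = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- if (inherits(db, "sim_db")) db_sequences(db$db) else db_sequences(db)
  if (is.null(proportions))
    proportions <- setNames(rep(1 / length(seqs), length(seqs)), names(seqs))
  stopifnot(all(names(proportions) %in% names(seqs)),
            abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0))
  rl <- config$read_length
  short <- nchar(seqs[names(proportions)]) < rl
  if (any(short))
    stop("record(s) shorter than read length: ",
         paste(names(proportions)[short], collapse = ", "))
  with_seed(config$seed + 1L, {
    all_pairs <- list(); truth_reads <- list()
    for (s in samples) {
      counts <- if (exact_counts) {
        base_counts <- floor(n_pairs * proportions)
        rem <- n_pairs - sum(base_counts)
        frac <- n_pairs * proportions - base_counts
        extra <- order(-frac)[seq_len(rem)]
        base_counts[extra] <- base_counts[extra] + 1
        base_counts
      } else {
        drop(rmultinom(1, n_pairs, proportions))
      }
      src <- rep(names(proportions), counts)
      pieces1 <- list(); pieces2 <- list()
      for (id in names(proportions)[counts > 0]) {
        k <- counts[[id]]
        sq <- seqs[[id]]
        m1 <- substr(sq, 1, rl)
        m2 <- revcomp(substr(sq, nchar(sq) - rl + 1, nchar(sq)))
        mk <- function(tmpl) {
          mat <- matrix(strsplit(tmpl, "")[[1]], nrow = rl, ncol = k)
          mat <- add_substitutions(mat, config$error_rate)
          apply(mat, 2, paste, collapse = "")
        }
        pieces1[[id]] <- mk(m1); pieces2[[id]] <- mk(m2)
      }
      seq1 <- unlist(pieces1, use.names = FALSE)
      seq2 <- unlist(pieces2, use.names = FALSE)
      qual <- quality_string(rl, config$quality, config$quality_decay)
      qual1 <- rep(qual, length(seq1)); qual2 <- rep(qual, length(seq2))
      if (!is.null(barcodes)) {
        bc <- barcodes[[s]]
        if (is.null(bc)) stop("no barcode for sample ", s)
        seq1 <- paste0(bc, seq1)
        qual1 <- paste0(quality_string(nchar(bc), config$quality, 0), qual1)
      }
      ids <- sprintf("%s_pair%06d", s, seq_along(seq1))
      all_pairs[[s]] <- data.frame(id = ids, sample = s, seq1 = seq1,
                                   qual1 = qual1, seq2 = seq2, qual2 = qual2)
      truth_reads[[s]] <- data.frame(id = ids, sample = s, source = src)
    }
    structure(list(pairs = do.call(rbind, c(all_pairs, make.row.names = FALSE)),
                   truth = list(
                     proportions = proportions,
                     per_read = do.call(rbind, c(truth_reads,
                                                 make.row.names = FALSE)))),
              class = "sim_reads")
  })
}

#' Simulate a community abundance profile
#'
#' Equimolar, user-specified, or log-normal (soil-like, rank-skewed)
#' proportions over `n` species, always renormalised to sum to 1.
#'
#' @param n Number of species.
#' @param profile `"equimolar"`, `"specified"`, or `"lognormal"`.
#' @param values Proportions for `"specified"` (nonnegative, renormalised).
#' @param sigma Log-normal sigma for `"lognormal"` (default 1.5).
#' @param seed RNG seed (required for `"lognormal"`).
#' @return Numeric proportions of length `n` summing to 1.
#' @export
simulate_community_profile <- function(n, profile = c("equimolar", "specified",
                                                      "lognormal"),
                                       values = NULL, sigma = 1.5, seed = NULL) {
  profile <- match.arg(profile)
  switch(profile,
    equimolar = rep(1 / n, n),
    specified = {
      stopifnot(!is.null(values), length(values) == n)
      if (any(values < 0)) stop("negative specified proportion")
      if (sum(values) == 0) stop("all-zero specified proportions")
      values / sum(values)
    },
    lognormal = {
      stopifnot(!is.null(seed))
      with_seed(seed, {
        x <- rlnorm(n, meanlog = 0, sdlog = sigma)
        x / sum(x)
      })
    })
}
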