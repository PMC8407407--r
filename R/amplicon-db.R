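# Primer-trimmed, taxonomy-labelled amplicon reference database and its
# species-discriminating power.

#' Build an amplicon reference database
#'
#' Runs in-silico PCR on every template, keeps the shortest product per
#' template (a single marker-gene copy is expected; the rule matters only for
#' anomalous templates), trims both primer footprints and attaches taxonomy.
#' Templates yielding no product are listed in a rejects report.
#'
#' @param templates Named character vector of template sequences.
#' @param taxonomy Data frame with columns `id`, `species`, `group`,
#'   `subgroup` (optional column `type_strain`); every template id must have
#'   a row.
#' @param forward,reverse [primer] objects (default PsEG30F/PsEG790R).
#' @param max_mismatch,max_indel Per-site edit budgets.
#' @param length_window Length-2 vector: accepted trimmed-product length
#'   range; products outside it are rejected with reason `"length"`.
#' @param ... Passed to [amplify()].
#' @return An object of class `amplicon_db`: list with `records` (data frame
#'   `id`, `species`, `group`, `subgroup`, `sequence`, `source_id`) and
#'   `rejects` (data frame `id`, `reason`).
#' @export
build_database <- function(templates, taxonomy,
                           forward = rpod_primers()$PsEG30F,
                           reverse = rpod_primers()$PsEG790R,
                           max_mismatch = 1, max_indel = 1,
                           length_window = c(100, 5000), ...) {
  stopifnot(is.character(templates), !is.null(names(templates)))
  req <- c("id", "species", "group")
  if (!all(req %in% names(taxonomy)))
    stop("taxonomy must have columns id, species, group")
  if (!"subgroup" %in% names(taxonomy)) taxonomy$subgroup <- NA_character_
  missing_tax <- setdiff(names(templates), taxonomy$id)
  if (length(missing_tax))
    stop("no taxonomy row for template(s): ",
         paste(missing_tax, collapse = ", "))
  if (anyDuplicated(taxonomy$id)) stop("duplicate ids in taxonomy")
  recs <- list(); rejects <- list()
  for (id in names(templates)) {
    amps <- amplify(forward, reverse, templates[[id]],
                    max_mismatch = max_mismatch, max_indel = max_indel, ...)
    if (!nrow(amps)) {
      rejects[[id]] <- data.frame(id = id, reason = "no_amplicon")
      next
    }
    a <- amps[which.min(amps$length), ]
    trimmed <- substr(a$sequence, a$fwd_len + 1, nchar(a$sequence) - a$rev_len)
    if (nchar(trimmed) < length_window[1] || nchar(trimmed) > length_window[2]) {
      rejects[[id]] <- data.frame(id = id, reason = "length")
      next
    }
    tx <- taxonomy[taxonomy$id == id, ]
    recs[[id]] <- data.frame(
      id = id, species = tx$species, group = tx$group,
      subgroup = as.character(tx$subgroup), sequence = trimmed, source_id = id)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = character(), species = character(), group = character(),
               subgroup = character(), sequence = character(),
               source_id = character())
  rownames(records) <- NULL
  rej <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(id = character(), reason = character())
  rownames(rej) <- NULL
  structure(list(records = records, rejects = rej), class = "amplicon_db")
}

#' @export
print.amplicon_db <- function(x, ...) {
  cat(sprintf("<amplicon_db> %d records (%d species, %d groups), %d rejects\n",
              nrow(x$records), length(unique(x$records$species)),
              length(unique(x$records$group)), nrow(x$rejects)))
  invisible(x)
}

#' Pairwise identity under global alignment
#'
#' Fraction of matching columns in a unit-cost (substitution 1, gap 1) global
#' alignment; the denominator is the full alignment length including gap
#' columns, a conservative choice for clustering.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  v <- .cpp_global_identity(toupper(a), toupper(b))
  v[1] / v[2]
}

#' Greedy identity clustering at a similarity threshold
#'
#' Records are seeded in descending length order (ties broken
#' lexicographically by id, for reproducibility); each record joins the first
#' existing centroid with identity >= `threshold`, otherwise founds a new
#' cluster.
#'
#' @param db An `amplicon_db`, or a named character vector of sequences.
#' @param threshold Identity threshold in `[0, 1]` (default 0.97, the
#'   conventional species-level cutoff).
#' @return Data frame `id`, `cluster` (integer), `is_centroid`.
#' @export
cluster_at_threshold <- function(db, threshold = 0.97) {
  seqs <- if (inherits(db, "amplicon_db"))
    setNames(db$records$sequence, db$records$id) else db
  if (!length(seqs)) stop("at least one record required")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroid_idx <- integer()
  cluster <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (ci in seq_along(centroid_idx)) {
      if (pairwise_identity(seqs[[i]], seqs[[centroid_idx[ci]]]) >= threshold) {
        cluster[i] <- ci; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      centroid_idx <- c(centroid_idx, i)
      cluster[i] <- length(centroid_idx)
    }
  }
  data.frame(id = names(seqs), cluster = cluster,
             is_centroid = seq_along(seqs) %in% centroid_idx,
             row.names = NULL)
}

#' Species discriminability of an amplicon database
#'
#' Clusters the database at an identity threshold; species whose records
#' share a cluster with another species are mutually confusable (e.g. the
#' near-identical P. putida / P. monteilii pair), all others are resolvable.
#'
#' @param db An `amplicon_db`.
#' @param threshold Identity threshold (default 0.97).
#' @return List with `species` (data frame `species`, `resolvable`) and
#'   `confusable_sets` (list of character vectors of species sharing a
#'   cluster).
#' @export
discriminability_report <- function(db, threshold = 0.97) {
  stopifnot(inherits(db, "amplicon_db"))
  cl <- cluster_at_threshold(db, threshold)
  sp <- db$records$species[match(cl$id, db$records$id)]
  sets <- lapply(split(sp, cl$cluster), unique)
  confusable_sets <- unname(Filter(function(s) length(s) > 1, sets))
  confusable <- unique(unlist(confusable_sets))
  species <- sort(unique(db$records$species))
  list(species = data.frame(species = species,
                            resolvable = !species %in% confusable),
       confusable_sets = confusable_sets)
}

#' Write / read an amplicon database as FASTA
#'
#' Serialization contract shared with the classifier: headers are
#' `id|species|group|subgroup` (fields must not contain `|`; missing
#' subgroups are written as `NA`).
#'
#' @param db An `amplicon_db`.
#' @param path FASTA file path (`.gz` handled transparently).
#' @return `write_database` returns `path` invisibly; `read_database` returns
#'   an `amplicon_db`.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "amplicon_db"))
  r <- db$records
  if (any(grepl("|", c(r$id, r$species, r$group, r$subgroup), fixed = TRUE)))
    stop("database fields must not contain '|'")
  headers <- paste(r$id, r$species, r$group, r$subgroup, sep = "|")
  write_fasta(setNames(r$sequence, headers), path)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("database headers must be id|species|group|subgroup")
  m <- do.call(rbind, parts)
  records <- data.frame(id = m[, 1], species = m[, 2], group = m[, 3],
                        subgroup = ifelse(m[, 4] == "NA", NA, m[, 4]),
                        sequence = unname(seqs), source_id = m[, 1])
  structure(list(records = records,
                 rejects = data.frame(id = character(), reason = character())),
            class = "amplicon_db")
}
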