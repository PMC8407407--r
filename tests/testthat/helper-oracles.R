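# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately re-derive results by exhaustive
# enumeration so they share no code with the implementation under test.

# All start positions (1-based) where `v` occurs as an exact substring.
all_occurrences <- function(v, template) {
  L <- nchar(template); n <- nchar(v)
  if (n > L) return(integer())
  starts <- 1:(L - n + 1)
  starts[substring(template, starts, starts + n - 1) == v]
}

# Every sequence reachable from `x` with at most one single-base indel:
# deletion of any base, or insertion of any base at an internal junction.
indel_variants <- function(x) {
  n <- nchar(x)
  vars <- character()
  for (i in seq_len(n))                       # deletions
    vars <- c(vars, paste0(substr(x, 1, i - 1), substr(x, i + 1, n)))
  if (n >= 2) for (i in 1:(n - 1))            # internal insertions
    for (b in c("A", "C", "G", "T"))
      vars <- c(vars, paste0(substr(x, 1, i), b, substr(x, i + 1, n)))
  unique(vars)
}

# Every sequence reachable with at most one substitution.
sub_variants <- function(x) {
  n <- nchar(x)
  vars <- x
  for (i in seq_len(n)) for (b in c("A", "C", "G", "T"))
    vars <- c(vars, paste0(substr(x, 1, i - 1), b, substr(x, i + 1, n)))
  unique(vars)
}

# Brute-force site scan: enumerate all IUPAC expansions x (<=1 indel) x
# (<=1 substitution) variants of the primer and collect every (strand, start)
# where some variant occurs verbatim. Start positions of reverse-strand hits
# are mapped to forward-strand coordinates.
oracle_scan_starts <- function(primer_seq, template) {
  variants <- unique(unlist(lapply(expand_iupac(primer_seq), function(e)
    unlist(lapply(c(e, indel_variants(e)), sub_variants)))))
  L <- nchar(template)
  rc <- revcomp(template)
  hits <- list()
  for (v in variants) {
    for (s in all_occurrences(v, template))
      hits[[length(hits) + 1]] <- c("+", s)
    for (s in all_occurrences(v, rc))   # keyed by reverse-complement start
      hits[[length(hits) + 1]] <- c("-", s)
  }
  if (!length(hits)) return(data.frame(strand = character(), start = integer()))
  df <- unique(data.frame(strand = sapply(hits, `[`, 1),
                          start = as.integer(sapply(hits, `[`, 2))))
  df[order(df$strand, df$start), ]
}

# Read-pair data frame from raw vectors, constant quality.
make_pairs <- function(seq1, seq2, q = 40, sample = NULL) {
  qs <- function(s) vapply(nchar(s), function(n) strrep(intToUtf8(q + 33), n),
                           character(1))
  df <- data.frame(id = sprintf("p%03d", seq_along(seq1)),
                   seq1 = seq1, qual1 = qs(seq1),
                   seq2 = seq2, qual2 = qs(seq2))
  if (!is.null(sample)) df$sample <- sample
  df
}

# Well-separated toy reference set: n sequences of length L with guaranteed
# pairwise divergence (independent random draws; for n small and L moderate
# the divergence is ~75% with overwhelming probability).
random_refs <- function(n, L, seed) {
  with_seed <- function(seed, code) { set.seed(seed); force(code) }
  with_seed(seed, {
    setNames(vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1)), sprintf("ref%02d", seq_len(n)))
  })
}

# Perfect read pair (prefix / reverse-complemented suffix) from a reference.
perfect_pair <- function(ref_seq, read_len) {
  list(m1 = substr(ref_seq, 1, read_len),
       m2 = revcomp(substr(ref_seq, nchar(ref_seq) - read_len + 1,
                           nchar(ref_seq))))
}

# Mutate `n_sub` fixed positions of a sequence (deterministic; positions
# spread evenly, substitution cycles A->C->G->T->A).
mutate_positions <- function(x, positions) {
  ch <- strsplit(x, "")[[1]]
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  ch[positions] <- cyc[ch[positions]]
  paste(ch, collapse = "")
}

# Canonical hit keys for oracle comparison: matches are keyed by the start of
# the alignment on the strand the primer matched (for the minus strand that
# is the start within the reverse complement), so one key identifies one
# physical site regardless of indel-induced end wobble.
scan_start_keys <- function(hits, L) {
  pos <- ifelse(hits$strand == "+", hits$start, L - hits$end + 1)
  sort(unique(paste(hits$strand, pos)))
}

oracle_start_keys <- function(hits, L) {
  sort(unique(paste(hits$strand, hits$start)))
}
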