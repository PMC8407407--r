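# Demultiplexing, quality filtering, alignment and classification.

test_that("barcode demultiplexing assigns by exact prefix and strips it", {
  bc <- data.frame(sample = c("A", "B"), barcode = c("ACGT", "TGCA"))
  pairs <- make_pairs(c("ACGTGGGCCC", "TGCAGGGCCC", "CCCCGGGCCC"),
                      c("TTTTTTTTTT", "TTTTTTTTTT", "TTTTTTTTTT"))
  d <- demultiplex(pairs, bc)
  expect_equal(d$assigned$sample, c("A", "B"))
  expect_equal(d$assigned$seq1, c("GGGCCC", "GGGCCC"))
  expect_equal(nchar(d$assigned$qual1), c(6, 6))
  expect_equal(nrow(d$unassigned), 1)
  expect_error(demultiplex(pairs, data.frame(sample = c("A", "B"),
                                             barcode = c("ACGT", "ACGT"))),
               "duplicate")
})

test_that("demultiplexed counts match the simulator's ground truth", {
  cfg <- sim_config(seed = 71, n_species = 6, divergence = 0.04)
  sdb <- simulate_reference_db(cfg)
  barcodes <- c(s1 = "AAGGTT", s2 = "CCAATT", s3 = "GGTTAA", s4 = "TTCCGG")
  reads <- simulate_read_pairs(sdb, cfg, n_pairs = 25,
                               samples = names(barcodes), barcodes = barcodes)
  # strip the sample column to emulate un-demultiplexed input
  raw <- reads$pairs[setdiff(names(reads$pairs), "sample")]
  d <- demultiplex(raw, data.frame(sample = names(barcodes),
                                   barcode = unname(barcodes)))
  expect_equal(nrow(d$unassigned), 0)
  got <- table(d$assigned$sample)
  want <- table(reads$pairs$sample)
  expect_equal(as.numeric(got[names(want)]), as.numeric(want))
  # barcodes are stripped back to the plain read
  expect_equal(sort(d$assigned$seq1),
               sort(substr(reads$pairs$seq1, 7, nchar(reads$pairs$seq1))))
})

test_that("sliding-window trimming removes exactly a low-quality tail", {
  q40 <- strrep(intToUtf8(40 + 33), 250)
  q10 <- strrep(intToUtf8(10 + 33), 50)
  seq300 <- strrep("ACGT", 75)
  pairs <- data.frame(id = "p1", seq1 = seq300, qual1 = paste0(q40, q10),
                      seq2 = seq300, qual2 = strrep(intToUtf8(40 + 33), 300))
  f <- quality_filter(pairs, min_len = 100)
  expect_equal(nchar(f$kept$seq1), 250)   # the 50-nt Q10 tail, exactly
  expect_equal(nchar(f$kept$seq2), 300)   # all-Q40 mate untouched
  expect_equal(f$kept$seq1, substr(seq300, 1, 250))
  # a mate collapsing below min_len discards the whole pair
  bad <- data.frame(id = "p2", seq1 = seq300,
                    qual1 = paste0(strrep(intToUtf8(40 + 33), 50),
                                   strrep(intToUtf8(5 + 33), 250)),
                    seq2 = seq300, qual2 = strrep(intToUtf8(40 + 33), 300))
  f2 <- quality_filter(bad, min_len = 100)
  expect_equal(nrow(f2$kept), 0)
  expect_equal(nrow(f2$discarded), 1)
})

test_that("mate alignment scores follow the scoring scheme", {
  refs <- random_refs(4, 500, seed = 73)
  # verbatim copy: maximal score 2 * L
  mate <- substr(refs[[2]], 101, 220)
  h <- align_mate(mate, refs)
  expect_equal(h$ref[which.max(h$score)], names(refs)[2])
  expect_equal(max(h$score), 2 * nchar(mate))
  expect_equal(h$start[which.max(h$score)], 101)
  expect_equal(h$end[which.max(h$score)], 220)
  # three interior substitutions: score = 2 (L - 3) - 3 * 3
  L <- 120
  mate3 <- mutate_positions(substr(refs[[1]], 51, 50 + L), c(30, 60, 90))
  h3 <- align_mate(mate3, refs)
  expect_equal(max(h3$score), 2 * (L - 3) - 9)
  # random sequence: nothing above the floor
  set.seed(79)
  noise <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  expect_equal(nrow(align_mate(noise, refs)), 0)
})

test_that("pair classification requires concordance and uniqueness", {
  refs <- random_refs(5, 700, seed = 83)
  pp <- perfect_pair(refs[[3]], 250)
  # clean pair in a well-separated database: assigned at the uniqueness cap
  res <- classify_pair(pp$m1, pp$m2, refs)
  expect_equal(res$status, "assigned")
  expect_equal(res$species, names(refs)[3])
  expect_equal(res$q, 42)
  expect_equal(res$fragment, 700)
  # two identical references: exact tie, Q = 0, unassigned
  dup <- c(refs, dupref = unname(refs[3]))
  res2 <- classify_pair(pp$m1, pp$m2, dup)
  expect_equal(res2$q, 0)
  expect_equal(res2$status, "ambiguous")
  # mates from different references: discordant
  other <- perfect_pair(refs[[1]], 250)
  res3 <- classify_pair(pp$m1, other$m2, refs)
  expect_equal(res3$status, "discordant")
  # fragment window excludes the true span: no concordant reference
  res4 <- classify_pair(pp$m1, pp$m2, refs, frag_window = c(100, 300))
  expect_equal(res4$status, "discordant")
})

test_that("classification conserves pairs across statuses", {
  cfg <- sim_config(seed = 89, n_species = 20, divergence = 0.03)
  sdb <- simulate_reference_db(cfg)
  reads <- simulate_read_pairs(sdb, cfg, n_pairs = 300)
  set.seed(97)
  noise <- make_pairs(
    vapply(1:20, function(i) paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                                   collapse = ""), character(1)),
    vapply(1:20, function(i) paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                                   collapse = ""), character(1)))
  noise$id <- paste0("noise", 1:20)
  all_pairs <- rbind(reads$pairs[names(noise)], noise)
  res <- classify_pairs(all_pairs, sdb$db)
  expect_equal(nrow(res), nrow(all_pairs))
  expect_equal(sum(table(res$status)), nrow(all_pairs))
  tab <- tabulate_assignments(res)
  expect_equal(sum(tab) + sum(attr(tab, "unassigned")), nrow(all_pairs))
})

test_that("raising the uniqueness threshold never adds assignments", {
  cfg <- sim_config(seed = 101, n_species = 30, divergence = 0.02,
                    error_rate = 0.02)
  sdb <- simulate_reference_db(cfg)
  reads <- simulate_read_pairs(sdb, cfg, n_pairs = 200)
  counts <- vapply(c(0, 5, 10, 20, 41), function(th) {
    res <- classify_pairs(reads$pairs, sdb$db, q_threshold = th)
    sum(res$status == "assigned")
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("tables are identical regardless of read order", {
  cfg <- sim_config(seed = 103, n_species = 10, divergence = 0.04)
  sdb <- simulate_reference_db(cfg)
  reads <- simulate_read_pairs(sdb, cfg, n_pairs = 120)
  res1 <- classify_pairs(reads$pairs, sdb$db)
  set.seed(1)
  shuffled <- reads$pairs[sample(nrow(reads$pairs)), ]
  res2 <- classify_pairs(shuffled, sdb$db)
  t1 <- tabulate_assignments(res1)
  t2 <- tabulate_assignments(res2)
  expect_equal(unclass(t1)[, colnames(t1)], unclass(t2)[, colnames(t1)])
})

test_that("tabulation splits assigned and unassigned without double counting", {
  a <- data.frame(id = paste0("p", 1:6),
                  sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
                  ref = c("r1", "r1", NA, "r2", NA, NA),
                  species = c("spA", "spA", NA, "spB", NA, NA),
                  q = c(42, 42, 0, 42, 0, 0), score = 0, fragment = NA,
                  status = c("assigned", "assigned", "ambiguous",
                             "assigned", "no_hit", "discordant"))
  tab <- tabulate_assignments(a)
  expect_equal(dim(tab), c(2, 2))
  expect_equal(unname(unclass(tab)["s1", "spA"]), 2)
  expect_equal(unname(unclass(tab)["s2", "spB"]), 1)
  expect_equal(unname(attr(tab, "unassigned")), c(1, 2))
  # empty assignment set: all pairs unassigned
  none <- a; none$status <- "no_hit"
  tab0 <- tabulate_assignments(none)
  expect_equal(ncol(tab0), 0)
  expect_equal(sum(attr(tab0, "unassigned")), 6)
})

test_that("depth normalization scales rows to an exact constant", {
  m <- abundance_table(matrix(c(2, 3, 5, 1, 1, 1), nrow = 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  norm <- normalize_to_depth(m, 100000)
  expect_equal(unname(unclass(norm)["s1", ]), c(20000, 30000, 50000))
  expect_equal(unname(unclass(norm)["s2", ]),
               rep(100000 / 3, 3))
  expect_equal(unname(rowSums(norm)), c(100000, 100000))
  expect_equal(attr(norm, "normalization"), "normalized_to_depth")
  # an already-normalized row is unchanged
  pre <- abundance_table(matrix(c(60000, 40000), 1,
                                dimnames = list("s", c("a", "b"))))
  expect_equal(unclass(normalize_to_depth(pre, 100000))[1, ],
               unclass(pre)[1, ])
  # zero-total samples are rejected by name
  z <- abundance_table(matrix(c(1, 0), 2, 1,
                              dimnames = list(c("ok", "empty"), "a")))
  expect_error(normalize_to_depth(z), "empty")
})

test_that("seeded subsampling reaches the depth exactly and reproducibly", {
  m <- abundance_table(matrix(c(500, 300, 200), 1,
                              dimnames = list("s1", c("a", "b", "c"))))
  s1 <- subsample_to_depth(m, depth = 100, seed = 7)
  s2 <- subsample_to_depth(m, depth = 100, seed = 7)
  expect_equal(unclass(s1), unclass(s2))
  expect_equal(sum(s1), 100)
  expect_error(subsample_to_depth(m, depth = 2000, seed = 7), "shallower")
})
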