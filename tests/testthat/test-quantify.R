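# A hand-built two-miRNA reference with known hairpin context, so every
# isomiR call below is verifiable by eye.
mk_ref <- function() {
  m1 <- "TGACAGAAGAGAGTGAGCACA"                       # 21 nt
  m2 <- "TTGGACTGAAGGGAGCTCCCT"                       # 21 nt
  data.frame(
    id = c("sim-miR1a-5p", "sim-miR2a-3p"),
    mature = c(m1, m2),
    hairpin = c(paste0("ACGTACGTACGT", m1, "GGCCTTAAGGCCTTAAGGCCTTAAGG"),
                paste0("TTCCGGAATTCC", m2, "AATTGGCCAATTGGCCAATTGGCCAA")),
    stringsAsFactors = FALSE
  )
}

test_that("classify_isomir reproduces hand-derived calls", {
  ref <- mk_ref()
  m1 <- ref$mature[1]

  exact <- classify_isomir(m1, ref)
  expect_equal(exact$class, "canonical")
  expect_equal(exact$canonical_id, ref$id[1])
  expect_equal(c(exact$offset5, exact$offset3, exact$n_substitutions),
               c(0L, 0L, 0L))

  tr5 <- classify_isomir(substr(m1, 2, 21), ref)
  expect_equal(tr5$class, "5p_variant")
  expect_equal(tr5$offset5, 1L)
  expect_equal(tr5$offset3, 0L)

  # templated 3' extension: next hairpin base after m1 is "G"
  ext_t <- classify_isomir(paste0(m1, "G"), ref)
  expect_equal(ext_t$class, "3p_variant")
  expect_equal(ext_t$offset3, 1L)
  expect_true(ext_t$templated3)

  ext_u <- classify_isomir(paste0(m1, "T"), ref)
  expect_equal(ext_u$class, "3p_variant")
  expect_false(ext_u$templated3)

  sub1 <- sub("GAGAGTG", "GAGCGTG", m1)      # one internal substitution
  int <- classify_isomir(sub1, ref)
  expect_equal(int$class, "internal_variant")
  expect_equal(int$n_substitutions, 1L)
  expect_equal(c(int$offset5, int$offset3), c(0L, 0L))

  both <- classify_isomir(substr(paste0(m1, "G"), 2, 22), ref)
  expect_equal(both$class, "both_variant")
  expect_equal(c(both$offset5, both$offset3), c(1L, 1L))

  novel <- classify_isomir(strrep("T", 22), ref)
  expect_equal(novel$class, "variant_novel")
  expect_true(is.na(novel$canonical_id))
})

test_that("cost ties break on abundance when given, reference order otherwise", {
  x <- "ACGGATTCGCATCGAACGTG"                          # 20 nt
  ref <- data.frame(
    id = c("mirA", "mirB"),
    mature = c(paste0(x, "A"), paste0(x, "G")),
    hairpin = c(paste0(strrep("C", 12), x, "A", strrep("T", 20)),
                paste0(strrep("C", 12), x, "G", strrep("T", 20))),
    stringsAsFactors = FALSE
  )
  # the tag is a 1-base 3' truncation of either mature: identical edit cost
  tie <- classify_isomir(x, ref)
  expect_equal(tie$canonical_id, "mirA")
  tie2 <- classify_isomir(x, ref, abundance = c(mirA = 1, mirB = 50))
  expect_equal(tie2$canonical_id, "mirB")
})

test_that("identical mature sequences collapse to one merged-ID group", {
  ref <- mk_ref()
  ref <- rbind(ref, data.frame(id = "sim-miR1b-5p", mature = ref$mature[1],
                               hairpin = ref$hairpin[1]))
  merged <- build_reference_index(ref)$merged
  expect_equal(nrow(merged), 2)
  expect_equal(merged$group_id[1], "sim-miR1a-5p,sim-miR1b-5p")

  tags <- data.frame(sequence = c(ref$mature[1], ref$mature[2]),
                     count = c(10L, 4L))
  a <- match_tags(tags, ref)
  expect_equal(a$assigned_id,
               c("sim-miR1a-5p,sim-miR1b-5p", "sim-miR2a-3p"))
  cnt <- mirna_counts(list(lib1 = a))
  # shared-sequence members are counted once, as the merged group
  expect_equal(sum(cnt[, "lib1"]), 14L)
  expect_equal(unname(cnt["sim-miR1a-5p,sim-miR1b-5p", "lib1"]), 10L)
})

test_that("isomiR counts are never added to canonical counts", {
  ref <- mk_ref()
  tags <- data.frame(
    sequence = c(ref$mature[1], paste0(ref$mature[1], "G")),
    count = c(7L, 5L))
  a <- match_tags(tags, ref)
  cnt <- mirna_counts(list(L = a))
  expect_equal(unname(cnt[ref$id[1], "L"]), 7L)
  cnt_all <- mirna_counts(list(L = a), canonical_only = FALSE)
  expect_equal(unname(cnt_all[ref$id[1], "L"]), 12L)
})

test_that("read-level isomiR calls agree with simulation truth", {
  b <- tiny_reference(seed = 8)
  lib <- simulate_srna_library(b, isomir_rate = 0.3, seed = 4, depth = 1500,
                               low_quality_fraction = 0, short_fraction = 0)
  tags <- preprocess_srna(lib$reads, "CTGGAGTTCAGACGTGTGCTCTTCCGATCT")
  a <- match_tags(tags, b$reference)
  pred_class <- setNames(a$class, a$sequence)
  pred_id <- setNames(a$assigned_id, a$sequence)
  ok_class <- pred_class[lib$truth$insert] == lib$truth$class
  expect_gte(mean(ok_class), 0.95)
  # canonical reads must be assigned to a merged group containing the true id
  can <- lib$truth$class == "canonical"
  members <- strsplit(pred_id[lib$truth$insert[can]], ",", fixed = TRUE)
  hit <- mapply(function(m, id) id %in% m, members, lib$truth$mirna_id[can])
  expect_true(all(hit))
})

test_that("RPTM and the retention filter match hand values and the oracle", {
  counts <- rbind(a = c(10, 0, 5, 2), b = c(4000, 3500, 5000, 4200))
  totals <- c(1e6, 2e6, 5e6, 1e7)
  rptm <- rptm_normalize(counts, totals)
  expect_equal(unname(rptm["a", ]), c(100, 0, 10, 2))
  expect_error(rptm_normalize(counts, c(1e6, 0, 5e6, 1e7)))

  set.seed(33)
  mat <- matrix(rexp(50 * 8, rate = 1), 50, 8,
                dimnames = list(paste0("f", 1:50), NULL))
  groups <- rep(c("WW", "mild"), each = 4)
  kept <- retention_filter(mat, groups)
  oracle <- rownames(mat)[apply(mat, 1, brute_retained, groups = groups)]
  expect_setequal(kept, oracle)
  # boundary: exactly min_rptm in exactly min_libs libraries is retained
  edge <- matrix(c(1, 1, 1, 0.999, 0, 0, 0, 0), 1,
                 dimnames = list("edge", NULL))
  expect_equal(retention_filter(edge, groups), "edge")
  edge2 <- matrix(c(1, 1, 0.999, 0.999, 0, 0, 0, 0), 1,
                  dimnames = list("edge2", NULL))
  expect_equal(length(retention_filter(edge2, groups)), 0)
})
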