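test_that("find_sites matches the brute-force scan on random sequences", {
  set.seed(19)
  for (rep in 1:25) {
    mir <- random_dna(1, sample(18:24, 1))
    tx <- random_dna(1, 120)
    if (rep %% 3 == 0) {
      # plant a near-complementary window so hits actually occur
      s <- sample(1:(120 - nchar(mir) + 1), 1)
      site <- revcomp(mir)
      n_mm <- sample(0:3, 1)
      if (n_mm > 0) {
        ch <- seq_chars(site)
        for (p in sample(nchar(site), n_mm)) {
          ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
        }
        site <- paste(ch, collapse = "")
      }
      substr(tx, s, s + nchar(mir) - 1) <- site
    }
    found <- find_sites(mir, tx)
    expect_identical(found$site_start, brute_sites(mir, tx), label = paste("rep", rep))
  }
})

test_that("site geometry is antiparallel with hand-checkable pairing strings", {
  mir <- "TGACAGAAGAGAGTGAGCACA"                 # 21 nt
  s <- 31
  tx <- paste0(strrep("A", 30), revcomp(mir), strrep("A", 30))
  hit <- find_sites(mir, tx)
  hit <- hit[hit$site_start == s, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$site_end, s + 20)
  expect_equal(hit$mismatch_count, 0)
  expect_equal(hit$pairing, strrep("|", 21))
  # the non-reversed complement is NOT a site (orientation matters)
  comp_only <- chartr("ACGT", "TGCA", mir)
  tx2 <- paste0(strrep("A", 30), comp_only, strrep("A", 30))
  expect_equal(nrow(find_sites(mir, tx2)), 0)

  # G:U wobble: miRNA position 4 is C -> make the paired transcript base A
  ch <- seq_chars(revcomp(mir))
  expect_equal(ch[21 - 4 + 1], "G")              # pairs miRNA position 4
  ch[21 - 4 + 1] <- "A"                           # A opposite C: plain mismatch
  txa <- paste0(strrep("A", 30), paste(ch, collapse = ""), strrep("A", 30))
  h <- find_sites(mir, txa)
  h <- h[h$site_start == s, ]
  expect_equal(h$mismatch_count, 1)
  expect_equal(substr(h$pairing, 4, 4), "x")

  # miRNA position 1 is T (U); transcript G opposite it is a wobble pair
  ch2 <- seq_chars(revcomp(mir))
  expect_equal(ch2[21], "A")
  ch2[21] <- "G"
  txw <- paste0(strrep("A", 30), paste(ch2, collapse = ""), strrep("A", 30))
  hw <- find_sites(mir, txw)
  hw <- hw[hw$site_start == s, ]
  expect_equal(hw$mismatch_count, 1)              # default: wobble = mismatch
  expect_equal(substr(hw$pairing, 1, 1), "o")
  expect_equal(find_sites(mir, txw, gu_policy = "match")$mismatch_count[
    find_sites(mir, txw, gu_policy = "match")$site_start == 31], 0)
  hh <- find_sites(mir, txw, gu_policy = "half")
  expect_equal(hh$mismatch_count[hh$site_start == 31], 0.5)
})

test_that("pileups count multi-mapping tags at every locus and flag them", {
  txs <- c(t1 = paste0("ACGTACGTACGTACGTACGTGG", strrep("T", 30),
                       "ACGTACGTACGTACGTACGTGG"),
           t2 = paste0(strrep("C", 10), "ACGTACGTACGTACGTACGTGG",
                       strrep("C", 10)))
  tag <- "ACGTACGTACGTACGTACGT"                  # 20 nt, multi-mapping
  pl <- pileup_tags(data.frame(sequence = tag, count = 3L), txs)
  expect_equal(pl$multi_tags, tag)
  expect_equal(pl$pileups$t1[c(1, 53)], c(3, 3))
  expect_equal(pl$pileups$t2[11], 3)
  pu <- pileup_tags(data.frame(sequence = tag, count = 3L), txs,
                    unique_only = TRUE)
  expect_equal(sum(unlist(pu$pileups)), 0)
  expect_error(pileup_from_table(
    data.frame(transcript_id = "nope", position = 1L, count = 1L), txs))
  expect_error(pileup_from_table(
    data.frame(transcript_id = "t2", position = 1000L, count = 1L), txs))
})

test_that("call_targets applies the 9-11 / <4-mismatch rule with categories", {
  mir <- "TGACAGAAGAGAGTGAGCACA"                 # M = 21
  tx <- paste0(strrep("A", 30), revcomp(mir), strrep("A", 30))
  txs <- c(tx1 = tx)
  sites <- find_sites(mir, tx, transcript_id = "tx1")
  s <- sites$site_start
  # tag 5' end on the base paired to miRNA position 10 -> valid, dominant
  p10 <- s + 21 - 10
  pl <- pileup_from_table(
    data.frame(transcript_id = "tx1", position = p10, count = 5L), txs)
  ct <- call_targets(sites, pl)
  expect_true(ct$valid)
  expect_equal(ct$category, "dominant-peak")
  expect_equal(ct$valid_reads_9_11, 5)
  expect_equal(ct$peak_position, p10)

  # signal only outside 9-11 -> not valid, minor
  pl2 <- pileup_from_table(
    data.frame(transcript_id = "tx1", position = s, count = 9L), txs)
  ct2 <- call_targets(sites, pl2)
  expect_false(ct2$valid)
  expect_equal(ct2$category, "minor")

  # tie between a 9-11 base and an outside base -> valid but co-dominant
  pl3 <- pileup_from_table(
    data.frame(transcript_id = "tx1", position = c(p10, s), count = c(4L, 4L)),
    txs)
  ct3 <- call_targets(sites, pl3)
  expect_true(ct3$valid)
  expect_equal(ct3$category, "co-dominant")

  # four mismatches invalidate the site even with a perfect peak
  sites4 <- sites; sites4$mismatch_count <- 4
  expect_false(call_targets(sites4, pl)$valid)

  sites_bad <- sites; sites_bad$transcript_id <- "missing"
  expect_error(call_targets(sites_bad, pl))
})

test_that("validity calls equal the brute-force oracle on random pileups", {
  set.seed(5)
  mir <- random_dna(1, 21)
  tx <- paste0(random_dna(1, 40), revcomp(mir), random_dna(1, 40))
  txs <- c(tx = tx)
  sites <- find_sites(mir, tx, transcript_id = "tx")
  for (r in 1:20) {
    pos <- sample(nchar(tx), 3)
    pl <- pileup_from_table(
      data.frame(transcript_id = "tx", position = pos, count = c(1L, 2L, 1L)),
      txs)
    ct <- call_targets(sites, pl)
    oracle <- vapply(seq_len(nrow(sites)), function(i) {
      brute_valid(sites$site_start[i], 21, sites$mismatch_count[i],
                  pl$pileups$tx)
    }, logical(1))
    expect_equal(ct$valid, oracle)
  }
})

test_that("planted sites validate through both the tag-table and FASTQ routes", {
  b <- tiny_reference(seed = 27)
  deg <- simulate_degradome(b, peak_fraction = 0.8, noise_rate = 0.01,
                            seed = 6)
  mirs <- setNames(b$reference$mature, b$reference$id)
  sites <- find_sites_all(mirs, b$transcripts)
  pl_a <- pileup_from_table(deg$tags, b$transcripts)
  pl_b <- pileup_tags(preprocess_degradome(deg$reads), b$transcripts)
  ct_a <- call_targets(sites, pl_a)
  ct_b <- call_targets(sites, pl_b)
  truth <- b$truth$target_sites
  key <- function(d) paste(d$mirna_id, d$transcript_id, d$site_start)
  planted_a <- ct_a[key(ct_a) %in% key(truth), ]
  expect_equal(nrow(planted_a), nrow(truth))
  expect_true(all(planted_a$valid))
  planted_b <- ct_b[key(ct_b) %in% key(truth), ]
  expect_true(all(planted_b$valid))
})
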