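test_that("seeded generation is reproducible and writes consistent files", {
  cfg <- sim_config(n_families = 2, members_per_family = 2, n_transcripts = 5,
                    n_target_sites = 2, transcript_length = c(300L, 400L),
                    seed = 7)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_dataset(cfg, d1, srna_depth = 500)
  simulate_dataset(cfg, d2, srna_depth = 500)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # emitted truth is consistent with emitted sequence files (re-parse)
  ref <- read.delim(file.path(d1, "reference.tsv"))
  mature <- read_fasta(file.path(d1, "mature.fa"))
  hairpin <- read_fasta(file.path(d1, "hairpin.fa"))
  txs <- read_fasta(file.path(d1, "transcripts.fa"))
  expect_identical(unname(mature[ref$id]), ref$mature)
  expect_true(all(mapply(grepl, ref$mature, hairpin[ref$id],
                         MoreArgs = list(fixed = TRUE))))
  sites <- read.delim(file.path(d1, "target_sites.tsv"))
  for (i in seq_len(nrow(sites))) {
    m <- mature[[sites$mirna_id[i]]]
    window <- substr(txs[[sites$transcript_id[i]]], sites$site_start[i],
                     sites$site_end[i])
    hamming <- sum(strsplit(window, "")[[1]] !=
                   strsplit(as.character(
                     Biostrings::reverseComplement(Biostrings::DNAString(m))
                   ), "")[[1]])
    expect_equal(hamming, sites$mismatches[i])
  }
  mimic <- read.delim(file.path(d1, "mimic_locus.tsv"))
  expect_true(mimic$transcript_id %in% names(txs))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted binding sites and mimic are recovered by construction", {
  b <- tiny_reference(seed = 13)
  mirs <- setNames(b$reference$mature, b$reference$id)
  sites <- b$truth$target_sites
  for (i in seq_len(nrow(sites))) {
    found <- find_sites(mirs[[sites$mirna_id[i]]],
                        b$transcripts[[sites$transcript_id[i]]])
    expect_true(sites$site_start[i] %in% found$site_start)
    row <- found[found$site_start == sites$site_start[i], ]
    expect_equal(row$mismatch_count, sites$mismatches[i])
  }
  mm <- b$truth$mimic
  hits <- scan_mimics(b$transcripts, mirs[[mm$mirna_id]],
                      mirna_id = mm$mirna_id)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$transcript_id, mm$transcript_id)
  expect_equal(hits$region_start, mm$region_start)
  expect_equal(hits$region_end, mm$region_end)
})

test_that("isomir_rate = 0 yields only canonical reads; RPTM expectation holds", {
  b <- tiny_reference(seed = 3)
  lib <- simulate_srna_library(b, isomir_rate = 0, seed = 9, depth = 2000,
                               low_quality_fraction = 0, short_fraction = 0)
  expect_true(all(lib$truth$class == "canonical"))
  expect_true(all(lib$truth$insert %in% b$reference$mature))

  # one miRNA at relative abundance 5e-4 at depth 1e5: expected RPTM 5000
  ab <- setNames(rep(1, nrow(b$reference)), b$reference$id)
  ab <- ab / sum(ab)
  target <- b$reference$id[1]
  ab <- ab * (1 - 5e-4) ; ab[target] <- 5e-4
  lib2 <- simulate_srna_library(b, abundance = ab, isomir_rate = 0, seed = 11,
                                depth = 1e5, low_quality_fraction = 0,
                                short_fraction = 0)
  n <- sum(lib2$truth$mirna_id == target)
  rptm <- 1e7 * n / 1e5
  se <- 1e7 * sqrt(1e5 * 5e-4) / 1e5
  expect_lt(abs(rptm - 5000), 4 * se)
})

test_that("degradome peak placement follows peak_fraction", {
  b <- tiny_reference(seed = 21)
  deg <- simulate_degradome(b, peak_fraction = 1, noise_rate = 0, seed = 2)
  sites <- b$truth$target_sites
  for (i in seq_len(nrow(sites))) {
    tg <- deg$tags[deg$tags$transcript_id == sites$transcript_id[i], ]
    expect_equal(tg$position, sites$cleavage_pos[i])
  }
  # raw degradome reads start at the tag 5' end
  tags <- preprocess_degradome(deg$reads)
  pl <- pileup_tags(tags, b$transcripts)
  for (i in seq_len(nrow(sites))) {
    expect_gt(pl$pileups[[sites$transcript_id[i]]][sites$cleavage_pos[i]], 0)
  }
})

test_that("simulated counts match negative-binomial moments", {
  cfg <- sim_config(n_families = 2, members_per_family = 1, dispersion = 0.2,
                    de_fraction = 0, n_libraries_per_group = 1000,
                    groups = c("WW", "mild"), library_depth = 1e6, seed = 5)
  cm <- simulate_counts(cfg)
  # library-depth jitter is lognormal(sd 0.15), adding cv^2 to the quadratic
  # variance term: Var = mu + (phi + cv2) mu^2
  cv2 <- exp(0.15^2) - 1
  x <- cm$counts[1, cm$groups == "WW"]
  mu <- mean(x)
  expect_lt(abs(var(x) / (mu + (0.2 + cv2) * mu^2) - 1), 0.3)

  cfg0 <- sim_config(n_families = 2, members_per_family = 1, dispersion = 0,
                     de_fraction = 0, n_libraries_per_group = 1000,
                     groups = c("WW", "mild"), library_depth = 1e6, seed = 5)
  cm0 <- simulate_counts(cfg0)
  x0 <- cm0$counts[1, cm0$groups == "WW"]
  mu0 <- mean(x0)
  # dispersion 0: Poisson given depth, so Var = mu + cv2 mu^2
  expect_lt(abs(var(x0) / (mu0 + cv2 * mu0^2) - 1), 0.3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(isomir_rate = 1.5))
  expect_error(sim_config(library_depth = 0))
  expect_error(sim_config(mirna_length_range = c(15, 24)))
  expect_error(sim_config(site_mismatches = 0:4))
})
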