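# Synthetic-data generator: emits every input the pipeline consumes (miRNA
# reference, transcripts, small-RNA and degradome libraries, count matrices,
# qPCR Ct tables) with ground-truth labels, emulating the study design of
# three watering treatments with four biological replicates each.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults emulate the
#' study conditions: three treatment groups (well-watered, mild and severe
#' water deficit) with four libraries each, ~78 miRNAs in 26 families,
#' negative-binomially dispersed counts, and a differential subset.
#'
#' @param n_families Number of miRNA families.
#' @param members_per_family Members per family.
#' @param mirna_length_range Range of mature miRNA lengths (nt), within 18-30.
#' @param n_libraries_per_group Libraries per treatment group.
#' @param groups Treatment labels.
#' @param isomir_rate Per-read probability that a read is an isomiR variant.
#' @param de_fraction Probability a miRNA is differentially abundant.
#' @param fold_changes Multiplicative effects sampled for differential miRNAs.
#' @param dispersion Negative-binomial dispersion phi (>= 0; 0 gives Poisson).
#' @param library_depth Expected mapped tags per library.
#' @param n_transcripts Number of background transcripts.
#' @param transcript_length Min/max transcript length (nt).
#' @param n_target_sites Number of planted miRNA binding sites.
#' @param site_mismatches Mismatch counts sampled for planted sites (< 4).
#' @param adapter 3' sequencing adapter planted on small-RNA reads.
#' @param seed Integer seed; every sub-generator derives a named stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 26L,
                       members_per_family = 3L,
                       mirna_length_range = c(21L, 24L),
                       n_libraries_per_group = 4L,
                       groups = c("WW", "mild", "severe"),
                       isomir_rate = 0.2,
                       de_fraction = 0.4,
                       fold_changes = c(0.125, 0.25, 4, 8),
                       dispersion = 0.1,
                       library_depth = 4e6,
                       n_transcripts = 30L,
                       transcript_length = c(800L, 2000L),
                       n_target_sites = 8L,
                       site_mismatches = 0:2,
                       adapter = "CTGGAGTTCAGACGTGTGCTCTTCCGATCT",
                       seed = 1L) {
  stopifnot(
    n_families >= 1L, members_per_family >= 1L,
    mirna_length_range[1] >= 18L, mirna_length_range[2] <= 30L,
    mirna_length_range[1] <= mirna_length_range[2],
    n_libraries_per_group >= 2L, length(groups) >= 2L,
    isomir_rate >= 0, isomir_rate <= 1,
    de_fraction >= 0, de_fraction <= 1,
    all(fold_changes > 0), dispersion >= 0, library_depth > 0,
    n_transcripts >= 1L, n_target_sites >= 0L,
    all(site_mismatches >= 0L), all(site_mismatches < 4L),
    nzchar(adapter)
  )
  if (max(site_mismatches) >= mirna_length_range[1]) {
    stop("site_mismatches must be smaller than the miRNA length")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

mutate_bases <- function(seq, positions) {
  ch <- seq_chars(seq)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a miRNA reference, transcripts and ground truth
#'
#' Creates miRBase-style mature/hairpin pairs (mature sequences are
#' subsequences of their hairpins), a transcript set carrying planted miRNA
#' binding sites (reverse complement of the mature sequence with a configured
#' number of mismatches), and exactly one transcript carrying a target-mimic
#' region: complementary to a chosen miRNA except for a 3-nt non-complementary
#' insertion opposite miRNA positions 10-11 (the IPS1/pilncr1 architecture).
#' One family contains two members with identical mature sequences so that
#' merged-ID assignment (e.g. "miR399e,i,j-3p") is exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements `reference` (data frame: `id`, `mature`,
#'   `hairpin`, `arm`, `family`), `transcripts` (named character vector) and
#'   `truth` (list with `target_sites` and `mimic`).
#' @export
make_reference <- function(config) {
  with_stream(config$seed, "reference", {
    fams <- seq_len(config$n_families)
    letters_pool <- letters
    rows <- list()
    for (f in fams) {
      fam_label <- paste0("sim-miR", f)
      len <- sample(seq(config$mirna_length_range[1],
                        config$mirna_length_range[2]), 1L)
      for (m in seq_len(config$members_per_family)) {
        id <- paste0(fam_label, letters_pool[m], "-",
                     sample(c("5p", "3p"), 1L))
        if (f == 1L && m == 2L) {
          # identical mature sequence within the family -> merged-ID group
          mature <- rows[[1L]]$mature
          id <- paste0(fam_label, letters_pool[m], "-",
                       sub(".*-", "", rows[[1L]]$id))
        } else {
          # the adapter trimmer keys on the first 8 adapter bases; a mature
          # sequence containing (or abutting into) that prefix would make raw
          # reads ambiguous and truth labels meaningless, so redraw
          prefix <- substr(config$adapter, 1L, 8L)
          repeat {
            mature <- random_dna(1L, len)
            at <- regexpr(prefix, paste0(mature, config$adapter),
                          fixed = TRUE)
            if (at == len + 1L) break
          }
        }
        flank5 <- random_dna(1L, 12L)
        flank3 <- random_dna(1L, 40L)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, mature = mature,
          hairpin = paste0(flank5, mature, flank3),
          arm = sub(".*-", "", id), family = fam_label,
          stringsAsFactors = FALSE
        )
      }
    }
    reference <- do.call(rbind, rows)
    stopifnot(!anyDuplicated(reference$id))

    tlen <- sample(seq(config$transcript_length[1], config$transcript_length[2]),
                   config$n_transcripts, replace = TRUE)
    transcripts <- setNames(
      vapply(tlen, function(l) random_dna(1L, l), character(1)),
      sprintf("tx%03d", seq_len(config$n_transcripts))
    )

    # plant binding sites (distinct transcripts; transcript 1 is reserved for
    # the mimic)
    n_sites <- min(config$n_target_sites, config$n_transcripts - 1L)
    site_tx <- sample(names(transcripts)[-1L], n_sites)
    site_mirna <- sample(reference$id, n_sites)
    sites <- vector("list", n_sites)
    for (k in seq_len(n_sites)) {
      mir <- reference$mature[reference$id == site_mirna[k]]
      M <- nchar(mir)
      site_seq <- revcomp(mir)
      n_mm <- sample(rep(config$site_mismatches, 2L), 1L)
      if (n_mm > 0L) {
        site_seq <- mutate_bases(site_seq, sample(M, n_mm))
      }
      tx <- transcripts[[site_tx[k]]]
      start <- sample(seq(50L, nchar(tx) - M - 50L), 1L)
      substr(tx, start, start + M - 1L) <- site_seq
      transcripts[[site_tx[k]]] <- tx
      sites[[k]] <- data.frame(
        mirna_id = site_mirna[k], transcript_id = site_tx[k],
        site_start = start, site_end = start + M - 1L,
        mismatches = n_mm,
        cleavage_pos = start + M - 10L,  # base paired to miRNA position 10
        stringsAsFactors = FALSE
      )
    }
    target_sites <- if (n_sites > 0L) do.call(rbind, sites) else NULL

    # plant one mimic on transcript 1: rc(mature) with a 3-nt insertion
    # between the partners of miRNA positions 11 and 10
    mimic_mirna <- reference$id[1L]
    mir <- reference$mature[1L]
    M <- nchar(mir)
    rc <- revcomp(mir)
    mch <- seq_chars(mir)
    ins <- vapply(c(10L, 11L, 10L), function(i) {
      sample(setdiff(c("A", "C", "G", "T"), complement_base[[mch[i]]]), 1L)
    }, character(1))
    region <- paste0(substr(rc, 1L, M - 10L), paste(ins, collapse = ""),
                     substr(rc, M - 9L, M))
    tx <- transcripts[[1L]]
    start <- sample(seq(100L, nchar(tx) - nchar(region) - 100L), 1L)
    substr(tx, start, start + nchar(region) - 1L) <- region
    transcripts[[1L]] <- tx
    mimic <- data.frame(
      transcript_id = names(transcripts)[1L],
      region_start = start, region_end = start + nchar(region) - 1L,
      mirna_id = mimic_mirna, insert_len = 3L,
      stringsAsFactors = FALSE
    )

    list(reference = reference, transcripts = transcripts,
         truth = list(target_sites = target_sites, mimic = mimic))
  })
}

isomir_variant <- function(mature, hairpin, max_len = 30L) {
  # returns list(seq, class) for one randomly drawn isomiR of `mature`
  M <- nchar(mature)
  start <- as.integer(regexpr(mature, hairpin, fixed = TRUE))
  type <- sample(c("5p_trim", "5p_ext", "3p_trim", "3p_ext_t", "3p_ext_u",
                   "internal", "both"), 1L)
  seq <- mature
  cls <- "canonical"
  if (type == "5p_trim") {
    k <- sample(1:2, 1L)
    seq <- substr(mature, 1L + k, M)
    cls <- "5p_variant"
  } else if (type == "5p_ext") {
    k <- sample(1:2, 1L)
    seq <- substr(hairpin, start - k, start + M - 1L)
    cls <- "5p_variant"
  } else if (type == "3p_trim") {
    k <- sample(1:3, 1L)
    seq <- substr(mature, 1L, M - k)
    cls <- "3p_variant"
  } else if (type == "3p_ext_t") {
    k <- sample(1:3, 1L)
    seq <- substr(hairpin, start, start + M - 1L + k)
    cls <- "3p_variant"
  } else if (type == "3p_ext_u") {
    templ <- substr(hairpin, start + M, start + M)
    base <- sample(setdiff(c("A", "C", "G", "T"), templ), 1L)
    seq <- paste0(mature, base)
    cls <- "3p_variant"
  } else if (type == "internal") {
    k <- sample(1:2, 1L)
    seq <- mutate_bases(mature, sample(seq(2L, M - 1L), k))
    cls <- "internal_variant"
  } else { # both ends
    seq <- substr(hairpin, start + 1L, start + M)
    cls <- "both_variant"
  }
  if (nchar(seq) < 18L || nchar(seq) > max_len) {
    return(list(seq = mature, class = "canonical"))
  }
  list(seq = seq, class = cls)
}

#' Simulate one small-RNA sequencing library
#'
#' Draws reads from the reference miRNAs in proportion to `abundance`; a
#' configured fraction of reads are isomiRs (5'/3' trimming or extension --
#' templated from the hairpin or untemplated -- and internal substitutions).
#' Raw reads carry the 3' adapter and Phred+33 qualities >= Q30, except for a
#' planted fraction with a Q24 base inside the leading 25-nt quality window and
#' a planted fraction of sub-18-nt inserts, so the read-cleaning rules can be
#' verified exactly against truth labels.
#'
#' @param bundle Output of [make_reference()].
#' @param abundance Named relative-abundance vector over reference ids
#'   (defaults to a log-uniform draw).
#' @param isomir_rate Per-read isomiR probability.
#' @param seed Integer seed.
#' @param depth Number of reads.
#' @param low_quality_fraction Fraction of reads planted with a Q24 base.
#' @param short_fraction Fraction of reads with an insert shorter than 18 nt.
#' @param adapter 3' adapter appended to each insert.
#' @param read_length Raw read length (insert + adapter, truncated).
#' @return List with `reads` (data frame `id`, `sequence`, `quality`) and
#'   `truth` (one row per read: `read_id`, `mirna_id`, `class`, `insert`,
#'   `planted_low_quality`, `planted_short`).
#' @export
simulate_srna_library <- function(bundle, abundance = NULL, isomir_rate = 0.2,
                                  seed = 1L, depth = 1e5,
                                  low_quality_fraction = 0.01,
                                  short_fraction = 0.005,
                                  adapter = "CTGGAGTTCAGACGTGTGCTCTTCCGATCT",
                                  read_length = 36L) {
  ref <- bundle$reference
  if (nrow(ref) == 0L) stop("empty reference")
  stopifnot(isomir_rate >= 0, isomir_rate <= 1, depth >= 1)
  with_stream(seed, "srna_library", {
    if (is.null(abundance)) {
      abundance <- setNames(10^runif(nrow(ref), -5, -2.5), ref$id)
    }
    stopifnot(all(abundance >= 0), all(names(abundance) %in% ref$id))
    p <- abundance / sum(abundance)
    idx <- sample(match(names(abundance), ref$id), depth, replace = TRUE,
                  prob = p)
    insert <- ref$mature[idx]
    cls <- rep("canonical", depth)
    is_iso <- runif(depth) < isomir_rate
    for (i in which(is_iso)) {
      v <- isomir_variant(ref$mature[idx[i]], ref$hairpin[idx[i]])
      insert[i] <- v$seq
      cls[i] <- v$class
    }
    # a variant whose insert creates an adapter-prefix match before the true
    # insert/adapter boundary would be trimmed short of its label; such reads
    # are ambiguous by construction, so emit the canonical sequence instead
    prefix <- substr(adapter, 1L, 8L)
    bad <- which(regexpr(prefix, paste0(insert, adapter),
                         fixed = TRUE) != nchar(insert) + 1L)
    if (length(bad)) {
      insert[bad] <- ref$mature[idx[bad]]
      cls[bad] <- "canonical"
    }
    planted_short <- runif(depth) < short_fraction
    for (i in which(planted_short)) {
      insert[i] <- substr(insert[i], 1L, sample(12:17, 1L))
      cls[i] <- "planted_short"
    }
    raw <- substr(paste0(insert, adapter), 1L, read_length)
    len <- nchar(raw)
    qual <- vapply(len, function(l) {
      intToUtf8(sample(30:40, l, replace = TRUE) + 33L)
    }, character(1))
    planted_lq <- runif(depth) < low_quality_fraction
    for (i in which(planted_lq)) {
      pos <- sample(seq_len(min(25L, len[i])), 1L)
      substr(qual[i], pos, pos) <- intToUtf8(24L + 33L)
    }
    ids <- sprintf("read%07d", seq_len(depth))
    list(
      reads = data.frame(id = ids, sequence = raw, quality = qual,
                         stringsAsFactors = FALSE),
      truth = data.frame(
        read_id = ids, mirna_id = ref$id[idx], class = cls, insert = insert,
        planted_low_quality = planted_lq, planted_short = planted_short,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate a degradome (PARE) library
#'
#' For every planted binding site, emits 20-nt tags whose 5' ends fall on the
#' canonical cleavage base (the transcript base paired to miRNA position 10)
#' with probability `peak_fraction`, and uniformly on the transcript otherwise.
#' An additional `noise_rate` fraction of tags is scattered uniformly over all
#' transcripts. Returned both as a pre-mapped tag table and as raw reads
#' (transcript suffix from the tag 5' end, so the first 20 nt are the tag).
#'
#' @param bundle Output of [make_reference()].
#' @param peak_fraction Probability a site tag sits exactly on the cleavage base.
#' @param noise_rate Fraction of extra background tags.
#' @param tags_per_site Tags drawn per planted site.
#' @param seed Integer seed.
#' @param read_length Raw read length (>= 20).
#' @return List with `tags` (data frame `transcript_id`, `position`, `count`),
#'   `reads` (raw reads) and `truth` (the planted site table).
#' @export
simulate_degradome <- function(bundle, peak_fraction = 0.8, noise_rate = 0.01,
                               tags_per_site = 50L, seed = 1L,
                               read_length = 40L) {
  stopifnot(peak_fraction >= 0, peak_fraction <= 1, noise_rate >= 0)
  sites <- bundle$truth$target_sites
  txs <- bundle$transcripts
  with_stream(seed, "degradome", {
    pos_tab <- list()
    add <- function(tx, pos) {
      pos_tab[[length(pos_tab) + 1L]] <<- data.frame(
        transcript_id = tx, position = pos, stringsAsFactors = FALSE)
    }
    n_site_tags <- 0L
    if (!is.null(sites)) {
      for (k in seq_len(nrow(sites))) {
        L <- nchar(txs[[sites$transcript_id[k]]])
        at_peak <- runif(tags_per_site) < peak_fraction
        pos <- ifelse(at_peak, sites$cleavage_pos[k],
                      sample(seq_len(L - 19L), tags_per_site, replace = TRUE))
        add(sites$transcript_id[k], pos)
        n_site_tags <- n_site_tags + tags_per_site
      }
    }
    n_noise <- round(noise_rate * max(n_site_tags, 100L))
    if (n_noise > 0L) {
      tx_noise <- sample(names(txs), n_noise, replace = TRUE)
      pos_noise <- vapply(tx_noise, function(t) {
        sample(seq_len(nchar(txs[[t]]) - 19L), 1L)
      }, integer(1))
      add(tx_noise, pos_noise)
    }
    all_pos <- do.call(rbind, pos_tab)
    agg <- stats::aggregate(list(count = rep(1L, nrow(all_pos))),
                            all_pos[c("transcript_id", "position")], sum)
    agg <- agg[order(agg$transcript_id, agg$position), , drop = FALSE]
    rownames(agg) <- NULL
    seqs <- vapply(seq_len(nrow(all_pos)), function(i) {
      tx <- txs[[all_pos$transcript_id[i]]]
      substr(tx, all_pos$position[i],
             min(nchar(tx), all_pos$position[i] + read_length - 1L))
    }, character(1))
    ids <- sprintf("dtag%06d", seq_len(nrow(all_pos)))
    reads <- data.frame(
      id = ids, sequence = seqs,
      quality = vapply(nchar(seqs), function(l) {
        intToUtf8(rep(35L + 33L, l))
      }, character(1)),
      stringsAsFactors = FALSE
    )
    list(tags = agg, reads = reads, truth = sites)
  })
}

#' Simulate a miRNA count matrix across treatment groups
#'
#' Counts are drawn from a negative-binomial model: mean = library depth x
#' relative abundance x group effect, with dispersion `config$dispersion`
#' (Poisson when 0). A `de_fraction` subset of miRNAs receives multiplicative
#' effects in the water-deficit groups, with contrast patterns mirroring the
#' study (most severe-only, some in both contrasts, few mild-only). Two
#' moderately abundant non-differential miRNAs are flagged as reference
#' candidates for qPCR normalization.
#'
#' @param config A [sim_config()].
#' @param ids Feature ids (defaults to synthetic family/member ids).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param spike_min_abundance Minimum relative abundance of features eligible
#'   for a planted effect (default `10^-4.5`); differential miRNAs are planted
#'   at quantifiable abundance, mirroring that detected water-deficit
#'   responders were quantifiable in all libraries.
#' @return List with `counts` (features x libraries integer matrix), `groups`
#'   (factor, one per library) and `truth` (per-feature data frame).
#' @export
simulate_counts <- function(config, ids = NULL, seed = config$seed,
                            spike_min_abundance = 10^-4.5) {
  if (is.null(ids)) {
    ids <- as.vector(outer(
      paste0("sim-miR", seq_len(config$n_families)),
      letters[seq_len(config$members_per_family)], paste0))
  }
  G <- length(ids)
  nlib <- config$n_libraries_per_group
  groups <- factor(rep(config$groups, each = nlib), levels = config$groups)
  libs <- paste0(rep(config$groups, each = nlib), "_R", seq_len(nlib))
  with_stream(seed, "counts", {
    base <- 10^runif(G, -6, -2.5)
    eligible <- base >= spike_min_abundance
    is_de <- runif(G) < config$de_fraction & eligible
    pattern <- rep("none", G)
    pattern[is_de] <- sample(c("severe_only", "both", "mild_only"),
                             sum(is_de), replace = TRUE,
                             prob = c(0.6, 0.3, 0.1))
    fold <- rep(1, G)
    fold[is_de] <- sample(config$fold_changes, sum(is_de), replace = TRUE)
    fold_mild <- ifelse(pattern %in% c("both", "mild_only"),
                        ifelse(pattern == "both", 2^(0.6 * log2(fold)), fold), 1)
    fold_severe <- ifelse(pattern %in% c("both", "severe_only"), fold, 1)
    # two stable, moderately abundant reference candidates
    ord <- order(abs(log10(base) + 4))
    ref_idx <- ord[!is_de[ord]][1:2]
    is_ref <- seq_len(G) %in% ref_idx
    fold_mild[is_ref] <- 1; fold_severe[is_ref] <- 1
    pattern[is_ref] <- "none"; is_de[is_ref] <- FALSE

    depth <- round(config$library_depth * exp(rnorm(length(libs), 0, 0.15)))
    eff <- cbind(WW = rep(1, G), mild = fold_mild, severe = fold_severe)
    colnames(eff) <- config$groups[1:3]
    counts <- matrix(0L, G, length(libs), dimnames = list(ids, libs))
    for (j in seq_along(libs)) {
      mu <- depth[j] * base * eff[, as.character(groups[j])]
      counts[, j] <- if (config$dispersion == 0) {
        rpois(G, mu)
      } else {
        rnbinom(G, mu = mu, size = 1 / config$dispersion)
      }
    }
    truth <- data.frame(
      id = ids, base_abundance = base, de = is_de, pattern = pattern,
      fold_mild = fold_mild, fold_severe = fold_severe,
      is_reference = is_ref, stringsAsFactors = FALSE
    )
    list(counts = counts, groups = groups, truth = truth,
         lib_depth = setNames(depth, libs))
  })
}

#' Simulate a stem-loop RT-qPCR Ct table
#'
#' Ct values follow `intercept - log2(abundance x group effect)` plus Gaussian
#' biological and technical noise, in the study layout: biological replicates
#' per treatment, technical triplicates.
#'
#' @param truth Per-feature truth from [simulate_counts()].
#' @param seed Integer seed.
#' @param targets Ids to assay (default: all differential plus reference
#'   candidates).
#' @param groups Treatment labels.
#' @param n_bio,n_tech Biological / technical replicates.
#' @param sd_bio,sd_tech Gaussian noise SDs (cycles).
#' @param intercept Ct of a transcript at relative abundance 1.
#' @return Data frame `target_id`, `treatment`, `bio_rep`, `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(truth, seed = 1L, targets = NULL,
                          groups = c("WW", "mild", "severe"),
                          n_bio = 4L, n_tech = 3L,
                          sd_bio = 0.15, sd_tech = 0.1, intercept = 12) {
  if (is.null(targets)) {
    targets <- truth$id[truth$de | truth$is_reference]
  }
  tt <- truth[match(targets, truth$id), , drop = FALSE]
  with_stream(seed, "qpcr", {
    rows <- list()
    for (k in seq_len(nrow(tt))) {
      eff <- c(WW = 1, mild = tt$fold_mild[k], severe = tt$fold_severe[k])
      for (g in groups) {
        mu <- intercept - log2(tt$base_abundance[k] * eff[[g]])
        for (b in seq_len(n_bio)) {
          ct_b <- mu + rnorm(1, 0, sd_bio)
          for (r in seq_len(n_tech)) {
            rows[[length(rows) + 1L]] <- data.frame(
              target_id = tt$id[k], treatment = g, bio_rep = b, tech_rep = r,
              ct = ct_b + rnorm(1, 0, sd_tech), stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the reference FASTA (mature and hairpin), transcript FASTA, one
#' small-RNA FASTQ per library, the degradome FASTQ and pre-mapped tag TSV,
#' the count and truth TSVs, and the qPCR Ct table, so the whole pipeline can
#' be run from files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param srna_depth Reads per simulated small-RNA FASTQ library.
#' @return Invisibly, the in-memory bundle of everything written.
#' @export
simulate_dataset <- function(config, outdir, srna_depth = 2e4) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- make_reference(config)
  write_fasta(setNames(bundle$reference$mature, bundle$reference$id),
              file.path(outdir, "mature.fa"))
  write_fasta(setNames(bundle$reference$hairpin, bundle$reference$id),
              file.path(outdir, "hairpin.fa"))
  write_fasta(bundle$transcripts, file.path(outdir, "transcripts.fa"))
  write_tsv(bundle$reference, file.path(outdir, "reference.tsv"))

  lib <- simulate_srna_library(bundle, seed = config$seed,
                               isomir_rate = config$isomir_rate,
                               depth = srna_depth, adapter = config$adapter)
  write_fastq(lib$reads, file.path(outdir, "srna_WW_R1.fastq"))
  write_tsv(lib$truth, file.path(outdir, "srna_WW_R1.truth.tsv"))

  deg <- simulate_degradome(bundle, seed = config$seed)
  write_fastq(deg$reads, file.path(outdir, "degradome.fastq"))
  write_tsv(deg$tags, file.path(outdir, "degradome_tags.tsv"))
  if (!is.null(bundle$truth$target_sites)) {
    write_tsv(bundle$truth$target_sites, file.path(outdir, "target_sites.tsv"))
  }
  write_tsv(bundle$truth$mimic, file.path(outdir, "mimic_locus.tsv"))

  cm <- simulate_counts(config, ids = bundle$reference$id)
  counts_df <- data.frame(id = rownames(cm$counts), cm$counts,
                          check.names = FALSE)
  write_tsv(counts_df, file.path(outdir, "counts.tsv"))
  write_tsv(data.frame(library_id = colnames(cm$counts),
                       group = as.character(cm$groups)),
            file.path(outdir, "libraries.tsv"))
  write_tsv(cm$truth, file.path(outdir, "counts_truth.tsv"))

  qp <- simulate_qpcr(cm$truth, seed = config$seed)
  write_tsv(qp, file.path(outdir, "qpcr_ct.tsv"))

  invisible(list(bundle = bundle, srna = lib, degradome = deg, counts = cm,
                 qpcr = qp))
}
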