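# Assignment of unique tags to canonical miRNAs or isomiR classes, RPTM
# normalization and the retention filter.

#' Precompute the lookup structures used by the isomiR classifier
#'
#' Builds merged-ID groups and per-group character decompositions of the
#' mature and hairpin sequences once, so that classifying many tags does not
#' repeat the work.
#'
#' @param reference Reference data frame (`id`, `mature`, `hairpin`).
#' @return An opaque list consumed by [classify_isomir()] / [match_tags()].
#' @export
build_reference_index <- function(reference) {
  merged <- merged_reference(reference)
  members <- strsplit(merged$members, ",", fixed = TRUE)
  first <- vapply(members, `[`, character(1), 1L)
  hairpin <- reference$hairpin[match(first, reference$id)]
  hstart <- mapply(function(m, h) as.integer(regexpr(m, h, fixed = TRUE)),
                   merged$mature, hairpin)
  list(
    merged = merged,
    members = members,
    mlen = nchar(merged$mature),
    hstart = as.integer(hstart),
    h_ch = lapply(hairpin, seq_chars),
    m_ch = lapply(merged$mature, seq_chars)
  )
}

# Collapse reference entries with identical mature sequences to merged-ID
# groups, e.g. "miR399e,i,j-3p" style ids for family members that share a
# mature sequence.
merged_reference <- function(reference) {
  key <- norm_seq(reference$mature)
  groups <- split(seq_len(nrow(reference)), key)
  rows <- lapply(groups, function(ix) {
    data.frame(
      group_id = paste(reference$id[ix], collapse = ","),
      mature = key[ix[1L]],
      members = paste(reference$id[ix], collapse = ","),
      n_members = length(ix),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  first_ix <- vapply(groups, min, integer(1))
  out <- out[order(first_ix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign unique tags to canonical miRNAs
#'
#' Exact-sequence matching against the mature reference. Family members with
#' identical mature sequences are merged into a single ID group and counted
#' once. Non-matching tags are forwarded to [classify_isomir()] when
#' `classify = TRUE`, otherwise left unassigned.
#'
#' @param tags Data frame with columns `sequence`, `count`.
#' @param reference Reference data frame (`id`, `mature`, `hairpin`, ...).
#' @param classify Run isomiR classification on non-exact tags (default TRUE).
#' @param ... Passed to [classify_isomir()].
#' @return Data frame: one row per tag with `sequence`, `count`, `assigned_id`
#'   (merged ID group or `NA`), `class` and the isomiR fields.
#' @export
match_tags <- function(tags, reference, classify = TRUE, ...) {
  stopifnot(!anyDuplicated(reference$id))
  merged <- merged_reference(reference)
  seqs <- norm_seq(tags$sequence)
  hit <- match(seqs, merged$mature)
  out <- data.frame(
    sequence = seqs,
    count = tags$count,
    assigned_id = ifelse(is.na(hit), NA_character_, merged$group_id[hit]),
    class = ifelse(is.na(hit), NA_character_, "canonical"),
    offset5 = ifelse(is.na(hit), NA_integer_, 0L),
    offset3 = ifelse(is.na(hit), NA_integer_, 0L),
    templated3 = ifelse(is.na(hit), NA, TRUE),
    n_substitutions = ifelse(is.na(hit), NA_integer_, 0L),
    stringsAsFactors = FALSE
  )
  if (classify) {
    index <- build_reference_index(reference)
    todo <- which(is.na(hit))
    for (i in todo) {
      call <- classify_isomir(seqs[i], reference, index = index, ...)
      out$assigned_id[i] <- call$canonical_id
      out$class[i] <- call$class
      out$offset5[i] <- call$offset5
      out$offset3[i] <- call$offset3
      out$templated3[i] <- call$templated3
      out$n_substitutions[i] <- call$n_substitutions
    }
  }
  out
}

#' Classify a tag as an isomiR of its best-matching canonical miRNA
#'
#' Finds the smallest-edit interpretation of the tag against each canonical
#' mature sequence, allowing 5'/3' end offsets (truncation or extension) and
#' internal substitutions. Edit cost is ordered: end offsets are cheapest,
#' untemplated end bases next, internal substitutions most expensive
#' (compared lexicographically in reverse: substitutions, then untemplated
#' bases, then total offset). 3' extensions are checked against the hairpin;
#' `templated3` is `TRUE` when every extension base is the next consecutive
#' hairpin base. Tags with no interpretation within the edit bounds are
#' `variant_novel`.
#'
#' Offsets follow the convention `offset5 = +k` for a 5' truncation by k bases
#' (negative for extension) and `offset3 = +k` for a 3' extension (negative
#' for truncation). When both end offsets and internal substitutions occur the
#' class is the end-based one, with substitutions reported in the fields.
#'
#' @param tag Tag sequence (>= 18 nt).
#' @param reference Reference data frame.
#' @param max_offset5,max_offset3 Edit bounds on end offsets (defaults 2, 3).
#' @param max_substitutions Internal substitution bound (default 2).
#' @param abundance Optional named canonical abundances used to break cost ties
#'   (highest wins); default ties break on reference order.
#' @param index Prebuilt reference index from [build_reference_index()]
#'   (built on the fly when `NULL`; pass it when classifying many tags).
#' @return A one-row data frame: `tag_seq`, `canonical_id` (merged ID group),
#'   `class` in `{canonical, 5p_variant, 3p_variant, both_variant,
#'   internal_variant, variant_novel}`, `offset5`, `offset3`, `templated3`,
#'   `n_substitutions`.
#' @export
classify_isomir <- function(tag, reference, max_offset5 = 2L, max_offset3 = 3L,
                            max_substitutions = 2L, abundance = NULL,
                            index = NULL) {
  if (nrow(reference) == 0L) stop("no reference loaded")
  if (is.null(index)) index <- build_reference_index(reference)
  tag <- norm_seq(tag)
  stopifnot(nchar(tag) >= 18L)
  L <- nchar(tag)
  tag_ch <- seq_chars(tag)
  merged <- index$merged
  best <- NULL
  best_cost <- c(Inf, Inf, Inf)   # (substitutions, untemplated, |offsets|)
  best_ab <- -Inf
  for (g in seq_len(nrow(merged))) {
    M <- index$mlen[g]
    if (abs(L - M) > max_offset5 + max_offset3) next
    hstart <- index$hstart[g]
    h_ch <- index$h_ch[[g]]
    m_ch <- index$m_ch[[g]]
    for (o5 in seq(-max_offset5, max_offset5)) {
      o3 <- L - M + o5
      if (abs(o3) > max_offset3) next
      # tag position t corresponds to mature position o5 + t
      mpos <- o5 + seq_len(L)
      core <- which(mpos >= 1L & mpos <= M)
      nsub <- sum(tag_ch[core] != m_ch[mpos[core]])
      if (nsub > max_substitutions) next
      nuntemp <- 0L
      templated3 <- TRUE
      ext5 <- which(mpos < 1L)
      if (length(ext5)) {
        hp <- hstart + mpos[ext5] - 1L
        ok <- hp >= 1L
        nuntemp <- nuntemp + sum(!ok) +
          sum(tag_ch[ext5[ok]] != h_ch[hp[ok]])
      }
      ext3 <- which(mpos > M)
      if (length(ext3)) {
        hp <- hstart + mpos[ext3] - 1L
        ok <- hp <= length(h_ch)
        mismatch3 <- sum(!ok) + sum(tag_ch[ext3[ok]] != h_ch[hp[ok]])
        nuntemp <- nuntemp + mismatch3
        templated3 <- mismatch3 == 0L
      }
      cost <- c(nsub, nuntemp, abs(o5) + abs(o3))
      ab <- if (!is.null(abundance)) {
        max(abundance[intersect(names(abundance), index$members[[g]])], -Inf)
      } else -g
      better <- isTRUE(cost[1] < best_cost[1] ||
        (cost[1] == best_cost[1] && (cost[2] < best_cost[2] ||
          (cost[2] == best_cost[2] && (cost[3] < best_cost[3] ||
            (cost[3] == best_cost[3] && ab > best_ab))))))
      if (better) {
        best_cost <- cost
        best_ab <- ab
        best <- list(id = merged$group_id[g], o5 = o5, o3 = o3,
                     nsub = nsub, templated3 = templated3)
      }
    }
  }
  if (is.null(best)) {
    return(data.frame(tag_seq = tag, canonical_id = NA_character_,
                      class = "variant_novel", offset5 = NA_integer_,
                      offset3 = NA_integer_, templated3 = NA,
                      n_substitutions = NA_integer_, stringsAsFactors = FALSE))
  }
  cls <- if (best$o5 == 0L && best$o3 == 0L && best$nsub == 0L) {
    "canonical"
  } else if (best$o5 != 0L && best$o3 != 0L) {
    "both_variant"
  } else if (best$o5 != 0L) {
    "5p_variant"
  } else if (best$o3 != 0L) {
    "3p_variant"
  } else {
    "internal_variant"
  }
  data.frame(tag_seq = tag, canonical_id = best$id, class = cls,
             offset5 = best$o5, offset3 = best$o3,
             templated3 = best$templated3, n_substitutions = best$nsub,
             stringsAsFactors = FALSE)
}

#' Aggregate assigned tag counts to a canonical miRNA count matrix
#'
#' Sums the counts of tags assigned as canonical to each merged miRNA ID per
#' library. IsomiR counts are reported separately and never added to canonical
#' counts.
#'
#' @param assignments_by_library Named list of [match_tags()] outputs (one per
#'   library).
#' @param canonical_only Count only class `"canonical"` tags (default TRUE).
#' @return Integer matrix (merged miRNA ids x libraries).
#' @export
mirna_counts <- function(assignments_by_library, canonical_only = TRUE) {
  ids <- sort(unique(unlist(lapply(assignments_by_library, function(a) {
    a$assigned_id[!is.na(a$assigned_id)]
  }))))
  mat <- matrix(0L, length(ids), length(assignments_by_library),
                dimnames = list(ids, names(assignments_by_library)))
  for (j in seq_along(assignments_by_library)) {
    a <- assignments_by_library[[j]]
    if (canonical_only) a <- a[!is.na(a$class) & a$class == "canonical", ]
    a <- a[!is.na(a$assigned_id), ]
    if (nrow(a)) {
      s <- tapply(a$count, a$assigned_id, sum)
      mat[names(s), j] <- as.integer(s)
    }
  }
  mat
}

#' Normalize counts to reads per ten million (RPTM)
#'
#' @param counts Count matrix (features x libraries) or vector.
#' @param totals Per-library mapped-tag totals (> 0).
#' @return Matrix of `1e7 * count / total`.
#' @export
rptm_normalize <- function(counts, totals) {
  counts <- as.matrix(counts)
  stopifnot(length(totals) == ncol(counts))
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(counts, 2L, totals, "/") * 1e7
}

#' Retention filter on RPTM values
#'
#' A miRNA is retained if, in at least one treatment group, at least
#' `min_libs` libraries have RPTM >= `min_rptm` (the published rule: >= 1 RPTM
#' in at least 3 of the 4 libraries of a treatment group).
#'
#' @param rptm RPTM matrix (features x libraries).
#' @param groups Group label per library.
#' @param min_rptm Abundance threshold (default 1).
#' @param min_libs Library threshold within a group (default 3).
#' @return Character vector of retained feature ids.
#' @export
retention_filter <- function(rptm, groups, min_rptm = 1, min_libs = 3L) {
  groups <- as.factor(groups)
  stopifnot(ncol(rptm) == length(groups))
  if (!any(table(groups) >= min_libs)) {
    stop("no group has at least min_libs libraries")
  }
  keep <- vapply(seq_len(nrow(rptm)), function(i) {
    ok <- tapply(rptm[i, ] >= min_rptm, groups, sum)
    any(ok >= min_libs)
  }, logical(1))
  rownames(rptm)[keep]
}
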