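# Star scoring of curated V_L/V_H sequences and the cohort census.
#
# Each retained sequence earns up to 2 stars from read support (its ASV
# fraction within the well) and up to 3 stars from replicate consistency:
#
#   ASV Score   = ReadPerSequence / ReadsPerPrimerWell
#   MatchScore  = (BR + 0.75*TR) - (1 - (BR + TR) / TotalSeqs)
#   TotalScore  = clamp(3*ln(MatchScore), 0, 3) + 2*ASV Score
#
# where BR counts other biological-replicate samples (same parent, different
# subclone) carrying the identical trimmed sequence, TR counts other
# technical-replicate samples (same subclone), and TotalSeqs is the number
# of sequenced replicate samples in the parent group for that chain.
# 3*ln(MatchScore) is unbounded above and undefined at MatchScore <= 0, so
# the match component is clamped to [0, 3] (MatchScore <= 1 contributes 0),
# which reproduces the published 0-5 star range.

#' Parse a structured mAb identifier
#'
#' The identifier convention is `ProjectID/ParentID.SubcloneID`; the subclone
#' part is optional (parent-level samples).
#'
#' @param text identifier string, e.g. `"K89/34.1"`.
#' @return list of class `mab_id` with `project`, `parent`, `subclone`
#'   (`NA` when absent) and the original `text`.
#' @export
parse_mab_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("/", text, fixed = TRUE)) {
    stop("malformed mAb ID (no '/'): ", text)
  }
  parts <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
    stop("malformed mAb ID: ", text)
  }
  pp <- strsplit(parts[2], ".", fixed = TRUE)[[1]]
  structure(list(project = parts[1], parent = pp[1],
                 subclone = if (length(pp) > 1L) pp[2] else NA_character_,
                 text = text),
            class = "mab_id")
}

#' @export
format.mab_id <- function(x, ...) {
  paste0(x$project, "/", x$parent,
         if (!is.na(x$subclone)) paste0(".", x$subclone))
}

#' @export
print.mab_id <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# parent-level key of an identifier string
.parent_key <- function(text) {
  vapply(text, function(t) {
    id <- parse_mab_id(t)
    paste0(id$project, "/", id$parent)
  }, character(1), USE.NAMES = FALSE)
}

#' ASV score: read support of a sequence within its well
#'
#' @param read_per_sequence reads attributed to the sequence.
#' @param reads_per_primer_well total retained reads for that well and chain
#'   primer.
#' @return fraction in `[0, 1]`; 0 with a warning if the denominator is 0.
#' @export
asv_score <- function(read_per_sequence, reads_per_primer_well) {
  if (reads_per_primer_well == 0) {
    warning("zero reads for well/primer; ASV score undefined, returning 0")
    return(0)
  }
  stopifnot(read_per_sequence >= 0,
            reads_per_primer_well >= read_per_sequence)
  read_per_sequence / reads_per_primer_well
}

#' Replicate-consistency match score
#'
#' `MatchScore = (BR + 0.75*TR) - (1 - (BR + TR)/TotalSeqs)`. May be zero or
#' negative (a sequence seen in no other replicate is penalized).
#'
#' @param br biological-replicate matches.
#' @param tr technical-replicate matches.
#' @param total_seqs sequenced replicate samples in the parent group.
#' @return numeric match score.
#' @export
match_score <- function(br, tr, total_seqs) {
  if (total_seqs < 1) stop("total_seqs must be >= 1")
  stopifnot(br >= 0, tr >= 0)
  (br + 0.75 * tr) - (1 - (br + tr) / total_seqs)
}

#' Total star score
#'
#' `clamp(3*ln(match_score), 0, 3) + 2*asv_score`, in `[0, 5]`. Match scores
#' at or below 1 (including non-positive values, where the logarithm is
#' undefined) contribute 0 to the match component.
#'
#' @param match_score value from [match_score()].
#' @param asv_score fraction from [asv_score()].
#' @return stars in `[0, 5]`.
#' @export
total_score <- function(match_score, asv_score) {
  comp <- if (match_score <= 1) 0 else min(3, 3 * log(match_score))
  comp + 2 * asv_score
}

#' Count replicate evidence for one entry
#'
#' A *sample* is one sequenced well (a plate/well holding one vial). BR
#' counts other samples with the same project/parent but a different
#' subclone that contain the identical trimmed sequence for the same chain;
#' TR counts other samples of the same subclone containing it. TotalSeqs is
#' the number of samples of the parent group that yielded any sequence of
#' that chain (including the focal sample).
#'
#' @param entry one-row data frame (`mab_id`, `sample`, `chain`,
#'   `trimmed_nt`).
#' @param cohort data frame of all entries, same columns.
#' @param total_seqs_mode `"samples"` (default: replicate samples in the
#'   parent group) or `"sequences"` (distinct sequences returned for the
#'   group).
#' @return list with `br`, `tr`, `total_seqs`.
#' @export
count_replicates <- function(entry, cohort,
                             total_seqs_mode = c("samples", "sequences")) {
  total_seqs_mode <- match.arg(total_seqs_mode)
  id <- parse_mab_id(entry$mab_id)
  pk <- paste0(id$project, "/", id$parent)
  grp <- cohort[.parent_key(cohort$mab_id) == pk &
                  cohort$chain == entry$chain, , drop = FALSE]
  other <- grp[grp$sample != entry$sample, , drop = FALSE]
  carriers <- other[other$trimmed_nt == entry$trimmed_nt, , drop = FALSE]
  sub_of <- function(ids) vapply(ids, function(t) {
    s <- parse_mab_id(t)$subclone
    if (is.na(s)) "" else s
  }, character(1), USE.NAMES = FALSE)
  focal_sub <- if (is.na(id$subclone)) "" else id$subclone
  carrier_subs <- sub_of(carriers$mab_id)
  br <- length(unique(carriers$sample[carrier_subs != focal_sub]))
  tr <- length(unique(carriers$sample[carrier_subs == focal_sub]))
  total <- if (total_seqs_mode == "samples") {
    length(unique(grp$sample))
  } else {
    length(unique(grp$trimmed_nt))
  }
  list(br = br, tr = tr, total_seqs = max(1L, total))
}

#' Score every entry of an annotated cohort
#'
#' @param entries data frame with one row per (sample, chain, distinct
#'   trimmed sequence): columns `mab_id`, `plate`, `well`, `chain`,
#'   `trimmed_nt`, `count`, `fraction`.
#' @param config assay configuration (`total_seqs_mode`).
#' @return the input with `sample`, `br`, `tr`, `total_seqs`, `asv_score`,
#'   `match_score` and `total_score` columns added.
#' @export
score_entries <- function(entries, config = hyb_config()) {
  if (nrow(entries) == 0L) {
    for (cl in c("sample", "br", "tr", "total_seqs", "asv_score",
                 "match_score", "total_score")) entries[[cl]] <- numeric(0)
    return(entries)
  }
  entries$sample <- paste(entries$plate, entries$well, sep = ":")
  wc <- paste(entries$sample, entries$chain, sep = "\r")
  denom <- tapply(entries$count, wc, sum)[wc]
  entries$asv_score <- mapply(asv_score, entries$count, as.vector(denom))
  reps <- lapply(seq_len(nrow(entries)), function(i)
    count_replicates(entries[i, ], entries, config$total_seqs_mode))
  entries$br <- vapply(reps, `[[`, numeric(1), "br")
  entries$tr <- vapply(reps, `[[`, numeric(1), "tr")
  entries$total_seqs <- vapply(reps, `[[`, numeric(1), "total_seqs")
  entries$match_score <- mapply(match_score, entries$br, entries$tr,
                                entries$total_seqs)
  entries$total_score <- mapply(total_score, entries$match_score,
                                entries$asv_score)
  entries
}

#' Filter scored entries on the minimum star score
#'
#' @param entries scored data frame.
#' @param min_score retention threshold (default 3): entries scoring below it
#'   are filtered out.
#' @return the retained rows.
#' @export
quality_filter <- function(entries, min_score = 3) {
  entries[entries$total_score >= min_score, , drop = FALSE]
}

#' Chain multiplicity of a parent hybridoma
#'
#' Per replicate sample, counts the distinct retained trimmed sequences of
#' the chain; returns the mean across samples rounded to the nearest integer
#' (halves away from zero).
#'
#' @param entries retained entries of one parent group and chain (columns
#'   `sample`, `trimmed_nt`).
#' @return integer multiplicity (0 for an empty group).
#' @export
chain_multiplicity <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0L) return(0L)
  per_sample <- tapply(entries$trimmed_nt, entries$sample,
                       function(x) length(unique(x)))
  m <- mean(per_sample)
  as.integer(sign(m) * floor(abs(m) + 0.5))
}

#' Percentage as printed in cohort summaries
#'
#' @param count category count.
#' @param total cohort size.
#' @return `100 * count / total` rounded to one decimal.
#' @export
census_percent <- function(count, total) {
  round(100 * count / total, 1)
}

#' Summarize a cohort of unique mAb IDs
#'
#' Builds the sequencing census: how many unique parent hybridomas lack a
#' V_L or V_H, how many have both, and how many carry additional productive
#' chains (one extra V_L, one extra V_H, or both). Percentages are relative
#' to the full cohort. Optionally stratified by a categorical covariate
#' (e.g. fusion method).
#'
#' @param multiplicities data frame with one row per unique parent mAb ID:
#'   columns `mab_id`, `vl` and `vh` (chain multiplicities), and optionally
#'   the stratification column.
#' @param stratify_by name of the covariate column, or `NULL`.
#' @return data frame with `category`, `count`, `percent` (plus one
#'   count/percent pair per stratum when stratified).
#' @export
summarize_cohort <- function(multiplicities, stratify_by = NULL) {
  tab <- function(df) {
    n <- nrow(df)
    both <- df$vl >= 1 & df$vh >= 1
    cats <- list(
      "VL or VH = 0" = !both,
      "Total (VL >= 1 and VH >= 1)" = both,
      "No additional chain" = both & df$vl == 1 & df$vh == 1,
      "Additional chains of some sort" = both & (df$vl > 1 | df$vh > 1),
      "One additional VL only" = both & df$vl == 2 & df$vh == 1,
      "One additional VH only" = both & df$vl == 1 & df$vh == 2,
      "One additional VL and VH" = both & df$vl == 2 & df$vh == 2
    )
    data.frame(category = names(cats),
               count = vapply(cats, sum, integer(1)),
               percent = vapply(cats, function(x) census_percent(sum(x), n),
                                numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- tab(multiplicities)
  if (!is.null(stratify_by)) {
    for (lev in unique(multiplicities[[stratify_by]])) {
      sub <- tab(multiplicities[multiplicities[[stratify_by]] == lev, ,
                                drop = FALSE])
      out[[paste0(lev, "_count")]] <- sub$count
      out[[paste0(lev, "_percent")]] <- sub$percent
    }
  }
  out
}

#' Chain multiplicities for every parent in a scored cohort
#'
#' Applies the score filter, then computes the light- and heavy-chain
#' multiplicities per unique parent mAb ID.
#'
#' @param scored scored entries ([score_entries()]).
#' @param config assay configuration (`min_score`).
#' @return data frame with `mab_id` (parent-level), `vl`, `vh`.
#' @export
cohort_multiplicities <- function(scored, config = hyb_config()) {
  kept <- quality_filter(scored, config$min_score)
  parents <- unique(.parent_key(scored$mab_id))
  rows <- lapply(parents, function(pk) {
    grp <- kept[.parent_key(kept$mab_id) == pk, , drop = FALSE]
    is_light <- vapply(grp$chain, function(ch) .chain_kind(ch) == "light",
                       logical(1), USE.NAMES = FALSE)
    data.frame(
      mab_id = pk,
      vl = chain_multiplicity(grp[is_light, , drop = FALSE]),
      vh = chain_multiplicity(grp[!is_light, , drop = FALSE]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
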