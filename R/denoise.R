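# Collapse merged reads into amplicon sequence variants (ASVs), absorb
# likely error reads into their parents, remove the aberrant Sp2/0 light
# chain, and apply the >= 10% read-support filter.
#
# The denoiser is a greedy abundance-skew absorber: sequences are visited in
# decreasing abundance and a sequence at Hamming distance d from an accepted
# ASV is absorbed when its abundance ratio does not exceed 2^-(alpha*d + 1).
# The parametric error model of a full ASV caller is intentionally not
# reproduced; what is guaranteed (and tested) is the contract: true
# sequences are recovered, error reads are absorbed into them.

#' Dereplicate merged reads
#'
#' Exact-sequence grouping of reads that share a well and chain.
#'
#' @param reads character vector of merged-read sequences.
#' @return named integer vector (sequence -> count), in decreasing count
#'   order with lexicographic tie-break; counts sum to `length(reads)`.
#' @export
dereplicate <- function(reads) {
  if (length(reads) == 0L) return(integer(0))
  tb <- table(reads)
  cnt <- as.integer(tb)
  names(cnt) <- names(tb)
  cnt[order(-cnt, names(cnt))]
}

#' Denoise dereplicated sequences into ASVs
#'
#' Sequences are processed in decreasing abundance (ties broken
#' lexicographically so read order never matters). A sequence at Hamming
#' distance `d` (1..`max_d`, equal lengths only) from an already-accepted ASV
#' is absorbed into it iff `count / parent_count <= 2^-(alpha*d + 1)`;
#' otherwise it founds a new ASV. Absorbed counts add to the parent, so ASV
#' counts conserve the input read total.
#'
#' @param derep named count vector from [dereplicate()].
#' @param alpha abundance-skew steepness (default 2).
#' @param max_d maximum Hamming distance absorbed (default 4).
#' @return data frame with `sequence` and `count`, decreasing count order.
#' @export
denoise_asvs <- function(derep, alpha = 2, max_d = 4) {
  stopifnot(length(derep) > 0)
  derep <- derep[order(-as.integer(derep), names(derep))]
  seqs <- names(derep)
  asv_seq <- character(0)
  asv_count <- numeric(0)
  for (i in seq_along(derep)) {
    s <- seqs[i]
    cnt <- derep[[i]]
    absorbed <- FALSE
    for (j in seq_along(asv_seq)) {
      if (nchar(asv_seq[j]) != nchar(s)) next
      d <- hamming(asv_seq[j], s)
      if (d < 1L || d > max_d) next
      if (cnt / asv_count[j] <= 2^-(alpha * d + 1)) {
        asv_count[j] <- asv_count[j] + cnt
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      asv_seq <- c(asv_seq, s)
      asv_count <- c(asv_count, cnt)
    }
  }
  ord <- order(-asv_count, asv_seq)
  data.frame(sequence = asv_seq[ord], count = asv_count[ord],
             stringsAsFactors = FALSE)
}

# fixed scoring matrix so alignments skip per-call quality-matrix setup
.nt_submat_cache <- new.env(parent = emptyenv())
.nt_submat <- function() {
  if (is.null(.nt_submat_cache$m)) {
    .nt_submat_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
  }
  .nt_submat_cache$m
}

#' Flag ASVs matching the aberrant Sp2/0 light-chain reference
#'
#' An ASV is flagged (excluded from all downstream analysis) when its global
#' alignment to the aberrant reference reaches `min_identity` over at least
#' `min_coverage` of the shorter sequence. Heavy-chain ASVs are never
#' flagged.
#'
#' @param sequence ASV nucleotide sequence.
#' @param chain chain class of the ASV.
#' @param aberrant_ref aberrant transcript reference sequence (required when
#'   light-chain ASVs are present).
#' @param min_identity,min_coverage matching thresholds.
#' @return `TRUE` when the ASV is aberrant (to be excluded).
#' @export
filter_aberrant <- function(sequence, chain, aberrant_ref,
                            min_identity = 0.97, min_coverage = 0.90) {
  if (.chain_kind(chain) == "heavy") return(FALSE)
  if (is.null(aberrant_ref)) {
    stop("aberrant reference required to screen light-chain ASVs")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sequence), Biostrings::DNAString(aberrant_ref),
    type = "local", substitutionMatrix = .nt_submat(),
    gapOpening = 10, gapExtension = 2)
  shorter <- min(nchar(sequence), nchar(aberrant_ref))
  cov <- Biostrings::nchar(al) / shorter
  ident <- Biostrings::pid(al) / 100
  ident >= min_identity && cov >= min_coverage
}

#' Apply the minimum ASV-fraction filter
#'
#' Fractions are computed per well and chain over the retained (post-
#' aberrant-removal) ASV reads; only ASVs at or above `min_fraction` of that
#' total are kept.
#'
#' @param asvs data frame with `sequence` and `count` for one well+chain.
#' @param min_fraction retention threshold (default 0.10).
#' @return the retained rows with a `fraction` column added.
#' @export
fraction_filter <- function(asvs, min_fraction = 0.10) {
  if (nrow(asvs) == 0L) {
    asvs$fraction <- numeric(0)
    return(asvs)
  }
  asvs$fraction <- asvs$count / sum(asvs$count)
  asvs[asvs$fraction >= min_fraction, , drop = FALSE]
}

#' Denoise all wells of a processed plate
#'
#' Runs dereplication, denoising, aberrant-transcript screening and the
#' fraction filter for every (well, chain) group. Aberrant ASVs are removed
#' before fractions are computed, so light-chain fractions renormalize over
#' productive reads only.
#'
#' @param merged data frame from [process_reads()] (`well`, `chain`,
#'   `sequence`).
#' @param config assay configuration.
#' @return data frame of retained ASVs: `well`, `chain`, `sequence`, `count`,
#'   `fraction`, `aberrant` (all `FALSE` among retained rows; flagged rows
#'   are returned in the `"removed"` attribute for accounting).
#' @export
denoise_wells <- function(merged, config = hyb_config()) {
  groups <- split(merged, paste(merged$well, merged$chain, sep = "\r"))
  out <- list()
  removed <- list()
  for (g in groups) {
    asvs <- denoise_asvs(dereplicate(g$sequence),
                         config$denoise_alpha, config$denoise_max_d)
    ab <- vapply(asvs$sequence, filter_aberrant, logical(1),
                 chain = g$chain[1], aberrant_ref = config$aberrant_ref,
                 min_identity = config$aberrant_min_identity,
                 min_coverage = config$aberrant_min_coverage,
                 USE.NAMES = FALSE)
    dropped <- asvs[ab, , drop = FALSE]
    kept <- fraction_filter(asvs[!ab, , drop = FALSE], config$min_fraction)
    if (nrow(kept)) {
      kept <- cbind(well = g$well[1], chain = g$chain[1], kept,
                    aberrant = FALSE, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- kept
    }
    if (nrow(dropped)) {
      dropped <- cbind(well = g$well[1], chain = g$chain[1], dropped,
                       aberrant = TRUE, stringsAsFactors = FALSE)
      removed[[length(removed) + 1L]] <- dropped
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(well = character(0), chain = character(0),
               sequence = character(0), count = numeric(0),
               fraction = numeric(0), aberrant = logical(0))
  rownames(res) <- NULL
  attr(res, "removed") <- if (length(removed)) do.call(rbind, removed)
  res
}
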