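# IMGT numbering, framework/CDR segmentation and validity filtering of
# translated V domains.
#
# A germline-HMM aligner is replaced here by detection of the four positional
# anchors every productive V domain carries under IMGT numbering:
#
#   1st-CYS at position 23, conserved TRP at 41, 2nd-CYS at 104, and the
#   J-motif F/W-G-x-G whose F/W sits at position 118.
#
# Framework lengths between anchors are fixed by the numbering scheme
# (FR2 = 17, FR3 = 39 slots); CDR lengths float and are laid out with the
# IMGT middle-of-loop gap rule, with lettered insertion positions at 111/112
# for CDR3 loops longer than 13 residues. Light chains end at position 127,
# heavy chains at 128.

# region boundaries on the numeric IMGT key
.imgt_regions <- list(
  FR1 = c(1, 26), CDR1 = c(27, 38), FR2 = c(39, 55), CDR2 = c(56, 65),
  FR3 = c(66, 104), CDR3 = c(105, 117.995), FR4 = c(118, 200)
)

# light-chain classes all use the generic light numbering (1-127)
.chain_kind <- function(chain) {
  if (chain %in% c("kappa", "lambda", "light")) "light"
  else if (chain == "heavy") "heavy"
  else stop("unknown chain class '", chain, "'")
}

# Sort key for an IMGT label. Insertions after 111 ascend (111A = 111.01);
# insertions before 112 descend (112A = 111.99), giving the IMGT CDR3
# sequence order 111, 111A, 111B, ..., 112B, 112A, 112.
imgt_label_key <- function(label) {
  vapply(label, function(l) {
    if (grepl("^[0-9]+$", l)) return(as.numeric(l))
    base <- as.numeric(sub("[A-Z]$", "", l))
    k <- match(sub("^[0-9]+", "", l), LETTERS)
    if (base == 112) base - k / 100 else base + k / 100
  }, numeric(1), USE.NAMES = FALSE)
}

# IMGT gap rule for a short loop: fill slots from both ends, leaving the gap
# in the middle of the loop, front half taking the extra residue.
.middle_fill <- function(slots, L) {
  stopifnot(L <= length(slots))
  front <- ceiling(L / 2)
  back <- L - front
  c(utils::head(slots, front), if (back > 0) utils::tail(slots, back))
}

# CDR3 labels for a loop of L residues (positions 105-117 plus insertions).
.cdr3_labels <- function(L) {
  if (L <= 13L) return(as.character(.middle_fill(105:117, L)))
  n_ins <- L - 13L
  ins111 <- floor(n_ins / 2)
  ins112 <- ceiling(n_ins / 2)
  c(as.character(105:111),
    if (ins111 > 0) paste0("111", LETTERS[seq_len(ins111)]),
    paste0("112", LETTERS[rev(seq_len(ins112))]),
    as.character(112:117))
}

# Locate the anchor parse of a V domain inside a translated amplicon.
# Returns NULL when no arrangement of anchors satisfies the IMGT spacing
# constraints; among valid parses the one covering the most residues wins.
.parse_v_domain <- function(aa, chain) {
  v <- chars(aa)
  n <- length(v)
  fr4_len <- if (.chain_kind(chain) == "heavy") 11L else 10L
  cys <- which(v == "C")
  best <- NULL
  for (c1 in cys) {
    # conserved TRP at 41 = c1 + 6 + L1 with CDR1 length 5..12
    for (w in (c1 + 11L):(c1 + 18L)) {
      if (w > n || v[w] != "W") next
      L1 <- w - c1 - 6L
      for (c2 in cys[cys > w]) {
        L2 <- c2 - w - 53L        # 14 FR2 slots past 41, then 39 FR3 slots
        if (L2 < 0L || L2 > 10L) next
        jmax <- min(n - 3L, c2 + 26L)
        for (j in (c2 + 3L):jmax) {
          if (j < c2 + 3L || j > n) break
          if (!(v[j] %in% c("F", "W"))) next
          if (v[j + 1L] != "G" || v[j + 3L] != "G") next
          L3 <- j - c2 - 1L
          if (L3 < 2L || L3 > 25L) next
          start <- max(1L, c1 - 22L)
          end <- min(n, j + fr4_len - 1L)
          if (any(v[start:end] == "*")) break
          cand <- list(c1 = c1, w = w, c2 = c2, j = j, L1 = L1, L2 = L2,
                       L3 = L3, start = start, end = end,
                       coverage = end - start + 1L)
          if (is.null(best) || cand$coverage > best$coverage) best <- cand
          break   # nearest J-motif past 2nd-CYS wins for this (c1,w,c2)
        }
      }
    }
  }
  best
}

#' Find the reading frame of a V-domain amplicon
#'
#' Translates the sequence in all three frames and keeps the frame in which
#' the V-domain anchors are found, an ATG start codon lies upstream of the
#' domain, and no stop codon occurs between that start codon and the end of
#' FR4.
#'
#' @param asv_nt denoised amplicon nucleotide sequence.
#' @param chain `"heavy"`, `"kappa"`, `"lambda"` or `"light"`.
#' @return a list with `frame` (0-based offset), `aa_full`, the anchor
#'   `parse`, and `atg_aa` (index of the leader methionine); `NULL` when no
#'   frame satisfies the constraints.
#' @export
find_reading_frame <- function(asv_nt, chain) {
  stopifnot(is.character(asv_nt), length(asv_nt) == 1L)
  for (frame in 0:2) {
    aa <- dna_translate(substring(asv_nt, frame + 1L))
    p <- .parse_v_domain(aa, chain)
    if (is.null(p)) next
    v <- chars(aa)
    atg <- NULL
    # rightmost ATG at or before the domain start with a clean run to FR4
    # (reads can begin exactly at the start codon)
    for (m in rev(seq_len(p$start))) {
      if (v[m] != "M") next
      if (!any(v[m:p$end] == "*")) { atg <- m; break }
    }
    if (is.null(atg)) next
    return(list(frame = frame, aa_full = aa, parse = p, atg_aa = atg))
  }
  NULL
}

#' Assign IMGT position labels to a translated V domain
#'
#' @param aa_full translated amplicon (single amino-acid string).
#' @param chain chain class; kappa and lambda share the light numbering.
#' @return a data frame with columns `label` (IMGT position, e.g. `"112A"`),
#'   `key` (numeric sort key), `residue`, and `aa_index` (position in
#'   `aa_full`), or `NULL` when an anchor is missing.
#' @export
assign_imgt_numbering <- function(aa_full, chain) {
  p <- .parse_v_domain(aa_full, chain)
  if (is.null(p)) return(NULL)
  v <- chars(aa_full)
  fr4_len <- if (.chain_kind(chain) == "heavy") 11L else 10L

  idx <- list(
    FR1  = p$start:(p$c1 + 3L),
    CDR1 = (p$c1 + 4L):(p$w - 3L),
    FR2  = (p$w - 2L):(p$w + 14L),
    CDR2 = if (p$L2 > 0L) (p$w + 15L):(p$c2 - 39L) else integer(0),
    FR3  = (p$c2 - 38L):p$c2,
    CDR3 = (p$c2 + 1L):(p$j - 1L),
    FR4  = p$j:p$end
  )
  lab <- list(
    FR1  = as.character((23L + (p$start - p$c1)):26L),
    CDR1 = as.character(.middle_fill(27:38, p$L1)),
    FR2  = as.character(39:55),
    CDR2 = as.character(.middle_fill(56:65, p$L2)),
    FR3  = as.character(66:104),
    CDR3 = .cdr3_labels(p$L3),
    FR4  = as.character(118L:(117L + length(idx$FR4)))
  )
  ai <- unlist(idx, use.names = FALSE)
  ll <- unlist(lab, use.names = FALSE)
  stopifnot(length(ai) == length(ll))
  data.frame(label = ll, key = imgt_label_key(ll), residue = v[ai],
             aa_index = ai, stringsAsFactors = FALSE)
}

#' Segment an IMGT-numbered domain into FR and CDR regions
#'
#' IMGT boundaries: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104,
#' CDR3 105-117 (plus insertions), FR4 118 to the chain end.
#'
#' @param imgt_map data frame from [assign_imgt_numbering()].
#' @return named list of region residue strings (`FR1` ... `FR4`).
#' @export
segment_regions <- function(imgt_map) {
  out <- lapply(.imgt_regions, function(b) {
    paste(imgt_map$residue[imgt_map$key >= b[1] & imgt_map$key <= b[2]],
          collapse = "")
  })
  out
}

#' Annotate one denoised amplicon
#'
#' Runs frame finding, IMGT numbering, region segmentation, validity checks
#' and trimming in one pass.
#'
#' @param asv_nt amplicon nucleotide sequence.
#' @param chain chain class.
#' @return object of class `hyb_annotation`: a list with `chain`, `frame`,
#'   `aa_full`, `imgt_map`, `regions`, `trimmed_nt`, `aa_imgt`, `valid` and
#'   `reasons`. When no reading frame is found only `valid`/`reasons` are
#'   populated.
#' @export
annotate_asv <- function(asv_nt, chain) {
  fr <- find_reading_frame(asv_nt, chain)
  if (is.null(fr)) {
    return(structure(list(chain = chain, frame = NA_integer_,
                          aa_full = NA_character_, imgt_map = NULL,
                          regions = NULL, trimmed_nt = NA_character_,
                          aa_imgt = NA_character_, valid = FALSE,
                          reasons = "no reading frame with intact V-domain anchors"),
                     class = "hyb_annotation"))
  }
  map <- assign_imgt_numbering(fr$aa_full, chain)
  regions <- segment_regions(map)
  ann <- structure(list(
    chain = chain, frame = fr$frame, aa_full = fr$aa_full, imgt_map = map,
    regions = regions,
    trimmed_nt = trim_to_imgt(asv_nt, list(frame = fr$frame, imgt_map = map)),
    aa_imgt = paste(map$residue, collapse = ""),
    has_start_codon = !is.null(fr$atg_aa),
    valid = NA, reasons = character(0)
  ), class = "hyb_annotation")
  v <- validate_domain(ann)
  ann$valid <- v$valid
  ann$reasons <- v$reasons
  ann
}

#' Apply the validity filters to an annotated domain
#'
#' A domain is retained only if every FR and CDR has at least one residue,
#' the first 10 FR1 positions and the last 10 FR4 positions are all present,
#' an ATG start codon lies upstream, and no stop codon falls within the IMGT
#' span.
#'
#' @param annotation `hyb_annotation` object (or a list with `chain`,
#'   `imgt_map`, `regions`, `has_start_codon`).
#' @return list with `valid` (logical) and `reasons` (character vector).
#' @export
validate_domain <- function(annotation) {
  reasons <- character(0)
  map <- annotation$imgt_map
  if (is.null(map)) {
    return(list(valid = FALSE,
                reasons = "no reading frame with intact V-domain anchors"))
  }
  for (rg in names(.imgt_regions)) {
    if (nchar(annotation$regions[[rg]]) == 0L) {
      reasons <- c(reasons, paste0("zero-length region ", rg))
    }
  }
  if (!all(as.character(1:10) %in% map$label)) {
    reasons <- c(reasons, "first 10 amino acids of FR1 not all present")
  }
  last_pos <- if (.chain_kind(annotation$chain) == "heavy") 119:128 else 118:127
  if (!all(as.character(last_pos) %in% map$label)) {
    reasons <- c(reasons, "last 10 amino acids of FR4 not all present")
  }
  if (any(map$residue == "*")) {
    reasons <- c(reasons, "stop codon within the IMGT span")
  }
  if (!isTRUE(annotation$has_start_codon)) {
    reasons <- c(reasons, "no upstream start codon")
  }
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Trim an amplicon to the nucleotides encoding its IMGT span
#'
#' @param asv_nt amplicon nucleotide sequence.
#' @param annotation list with `frame` and `imgt_map` (as produced by
#'   [annotate_asv()]).
#' @return nucleotide string of exactly 3x the number of IMGT residues;
#'   translating it reproduces the IMGT residues.
#' @export
trim_to_imgt <- function(asv_nt, annotation) {
  map <- annotation$imgt_map
  stopifnot(!is.null(map))
  first <- min(map$aa_index)
  last <- max(map$aa_index)
  substring(asv_nt, annotation$frame + 3L * (first - 1L) + 1L,
            annotation$frame + 3L * last)
}

#' @export
print.hyb_annotation <- function(x, ...) {
  cat("V-domain annotation (", x$chain, " chain)\n", sep = "")
  if (is.null(x$imgt_map)) {
    cat("  annotation failed:", x$reasons, "\n")
    return(invisible(x))
  }
  cat("  frame:", x$frame, "| IMGT residues:", nrow(x$imgt_map), "\n")
  for (rg in names(x$regions)) cat(sprintf("  %-4s %s\n", rg, x$regions[[rg]]))
  cat("  valid:", x$valid,
      if (length(x$reasons)) paste0("(", paste(x$reasons, collapse = "; "), ")"),
      "\n")
  invisible(x)
}

#' Annotate a table of ASVs
#'
#' @param asvs data frame with columns `well`, `chain`, `sequence`, `count`
#'   (the output of [denoise_wells()]).
#' @return data frame with one row per ASV: identifiers, trimmed and
#'   translated sequences, per-region strings, validity verdict and reasons.
#' @export
annotate_asvs <- function(asvs) {
  rows <- lapply(seq_len(nrow(asvs)), function(i) {
    ann <- annotate_asv(asvs$sequence[i], asvs$chain[i])
    data.frame(
      well = asvs$well[i], chain = asvs$chain[i],
      sequence = asvs$sequence[i], count = asvs$count[i],
      trimmed_nt = ann$trimmed_nt, aa_imgt = ann$aa_imgt,
      aa_full = ann$aa_full,
      FR1 = ann$regions$FR1 %||% NA_character_,
      CDR1 = ann$regions$CDR1 %||% NA_character_,
      FR2 = ann$regions$FR2 %||% NA_character_,
      CDR2 = ann$regions$CDR2 %||% NA_character_,
      FR3 = ann$regions$FR3 %||% NA_character_,
      CDR3 = ann$regions$CDR3 %||% NA_character_,
      FR4 = ann$regions$FR4 %||% NA_character_,
      valid = ann$valid,
      reasons = paste(ann$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Additively group ASVs with identical trimmed sequences
#'
#' Distinct denoised variants frequently differ only outside the IMGT span
#' (UTR/leader edges, constant-region stub); after trimming they collapse to
#' one entry whose read counts are summed and whose within-sample fractions
#' are recomputed.
#'
#' @param ann annotated ASV data frame (valid rows of [annotate_asvs()]).
#' @param key `"nt"` groups on the trimmed nucleotide sequence (default),
#'   `"aa"` on the translated IMGT residues.
#' @return data frame with one row per (well, chain, distinct trimmed
#'   sequence), counts summed and `fraction` recomputed per well and chain.
#' @export
group_identical <- function(ann, key = c("nt", "aa")) {
  key <- match.arg(key)
  if (nrow(ann) == 0L) return(ann)
  kcol <- if (key == "nt") ann$trimmed_nt else ann$aa_imgt
  gid <- paste(ann$well, ann$chain, kcol, sep = "\r")
  first <- !duplicated(gid)
  out <- ann[first, , drop = FALSE]
  out$count <- as.vector(tapply(ann$count, gid, sum)[gid[first]])
  wc <- paste(out$well, out$chain, sep = "\r")
  tot <- tapply(out$count, wc, sum)
  out$fraction <- out$count / as.vector(tot[wc])
  rownames(out) <- NULL
  out
}
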