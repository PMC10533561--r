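# Read cleaning, demultiplexing, chain assignment, quality trimming and
# paired-read merging. Order of operations per read pair:
#
#   1. inline barcode -> well (R1 prefix, longest match wins), TSO stripped
#   2. nested constant-region primer -> chain (R2 prefix), primer stripped
#   3. reads containing 'N' discarded
#   4. 3'-end run-based quality trimming (Phred < qmin)
#   5. overlap merging (R2 reverse-complemented), higher-quality base wins
#      at disagreements
#   6. merged length filter (>= 385 nt retained)
#
# Every read is accounted for: assigned + unassigned + discarded = input,
# and the per-stage counts are returned alongside the merged reads.

#' Demultiplex one read by its inline barcode
#'
#' Matches the read prefix against the sample-sheet barcodes (5-8 nt). When
#' barcodes nest, the longest matching barcode wins; two equal-length matches
#' are ambiguous and the read stays unassigned. The barcode and the TSO
#' immediately following it are stripped; if the TSO is not found within
#' `tso_window` nt after the barcode the read is unassigned (guards against
#' barcode false positives).
#'
#' @param seq,qual R1 sequence and integer Phred vector.
#' @param sheet sample sheet data frame with `well` and `barcode` columns.
#' @param tso template-switching-oligo sequence.
#' @param max_mismatch allowed barcode mismatches (default 0: barcodes are
#'   short, so tolerance risks collisions).
#' @param tso_window how far past the barcode the TSO may start.
#' @return list with `well` (label or `NA`), trimmed `seq`/`qual`, and
#'   `reason` when unassigned.
#' @export
demultiplex_read <- function(seq, qual, sheet, tso, max_mismatch = 0,
                             tso_window = 20) {
  stopifnot(nrow(sheet) > 0)
  blen <- nchar(sheet$barcode)
  d <- vapply(seq_len(nrow(sheet)), function(i) {
    if (nchar(seq) < blen[i]) return(Inf)
    hamming(substring(seq, 1L, blen[i]), sheet$barcode[i])
  }, numeric(1))
  hit <- which(d <= max_mismatch)
  if (length(hit) == 0L) {
    return(list(well = NA_character_, reason = "no barcode match"))
  }
  hit <- hit[blen[hit] == max(blen[hit])]   # longest barcode wins
  if (length(hit) > 1L) {
    return(list(well = NA_character_, reason = "ambiguous barcode"))
  }
  bl <- blen[hit]
  window <- substring(seq, bl + 1L, bl + tso_window + nchar(tso) - 1L)
  pos <- regexpr(tso, window, fixed = TRUE)
  if (pos < 1L) {
    return(list(well = NA_character_, reason = "TSO not found"))
  }
  cut <- bl + as.integer(pos) + nchar(tso)
  list(well = sheet$well[hit], seq = substring(seq, cut),
       qual = qual[seq(cut, length(qual))])
}

#' Assign the chain class from the R2 prefix
#'
#' @param seq,qual R2 sequence and quality.
#' @param primers named list of nested primer sequences (heavy/kappa/lambda).
#' @param max_mismatch allowed primer mismatches (default 1).
#' @return list with `chain` (or `NA`), primer-stripped `seq`/`qual`.
#' @export
assign_chain <- function(seq, qual, primers, max_mismatch = 1) {
  d <- vapply(names(primers), function(ch) {
    p <- primers[[ch]]
    if (nchar(seq) < nchar(p)) return(Inf)
    hamming(substring(seq, 1L, nchar(p)), p)
  }, numeric(1))
  ok <- which(d <= max_mismatch)
  if (length(ok) == 0L) return(list(chain = NA_character_,
                                    reason = "no primer match"))
  best <- ok[d[ok] == min(d[ok])]
  if (length(best) > 1L) return(list(chain = NA_character_,
                                     reason = "ambiguous primer"))
  ch <- names(primers)[best]
  cut <- nchar(primers[[ch]]) + 1L
  list(chain = ch, seq = substring(seq, cut),
       qual = qual[seq(cut, length(qual))])
}

#' Keep or discard a read on the presence of 'N'
#'
#' @param seq nucleotide string.
#' @return `TRUE` to keep (no `N` anywhere), `FALSE` to discard.
#' @export
drop_n_reads <- function(seq) {
  !grepl("N", seq, fixed = TRUE)
}

#' Trim low-quality bases from the 3' end
#'
#' Removes the maximal trailing run of bases with Phred quality below `qmin`;
#' interior low-quality bases are untouched.
#'
#' @param seq nucleotide string.
#' @param qual integer Phred vector, same length.
#' @param qmin quality threshold (default 10).
#' @return list with trimmed `seq` and `qual` (possibly empty).
#' @export
quality_trim_3prime <- function(seq, qual, qmin = 10) {
  stopifnot(nchar(seq) == length(qual))
  keep <- which(qual >= qmin)
  if (length(keep) == 0L) return(list(seq = "", qual = integer(0)))
  last <- max(keep)
  list(seq = substring(seq, 1L, last), qual = qual[seq_len(last)])
}

# Evaluate one overlap size; returns matches or -1 when over the mismatch cap.
.overlap_matches <- function(a1, a2, o, cap) {
  m <- sum(a1[(length(a1) - o + 1L):length(a1)] == a2[seq_len(o)])
  if ((o - m) / o > cap) -1L else m
}

#' Merge a read pair over its overlap
#'
#' R2 is reverse-complemented, then the overlap offset maximizing matched
#' bases (mismatch fraction within `max_mismatch_frac`, overlap at least
#' `min_overlap`) is chosen. Seed-and-extend: exact 15-mers from the start of
#' the reverse-complemented R2 locate candidate offsets in R1; if no seeded
#' offset is acceptable, all offsets are scanned. At a disagreeing position
#' the higher-quality base wins and the merged quality is the maximum of the
#' two; where the mates agree the merged quality is `min(q1 + q2, 41)`.
#'
#' @param read1,read2 lists with `seq` and integer `qual`.
#' @param min_overlap minimum acceptable overlap (nt).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return list with merged `seq`, `qual` and `overlap`, or `NULL` when no
#'   acceptable overlap exists (a counted, normal outcome).
#' @export
merge_pairs <- function(read1, read2, min_overlap = 20,
                        max_mismatch_frac = 0.10) {
  s1 <- read1$seq; q1 <- read1$qual
  s2 <- dna_revcomp(read2$seq); q2 <- rev(read2$qual)
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 == 0L || n2 == 0L) return(NULL)
  a1 <- utf8ToInt(s1); a2 <- utf8ToInt(s2)
  max_o <- min(n1, n2)
  if (max_o < min_overlap) return(NULL)

  cand <- integer(0)
  for (off in c(0L, 20L, 40L)) {
    if (off + 15L > n2) break
    seed <- substring(s2, off + 1L, off + 15L)
    p <- gregexpr(seed, s1, fixed = TRUE)[[1]]
    p <- p[p > 0L]
    cand <- c(cand, n1 - p + 1L + off)
  }
  cand <- unique(cand[cand >= min_overlap & cand <= max_o])

  best_o <- 0L; best_m <- -1L
  for (o in cand) {
    m <- .overlap_matches(a1, a2, o, max_mismatch_frac)
    if (m > best_m) { best_m <- m; best_o <- o }
  }
  if (best_m < 0L || best_m == 0L) {
    for (o in max_o:min_overlap) {
      m <- .overlap_matches(a1, a2, o, max_mismatch_frac)
      if (m > best_m) { best_m <- m; best_o <- o }
    }
  }
  if (best_m <= 0L) return(NULL)

  o <- best_o
  i1 <- (n1 - o + 1L):n1
  i2 <- seq_len(o)
  agree <- a1[i1] == a2[i2]
  cons_code <- ifelse(agree | q1[i1] >= q2[i2], a1[i1], a2[i2])
  cons_q <- ifelse(agree, pmin(q1[i1] + q2[i2], 41L), pmax(q1[i1], q2[i2]))
  merged_seq <- paste0(substring(s1, 1L, n1 - o), intToUtf8(cons_code),
                       substring(s2, o + 1L))
  merged_q <- c(q1[seq_len(n1 - o)], cons_q,
                if (o < n2) q2[(o + 1L):n2])
  list(seq = merged_seq, qual = merged_q, overlap = o)
}

#' Length filter for merged reads
#'
#' @param merged merged-read list (or anything with a `seq` field) or a
#'   character sequence.
#' @param min_len minimum retained length in nt (default 385).
#' @return `TRUE` iff the merged sequence is at least `min_len` nt.
#' @export
length_filter <- function(merged, min_len = 385) {
  s <- if (is.list(merged)) merged$seq else merged
  nchar(s) >= min_len
}

# Read a FASTQ (optionally gzipped) into seqs + Phred-33 quality strings.
# An empty file is an empty plate, not an error.
.read_fastq <- function(path) {
  if (file.exists(path) && file.size(path) == 0L) {
    return(list(seq = character(0), qual = character(0)))
  }
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(seq = as.character(x),
       qual = as.character(Biostrings::quality(x)))
}

# Vectorized mismatch counts of the prefixes of `seqs` against one pattern.
.prefix_mismatches <- function(seqs, pattern) {
  plen <- nchar(pattern)
  pref <- substr(seqs, 1L, plen)
  full <- nchar(pref) == plen
  out <- rep(Inf, length(seqs))
  if (!any(full)) return(out)
  m <- matrix(unlist(strsplit(pref[full], "", fixed = TRUE)), nrow = plen)
  out[full] <- colSums(m != chars(pattern))
  out
}

#' Process a plate of paired FASTQ files into merged reads
#'
#' Runs the full cleaning cascade and keeps per-stage counts so that
#' assigned + unassigned + discarded reconciles with the input at every
#' stage. The barcode, chain and N stages are vectorized; merging works
#' per pair on the surviving reads.
#'
#' @param r1_path,r2_path paired FASTQ files (may be gzipped).
#' @param sheet sample sheet data frame (`well`, `barcode`, `mab_id`, ...).
#' @param config assay configuration.
#' @return list with `merged` (data frame: `well`, `chain`, `sequence`) and
#'   `counts` (named integer vector of stage tallies).
#' @export
process_reads <- function(r1_path, r2_path, sheet, config = hyb_config()) {
  r1 <- .read_fastq(r1_path)
  r2 <- .read_fastq(r2_path)
  n <- length(r1$seq)
  stopifnot(length(r2$seq) == n)
  counts <- c(input = n, unassigned_barcode = 0L, unassigned_chain = 0L,
              n_containing = 0L, merge_rejected = 0L, too_short = 0L,
              retained = 0L)
  empty <- data.frame(well = character(0), chain = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(merged = empty, counts = counts))

  # -- barcode -> well (longest exact match wins; per-read fallback when
  #    mismatches are tolerated) --------------------------------------------
  well <- rep(NA_character_, n)
  blen <- rep(NA_integer_, n)
  if (config$barcode_mismatch == 0) {
    for (len in sort(unique(nchar(sheet$barcode)), decreasing = TRUE)) {
      bc <- sheet$barcode[nchar(sheet$barcode) == len]
      wl <- sheet$well[nchar(sheet$barcode) == len]
      todo <- is.na(well)
      idx <- match(substr(r1$seq[todo], 1L, len), bc)
      well[todo] <- wl[idx]
      blen[todo][!is.na(idx)] <- len
    }
  } else {
    for (i in seq_len(n)) {
      dm <- demultiplex_read(r1$seq[i], integer(0), sheet, config$tso,
                             config$barcode_mismatch,
                             config$tso_search_window)
      if (!is.na(dm$well)) {
        well[i] <- dm$well
        blen[i] <- nchar(sheet$barcode[match(dm$well, sheet$well)])
      }
    }
  }
  # TSO must follow the barcode closely
  tlen <- nchar(config$tso)
  win <- substr(r1$seq, blen + 1L, blen + config$tso_search_window + tlen - 1L)
  pos <- unlist(lapply(win, function(w) regexpr(config$tso, w, fixed = TRUE)))
  well[!is.na(well) & pos < 1L] <- NA_character_
  counts["unassigned_barcode"] <- sum(is.na(well))
  cut1 <- blen + pos + tlen
  pay1 <- ifelse(is.na(well), NA, substr(r1$seq, cut1, nchar(r1$seq)))
  pq1 <- ifelse(is.na(well), NA, substr(r1$qual, cut1, nchar(r1$qual)))

  # -- primer -> chain ------------------------------------------------------
  mm <- vapply(names(config$primers),
               function(ch) .prefix_mismatches(r2$seq, config$primers[[ch]]),
               numeric(n))
  mm <- matrix(mm, nrow = n)
  best <- apply(mm, 1L, min)
  nbest <- rowSums(mm == best)
  chain <- ifelse(best <= config$primer_mismatch & nbest == 1L,
                  names(config$primers)[apply(mm, 1L, which.min)],
                  NA_character_)
  counts["unassigned_chain"] <- sum(!is.na(well) & is.na(chain))
  plen <- nchar(unlist(config$primers))[match(chain, names(config$primers))]
  pay2 <- ifelse(is.na(chain), NA, substr(r2$seq, plen + 1L, nchar(r2$seq)))
  pq2 <- ifelse(is.na(chain), NA, substr(r2$qual, plen + 1L, nchar(r2$qual)))

  ok <- !is.na(well) & !is.na(chain)

  # -- N filter -------------------------------------------------------------
  has_n <- ok & (grepl("N", pay1, fixed = TRUE) | grepl("N", pay2, fixed = TRUE))
  counts["n_containing"] <- sum(has_n)
  ok <- ok & !has_n

  # -- trim + merge + length filter ----------------------------------------
  keep_i <- which(ok)
  out_well <- character(length(keep_i))
  out_chain <- character(length(keep_i))
  out_seq <- character(length(keep_i))
  kept <- 0L
  for (i in keep_i) {
    t1 <- quality_trim_3prime(pay1[i], utf8ToInt(pq1[i]) - 33L, config$qmin)
    t2 <- quality_trim_3prime(pay2[i], utf8ToInt(pq2[i]) - 33L, config$qmin)
    mg <- merge_pairs(t1, t2, config$min_overlap, config$max_overlap_mismatch)
    if (is.null(mg)) {
      counts["merge_rejected"] <- counts["merge_rejected"] + 1L
      next
    }
    if (!length_filter(mg, config$min_merged_length)) {
      counts["too_short"] <- counts["too_short"] + 1L
      next
    }
    kept <- kept + 1L
    out_well[kept] <- well[i]
    out_chain[kept] <- chain[i]
    out_seq[kept] <- mg$seq
  }
  counts["retained"] <- kept
  list(merged = data.frame(well = out_well[seq_len(kept)],
                           chain = out_chain[seq_len(kept)],
                           sequence = out_seq[seq_len(kept)],
                           stringsAsFactors = FALSE),
       counts = counts)
}
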