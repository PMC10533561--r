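# Pipeline orchestration, flat-file database export, and a k-mer seeded
# similarity search over the database.

#' Read a sample sheet TSV
#'
#' Expected columns: `plate`, `well`, `barcode`, `mab_id`. Barcodes must be
#' 5-8 nt and unique within a plate; mAb IDs must parse.
#'
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("plate", "well", "barcode", "mab_id")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (any(nchar(sheet$barcode) < 5 | nchar(sheet$barcode) > 8)) {
    stop("barcodes must be 5-8 nt")
  }
  for (p in unique(sheet$plate)) {
    b <- sheet$barcode[sheet$plate == p]
    w <- sheet$well[sheet$plate == p]
    if (anyDuplicated(b)) stop("duplicate barcodes on plate ", p)
    if (anyDuplicated(w)) stop("duplicate wells on plate ", p)
  }
  invisible(lapply(sheet$mab_id, parse_mab_id))   # errors on malformed IDs
  sheet
}

#' Run the full pipeline on one plate
#'
#' Executes read processing, denoising, annotation (with validity filtering,
#' trimming and additive grouping), scoring and the census, and writes the
#' flat-file outputs. Deterministic: rerunning on identical inputs gives a
#' byte-identical database.
#'
#' @param r1_path,r2_path paired FASTQ files.
#' @param sheet_path sample sheet TSV.
#' @param out_dir output directory (created if needed).
#' @param config assay configuration.
#' @return invisible list with `database`, `census`, `qc` (per-stage counts)
#'   and output `paths`.
#' @export
run_pipeline <- function(r1_path, r2_path, sheet_path, out_dir,
                         config = hyb_config()) {
  sheet <- read_sample_sheet(sheet_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  proc <- process_reads(r1_path, r2_path, sheet, config)
  asvs <- denoise_wells(proc$merged, config)
  removed <- attr(asvs, "removed")
  qc <- list(reads = as.list(proc$counts),
             asvs_total = nrow(asvs) + if (is.null(removed)) 0L else
               nrow(removed),
             asvs_aberrant = if (is.null(removed)) 0L else nrow(removed),
             asvs_retained = nrow(asvs))

  if (nrow(asvs) > 0L) {
    ann <- annotate_asvs(asvs)
    qc$annotation_failed <- sum(!ann$valid)
    ann <- ann[ann$valid, , drop = FALSE]
    grouped <- group_identical(ann)
  } else {
    grouped <- cbind(asvs[0, ], trimmed_nt = character(0),
                     aa_imgt = character(0))
    qc$annotation_failed <- 0L
  }

  if (nrow(grouped) > 0L) {
    meta <- sheet[match(grouped$well, sheet$well), c("plate", "mab_id")]
    # valid/reasons are constant on retained rows; keep the database lean
    entries <- cbind(meta, grouped[, setdiff(names(grouped),
                                             c("sequence", "valid",
                                               "reasons"))])
    rownames(entries) <- NULL
    scored <- score_entries(entries, config)
    mult <- cohort_multiplicities(scored, config)
    census <- summarize_cohort(mult)
    db <- scored[order(scored$mab_id, scored$chain, scored$trimmed_nt), ,
                 drop = FALSE]
    rownames(db) <- NULL
  } else {
    db <- data.frame()
    census <- summarize_cohort(data.frame(mab_id = character(0),
                                          vl = integer(0), vh = integer(0)))
  }
  qc$entries_scored <- nrow(db)
  qc$entries_high_quality <- if (nrow(db)) sum(db$total_score >=
                                                 config$min_score) else 0L

  paths <- list(database = file.path(out_dir, "database.tsv"),
                census = file.path(out_dir, "census.tsv"),
                qc = file.path(out_dir, "qc.json"))
  write_database(db, paths$database)
  utils::write.table(census, paths$census, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(database = db, census = census, qc = qc, paths = paths))
}

#' Write the curated database as TSV
#'
#' @param db data frame of scored entries.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a database TSV written by [write_database()]
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_database <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  # column-wise type restoration that keeps empty strings as "" (an
  # all-empty column must not degrade to logical NA)
  db[] <- lapply(db, function(x)
    utils::type.convert(x, as.is = TRUE, na.strings = character(0)))
  db
}

#' k-mer seeded similarity search over the database
#'
#' A light-weight stand-in for a full alignment search: exact k-mer seeds
#' locate candidate diagonals, each seed is extended without gaps to the
#' full overlap of query and subject on that diagonal, and hits are scored
#' by identity over the aligned span. Works for nucleotide or protein
#' queries (the caller picks the database column to search).
#'
#' @param query nucleotide or protein sequence (non-empty).
#' @param subjects character vector of database sequences.
#' @param k seed length (>= 6 for nucleotides, >= 3 for proteins).
#' @param min_identity minimum reported identity.
#' @return data frame of hits (`subject` index, `identity`, `span`), ranked
#'   by identity then span, both decreasing.
#' @export
kmer_search <- function(query, subjects, k = 11, min_identity = 0.8) {
  if (!is.character(query) || nchar(query) == 0L) {
    stop("query must be a non-empty sequence")
  }
  is_nt <- grepl("^[ACGTN]+$", query)
  if ((is_nt && k < 6) || (!is_nt && k < 3)) {
    stop("seed length too small for the query alphabet")
  }
  nq <- nchar(query)
  if (nq < k) stop("query shorter than the seed length")
  qkmers <- substring(query, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)

  hits <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    ns <- nchar(s)
    if (ns < k) next
    skmers <- substring(s, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
    m <- match(skmers, qkmers)
    diag <- unique(which(!is.na(m)) - m[!is.na(m)])   # subject offset - query offset
    best_id <- 0; best_span <- 0L
    for (d in diag) {
      qs <- max(1L, 1L - d); ss <- qs + d
      span <- min(nq - qs, ns - ss) + 1L
      if (span <= 0L) next
      a <- utf8ToInt(substring(query, qs, qs + span - 1L))
      b <- utf8ToInt(substring(s, ss, ss + span - 1L))
      ident <- sum(a == b) / span
      if (ident > best_id || (ident == best_id && span > best_span)) {
        best_id <- ident; best_span <- span
      }
    }
    if (best_span > 0L && best_id >= min_identity) {
      hits[[length(hits) + 1L]] <- data.frame(subject = si,
                                              identity = best_id,
                                              span = best_span)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(subject = integer(0), identity = numeric(0),
                      span = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(-out$identity, -out$span), , drop = FALSE]
}
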