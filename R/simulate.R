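# Synthetic plate simulator.
#
# Emits paired-end 300 bp reads from barcoded V-domain amplicons with known
# ground truth, so every downstream stage can be exercised and checked
# without external sequencing data. Amplicon anatomy mirrors the assay:
#
#   barcode (5-8 nt) + TSO + 5'UTR pad + leader + V domain + constant-region
#   stub ending in the reverse-complemented nested chain primer,
#
# 500-550 bp in total, so 300 bp mates overlap by at least 50 bp. The
# scaffold V genes are synthetic mouse-like consensus sequences (not real
# germlines); clones differ in randomized CDR residues. Every well's
# light-chain reads are contaminated with an aberrant Sp2/0-style kappa
# transcript at a configurable fraction, as in real Sp2/0-derived hybridomas.

# Scaffold framework/CDR building blocks. Anchors: 1st-CYS at FR1 position
# 23, TRP at FR2 position 41, 2nd-CYS at the FR3 end (104), F/W-G-x-G at the
# FR4 start (118). CDR residues are randomized per clone from an alphabet
# free of C/W/F so no spurious anchor can arise inside a loop.
.scaffold <- list(
  light = list(
    FR1 = "DIQMTQSPSSLSASVGDRVTITCRAS",
    CDR1 = "QDISNYL",
    FR2 = "LAWYQQKPGKAPKLLIY",
    CDR2 = "DAS",
    FR3 = "VPSNRATGIPDRFSGSGSGTDFTLTISRLEPEDFAVYYC",
    CDR3 = "QQYDNLPLT",
    FR4 = "FGQGTKLEIK",
    cdr3_lens = 8:11
  ),
  heavy = list(
    FR1 = "EVQLQQSGAELVKPGASVKMSSCKAS",
    CDR1 = "GYTATSYA",
    FR2 = "IGWVRQAPGQGLEWMGR",
    CDR2 = "INPSNGGT",
    FR3 = "NYAQKFQGRVTITADKSTSTAYMELSSSLRSEDTAVYYC",
    CDR3 = "ARGDYYGSSYGD",
    FR4 = "WGQGTTLTVSS",
    cdr3_lens = 10:16
  )
)

.cdr_alphabet <- strsplit("ADEGHIKLMNPQRSTVY", "")[[1]]   # no C/W/F, no stop

.encode_aa <- function(aa, table = hyb_codon_table) {
  if (nchar(aa) == 0L) return("")
  codons <- unlist(table[chars(aa)], use.names = FALSE)
  if (length(codons) != nchar(aa)) stop("residue outside codon table")
  paste(codons, collapse = "")
}

# Random V domain from a scaffold: framework fixed, CDR residues (and CDR3
# length) drawn from the running RNG stream.
.random_domain_aa <- function(kind) {
  sc <- .scaffold[[kind]]
  rand <- function(n) paste(sample(.cdr_alphabet, n, replace = TRUE),
                            collapse = "")
  cdr3_len <- sample(sc$cdr3_lens, 1)
  paste0(sc$FR1, rand(nchar(sc$CDR1)), sc$FR2, rand(nchar(sc$CDR2)),
         sc$FR3, rand(cdr3_len), sc$FR4)
}

#' Generate a reference set of ground-truth clones
#'
#' Each clone carries one productive light (kappa) and one heavy V domain
#' built from the bundled synthetic scaffolds with randomized CDRs. Clones
#' optionally carry an additional productive chain at a target abundance,
#' emulating hybridomas with more than one productive transcript.
#'
#' @param n_clones number of parent clones (>= 1).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param project project label used in the parent mAb IDs.
#' @param extra_light_clones indices of clones that receive a second
#'   productive light chain.
#' @param extra_fraction target abundance of the additional chain, in (0,1).
#' @param config assay configuration, for the leader and codon table.
#' @return list of `hyb_clone` objects with fields `mab_id` (parent-level,
#'   `project/parent`), `vl_nt`/`vh_nt` (leader + V coding region),
#'   `vl_trimmed`/`vh_trimmed` (IMGT-span nucleotides) and `extra_chains`.
#' @export
make_reference_set <- function(n_clones, seed, project = "S1",
                               extra_light_clones = integer(0),
                               extra_fraction = 0.4,
                               config = hyb_config()) {
  if (!is.numeric(n_clones) || n_clones < 1) {
    stop("n_clones must be >= 1")
  }
  stopifnot(extra_fraction > 0, extra_fraction < 1)
  set.seed(seed)
  leader_nt <- .encode_aa(config$leader_aa, config$codon_table)
  mk_chain <- function(kind) {
    aa <- .random_domain_aa(kind)
    nt <- .encode_aa(aa, config$codon_table)
    list(domain_aa = aa, trimmed = nt, full = paste0(leader_nt, nt))
  }
  lapply(seq_len(n_clones), function(i) {
    vl <- mk_chain("light")
    vh <- mk_chain("heavy")
    extra <- list()
    if (i %in% extra_light_clones) {
      e <- mk_chain("light")
      extra <- list(list(chain = "kappa", nt = e$full, trimmed = e$trimmed,
                         fraction = extra_fraction))
    }
    structure(list(
      mab_id = paste0(project, "/", i),
      vl_nt = vl$full, vh_nt = vh$full,
      vl_trimmed = vl$trimmed, vh_trimmed = vh$trimmed,
      vl_aa = vl$domain_aa, vh_aa = vh$domain_aa,
      extra_chains = extra
    ), class = "hyb_clone")
  })
}

#' Assemble a full amplicon from a V coding region
#'
#' @param clone_chain_nt leader + V-domain coding sequence (e.g. `vl_nt` of a
#'   clone).
#' @param barcode inline well barcode, 5-8 nt.
#' @param chain chain class, used to select the nested primer and constant
#'   stub.
#' @param config assay configuration.
#' @return amplicon nucleotide string: `barcode + TSO + UTR + coding region +
#'   constant pad + revcomp(nested primer)`; 500-550 nt with the bundled
#'   defaults.
#' @export
build_amplicon <- function(clone_chain_nt, barcode, chain,
                           config = hyb_config()) {
  if (!is.character(barcode) || nchar(barcode) < 5 || nchar(barcode) > 8) {
    stop("barcode must be 5-8 nt")
  }
  primer <- chain_primer(config, chain)
  pad <- config$const_pads[[chain]]
  if (is.null(pad)) stop("no constant pad configured for chain '", chain, "'")
  paste0(barcode, config$tso, config$utr, clone_chain_nt, pad,
         dna_revcomp(primer))
}

# The aberrant Sp2/0-style kappa transcript shipped with the defaults:
# a light-chain amplicon interior whose V region carries a 4 nt deletion at
# the FR3/CDR3 junction, frameshifting the domain so it can never translate
# to a productive V_L. Synthetic stand-in for the myeloma-derived transcript;
# deterministic, no RNG.
build_aberrant_reference <- function(cfg) {
  sc <- .scaffold$light
  aa <- paste0(sc$FR1, sc$CDR1, sc$FR2, sc$CDR2, sc$FR3, sc$CDR3, sc$FR4)
  nt <- .encode_aa(aa, cfg$codon_table)
  cut <- 3L * (nchar(sc$FR1) + nchar(sc$CDR1) + nchar(sc$FR2) +
                 nchar(sc$CDR2) + nchar(sc$FR3))   # end of FR3
  broken <- paste0(substring(nt, 1L, cut - 4L), substring(nt, cut + 1L))
  leader_nt <- .encode_aa(cfg$leader_aa, cfg$codon_table)
  paste0(cfg$utr, leader_nt, broken, cfg$const_pads$kappa)
}

# Deterministic prefix-free barcode set: lengths cycle 5-8 nt.
.make_barcodes <- function(n) {
  lens <- rep(5:8, length.out = n)
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), lens[length(out) + 1L],
                         replace = TRUE), collapse = "")
    clash <- any(startsWith(cand, out) | startsWith(out, cand))
    if (!clash) out <- c(out, cand)
  }
  out
}

#' Build a plate specification from a clone reference set
#'
#' Lays clones out with the replicate structure of the assay: each parent
#' contributes `n_bio` biological-replicate wells (subclones `.1`, `.2`, ...)
#' and `n_tech` additional technical-replicate wells of subclone `.1`.
#'
#' @param clones list from [make_reference_set()].
#' @param n_bio biological replicates (subclones) per parent.
#' @param n_tech technical replicates of the first subclone.
#' @param depth reads per well per chain.
#' @param error_rate per-base substitution probability.
#' @param aberrant_fraction fraction of each well's light-chain reads drawn
#'   from the aberrant Sp2/0 reference; in [0, 1).
#' @param seed RNG seed for barcode generation and read simulation.
#' @param plate plate label.
#' @param config assay configuration.
#' @return object of class `hyb_plate_spec`.
#' @export
make_plate_spec <- function(clones, n_bio = 3, n_tech = 1, depth = 50,
                            error_rate = 0.002, aberrant_fraction = 0.2,
                            seed = 1, plate = "P1", config = hyb_config()) {
  stopifnot(depth > 0, aberrant_fraction >= 0, aberrant_fraction < 1)
  n_wells <- length(clones) * (n_bio + n_tech)
  if (n_wells > 96) stop("plate layout exceeds 96 wells")
  set.seed(seed)
  barcodes <- .make_barcodes(n_wells)
  wells <- list()
  k <- 0L
  for (cl in clones) {
    roles <- c(seq_len(n_bio), rep(1L, n_tech))
    for (sub in roles) {
      k <- k + 1L
      wid <- sprintf("%s%02d", LETTERS[(k - 1L) %/% 12L + 1L],
                     (k - 1L) %% 12L + 1L)
      wells[[wid]] <- list(barcode = barcodes[k], clone = cl,
                           mab_id = paste0(cl$mab_id, ".", sub))
    }
  }
  structure(list(wells = wells, depth = depth, error_rate = error_rate,
                 aberrant_fraction = aberrant_fraction, seed = seed,
                 plate = plate, config = config),
            class = "hyb_plate_spec")
}

# Apply substitution errors and per-base qualities to a read.
# Quality is a deterministic function of the error rate plus seeded jitter.
.noisy_read <- function(seq, error_rate) {
  n <- nchar(seq)
  if (error_rate > 0) {
    hits <- which(stats::runif(n) < error_rate)
    if (length(hits)) {
      b <- chars(seq)
      for (i in hits) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
      seq <- paste(b, collapse = "")
    }
    q0 <- max(2L, min(40L, round(-10 * log10(error_rate))))
    q <- pmax(2L, pmin(40L, q0 + sample(-3:3, n, replace = TRUE)))
  } else {
    q <- rep(40L, n)
  }
  list(seq = seq, qual = q)
}

.phred_string <- function(q) rawToChar(as.raw(q + 33L))

#' Simulate a plate of paired-end reads
#'
#' Writes gzip-compressed R1/R2 FASTQ (R1 from the barcode/TSO end, R2 the
#' reverse complement of the amplicon 3' end), a ground-truth TSV, a sample
#' sheet TSV and the plate spec as YAML.
#'
#' @param spec a `hyb_plate_spec` from [make_plate_spec()].
#' @param out_prefix path prefix for output files.
#' @param read_length mate length in nt.
#' @return invisible list with `paths` (output files) and the `truth` and
#'   `sheet` data frames.
#' @export
simulate_plate <- function(spec, out_prefix, read_length = 300L) {
  stopifnot(inherits(spec, "hyb_plate_spec"))
  if (spec$depth <= 0) stop("depth must be > 0")
  cfg <- spec$config
  set.seed(spec$seed)

  r1_seq <- character(0); r1_q <- character(0)
  r2_seq <- character(0); r2_q <- character(0)
  ids <- character(0)
  truth <- list()
  sheet <- list()
  read_i <- 0L

  for (wid in names(spec$wells)) {
    w <- spec$wells[[wid]]
    cl <- w$clone
    sheet[[wid]] <- data.frame(plate = spec$plate, well = wid,
                               barcode = w$barcode, mab_id = w$mab_id,
                               stringsAsFactors = FALSE)
    # variant table: (chain, coding nt, trimmed nt, productive fraction)
    extra_l <- Filter(function(e) e$chain %in% c("kappa", "lambda", "light"),
                      cl$extra_chains)
    main_l_frac <- 1 - sum(vapply(extra_l, `[[`, numeric(1), "fraction"))
    variants <- list(
      list(chain = "kappa", nt = cl$vl_nt, trimmed = cl$vl_trimmed,
           fraction = main_l_frac),
      list(chain = "heavy", nt = cl$vh_nt, trimmed = cl$vh_trimmed,
           fraction = 1)
    )
    variants <- c(variants, extra_l)

    for (chain in c("kappa", "heavy")) {
      vs <- Filter(function(v) v$chain == chain, variants)
      n_ab <- if (chain == "kappa" && spec$aberrant_fraction > 0) {
        stats::rbinom(1, spec$depth, spec$aberrant_fraction)
      } else 0L
      n_true <- spec$depth - n_ab
      fr <- vapply(vs, `[[`, numeric(1), "fraction")
      counts <- as.vector(stats::rmultinom(1, n_true, fr))
      amps <- c(
        lapply(vs, function(v) build_amplicon(v$nt, w$barcode, chain, cfg)),
        if (n_ab > 0) list(paste0(w$barcode, cfg$tso, cfg$aberrant_ref,
                                  dna_revcomp(chain_primer(cfg, "kappa"))))
      )
      counts <- c(counts, if (n_ab > 0) n_ab)
      for (vi in seq_along(amps)) {
        amp <- amps[[vi]]
        L <- nchar(amp)
        for (r in seq_len(counts[vi])) {
          read_i <- read_i + 1L
          m1 <- .noisy_read(substring(amp, 1L, read_length), spec$error_rate)
          m2 <- .noisy_read(dna_revcomp(substring(amp, L - read_length + 1L, L)),
                            spec$error_rate)
          r1_seq[read_i] <- m1$seq; r1_q[read_i] <- .phred_string(m1$qual)
          r2_seq[read_i] <- m2$seq; r2_q[read_i] <- .phred_string(m2$qual)
          ids[read_i] <- sprintf("sim_%s_%s_%d", wid, chain, r)
        }
      }
      for (vi in seq_along(vs)) {
        truth[[length(truth) + 1L]] <- data.frame(
          plate = spec$plate, well = wid, mab_id = w$mab_id, chain = chain,
          sequence = vs[[vi]]$trimmed, fraction = vs[[vi]]$fraction,
          stringsAsFactors = FALSE)
      }
    }
  }

  perm <- sample(read_i)   # shuffle so well/chain order carries no signal
  paths <- list(r1 = paste0(out_prefix, "_R1.fastq.gz"),
                r2 = paste0(out_prefix, "_R2.fastq.gz"),
                truth = paste0(out_prefix, "_truth.tsv"),
                sheet = paste0(out_prefix, "_sheet.tsv"),
                spec = paste0(out_prefix, "_spec.yaml"))
  .write_fastq(ids[perm], r1_seq[perm], r1_q[perm], paths$r1)
  .write_fastq(ids[perm], r2_seq[perm], r2_q[perm], paths$r2)
  truth_df <- do.call(rbind, truth)
  sheet_df <- do.call(rbind, sheet)
  rownames(sheet_df) <- NULL
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sheet_df, paths$sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(plate = spec$plate, depth = spec$depth,
                        error_rate = spec$error_rate,
                        aberrant_fraction = spec$aberrant_fraction,
                        seed = spec$seed,
                        wells = lapply(spec$wells, function(w)
                          list(barcode = w$barcode, mab_id = w$mab_id))),
                   paths$spec)
  invisible(list(paths = paths, truth = truth_df, sheet = sheet_df))
}

.write_fastq <- function(ids, seqs, quals, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  # Biostrings warns that the quality mcols it attaches are dropped again
  # on write; the qualities do land in the FASTQ
  suppressWarnings(
    Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = endsWith(path, ".gz")))
  invisible(path)
}
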