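# Assay configuration: every sequence the wet-lab protocol fixes (TSO, nested
# constant-region primers, overhangs, linker/leader peptides) plus pipeline
# thresholds. The bundled defaults are synthetic stand-ins suitable for
# simulation and testing; a real assay supplies its own values via YAML.

#' Default pipeline configuration
#'
#' Returns the full set of assay sequences and thresholds used by the
#' simulator and the processing stages. All values can be overridden either
#' by arguments here or by loading a YAML file with [read_config()].
#'
#' The primer, TSO and UTR sequences bundled here are synthetic defaults
#' (the assay's real oligos are proprietary inputs); the Gibson overhangs,
#' the scFv leader and the glycine-serine linker are the published values.
#'
#' @param ... named overrides of any top-level config entry.
#' @return a list of class `hyb_config`.
#' @export
hyb_config <- function(...) {
  cfg <- list(
    # -- amplicon anatomy ----------------------------------------------------
    tso = "AAGCAGTGGTATCAACGCAGAGTACATGGG",
    utr = "GCTCTGACTTCAGGGACAAGCTTGACCTCAGGGTA",   # 35 nt 5'UTR pad
    leader_aa = "MGWSCIILFLVATATGVHS",
    primers = list(
      heavy  = "CAGGTCACTGTCACTGGCTCAGGGA",
      kappa  = "GATGGATACAGTTGGTGCAGCATCA",
      lambda = "GGGGTACCATCTACCTTCCAGTCCA"
    ),
    const_pads = list(
      heavy  = "GCCAAAACGACACCCCCA",
      kappa  = "CGGGCTGATGCTGCACCA",
      lambda = "GGTCAGCCCAAGTCTTCG"
    ),
    # -- read processing -----------------------------------------------------
    qmin = 10,                  # 3' quality-trim threshold (Phred)
    min_merged_length = 385,    # retained merged reads must reach this
    min_overlap = 20,
    max_overlap_mismatch = 0.10,
    barcode_mismatch = 0,
    primer_mismatch = 1,
    tso_search_window = 20,
    # -- denoising -----------------------------------------------------------
    denoise_alpha = 2,
    denoise_max_d = 4,
    min_fraction = 0.10,
    aberrant_min_identity = 0.97,
    aberrant_min_coverage = 0.90,
    fraction_per_chain = TRUE,  # ReadsPerPrimerWell = reads per well AND chain
    # -- scoring -------------------------------------------------------------
    min_score = 3,
    total_seqs_mode = "samples",   # or "sequences"
    include_focal = FALSE,         # BR/TR count *other* samples
    # -- fragment design -----------------------------------------------------
    overhangs = list(
      vl5 = "AGACCCAGGTACTCATGTCCCTGCTGCTCTGCATGTCTGGTGCGGCCGCA",
      vl3 = "CGGGCTGATGCTGCACCAACTGTATCCATCTTCCCACCATCCAGTGAGCA",
      vh5 = "CTGTTCTGCTAGTGGTGCTGCTATTGTTCACGAGTCCAGCCTCAAGCAGT",
      vh3 = "GCGCGCCCAACAGCCCCATCGGTCTATCCACTGGCCCCTGTGTGTGGAGA"
    ),
    scfv = list(
      leader_aa = "MGWSCIILFLVATATGVHS",
      linker_aa = "GGGGSGGGGSGGGGSGGGS",
      tags = list(ha = "YPYDVPDYA", sortase = "LPETGG", his6 = "HHHHHH"),
      # synthetic homology arms standing in for the expression-vector
      # polylinker flanks (vector-specific, supplied per assay)
      overhang5 = "CTGGCTAGCGTTTAAACTTAAGCTTGGTACCGAGCTCGGATCCACTAGT",
      overhang3 = "TGAGTTTAAACCCGCTGATCAGCCTCGACTGTGCCTTCTAGTTGCCAGC"
    ),
    codon_table = as.list(hyb_codon_table),
    aberrant_ref = NULL
  )
  cfg$aberrant_ref <- build_aberrant_reference(cfg)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "hyb_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults from [hyb_config()].
#'
#' @param path YAML file.
#' @return a `hyb_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- hyb_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg a `hyb_config` list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.hyb_config <- function(x, ...) {
  cat("hybseq assay configuration\n")
  cat("  TSO:", x$tso, "\n")
  cat("  chains:", paste(names(x$primers), collapse = ", "), "\n")
  cat("  min merged length:", x$min_merged_length,
      "| min ASV fraction:", x$min_fraction,
      "| min score:", x$min_score, "\n")
  invisible(x)
}

# The nested primer for a chain class, erroring if absent.
chain_primer <- function(cfg, chain) {
  p <- cfg$primers[[chain]]
  if (is.null(p)) stop("no nested primer configured for chain '", chain, "'")
  p
}
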