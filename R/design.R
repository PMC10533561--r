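# Gibson-Assembly gene-fragment design for recombinant-mAb expression
# plasmids and scFv constructs, from curated IMGT-trimmed V sequences.

# restriction motifs screened inside V inserts
.re_sites <- c(NotI = "GCGGCCGC", AscI = "GGCGCGCC", BssHII = "GCGCGC")

.scan_sites <- function(nt, label) {
  warnings <- character(0)
  for (enz in names(.re_sites)) {
    if (grepl(.re_sites[[enz]], nt, fixed = TRUE)) {
      warnings <- c(warnings,
                    sprintf("internal %s site in %s", enz, label))
    }
  }
  warnings
}

.new_fragment <- function(kind, insert_nt, full_nt, features, warnings) {
  structure(list(kind = kind, insert_nt = insert_nt, full_nt = full_nt,
                 features = features, warnings = warnings),
            class = "hyb_fragment")
}

#' @export
print.hyb_fragment <- function(x, ...) {
  cat("Gene fragment (", x$kind, "), ", nchar(x$full_nt), " nt\n", sep = "")
  for (i in seq_len(nrow(x$features))) {
    f <- x$features[i, ]
    cat(sprintf("  %-10s %5d..%-5d\n", f$name, f$start, f$end))
  }
  if (length(x$warnings)) cat("  warnings:",
                              paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Deterministic reverse translation
#'
#' One fixed codon per residue; `translate(reverse_translate(x)) == x` by
#' construction.
#'
#' @param aa amino-acid string (may include `*`).
#' @param codon_table named residue -> codon map (default: the bundled
#'   high-usage mouse table).
#' @return nucleotide string.
#' @export
reverse_translate <- function(aa, codon_table = hyb_codon_table) {
  if (nchar(aa) == 0L) return("")
  ct <- unlist(codon_table)
  codons <- unname(ct[chars(aa)])
  if (anyNA(codons) || length(codons) != nchar(aa)) {
    bad <- setdiff(chars(aa), names(ct))
    stop("residues outside codon table: ", paste(bad, collapse = ", "))
  }
  paste(codons, collapse = "")
}

#' Design the V_L and V_H gene fragments for an R-mAb expression plasmid
#'
#' Each trimmed V coding region (IMGT positions 1-127 light, 1-128 heavy) is
#' flanked by the published 50 bp homology overhangs to the expression-
#' plasmid backbone and joining fragment. Internal NotI/AscI/BssHII sites
#' within the V inserts are reported as warnings (they would interfere with
#' downstream subclass switching).
#'
#' @param vl_nt,vh_nt trimmed V nucleotide sequences (length divisible by 3).
#' @param config assay configuration carrying the overhangs.
#' @return list with `vl` and `vh` fragments (class `hyb_fragment`).
#' @export
design_rmab_fragments <- function(vl_nt, vh_nt, config = hyb_config()) {
  if (nchar(vl_nt) %% 3 != 0 || nchar(vh_nt) %% 3 != 0) {
    stop("V coding regions must have length divisible by 3")
  }
  oh <- config$overhangs
  mk <- function(kind, vname, insert, oh5, oh3) {
    full <- paste0(oh5, insert, oh3)
    feats <- data.frame(
      name = c("overhang5", vname, "overhang3"),
      start = c(1L, nchar(oh5) + 1L, nchar(oh5) + nchar(insert) + 1L),
      end = c(nchar(oh5), nchar(oh5) + nchar(insert), nchar(full)),
      stringsAsFactors = FALSE)
    .new_fragment(kind, insert, full, feats,
                  .scan_sites(insert, paste0("the ", vname, " insert")))
  }
  list(vl = mk("rmab_vl", "V_L", vl_nt, oh$vl5, oh$vl3),
       vh = mk("rmab_vh", "V_H", vh_nt, oh$vh5, oh$vh3))
}

#' Design an scFv gene fragment
#'
#' Payload: leader, the two V domains joined by the glycine-serine linker in
#' the requested orientation, then HA, sortase and His6 tags and a stop
#' codon; flanked by the configured vector homology overhangs. Leader,
#' linker and tags are reverse-translated with the fixed codon table, so the
#' translated payload carries the leader `MGWSCIILFLVATATGVHS` and linker
#' `GGGGSGGGGSGGGGSGGGS` verbatim.
#'
#' @param vh_nt,vl_nt trimmed V nucleotide sequences.
#' @param orientation `"VH-linker-VL"` (default) or `"VL-linker-VH"`.
#' @param config assay configuration (`scfv` block).
#' @return a `hyb_fragment`.
#' @export
design_scfv_fragment <- function(vh_nt, vl_nt,
                                 orientation = c("VH-linker-VL",
                                                 "VL-linker-VH"),
                                 config = hyb_config()) {
  orientation <- match.arg(orientation)
  sc <- config$scfv
  if (is.null(sc$overhang5) || is.null(sc$overhang3)) {
    stop("scFv vector overhangs missing from config")
  }
  ct <- config$codon_table
  leader <- reverse_translate(sc$leader_aa, ct)
  linker <- reverse_translate(sc$linker_aa, ct)
  tags <- paste0(reverse_translate(sc$tags$ha, ct),
                 reverse_translate(sc$tags$sortase, ct),
                 reverse_translate(sc$tags$his6, ct))
  stop_nt <- reverse_translate("*", ct)
  first <- if (orientation == "VH-linker-VL") vh_nt else vl_nt
  second <- if (orientation == "VH-linker-VL") vl_nt else vh_nt
  payload <- paste0(leader, first, linker, second, tags, stop_nt)
  full <- paste0(sc$overhang5, payload, sc$overhang3)

  seg <- c(overhang5 = nchar(sc$overhang5), leader = nchar(leader),
           V1 = nchar(first), linker = nchar(linker), V2 = nchar(second),
           tags = nchar(tags), stop = nchar(stop_nt),
           overhang3 = nchar(sc$overhang3))
  ends <- cumsum(seg)
  feats <- data.frame(name = names(seg),
                      start = as.integer(ends - seg + 1L),
                      end = as.integer(ends), stringsAsFactors = FALSE)
  v_names <- if (orientation == "VH-linker-VL") c("V_H", "V_L") else
    c("V_L", "V_H")
  feats$name[feats$name == "V1"] <- v_names[1]
  feats$name[feats$name == "V2"] <- v_names[2]
  .new_fragment("scfv", paste0(first, linker, second), full, feats,
                c(.scan_sites(vh_nt, "the VH insert"),
                  .scan_sites(vl_nt, "the VL insert")))
}

#' Verify the restriction layout for IgG subclass switching
#'
#' Subclass switching moves the V_L-joining-V_H cassette between expression
#' plasmids as a NotI/BssHII fragment, so exactly one NotI and one BssHII
#' site must flank the cassette and no extra site may fall inside it.
#'
#' @param plasmid_map data frame with columns `site` (`"NotI"`/`"BssHII"`)
#'   and `pos` (cut coordinate on the plasmid).
#' @param cassette integer length-2 vector: start and end of the
#'   V_L-joining-V_H cassette.
#' @return list with `pass`, `fragment_length` (between the two flanking
#'   sites; `NA` on failure) and `problems`.
#' @export
subclass_switch_check <- function(plasmid_map, cassette) {
  problems <- character(0)
  noti <- plasmid_map$pos[plasmid_map$site == "NotI"]
  bssh <- plasmid_map$pos[plasmid_map$site == "BssHII"]
  if (length(noti) == 0L) problems <- c(problems, "no NotI site")
  if (length(bssh) == 0L) problems <- c(problems, "no BssHII site")
  inside <- function(p) p > cassette[1] & p < cassette[2]
  for (p in c(noti[inside(noti)], bssh[inside(bssh)])) {
    problems <- c(problems, sprintf("internal site at %d", p))
  }
  if (length(noti) > 1L) problems <- c(problems, "multiple NotI sites")
  if (length(bssh) > 1L) problems <- c(problems, "multiple BssHII sites")
  if (length(problems)) {
    return(list(pass = FALSE, fragment_length = NA_integer_,
                problems = problems))
  }
  flank <- sort(c(noti, bssh))
  if (!(flank[1] <= cassette[1] && flank[2] >= cassette[2])) {
    return(list(pass = FALSE, fragment_length = NA_integer_,
                problems = "sites do not flank the cassette"))
  }
  list(pass = TRUE, fragment_length = as.integer(flank[2] - flank[1]),
       problems = character(0))
}
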