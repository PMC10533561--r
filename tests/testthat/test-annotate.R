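# All fixtures are built from the simulator scaffolds, whose construction
# fixes the true frame, region boundaries and IMGT span.

local_clone <- function(seed = 17) {
  make_reference_set(1, seed = seed, config = fixture_config())[[1]]
}

test_that("the reading frame of a constructed amplicon is recovered", {
  cfg <- fixture_config()
  cl <- local_clone()
  interior <- fixture_interior(cl, "kappa", cfg)
  fr <- find_reading_frame(interior, "kappa")
  expect_false(is.null(fr))
  # UTR pad is 35 nt, so the leader ATG starts at nt 36: frame (36-1) %% 3
  expect_identical(fr$frame, 35L %% 3L)

  # shifting the input by one base shifts the detected frame accordingly
  fr2 <- find_reading_frame(paste0("G", interior), "kappa")
  expect_identical(fr2$frame, (35L + 1L) %% 3L)
})

test_that("stop codons and frameshifts abolish annotation", {
  cfg <- fixture_config()
  cl <- local_clone()
  interior <- fixture_interior(cl, "kappa", cfg)
  ann0 <- annotate_asv(interior, "kappa")
  expect_true(ann0$valid)

  # engineer a TAA into FR3 (in the construction frame)
  fr3_codon_aa <- 35 + 57 + 3 * (26 + 7 + 17 + 3 + 10)   # 10 residues into FR3
  mutated <- paste0(substr(interior, 1, fr3_codon_aa),
                    "TAA", substr(interior, fr3_codon_aa + 4, nchar(interior)))
  annstop <- annotate_asv(mutated, "kappa")
  expect_false(annstop$valid)

  # a 1 nt deletion in FR2 frameshifts the downstream anchors
  fr2_nt <- 35 + 57 + 3 * (26 + 7) + 5
  del <- paste0(substr(interior, 1, fr2_nt - 1),
                substr(interior, fr2_nt + 1, nchar(interior)))
  expect_false(annotate_asv(del, "kappa")$valid)
})

test_that("CDR3 length drives IMGT insertion labels at 111/112", {
  cfg <- fixture_config()
  sc_fr <- list(FR1 = "DIQMTQSPSSLSASVGDRVTITCRAS", CDR1 = "QDISNYL",
                FR2 = "LAWYQQKPGKAPKLLIY", CDR2 = "DAS",
                FR3 = "VPSNRATGIPDRFSGSGSGTDFTLTISRLEPEDFAVYYC",
                FR4 = "FGQGTKLEIK")
  mk <- function(cdr3) {
    aa <- paste0("M", sc_fr$FR1, sc_fr$CDR1, sc_fr$FR2, sc_fr$CDR2,
                 sc_fr$FR3, cdr3, sc_fr$FR4)
    assign_imgt_numbering(aa, "kappa")
  }
  labels_in_cdr3 <- function(map) {
    map$label[map$key > 104 & map$key < 118]
  }

  m13 <- mk(paste0(strrep("QY", 6), "T"))   # 13 residues
  expect_identical(labels_in_cdr3(m13), as.character(105:117))

  m14 <- mk(paste0(strrep("QY", 6), "TS"))
  l14 <- labels_in_cdr3(m14)
  expect_identical(sum(grepl("[A-Z]$", l14)), 1L)
  expect_true("112A" %in% l14)

  m15 <- mk(paste0(strrep("QY", 6), "TSD"))
  l15 <- labels_in_cdr3(m15)
  expect_identical(l15, c(as.character(105:111), "111A", "112A",
                          as.character(112:117)))

  # short loops gap in the middle: 9 residues -> 105-109 then 114-117
  m9 <- mk("QQYDNLPLT")
  expect_identical(labels_in_cdr3(m9),
                   as.character(c(105:109, 114:117)))
})

test_that("region segmentation follows the IMGT boundary table", {
  cfg <- fixture_config()
  cl <- local_clone()
  ann <- annotate_asv(fixture_interior(cl, "kappa", cfg), "kappa")
  map <- ann$imgt_map

  # the seven regions partition the numbered residues
  expect_identical(sum(vapply(ann$regions, nchar, integer(1))),
                   nrow(map))
  expect_identical(paste(vapply(ann$regions, c, ""), collapse = ""),
                   ann$aa_imgt)

  region_at <- function(lbl) {
    key <- map$key[map$label == lbl]
    names(Filter(function(b) key >= b[1] & key <= b[2],
                 list(FR1 = c(1, 26), CDR1 = c(27, 38), FR2 = c(39, 55),
                      CDR2 = c(56, 65), FR3 = c(66, 104),
                      CDR3 = c(105, 117.9), FR4 = c(118, 200))))
  }
  expect_identical(region_at("27"), "CDR1")
  expect_identical(region_at("104"), "FR3")
  expect_identical(region_at("105"), "CDR3")
  expect_identical(region_at("118"), "FR4")

  # scaffold construction boundaries are recovered exactly
  expect_identical(ann$regions$FR1, "DIQMTQSPSSLSASVGDRVTITCRAS")
  expect_identical(ann$regions$FR4, "FGQGTKLEIK")
  expect_identical(nchar(ann$regions$FR2), 17L)
  expect_identical(nchar(ann$regions$FR3), 39L)
})

test_that("validity filters catch truncated and degenerate domains", {
  cfg <- fixture_config()
  cl <- local_clone()
  interior <- fixture_interior(cl, "kappa", cfg)
  ann <- annotate_asv(interior, "kappa")
  expect_true(ann$valid)

  # a read starting mid-FR1 (IMGT 1-7 lost) fails FR1 completeness
  cut <- 35 + 57 + 3 * 7
  trunc <- paste0("ATG", substr(interior, cut + 1, nchar(interior)))
  ann_tr <- annotate_asv(trunc, "kappa")
  expect_false(ann_tr$valid)
  expect_true(any(grepl("FR1", ann_tr$reasons)))

  # an annotation with an emptied CDR2 fails the zero-length check
  ann2 <- ann
  ann2$regions$CDR2 <- ""
  v <- validate_domain(ann2)
  expect_false(v$valid)
  expect_true(any(grepl("zero-length region CDR2", v$reasons)))
})

test_that("trimming returns exactly the IMGT codons and round-trips", {
  cfg <- fixture_config()
  for (seed in c(3, 14)) {
    cl <- local_clone(seed)
    for (chain in c("kappa", "heavy")) {
      ann <- annotate_asv(fixture_interior(cl, chain, cfg), chain)
      expect_identical(nchar(ann$trimmed_nt), 3L * nrow(ann$imgt_map))
      expect_identical(dna_translate(ann$trimmed_nt), ann$aa_imgt)
    }
  }
})

test_that("annotation is idempotent on trimmed sequences", {
  cfg <- fixture_config()
  cl <- local_clone(8)
  for (chain in c("kappa", "heavy")) {
    ann <- annotate_asv(fixture_interior(cl, chain, cfg), chain)
    # a trimmed domain has no leader; prepend a start codon context
    again <- annotate_asv(paste0("ATG", ann$trimmed_nt), chain)
    expect_true(again$valid)
    expect_identical(again$aa_imgt, ann$aa_imgt)
    expect_identical(again$imgt_map$label, ann$imgt_map$label)
    expect_identical(again$regions, ann$regions)
    expect_identical(again$trimmed_nt, ann$trimmed_nt)
  }
})

test_that("identical trimmed sequences group additively", {
  ann <- data.frame(
    well = "A01", chain = "kappa",
    sequence = c("X1", "X2", "Y"),
    count = c(700, 200, 100),
    trimmed_nt = c("AAATTT", "AAATTT", "CCCGGG"),
    aa_imgt = c("KF", "KF", "PG"),
    valid = TRUE, stringsAsFactors = FALSE)
  g <- group_identical(ann)
  expect_identical(nrow(g), 2L)
  expect_equal(g$count[g$trimmed_nt == "AAATTT"], 900)
  expect_equal(sort(g$fraction), c(0.1, 0.9))

  distinct <- group_identical(ann[c(1, 3), ])
  expect_identical(nrow(distinct), 2L)
  single <- group_identical(ann[1, ])
  expect_identical(nrow(single), 1L)
  expect_equal(single$fraction, 1)
})
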