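test_that("demultiplexing assigns by barcode prefix with longest-match rule", {
  cfg <- fixture_config()
  sheet <- data.frame(well = c("A01", "A02", "A03"),
                      barcode = c("ACGTC", "ACGTCAGA", "TTTTT"),
                      stringsAsFactors = FALSE)
  payload <- "GACCTTGACC"
  q <- rep(30L, 100)

  # exact 5 nt barcode; barcode + TSO stripped
  r <- paste0("ACGTC", cfg$tso, payload)
  dm <- demultiplex_read(r, rep(30L, nchar(r)), sheet, cfg$tso)
  expect_identical(dm$well, "A01")
  expect_identical(dm$seq, payload)

  # nested barcodes: the 8 nt one wins
  r8 <- paste0("ACGTCAGA", cfg$tso, payload)
  dm8 <- demultiplex_read(r8, rep(30L, nchar(r8)), sheet, cfg$tso)
  expect_identical(dm8$well, "A02")

  # no match -> unassigned
  miss <- demultiplex_read(paste0("GGGGG", cfg$tso, payload), q, sheet,
                           cfg$tso)
  expect_true(is.na(miss$well))

  # matching barcode but no TSO within the window -> unassigned
  no_tso <- demultiplex_read(paste0("ACGTC", strrep("A", 80)), q[1:85],
                             sheet, cfg$tso)
  expect_true(is.na(no_tso$well))
  expect_match(no_tso$reason, "TSO")
})

test_that("chain assignment tolerates one mismatch and rejects ties", {
  cfg <- fixture_config()
  pay <- "CCATGGCCATGG"
  r <- paste0(cfg$primers$kappa, pay)
  ca <- assign_chain(r, rep(30L, nchar(r)), cfg$primers, 1)
  expect_identical(ca$chain, "kappa")
  expect_identical(ca$seq, pay)

  # one substitution in the heavy primer still assigns heavy
  hp <- strsplit(cfg$primers$heavy, "")[[1]]
  hp[3] <- setdiff(c("A", "C", "G", "T"), hp[3])[1]
  r1mm <- paste0(paste(hp, collapse = ""), pay)
  expect_identical(assign_chain(r1mm, rep(30L, nchar(r1mm)),
                                cfg$primers, 1)$chain, "heavy")

  none <- assign_chain(strrep("AT", 30), rep(30L, 60), cfg$primers, 1)
  expect_true(is.na(none$chain))

  # equidistant primers -> unassigned
  tie <- assign_chain("AA", rep(30L, 2),
                      list(x = "AAC", y = "AAG"), 3)
  expect_true(is.na(tie$chain))
})

test_that("N-containing reads are discarded wherever the N falls", {
  expect_true(drop_n_reads("ACGT"))
  expect_false(drop_n_reads("ACNT"))
  expect_false(drop_n_reads("NNNN"))
  expect_false(drop_n_reads("ACGTN"))
})

test_that("3' quality trimming removes only the trailing low-quality run", {
  t1 <- quality_trim_3prime("ACG", c(30L, 30L, 30L))
  expect_identical(t1$seq, "ACG")

  t2 <- quality_trim_3prime("ACGT", c(30L, 30L, 9L, 8L))
  expect_identical(t2$seq, "AC")
  expect_identical(t2$qual, c(30L, 30L))

  # interior low-quality base survives
  t3 <- quality_trim_3prime("ACGT", c(30L, 5L, 30L, 30L))
  expect_identical(t3$seq, "ACGT")

  t4 <- quality_trim_3prime("ACG", c(5L, 6L, 7L))
  expect_identical(t4$seq, "")
  expect_length(t4$qual, 0)
})

test_that("pair merging takes the higher-quality base at disagreements", {
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  set.seed(42)

  # identical fully-overlapping mates merge to either mate
  m <- merge_pairs(read_of(s), read_of(dna_revcomp(s)))
  expect_identical(m$seq, s)
  expect_identical(m$overlap, 300L)
  # agreeing qualities are summed and capped at 41
  expect_true(all(m$qual == 41L))

  # single disagreement: R2 base G at q35 beats R1 base A at q20
  b <- strsplit(s, "")[[1]]; b[150] <- "A"; s1 <- paste(b, collapse = "")
  b[150] <- "G"; s2 <- paste(b, collapse = "")
  m2 <- merge_pairs(read_of(s1, 20L), read_of(dna_revcomp(s2), 35L))
  expect_identical(substr(m2$seq, 150, 150), "G")
  expect_identical(m2$qual[150], 35L)

  # disjoint reads reject
  r1 <- read_of(strrep("ACGT", 50))
  r2 <- read_of(strrep("GGTACCAT", 25))
  expect_null(merge_pairs(r1, r2))
})

test_that("merging an offset overlap reconstructs the amplicon interior", {
  fx <- fixture_plate(error_rate = 0)
  cl <- fx$clones[[1]]
  interior <- fixture_interior(cl, "kappa", fx$cfg)
  amp <- build_amplicon(cl$vl_nt, "ACGTCA", "kappa", fx$cfg)
  L <- nchar(amp)
  r1 <- substr(amp, 1, 300)
  r2 <- dna_revcomp(substr(amp, L - 299, L))
  m <- merge_pairs(read_of(r1), read_of(r2))
  expect_identical(m$seq, amp)
  expect_identical(m$overlap, 600L - L)
})

test_that("the merged-length filter keeps 385 nt and drops 384 nt", {
  expect_true(length_filter(strrep("A", 385)))
  expect_false(length_filter(strrep("A", 384)))
  expect_true(length_filter(strrep("A", 550)))
  expect_true(length_filter(list(seq = strrep("A", 385))))
})

test_that("every input read is accounted for across processing stages", {
  fx <- fixture_plate(error_rate = 0.002)
  sheet <- read_sample_sheet(fx$sim$paths$sheet)
  proc <- process_reads(fx$sim$paths$r1, fx$sim$paths$r2, sheet, fx$cfg)
  cnt <- proc$counts
  expect_identical(
    cnt[["input"]],
    cnt[["unassigned_barcode"]] + cnt[["unassigned_chain"]] +
      cnt[["n_containing"]] + cnt[["merge_rejected"]] +
      cnt[["too_short"]] + cnt[["retained"]])
  # each merged read belongs to exactly one well and chain
  expect_false(any(is.na(proc$merged$well)))
  expect_false(any(is.na(proc$merged$chain)))
})

test_that("error-free reads are fully assigned and merge to the true interiors", {
  fx <- fixture_plate(error_rate = 0)
  sheet <- read_sample_sheet(fx$sim$paths$sheet)
  proc <- process_reads(fx$sim$paths$r1, fx$sim$paths$r2, sheet, fx$cfg)
  expect_identical(proc$counts[["retained"]], proc$counts[["input"]])

  truths <- c(
    vapply(fx$clones, function(cl) fixture_interior(cl, "kappa", fx$cfg), ""),
    vapply(fx$clones, function(cl) fixture_interior(cl, "heavy", fx$cfg), ""),
    paste0(fx$cfg$aberrant_ref))
  expect_true(all(proc$merged$sequence %in% truths))
})
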