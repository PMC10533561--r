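test_that("mAb identifiers parse and round-trip", {
  id <- parse_mab_id("K89/34.1")
  expect_identical(id$project, "K89")
  expect_identical(id$parent, "34")
  expect_identical(id$subclone, "1")
  expect_identical(format(id), "K89/34.1")

  id2 <- parse_mab_id("L113/13.5")
  expect_identical(c(id2$project, id2$parent, id2$subclone),
                   c("L113", "13", "5"))

  parent_only <- parse_mab_id("K89/34")
  expect_true(is.na(parent_only$subclone))
  expect_identical(format(parent_only), "K89/34")

  expect_error(parse_mab_id("K89-34"), "malformed")
})

test_that("score formulas evaluate exactly as printed", {
  expect_equal(asv_score(450, 500), 0.9)
  expect_equal(asv_score(0, 500), 0.0)
  expect_equal(asv_score(500, 500), 1.0)
  expect_warning(z <- asv_score(0, 0), "undefined")
  expect_equal(z, 0)

  expect_equal(match_score(2, 1, 3), 2.75, tolerance = 1e-12)
  expect_equal(match_score(0, 0, 1), -1, tolerance = 1e-12)
  expect_equal(match_score(4, 0, 5), 3.8, tolerance = 1e-12)
  expect_error(match_score(1, 1, 0), "total_seqs")

  # 3*ln(2.75) = 3.035... caps at 3; plus 2*0.9
  expect_equal(total_score(2.75, 0.9), 4.8, tolerance = 1e-9)
  # non-positive match scores contribute nothing
  expect_equal(total_score(-1, 0.5), 1.0, tolerance = 1e-12)
  # ln(e) = 1 puts the match component exactly at its cap
  expect_equal(total_score(exp(1), 1.0), 5.0, tolerance = 1e-12)
})

test_that("the total score is bounded by 5 and monotone in its inputs", {
  for (br in 0:10) for (ts in 1:12) {
    for (tr in 0:min(3, ts)) for (f in seq(0, 1, by = 0.25)) {
      s <- total_score(match_score(br, tr, ts), f)
      expect_gte(s, 0)
      expect_lte(s, 5)
    }
  }
  # monotone in asv fraction, BR and TR (TotalSeqs fixed)
  ts <- 8
  for (br in 0:6) {
    expect_lte(total_score(match_score(br, 0, ts), 0.3),
               total_score(match_score(br, 0, ts), 0.8))
    expect_lte(total_score(match_score(br, 0, ts), 0.5),
               total_score(match_score(br + 1, 0, ts), 0.5))
    expect_lte(total_score(match_score(br, 0, ts), 0.5),
               total_score(match_score(br, 1, ts), 0.5))
  }
})

test_that("replicate counting distinguishes biological from technical replicates", {
  cohort <- data.frame(
    mab_id = c("K1/7.1", "K1/7.2", "K1/7.3", "K1/9.1"),
    sample = c("P1:A01", "P1:A02", "P1:A03", "P1:B01"),
    chain = "kappa",
    trimmed_nt = c("AAA", "AAA", "AAA", "CCC"),
    stringsAsFactors = FALSE)
  r <- count_replicates(cohort[1, ], cohort)
  expect_identical(r$br, 2L)   # subclones .2 and .3 carry the sequence
  expect_identical(r$tr, 0L)
  expect_identical(r$total_seqs, 3L)

  # sequence seen only in the focal sample of a group of 4
  lone <- data.frame(
    mab_id = paste0("K1/7.", 1:4),
    sample = paste0("P1:A0", 1:4),
    chain = "kappa",
    trimmed_nt = c("GGG", "AAA", "AAA", "AAA"),
    stringsAsFactors = FALSE)
  r2 <- count_replicates(lone[1, ], lone)
  expect_identical(r2$br, 0L)
  expect_identical(r2$tr, 0L)
  expect_identical(r2$total_seqs, 4L)

  # same subclone sequenced on two plates -> technical replicate
  tech <- data.frame(
    mab_id = c("K1/7.1", "K1/7.1"),
    sample = c("P1:A01", "P2:A01"),
    chain = "kappa",
    trimmed_nt = c("AAA", "AAA"),
    stringsAsFactors = FALSE)
  r3 <- count_replicates(tech[1, ], tech)
  expect_identical(r3$br, 0L)
  expect_identical(r3$tr, 1L)
})

test_that("the score filter drops entries below 3 stars", {
  entries <- data.frame(total_score = c(2.99, 3.0, 4.8))
  kept <- quality_filter(entries)
  expect_identical(kept$total_score, c(3.0, 4.8))
})

test_that("chain multiplicity is the rounded mean of per-sample counts", {
  mk <- function(counts) {
    do.call(rbind, lapply(seq_along(counts), function(i)
      data.frame(sample = paste0("S", i),
                 trimmed_nt = paste0("sq", seq_len(counts[i])),
                 stringsAsFactors = FALSE)))
  }
  expect_identical(chain_multiplicity(mk(c(1, 1, 2))), 1L)   # 1.33 -> 1
  expect_identical(chain_multiplicity(mk(c(2, 2, 2))), 2L)
  expect_identical(chain_multiplicity(mk(c(1, 2))), 2L)      # 1.5 rounds up
  expect_identical(chain_multiplicity(mk(integer(0))), 0L)
})

test_that("the cohort census partitions and matches hand-computed percentages", {
  mult <- data.frame(
    mab_id = paste0("K1/", 1:10),
    vl = c(2, rep(1, 8), 0),
    vh = c(1, rep(1, 8), 1))
  cz <- summarize_cohort(mult)
  get <- function(cat, col) cz[[col]][cz$category == cat]
  expect_identical(get("One additional VL only", "count"), 1L)
  expect_equal(get("One additional VL only", "percent"), 10)
  expect_identical(get("VL or VH = 0", "count"), 1L)
  expect_identical(get("Total (VL >= 1 and VH >= 1)", "count"), 9L)
  # census conservation: zero + both = cohort size
  expect_identical(get("VL or VH = 0", "count") +
                     get("Total (VL >= 1 and VH >= 1)", "count"),
                   nrow(mult))

  allsingle <- summarize_cohort(data.frame(mab_id = paste0("K/", 1:5),
                                           vl = 1, vh = 1))
  expect_equal(allsingle$percent[allsingle$category == "No additional chain"],
               100)
})

test_that("simulated replicate structure yields the closed-form star score", {
  # 2 biological replicates + 1 technical replicate of subclone .1, zero
  # error, one chain pair: BR/TR/TotalSeqs follow by construction and the
  # star score must equal the closed form clamp(3*ln(MatchScore),0,3) + 2
  fx <- fixture_plate(error_rate = 0, aberrant_fraction = 0,
                      depth = 30, n_clones = 1)
  res <- run_pipeline(fx$sim$paths$r1, fx$sim$paths$r2, fx$sim$paths$sheet,
                      tempfile("score"), fx$cfg)
  db <- res$database
  # fixture plate: 2 bio subclones + 1 tech of subclone .1
  f1 <- db[db$mab_id == "S1/1.1", ]
  expect_true(all(f1$br == 1 & f1$tr == 1 & f1$total_seqs == 3))
  ms <- (1 + 0.75 * 1) - (1 - (1 + 1) / 3)
  expect_equal(unique(f1$total_score),
               min(3, 3 * log(ms)) + 2, tolerance = 1e-9)
  f2 <- db[db$mab_id == "S1/1.2", ]
  ms2 <- (2 + 0) - (1 - 2 / 3)
  expect_equal(unique(f2$total_score),
               min(3, 3 * log(ms2)) + 2, tolerance = 1e-9)
})
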