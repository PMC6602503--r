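cas9 <- nuclease_spec("crispr", pam = "NGG")

test_that("a lone NGG yields one forward site cut 3 bp from the PAM", {
  # 30 nt, single AGG at 1-based positions 21-23, no other NGG/CCN
  seq <- "ATATCTATTATATCTATTATAGGATATTAT"
  rec <- read_sequence(seq)
  sites <- find_sites(rec, cas9)
  expect_equal(nrow(sites), 1L)
  expect_identical(sites$strand, "forward")
  expect_equal(sites$dsb_index, 20L - 3L)  # PAM start (0-based 20) minus 3
  expect_identical(sites$target_sequence, substr(seq, 1, 20))
  expect_identical(sites$tool_type, "NGG")
  expect_equal(sites$exon_id, 1L)  # unannotated input
})

test_that("the mirrored site appears on the complement strand", {
  seq <- "ATATCTATTATATCTATTATAGGATATTAT"
  rc <- reverse_complement(seq)
  sites <- find_sites(read_sequence(rc), cas9)
  expect_equal(nrow(sites), 1L)
  expect_identical(sites$strand, "complement")
  expect_equal(sites$dsb_index, nchar(seq) - 17L)
  expect_identical(sites$target_sequence, substr(seq, 1, 20))
})

test_that("exon selection filters sites and sets ordinals", {
  set.seed(21)
  rec <- random_locus(400, seed = 77,
                      exons = rbind(c(0L, 150L), c(250L, 400L)))
  sites <- find_sites(rec, cas9)
  expect_gt(nrow(sites), 0L)
  in_ex1 <- sites[!is.na(sites$exon_id) & sites$exon_id == 1L, ]
  only1 <- find_sites(rec, cas9, exon_selection = 1L)
  expect_identical(only1$dsb_index, in_ex1$dsb_index)
  expect_true(all(only1$dsb_index - 1L < 150L))
  expect_error(find_sites(rec, cas9, exon_selection = 3L), "unknown exon")
})

test_that("TALEN layouts respect arm/spacer ranges and the midpoint cut", {
  tal <- nuclease_spec("talen", talen_arm_range = c(15L, 16L),
                       talen_spacer_range = c(14L, 15L))
  rec <- random_locus(120, seed = 5)
  sites <- find_sites(rec, tal)
  if (nrow(sites)) {
    parts <- do.call(rbind, strsplit(sites$tool_type, "/"))
    a <- as.integer(parts[, 1]); s <- as.integer(parts[, 2])
    b <- as.integer(parts[, 3])
    expect_true(all(a %in% 15:16 & b %in% 15:16 & s %in% 14:15))
    expect_equal(nchar(sites$target_sequence), a + s + b)
    # flanking T...A rule and left-biased midpoint
    starts <- vapply(sites$target_sequence, function(ts) {
      as.integer(regexpr(ts, rec$sequence, fixed = TRUE)) - 1L
    }, integer(1), USE.NAMES = FALSE)
    expect_equal(sites$dsb_index, starts + a + s %/% 2L)
    flank5 <- substr(rec$sequence, starts, starts)        # base before arm
    flank3 <- substr(rec$sequence, starts + a + s + b + 1L,
                     starts + a + s + b + 1L)
    expect_true(all(flank5 == "T" & flank3 == "A"))
  }
  expect_gte(nrow(sites), 0L)
})

test_that("blunt context is the plain window; overhangs shorten the junction", {
  rec <- random_locus(200, seed = 13)
  ctx0 <- make_context(rec, 100L, window = 80L, overhang_length = 0L)
  expect_equal(nchar(ctx0$context), 80L)
  expect_equal(ctx0$dsb_index, 40L)
  expect_identical(ctx0$context, substr(rec$sequence, 61, 140))

  ctx4 <- make_context(rec, 100L, window = 80L, overhang_length = 4L)
  # pseudostring: 40 bases up to the cut + 40 bases past the overhang
  expect_identical(ctx4$context,
                   paste0(substr(rec$sequence, 61, 100),
                          substr(rec$sequence, 105, 144)))
  # on a 90-nt input the 4 overhang bases are the only difference
  rec90 <- random_locus(90, seed = 14)
  c90 <- make_context(rec90, 44L, window = 80L, overhang_length = 4L)
  expect_identical(c90$context,
                   paste0(substr(rec90$sequence, 5, 44),
                          substr(rec90$sequence, 49, 88)))
  # too close to an end: skipped with a warning, not an error
  expect_warning(res <- make_context(rec, 190L, window = 80L), "skipped")
  expect_null(res)
})

test_that("the site score is the quotient of the top two pattern scores", {
  imp <- implant_microhomology("GCGCGTGC", 10, length = 80, seed = 3)
  sc <- score_site(imp$record$sequence, imp$dsb_index)
  expect_true(sc$eligible)
  expect_equal(sc$top$arm, "GCGCGTGC")
  expect_equal(sc$menthu_score, sc$patterns$score[1] / sc$patterns$score[2])
  expect_gte(sc$menthu_score, 1)

  # whenever the two top pattern scores tie, the ratio is exactly 1.0 and
  # the site can never be recommended
  ties_seen <- 0L
  for (s in 1:300) {
    set.seed(s)
    ctx <- random_dna(40)
    sc2 <- score_site(ctx, 20L)
    if (!is.na(sc2$menthu_score) &&
        sc2$patterns$score[1] == sc2$patterns$score[2]) {
      expect_equal(sc2$menthu_score, 1.0)
      expect_lt(sc2$menthu_score, 1.5)
      ties_seen <- ties_seen + 1L
    }
  }
  expect_gt(ties_seen, 0L)

  # fewer than two patterns: score undefined, site ineligible
  none <- score_site("AAAAAAAAAACCCCCCCCCC", 10L)
  expect_true(is.na(none$menthu_score))
  expect_false(none$eligible)
})

test_that("sites whose top deletion has >5 intervening bases are ineligible", {
  # arm GCGCGG with 8 intervening bases dominates this context
  imp <- implant_microhomology("GCGCGGCG", 20, length = 80, seed = 8)
  sc <- score_site(imp$record$sequence, imp$dsb_index)
  expect_equal(sc$top$intervening, 12L)
  expect_false(sc$eligible)
})

test_that("scan reports an implanted dominant repeat as a recommended site", {
  # the right arm copy of this implant carries CGG three bases past the cut,
  # so a Cas9 NGG site cuts exactly at the implant junction
  imp <- implant_microhomology("GCCGGCGG", 10, length = 240, seed = 31)
  rec <- imp$record
  expect_identical(substr(rec$sequence, imp$dsb_index + 4, imp$dsb_index + 6),
                   "CGG")
  sc_direct <- score_site(make_context(rec, imp$dsb_index)$context, 40L)
  tab <- suppressWarnings(menthu_scan(rec, cas9))
  hit <- tab[tab$DSB_Location == imp$dsb_index, ]
  expect_gte(nrow(hit), 1L)
  expect_identical(hit$Microhomology[1], "GCCGGCGG")
  expect_equal(hit$MENTHU_Score[1], sc_direct$menthu_score)
})

test_that("scan output obeys the report rules", {
  rec <- random_locus(500, seed = 99)
  cfg <- gss_config()
  tab <- suppressWarnings(menthu_scan(rec, cas9, config = cfg))
  expect_identical(names(tab), c("Target_Sequence", "MENTHU_Score",
                                 "Frame_Shift", "Tool_Type", "Strand",
                                 "Exon_ID", "DSB_Location", "Microhomology",
                                 "PreMA_Sequence", "Context"))
  expect_gt(nrow(tab), 0L)
  expect_true(all(diff(tab$MENTHU_Score) <= 0))
  expect_true(all(tab$MENTHU_Score >= 1))
  expect_true(all(tab$Exon_ID == 1L))
  for (k in seq_len(nrow(tab))) {
    sc <- score_site(tab$Context[k], cfg$window %/% 2L, cfg)
    # every reported row: top intervening <= 5, frame shift = D mod 3 rule,
    # and applying the top deletion to Context reproduces PreMA_Sequence
    expect_lte(sc$top$intervening, cfg$intervening_max)
    expect_identical(tab$Frame_Shift[k], sc$top$deletion_length %% 3L != 0L)
    expect_identical(
      tab$PreMA_Sequence[k],
      paste0(substr(tab$Context[k], 1, sc$top$left_start),
             substring(tab$Context[k], sc$top$right_start + 1)))
    expect_equal(nchar(tab$PreMA_Sequence[k]),
                 nchar(tab$Context[k]) - sc$top$deletion_length)
  }
  rec_tab <- suppressWarnings(menthu_scan(rec, cas9, recommended_only = TRUE))
  expect_equal(rec_tab, tab[tab$MENTHU_Score >= 1.5, ], ignore_attr = TRUE)
  t7 <- suppressWarnings(menthu_scan(rec, cas9, t7_only = TRUE))
  expect_true(all(startsWith(t7$Target_Sequence, "GG")))
})

test_that("scanning a locus and its reverse complement gives the same scores", {
  for (s in c(41, 42)) {
    rec <- random_locus(300, seed = s)
    fwd <- suppressWarnings(menthu_scan(rec, cas9))
    rev <- suppressWarnings(menthu_scan(
      seq_record(reverse_complement(rec$sequence)), cas9))
    expect_equal(sort(fwd$MENTHU_Score), sort(rev$MENTHU_Score))
  }
})

test_that("the CSV round-trips with two-decimal scores and fixed header", {
  rec <- random_locus(400, seed = 7)
  tab <- suppressWarnings(menthu_scan(rec, cas9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_menthu_csv(tab, path)
  header <- readLines(path, n = 1L)
  expect_identical(header,
                   paste("Target_Sequence,MENTHU_Score,Frame_Shift,Tool_Type,",
                         "Strand,Exon_ID,DSB_Location,Microhomology,",
                         "PreMA_Sequence,Context", sep = ""))
  back <- read_menthu_csv(path)
  tab$MENTHU_Score <- as.numeric(sprintf("%.2f", tab$MENTHU_Score))
  expect_equal(back, tab)
  # empty table: header-only file
  empty <- tab[0, ]
  write_menthu_csv(empty, path)
  expect_identical(length(readLines(path)), 1L)
})
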