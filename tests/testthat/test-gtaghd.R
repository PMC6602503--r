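toy_record <- function(n = 160, seed = 50, phase_origin = 0L) {
  random_locus(n, seed = seed, cds_phase_origin = phase_origin)
}

test_that("the guide pins the cut 17 nt in, on either strand", {
  rec <- toy_record()
  g <- substr(rec$sequence, 31, 50)              # forward hit at 0-based 30
  site <- locate_integration_site(rec, g)
  expect_equal(site$dsb_index, 30L + 17L)
  expect_identical(site$strand, "forward")

  # the reverse-complement guide targets the same bases from the other
  # strand; its PAM-proximal end is the left end of the forward window, so
  # the cut lands 17 nt from the window's right edge: 50 - 17 = 33
  site2 <- locate_integration_site(rec, reverse_complement(g))
  expect_equal(site2$dsb_index, 33L)
  expect_identical(site2$strand, "complement")
})

test_that("zero or multiple guide hits are hard errors", {
  rec <- toy_record()
  expect_error(locate_integration_site(rec, strrep("ACGT", 5)), "not found")
  dup <- seq_record(paste0(rec$sequence, rec$sequence))
  g <- substr(rec$sequence, 31, 50)
  expect_error(locate_integration_site(dup, g), "not unique")
  # a palindromic guide matching both strands at one locus counts twice
  pal <- "ACGTACGTACGTACGTACGT"
  rec_pal <- seq_record(paste0(strrep("TTAACC", 10), pal, strrep("GGAATT", 10)))
  expect_error(locate_integration_site(rec_pal, pal), "not unique")
  expect_error(locate_integration_site(rec, "ACGT"), "exactly 20 nt")
})

test_that("arms are exact genomic flanks and frame repair pads to phase 0", {
  for (shift in 0:2) {
    rec <- toy_record(phase_origin = shift)
    g <- substr(rec$sequence, 41, 60)
    site <- locate_integration_site(rec, g)       # dsb_index 57
    arms <- design_arms(rec, site, arm_length = 24)
    dsb <- site$dsb_index
    phase <- (dsb - shift) %% 3L
    pad <- if (phase == 0L) 0L else 3L - phase
    expect_equal(arms$frame_pad, pad)
    expect_true(arms$frame_pad %in% 0:2)
    expect_equal((phase + arms$frame_pad) %% 3L, 0L)
    # 5' arm = upstream flank plus pad bases duplicated from downstream
    expect_identical(arms$five_arm,
                     paste0(substr(rec$sequence, dsb - 23, dsb),
                            substr(rec$sequence, dsb + 1, dsb + pad)))
    expect_identical(arms$three_arm, substr(rec$sequence, dsb + 1, dsb + 24))
    # without the pad, the two arms reconstitute the genomic window
    expect_identical(paste0(substr(arms$five_arm, 1, 24), arms$three_arm),
                     substr(rec$sequence, dsb - 23, dsb + 24))
  }
})

test_that("unannotated input disables frame repair with a warning", {
  rec <- random_locus(120, seed = 3)
  site <- locate_integration_site(rec, substr(rec$sequence, 21, 40))
  expect_warning(arms <- design_arms(rec, site, 16), "frame repair disabled")
  expect_equal(arms$frame_pad, 0L)
})

test_that("an infeasible arm length names the maximum possible", {
  rec <- toy_record(n = 60)
  site <- list(dsb_index = 30L)
  expect_error(design_arms(rec, site, 48), "maximum")
  expect_error(design_arms(rec, site, 48), "30")
})

test_that("oligo pairs are reverse complements after adapter stripping", {
  rec <- toy_record()
  oligos <- gtaghd_design(rec, substr(rec$sequence, 41, 60), arm_length = 20,
                          series = "goldengate_demo")
  strip <- function(x, prefix) substring(x, nchar(prefix) + 1L)
  expect_identical(strip(oligos$five_prime_forward, "AAAA"),
                   reverse_complement(strip(oligos$five_prime_reverse, "TTTT")))
  expect_identical(strip(oligos$three_prime_forward, "GGGG"),
                   reverse_complement(strip(oligos$three_prime_reverse, "CCCC")))
  # 4-nt sticky adapters: oligo length = arm length (+pad) + 4
  expect_equal(nchar(oligos$three_prime_forward), 20L + 4L)
  expect_equal(nchar(oligos$five_prime_forward),
               20L + oligos$frame_pad + 4L)
  # arms are genomic flanks of the cut
  expect_identical(oligos$arms$three_arm,
                   substr(rec$sequence, 58, 77))

  # identity adapters: forward oligo is the arm itself
  blunt <- assemble_oligos(oligos$arms, series = "blunt")
  expect_identical(blunt$five_prime_forward, oligos$arms$five_arm)
  expect_identical(blunt$five_prime_reverse,
                   reverse_complement(oligos$arms$five_arm))

  # custom plasmid path: guide templating is mandatory and applied
  expect_error(assemble_oligos(oligos$arms, series = "custom"),
               "custom_guide")
  cg <- "GGACGTAGCTAGCTAGCTAA"
  custom <- assemble_oligos(oligos$arms, series = "custom", custom_guide = cg)
  expect_true(startsWith(custom$five_prime_forward, reverse_complement(cg)))
  expect_true(endsWith(custom$five_prime_reverse, cg))
  expect_error(assemble_oligos(oligos$arms, series = "nope"), "available")
})

test_that("outputs: labelled text file always, GenBank map when templated", {
  rec <- toy_record()
  oligos <- gtaghd_design(rec, substr(rec$sequence, 41, 60), arm_length = 20,
                          series = "goldengate_demo")
  pfx <- file.path(withr::local_tempdir(), "run")
  files <- write_oligo_outputs(oligos, pfx)
  txt <- readLines(paste0(pfx, "_oligos.txt"))
  seq_lines <- grep("^(5F|5R|3F|3R)\t", txt, value = TRUE)
  expect_equal(length(seq_lines), 4L)
  expect_identical(sub("\t.*", "", seq_lines), c("5F", "5R", "3F", "3R"))
  expect_identical(sub(".*\t", "", seq_lines[1]), oligos$five_prime_forward)

  map <- read_genbank(paste0(pfx, "_map.gb"))
  feats <- attr(map, "features")
  five <- feats[feats$label %in% "five_prime_homology_arm", ]
  three <- feats[feats$label %in% "three_prime_homology_arm", ]
  expect_equal(nrow(five), 1L)
  expect_equal(nrow(three), 1L)
  expect_identical(substr(map$sequence, five$start, five$end),
                   oligos$arms$five_arm)
  expect_identical(substr(map$sequence, three$start, three$end),
                   oligos$arms$three_arm)

  # no template: text only, warning logged
  blunt <- assemble_oligos(oligos$arms, series = "blunt")
  expect_warning(files2 <- write_oligo_outputs(blunt, paste0(pfx, "2")),
                 "no plasmid template")
  expect_identical(unclass(files2), paste0(pfx, "2_oligos.txt"))
})
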