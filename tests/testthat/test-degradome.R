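test_that("degradome profiles anchor tag counts at 5' positions", {
  tx <- make_transcripts(t1 = random_seq(200))
  tag <- substr(unclass(tx)[["t1"]], 51, 70)
  prof <- build_profile(tag_library(setNames(24L, tag)), tx)
  expect_identical(prof[["t1"]][51], 24L)
  expect_identical(sum(prof[["t1"]]), 24L)

  none <- build_profile(tag_library(setNames(3L, random_seq(20))), tx)
  expect_true(all(none[["t1"]] == 0L))
})

test_that("site finding matches a brute-force complementarity scan", {
  set.seed(23)
  for (rep in 1:5) {
    srna <- random_seq(21)
    tx <- random_seq(200)
    got <- find_sites(c(q = srna), tx, max_mm = 21, transcript_id = "t")
    ora <- oracle_site_scan(srna, tx)
    got <- got[order(got$start), ]
    expect_identical(nrow(got), nrow(ora))
    expect_identical(got$start, ora$start)
    expect_equal(got$mismatches, ora$mismatches)
    expect_equal(got$gu_pairs, ora$gu)
  }
})

test_that("site finding reports perfect and near sites with cleavage positions", {
  set.seed(24)
  srna <- random_seq(21)
  tx <- paste0(random_seq(80), revcomp(srna), random_seq(80))
  hits <- find_sites(c(mir = srna), tx, max_mm = 4, transcript_id = "t")
  expect_identical(hits$mismatches[1], 0)
  expect_identical(hits$start[1], 80L)
  expect_identical(hits$cleavage_pos[1], 80L + 21L - 10L)

  # three substitutions still reported; G:U wobbles discounted at 0.5
  site3 <- revcomp(srna)
  for (p in c(3, 9, 16)) {
    substr(site3, p, p) <- c(A = "C", C = "A", G = "A", U = "C")[substr(site3, p, p)]
  }
  tx3 <- paste0(random_seq(50), site3, random_seq(50))
  h3 <- find_sites(c(mir = srna), tx3, max_mm = 4, transcript_id = "t")
  expect_true(any(h3$start == 50L & h3$mismatches <= 3))
})

test_that("valid reads count degradome support opposite positions 9-11", {
  tx <- make_transcripts(t1 = random_seq(150))
  srna <- revcomp(substr(unclass(tx)[["t1"]], 61, 81))  # perfect site [60,81)
  site <- find_sites(c(mir = srna), unclass(tx)[["t1"]], max_mm = 0,
                     transcript_id = "t1")[1, ]
  expect_identical(site$cleavage_pos, 71L)

  prof <- list(t1 = integer(150))
  class(prof) <- "degradome_profile"
  prof[["t1"]][71 + 1] <- 24L          # canonical position (0-based 71)
  cv <- classify_valid_reads(site, prof)
  expect_identical(cv$valid_reads, 24L)
  expect_identical(cv$reads_at_10, 24L)

  prof2 <- list(t1 = integer(150))
  class(prof2) <- "degradome_profile"
  prof2[["t1"]][71 + 1 + 5] <- 10L     # 5 nt downstream: not valid
  cv2 <- classify_valid_reads(site, prof2)
  expect_identical(cv2$valid_reads, 0L)
  expect_identical(cv2$total_site_reads, 10L)
})

test_that("target validation applies the conserved and novel rules", {
  base <- data.frame(
    small_rna_id = c("c1", "c1", "c2", "n1", "n1"),
    transcript_id = "t1",
    start = c(10L, 40L, 70L, 100L, 130L),
    end = c(31L, 61L, 91L, 121L, 151L),
    mismatches = c(2, 5, 4, 2, 2),
    raw_mismatches = c(2L, 5L, 4L, 2L, 2L),
    gu_pairs = 0L,
    cleavage_pos = c(21L, 51L, 81L, 111L, 141L))
  prof <- list(t1 = integer(200))
  class(prof) <- "degradome_profile"
  prof[["t1"]][111 + 1] <- 7L  # degradome support only for the first n1 site
  fam <- c(c1 = "miR156", c2 = "miR160")
  out <- validate_targets(base, prof, fam)
  # conserved <4 mm kept even without degradome reads
  expect_true(any(out$small_rna_id == "c1" & out$start == 10 &
                  out$rule == "conserved_lt4"))
  # the same family's 5-mm site is blocked by its 2-mm site
  expect_false(any(out$small_rna_id == "c1" & out$start == 40))
  # a family whose best site has 4 mm keeps it via the fallback
  expect_true(any(out$small_rna_id == "c2" & out$rule == "conserved_fallback_4_5"))
  # novel sites need >= 1 valid read
  expect_true(any(out$small_rna_id == "n1" & out$start == 100))
  expect_false(any(out$small_rna_id == "n1" & out$start == 130))
})

test_that("the conserved fallback never outranks a lower-mismatch family site", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    fams <- sample(c("famA", "famB"), n, replace = TRUE)
    sites <- data.frame(
      small_rna_id = fams, transcript_id = "t",
      start = seq(0L, by = 30L, length.out = n),
      end = seq(0L, by = 30L, length.out = n) + 21L,
      mismatches = sample(0:5, n, replace = TRUE),
      raw_mismatches = 0L, gu_pairs = 0L,
      cleavage_pos = seq(0L, by = 30L, length.out = n) + 11L)
    prof <- list(t = integer(400))
    class(prof) <- "degradome_profile"
    fam_map <- c(famA = "famA", famB = "famB")
    out <- validate_targets(sites, prof, fam_map)
    for (f in unique(fams)) {
      fs <- out[out$family == f & !is.na(out$family), ]
      if (!nrow(fs)) next
      if (any(fs$rule == "conserved_fallback_4_5")) {
        expect_gte(min(sites$mismatches[fams == f]), 4)
      }
    }
  }
})

test_that("validation is monotone in the site mismatch budget", {
  set.seed(78)
  srna <- random_seq(21)
  tx <- random_seq(400)
  loose <- find_sites(c(q = srna), tx, max_mm = 8, transcript_id = "t")
  tight <- find_sites(c(q = srna), tx, max_mm = 4, transcript_id = "t")
  expect_true(all(tight$start %in% loose$start))
  expect_true(all(tight$mismatches <= 4))
})

test_that("t-plot tables mark cleavage positions 1-based", {
  prof <- list(t1 = c(0L, 0L, 9L, 0L, 2L))
  class(prof) <- "degradome_profile"
  sites <- data.frame(small_rna_id = "m", transcript_id = "t1",
                      cleavage_pos = 2L)
  tp <- tplot_data(prof, "t1", sites)
  expect_identical(tp$data$position, c(3L, 5L))
  expect_identical(tp$data$reads, c(9L, 2L))
  expect_identical(tp$markers$position, 3L)
  empty <- tplot_data(list(t1 = integer(10)) |> structure(class = "degradome_profile"),
                      "t1")
  expect_identical(nrow(empty$data), 0L)
})

test_that("TAS3 loci need both miR390 sites and sit in register", {
  d <- sim_design(n_transcripts = 15L, n_planted_hairpins = 0L,
                  n_planted_phased_loci = 0L, n_decoy_loci = 0L, n_tas3 = 3L,
                  seed = 26)
  sim <- gen_transcriptome(d)
  refs <- read_fasta(system.file("extdata", "tasiarf_reference.fa",
                                 package = "srnaphase"))
  mir390 <- "AAGCUCAGGAGGGAUAGCGCC"
  tas <- find_tas3(setNames(as.character(unclass(refs)), names(refs)),
                   mir390, sim$transcripts)
  tr <- sim$truth$tas3
  expect_identical(sort(unique(tas$transcript_id)),
                   sort(unique(tr$transcript_id)))
  expect_true(all(tas$register == 0L))
  expect_true(all(tas$transcript_id %in% tr$transcript_id))

  # single-site decoys: tasiARF without the 3' miR390 site, and a lone
  # miR390 site without tasiARF
  tasi <- as.character(unclass(refs))[1]
  dec <- make_transcripts(
    d1 = paste0(random_seq(60), revcomp(mir390), random_seq(20), tasi,
                random_seq(120)),
    d2 = paste0(random_seq(100), revcomp(mir390), random_seq(100)))
  expect_identical(nrow(find_tas3(setNames(tasi, "tasiARF_D7"), mir390, dec)),
                   0L)
})
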