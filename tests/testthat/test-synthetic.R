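test_that("the whole generator is byte-deterministic under a fixed seed", {
  d <- sim_design(n_transcripts = 12L, n_planted_hairpins = 3L,
                  n_planted_phased_loci = 2L, n_decoy_loci = 2L, n_tas3 = 1L,
                  seed = 7)
  a <- gen_transcriptome(d)
  b <- gen_transcriptome(d)
  expect_identical(a, b)
  expect_identical(gen_srna_library(a, d), gen_srna_library(b, d))
  expect_identical(gen_count_libraries(a, d)$counts,
                   gen_count_libraries(b, d)$counts)
  expect_identical(gen_degradome(a, d)$profiles, gen_degradome(b, d)$profiles)
  expect_identical(gen_phenotypes(20, seed = 7), gen_phenotypes(20, seed = 7))
})

test_that("planted features sit disjointly inside their transcripts", {
  d <- sim_design(n_transcripts = 25L, n_planted_hairpins = 8L,
                  n_planted_phased_loci = 4L, n_decoy_loci = 3L, n_tas3 = 2L,
                  seed = 15)
  sim <- gen_transcriptome(d)
  lens <- nchar(unclass(sim$transcripts))
  tr <- sim$truth
  spans <- rbind(
    data.frame(tx = tr$hairpins$transcript_id, s = tr$hairpins$start,
               e = tr$hairpins$end),
    data.frame(tx = tr$phased$transcript_id, s = tr$phased$site_start,
               e = tr$phased$cleavage_pos + 231L),
    data.frame(tx = tr$tas3$transcript_id, s = tr$tas3$five_start,
               e = tr$tas3$three_end))
  for (tx in unique(spans$tx)) {
    ss <- spans[spans$tx == tx, ]
    ss <- ss[order(ss$s), ]
    expect_true(all(ss$s >= 0))
    expect_true(all(ss$e <= lens[[tx]]))
    if (nrow(ss) > 1) expect_true(all(ss$s[-1] >= ss$e[-nrow(ss)]))
  }
  # planted sequences really are at the recorded coordinates
  seqs <- unclass(sim$transcripts)
  hp <- tr$hairpins
  for (i in seq_len(nrow(hp))) {
    expect_identical(substr(seqs[[hp$transcript_id[i]]],
                            hp$mature_start[i] + 1L, hp$mature_start[i] + 21L),
                     hp$mature[i])
  }
  ph <- tr$phased
  for (i in seq_len(nrow(ph))) {
    expect_identical(substr(seqs[[ph$transcript_id[i]]],
                            ph$site_start[i] + 1L, ph$site_end[i]),
                     revcomp(ph$trigger_seq[i]))
  }
})

test_that("a featureless design yields plain random transcripts", {
  d <- sim_design(n_transcripts = 3L, n_planted_hairpins = 0L,
                  n_planted_phased_loci = 0L, n_decoy_loci = 0L, n_tas3 = 0L,
                  seed = 2)
  sim <- gen_transcriptome(d)
  expect_identical(length(sim$transcripts), 3L)
  expect_null(sim$truth$hairpins)
  expect_null(sim$truth$phased)
  expect_identical(nrow(sim$truth$decoys), 0L)
})

test_that("sim_design validates its parameters", {
  expect_error(sim_design(group_fold_change = 0), "positive")
  expect_error(sim_design(nb_dispersion = -1), "positive")
  expect_error(sim_design(offtarget_frac = 1.4), "0, 1")
  expect_error(sim_design(n_transcripts = -2), "non-negative")
  bad <- diag(3); bad[1, 2] <- 0.5
  expect_error(sim_design(phenotype_corr = bad), "symmetric")
  neg <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(sim_design(phenotype_corr = neg), "definite")
})

test_that("phased-locus reads land on the register as configured", {
  set.seed(30)
  tx <- random_seq(500)
  pure <- gen_phased_locus(tx, 100L, n_cycles = 10L, depth = 4L,
                           offtarget_frac = 0, antisense_frac = 0)
  expect_true(all((pure$pos - 100L) %% 21L == 0))
  expect_identical(length(unique(pure$pos)), 10L)
  expect_identical(sum(pure$count), 40L)
  expect_identical(unique(substr(pure$tag, 1, 21) == pure$tag), TRUE)

  anti <- gen_phased_locus(tx, 100L, n_cycles = 10L, depth = 4L,
                           offtarget_frac = 0, antisense_frac = 1)
  eff <- map_effective_positions(anti)
  expect_true(all((eff$effective - 100L) %% 21L == 0))
  expect_true(all(anti$strand == "-"))

  expect_error(gen_phased_locus(tx, 400L, 10L, 4L), "fit")
  expect_error(gen_phased_locus(tx, 100L, 10L, 4L, offtarget_frac = 2),
               "0, 1")
})

test_that("pure off-target loci behave like the null", {
  set.seed(33)
  ps <- replicate(200, {
    reads <- gen_phased_locus(500L, 100L, n_cycles = 10L, depth = 5L,
                              offtarget_frac = 1, antisense_frac = 0)
    reads$effective <- reads$pos
    rel <- reads$effective - 100L
    n <- length(unique(rel))
    k <- length(unique(rel[rel %% 21 == 0] %/% 21))
    window_pvalue(n, k, 10L)
  })
  # fully off-register placement leaves the register empty: the test is
  # conservative there, P = 1 exactly
  expect_true(all(ps == 1))
})

test_that("count libraries carry the designed fold change and TRM coupling", {
  d <- sim_design(group_fold_change = 3, n_diff = 10L, n_mirnas = 100L,
                  nb_dispersion = 0.005, seed = 44)
  cl <- gen_count_libraries(NULL, d)
  y <- sweep(cl$counts, 2, cl$library_sizes / mean(cl$library_sizes), "/")
  # the law-of-large-numbers bound needs decent depth per spike
  spikes <- intersect(cl$diff_truth$mirna_id,
                      rownames(y)[rowMeans(y) >= 20])
  expect_gt(length(spikes), 2)
  ratio <- rowMeans(y[spikes, cl$groups == "Large"]) /
    rowMeans(y[spikes, cl$groups == "Small"])
  expect_true(all(ratio > 2 & ratio < 4))
  nulls <- setdiff(rownames(y), spikes)
  nr <- rowMeans(y[nulls, cl$groups == "Large"]) /
    rowMeans(y[nulls, cl$groups == "Small"])
  expect_lt(abs(median(nr) - 1), 0.3)
  # spiked abundance correlates positively with TRM
  r <- cor(as.numeric(y[spikes[1], ]), cl$trm)
  expect_gt(r, 0.5)
  d_bad <- d
  d_bad$n_libraries_per_group <- 1L
  expect_error(gen_count_libraries(NULL, d_bad), "at least 2")
})

test_that("degradome generation puts peaks at true cleavage sites", {
  d <- sim_design(n_transcripts = 15L, n_planted_hairpins = 3L,
                  n_planted_phased_loci = 2L, n_decoy_loci = 0L, n_tas3 = 1L,
                  degradome_background = 0, seed = 18)
  sim <- gen_transcriptome(d)
  deg <- gen_degradome(sim, d)
  tt <- sim$truth$targets
  for (i in seq_len(nrow(tt))) {
    expect_gte(deg$profiles[[tt$transcript_id[i]]][tt$cleavage_pos[i] + 1L],
               d$degradome_peak_depth)
  }
  # two sites on one transcript give two spikes
  two <- table(tt$transcript_id)
  if (any(two >= 2)) {
    tx <- names(two)[two >= 2][1]
    expect_gte(sum(deg$profiles[[tx]] >= d$degradome_peak_depth), 2L)
  }
  # zero-depth sites are invisible
  d0 <- sim_design(n_transcripts = 15L, n_planted_hairpins = 3L,
                   n_planted_phased_loci = 2L, n_decoy_loci = 0L, n_tas3 = 1L,
                   degradome_background = 0, degradome_peak_depth = 0L,
                   seed = 18)
  deg0 <- gen_degradome(sim, d0)
  expect_true(all(vapply(deg0$profiles, sum, numeric(1)) == 0))
})

test_that("phenotype tables realize the requested correlation structure", {
  ident <- diag(7)
  dimnames(ident) <- dimnames(default_trait_corr())
  ph_id <- gen_phenotypes(200, corr = ident, seed = 91)
  tc <- trait_correlations(ph_id[, -1])
  expect_true(all(abs(tc$r[upper.tri(tc$r)]) < 0.2))

  ph <- gen_phenotypes(500, seed = 92)
  expect_lt(abs(cor(ph$TRM, ph$TLA) - default_trait_corr()["TRM", "TLA"]),
            0.08)
  expect_true(all(ph$TRM > 0))
  expect_error(gen_phenotypes(1), "at least 2")
})

test_that("dinucleotide shuffling preserves the dinucleotide composition", {
  set.seed(95)
  for (i in 1:10) {
    s <- random_seq(120)
    sh <- dinucleotide_shuffle(s)
    expect_identical(nchar(sh), 120L)
    din <- function(x) {
      v <- strsplit(x, "")[[1]]
      sort(table(paste0(v[-length(v)], v[-1])))
    }
    expect_identical(din(sh), din(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
  }
})
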