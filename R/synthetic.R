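#' Simulation design for synthetic pipeline inputs
#'
#' Bundles every parameter of the synthetic-data generator. Defaults are
#' chosen to emulate a root small-RNA study at desk scale: a few dozen
#' transcripts carrying planted fold-back precursors, 21-nt phased loci
#' downstream of trigger sites, TAS3-style dual-site loci, degradome peaks
#' at canonical cleavage positions, negative-binomial count libraries with
#' a Small/Large biomass effect, and correlated phenotype tables.
#'
#' @param n_transcripts number of transcripts.
#' @param transcript_len_range min/max transcript length (nt).
#' @param n_planted_hairpins planted pre-miRNA hairpins.
#' @param n_planted_phased_loci planted phasiRNA loci (trigger site plus a
#'   10-cycle 21-nt register).
#' @param n_decoy_loci transcripts carrying only uniformly placed reads.
#' @param n_tas3 planted TAS3-style loci (dual miR390 sites flanking two
#'   reference tasiARF 21-mers, register 0).
#' @param phased_read_depth phased reads per 21-nt cycle.
#' @param offtarget_frac fraction of locus reads placed off register.
#' @param antisense_frac fraction of phased reads on the antisense strand.
#' @param background_read_rate background sRNA reads per transcript nt.
#' @param decoy_read_rate additional reads per nt scattered uniformly over
#'   decoy transcripts, on top of the global background stream. The
#'   default 0 makes decoys pure background-noise transcripts.
#' @param hairpin_mature_reads,hairpin_star_reads reads emitted for the
#'   mature and star tag of each planted hairpin.
#' @param n_libraries_per_group samples in each of Small and Large.
#' @param n_medium_libraries samples in the held-out Medium group.
#' @param group_fold_change Large/Small mean ratio of spiked miRNAs.
#' @param nb_dispersion negative-binomial dispersion (var = mu + phi mu^2).
#' @param n_mirnas rows of the simulated count matrix.
#' @param n_diff truly differential (spiked) miRNAs.
#' @param degradome_peak_depth degradome reads at each true cleavage site.
#' @param degradome_background Poisson background rate per position.
#' @param phenotype_corr trait correlation matrix (unit diagonal, PSD).
#' @param seed integer seed; every generator draws from it.
#' @return validated list of class `sim_design`.
#' @export
sim_design <- function(n_transcripts = 30L,
                       transcript_len_range = c(600L, 1200L),
                       n_planted_hairpins = 10L,
                       n_planted_phased_loci = 5L,
                       n_decoy_loci = 5L,
                       n_tas3 = 2L,
                       phased_read_depth = 10L,
                       offtarget_frac = 0.1,
                       antisense_frac = 0.3,
                       background_read_rate = 0.02,
                       decoy_read_rate = 0,
                       hairpin_mature_reads = 50L,
                       hairpin_star_reads = 12L,
                       n_libraries_per_group = 6L,
                       n_medium_libraries = 5L,
                       group_fold_change = 3,
                       nb_dispersion = 0.05,
                       n_mirnas = 300L,
                       n_diff = 20L,
                       degradome_peak_depth = 24L,
                       degradome_background = 0.05,
                       phenotype_corr = default_trait_corr(),
                       seed = 1L) {
  d <- as.list(environment())
  counts <- c("n_transcripts", "n_planted_hairpins", "n_planted_phased_loci",
              "n_decoy_loci", "n_tas3", "phased_read_depth",
              "hairpin_mature_reads", "hairpin_star_reads",
              "n_libraries_per_group", "n_medium_libraries", "n_mirnas",
              "n_diff", "degradome_peak_depth")
  for (f in counts) {
    if (is.na(d[[f]]) || d[[f]] < 0) stop(f, " must be a non-negative count")
  }
  if (d$group_fold_change <= 0) stop("group_fold_change must be positive")
  if (d$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  for (f in c("offtarget_frac", "antisense_frac")) {
    if (d[[f]] < 0 || d[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  check_corr(d$phenotype_corr)
  d$seed <- as.integer(seed)
  class(d) <- "sim_design"
  d
}

check_corr <- function(corr) {
  if (!isSymmetric(unname(corr)) || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("phenotype correlation matrix must be symmetric with unit diagonal")
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("phenotype correlation matrix must be positive semi-definite")
  }
  invisible(TRUE)
}

#' Default trait correlation structure
#'
#' One-factor (size) model over the seven traits TRM, RM, HT, MLL, MLW,
#' TLA, LN: `corr = L L' + diag(1 - L^2)` with loadings chosen so that
#' strongly size-linked traits (root masses, leaf area) correlate highly
#' with TRM (r(TRM, TLA) ~ 0.78) while leaf number is nearly independent.
#'
#' @return 7 x 7 correlation matrix.
#' @export
default_trait_corr <- function() {
  loadings <- c(TRM = 0.95, RM = 0.90, HT = 0.50, MLL = 0.65, MLW = 0.60,
                TLA = 0.82, LN = 0.15)
  corr <- outer(loadings, loadings)
  diag(corr) <- 1
  corr
}

#' Generate a synthetic pre-miRNA hairpin
#'
#' The precursor is `mature + loop + star`, where the star arm is the
#' reverse complement of mature positions 1-19 with
#' `mismatches_in_duplex` self-base substitutions at interior positions
#' (self-oppositions can never pair), followed by a 2-nt tail - the
#' canonical miRNA/miRNA* duplex with 2-nt 3' overhangs on both strands.
#' When the loop is long enough its last two bases are complementary to
#' mature positions 20-21, so a maximum-pairing fold pairs at least
#' `21 - mismatches_in_duplex` mature positions (and always at least
#' `21 - mismatches_in_duplex - 2`).
#'
#' @param mature 21-nt mature sequence.
#' @param mismatches_in_duplex substitutions planted in the duplex (0-6).
#' @param loop_len loop length in nt (>= 3).
#' @return list with `sequence`, `mature_span`, `star_span` (0-based
#'   half-open within the precursor), `star_tag` (the 21-nt star read) and
#'   `mismatch_positions` (mature positions, 1-based).
#' @export
gen_hairpin <- function(mature, mismatches_in_duplex = 0L, loop_len = 8L) {
  mature <- as_rna(mature)
  if (nchar(mature) != 21) stop("mature must be 21 nt")
  if (mismatches_in_duplex < 0 || mismatches_in_duplex > 6) {
    stop("mismatches_in_duplex must lie in 0..6")
  }
  if (loop_len < 3) stop("loop_len < 3 gives an unfoldable hairpin")
  m <- strsplit(mature, "")[[1]]
  star19 <- strsplit(revcomp(substr(mature, 1, 19)), "")[[1]]
  mm_pos <- integer(0)
  if (mismatches_in_duplex > 0) {
    # interior mature positions 5..15 map to star positions 20 - i
    mm_pos <- sort(sample(5:15, mismatches_in_duplex))
    star19[20L - mm_pos] <- m[mm_pos]   # self-opposition: never pairs
  }
  loop <- strsplit(random_rna(loop_len), "")[[1]]
  if (loop_len >= 5) {
    loop[loop_len] <- wc_complement(m[20])
    loop[loop_len - 1L] <- wc_complement(m[21])
  }
  tail2 <- random_rna(2)
  star_tag <- paste0(paste(star19, collapse = ""), tail2)
  sequence <- paste0(mature, paste(loop, collapse = ""), star_tag)
  list(sequence = sequence,
       mature_span = c(0L, 21L),
       star_span = c(21L + loop_len, 21L + loop_len + 21L),
       star_tag = star_tag,
       mismatch_positions = mm_pos)
}

#' Generate reads for one phased siRNA locus
#'
#' A fraction `1 - offtarget_frac` of the reads start exactly on the 21-nt
#' register (`register_start + 21 i`); of these, `antisense_frac` are
#' emitted on the antisense strand at the duplex-partner position
#' (`register - 2`), which maps back onto the register after the +2
#' antisense offset. Off-target reads start uniformly at non-register
#' positions of the locus span.
#'
#' @param transcript transcript sequence, or its length when tag sequences
#'   are not needed.
#' @param register_start 0-based start of the phased register.
#' @param n_cycles number of 21-nt cycles.
#' @param depth phased reads per cycle.
#' @param offtarget_frac fraction of reads placed off register.
#' @param antisense_frac fraction of phased reads on the antisense strand.
#' @return data.frame with `pos` (0-based leftmost coordinate), `strand`,
#'   `tag` (21-nt sequence, `NA` when only a length was supplied), `count`.
#' @export
gen_phased_locus <- function(transcript, register_start, n_cycles = 10L,
                             depth = 10L, offtarget_frac = 0,
                             antisense_frac = 0) {
  have_seq <- is.character(transcript)
  len <- if (have_seq) nchar(transcript) else as.integer(transcript)
  if (offtarget_frac < 0 || offtarget_frac > 1 ||
      antisense_frac < 0 || antisense_frac > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (register_start + 21L * n_cycles > len) {
    stop("register does not fit the transcript")
  }
  per_cycle <- as.integer(round((1 - offtarget_frac) * depth))
  reads <- list()
  for (i in seq_len(n_cycles) - 1L) {
    p <- register_start + 21L * i
    if (per_cycle == 0L) next
    n_anti <- as.integer(round(antisense_frac * per_cycle))
    if (per_cycle - n_anti > 0) {
      reads[[length(reads) + 1L]] <- data.frame(
        pos = p, strand = "+", count = per_cycle - n_anti)
    }
    if (n_anti > 0 && p >= 2L) {
      reads[[length(reads) + 1L]] <- data.frame(
        pos = p - 2L, strand = "-", count = n_anti)
    }
  }
  n_off <- n_cycles * depth - n_cycles * per_cycle
  if (n_off > 0) {
    span <- seq.int(register_start, register_start + 21L * n_cycles - 1L)
    span <- span[(span - register_start) %% 21L != 0L]
    span <- span[span + 21L <= len]
    off_pos <- sample(span, n_off, replace = TRUE)
    tab <- table(off_pos)
    reads[[length(reads) + 1L]] <- data.frame(
      pos = as.integer(names(tab)), strand = "+",
      count = as.integer(tab))
  }
  out <- if (length(reads)) do.call(rbind, reads) else
    data.frame(pos = integer(0), strand = character(0), count = integer(0))
  out$tag <- NA_character_
  if (have_seq && nrow(out)) {
    raw <- substring(transcript, out$pos + 1L, out$pos + 21L)
    out$tag <- ifelse(out$strand == "-", revcomp(raw), raw)
  }
  out[, c("pos", "strand", "tag", "count")]
}

#' Generate a synthetic transcriptome with planted small-RNA features
#'
#' Background sequence is i.i.d. uniform over A/C/G/U. Planted features
#' (hairpin precursors, phased-locus trigger sites with reserved downstream
#' registers, TAS3-style dual-site blocks, and complementary target sites
#' for the hairpin matures) are inserted at non-overlapping positions;
#' `n_decoy_loci` additional transcripts are reserved as pure-noise decoys.
#' All randomness flows from `design$seed`; the same design yields
#' byte-identical output.
#'
#' @param design a [sim_design()].
#' @return list with `transcripts` (a [transcript_set()]) and `truth`
#'   (hairpins, phased loci, target sites, TAS3 loci, decoys, and the
#'   trigger/mature sequences).
#' @export
gen_transcriptome <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  withr::with_seed(design$seed, gen_transcriptome_impl(design))
}

gen_transcriptome_impl <- function(design) {
  lr <- design$transcript_len_range
  n_tx <- design$n_transcripts
  lens <- sample(seq.int(lr[1], lr[2]), n_tx, replace = TRUE)
  ids <- sprintf("TX%03d", seq_len(n_tx))
  chars <- lapply(lens, function(l) sample(RNA_BASES, l, replace = TRUE))
  names(chars) <- ids
  occupied <- setNames(rep(list(data.frame(start = integer(0),
                                           end = integer(0))), n_tx), ids)
  reserved_tx <- character(0)

  place <- function(width, tail_reserve = 0, exclude = reserved_tx,
                    pad = 10L, guard = 0L) {
    for (try in 1:500) {
      tx <- sample(setdiff(ids, exclude), 1)
      len <- lens[match(tx, ids)]
      if (len < width + tail_reserve + 2L * pad) next
      start <- sample.int(len - width - tail_reserve - pad, 1) - 1L + pad
      occ <- occupied[[tx]]
      lo <- start - pad
      hi <- start + width + tail_reserve + pad
      if (nrow(occ) && any(occ$end > lo & occ$start < hi)) next
      occupied[[tx]] <<- rbind(occ, data.frame(
        start = start - guard,
        end = start + width + tail_reserve + guard))
      return(list(tx = tx, start = start))
    }
    stop("could not place a ", width,
         "-nt feature without overlap; use longer or more transcripts")
  }
  unplace <- function(tx) {
    occupied[[tx]] <<- occupied[[tx]][-nrow(occupied[[tx]]), , drop = FALSE]
  }
  insert <- function(tx, start, seq) {
    chars[[tx]][seq.int(start + 1L, start + nchar(seq))] <<-
      strsplit(seq, "")[[1]]
  }

  # decoy transcripts: uniformly covered by reads, no planted signal
  decoys <- data.frame(transcript_id = character(0),
                       region_start = integer(0), region_end = integer(0))
  if (design$n_decoy_loci > 0) {
    cand <- ids[lens >= 300L]
    dec <- sample(cand, min(design$n_decoy_loci, length(cand)))
    reserved_tx <- dec
    decoys <- data.frame(
      transcript_id = dec,
      region_start = 20L,
      region_end = lens[match(dec, ids)] - 20L)
  }

  # hairpin precursors, embedded in a 10-nt lower stem as in real
  # fold-backs. A random duplex dropped into random flanks does not always
  # fold cleanly under the maximum-pairing model, so candidates are
  # resampled until the planted flanked window passes the precursor
  # filters - the generator only plants bona fide precursors, mirroring
  # the closure property the discovery stage is tested against. Hairpin
  # windows are guarded so no later feature lands within flank range.
  hairpins <- list()
  stem_ext <- 10L
  flank <- 150L
  for (i in seq_len(design$n_planted_hairpins)) {
    done <- FALSE
    for (attempt in 1:30) {
      mature <- random_rna(21)
      mm <- sample(0:2, 1)
      hp <- gen_hairpin(mature, mm, loop_len = 8L)
      ext <- random_rna(stem_ext)
      planted <- paste0(ext, hp$sequence, revcomp(ext))
      w <- nchar(planted)
      loc <- place(w, pad = flank + 10L, guard = flank)
      saved <- chars[[loc$tx]][seq.int(loc$start + 1L, loc$start + w)]
      insert(loc$tx, loc$start, planted)
      m_start <- loc$start + stem_ext
      tx_seq <- paste(chars[[loc$tx]], collapse = "")
      win <- extract_flanks(tx_seq, c(m_start, m_start + 21L), flank)
      cand <- hairpin_candidate(loc$tx, win$start, win$sequence,
                                fold(win$sequence),
                                c(win$mature_offset, win$mature_offset + 21L))
      cand <- mircheck_filter(hairpin_filter(cand))
      if (cand$verdicts$hairpin && cand$verdicts$mircheck) {
        hairpins[[i]] <- data.frame(
          name = sprintf("hp%02d", i), transcript_id = loc$tx,
          start = loc$start, end = loc$start + w,
          mature = mature, star_tag = hp$star_tag, duplex_mm = mm,
          mature_start = m_start,
          star_start = m_start + hp$star_span[1])
        done <- TRUE
        break
      }
      chars[[loc$tx]][seq.int(loc$start + 1L, loc$start + w)] <- saved
      unplace(loc$tx)
    }
    if (!done) stop("could not plant a clean hairpin after 30 attempts")
  }
  hairpins <- if (length(hairpins)) do.call(rbind, hairpins) else NULL

  # phased loci: trigger complementary site + reserved downstream register;
  # one locus per transcript so each call is attributable to its trigger
  phased <- list()
  triggers <- list()
  phased_tx <- character(0)
  for (i in seq_len(design$n_planted_phased_loci)) {
    trig <- random_rna(21)
    # site span 21 nt; cleavage opposite trigger position 10 = start + 11;
    # reserve 10 cycles + one phase beyond the site
    loc <- place(21L, tail_reserve = 11L + 210L + 21L,
                 exclude = c(reserved_tx, phased_tx))
    phased_tx <- c(phased_tx, loc$tx)
    insert(loc$tx, loc$start, revcomp(trig))
    cleave <- loc$start + 11L
    trig_id <- sprintf("trig%02d", i)
    triggers[[i]] <- setNames(trig, trig_id)
    phased[[i]] <- data.frame(
      locus_id = sprintf("phas%02d", i), transcript_id = loc$tx,
      trigger_id = trig_id, trigger_seq = trig,
      site_start = loc$start, site_end = loc$start + 21L,
      cleavage_pos = cleave)
  }
  phased <- if (length(phased)) do.call(rbind, phased) else NULL

  # complementary target sites for the hairpin matures
  targets <- list()
  if (!is.null(hairpins)) {
    for (i in seq_len(nrow(hairpins))) {
      loc <- place(21L, tail_reserve = 21L)
      insert(loc$tx, loc$start, revcomp(hairpins$mature[i]))
      targets[[length(targets) + 1L]] <- data.frame(
        small_rna_id = hairpins$name[i], sequence = hairpins$mature[i],
        transcript_id = loc$tx, site_start = loc$start,
        site_end = loc$start + 21L, cleavage_pos = loc$start + 11L)
    }
  }
  if (!is.null(phased)) {
    for (i in seq_len(nrow(phased))) {
      targets[[length(targets) + 1L]] <- data.frame(
        small_rna_id = phased$trigger_id[i],
        sequence = phased$trigger_seq[i],
        transcript_id = phased$transcript_id[i],
        site_start = phased$site_start[i], site_end = phased$site_end[i],
        cleavage_pos = phased$cleavage_pos[i])
    }
  }
  targets <- if (length(targets)) do.call(rbind, targets) else NULL

  # TAS3-style loci: [5' site][gap][tasiARF x2][gap][3' site], register 0
  refs <- tasiarf_reference()
  mir390 <- mir390_reference()
  tas3 <- list()
  for (i in seq_len(design$n_tas3)) {
    gap1 <- 20L
    block <- paste0(revcomp(mir390), random_rna(gap1),
                    refs[["tasiARF_D7"]], refs[["tasiARF_D8"]])
    t_start_rel <- 21L + gap1
    cleave_rel <- t_start_rel + 63L       # 3 cycles past the tasiARF start
    site3_rel <- cleave_rel - 11L
    block <- paste0(block, random_rna(site3_rel - nchar(block)))
    block <- paste0(block, revcomp(mir390))
    loc <- place(nchar(block), tail_reserve = 21L)
    insert(loc$tx, loc$start, block)
    tas3[[i]] <- data.frame(
      transcript_id = loc$tx, block_start = loc$start,
      tasi_start = loc$start + t_start_rel,
      five_start = loc$start, five_end = loc$start + 21L,
      three_start = loc$start + site3_rel,
      three_end = loc$start + site3_rel + 21L,
      cleavage_pos = loc$start + cleave_rel,
      register = 0L)
  }
  tas3 <- if (length(tas3)) do.call(rbind, tas3) else NULL

  seqs <- vapply(chars, paste, character(1), collapse = "")
  transcripts <- transcript_set(seqs)
  truth <- list(hairpins = hairpins, phased = phased, targets = targets,
                tas3 = tas3, decoys = decoys,
                triggers = if (length(triggers)) unlist(triggers) else
                  character(0))
  list(transcripts = transcripts, truth = truth)
}

# canonical Arabidopsis TAS3 tasiARF 21-mers (5'D7(+)/5'D8(+)) and the
# miR390 mature; shipped as the default, user-replaceable reference set
tasiarf_reference <- function() {
  path <- system.file("extdata", "tasiarf_reference.fa",
                      package = "srnaphase")
  if (nzchar(path)) {
    refs <- read_fasta(path)
    setNames(as.character(unclass(refs)), names(refs))
  } else {
    c(tasiARF_D7 = "UUCUUGACCUUGUAAGACCCC",
      tasiARF_D8 = "UUCUUGACCUUGUAAGGCCUU")
  }
}

mir390_reference <- function() {
  "AAGCUCAGGAGGGAUAGCGCC"
}

#' Generate a collapsed sRNA library from planted truth
#'
#' Emits mature/star reads for every planted hairpin, phased reads for
#' every phased locus (via [gen_phased_locus()]), uniform reads over decoy
#' regions, and Poisson background reads over all transcripts, then
#' collapses them into a [tag_library()].
#'
#' @param sim output of [gen_transcriptome()].
#' @param design the [sim_design()].
#' @param sample_id sample label.
#' @return a [tag_library()].
#' @export
gen_srna_library <- function(sim, design, sample_id = "sim") {
  withr::with_seed(design$seed + 11L, {
    seqs <- unclass(sim$transcripts)
    truth <- sim$truth
    entries <- list()
    add <- function(tag, count) {
      entries[[length(entries) + 1L]] <<- data.frame(tag = tag,
                                                     count = count)
    }
    if (!is.null(truth$hairpins)) {
      for (i in seq_len(nrow(truth$hairpins))) {
        add(truth$hairpins$mature[i], design$hairpin_mature_reads)
        add(truth$hairpins$star_tag[i], design$hairpin_star_reads)
      }
    }
    if (!is.null(truth$phased)) {
      for (i in seq_len(nrow(truth$phased))) {
        tx <- truth$phased$transcript_id[i]
        reads <- gen_phased_locus(
          seqs[[tx]], truth$phased$cleavage_pos[i], n_cycles = 10L,
          depth = design$phased_read_depth,
          offtarget_frac = design$offtarget_frac,
          antisense_frac = design$antisense_frac)
        if (nrow(reads)) add(reads$tag, reads$count)
      }
    }
    # background/decoy reads draw their lengths from the bimodal 20-24 nt
    # distribution typical of plant sRNA libraries (21- and 24-nt peaks);
    # only the 21-mers are phasing-eligible downstream
    bg_lengths <- function(n) {
      sample(20:24, n, replace = TRUE,
             prob = c(0.15, 0.30, 0.10, 0.10, 0.35))
    }
    rate <- if (is.null(design$decoy_read_rate)) 0 else design$decoy_read_rate
    if (nrow(truth$decoys) && rate > 0) {
      for (i in seq_len(nrow(truth$decoys))) {
        tx <- truth$decoys$transcript_id[i]
        lo <- truth$decoys$region_start[i]
        hi <- truth$decoys$region_end[i] - 24L
        n_reads <- max(1L, round(rate * (hi - lo)))
        pos <- sample(seq.int(lo, hi), n_reads, replace = TRUE)
        lens_r <- bg_lengths(n_reads)
        df <- aggregate(cnt ~ tag,
                        data = data.frame(tag = substring(seqs[[tx]],
                                                          pos + 1L,
                                                          pos + lens_r),
                                          cnt = 1L), sum)
        add(df$tag, df$cnt)
      }
    }
    if (design$background_read_rate > 0) {
      for (tx in names(seqs)) {
        len <- nchar(seqs[[tx]])
        n_bg <- rpois(1, design$background_read_rate * len)
        if (n_bg == 0) next
        pos <- sample.int(len - 24L, n_bg, replace = TRUE) - 1L
        lens_r <- bg_lengths(n_bg)
        df <- aggregate(cnt ~ tag,
                        data = data.frame(tag = substring(seqs[[tx]],
                                                          pos + 1L,
                                                          pos + lens_r),
                                          cnt = 1L), sum)
        add(df$tag, df$cnt)
      }
    }
    if (!length(entries)) {
      return(tag_library(setNames(integer(0), character(0)), sample_id))
    }
    df <- do.call(rbind, entries)
    cnt <- tapply(df$count, df$tag, sum)
    tag_library(setNames(as.integer(cnt), names(cnt)), sample_id)
  })
}

#' Generate negative-binomial count libraries with a biomass effect
#'
#' Counts follow a negative binomial with variance `mu + phi mu^2` and
#' per-sample library sizes. TRM values are drawn per group; spiked miRNAs
#' scale smoothly with TRM so that the Large/Small mean ratio equals the
#' design fold change and spiked abundances correlate positively with TRM.
#'
#' @param sim output of [gen_transcriptome()] (hairpin names seed the
#'   miRNA ids), or `NULL` for ids `mir001...`.
#' @param design the [sim_design()].
#' @return list with `counts` (miRNA x sample), `library_sizes`, `groups`
#'   (factor Small/Medium/Large), `trm` and `diff_truth`.
#' @export
gen_count_libraries <- function(sim, design) {
  if (design$n_libraries_per_group < 2) {
    stop("need at least 2 libraries per group")
  }
  withr::with_seed(design$seed + 22L, {
    n_g <- design$n_libraries_per_group
    n_m <- design$n_medium_libraries
    groups <- factor(rep(c("Small", "Medium", "Large"), c(n_g, n_m, n_g)),
                     levels = c("Small", "Medium", "Large"))
    n_lib <- length(groups)
    trm <- c(runif(n_g, 12, 20), runif(n_m, 26, 34), runif(n_g, 40, 48))
    lib_sizes <- round(runif(n_lib, 8e5, 1.2e6))
    hp_names <- if (!is.null(sim) && !is.null(sim$truth$hairpins)) {
      sim$truth$hairpins$name
    } else {
      character(0)
    }
    n_mir <- max(design$n_mirnas, length(hp_names))
    ids <- c(hp_names,
             sprintf("mir%03d", seq_len(n_mir - length(hp_names))))
    base <- stats::rlnorm(n_mir, meanlog = log(30), sdlog = 1.2)
    spiked <- if (design$n_diff > 0) {
      sample(ids, min(design$n_diff, n_mir))
    } else {
      character(0)
    }
    mean_l <- mean(trm[groups == "Large"])
    mean_s <- mean(trm[groups == "Small"])
    slope <- log(design$group_fold_change) / (mean_l - mean_s)
    counts <- matrix(0L, n_mir, n_lib, dimnames = list(ids, NULL))
    size <- 1 / design$nb_dispersion
    for (j in seq_len(n_lib)) {
      mult <- ifelse(ids %in% spiked,
                     exp(slope * (trm[j] - (mean_l + mean_s) / 2)), 1)
      mu <- base * mult * lib_sizes[j] / 1e6
      counts[, j] <- rnbinom(n_mir, mu = mu, size = size)
    }
    colnames(counts) <- sprintf("lib%02d", seq_len(n_lib))
    diff_truth <- if (length(spiked)) {
      data.frame(mirna_id = spiked, direction = "up",
                 fold_change = design$group_fold_change)
    } else {
      data.frame(mirna_id = character(0), direction = character(0),
                 fold_change = numeric(0))
    }
    list(counts = counts, library_sizes = lib_sizes, groups = groups,
         trm = setNames(trm, colnames(counts)),
         diff_truth = diff_truth)
  })
}

#' Generate degradome tags and 5'-end profiles
#'
#' Every true target site receives `degradome_peak_depth` reads whose 5'
#' ends sit at the cleavage position (between site positions 10 and 11);
#' Poisson background reads are scattered over all positions. Tags are
#' 20-nt 5'-anchored fragments extracted from the transcripts, and the
#' returned profile is built from the tags through [build_profile()], so
#' tags and profile are consistent by construction.
#'
#' @param sim output of [gen_transcriptome()].
#' @param design the [sim_design()].
#' @return list with `tags` (a [tag_library()]) and `profiles`
#'   (a `degradome_profile`).
#' @export
gen_degradome <- function(sim, design) {
  withr::with_seed(design$seed + 33L, {
    seqs <- unclass(sim$transcripts)
    entries <- list()
    frag <- function(tx, pos) substring(seqs[[tx]], pos + 1L, pos + 20L)
    truth <- sim$truth
    peaks <- rbind(
      if (!is.null(truth$targets))
        truth$targets[, c("transcript_id", "cleavage_pos")],
      if (!is.null(truth$tas3))
        truth$tas3[, c("transcript_id", "cleavage_pos")])
    if (!is.null(peaks) && design$degradome_peak_depth > 0) {
      for (r in seq_len(nrow(peaks))) {
        entries[[length(entries) + 1L]] <- data.frame(
          tag = frag(peaks$transcript_id[r], peaks$cleavage_pos[r]),
          count = design$degradome_peak_depth)
      }
    }
    if (design$degradome_background > 0) {
      for (tx in names(seqs)) {
        len <- nchar(seqs[[tx]])
        bg <- rpois(len - 20L, design$degradome_background)
        nz <- which(bg > 0)
        if (!length(nz)) next
        entries[[length(entries) + 1L]] <- data.frame(
          tag = frag(tx, nz - 1L), count = bg[nz])
      }
    }
    tags <- if (length(entries)) {
      df <- do.call(rbind, entries)
      cnt <- tapply(df$count, df$tag, sum)
      tag_library(setNames(as.integer(cnt), names(cnt)), "degradome")
    } else {
      tag_library(setNames(integer(0), character(0)), "degradome")
    }
    list(tags = tags, profiles = build_profile(tags, sim$transcripts))
  })
}

#' Generate a correlated phenotype table
#'
#' Rows are drawn from a multivariate normal with the requested correlation
#' matrix (Gaussian model; truncation to a small positive floor only at
#' output, so mild truncation barely disturbs the target correlations).
#'
#' @param n_plants number of plants (>= 2).
#' @param corr trait correlation matrix; defaults to
#'   [default_trait_corr()].
#' @param means,sds per-trait means and standard deviations; defaults are
#'   field-plausible values for TRM/RM (g), HT/MLL/MLW (cm), TLA (cm^2)
#'   and LN (count).
#' @param seed optional seed (uses the current RNG state when `NULL`).
#' @return data.frame with `plant_id` and one column per trait.
#' @export
gen_phenotypes <- function(n_plants, corr = default_trait_corr(),
                           means = NULL, sds = NULL, seed = NULL) {
  if (n_plants < 2) stop("n_plants must be at least 2")
  check_corr(corr)
  traits <- colnames(corr)
  if (is.null(traits)) {
    traits <- paste0("trait", seq_len(ncol(corr)))
    dimnames(corr) <- list(traits, traits)
  }
  if (is.null(means)) {
    means <- c(TRM = 30, RM = 25, HT = 30, MLL = 12, MLW = 4, TLA = 400,
               LN = 14)[traits]
    means[is.na(means)] <- 10
  }
  if (is.null(sds)) {
    sds <- c(TRM = 12, RM = 10, HT = 6, MLL = 2.5, MLW = 0.8, TLA = 120,
             LN = 3)[traits]
    sds[is.na(sds)] <- 2
  }
  draw <- function() {
    sigma <- diag(sds) %*% corr %*% diag(sds)
    x <- MASS::mvrnorm(n_plants, mu = means, Sigma = sigma)
    x <- pmax(x, 0.01)
    out <- as.data.frame(x)
    names(out) <- traits
    cbind(data.frame(plant_id = sprintf("plant%03d", seq_len(n_plants))),
          out)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes the sequence while preserving its
#' exact dinucleotide composition (random Eulerian walk on the transition
#' graph). Used to build realistic decoys for hairpin discovery.
#'
#' @param sequence RNA string.
#' @return shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(as_rna(sequence), "")[[1]]
  n <- length(s)
  if (n < 3) return(sequence)
  vertices <- unique(s)
  edges <- lapply(setNames(vertices, vertices),
                  function(v) s[which(s[-n] == v) + 1L])
  last_v <- s[n]
  for (try in 1:1000) {
    # pick a random "last edge" per vertex (except the final one) and
    # keep only choices whose last-edge graph reaches the final vertex
    last_edge <- vapply(vertices, function(v) {
      if (v == last_v) NA_character_ else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in vertices) {
      if (v == last_v) next
      cur <- v
      for (step in seq_along(vertices)) {
        cur <- last_edge[[cur]]
        if (is.na(cur) || cur == last_v) break
      }
      if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
    }
    if (!ok) next
    walk_edges <- lapply(setNames(vertices, vertices), function(v) {
      e <- edges[[v]]
      if (v == last_v) return(sample(e))
      idx <- which(e == last_edge[[v]])[1]
      rest <- e[-idx]
      c(if (length(rest)) sample(rest), e[idx])
    })
    out <- character(n)
    out[1] <- s[1]
    ptr <- setNames(rep(1L, length(vertices)), vertices)
    cur <- s[1]
    for (i in 2:n) {
      e <- walk_edges[[cur]]
      if (ptr[[cur]] > length(e)) { ok <- FALSE; break }
      nxt <- e[ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok && all(nzchar(out))) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian walk")
}
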