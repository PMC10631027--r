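# Fully synthetic reference genomes, methylomes and read sets with the
# statistical structure the pipeline assumes: CpG-dense loci whose
# methylation state separates tumor from non-tumor DNA, fragment sampling,
# cytosine conversion of unmethylated C to T, and cfDNA samples carrying a
# stated ctDNA fraction.

#' Synthetic-data configuration
#'
#' Defaults are sized so the full pipeline (DMR discovery, denoising,
#' training, scoring) runs in minutes on one CPU: 20 regions of 5 kb with
#' one planted CpG-dense locus each (12 tumor-hypomethylated, repeat-like;
#' 8 tumor-hypermethylated, promoter-like), 10 tumor / para-tumor tissue
#' pairs, 6 healthy-reference cfDNA samples, a 30-individual validation
#' cohort, and 2,000 reads per sample. Class methylation probabilities are
#' far apart by default so tests probe pipeline correctness rather than
#' statistical power.
#'
#' @param n_regions,region_len reference geometry.
#' @param locus_len planted locus length in bp.
#' @param n_hypo_dmr_loci,n_hyper_dmr_loci numbers of planted loci (their
#'   sum must not exceed `n_regions`; one locus per region, centred).
#' @param cpg_density_background,cpg_density_locus probability that a
#'   position starts a CpG outside / inside planted loci.
#' @param meth_params per-locus-class methylation probability for each read
#'   class (`healthy`, `LD`, `tumor`).
#' @param flip_noise per-CpG probability of flipping the drawn methylation
#'   state (biological + calling noise).
#' @param frag_len fragment length range in bp (min must be >= 36, the
#'   clean-read cutoff).
#' @param conversion_completeness probability that an unmethylated C reads
#'   as T after enzymatic conversion.
#' @param seq_error per-base sequencing error rate.
#' @param n_tissue_pairs,n_healthy_ref,n_val_healthy,n_val_ld,n_val_hcc
#'   cohort sizes (tissue pairs; healthy cfDNA used for bounds and label-0
#'   training; validation negatives and positives).
#' @param reads_per_sample reads per sample.
#' @param tumor_purity fraction of tumor-cell reads in tumor tissue.
#' @param ctdna_fractions ctDNA fractions for positive cfDNA samples
#'   (recycled over samples).
#' @param seed master seed; all outputs are deterministic given it.
#' @return a config list.
#' @export
synth_config <- function(n_regions = 20, region_len = 5000, locus_len = 400,
                         n_hypo_dmr_loci = 12, n_hyper_dmr_loci = 8,
                         cpg_density_background = 0.01,
                         cpg_density_locus = 0.10,
                         meth_params = list(
                           hypo = c(healthy = 0.90, LD = 0.90, tumor = 0.10),
                           hyper = c(healthy = 0.10, LD = 0.10, tumor = 0.90),
                           background = c(healthy = 0.75, LD = 0.75, tumor = 0.75)),
                         flip_noise = 0.02, frag_len = c(100, 290),
                         conversion_completeness = 0.995, seq_error = 0.002,
                         n_tissue_pairs = 10, n_healthy_ref = 6,
                         n_val_healthy = 8, n_val_ld = 7, n_val_hcc = 15,
                         reads_per_sample = 2000, tumor_purity = 0.8,
                         ctdna_fractions = c(0.10, 0.15, 0.20), seed = 1) {
  cfg <- as.list(environment())
  if (n_hypo_dmr_loci + n_hyper_dmr_loci > n_regions)
    stop("more planted loci than regions", call. = FALSE)
  if (frag_len[1] < 36)
    stop("fragment length below the 36 bp clean-read cutoff", call. = FALSE)
  probs <- unlist(meth_params)
  stopifnot(all(probs >= 0 & probs <= 1))
  cfg
}

#' Generate a synthetic reference with planted CpG-dense loci
#'
#' Each region is random sequence with sparse background CpGs; the planted
#' locus (centred in the region) has elevated CpG density. All "CG"
#' dinucleotides of the final sequence — planted or accidental — are CpG
#' sites.
#'
#' @param config a [synth_config].
#' @return list with `seqs` (named character vector of region sequences),
#'   `chars` (the same, pre-split), `cpg_sites` (per-region sorted 0-based C
#'   coordinates) and `truth` (data.table `chrom`, `locus_start`,
#'   `locus_end`, `class`).
#' @export
synth_reference <- function(config) {
  with_seed(config$seed, {
    classes <- c(rep("hypo", config$n_hypo_dmr_loci),
                 rep("hyper", config$n_hyper_dmr_loci),
                 rep(NA_character_,
                     config$n_regions - config$n_hypo_dmr_loci -
                       config$n_hyper_dmr_loci))
    len <- config$region_len
    lstart <- as.integer((len - config$locus_len) / 2)
    lend <- lstart + config$locus_len
    seqs <- character(config$n_regions)
    chars_list <- vector("list", config$n_regions)
    sites_list <- vector("list", config$n_regions)
    truth <- list()
    for (r in seq_len(config$n_regions)) {
      chrom <- sprintf("region%02d", r)
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3))
      dens <- rep(config$cpg_density_background, len - 1L)
      if (!is.na(classes[r]))
        dens[(lstart + 1L):lend] <- config$cpg_density_locus
      cand <- which(runif(len - 1L) < dens)            # 1-based C positions
      keep <- cand[c(TRUE, diff(cand) >= 2L)]
      # greedy spacing pass (diff on the filtered set can still be 1)
      if (length(keep) > 1L) {
        ok <- logical(length(keep)); last <- -10L
        for (i in seq_along(keep)) {
          if (keep[i] - last >= 2L) { ok[i] <- TRUE; last <- keep[i] }
        }
        keep <- keep[ok]
      }
      chars[keep] <- "C"; chars[keep + 1L] <- "G"
      # deplete accidental CpGs so site density matches the configuration
      # (genomes are CpG-depleted outside islands): any CG whose C was not
      # planted loses its G
      hits <- gregexpr("CG", paste(chars, collapse = ""), fixed = TRUE)[[1]]
      if (hits[1] != -1L) {
        extra <- setdiff(as.integer(hits), keep)
        if (length(extra))
          chars[extra + 1L] <- sample(c("A", "T"), length(extra), TRUE)
      }
      seqs[r] <- paste(chars, collapse = "")
      chars_list[[r]] <- chars
      hits <- gregexpr("CG", seqs[r], fixed = TRUE)[[1]]
      sites_list[[r]] <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
      if (!is.na(classes[r]))
        truth[[chrom]] <- data.table(chrom = chrom, locus_start = lstart,
                                     locus_end = lend, class = classes[r])
    }
    names(seqs) <- names(chars_list) <- names(sites_list) <-
      sprintf("region%02d", seq_len(config$n_regions))
    list(seqs = seqs, chars = chars_list, cpg_sites = sites_list,
         truth = rbindlist(truth), config = config)
  })
}

#' Simulate a methyl-seq sample from the synthetic reference
#'
#' Fragments are sampled uniformly (position and length); each read is drawn
#' from the tumor methylome with probability `tumor_fraction` and from the
#' `base_class` methylome otherwise. Per-CpG methylation states are Bernoulli
#' draws from the class/locus probability, flipped with `flip_noise`;
#' unmethylated cytosines (CpG and non-CpG) convert to T with probability
#' `conversion_completeness`; sequencing errors substitute random bases.
#' CpG calls are then derived from the converted sequence (C..G = methylated,
#' T..G = unmethylated; sites destroyed by errors are omitted), so every
#' emitted call is consistent with the read's converted sequence.
#'
#' @param ref a [synth_reference].
#' @param sample_id sample name.
#' @param n_reads number of fragments.
#' @param base_class methylome for non-tumor reads (`healthy` or `LD`).
#' @param tumor_fraction probability a read comes from the tumor methylome
#'   (tissue purity, or the ctDNA fraction of a cfDNA sample).
#' @param seed sample-level seed.
#' @return a [methyl_reads] table with a `source` column (`tumor` /
#'   `base_class`).
#' @export
synth_reads <- function(ref, sample_id, n_reads, base_class = "healthy",
                        tumor_fraction = 0, seed = 1) {
  config <- ref$config
  truth_by_chrom <- if (nrow(ref$truth))
    split(ref$truth, by = "chrom") else list()
  with_seed(seed, {
    chroms <- names(ref$seqs)
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      chrom <- sample(chroms, 1L)
      flen <- sample(config$frag_len[1]:config$frag_len[2], 1L)
      start <- sample.int(config$region_len - flen + 1L, 1L) - 1L
      end <- start + flen
      is_tumor <- runif(1) < tumor_fraction
      cls <- if (is_tumor) "tumor" else base_class
      chars <- ref$chars[[chrom]][(start + 1L):end]
      sites <- ref$cpg_sites[[chrom]]
      sites <- sites[sites >= start & sites + 1L < end]
      # locus class of each site (NA = background)
      locus_class <- rep(NA_character_, length(sites))
      tr <- truth_by_chrom[[chrom]]
      if (!is.null(tr) && nrow(tr) == 1L)
        locus_class[sites >= tr$locus_start & sites < tr$locus_end] <- tr$class
      pmeth <- ifelse(is.na(locus_class),
                      config$meth_params$background[cls],
                      ifelse(locus_class == "hypo",
                             config$meth_params$hypo[cls],
                             config$meth_params$hyper[cls]))
      state <- runif(length(sites)) < pmeth
      flip <- runif(length(sites)) < config$flip_noise
      state <- xor(state, flip)
      # conversion: unmethylated Cs (CpG or not) read as T
      off <- sites - start + 1L                    # 1-based C offsets
      c_pos <- which(chars == "C")
      conv <- runif(length(c_pos)) < config$conversion_completeness
      meth_off <- off[state]
      convert <- setdiff(c_pos[conv], meth_off)
      chars[convert] <- "T"
      # sequencing errors
      err <- which(runif(length(chars)) < config$seq_error)
      if (length(err))
        chars[err] <- vapply(chars[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      # derive calls from the converted sequence
      b1 <- chars[off]; b2 <- chars[off + 1L]
      keep <- b2 == "G" & b1 %in% c("C", "T")
      rows[[i]] <- list(read_id = sprintf("%s_r%06d", sample_id, i),
                        sample_id = sample_id, chrom = chrom,
                        start = start, end = end,
                        mapq = 40L,
                        converted_seq = paste(chars, collapse = ""),
                        cpg_positions = list(sites[keep]),
                        cpg_calls = list(b1[keep] == "C"),
                        mate_merged = FALSE,
                        source = if (is_tumor) "tumor" else base_class)
    }
    methyl_reads(rbindlist(rows), validate = FALSE)
  })
}

#' Generate a full synthetic cohort
#'
#' Builds the reference and all samples: tumor tissues (tumor reads at the
#' configured purity, the remainder healthy-like — resected tumors contain
#' normal and immune cells), matched para-tumor tissues, healthy-reference
#' cfDNA (for MCS bounds and label-0 training), and a validation cohort of
#' healthy, liver-disease (LD) and HCC cfDNA samples; HCC samples carry
#' tumor reads at the configured ctDNA fractions.
#'
#' @param config a [synth_config].
#' @return list with `reference`, `truth`, `sample_sheet` (data.table
#'   `sample_id`, `group`, `label`, `role`, `ctdna_fraction`) and `reads`
#'   (one [methyl_reads] table; `sample_id` keys into the sheet).
#' @export
synth_cohort <- function(config = synth_config()) {
  ref <- synth_reference(config)
  sheet <- list(); reads <- list()
  add <- function(sample_id, group, label, role, tumor_fraction,
                  base_class = "healthy", seed_offset) {
    r <- synth_reads(ref, sample_id, config$reads_per_sample,
                     base_class = base_class,
                     tumor_fraction = tumor_fraction,
                     seed = config$seed * 1000L + seed_offset)
    reads[[sample_id]] <<- r
    sheet[[sample_id]] <<- data.table(sample_id = sample_id, group = group,
                                      label = label, role = role,
                                      ctdna_fraction = tumor_fraction)
  }
  off <- 0L
  for (i in seq_len(config$n_tissue_pairs)) {
    add(sprintf("tumor_%02d", i), "tumor-tissue", 1L, "discovery",
        config$tumor_purity, seed_offset = (off <- off + 1L))
    add(sprintf("para_%02d", i), "para-tumor-tissue", 0L, "discovery",
        0, seed_offset = (off <- off + 1L))
  }
  for (i in seq_len(config$n_healthy_ref))
    add(sprintf("healthyref_%02d", i), "cfDNA-healthy", 0L, "reference",
        0, seed_offset = (off <- off + 1L))
  for (i in seq_len(config$n_val_healthy))
    add(sprintf("val_healthy_%02d", i), "cfDNA-healthy", 0L, "validation",
        0, seed_offset = (off <- off + 1L))
  for (i in seq_len(config$n_val_ld))
    add(sprintf("val_ld_%02d", i), "cfDNA-LD", 0L, "validation",
        0, base_class = "LD", seed_offset = (off <- off + 1L))
  fr <- rep_len(config$ctdna_fractions, config$n_val_hcc)
  for (i in seq_len(config$n_val_hcc))
    add(sprintf("val_hcc_%02d", i), "cfDNA-HCC", 1L, "validation",
        fr[i], seed_offset = (off <- off + 1L))
  list(reference = ref, truth = ref$truth,
       sample_sheet = rbindlist(sheet),
       reads = methyl_reads(rbindlist(reads), validate = FALSE))
}

#' Write the synthetic reference as FASTA (plus a truth BED)
#'
#' @param ref a [synth_reference].
#' @param fasta_path,bed_path output paths.
#' @export
write_synth_reference <- function(ref, fasta_path, bed_path = NULL) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (nm in names(ref$seqs)) {
    writeLines(paste0(">", nm), con)
    s <- ref$seqs[[nm]]
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(70, nchar(s) + 69, 70), nchar(s))), con)
  }
  if (!is.null(bed_path) && nrow(ref$truth))
    fwrite(ref$truth[, .(chrom, locus_start, locus_end, class)], bed_path,
           sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(fasta_path)
}
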