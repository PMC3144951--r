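# Seeded generators for populations, Ct tables, dilution series,
# phenotypes, gene models and ORF-bearing cDNAs with known ground truth.

#' Population specification for copy-number simulation
#'
#' @param population_id Label.
#' @param distribution Named numeric vector: copy number (>= 2) ->
#'   probability; must sum to 1 within 1e-12.
#' @param n Number of individuals to draw.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec("toy", c(`2` = 0.5, `3` = 0.5), 10)
#' @export
population_spec <- function(population_id, distribution, n) {
  if (is.null(names(distribution)) || any(!nzchar(names(distribution))))
    stop("distribution must be named by copy number")
  cn <- as.integer(names(distribution))
  if (any(is.na(cn)) || any(cn < 2L))
    stop("copy numbers must be integers >= 2")
  if (any(distribution < 0) || abs(sum(distribution) - 1) > 1e-12)
    stop("probabilities must be non-negative and sum to 1")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  structure(list(population_id = population_id,
                 distribution = setNames(as.numeric(distribution), cn),
                 n = n),
            class = "population_spec")
}

#' Cultured-population (JH-like) genotype distribution
#'
#' Copy numbers 2-6 with 3 and 4 copies dominating (40% and 49%), as
#' observed in the cultured JH pearl-mussel stock; the remaining 11% is
#' split over 2, 5 and 6 copies, whose exact shares were not published.
#'
#' @param n Number of individuals (the study phenotyped 100).
#' @return A [population_spec()].
#' @export
jh_population_spec <- function(n = 100L) {
  population_spec("JH", c(`2` = 0.04, `3` = 0.40, `4` = 0.49,
                          `5` = 0.05, `6` = 0.02), n)
}

#' Wild-population (PY-like) genotype distribution
#'
#' Copy numbers 2-12 with 7-10 copies dominating (23.3%, 16.7%, 20.0%,
#' 15.0%), as observed in the wild PY pearl-mussel stock; the remaining
#' 25% is spread over the minor classes, whose exact shares were not
#' published.
#'
#' @param n Number of individuals (the study genotyped 60).
#' @return A [population_spec()].
#' @export
py_population_spec <- function(n = 60L) {
  population_spec("PY", c(`2` = 0.017, `3` = 0.033, `4` = 0.05,
                          `5` = 0.05, `6` = 0.05,
                          `7` = 0.233, `8` = 0.167, `9` = 0.200,
                          `10` = 0.15, `11` = 0.033, `12` = 0.017), n)
}

#' Ct noise model for simulated qPCR wells
#'
#' @param baseline_control_ct Mean control-assay Ct (cycles).
#' @param replicate_sd Within-sample replicate SD (cycles).
#' @param between_sample_sd SD of per-sample control-Ct shifts (cycles);
#'   shared by both assays of a sample, so it cancels from the Ct
#'   difference.
#' @param eff_target,eff_control Fractional amplification efficiencies
#'   used to invert the copy-number equation (1.0 = perfect doubling).
#' @return An object of class `ct_noise_model`.
#' @export
ct_noise_model <- function(baseline_control_ct = 26, replicate_sd = 0.1,
                           between_sample_sd = 0.3,
                           eff_target = 1.0, eff_control = 1.0) {
  stopifnot(replicate_sd >= 0, between_sample_sd >= 0,
            baseline_control_ct > 0,
            eff_target > 0, eff_target <= 1.1,
            eff_control > 0, eff_control <= 1.1)
  structure(list(baseline_control_ct = baseline_control_ct,
                 replicate_sd = replicate_sd,
                 between_sample_sd = between_sample_sd,
                 eff_target = eff_target, eff_control = eff_control),
            class = "ct_noise_model")
}

#' Draw a population of true copy-number genotypes
#'
#' Categorical (multinomial) draw from the specified genotype
#' distribution, reproducible under `seed`.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed (optional).
#' @return A data.frame with `sample_id` and `true_copy_number`.
#' @examples
#' head(simulate_population(jh_population_spec(10), seed = 1))
#' @export
simulate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  cn <- as.integer(names(spec$distribution))
  draws <- cn[sample.int(length(cn), spec$n, replace = TRUE,
                         prob = spec$distribution)]
  data.frame(sample_id = sprintf("%s_%04d", spec$population_id,
                                 seq_len(spec$n)),
             true_copy_number = draws, stringsAsFactors = FALSE)
}

as_genotype_df <- function(genotypes) {
  if (is.data.frame(genotypes)) {
    stopifnot(all(c("sample_id", "true_copy_number") %in% names(genotypes)))
    return(genotypes)
  }
  if (is.null(names(genotypes)))
    names(genotypes) <- sprintf("s%04d", seq_along(genotypes))
  data.frame(sample_id = names(genotypes),
             true_copy_number = as.integer(genotypes),
             stringsAsFactors = FALSE)
}

#' Simulate a replicate Ct-well table from true genotypes
#'
#' Inverts the comparative-CT copy-number equation: each sample's control
#' assay is centred at `baseline_control_ct` plus a shared between-sample
#' shift, and its target assay is offset so that
#' `control_diploid_copies * (1+eff_control)^ct_control *
#' (1+eff_target)^(-ct_target)` equals the true copy number (which, at
#' 100% efficiencies, is the familiar `ct_target - ct_control =
#' -log2(copies/2)`).  Independent Gaussian replicate noise is then added
#' per well.
#'
#' @param genotypes Data.frame with `sample_id`, `true_copy_number`
#'   (e.g. from [simulate_population()]) or a named integer vector.
#' @param noise A [ct_noise_model()].
#' @param replicates Wells per sample per assay (triplicate by default).
#' @param seed Integer seed (optional).
#' @param control_diploid_copies Copies of the control locus.
#' @return A Ct-well data.frame (`sample_id`, `assay`, `replicate`, `ct`)
#'   accepted by [genotype_population()].
#' @examples
#' g <- simulate_population(jh_population_spec(5), seed = 1)
#' head(simulate_ct_table(g, seed = 2))
#' @export
simulate_ct_table <- function(genotypes, noise = ct_noise_model(),
                              replicates = 3L, seed = NULL,
                              control_diploid_copies = 2L) {
  stopifnot(inherits(noise, "ct_noise_model"))
  genotypes <- as_genotype_df(genotypes)
  if (any(genotypes$true_copy_number < 1L))
    stop("true copy numbers must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  replicates <- as.integer(replicates)
  ns <- nrow(genotypes)
  ctl_mean <- noise$baseline_control_ct +
    rnorm(ns, 0, noise$between_sample_sd)
  # target mean solves copies = C0 (1+ec)^ctc (1+et)^-ctt for ctt
  tgt_mean <- (log(control_diploid_copies / genotypes$true_copy_number) +
                 ctl_mean * log(1 + noise$eff_control)) /
    log(1 + noise$eff_target)
  wells <- expand.grid(replicate = seq_len(replicates),
                       assay = c("target", "control"),
                       idx = seq_len(ns),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(wells$assay == "target", tgt_mean[wells$idx],
               ctl_mean[wells$idx])
  data.frame(sample_id = genotypes$sample_id[wells$idx],
             assay = wells$assay,
             replicate = wells$replicate,
             ct = mu + rnorm(nrow(wells), 0, noise$replicate_sd),
             stringsAsFactors = FALSE)
}

#' Growth-trait effects of the cultured JH cohort
#'
#' Per-copy-number trait means and SDs for shell length (mm), shell width
#' (mm) and body weight (g), parameterized from the published cultured
#' cohort summaries: 3 copies (n = 40) 133.37 +/- 1.29, 33.23 +/- 1.35,
#' 256.85 +/- 15.66 and 4 copies (n = 49) 136.57 +/- 1.30, 32.98 +/-
#' 0.74, 267.39 +/- 9.97 (mean +/- SE).  SDs are reconstructed as
#' `SE * sqrt(n)`.
#'
#' @return A data.frame with columns `copy_number`, `trait`, `mean`, `sd`.
#' @export
jh_growth_effects <- function() {
  rbind(
    data.frame(copy_number = 3L,
               trait = c("shell_length", "shell_width", "body_weight"),
               mean = c(133.37, 33.23, 256.85),
               sd = c(1.29, 1.35, 15.66) * sqrt(40)),
    data.frame(copy_number = 4L,
               trait = c("shell_length", "shell_width", "body_weight"),
               mean = c(136.57, 32.98, 267.39),
               sd = c(1.30, 0.74, 9.97) * sqrt(49)))
}

#' Simulate phenotype records for genotyped individuals
#'
#' Independent normal draws per trait with the class mean and SD from
#' `effects`; traits are uncorrelated by construction.
#'
#' @param genotypes Data.frame with `sample_id`, `true_copy_number` or a
#'   named integer vector.
#' @param effects Data.frame with columns `copy_number`, `trait`, `mean`,
#'   `sd` (see [jh_growth_effects()]); every genotype present must be
#'   covered.
#' @param seed Integer seed (optional).
#' @return A data.frame with `sample_id` and one column per trait.
#' @examples
#' g <- data.frame(sample_id = c("a", "b"), true_copy_number = c(3L, 4L))
#' simulate_phenotypes(g, seed = 1)
#' @export
simulate_phenotypes <- function(genotypes, effects = jh_growth_effects(),
                                seed = NULL) {
  genotypes <- as_genotype_df(genotypes)
  stopifnot(all(c("copy_number", "trait", "mean", "sd") %in% names(effects)))
  if (any(effects$sd < 0)) stop("effect SDs must be non-negative")
  missing <- setdiff(unique(genotypes$true_copy_number),
                     unique(effects$copy_number))
  if (length(missing))
    stop("no phenotype effects for copy number(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(sample_id = genotypes$sample_id,
                    stringsAsFactors = FALSE)
  for (tr in unique(effects$trait)) {
    eff <- effects[effects$trait == tr, ]
    idx <- match(genotypes$true_copy_number, eff$copy_number)
    out[[tr]] <- rnorm(nrow(genotypes), eff$mean[idx], eff$sd[idx])
  }
  out
}

#' Simulate a qPCR dilution series
#'
#' Generates Ct values along a dilution series for a reaction with the
#' given per-cycle amplification factor `a` (template multiplies by `a`
#' each cycle, so Ct at log10 quantity `q` is
#' `baseline_ct - q * log(10)/log(a)`); a noiseless series therefore
#' fits a slope of `-log(10)/log(a)` and recovers efficiency
#' `(a - 1) * 100` percent.
#'
#' @param true_amplification_factor Per-cycle amplification factor in
#'   (1, 2.2]; 2 is perfect doubling.
#' @param levels Numeric vector of log10 relative quantities (default
#'   five ten-fold dilutions, 0 to -4).
#' @param replicates Wells per level.
#' @param noise_sd Gaussian Ct noise SD in cycles (0 = noiseless).
#' @param seed Integer seed (optional).
#' @param baseline_ct Ct of the undiluted (log10 quantity 0) template.
#' @return A data.frame with `log10_quantity`, `replicate`, `ct`, accepted
#'   by [fit_standard_curve()].
#' @examples
#' fit_standard_curve(simulate_dilution_series(1.97))
#' @export
simulate_dilution_series <- function(true_amplification_factor,
                                     levels = 0:-4, replicates = 3L,
                                     noise_sd = 0, seed = NULL,
                                     baseline_ct = 18) {
  a <- true_amplification_factor
  if (!is.finite(a) || a <= 1 || a > 2.2)
    stop("amplification factor must lie in (1, 2.2]")
  if (length(unique(levels)) < 3L)
    stop("at least 3 distinct dilution levels are required")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(as.integer(replicates)),
                      log10_quantity = as.numeric(levels),
                      KEEP.OUT.ATTRS = FALSE)
  ct <- baseline_ct - grid$log10_quantity * log(10) / log(a) +
    rnorm(nrow(grid), 0, noise_sd)
  data.frame(log10_quantity = grid$log10_quantity,
             replicate = grid$replicate, ct = ct)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genomic sequence with a known gene model
#'
#' Builds a random genomic sequence containing `n_exons` exons separated
#' by GT...AG introns, returning the genomic sequence, the spliced cDNA
#' and the true `gene_model`.  The base immediately following each
#' splice-donor position on the cDNA is forced away from G so that the
#' maximal exact match stops exactly at the exon boundary and greedy
#' re-mapping recovers the model.
#'
#' @param n_exons Number of exons.
#' @param exon_length_range,intron_length_range Integer ranges (min, max)
#'   to draw lengths from; introns are at least 4 nt.
#' @param flank Length of untranscribed flanking sequence on each side.
#' @param seed Integer seed (optional).
#' @return A list with `genomic` and `cdna` (character) and `model`
#'   (a `gene_model`).
#' @examples
#' sim <- simulate_gene_model(4, seed = 1)
#' sim$model
#' @export
simulate_gene_model <- function(n_exons = 4L,
                                exon_length_range = c(60L, 300L),
                                intron_length_range = c(40L, 400L),
                                flank = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_exons <- as.integer(n_exons)
  stopifnot(n_exons >= 1L, intron_length_range[1L] >= 4L)
  exon_len <- sample(exon_length_range[1L]:exon_length_range[2L], n_exons,
                     replace = TRUE)
  intron_len <- if (n_exons > 1L)
    sample(intron_length_range[1L]:intron_length_range[2L], n_exons - 1L,
           replace = TRUE) else integer()
  exon_seq <- vapply(exon_len, random_dna, character(1))
  # next exon must not start with G, so the exact match cannot run into
  # the GT donor
  for (i in seq_along(exon_seq)[-1L]) {
    if (substr(exon_seq[i], 1L, 1L) == "G")
      substr(exon_seq[i], 1L, 1L) <- sample(c("A", "C", "T"), 1L)
  }
  intron_seq <- vapply(intron_len, function(l) {
    paste0("GT", if (l > 4L) random_dna(l - 4L) else "", "AG")
  }, character(1))
  pieces <- character(0)
  exons <- data.frame(start = integer(n_exons), end = integer(n_exons))
  introns <- data.frame(start = integer(n_exons - 1L),
                        end = integer(n_exons - 1L),
                        donor = character(n_exons - 1L),
                        acceptor = character(n_exons - 1L),
                        canonical = logical(n_exons - 1L),
                        stringsAsFactors = FALSE)
  pos <- flank + 1L
  for (i in seq_len(n_exons)) {
    exons$start[i] <- pos
    exons$end[i] <- pos + exon_len[i] - 1L
    pieces <- c(pieces, exon_seq[i])
    pos <- pos + exon_len[i]
    if (i < n_exons) {
      introns$start[i] <- pos
      introns$end[i] <- pos + intron_len[i] - 1L
      introns$donor[i] <- "GT"
      introns$acceptor[i] <- "AG"
      introns$canonical[i] <- TRUE
      pieces <- c(pieces, intron_seq[i])
      pos <- pos + intron_len[i]
    }
  }
  genomic <- paste0(if (flank > 0L) random_dna(flank) else "",
                    paste(pieces, collapse = ""),
                    if (flank > 0L) random_dna(flank) else "")
  list(genomic = genomic,
       cdna = paste(exon_seq, collapse = ""),
       model = new_gene_model(exons, introns,
                              sum(nchar(exon_seq))))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# longest ATG..stop ORF length in a DNA string (independent of find_orf's
# bookkeeping; used only for rejection sampling in the generator)
longest_orf_length <- function(s) {
  n <- nchar(s)
  best <- 0L
  atg <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
  if (atg[1L] == -1L) return(0L)
  for (a in as.integer(atg)) {
    p <- a
    while (p + 2L <= n) {
      if (substr(s, p, p + 2L) %in% STOP_CODONS) {
        best <- max(best, p + 2L - a + 1L)
        break
      }
      p <- p + 3L
    }
  }
  best
}

#' Simulate a cDNA with a designed ORF/UTR partition
#'
#' Builds a transcript with the requested 5' UTR, ORF and 3' UTR lengths:
#' UTRs are random sequence with every ATG scrubbed, and the ORF is ATG +
#' random sense codons + TAA.  Draws are rejected (and redrawn) in the
#' rare event that a chance reading frame elsewhere ties or exceeds the
#' designed ORF, so the designed ORF is always the unique longest.
#'
#' @param utr5_length,utr3_length UTR lengths in nt.
#' @param orf_length_nt ORF length in nt including the stop codon; must
#'   be a multiple of 3, at least 6.
#' @param seed Integer seed (optional).
#' @return An [nt_sequence()] of length
#'   `utr5_length + orf_length_nt + utr3_length`.
#' @examples
#' s <- simulate_cdna(seed = 1)   # 153 + 525 + 144 = 822 nt
#' nchar(s$residues)
#' @export
simulate_cdna <- function(utr5_length = 153L, orf_length_nt = 525L,
                          utr3_length = 144L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  orf_length_nt <- as.integer(orf_length_nt)
  if (orf_length_nt %% 3L != 0L || orf_length_nt < 6L)
    stop("orf_length_nt must be a multiple of 3, at least 6")
  scrubbed_utr <- function(n) {
    if (n == 0L) return("")
    s <- random_dna(n)
    repeat {
      hit <- regexpr("ATG", s, fixed = TRUE)[1L]
      if (hit == -1L) return(s)
      substr(s, hit + 1L, hit + 1L) <- "C"     # ATG -> ACG
    }
  }
  for (attempt in 1:100) {
    orf <- paste0("ATG", random_codons(orf_length_nt / 3L - 2L), "TAA")
    s <- paste0(scrubbed_utr(utr5_length), orf, scrubbed_utr(utr3_length))
    if (longest_orf_length(s) == orf_length_nt)
      return(nt_sequence("synthetic_cdna", s))
  }
  stop("failed to generate a cDNA with the designed ORF dominant")
}
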