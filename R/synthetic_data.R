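#' Simulation configuration
#'
#' Holds the stated world of the synthetic cohort: a genotyped cohort of
#' 325 donors (the analyzable intersection of proteomics and genotyping),
#' common PAVs with MAF in (0.10, 0.50], variant-peptide detection
#' calibrated to the GIP worked example (58% sensitivity in allele
#' carriers, 5% false-positive detections in non-carriers), five
#' nanoparticle fractions, and covariates (age 18-80, sex/diabetes in equal
#' proportions, BMI, three genotype PCs).
#'
#' Protein log2-intensities are simulated with conditional standard
#' deviation `log2_sd` (default 0.5, a typical plasma-proteome biological
#' spread); `pqtl_beta` is the per-minor-allele-copy effect in units of
#' that spread, i.e. approximately inverse-normal units, and is applied as
#' an abundance *decrease* (destabilizing missense allele) so that
#' composition and abundance signals align. `variant_ion_boost` is the
#' log2 ratio of the variant peptide's total ionization to the summed
#' ionization of its protein's invariant peptides: engine protein
#' estimates are dominated by the best-ionizing peptides, which is what
#' makes a genotype-dependently missing peptide visible at protein level.
#'
#' @param seed Integer seed driving every generator.
#' @param n_samples Cohort size (default 325).
#' @param n_proteins Number of simulated proteins (default 6).
#' @param peptides_per_protein Range (min, max) of tryptic fragments per
#'   protein (default 3-6).
#' @param n_pavs Number of protein-altering variants (default 3, at most
#'   one per protein).
#' @param maf_range Minor allele frequency range (default 0.10-0.50).
#' @param detection_sensitivity Detection probability of a variant peptide
#'   in a carrier of its allele (default 0.58).
#' @param detection_fpr False-positive detection probability in
#'   non-carriers (default 0.05).
#' @param log2_mean,log2_sd Mean and conditional SD of protein
#'   log2-intensities (defaults 20 and 0.5).
#' @param missingness Random missingness of invariant peptide observations
#'   (default 0.05).
#' @param covariate_effects Named vector of log2-scale effects for `age`
#'   (per year, centred), `sex`, `bmi` (per unit, centred), `diabetes` and
#'   `pc` (per PC unit).
#' @param pqtl_beta Abundance effect magnitude per minor-allele copy, in
#'   `log2_sd` units (default 0.7; applied with negative sign).
#' @param variant_ion_boost log2 ionization ratio of variant peptide to
#'   its protein's invariant-peptide sum (default 1.5).
#' @param np_presence Probability that an invariant peptide is measurable
#'   in a given nanoparticle fraction (default 0.75).
#' @param n_nanoparticles Number of nanoparticle fractions (default 5).
#' @param scenario `"epitope"` (allele-specific peptide, no abundance
#'   effect), `"true_pqtl"` (genuine abundance effect) or `"null"`
#'   (variant peptide detected regardless of genotype, emulating a
#'   spectral-confusion false identification).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 325L,
                       n_proteins = 6L,
                       peptides_per_protein = c(3L, 6L),
                       n_pavs = 3L,
                       maf_range = c(0.10, 0.50),
                       detection_sensitivity = 0.58,
                       detection_fpr = 0.05,
                       log2_mean = 20,
                       log2_sd = 0.5,
                       missingness = 0.05,
                       covariate_effects = c(age = 0.005, sex = 0.2,
                                             bmi = 0.01, diabetes = 0.2,
                                             pc = 0.05),
                       pqtl_beta = 0.7,
                       variant_ion_boost = 1.5,
                       np_presence = 0.75,
                       n_nanoparticles = 5L,
                       scenario = c("epitope", "true_pqtl", "null")) {
  scenario <- match.arg(scenario)
  if (any(c(detection_sensitivity, detection_fpr, missingness, np_presence) < 0 |
            c(detection_sensitivity, detection_fpr, missingness, np_presence) > 1)) {
    abort("All rates must lie in [0, 1].")
  }
  if (maf_range[1] < 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing range within [0, 0.5].")
  }
  if (n_pavs > n_proteins) abort("`n_pavs` must not exceed `n_proteins`.")
  if (peptides_per_protein[1] < 3) {
    abort("Need at least 3 peptides per protein.")
  }
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_pavs = as.integer(n_pavs), maf_range = maf_range,
    detection_sensitivity = detection_sensitivity,
    detection_fpr = detection_fpr, log2_mean = log2_mean,
    log2_sd = log2_sd, missingness = missingness,
    covariate_effects = covariate_effects, pqtl_beta = pqtl_beta,
    variant_ion_boost = variant_ion_boost, np_presence = np_presence,
    n_nanoparticles = as.integer(n_nanoparticles), scenario = scenario
  ), class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_aa <- function(n, exclude = c("K", "R")) {
  paste(sample(setdiff(STANDARD_AA, exclude), n, replace = TRUE),
        collapse = "")
}

aa_to_codon_map <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc)) |> map_chr(~ sort(.x)[1])
}

#' Simulate a toy genome, BED12 gene model and protein FASTA
#'
#' Generates `n_proteins` coding genes: each protein starts with
#' methionine and is a concatenation of tryptic fragments of length 7-14
#' (so the length-7-30 digest recovers every fragment); the CDS (with a
#' trailing stop codon) is split over 1-3 coding blocks, placed on one of
#' two toy chromosomes, on alternating strands, separated by random
#' intergenic sequence. Every entry passes the translate-and-compare round
#' trip by construction.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_gene_model`: list with `genome` (named
#'   character), `model` (resolved gene-model tibble), `bed` (BED12
#'   tibble), `proteins` (tibble `protein_id`, `protein_seq`).
#' @export
simulate_gene_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  codon_of <- aa_to_codon_map()
  rng <- config$peptides_per_protein
  chroms <- c("chrS1", "chrS2")
  chrom_seq <- setNames(rep("", 2), chroms)
  rows <- list()
  bed_rows <- list()
  for (i in seq_len(config$n_proteins)) {
    pid <- sprintf("PROT%03d", i)
    n_pep <- sample(seq(rng[1], rng[2]), 1)
    segs <- map_chr(seq_len(n_pep), function(k) {
      len <- sample(6:13, 1)
      body <- if (k == 1) paste0("M", rand_aa(len - 1)) else rand_aa(len)
      paste0(body, sample(c("K", "R"), 1))
    })
    prot <- paste(segs, collapse = "")
    cds <- paste0(paste(codon_of[strsplit(prot, "")[[1]]], collapse = ""),
                  "TAA")
    strand <- if (i %% 2 == 0) "-" else "+"
    chrom <- chroms[if (i <= ceiling(config$n_proteins / 2)) 1L else 2L]
    cds_len <- nchar(cds)
    nb <- sample(1:3, 1)
    cutpoints <- if (nb > 1) sort(sample(seq_len(cds_len - 1), nb - 1)) else integer(0)
    exon_concat <- if (strand == "-") revcomp_dna(cds) else cds
    starts_rel <- c(0L, cutpoints)
    ends_rel <- c(cutpoints, cds_len)
    pieces <- str_sub(exon_concat, starts_rel + 1L, ends_rel)

    offset <- nchar(chrom_seq[[chrom]]) + sample(20:60, 1)
    g_start <- integer(nb); g_end <- integer(nb)
    cursor <- offset
    locus <- ""
    for (b in seq_len(nb)) {
      g_start[b] <- cursor
      locus <- paste0(locus, pieces[b])
      cursor <- cursor + nchar(pieces[b])
      g_end[b] <- cursor
      if (b < nb) {
        intron <- rand_dna(sample(20:60, 1))
        locus <- paste0(locus, intron)
        cursor <- cursor + nchar(intron)
      }
    }
    pad <- rand_dna(offset - nchar(chrom_seq[[chrom]]))
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], pad, locus)

    blocks <- tibble(start = g_start, end = g_end)
    if (strand == "-") blocks <- blocks[rev(seq_len(nb)), ]
    rows[[i]] <- tibble(
      protein_id = pid, chrom = chrom, strand = strand,
      blocks = list(blocks), cds_length = cds_len, protein_seq = prot,
      is_canonical = TRUE, bed_line = i
    )
    bed_rows[[i]] <- tibble(
      chrom = chrom, chrom_start = g_start[1], chrom_end = g_end[nb],
      protein_id = pid, score = 0L, strand = strand,
      thick_start = g_start[1], thick_end = g_end[nb], rgb = "0,0,0",
      block_count = nb,
      block_sizes = paste(g_end - g_start, collapse = ","),
      block_starts = paste(g_start - g_start[1], collapse = ","),
      canonical = 1L
    )
  }
  model <- list_rbind(rows)
  genome <- chrom_seq
  # construction invariant: every entry translates back to its protein
  for (i in seq_len(nrow(model))) {
    tr <- translate_cds(model[i, ], genome)
    stopifnot(tr$valid, tr$protein == model$protein_seq[i])
  }
  structure(list(
    genome = genome, model = model, bed = list_rbind(bed_rows),
    proteins = select(model, "protein_id", "protein_seq")
  ), class = "sim_gene_model")
}

#' Simulate protein-altering variants on a toy gene model
#'
#' Draws at most one missense SNV per protein (variants treated as
#' independent), restricted to substitutions that neither create nor
#' destroy a K/R cleavage site (simple-match variants), with MAF uniform in
#' `maf_range`. The genomic position and alleles are derived by inverting
#' the CDS coordinate mapping, so re-mapping each variant through
#' [map_variant_to_protein()] reproduces the record.
#'
#' @param config A [sim_config()].
#' @param gene_model A `sim_gene_model`.
#' @return Tibble of PAV records with genomic fields (`chrom`, `pos`,
#'   `ref`, `alt`) and truth fields (`class`, `true_beta`).
#' @export
simulate_pavs <- function(config, gene_model) {
  stopifnot(inherits(gene_model, "sim_gene_model"))
  set.seed(config$seed + 13L)
  model <- gene_model$model
  pids <- sample(model$protein_id, config$n_pavs)
  out <- list()
  for (k in seq_along(pids)) {
    entry <- model[model$protein_id == pids[k], ]
    tr <- translate_cds(entry, gene_model$genome)
    prot <- entry$protein_seq
    found <- FALSE
    for (try in 1:200) {
      ppos <- sample(2:nchar(prot), 1)
      ref_aa <- str_sub(prot, ppos, ppos)
      if (ref_aa %in% c("K", "R")) next
      codon <- str_sub(tr$cds, 3 * (ppos - 1) + 1, 3 * (ppos - 1) + 3)
      muts <- list()
      for (j in 1:3) {
        for (b in c("A", "C", "G", "T")) {
          if (str_sub(codon, j, j) == b) next
          alt_codon <- codon
          str_sub(alt_codon, j, j) <- b
          aa <- codon_to_aa(alt_codon)
          if (aa != ref_aa && aa != "*" && !aa %in% c("K", "R")) {
            muts[[length(muts) + 1L]] <- list(j = j, base = b, alt_aa = aa)
          }
        }
      }
      if (length(muts) == 0) next
      m <- muts[[sample(length(muts), 1)]]
      offset <- 3L * (ppos - 1L) + (m$j - 1L)
      gpos <- cds_offset_to_genomic(offset, entry$blocks[[1]], entry$strand)
      ref_cds <- str_sub(codon, m$j, m$j)
      if (entry$strand == "-") {
        ref_base <- complement_base(ref_cds); alt_base <- complement_base(m$base)
      } else {
        ref_base <- ref_cds; alt_base <- m$base
      }
      maf <- runif(1, config$maf_range[1], config$maf_range[2])
      out[[k]] <- tibble(
        variant_id = sprintf("%s:%d:%s:%s", entry$chrom, gpos, ref_base,
                             alt_base),
        rsid = sprintf("rs%d", (abs(config$seed) %% 1000000L) * 100L + k),
        chrom = entry$chrom, pos = gpos, ref = ref_base, alt = alt_base,
        protein_id = entry$protein_id, protein_pos = ppos,
        ref_aa = ref_aa, alt_aa = m$alt_aa, maf = maf,
        class = config$scenario,
        true_beta = if (config$scenario == "true_pqtl") -config$pqtl_beta else 0
      )
      found <- TRUE
      break
    }
    if (!found) abort(sprintf("Could not place a PAV on %s.", pids[k]))
  }
  list_rbind(out)
}

#' Simulate genotypes and covariates under Hardy-Weinberg equilibrium
#'
#' Dosages are Binomial(2, MAF) per sample and variant; covariates follow
#' the cohort description: age uniform on 18-80, sex and diabetes status
#' Bernoulli(0.5), BMI normal (mean 28, sd 4.5), three genotype PCs
#' standard normal. The sample MAF is recomputed and stored.
#'
#' @param config A [sim_config()].
#' @param pavs PAV tibble from [simulate_pavs()] (needs `variant_id`,
#'   `maf`).
#' @param seed Seed override (defaults to `config$seed + 17`); use for
#'   replicate cohorts on a fixed proteome.
#' @return List with `dosages` (long tibble `sample`, `variant_id`,
#'   `dosage`), `covariates` (tibble `sample` + covariate columns),
#'   `maf_hat` (tibble `variant_id`, `maf`, `maf_hat`).
#' @export
simulate_genotypes <- function(config, pavs, seed = config$seed + 17L) {
  set.seed(seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  dose <- map(seq_len(nrow(pavs)), function(i) {
    tibble(sample = samples, variant_id = pavs$variant_id[i],
           dosage = rbinom(n, 2, pavs$maf[i]))
  }) |> list_rbind()
  covariates <- tibble(
    sample = samples,
    age = runif(n, 18, 80),
    sex = rbinom(n, 1, 0.5),
    bmi = rnorm(n, 28, 4.5),
    diabetes = rbinom(n, 1, 0.5),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n)
  )
  maf_hat <- dose |>
    group_by(.data$variant_id) |>
    summarise(af_hat = mean(.data$dosage) / 2, .groups = "drop") |>
    mutate(maf_hat = pmin(.data$af_hat, 1 - .data$af_hat)) |>
    left_join(select(pavs, "variant_id", "maf"), by = "variant_id")
  list(dosages = dose, covariates = covariates, samples = samples,
       maf_hat = maf_hat)
}

#' Simulate DIA-style quantification reports
#'
#' Per-sample protein log2-abundances carry covariate effects and, for
#' `true_pqtl` variants, a `-pqtl_beta * dosage` shift. Invariant peptide
#' intensity is abundance times a peptide-specific ionization factor and a
#' nanoparticle offset; allele-specific peptide intensity additionally
#' scales with (copies of that allele)/2 — the reference-allele peptide
#' halves in heterozygotes and vanishes in alternate homozygotes, which is
#' the epitope mechanism. Variant peptides are detected with probability
#' `detection_sensitivity` in carriers and `detection_fpr` in non-carriers
#' (at a spurious half intensity); in the `null` scenario detection is
#' genotype-independent. Invariant peptides are subject to random
#' missingness and per-nanoparticle presence.
#'
#' @param config A [sim_config()].
#' @param libraries `library_set` built from the simulated model and PAVs.
#' @param genotypes Output of [simulate_genotypes()].
#' @param pavs PAV truth tibble from [simulate_pavs()].
#' @param seed Seed override (defaults to `config$seed + 19`).
#' @return List with `report` (long tibble: `sample`, `nanoparticle`,
#'   `stripped_sequence`, `protein_group`, `precursor_charge`,
#'   `precursor_quantity`) and `truth` (list: `variants`, `peptides`,
#'   `protein_abundance` on log2 scale).
#' @export
simulate_report <- function(config, libraries, genotypes, pavs,
                            seed = config$seed + 19L) {
  stopifnot(inherits(libraries, "library_set"))
  set.seed(seed)
  samples <- genotypes$samples
  n <- length(samples)
  cov <- genotypes$covariates
  ce <- config$covariate_effects
  eta <- ce[["age"]] * (cov$age - 49) + ce[["sex"]] * cov$sex +
    ce[["bmi"]] * (cov$bmi - 28) + ce[["diabetes"]] * cov$diabetes +
    ce[["pc"]] * (cov$pc1 + cov$pc2 + cov$pc3)

  catalog <- libraries$pav_inclusive |>
    distinct(.data$sequence, .data$protein_id, .data$origin, .data$variant_id)
  proteins <- unique(catalog$protein_id)

  # per-sample protein abundance (log2), unit-variance conditional scale
  dose_w <- genotypes$dosages |>
    pivot_wider(names_from = "variant_id", values_from = "dosage")
  abundance <- map(proteins, function(p) {
    pv <- pavs[pavs$protein_id == p, ]
    shift <- 0
    sd_p <- config$log2_sd
    if (nrow(pv) == 1 && pv$class == "true_pqtl") {
      d <- dose_w[[pv$variant_id]][match(samples, dose_w$sample)]
      shift <- pv$true_beta * config$log2_sd * d
      sd_p <- config$log2_sd *
        sqrt(max(0.1, 1 - pv$true_beta^2 * 2 * pv$maf * (1 - pv$maf)))
    }
    tibble(protein_id = p, sample = samples,
           log2_abundance = config$log2_mean + eta + shift + rnorm(n, 0, sd_p))
  }) |> list_rbind()

  # ionization: invariant peptides ~ 2^N(0,1); variant forms share a boosted
  # budget of 2^variant_ion_boost times the protein's invariant sum
  inv_cat <- filter(catalog, .data$origin == "invariant")
  inv_cat$ion <- rnorm(nrow(inv_cat), 0, 1)
  var_cat <- filter(catalog, .data$origin != "invariant")
  if (nrow(var_cat) > 0) {
    inv_sum <- inv_cat |>
      group_by(.data$protein_id) |>
      summarise(t_ion = sum(2^.data$ion), .groups = "drop")
    n_ref_forms <- var_cat |>
      filter(.data$origin == "ref_allele") |>
      count(.data$protein_id, name = "n_forms")
    var_cat <- var_cat |>
      left_join(inv_sum, by = "protein_id") |>
      left_join(n_ref_forms, by = "protein_id") |>
      mutate(
        ion = log2(.data$t_ion * 2^config$variant_ion_boost /
                     pmax(.data$n_forms, 1)) + rnorm(n(), 0, 0.2)
      ) |>
      select(-"t_ion", -"n_forms")
  }
  catalog <- bind_rows(inv_cat, var_cat)
  charges <- catalog |>
    distinct(.data$sequence) |>
    mutate(precursor_charge = sample(c(2L, 3L), n(), replace = TRUE,
                                     prob = c(0.85, 0.15)))
  catalog <- left_join(catalog, charges, by = "sequence")

  np_labels <- sprintf("NP%d", seq_len(config$n_nanoparticles))
  np_offset <- setNames(rnorm(config$n_nanoparticles, 0, 0.5), np_labels)
  # per (invariant peptide, nanoparticle) measurability
  presence <- crossing(
    catalog |> distinct(.data$sequence, .data$origin),
    nanoparticle = np_labels
  ) |>
    mutate(present = .data$origin != "invariant" |
             runif(n()) < config$np_presence) |>
    select("sequence", "nanoparticle", "present")

  dose_of <- function(variant_id) {
    dose_w[[variant_id]][match(samples, dose_w$sample)]
  }

  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    entry <- catalog[i, ]
    ab <- abundance$log2_abundance[abundance$protein_id == entry$protein_id]
    for (np in np_labels) {
      if (!presence$present[presence$sequence == entry$sequence &
                              presence$nanoparticle == np][1]) next
      base <- ab + entry$ion + np_offset[[np]] + rnorm(n, 0, 0.2)
      if (entry$origin == "invariant") {
        detected <- runif(n) >= config$missingness
        quantity <- 2^base
      } else {
        d <- dose_of(entry$variant_id)
        copies <- if (entry$origin == "alt_allele") d else 2L - d
        if (config$scenario == "null") {
          detected <- runif(n) < config$detection_sensitivity
          quantity <- 2^base
        } else {
          carrier <- copies >= 1
          detected <- if_else(carrier,
                              runif(n) < config$detection_sensitivity,
                              runif(n) < config$detection_fpr)
          quantity <- if_else(carrier, 2^base * copies / 2, 2^base * 0.5)
        }
      }
      if (!any(detected)) next
      rows[[length(rows) + 1L]] <- tibble(
        sample = samples[detected],
        nanoparticle = np,
        stripped_sequence = entry$sequence,
        protein_group = entry$protein_id,
        precursor_charge = entry$precursor_charge,
        precursor_quantity = quantity[detected]
      )
    }
  }
  report <- list_rbind(rows) |> arrange(.data$nanoparticle, .data$sample)
  truth <- list(
    variants = select(pavs, "variant_id", "rsid", "protein_id", "maf",
                      "class", "true_beta"),
    peptides = select(catalog, "sequence", "protein_id", "origin",
                      "variant_id", "ion", "precursor_charge"),
    protein_abundance = abundance
  )
  list(report = report, truth = truth)
}

#' Simulate a complete study
#'
#' Chains the three generators (gene model, genotypes, report) and builds
#' the peptide libraries, optionally writing every artifact to disk as
#' plain text (genome.fa, proteins.fa, model.bed, genotypes.vcf,
#' covariates.tsv, one report_NP*.tsv per nanoparticle in DIA-NN-dialect
#' columns, truth.tsv).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `sim_study`: list with `config`, `gene_model`,
#'   `pavs`, `libraries`, `genotypes`, `report`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  gm <- simulate_gene_model(config)
  pavs <- simulate_pavs(config, gm)
  libraries <- build_libraries(gm$model, pavs)
  genotypes <- simulate_genotypes(config, pavs)
  rep_out <- simulate_report(config, libraries, genotypes, pavs)
  study <- structure(list(
    config = config, gene_model = gm, pavs = pavs, libraries = libraries,
    genotypes = genotypes, report = rep_out$report, truth = rep_out$truth
  ), class = "sim_study")
  if (!is.null(out_dir)) write_sim_study(study, out_dir)
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>", x$config$scenario, "scenario\n")
  cat(sprintf("  %d samples, %d proteins, %d PAVs, %d nanoparticles\n",
              x$config$n_samples, x$config$n_proteins, nrow(x$pavs),
              x$config$n_nanoparticles))
  cat(sprintf("  report: %d rows\n", nrow(x$report)))
  invisible(x)
}

#' Write a BED12 table
#'
#' @param bed BED tibble as produced by [simulate_gene_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed12 <- function(bed, path) {
  lines <- with(bed, paste(
    chrom, chrom_start, chrom_end, protein_id, score, strand,
    thick_start, thick_end, rgb, block_count, block_sizes, block_starts,
    canonical, sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulated genotypes as a VCF
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param pavs PAV tibble with genomic fields (`chrom`, `pos`, `ref`,
#'   `alt`, `rsid`, `maf`).
#' @param path Output path.
#' @param genome Optional named genome (for contig lengths in the header).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(genotypes, pavs, path, genome = NULL) {
  samples <- genotypes$samples
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(genome)) {
    seqs <- genome_seqs(genome)
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>", names(seqs),
                                nchar(seqs)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  dose_w <- genotypes$dosages |>
    pivot_wider(names_from = "variant_id", values_from = "dosage")
  body <- map_chr(seq_len(nrow(pavs)), function(i) {
    d <- dose_w[[pavs$variant_id[i]]][match(samples, dose_w$sample)]
    gt <- if_else(is.na(d), "./.", gt_code[d + 1L])
    paste(c(pavs$chrom[i], pavs$pos[i], pavs$rsid[i], pavs$ref[i],
            pavs$alt[i], ".", "PASS", sprintf("AF=%.6f", pavs$maf[i]),
            "GT", gt), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write every artifact of a simulated study
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- study$gene_model
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    proteins = file.path(dir, "proteins.fa"),
    bed = file.path(dir, "model.bed"),
    vcf = file.path(dir, "genotypes.vcf"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gm$genome),
                              paths[["genome"]])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(gm$proteins$protein_seq,
                                     gm$proteins$protein_id)),
    paths[["proteins"]]
  )
  write_bed12(gm$bed, paths[["bed"]])
  write_vcf(study$genotypes, study$pavs, paths[["vcf"]], gm$genome)
  readr::write_tsv(study$genotypes$covariates, paths[["covariates"]])
  readr::write_tsv(study$truth$variants, paths[["truth"]])
  for (np in unique(study$report$nanoparticle)) {
    p <- file.path(dir, sprintf("report_%s.tsv", np))
    study$report |>
      filter(.data$nanoparticle == np) |>
      select(Run = "sample", Protein.Group = "protein_group",
             Stripped.Sequence = "stripped_sequence",
             Precursor.Charge = "precursor_charge",
             Precursor.Quantity = "precursor_quantity") |>
      readr::write_tsv(p)
    paths[[paste0("report_", np)]] <- p
  }
  invisible(paths)
}

#' Simulate an external pQTL summary-statistic table
#'
#' Builds a desk-scale stand-in for a consortium summary table: each
#' MS-PAV x target pair receives a null p-value, except planted cis hits.
#' Used for exercising the overlap classifier; it is synthetic and carries
#' no information about any real platform.
#'
#' @param pavs PAV tibble (`variant_id`, `protein_id`).
#' @param platform Label.
#' @param cis_variants Variant ids to plant strong own-protein hits for.
#' @param n_extra_targets Extra assayed proteins beyond the PAV proteins.
#' @param seed Seed.
#' @return An [external_summary()].
#' @export
simulate_external_summary <- function(pavs, platform = "synthPlatform",
                                      cis_variants = character(),
                                      n_extra_targets = 20, seed = 1L) {
  set.seed(seed)
  targets <- c(unique(pavs$protein_id),
               sprintf("EXT%03d", seq_len(n_extra_targets)))
  assoc <- crossing(variant_id = unique(pavs$variant_id),
                    target_id = targets) |>
    mutate(p = runif(n()))
  own <- distinct(pavs, .data$variant_id, .data$protein_id)
  assoc <- assoc |>
    left_join(own, by = "variant_id") |>
    mutate(p = if_else(.data$variant_id %in% cis_variants &
                         .data$target_id == .data$protein_id,
                       1e-12, .data$p)) |>
    select(-"protein_id")
  external_summary(assoc, platform, n_assayed_proteins = length(targets),
                   assayed_targets = targets)
}
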