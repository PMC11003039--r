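# End-to-end orchestration on a run configuration, shared TSV emission and a
# consistency-checked summary bundle.

#' Per-chromosome length and GC table for a genome
#'
#' GC per chromosome is (G+C)/(A+C+G+T); ambiguity codes are excluded from the
#' denominator. The genome-wide GC is computed over the concatenated bases
#' (not the mean of per-chromosome values).
#'
#' @param genome an [mc_genome()] or named character vector
#' @return list with `per_chromosome` (chromosome, length, gc),
#'   `n_chromosomes`, `total_length`, `genome_gc`, `gc_range`
#' @export
genome_stats <- function(genome) {
  seqs <- genome_seqs(genome)
  stopifnot(length(seqs) >= 1)
  if (any(nchar(seqs) == 0)) stop("empty chromosome sequence")
  counts <- t(vapply(seqs, function(s) {
    b <- table(factor(strsplit(toupper(s), "")[[1]],
                      levels = c("A", "C", "G", "T")))
    as.numeric(b)
  }, numeric(4)))
  colnames(counts) <- c("A", "C", "G", "T")
  denom <- rowSums(counts)
  if (any(denom == 0)) stop("chromosome with no unambiguous bases")
  gc <- (counts[, "G"] + counts[, "C"]) / denom
  per <- data.frame(chromosome = names(seqs), length = nchar(seqs), gc = gc,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(per_chromosome = per,
       n_chromosomes = length(seqs),
       total_length = sum(per$length),
       genome_gc = sum(counts[, "G"] + counts[, "C"]) / sum(denom),
       gc_range = range(gc))
}

#' Default run configuration
#'
#' @param outdir output directory for stage TSVs
#' @param stages character vector of stages to run, any of "simulate",
#'   "stats", "recruit", "codon", "editing", "repeats", "transfer"
#' @param seed global seed (propagated to the simulator and read simulation)
#' @param sim optional list of [sim_config()] argument overrides
#' @return a `run_config` list
#' @export
default_run_config <- function(outdir = tempfile("mitocharter_run_"),
                               stages = c("simulate", "stats", "codon",
                                          "editing", "repeats", "transfer"),
                               seed = 1L, sim = list()) {
  structure(list(outdir = outdir, stages = stages, seed = as.integer(seed),
                 sim = sim,
                 params = list(
                   repeats = list(ssr_params = as.list(misa_default_params),
                                  tandem_min_unit = 7, tandem_min_match = 0.68,
                                  dispersed_min_len = 27,
                                  dispersed_min_identity = 0.90,
                                  dispersed_max_e = 1e-5),
                   transfer = list(min_identity = 0.70, min_len = 30,
                                   max_e = 1e-5),
                   recruit = list(min_overlap_bp = 1000, min_identity = 0.70,
                                  min_match_bp = 50, max_iter = 50),
                   editing = list(cutoff = 0.5))),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file
#' @return a `run_config` list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$seed <- as.integer(base$seed)
  base
}

#' Write a run configuration as YAML
#' @param config a `run_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline on a configuration
#'
#' Stages run in dependency order: `simulate` builds the genomes and truth
#' manifest; `stats`, `codon`, `editing`, `repeats`, `transfer` and `recruit`
#' consume them. Each enabled stage writes TSV outputs under
#' `config$outdir`; disabled stages write nothing. The returned bundle's
#' `summary` is cross-checked against the stage outputs at build time.
#'
#' @param config a `run_config` from [default_run_config()] /
#'   [read_run_config()]
#' @return a `report_bundle` list with the stage results and `summary`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  stages <- config$stages
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (!"simulate" %in% stages) {
    stop("missing required input: the bundled pipeline runs from the 'simulate' stage")
  }
  sim_args <- config$sim
  sim_args$rng_seed <- config$seed
  sc <- do.call(sim_config, sim_args)
  sim <- generate_mitogenome(sc)
  comp <- generate_companion_genomes(sim, sc)
  write_fasta(sim$genome$seq, file.path(config$outdir, "mito.fasta"))
  write_fasta(comp$plastome$seq, file.path(config$outdir, "plastome.fasta"))
  write_gff3(sim$genes, file.path(config$outdir, "genes.gff3"),
             nchar(sim$genome$seq))
  write_manifest(rbind(sim$manifest, comp$manifest),
                 file.path(config$outdir, "truth_manifest.tsv"))
  bundle <- list(config = config, sim = sim, companions = comp)
  summary <- list(n_chromosomes = sc$n_chromosomes)

  if ("stats" %in% stages) {
    st <- genome_stats(sim$genome)
    write_tsv(st$per_chromosome, config$outdir, "genome_stats")
    bundle$stats <- st
    summary$total_length <- st$total_length
    summary$genome_gc <- st$genome_gc
  }
  cds <- extract_cds(sim$genome, sim$genes)
  if ("codon" %in% stages) {
    usage <- count_codons(cds, unique_cds = TRUE)
    gcpos <- positional_gc(usage)
    r <- rscu(usage)
    codon_tab <- data.frame(codon = names(usage$counts),
                            count = as.integer(usage$counts),
                            rscu = as.numeric(r[names(usage$counts)]),
                            stringsAsFactors = FALSE)
    write_tsv(codon_tab, config$outdir, "codon_usage")
    bundle$codon <- list(usage = usage, positional_gc = gcpos, rscu = r,
                         nc = effective_number_of_codons(usage))
    summary$n_codons <- usage$n_codons
    summary$nc <- bundle$codon$nc
  }
  if ("editing" %in% stages) {
    truth <- apply_editing_truth(cds, sc$editing_rate, seed = config$seed)
    refs <- stats::setNames(
      vapply(truth$edited, function(x) sub("\\*$", "", translate_cds(x)), ""),
      names(truth$edited))
    pred <- NULL
    for (gene in names(cds)) {
      ev <- predict_edit_sites(cds[gene], refs[[gene]],
                               cutoff = config$params$editing$cutoff)
      pred <- rbind(pred, ev)
    }
    if (is.null(pred)) pred <- truth$events[0, ]
    write_tsv(pred, config$outdir, "editing_events")
    bundle$editing <- list(truth = truth$events, predicted = pred,
                           summary = summarize_edits(pred))
    summary$n_editing_events <- nrow(pred)
  }
  if ("repeats" %in% stages) {
    p <- config$params$repeats
    ssrs <- do.call(rbind, lapply(names(sim$genome$seq), function(ch) {
      find_ssrs(sim$genome$seq[[ch]], chrom = ch, circular = TRUE)
    }))
    tandems <- do.call(rbind, lapply(names(sim$genome$seq), function(ch) {
      find_tandem_repeats(sim$genome$seq[[ch]], min_unit = p$tandem_min_unit,
                          min_match = p$tandem_min_match, chrom = ch,
                          circular = TRUE)
    }))
    excl <- rbind(ssrs[, c("chromosome", "start", "end")],
                  tandems[, c("chromosome", "start", "end")])
    disp <- find_dispersed_repeats(sim$genome$seq,
                                   min_len = p$dispersed_min_len,
                                   min_identity = p$dispersed_min_identity,
                                   max_e = p$dispersed_max_e, exclude = excl)
    write_tsv(ssrs, config$outdir, "ssr")
    write_tsv(tandems, config$outdir, "tandem")
    write_tsv(disp, config$outdir, "dispersed")
    rsum <- repeat_summary(ssrs, tandems, disp)
    bundle$repeats <- list(ssrs = ssrs, tandems = tandems, dispersed = disp,
                           summary = rsum)
    summary$repeat_totals <- rsum$totals
  }
  if ("transfer" %in% stages) {
    p <- config$params$transfer
    frags <- find_homologous_fragments(sim$genome, comp$plastome,
                                       min_identity = p$min_identity,
                                       min_len = p$min_len, max_e = p$max_e)
    cov <- merged_coverage(frags, sim$genome)
    write_tsv(frags, config$outdir, "transfer_fragments")
    write_tsv(cov$per_chromosome, config$outdir, "transfer_coverage")
    bundle$transfer <- list(fragments = frags, coverage = cov)
    summary$transfer_covered_bp <- cov$covered_bp
    summary$transfer_fraction <- cov$fraction
  }
  if ("recruit" %in% stages) {
    p <- config$params$recruit
    reads <- simulate_reads(list(mito = sim$genome, nuclear = comp$nuclear),
                            sc$read_params, seed = config$seed)
    write_fastq(reads$reads, file.path(config$outdir, "reads.fastq"))
    cand <- select_candidates(reads$reads, cds,
                              min_match_bp = p$min_match_bp)
    seeds <- choose_seed(cand$matches, cover = TRUE)
    state <- recruit_iteratively(reads$reads, seeds,
                                 min_overlap_bp = p$min_overlap_bp,
                                 min_identity = p$min_identity,
                                 max_iter = p$max_iter)
    write_fastq(reads$reads[state$recruited],
                file.path(config$outdir, "recruited.fastq"))
    write_tsv(state$iterations, config$outdir, "recruit_iterations")
    scores <- recruitment_scores(state, reads$origins)
    bundle$recruit <- list(state = state, scores = scores,
                           origins = reads$origins)
    summary$recruit_recall <- scores$recall
    summary$recruit_precision <- scores$precision
  }
  # cross-check: summary numbers must equal the stage-output aggregates
  if (!is.null(bundle$repeats)) {
    stopifnot(summary$repeat_totals[["all"]] ==
                nrow(bundle$repeats$ssrs) + nrow(bundle$repeats$tandems) +
                nrow(bundle$repeats$dispersed))
  }
  if (!is.null(bundle$stats)) {
    stopifnot(summary$total_length == sum(bundle$stats$per_chromosome$length))
  }
  bundle$summary <- summary
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle with stages:",
      paste(intersect(names(x), c("stats", "codon", "editing", "repeats",
                                  "transfer", "recruit")), collapse = ", "),
      "\n")
  invisible(x)
}
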