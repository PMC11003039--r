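# Synthetic multichromosomal genome generator with a ground-truth manifest.
# Defaults emulate the study system: 19 circular chromosomes of 22-48 kb at
# ~44% GC, 1-4 protein-coding genes per chromosome, microsatellites, tandem
# arrays, dispersed repeats, plastid-shared segments spanning the observed
# MTPT length spectrum, short NUMT-like mito->nuclear segments, C->U editing
# in CDS, and ~10 kb long reads.

#' Simulation configuration
#'
#' Builds the configuration consumed by [generate_mitogenome()],
#' [generate_companion_genomes()] and [simulate_reads()]. Defaults describe a
#' 19-chromosome circular mitogenome of 21,995-48,212 bp chromosomes at 44% GC.
#'
#' @param n_chromosomes number of circular mitochondrial chromosomes
#' @param chrom_length_range `(min_bp, max_bp)` for chromosome lengths
#' @param gc_target background GC fraction (0-1, exclusive)
#' @param n_genes_per_chrom protein-coding genes planted per chromosome
#' @param plastid_insert_spec list of `c(length_bp, identity)` pairs for
#'   segments shared between the mitogenome and the plastome; the default
#'   spans the 37 bp - 11 kb range at 0.75-1.0 identity
#' @param nuclear_insert_spec list of `c(length_bp, identity)` for NUMT-like
#'   mito-derived nuclear segments (kept under 1 kb so that nuclear reads
#'   cannot legitimately overlap mitochondrial reads by 1 kb)
#' @param ssr_plan,tandem_plan,dispersed_plan per-chromosome planted-repeat
#'   descriptor lists; see [default_ssr_plan()] and friends
#' @param editing_rate expected C-to-U edits per CDS (Poisson)
#' @param read_params list with `mean_len` (bp), `error_rate` (substitutions
#'   per base) and `depth` (fold coverage)
#' @param n_nuclear_chromosomes,nuclear_chrom_length nuclear decoy genome shape
#' @param plastome_length plastome length in bp
#' @param rng_seed integer seed; identical configs give byte-identical outputs
#' @return a `sim_config` list
#' @export
sim_config <- function(n_chromosomes = 19,
                       chrom_length_range = c(21995, 48212),
                       gc_target = 0.44,
                       n_genes_per_chrom = 2,
                       plastid_insert_spec = default_plastid_inserts(),
                       nuclear_insert_spec = default_nuclear_inserts(),
                       ssr_plan = default_ssr_plan(),
                       tandem_plan = default_tandem_plan(),
                       dispersed_plan = default_dispersed_plan(),
                       editing_rate = 18,
                       read_params = list(mean_len = 10000, error_rate = 0.05,
                                          depth = 20),
                       n_nuclear_chromosomes = 4,
                       nuclear_chrom_length = 60000,
                       plastome_length = 45000,
                       rng_seed = 1L) {
  stopifnot(n_chromosomes >= 1,
            length(chrom_length_range) == 2,
            all(chrom_length_range > 0),
            chrom_length_range[1] <= chrom_length_range[2],
            gc_target > 0, gc_target < 1,
            n_genes_per_chrom >= 0,
            editing_rate >= 0,
            read_params$mean_len > 0, read_params$depth >= 0,
            read_params$error_rate >= 0, read_params$error_rate < 1)
  for (ins in c(plastid_insert_spec, nuclear_insert_spec)) {
    if (ins[1] <= 0) stop("insert length must be positive")
    if (ins[2] < 0 || ins[2] > 1) stop("identity must be in [0, 1]")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_range = as.integer(chrom_length_range),
    gc_target = gc_target,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    plastid_insert_spec = plastid_insert_spec,
    nuclear_insert_spec = nuclear_insert_spec,
    ssr_plan = ssr_plan, tandem_plan = tandem_plan,
    dispersed_plan = dispersed_plan,
    editing_rate = editing_rate,
    read_params = read_params,
    n_nuclear_chromosomes = as.integer(n_nuclear_chromosomes),
    nuclear_chrom_length = as.integer(nuclear_chrom_length),
    plastome_length = as.integer(plastome_length),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Default planted microsatellites (per chromosome)
#'
#' One run of each descriptor is planted on every chromosome; motifs cover the
#' monomer/dimer/trimer/tetramer/pentamer classes at or above the MISA minima
#' (1-10 2-5 3-4 4-3 5-3 6-3).
#' @return list of `list(motif=, copies=)`
#' @export
default_ssr_plan <- function() {
  list(list(motif = "A", copies = 12),
       list(motif = "T", copies = 11),
       list(motif = "AG", copies = 6),
       list(motif = "AT", copies = 5),
       list(motif = "AAG", copies = 4),
       list(motif = "AAAC", copies = 3),
       list(motif = "AGAT", copies = 3),
       list(motif = "AGAGG", copies = 3))
}

#' Default planted tandem arrays (per chromosome)
#' @return list of `list(unit_length=, copies=, n_sub=)`
#' @export
default_tandem_plan <- function() {
  list(list(unit_length = 12, copies = 4, n_sub = 0),
       list(unit_length = 20, copies = 3, n_sub = 1))
}

#' Default planted dispersed repeats (per chromosome)
#'
#' Copies are pasted onto a random chromosome (possibly another one), forward
#' or reverse-complemented, at the stated Hamming identity.
#' @return list of `list(length=, identity=, orientation=)`
#' @export
default_dispersed_plan <- function() {
  list(list(length = 30, identity = 1.0, orientation = "forward"),
       list(length = 60, identity = 0.95, orientation = "palindromic"),
       list(length = 120, identity = 0.95, orientation = "forward"),
       list(length = 300, identity = 0.98, orientation = "palindromic"))
}

#' Default mitogenome-plastome shared segments
#'
#' Lengths/identities span the MTPT spectrum reported for multichromosomal
#' orchid mitogenomes (tens of bp to >10 kb, identity 0.74-1.0); segments at
#' low identity are long so they stay detectable at E <= 1e-5.
#' @return list of `c(length_bp, identity)`
#' @export
default_plastid_inserts <- function() {
  list(c(11000, 0.95), c(5000, 0.98), c(2000, 0.85), c(800, 0.80),
       c(500, 0.75), c(200, 0.90), c(100, 1.0), c(37, 1.0))
}

#' Default NUMT-like mito-derived nuclear segments (all < 1 kb)
#' @return list of `c(length_bp, identity)`
#' @export
default_nuclear_inserts <- function() {
  list(c(800, 0.92), c(600, 0.95), c(400, 0.98), c(300, 1.0), c(200, 0.90))
}

# --- placement bookkeeping -------------------------------------------------

new_occupancy <- function(lengths) lapply(lengths, function(l) {
  list(len = l, iv = matrix(numeric(0), ncol = 2))
})

# find a free [s, s+len) interval with margin; 0-based
allocate_interval <- function(occ, chrom, len, margin = 10, tries = 400) {
  st <- occ[[chrom]]
  if (len + 2 * margin >= st$len) {
    stop(sprintf("infeasible plan: feature of %d bp does not fit on chromosome %s",
                 len, names(occ)[chrom]))
  }
  for (i in seq_len(tries)) {
    s <- sample.int(st$len - len - margin, 1) + margin
    ok <- TRUE
    if (nrow(st$iv)) {
      ok <- all(s + len + margin <= st$iv[, 1] | s - margin >= st$iv[, 2])
    }
    if (ok) return(s - 1L)  # to 0-based
  }
  stop(sprintf("infeasible plan: no room left for a %d bp feature on chromosome %s",
               len, names(occ)[chrom]))
}

mark_interval <- function(occ, chrom, start, end) {
  occ[[chrom]]$iv <- rbind(occ[[chrom]]$iv, c(start, end))
  occ
}

paste_segment <- function(seq, start, segment) {
  paste0(substr(seq, 1, start), segment,
         substr(seq, start + nchar(segment) + 1, nchar(seq)))
}

manifest_row <- function(kind, genome, chrom, start, end, strand = "+",
                         payload = "", partner_genome = NA, partner_chrom = NA,
                         partner_start = NA, partner_end = NA, identity = NA) {
  data.frame(kind = kind, genome = genome, chrom = chrom,
             start = as.integer(start), end = as.integer(end), strand = strand,
             payload = payload, partner_genome = partner_genome,
             partner_chrom = partner_chrom,
             partner_start = as.integer(partner_start),
             partner_end = as.integer(partner_end),
             identity = as.numeric(identity), stringsAsFactors = FALSE)
}

empty_manifest <- function() {
  manifest_row(character(0), character(0), character(0), integer(0),
               integer(0), character(0), character(0), character(0),
               character(0), integer(0), integer(0), numeric(0))
}

random_cds <- function(n_codons) {
  sense <- setdiff(names(codon_table()), c("TAA", "TAG", "TGA"))
  body <- sample(sense, n_codons - 2, replace = TRUE)
  paste0("ATG", paste0(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

# --- genome objects --------------------------------------------------------

#' Construct a genome object
#' @param seqs named character vector of chromosome sequences
#' @param topology "circular" or "linear", recycled per chromosome
#' @return an `mc_genome` list with `$seq` and `$topology`
#' @export
mc_genome <- function(seqs, topology = "circular") {
  stopifnot(!is.null(names(seqs)))
  structure(list(seq = seqs,
                 topology = stats::setNames(rep(topology,
                                                length.out = length(seqs)),
                                            names(seqs))),
            class = "mc_genome")
}

#' @export
print.mc_genome <- function(x, ...) {
  cat(sprintf("mc_genome: %d chromosome(s), %s bp total\n", length(x$seq),
              format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

genome_seqs <- function(g) if (inherits(g, "mc_genome")) g$seq else g

# --- main generators -------------------------------------------------------

#' Generate a multichromosomal mitochondrial genome with planted features
#'
#' Background bases are i.i.d. at `gc_target`. Protein-coding genes (valid ATG
#' start, TAA/TAG/TGA stop, no internal stops), microsatellites, tandem arrays
#' and dispersed repeats are planted at non-overlapping positions and recorded
#' in a truth manifest (0-based half-open coordinates).
#'
#' @param config a [sim_config()]
#' @return list with `genome` (an [mc_genome()]), `genes` (data.frame:
#'   gene_id, chrom, start, end, strand), `manifest` (truth data.frame) and
#'   `config`
#' @export
generate_mitogenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_chromosomes
  lens <- if (config$chrom_length_range[1] == config$chrom_length_range[2]) {
    rep(config$chrom_length_range[1], n)
  } else {
    sample(seq(config$chrom_length_range[1], config$chrom_length_range[2]), n,
           replace = TRUE)
  }
  chrom_names <- sprintf("chr%d", seq_len(n))
  seqs <- stats::setNames(vapply(lens, random_dna, "", gc = config$gc_target),
                          chrom_names)
  occ <- stats::setNames(new_occupancy(lens), chrom_names)
  manifest <- empty_manifest()
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  gidx <- 0L
  for (ci in seq_len(n)) {
    for (gi in seq_len(config$n_genes_per_chrom)) {
      gidx <- gidx + 1L
      n_codons <- sample(seq(100, 500), 1)
      cds <- random_cds(n_codons)
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") cds else rc(cds)
      s <- allocate_interval(occ, ci, nchar(planted))
      seqs[ci] <- paste_segment(seqs[ci], s, planted)
      occ <- mark_interval(occ, ci, s, s + nchar(planted))
      gene_id <- sprintf("gene%03d", gidx)
      genes <- rbind(genes, data.frame(
        gene_id = gene_id, chrom = chrom_names[ci], start = s,
        end = s + nchar(planted), strand = strand, stringsAsFactors = FALSE))
      manifest <- rbind(manifest, manifest_row(
        "gene", "mito", chrom_names[ci], s, s + nchar(planted), strand,
        gene_id))
    }
  }
  for (ci in seq_len(n)) {
    for (d in config$ssr_plan) {
      run <- strrep(d$motif, d$copies)
      s <- allocate_interval(occ, ci, nchar(run))
      seqs[ci] <- paste_segment(seqs[ci], s, run)
      occ <- mark_interval(occ, ci, s, s + nchar(run))
      manifest <- rbind(manifest, manifest_row(
        "ssr", "mito", chrom_names[ci], s, s + nchar(run), "+",
        paste0(d$motif, "x", d$copies)))
    }
    for (d in config$tandem_plan) {
      unit <- random_dna(d$unit_length, config$gc_target)
      arr <- strrep(unit, d$copies)
      if (d$n_sub > 0) arr <- mutate_substitutions(arr, d$n_sub)$seq
      s <- allocate_interval(occ, ci, nchar(arr))
      seqs[ci] <- paste_segment(seqs[ci], s, arr)
      occ <- mark_interval(occ, ci, s, s + nchar(arr))
      manifest <- rbind(manifest, manifest_row(
        "tandem", "mito", chrom_names[ci], s, s + nchar(arr), "+",
        paste0(d$unit_length, "bp x", d$copies)))
    }
  }
  # dispersed repeats last, so the copied source content is final
  for (ci in seq_len(n)) {
    for (d in config$dispersed_plan) {
      src_chrom <- ci
      src <- allocate_interval(occ, src_chrom, d$length)
      occ <- mark_interval(occ, src_chrom, src, src + d$length)
      segment <- substr(seqs[src_chrom], src + 1, src + d$length)
      n_sub <- round((1 - d$identity) * d$length)
      copy <- mutate_substitutions(segment, n_sub)$seq
      if (d$orientation == "palindromic") copy <- rc(copy)
      dst_chrom <- sample.int(n, 1)
      dst <- allocate_interval(occ, dst_chrom, d$length)
      seqs[dst_chrom] <- paste_segment(seqs[dst_chrom], dst, copy)
      occ <- mark_interval(occ, dst_chrom, dst, dst + d$length)
      manifest <- rbind(manifest, manifest_row(
        "dispersed", "mito", chrom_names[src_chrom], src, src + d$length, "+",
        d$orientation, "mito", chrom_names[dst_chrom], dst, dst + d$length,
        1 - n_sub / d$length))
    }
  }
  bad <- manifest$end > nchar(seqs)[match(manifest$chrom, chrom_names)]
  if (any(bad)) stop("internal error: planted feature out of range")
  list(genome = mc_genome(seqs, "circular"), genes = genes,
       manifest = manifest, config = config)
}

#' Generate companion plastid and nuclear genomes sharing segments with the
#' mitogenome
#'
#' Segments of the mitochondrial chromosomes are copied (with point mutations
#' to reach the requested Hamming identity) into a circular plastome and into
#' linear nuclear chromosomes, so every shared segment exists in both genomes
#' and is recorded with both coordinate pairs.
#'
#' @param mito result of [generate_mitogenome()] (or an [mc_genome()])
#' @param config the [sim_config()] used for the mitogenome
#' @return list with `plastome`, `nuclear` (both [mc_genome()]) and `manifest`
#' @export
generate_companion_genomes <- function(mito, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  mseqs <- if (inherits(mito, "mc_genome")) mito$seq else mito$genome$seq
  plast <- stats::setNames(random_dna(config$plastome_length,
                                      config$gc_target + 0.02), "ptDNA")
  nuc_names <- sprintf("nchr%d", seq_len(config$n_nuclear_chromosomes))
  nuc <- stats::setNames(vapply(rep(config$nuclear_chrom_length,
                                    config$n_nuclear_chromosomes),
                                random_dna, "", gc = config$gc_target - 0.04),
                         nuc_names)
  manifest <- empty_manifest()
  plant_into <- function(host_seqs, host_genome, spec) {
    occ <- stats::setNames(new_occupancy(nchar(host_seqs)), names(host_seqs))
    for (ins in spec) {
      len <- as.integer(ins[1]); ident <- ins[2]
      eligible <- names(mseqs)[nchar(mseqs) > len + 40]
      if (length(eligible) == 0) {
        stop(sprintf("infeasible plan: no mitochondrial chromosome can donate a %d bp segment", len))
      }
      src_chrom <- sample(eligible, 1)
      src <- sample.int(nchar(mseqs[[src_chrom]]) - len, 1) - 1L
      segment <- substr(mseqs[[src_chrom]], src + 1, src + len)
      copy <- mutate_substitutions(segment, round((1 - ident) * len))$seq
      hi <- sample.int(length(host_seqs), 1)
      dst <- allocate_interval(occ, hi, len)
      host_seqs[hi] <- paste_segment(host_seqs[hi], dst, copy)
      occ <- mark_interval(occ, hi, dst, dst + len)
      manifest <<- rbind(manifest, manifest_row(
        "transfer", "mito", src_chrom, src, src + len, "+", host_genome,
        host_genome, names(host_seqs)[hi], dst, dst + len,
        1 - round((1 - ident) * len) / len))
    }
    host_seqs
  }
  plast <- plant_into(plast, "plastid", config$plastid_insert_spec)
  nuc <- plant_into(nuc, "nuclear", config$nuclear_insert_spec)
  list(plastome = mc_genome(plast, "circular"),
       nuclear = mc_genome(nuc, "linear"),
       manifest = manifest)
}

#' Simulate long reads from one or more genomes
#'
#' Read lengths are normal around `mean_len` (sd 10%), truncated to
#' `[0.5, 1.5] * mean_len`; starts are uniform; reads from circular templates
#' may span the origin. Errors are uniform substitutions. Each read's origin
#' (genome label, chromosome, interval, strand) is recorded.
#'
#' @param genomes named list of [mc_genome()] objects; names become origin
#'   labels (e.g. `list(mito = ..., nuclear = ...)`)
#' @param read_params list with `mean_len`, `error_rate`, `depth`
#' @param seed RNG seed
#' @return list with `reads` (named character vector) and `origins`
#'   (data.frame: read_id, genome, chrom, start, end, strand, length)
#' @export
simulate_reads <- function(genomes, read_params, seed = 1L) {
  stopifnot(read_params$depth > 0)
  set.seed(seed)
  reads <- character(0)
  origins <- data.frame(read_id = character(0), genome = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        length = integer(0), stringsAsFactors = FALSE)
  for (glab in names(genomes)) {
    g <- genomes[[glab]]
    for (chrom in names(g$seq)) {
      seq <- g$seq[[chrom]]
      len <- nchar(seq)
      circular <- g$topology[[chrom]] == "circular"
      if (!circular && read_params$mean_len > len) {
        stop(sprintf("mean read length %d exceeds linear chromosome %s (%d bp)",
                     read_params$mean_len, chrom, len))
      }
      n_reads <- max(1L, round(read_params$depth * len / read_params$mean_len))
      for (i in seq_len(n_reads)) {
        rl <- round(stats::rnorm(1, read_params$mean_len,
                                 0.1 * read_params$mean_len))
        rl <- max(round(0.5 * read_params$mean_len),
                  min(round(1.5 * read_params$mean_len), rl))
        if (!circular) rl <- min(rl, len)
        s <- sample.int(if (circular) len else len - rl + 1L, 1) - 1L
        raw <- if (s + rl <= len) {
          substr(seq, s + 1, s + rl)
        } else { # origin-spanning read on a circular template
          paste0(substr(seq, s + 1, len), substr(seq, 1, s + rl - len))
        }
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") raw <- rc(raw)
        n_err <- stats::rbinom(1, rl, read_params$error_rate)
        if (n_err > 0) raw <- mutate_substitutions(raw, n_err)$seq
        rid <- sprintf("%s_%s_r%04d", glab, chrom, i)
        reads[[rid]] <- raw
        origins <- rbind(origins, data.frame(
          read_id = rid, genome = glab, chrom = chrom, start = s,
          end = s + rl, strand = strand, length = rl, stringsAsFactors = FALSE))
      }
    }
  }
  list(reads = reads, origins = origins)
}

#' Plant C-to-U editing events into CDS transcripts
#'
#' Each CDS receives a Poisson(`editing_rate`) number of C->T edits at codon
#' positions 1 or 2. By default only nonsynonymous, non-stop-creating edits
#' are planted so transcripts stay translatable and predictor recall is
#' well-defined; the classifier itself handles stop gains.
#'
#' @param cds named character vector of in-frame CDS sequences
#' @param editing_rate expected edits per CDS
#' @param seed RNG seed
#' @param allow_stop permit edits creating a stop codon
#' @param allow_synonymous permit synonymous position-1 edits (CTA/CTG -> TTA/TTG)
#' @return list with `edited` (edited transcript sequences) and `events`
#'   (data.frame of truth [classify_edit()] records plus gene_id, codon_index)
#' @export
apply_editing_truth <- function(cds, editing_rate, seed = 1L,
                                allow_stop = FALSE, allow_synonymous = FALSE) {
  set.seed(seed)
  gc_map <- codon_table()
  edited <- cds
  events <- NULL
  for (gene in names(cds)) {
    codons <- split_codons(cds[[gene]])
    if (any(gc_map[codons[-length(codons)]] == "*")) {
      stop(sprintf("CDS %s contains an internal stop codon", gene))
    }
    cand <- list()
    for (i in seq_along(codons)) {
      if (gc_map[[codons[i]]] == "*") next
      for (pos in 1:2) {
        if (substr(codons[i], pos, pos) != "C") next
        new <- codons[i]
        substr(new, pos, pos) <- "T"
        aa_new <- gc_map[[new]]
        if (!allow_stop && aa_new == "*") next
        if (!allow_synonymous && aa_new == gc_map[[codons[i]]]) next
        cand[[length(cand) + 1]] <- list(idx = i, pos = pos, new = new)
      }
    }
    n_ev <- min(stats::rpois(1, editing_rate), length(cand))
    if (n_ev == 0 || length(cand) == 0) next
    pick_idx <- sample(seq_along(cand), n_ev)
    # at most one edit per codon
    picked <- cand[pick_idx]
    picked <- picked[!duplicated(vapply(picked, function(p) p$idx, 0L))]
    for (p in picked) {
      ev <- classify_edit(codons[p$idx], p$new)
      ev$gene_id <- gene
      ev$codon_index <- p$idx - 1L
      events <- rbind(events, ev)
      codons[p$idx] <- p$new
    }
    edited[[gene]] <- paste0(codons, collapse = "")
  }
  if (is.null(events)) {
    events <- cbind(classify_edit("TCA", "TTA"),
                    gene_id = "x", codon_index = 0L)[0, ]
  }
  list(edited = edited, events = events)
}

# --- file emission ---------------------------------------------------------

#' Write gene models as GFF3
#'
#' Coordinates are converted from the package's 0-based half-open convention
#' to GFF3 1-based inclusive. A feature extending past the end of a circular
#' chromosome is emitted as two parts sharing an ID.
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand
#' @param path output file
#' @param chrom_lengths named integer vector of chromosome lengths
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path, chrom_lengths) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(chrom_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch, chrom_lengths[[ch]]), con)
  }
  emit <- function(type, ch, s, e, strand, id, parent = NULL) {
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    writeLines(paste(ch, "mitocharter", type, s, e, ".", strand, ".", attrs,
                     sep = "\t"), con)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- chrom_lengths[[g$chrom]]
    parts <- if (g$end <= L) {
      list(c(g$start + 1, g$end))
    } else { # origin-spanning: two parts sharing the ID
      list(c(g$start + 1, L), c(1, g$end - L))
    }
    for (p in parts) emit("gene", g$chrom, p[1], p[2], g$strand, g$gene_id)
    for (p in parts) {
      emit("exon", g$chrom, p[1], p[2], g$strand,
           paste0(g$gene_id, ".exon"), g$gene_id)
      emit("CDS", g$chrom, p[1], p[2], g$strand,
           paste0(g$gene_id, ".cds"), g$gene_id)
    }
  }
  invisible(path)
}

#' Read gene models from a GFF3 file written by [write_gff3()]
#' @param path GFF3 file
#' @return data.frame with gene_id, chrom, start, end, strand (0-based
#'   half-open; origin-spanning parts re-joined)
#' @export
read_gff3_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, function(x) length(x) == 9 && x[3] == "gene", TRUE)]
  df <- do.call(rbind, lapply(f, function(x) {
    id <- sub("^.*ID=([^;]+).*$", "\\1", x[9])
    data.frame(gene_id = id, chrom = x[1], start = as.integer(x[4]) - 1L,
               end = as.integer(x[5]), strand = x[7], stringsAsFactors = FALSE)
  }))
  # rejoin origin-spanning parts (same ID, two rows)
  out <- NULL
  for (id in unique(df$gene_id)) {
    rows <- df[df$gene_id == id, , drop = FALSE]
    if (nrow(rows) == 1) { out <- rbind(out, rows); next }
    main <- rows[which.max(rows$start), , drop = FALSE]
    wrap <- rows[which.min(rows$start), , drop = FALSE]
    main$end <- main$end + wrap$end
    out <- rbind(out, main)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Extract (strand-aware) CDS sequences for gene models
#'
#' Supports genes running across the origin of a circular chromosome
#' (end > chromosome length wraps around).
#' @param genome an [mc_genome()] or named character vector
#' @param genes gene model data.frame (gene_id, chrom, start, end, strand)
#' @return named character vector of CDS sequences
#' @export
extract_cds <- function(genome, genes) {
  seqs <- genome_seqs(genome)
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seq <- seqs[[g$chrom]]
    L <- nchar(seq)
    s <- if (g$end <= L) {
      substr(seq, g$start + 1, g$end)
    } else {
      paste0(substr(seq, g$start + 1, L), substr(seq, 1, g$end - L))
    }
    out[i] <- if (g$strand == "-") rc(s) else s
  }
  stats::setNames(out, genes$gene_id)
}

#' Write a truth manifest as TSV
#' @param manifest manifest data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
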