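# Pipeline orchestration: a validated run configuration plus the two
# composite stages (annotate one genome; compare two or more annotated
# genomes). All outputs are plain TSV/GFF3 for diff-ability; progress goes
# to stderr via message().

CONFIG_DEFAULTS <- list(
  species = NULL, fasta = NULL, gff = NULL, hits = NULL,
  genomes = NULL,                 # for compare: list of {species, fasta, gff}
  out_dir = ".", seed = 1L, verbose = TRUE,
  min_protein_aa = 50L, intron_min = 18L, intron_max = 23L,
  max_introns_per_gene = 12L, require_atg = TRUE,
  evalue_cutoff = 0.001, min_genes = 4L, max_gap = 3L,
  min_dup_len = 1000L, subtel_search_depth = 50000L, min_subtel_unit = 100L)

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; absent keys take their documented defaults.
#'
#' @param path YAML file.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw)
  structure(cfg, class = "run_config")
}

#' Build a run configuration from arguments
#'
#' @param ... configuration values overriding the defaults (same keys as the
#'   YAML file; unknown keys rejected).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  raw <- list(...)
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(utils::modifyList(CONFIG_DEFAULTS, raw), class = "run_config")
}

say <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

caller_params_from <- function(cfg) {
  caller_params(min_protein_aa = cfg$min_protein_aa,
                intron_min = cfg$intron_min, intron_max = cfg$intron_max,
                max_introns_per_gene = cfg$max_introns_per_gene,
                require_atg = cfg$require_atg)
}

#' Annotate a genome end to end
#'
#' Chains gene calling, optional homology-based classification, telomere /
#' subtelomere / duplication discovery, and writes GFF3 plus repeat TSVs to
#' the configured output directory.
#'
#' @param config a `run_config` with at least `fasta` set.
#' @return list with genome, annotation, telomeres, subtelomere,
#'   duplications, validation, and the output paths.
#' @export
run_annotate <- function(config) {
  if (is.null(config$fasta)) stop("config needs 'fasta'")
  if (!file.exists(config$fasta)) {
    stop(sprintf("no such file: %s", config$fasta))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- load_genome(config$fasta, species = config$species)
  say(config, "annotate: %s (%d chromosomes, %d bp)", genome$species,
      length(genome$chromosomes), total_bp(genome))
  params <- caller_params_from(config)
  annotation <- annotate_genome(genome, params)
  proteins <- attr(annotation, "proteins")
  if (!is.null(config$hits)) {
    hits <- read_hits_tsv(config$hits)
    for (i in seq_along(annotation$genes)) {
      id <- annotation$genes[[i]]$id
      annotation$genes[[i]]$category <-
        classify_gene(id, hits, config$evalue_cutoff)
    }
  }
  say(config, "annotate: %d gene models, %d introns",
      length(annotation$genes), nrow(annotation_introns(annotation)))

  telomeres <- list()
  for (cid in names(genome$chromosomes)) {
    for (e in c("left", "right")) {
      t <- detect_telomere(genome$chromosomes[[cid]], e,
                           chromosome_id = cid)
      if (!is.null(t)) telomeres[[length(telomeres) + 1L]] <- t
    }
  }
  tel_df <- if (length(telomeres) > 0L) {
    do.call(rbind, lapply(telomeres, function(t) {
      data.frame(chromosome_id = t$chromosome_id, end = t$end,
                 motif = t$motif, motif_observed = t$motif_observed,
                 copies = t$copies, start = t$span[1L], stop = t$span[2L],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame()
  }
  subtel <- if (length(genome$chromosomes) >= 2L) {
    find_shared_terminal_repeat(genome, config$subtel_search_depth,
                                config$min_subtel_unit)
  } else {
    NULL
  }
  excl <- if (!is.null(subtel) && subtel$unit_length > 0L) {
    data.frame(chromosome_id = subtel$occurrences$chromosome_id,
               start = subtel$occurrences$start,
               stop = subtel$occurrences$stop, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  dups <- find_duplicated_regions(genome, config$min_dup_len, exclude = excl)
  say(config, "repeats: %d telomere(s), subtelomeric unit %d bp, %d duplicated region(s)",
      nrow(tel_df), if (is.null(subtel)) 0L else subtel$unit_length,
      nrow(dups))

  gff_path <- file.path(config$out_dir,
                        paste0(genome$species, ".gff3"))
  write_annotation(annotation, gff_path)
  tel_path <- file.path(config$out_dir, paste0(genome$species,
                                               "_telomeres.tsv"))
  utils::write.table(tel_df, tel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dup_path <- file.path(config$out_dir, paste0(genome$species,
                                               "_duplications.tsv"))
  utils::write.table(dups, dup_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  validation <- validate_annotation(genome, annotation)
  list(genome = genome, annotation = annotation, proteins = proteins,
       telomeres = tel_df, subtelomere = subtel, duplications = dups,
       validation = validation,
       paths = c(gff = gff_path, telomeres = tel_path,
                 duplications = dup_path))
}

#' Compare two or more annotated genomes
#'
#' Builds homolog families from all-vs-all protein search, detects synteny
#' blocks for every genome pair, summarizes block statistics, gene content
#' and intron position conservation, and writes Table-1-style summaries.
#'
#' @param config a `run_config` whose `genomes` lists at least two entries
#'   with `species`, `fasta` and `gff` paths.
#' @return list with annotations, families, blocks (per pair),
#'   block_summaries, content, conservation, summaries.
#' @export
run_compare <- function(config) {
  if (is.null(config$genomes) || length(config$genomes) < 2L) {
    stop("compare needs at least 2 genomes")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- list()
  annotations <- list()
  proteins <- character(0)
  for (entry in config$genomes) {
    g <- load_genome(entry$fasta, species = entry$species)
    a <- load_annotation(entry$gff, g)
    genomes[[g$species]] <- g
    annotations[[g$species]] <- a
    prots <- vapply(Filter(is_protein_coding, a$genes), function(gene) {
      translate_gene(gene, g)
    }, character(1L))
    proteins <- c(proteins, prots)
    say(config, "compare: loaded %s (%d genes)", g$species, length(a$genes))
  }
  sp <- names(annotations)
  hits <- list()
  for (i in seq_along(sp)) {
    for (j in i:length(sp)) {
      pa <- proteins[names(proteins) %in%
                       vapply(annotations[[sp[i]]]$genes, `[[`,
                              character(1L), "id")]
      pb <- proteins[names(proteins) %in%
                       vapply(annotations[[sp[j]]]$genes, `[[`,
                              character(1L), "id")]
      hits[[length(hits) + 1L]] <- search_homologs(pa, pb)
    }
  }
  hits <- do.call(rbind, hits)
  families <- build_families(hits, config$evalue_cutoff,
                             all_genes = names(proteins))
  annotations <- lapply(annotations, assign_families, families = families)
  say(config, "compare: %d families", length(unique(families$family_id)))

  blocks <- list()
  block_summaries <- list()
  for (i in seq_len(length(sp) - 1L)) {
    for (j in (i + 1L):length(sp)) {
      key <- paste(sp[i], sp[j], sep = "~")
      b <- find_synteny_blocks(annotations[[sp[i]]], annotations[[sp[j]]],
                               families, min_genes = config$min_genes,
                               max_gap = config$max_gap)
      blocks[[key]] <- b
      block_summaries[[key]] <- block_summary(b)
      say(config, "compare: %s -> %d blocks (mean %.1f genes)", key,
          block_summaries[[key]][["n_blocks"]],
          block_summaries[[key]][["mean_genes"]])
    }
  }
  content <- gene_content_comparison(annotations)

  # intron conservation over families with members in every genome
  fam_split <- split(families$gene_id, families$family_id)
  genome_of <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in sp) {
    for (g in annotations[[s]]$genes) genome_of[[g$id]] <- s
  }
  positions <- list()
  for (fid in names(fam_split)) {
    members <- fam_split[[fid]]
    members <- members[members %in% names(proteins)]
    gs <- vapply(members, function(m) genome_of[[m]], character(1L))
    if (length(unique(gs)) < 2L) next
    # one member per genome: keep the first by id order
    keep <- members[!duplicated(gs)]
    if (length(keep) < 2L) next
    msa <- align_family(proteins[keep])
    positions[[length(positions) + 1L]] <-
      map_intron_positions(fid, msa, annotations)
  }
  positions <- if (length(positions) > 0L) do.call(rbind, positions) else
    data.frame(family_id = character(), genome = character(),
               gene_id = character(), alignment_column = integer(),
               phase = integer(), stringsAsFactors = FALSE)
  conservation <- conservation_summary(positions, n_genomes = length(sp))

  summaries <- lapply(sp, function(s) {
    summary_report(genomes[[s]], annotations[[s]])
  })
  names(summaries) <- sp

  sum_path <- file.path(config$out_dir, "genome_summaries.tsv")
  utils::write.table(do.call(rbind, lapply(summaries, as.data.frame)),
                     sum_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fam_path <- file.path(config$out_dir, "families.tsv")
  utils::write.table(families, fam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  blk_path <- file.path(config$out_dir, "synteny_blocks.tsv")
  blk_rows <- list()
  for (key in names(blocks)) {
    for (b in blocks[[key]]) {
      blk_rows[[length(blk_rows) + 1L]] <- data.frame(
        pair = key, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
        orientation = b$orientation, size = b$size,
        genes_a = paste(b$pairs$gene_a, collapse = ","),
        genes_b = paste(b$pairs$gene_b, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(if (length(blk_rows)) do.call(rbind, blk_rows) else
    data.frame(), blk_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(genomes = genomes, annotations = annotations, families = families,
       hits = hits, blocks = blocks, block_summaries = block_summaries,
       content = content, positions = positions,
       conservation = conservation, summaries = summaries,
       paths = c(summaries = sum_path, families = fam_path,
                 blocks = blk_path))
}

#' Write a simulated genome to disk
#'
#' Writes FASTA, GFF3 and ground-truth TSVs for a `sim_truth`.
#'
#' @param truth a `sim_truth`.
#' @param out_dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_simulation <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, paste0(truth$species, ".fa"))
  gff <- file.path(out_dir, paste0(truth$species, ".gff3"))
  write_genome(truth$genome, fa)
  write_annotation(truth$annotation, gff)
  paths <- c(fasta = fa, gff = gff)
  for (part in c("telomeres", "subtelomeres", "duplications", "families",
                 "events")) {
    df <- truth[[part]]
    if (is.null(df)) next
    p <- file.path(out_dir, paste0(truth$species, "_", part, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[part]] <- p
  }
  invisible(paths)
}
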