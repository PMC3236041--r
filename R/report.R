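#' Genome summary statistics from FASTA (and optional annotation)
#'
#' Computes the usual genome-table statistics: total size, contig count,
#' G+C content (as a percentage of unambiguous A/C/G/T bases; `N` and
#' other ambiguity codes are excluded from the denominator), and — when
#' an annotation is supplied — the coding region size as the length of
#' the per-contig union of CDS intervals (overlaps counted once) and the
#' coding fraction of the genome.
#'
#' @param fasta Path to a nucleotide FASTA file, or a `DNAStringSet`.
#' @param annotation Optional path to a GFF3 file (CDS features, 1-based
#'   inclusive coordinates) or to a fallback gene-coordinates TSV with
#'   header columns `start` and `end` (optionally preceded by `contig`;
#'   single-contig genomes may omit it).
#' @return Object of class `genome_summary`: list with `size_bp`,
#'   `contigs`, `gc_bp`, `gc_pct`, `coding_bp`, `coding_fraction`,
#'   `gene_count` (number of annotation features; `NA` without
#'   annotation).
#' @export
genome_summary <- function(fasta, annotation = NULL) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) {
    fasta
  } else {
    Biostrings::readDNAStringSet(fasta)
  }
  if (length(seqs) == 0L) stop("FASTA contains no sequences", call. = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  tot <- colSums(af)
  acgt <- sum(tot[c("A", "C", "G", "T")])
  gc_bp <- sum(tot[c("C", "G")])
  size <- sum(Biostrings::width(seqs))
  coding_bp <- 0L
  gene_count <- NA_integer_
  if (!is.null(annotation)) {
    feats <- read_cds_features(annotation)
    if (anyNA(feats$contig)) {
      # contig-less fallback dialect: only unambiguous for one contig
      if (length(seqs) != 1L) {
        stop("coordinate table without a 'contig' column needs a ",
             "single-contig genome", call. = FALSE)
      }
      feats$contig[is.na(feats$contig)] <- names(seqs)
    }
    unknown <- !feats$contig %in% names(seqs)
    if (any(unknown)) {
      i <- which(unknown)[1L]
      stop("annotation feature ", i, " ('", feats$contig[i], "' ",
           feats$start[i], "..", feats$end[i],
           ") references an unknown contig", call. = FALSE)
    }
    gene_count <- nrow(feats)
    for (ctg in unique(feats$contig)) {
      f <- feats[feats$contig == ctg, , drop = FALSE]
      r <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
      coding_bp <- coding_bp + sum(IRanges::width(r))
    }
  }
  structure(list(
    size_bp = size, contigs = length(seqs),
    gc_bp = gc_bp, gc_pct = if (acgt > 0) 100 * gc_bp / acgt else NA_real_,
    coding_bp = as.integer(coding_bp),
    coding_fraction = coding_bp / size,
    gene_count = gene_count),
    class = "genome_summary")
}

# CDS intervals (1-based inclusive) from GFF3, or from the fallback
# gene-coordinates TSV dialect
read_cds_features <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff") ||
      length(strsplit(first, "\t", fixed = TRUE)[[1L]]) == 9L) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    if ("type" %in% names(df)) {
      df <- df[df$type == "CDS", , drop = FALSE]
    }
    if (nrow(df) == 0L) {
      stop("no CDS features in ", path, call. = FALSE)
    }
    return(data.frame(contig = as.character(df$seqnames),
                      start = df$start, end = df$end))
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("start", "end") %in% names(tab))) {
    stop("fallback coordinate table needs 'start' and 'end' columns",
         call. = FALSE)
  }
  data.frame(
    contig = if ("contig" %in% names(tab)) as.character(tab$contig)
             else NA_character_,
    start = as.integer(tab$start), end = as.integer(tab$end))
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("Genome summary\n")
  cat(sprintf("  size        : %s bp in %d contig(s)\n",
              format(x$size_bp, big.mark = ","), x$contigs))
  cat(sprintf("  G+C         : %s bp (%.2f%%)\n",
              format(x$gc_bp, big.mark = ","), x$gc_pct))
  cat(sprintf("  coding      : %s bp (%.2f%%)\n",
              format(x$coding_bp, big.mark = ","),
              100 * x$coding_fraction))
  if (!is.na(x$gene_count)) {
    cat(sprintf("  CDS features: %d\n", x$gene_count))
  }
  invisible(x)
}

# read a (possibly multi-contig) genome FASTA; contigs are concatenated
# with 100xN spacers so HSP coordinates stay single-sequence, while the
# true length (sum of contig lengths, spacers excluded) is kept for the
# ratio denominators
read_genome_concat <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA contains no sequences", call. = FALSE)
  true_len <- sum(Biostrings::width(seqs))
  spacer <- strrep("N", 100L)
  concat <- paste(as.character(seqs), collapse = spacer)
  list(seq = Biostrings::DNAString(concat), true_len = true_len,
       contigs = length(seqs))
}

#' Assemble a pipeline run configuration
#'
#' Collects inputs, parameters and the output directory for
#' [run_pipeline()]. Stages run only when their inputs are present:
#' `redundancy` (and the over-representation overlay) needs
#' `assignments`; `shared` needs three `proteomes`; `distance` needs two
#' `genomes`; `summary` needs `summary_fasta`.
#'
#' @param out_dir Output directory (created if missing).
#' @param assignments Path to a gene-to-category TSV.
#' @param genome_ids Genomes to profile (default: all in the table).
#' @param multi_policy Passed to [build_profile()].
#' @param top Ranks kept in the overlay TSV (default 100).
#' @param proteomes Named character vector of 3 protein FASTA paths.
#' @param genomes Character vector of 2 nucleotide FASTA paths.
#' @param summary_fasta,summary_annotation Inputs for [genome_summary()].
#' @param homology A [homology_params()].
#' @param word_size,xdrop,min_length,both_strands Passed to [find_hsps()].
#' @param seed Integer seed recorded in (and applied before) every stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, assignments = NULL, genome_ids = NULL,
                       multi_policy = "per_pair", top = 100L,
                       proteomes = NULL, genomes = NULL,
                       summary_fasta = NULL, summary_annotation = NULL,
                       homology = homology_params(), word_size = 11L,
                       xdrop = 20L, min_length = 50L,
                       both_strands = FALSE, seed = 42L) {
  for (p in c(assignments, proteomes, genomes, summary_fasta,
              summary_annotation)) {
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  }
  if (!is.null(proteomes) && length(proteomes) != 3L) {
    stop("'proteomes' must list exactly three FASTA files", call. = FALSE)
  }
  if (!is.null(genomes) && length(genomes) != 2L) {
    stop("'genomes' must list exactly two FASTA files", call. = FALSE)
  }
  structure(list(out_dir = out_dir, assignments = assignments,
                 genome_ids = genome_ids, multi_policy = multi_policy,
                 top = top, proteomes = proteomes, genomes = genomes,
                 summary_fasta = summary_fasta,
                 summary_annotation = summary_annotation,
                 homology = homology, word_size = word_size,
                 xdrop = xdrop, min_length = min_length,
                 both_strands = both_strands, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes every stage whose inputs are configured, writes one JSON
#' report per stage (plus plot-ready TSV tables) into `out_dir`, and a
#' combined `report.json`. Every JSON embeds the resolved configuration
#' and seed; output is deterministic given the seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  say <- function(...) if (!quiet) message(...)
  results <- list()
  cfg_json <- resolve_config(config)

  if (!is.null(config$assignments)) {
    say("stage redundancy: ", config$assignments)
    asg <- read_assignments(config$assignments)
    ids <- config$genome_ids
    if (is.null(ids)) ids <- unique(asg$genome_id)
    reds <- list()
    for (g in ids) {
      prof <- build_profile(asg, g, config$multi_policy)
      reds[[g]] <- redundancy_report(prof)
      utils::write.table(
        rank_overlay(prof, config$top),
        file.path(config$out_dir, paste0("overlay_", g, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$redundancy <- reds
    write_stage_json(lapply(reds, unclass),
                     file.path(config$out_dir, "redundancy.json"),
                     cfg_json)
  }

  if (!is.null(config$proteomes)) {
    say("stage shared: ", paste(config$proteomes, collapse = ", "))
    prots <- lapply(config$proteomes, Biostrings::readAAStringSet)
    names(prots) <- if (!is.null(names(config$proteomes)) &&
                        all(nzchar(names(config$proteomes)))) {
      names(config$proteomes)
    } else {
      sub("\\.[^.]*$", "", basename(config$proteomes))
    }
    prots <- lapply(prots, function(p) {
      names(p) <- sub("\\s.*$", "", names(p))
      p
    })
    vp <- venn3(prots, config$homology)
    results$shared <- vp
    write_stage_json(unclass(vp),
                     file.path(config$out_dir, "shared.json"), cfg_json)
  }

  if (!is.null(config$genomes)) {
    say("stage distance: ", paste(config$genomes, collapse = " vs "))
    ga <- read_genome_concat(config$genomes[1L])
    gb <- read_genome_concat(config$genomes[2L])
    hsps <- find_hsps(ga$seq, gb$seq, word_size = config$word_size,
                      xdrop = config$xdrop,
                      min_length = config$min_length,
                      both_strands = config$both_strands)
    gg <- ggdc_formulas(hsps, ga$true_len, gb$true_len)
    write_hsps(hsps, file.path(config$out_dir, "hsps.tsv"))
    results$distance <- gg
    write_stage_json(unclass(gg),
                     file.path(config$out_dir, "distance.json"), cfg_json)
  }

  if (!is.null(config$summary_fasta)) {
    say("stage summary: ", config$summary_fasta)
    gs <- genome_summary(config$summary_fasta, config$summary_annotation)
    results$summary <- gs
    write_stage_json(unclass(gs),
                     file.path(config$out_dir, "summary.json"), cfg_json)
  }

  combined <- list(config = cfg_json,
                   stages = names(results),
                   reports = lapply(results, function(r) {
                     if (is.data.frame(r)) r else unclass_deep(r)
                   }))
  jsonlite::write_json(combined, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  say("wrote ", file.path(config$out_dir, "report.json"))
  invisible(results)
}

resolve_config <- function(config) {
  cfg <- unclass(config)
  cfg$homology <- unclass(cfg$homology)
  cfg
}

write_stage_json <- function(payload, path, cfg_json) {
  jsonlite::write_json(list(config = cfg_json, result = payload), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
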