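AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
DNA4 <- c("A", "C", "G", "T")

# uniform random protein as a character vector
random_protein_chars <- function(len) sample(AA20, len, replace = TRUE)

# random DNA with the stated G+C fraction
random_dna_chars <- function(len, gc = 0.5) {
  sample(DNA4, len, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Point substitutions at the given rate; a substituted position always
# receives a *different* symbol, so expected identity to the input is
# exactly 1 - rate.
mutate_chars <- function(chars, rate, alphabet) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    k <- length(alphabet)
    idx <- match(chars[hit], alphabet)
    # draw among the k-1 other symbols
    off <- sample.int(k - 1L, length(hit), replace = TRUE)
    chars[hit] <- alphabet[((idx - 1L + off) %% k) + 1L]
  }
  chars
}

# place segments of the given lengths without overlap on [0, total_len):
# distributes the free space as random gaps; returns 0-based starts
place_nonoverlapping <- function(total_len, seg_lengths) {
  k <- length(seg_lengths)
  if (k == 0L) return(integer())
  free <- total_len - sum(seg_lengths)
  if (free < 0) {
    stop("planted segments (", sum(seg_lengths),
         " bp) do not fit in ", total_len, " bp", call. = FALSE)
  }
  # k+1 gaps summing to `free`, uniform over compositions
  cuts <- sort(sample.int(free + k, k)) - seq_len(k)
  gaps <- diff(c(0L, cuts))
  starts <- cumsum(gaps) + cumsum(c(0L, seg_lengths[-k]))
  as.integer(starts)
}

#' Configuration for the category-count simulator
#'
#' Describes a synthetic genome of `n_genes` genes spread over
#' `n_categories` functional categories according to an abundance model:
#' \describe{
#'   \item{uniform}{one gene per category, round-robin (perfectly even).}
#'   \item{brokenstick}{multinomial draw over the broken-stick expected
#'     proportions — data that match the null on average.}
#'   \item{geometric}{multinomial over normalised \eqn{k^i} (decay ratio
#'     `k`), a classical strongly-uneven abundance model.}
#'   \item{dirichlet}{multinomial over a Dirichlet(\eqn{\alpha \mathbf 1})
#'     draw: small `alpha` gives sparse, highly redundant profiles; large
#'     `alpha` approaches uniform.}
#'   \item{transposon_burst}{Dirichlet baseline on the ordinary categories
#'     plus `n_burst` designated mobile-element-like families jointly
#'     absorbing `burst_mass` of the genes — emulates a heavy-tailed
#'     transposase expansion.}
#' }
#'
#' @param n_genes,n_categories Problem size; `n_categories <= n_genes`.
#' @param model One of the five model names above.
#' @param k Geometric decay ratio in (0, 1).
#' @param alpha Dirichlet concentration (> 0).
#' @param n_burst Number of burst families.
#' @param burst_mass Fraction of genes absorbed by the burst families,
#'   in (0, 1).
#' @param genome_id Genome label written into the table.
#' @param seed Integer seed; same seed, same output.
#' @return A `cog_sim_config` list.
#' @export
cog_sim_config <- function(n_genes, n_categories,
                           model = c("uniform", "brokenstick", "geometric",
                                     "dirichlet", "transposon_burst"),
                           k = 0.5, alpha = 1, n_burst = 1L,
                           burst_mass = 0.3, genome_id = "SIM",
                           seed = 42L) {
  model <- match.arg(model)
  n_genes <- assert_count(n_genes, "n_genes")
  n_categories <- assert_count(n_categories, "n_categories")
  if (n_categories > n_genes) {
    stop("n_categories must not exceed n_genes", call. = FALSE)
  }
  if (model == "geometric" && (k <= 0 || k >= 1)) {
    stop("geometric ratio 'k' must lie in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (model == "transposon_burst") {
    n_burst <- assert_count(n_burst, "n_burst")
    if (burst_mass <= 0 || burst_mass >= 1) {
      stop("'burst_mass' must lie in (0, 1)", call. = FALSE)
    }
    if (n_burst >= n_categories) {
      stop("'n_burst' must be smaller than n_categories", call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, n_categories = n_categories,
                 model = model, k = k, alpha = alpha, n_burst = n_burst,
                 burst_mass = burst_mass, genome_id = genome_id,
                 seed = as.integer(seed)),
            class = "cog_sim_config")
}

#' Simulate a gene-to-category assignment table
#'
#' Draws category counts under the model in `cfg` and expands them into an
#' assignment table (one row per gene) with unique gene ids. The truth
#' manifest records the drawn count of every category, including zeros;
#' zero-count categories naturally never appear in the table.
#'
#' @param cfg A [cog_sim_config()].
#' @return List with `assignments` (data frame: `genome_id`, `gene_id`,
#'   `category_id`) and `truth` (list: `counts` named over all category
#'   ids, `burst_categories`, `model`, `config`).
#' @export
simulate_cog_table <- function(cfg) {
  stopifnot(inherits(cfg, "cog_sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_categories
  n <- cfg$n_genes
  cat_ids <- sprintf("CAT%05d", seq_len(S))
  burst <- character()
  if (cfg$model == "uniform") {
    counts <- tabulate(rep_len(seq_len(S), n), nbins = S)
  } else {
    prob <- switch(cfg$model,
      brokenstick = broken_stick(S)$proportions,
      geometric = {
        p <- cfg$k^seq_len(S)
        p / sum(p)
      },
      dirichlet = {
        g <- stats::rgamma(S, shape = cfg$alpha)
        g / sum(g)
      },
      transposon_burst = {
        nb <- cfg$n_burst
        g <- stats::rgamma(S - nb, shape = cfg$alpha)
        burst <- cat_ids[seq_len(nb)]
        c(rep(cfg$burst_mass / nb, nb), (1 - cfg$burst_mass) * g / sum(g))
      })
    counts <- as.integer(stats::rmultinom(1L, n, prob))
  }
  names(counts) <- cat_ids
  assignments <- data.frame(
    genome_id = cfg$genome_id,
    gene_id = sprintf("G%06d", seq_len(n)),
    category_id = rep(cat_ids, counts))
  list(assignments = assignments,
       truth = list(counts = counts, burst_categories = burst,
                    model = cfg$model, config = unclass(cfg)))
}

#' Configuration for the proteome-triple simulator
#'
#' Plants homolog families across 2 or 3 synthetic proteomes: core
#' families present in every genome, pairwise families present in exactly
#' two, and unique genes present in one. Family members descend from a
#' common random ancestral sequence by point substitutions tuned so that
#' the expected *pairwise* identity between members equals
#' `within_family_identity` (each member is mutated at rate
#' \eqn{1 - \sqrt{q}}, so two members agree at a site with probability
#' \eqn{q} plus a negligible coincidental-match term).
#'
#' @param n_genomes 2 or 3; genomes are named `A`, `B` (`, C`).
#' @param n_core_families Families present in all genomes.
#' @param n_pairwise_families Named list/vector of family counts per pair,
#'   names like `"A_B"`, `"A_C"`, `"B_C"`.
#' @param n_unique Named list/vector of unique-gene counts per genome.
#' @param protein_length Length of every simulated protein (>= 30).
#' @param within_family_identity Target pairwise identity in (0, 1].
#' @param seed Integer seed.
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(n_genomes = 3L, n_core_families = 5L,
                                n_pairwise_families = list(),
                                n_unique = list(),
                                protein_length = 120L,
                                within_family_identity = 0.9,
                                seed = 42L) {
  if (!n_genomes %in% c(2L, 3L)) {
    stop("'n_genomes' must be 2 or 3", call. = FALSE)
  }
  if (protein_length < 30L) {
    stop("'protein_length' must be at least 30", call. = FALSE)
  }
  if (within_family_identity <= 0 || within_family_identity > 1) {
    stop("'within_family_identity' must lie in (0, 1]", call. = FALSE)
  }
  genomes <- LETTERS[seq_len(n_genomes)]
  pairs <- utils::combn(genomes, 2L, paste, collapse = "_")
  npw <- stats::setNames(rep(0L, length(pairs)), pairs)
  if (length(n_pairwise_families)) {
    bad <- setdiff(names(n_pairwise_families), pairs)
    if (length(bad)) stop("unknown genome pair: ", bad[1L], call. = FALSE)
    npw[names(n_pairwise_families)] <- as.integer(unlist(n_pairwise_families))
  }
  nun <- stats::setNames(rep(0L, n_genomes), genomes)
  if (length(n_unique)) {
    bad <- setdiff(names(n_unique), genomes)
    if (length(bad)) stop("unknown genome: ", bad[1L], call. = FALSE)
    nun[names(n_unique)] <- as.integer(unlist(n_unique))
  }
  n_core_families <- as.integer(n_core_families)
  if (is.na(n_core_families) || n_core_families < 0L) {
    stop("'n_core_families' must be a non-negative integer", call. = FALSE)
  }
  structure(list(genomes = genomes,
                 n_core_families = n_core_families,
                 n_pairwise_families = npw, n_unique = nun,
                 protein_length = as.integer(protein_length),
                 within_family_identity = within_family_identity,
                 seed = as.integer(seed)),
            class = "proteome_sim_config")
}

#' Simulate proteomes with planted homolog families
#'
#' @param cfg A [proteome_sim_config()].
#' @return List with `proteomes` (named list of
#'   [Biostrings::AAStringSet] objects, one per genome) and `truth`
#'   (data frame: `genome`, `gene_id`, `family`, `type`; `family` is `NA`
#'   for unique genes).
#' @export
simulate_proteomes <- function(cfg) {
  stopifnot(inherits(cfg, "proteome_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$protein_length
  q <- cfg$within_family_identity
  rate <- 1 - sqrt(q)
  seqs <- stats::setNames(vector("list", length(cfg$genomes)), cfg$genomes)
  truth <- list()
  add_family <- function(fam_id, members, type) {
    anc <- random_protein_chars(L)
    for (g in members) {
      gene <- sprintf("%s_%s", g, fam_id)
      seqs[[g]][[gene]] <<- paste(mutate_chars(anc, rate, AA20),
                                  collapse = "")
      truth[[length(truth) + 1L]] <<- data.frame(
        genome = g, gene_id = gene, family = fam_id, type = type)
    }
  }
  for (i in seq_len(cfg$n_core_families)) {
    add_family(sprintf("core%03d", i), cfg$genomes, "core")
  }
  for (pair in names(cfg$n_pairwise_families)) {
    members <- strsplit(pair, "_", fixed = TRUE)[[1L]]
    for (i in seq_len(cfg$n_pairwise_families[[pair]])) {
      add_family(sprintf("pw%s%03d", gsub("_", "", pair), i), members,
                 "pairwise")
    }
  }
  for (g in cfg$genomes) {
    for (i in seq_len(cfg$n_unique[[g]])) {
      gene <- sprintf("%s_uniq%03d", g, i)
      seqs[[g]][[gene]] <- paste(random_protein_chars(L), collapse = "")
      truth[[length(truth) + 1L]] <- data.frame(
        genome = g, gene_id = gene, family = NA_character_,
        type = "unique")
    }
  }
  proteomes <- lapply(seqs, function(x) {
    if (length(x) == 0L) return(Biostrings::AAStringSet())
    Biostrings::AAStringSet(unlist(x))
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(proteomes = proteomes, truth = truth, config = unclass(cfg))
}

#' Configuration for the genome-pair simulator
#'
#' Two independent random genomes at the stated G+C content, with planted
#' homologous segments: each segment is drawn from genome A and copied
#' into genome B with point substitutions so the copy's identity to the
#' source equals the stated fraction in expectation. Segments are placed
#' without overlap on both genomes (forward strand).
#'
#' @param len_a,len_b Genome lengths in bp.
#' @param planted_segments List of `c(length, identity)` pairs (identity
#'   in (0, 1]); total length must fit in both genomes.
#' @param gc G+C fraction of the random background.
#' @param seed Integer seed.
#' @return A `genome_pair_sim_config` list.
#' @export
genome_pair_sim_config <- function(len_a, len_b, planted_segments = list(),
                                   gc = 0.5, seed = 42L) {
  len_a <- assert_count(len_a, "len_a")
  len_b <- assert_count(len_b, "len_b")
  if (gc < 0 || gc > 1) stop("'gc' must lie in [0, 1]", call. = FALSE)
  segs <- lapply(planted_segments, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2L || s[1L] < 1 || s[2L] <= 0 || s[2L] > 1) {
      stop("each planted segment must be c(length >= 1, identity in (0,1])",
           call. = FALSE)
    }
    list(length = as.integer(s[1L]), identity = s[2L])
  })
  total <- sum(vapply(segs, `[[`, integer(1), "length"))
  if (total > min(len_a, len_b)) {
    stop("total planted length exceeds the shorter genome", call. = FALSE)
  }
  structure(list(len_a = len_a, len_b = len_b, segments = segs, gc = gc,
                 seed = as.integer(seed)),
            class = "genome_pair_sim_config")
}

#' Simulate a genome pair with planted shared segments
#'
#' @param cfg A [genome_pair_sim_config()].
#' @return List with `seq_a`, `seq_b` ([Biostrings::DNAString]) and
#'   `truth`, a data frame of planted intervals (0-based half-open:
#'   `a_start`, `a_end`, `b_start`, `b_end`) with `length` and `identity`.
#' @export
simulate_genome_pair <- function(cfg) {
  stopifnot(inherits(cfg, "genome_pair_sim_config"))
  set.seed(cfg$seed)
  a <- random_dna_chars(cfg$len_a, cfg$gc)
  b <- random_dna_chars(cfg$len_b, cfg$gc)
  lens <- vapply(cfg$segments, `[[`, integer(1), "length")
  a_starts <- place_nonoverlapping(cfg$len_a, lens)
  b_starts <- place_nonoverlapping(cfg$len_b, lens)
  truth <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), identity = numeric())
  for (i in seq_along(cfg$segments)) {
    len <- lens[i]
    src <- a[(a_starts[i] + 1L):(a_starts[i] + len)]
    copy <- mutate_chars(src, 1 - cfg$segments[[i]]$identity, DNA4)
    b[(b_starts[i] + 1L):(b_starts[i] + len)] <- copy
    truth[i, ] <- list(a_starts[i], a_starts[i] + len,
                       b_starts[i], b_starts[i] + len,
                       len, cfg$segments[[i]]$identity)
  }
  list(seq_a = Biostrings::DNAString(paste(a, collapse = "")),
       seq_b = Biostrings::DNAString(paste(b, collapse = "")),
       truth = truth, config = unclass(cfg))
}

#' Write sequences as wrapped FASTA
#'
#' @param x An `XStringSet` (or named list of them, one file per element
#'   is NOT created -- pass one set per call).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
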