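#' Configuration for the synthetic data generator
#'
#' Describes a ground-truthed study: a negative-binomial whole-body RNA-seq
#' count matrix over two male and two female samples with planted bias
#' classes, and a heavy-tailed interactome with planted conflict motifs.
#' Defaults emulate the stringent conflict regime: planted biased genes sit
#' at a 64-fold (log2 effect 6) expression difference, safely beyond the
#' 32-fold detection threshold, on a moderately overdispersed baseline.
#'
#' @param n_genes total number of genes.
#' @param prop_male,prop_female,prop_unbiased,prop_zero class proportions
#'   (must sum to 1). `zero` genes are silent in every sample and exercise
#'   the discard rule.
#' @param effect_size planted log2 male/female difference for biased genes
#'   (6 = 64-fold), applied symmetrically: x2^(e/2) in the favoured sex,
#'   /2^(e/2) in the other, so the planted bias equals `effect_size`
#'   regardless of baseline.
#' @param baseline_mean,baseline_sdlog log-normal distribution of per-gene
#'   baseline expression. The unit is total read depth summed over a gene's
#'   coding sequence (per-base depth sums), so magnitudes are in the
#'   thousands for deep whole-body libraries; the default of 3000
#'   corresponds to a modest gene at ~30x coverage.
#' @param dispersion negative-binomial dispersion (1/size); 0.1 is a
#'   moderate bulk RNA-seq value.
#' @param samples_per_sex samples per sex (default 2, whole-body design).
#' @param libsize_sdlog log-normal spread of per-sample library-size
#'   factors.
#' @param degree_exponent target power-law exponent of the interactome
#'   degree tail.
#' @param mean_degree target mean degree of the interactome.
#' @param n_indirect,n_direct planted indirect-conflict genes and planted
#'   direct-conflict edges.
#' @param exact_motifs when `TRUE`, background edges that would create
#'   accidental conflict motifs are rewired away, so recovery tests can
#'   demand exact equality with the planted truth.
#' @param seed RNG seed; a fixed seed makes every emitted object and file
#'   byte-reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000,
                             prop_male = 0.10, prop_female = 0.10,
                             prop_unbiased = 0.75, prop_zero = 0.05,
                             effect_size = 6,
                             baseline_mean = 3000, baseline_sdlog = 1,
                             dispersion = 0.1,
                             samples_per_sex = 2,
                             libsize_sdlog = 0.2,
                             degree_exponent = 2.5,
                             mean_degree = 10,
                             n_indirect = 20, n_direct = 20,
                             exact_motifs = FALSE,
                             seed = 1L) {
  props <- c(male = prop_male, female = prop_female,
             unbiased = prop_unbiased, zero = prop_zero)
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8) {
    stop("class proportions must be non-negative and sum to 1")
  }
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (samples_per_sex < 1) stop("need at least one sample per sex")
  structure(list(n_genes = as.integer(n_genes), props = props,
                 effect_size = effect_size,
                 baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 samples_per_sex = as.integer(samples_per_sex),
                 libsize_sdlog = libsize_sdlog,
                 degree_exponent = degree_exponent, mean_degree = mean_degree,
                 n_indirect = as.integer(n_indirect),
                 n_direct = as.integer(n_direct),
                 exact_motifs = isTRUE(exact_motifs),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic class assignment: contiguous blocks in gene order.
assign_classes <- function(cfg) {
  n_by <- floor(cfg$props * cfg$n_genes)
  n_by["unbiased"] <- cfg$n_genes - sum(n_by[c("male", "female", "zero")])
  rep(c("male", "female", "unbiased", "zero"),
      n_by[c("male", "female", "unbiased", "zero")])
}

#' Generate a synthetic expression matrix with planted bias classes
#'
#' Counts are negative-binomial with mean
#' `baseline x sex-effect x library factor`; biased classes receive the sex
#' effect symmetrically in the two sexes, zero-class genes are all-zero.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `expr` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene`, `class`, `true_bias`; `true_bias` is the planted
#'   log2 bias, `NA` for zero-class genes).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  k <- cfg$samples_per_sex
  genes <- sprintf("g%05d", seq_len(n))
  cls <- assign_classes(cfg)
  baseline <- stats::rlnorm(n, meanlog = log(cfg$baseline_mean),
                            sdlog = cfg$baseline_sdlog)
  samples <- c(sprintf("m%d", seq_len(k)), sprintf("f%d", seq_len(k)))
  sex <- rep(c("male", "female"), each = k)
  libfac <- stats::rlnorm(2 * k, meanlog = 0, sdlog = cfg$libsize_sdlog)

  half <- cfg$effect_size / 2
  # per-gene log2 shift in male samples (negated in female samples)
  shift <- ifelse(cls == "male", half, ifelse(cls == "female", -half, 0))
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf

  counts <- matrix(0, nrow = n, ncol = 2 * k,
                   dimnames = list(genes, samples))
  live <- cls != "zero"
  for (j in seq_len(2 * k)) {
    sgn <- if (sex[j] == "male") 1 else -1
    mu <- baseline[live] * 2^(sgn * shift[live]) * libfac[j]
    counts[live, j] <- if (is.finite(size)) {
      stats::rnbinom(sum(live), mu = mu, size = size)
    } else {
      stats::rpois(sum(live), lambda = mu)
    }
  }
  truth <- data.frame(
    gene = genes, class = cls,
    true_bias = ifelse(cls == "male", cfg$effect_size,
                       ifelse(cls == "female", -cfg$effect_size,
                              ifelse(cls == "zero", NA_real_, 0))),
    stringsAsFactors = FALSE)
  list(expr = expression_matrix(counts, stats::setNames(sex, samples)),
       truth = truth)
}

#' Generate a synthetic interactome with planted conflict motifs
#'
#' Background wiring is a configuration model: per-node degrees are drawn
#' from a discrete power law `p(k) ~ k^-gamma` on `[kmin, kmax]`, where
#' `kmin` is derived from the target mean degree (`mean x (gamma-2) /
#' (gamma-1)`, the heavy-tail mean relation) and `kmax` is the structural
#' cutoff `sqrt(n x mean degree)` that keeps the realised simple graph
#' uncorrelated. The sequence is realised as a simple graph by igraph's
#' degree-preserving edge-switching sampler, so network degrees equal the
#' sampled sequence exactly. Genes are assigned to vertices at random so
#' degree is independent of bias class. On top of the background, motifs
#' are wired
#' explicitly: each planted indirect gene (sex-unbiased) gains an edge to at
#' least one planted male and one planted female gene; each planted direct
#' motif is a male-female edge. With `exact_motifs = TRUE`, background edges
#' that would create accidental motifs are removed (male-female edges
#' outside the planted pairs; one sex's edges on accidentally bridging
#' unbiased genes) and any gene isolated by the cleanup is re-attached to a
#' same-class partner, so the recoverable conflict sets equal the planted
#' truth exactly.
#'
#' @param cfg a [synthetic_config()].
#' @param truth the truth data.frame from [generate_expression()].
#' @return A list with `network` (undirected simple `igraph`) and `planted`
#'   (list `indirect`, `direct_pairs`, `direct_male`, `direct_female`).
#' @export
generate_network <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  live <- truth[truth$class != "zero", ]
  n <- nrow(live)
  if (n < 3) stop("need at least 3 non-silent genes to build a network")
  males <- live$gene[live$class == "male"]
  females <- live$gene[live$class == "female"]
  unbiased <- live$gene[live$class == "unbiased"]
  if (cfg$n_indirect > length(unbiased)) {
    stop("n_indirect exceeds the number of unbiased genes")
  }
  if (cfg$n_direct > min(length(males), length(females))) {
    stop("n_direct exceeds the number of available biased genes")
  }

  gamma <- cfg$degree_exponent
  kmin <- max(1, round(cfg$mean_degree * (gamma - 2) / (gamma - 1)))
  kmax <- min(n - 1, max(kmin + 10, round(sqrt(n * cfg$mean_degree))))
  ks <- kmin:kmax
  degs <- sample(ks, n, replace = TRUE, prob = ks^-gamma)
  if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1
  g <- igraph::sample_degseq(degs, method = "edge.switching.simple")
  igraph::V(g)$name <- sample(live$gene)  # degree independent of class

  planted_indirect <- sort(sample(unbiased, cfg$n_indirect))
  direct_pairs <- data.frame(
    male = sample(males, cfg$n_direct),
    female = sample(females, cfg$n_direct),
    stringsAsFactors = FALSE)
  motif_edges <- c(
    rbind(planted_indirect, sample(males, cfg$n_indirect, replace = TRUE)),
    rbind(planted_indirect, sample(females, cfg$n_indirect, replace = TRUE)),
    rbind(direct_pairs$male, direct_pairs$female))
  g <- igraph::simplify(igraph::add_edges(g, motif_edges))

  if (cfg$exact_motifs) {
    g <- scrub_accidental_motifs(g, live, planted_indirect, direct_pairs)
  }
  direct_pairs <- direct_pairs[order(direct_pairs$male, direct_pairs$female), ]
  rownames(direct_pairs) <- NULL
  list(network = g,
       planted = list(indirect = planted_indirect,
                      direct_pairs = direct_pairs,
                      direct_male = sort(unique(direct_pairs$male)),
                      direct_female = sort(unique(direct_pairs$female))))
}

# Remove background edges that would create conflict motifs beyond the
# planted ones; re-attach genes the cleanup isolates to a same-class
# partner (same-class and unbiased-unbiased edges can never form a motif).
scrub_accidental_motifs <- function(g, live, planted_indirect, direct_pairs) {
  cls <- stats::setNames(live$class, live$gene)
  el <- igraph::as_edgelist(g, names = TRUE)
  c1 <- cls[el[, 1]]
  c2 <- cls[el[, 2]]
  # male-female edges not planted as direct pairs
  key <- function(m, f) paste(m, f)
  planted_keys <- key(direct_pairs$male, direct_pairs$female)
  mf <- (c1 == "male" & c2 == "female") | (c1 == "female" & c2 == "male")
  m_side <- ifelse(cls[el[, 1]] == "male", el[, 1], el[, 2])
  f_side <- ifelse(cls[el[, 1]] == "female", el[, 1], el[, 2])
  drop <- mf & !(key(m_side, f_side) %in% planted_keys)
  g <- igraph::delete_edges(g, which(drop))

  # unbiased genes outside the planted indirect set must not bridge both
  # sexes: cut their male-side edges
  el <- igraph::as_edgelist(g, names = TRUE)
  c1 <- cls[el[, 1]]
  c2 <- cls[el[, 2]]
  repeat {
    u_end1 <- c1 == "unbiased" & !(el[, 1] %in% planted_indirect)
    u_end2 <- c2 == "unbiased" & !(el[, 2] %in% planted_indirect)
    has_m <- unique(c(el[u_end1 & c2 == "male", 1], el[u_end2 & c1 == "male", 2]))
    has_f <- unique(c(el[u_end1 & c2 == "female", 1], el[u_end2 & c1 == "female", 2]))
    bridge <- intersect(has_m, has_f)
    if (length(bridge) == 0) break
    cut <- ((el[, 1] %in% bridge & c2 == "male") |
            (el[, 2] %in% bridge & c1 == "male"))
    g <- igraph::delete_edges(g, which(cut))
    el <- igraph::as_edgelist(g, names = TRUE)
    c1 <- cls[el[, 1]]
    c2 <- cls[el[, 2]]
  }

  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  for (v in iso) {
    mates <- setdiff(live$gene[live$class == cls[v]], v)
    if (length(mates)) {
      g <- igraph::add_edges(g, c(v, sample(mates, 1)))
    }
  }
  igraph::simplify(g)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: expression matrix, truth labels, true-bias table
#' and interactome from one config.
#'
#' @param cfg a [synthetic_config()].
#' @return A list `expr`, `truth`, `true_bias` (a `sex_bias_table` of the
#'   planted biases over non-silent genes), `network`, `planted`.
#' @export
generate_dataset <- function(cfg) {
  ge <- generate_expression(cfg)
  gn <- generate_network(cfg, ge$truth)
  tb <- ge$truth[!is.na(ge$truth$true_bias), c("gene", "true_bias")]
  names(tb) <- c("gene", "bias")
  rownames(tb) <- NULL
  class(tb) <- c("sex_bias_table", "data.frame")
  list(expr = ge$expr, truth = ge$truth, true_bias = tb,
       network = gn$network, planted = gn$planted)
}

#' Write a synthetic dataset in the pipeline's file dialects
#'
#' Emits `counts.tsv` + `samples.tsv` (count-table dialect),
#' `gene_bias.txt` (planted true biases, two-column dialect),
#' `ppi.txt` (edge-list dialect) and `truth.tsv` (gene, class, true bias).
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             bias = file.path(dir, "gene_bias.txt"),
             edges = file.path(dir, "ppi.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(ds$expr, paths["counts"], paths["samples"])
  write_bias_table(ds$true_bias, paths["bias"])
  write_edge_list(ds$network, paths["edges"])
  utils::write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
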