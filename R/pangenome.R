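# Pan/core-genome statistics from ortholog cluster membership.

#' Construct an ortholog table
#'
#' @param membership data.frame with columns `cluster_id`, `genome_id`,
#'   `gene_id` (one row per gene-in-cluster).
#' @param genomes genome ids; defaults to those referenced, but can be wider
#'   (genomes contributing only singletons).
#' @param singletons optional data.frame with columns `genome_id`, `gene_id`
#'   of genes not included in any cluster.
#' @return an [OrthologTable-class].
#' @export
OrthologTable <- function(membership,
                          genomes = sort(unique(membership$genome_id)),
                          singletons = NULL) {
  if (is.null(singletons))
    singletons <- data.frame(genome_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE)
  new("OrthologTable", membership = membership,
      genomes = sort(unique(c(genomes, membership$genome_id))),
      singletons = singletons)
}

#' Read ortholog cluster membership from a TSV
#'
#' @param path TSV with columns `cluster_id`, `genome_id`, `gene_id`.
#' @param singletonsPath optional TSV with columns `genome_id`, `gene_id`.
#' @return an [OrthologTable-class].
#' @export
readOrthologTable <- function(path, singletonsPath = NULL) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  s <- if (!is.null(singletonsPath))
    utils::read.delim(singletonsPath, stringsAsFactors = FALSE) else NULL
  OrthologTable(m, singletons = s)
}

# Internal: clusters x genomes incidence (does the cluster contain >=1 gene
# from the genome?).
.incidence <- function(t) {
  m <- t@membership
  unclass(table(factor(m$cluster_id), factor(m$genome_id, levels = t@genomes))) > 0
}

#' Core and pan cluster sets over a genome subset
#'
#' The core is the set of ortholog clusters with at least one gene in every
#' genome of the subset; the pan set those with a gene in any of them.
#'
#' @param t an [OrthologTable-class].
#' @param genomeSubset genome ids (default: all genomes).
#' @return list with character vectors `core` and `pan` of cluster ids.
#' @examples
#' t <- OrthologTable(data.frame(
#'   cluster_id = c("a", "b", "b", "c"),
#'   genome_id = c("G1", "G1", "G2", "G2"),
#'   gene_id = c("g1", "g2", "g3", "g4")))
#' lengths(corePanSets(t))  # core 1 (b), pan 3
#' @export
corePanSets <- function(t, genomeSubset = genomes(t)) {
  if (length(genomeSubset) == 0L) stop("genome subset is empty")
  unknown <- setdiff(genomeSubset, genomes(t))
  if (length(unknown))
    stop("unknown genome(s): ", paste(unknown, collapse = ", "))
  inc <- .incidence(t)[, unique(genomeSubset), drop = FALSE]
  list(core = rownames(inc)[rowSums(inc) == ncol(inc)],
       pan = rownames(inc)[rowSums(inc) > 0])
}

#' Pan/core genome accumulation curves with resampling
#'
#' For each resampling draw, a genome order of length N is sampled with
#' replacement; core and pan cluster counts are computed over the distinct
#' genomes among the first k positions, for k = 1..N (a genome drawn twice
#' contributes once — duplicates do not shrink the core further). Reported
#' are the mean and the 2.5/97.5 percentile envelope across draws, per k.
#' With `exhaustive = TRUE` every one of the N^N equally likely ordered
#' draws is enumerated instead of sampled (small N only), giving the exact
#' expectation.
#'
#' @param t an [OrthologTable-class] with at least two genomes.
#' @param nResamples number of draws (default 200).
#' @param seed integer seed (ignored when exhaustive).
#' @param exhaustive enumerate all N^N ordered draws instead of sampling.
#' @param keepDraws retain the per-draw core/pan trajectories (arrays
#'   `draws_core`, `draws_pan` in the attributes) for diagnostics.
#' @return data.frame with columns `k`, `core_mean`, `core_lo`, `core_hi`,
#'   `pan_mean`, `pan_lo`, `pan_hi`; attributes `n_resamples` and `seed`.
#' @export
accumulationCurves <- function(t, nResamples = 200, seed = 1,
                               exhaustive = FALSE, keepDraws = FALSE) {
  N <- length(genomes(t))
  if (N < 2L) stop("need at least two genomes")
  inc <- .incidence(t)
  curveFor <- function(ord) {
    core <- pan <- integer(N)
    for (k in seq_len(N)) {
      set <- unique(ord[seq_len(k)])
      sub <- inc[, set, drop = FALSE]
      rs <- rowSums(sub)
      core[k] <- sum(rs == length(set))
      pan[k] <- sum(rs > 0)
    }
    cbind(core = core, pan = pan)
  }
  if (exhaustive) {
    nDraws <- N^N
    if (nDraws > 50000) stop("exhaustive enumeration infeasible for N = ", N)
    orders <- as.matrix(expand.grid(rep(list(seq_len(N)), N)))[, N:1, drop = FALSE]
  } else {
    set.seed(seed)
    nDraws <- nResamples
    orders <- matrix(sample.int(N, N * nDraws, replace = TRUE), nrow = nDraws)
  }
  coreM <- panM <- matrix(0L, nDraws, N)
  for (d in seq_len(nDraws)) {
    cv <- curveFor(orders[d, ])
    coreM[d, ] <- cv[, "core"]
    panM[d, ] <- cv[, "pan"]
  }
  out <- data.frame(
    k = seq_len(N),
    core_mean = colMeans(coreM),
    core_lo = apply(coreM, 2, stats::quantile, 0.025),
    core_hi = apply(coreM, 2, stats::quantile, 0.975),
    pan_mean = colMeans(panM),
    pan_lo = apply(panM, 2, stats::quantile, 0.025),
    pan_hi = apply(panM, 2, stats::quantile, 0.975))
  attr(out, "n_resamples") <- nDraws
  attr(out, "seed") <- if (exhaustive) NA_integer_ else as.integer(seed)
  if (keepDraws) {
    attr(out, "draws_core") <- coreM
    attr(out, "draws_pan") <- panM
  }
  out
}
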