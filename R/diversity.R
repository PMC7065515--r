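# Clone-library diversity: pairwise p-distances on aligned marker genes,
# furthest-neighbor (complete-linkage) OTU clustering, and the nonparametric
# richness/coverage/rarefaction statistics used for small clone libraries.

#' Aligned nucleotide sequence set
#'
#' @param ids Unique sequence labels.
#' @param sequences Equal-length aligned nucleotide strings over
#'   A, C, G, T, N and the gap character `-` (case-insensitive).
#' @return A list of class `aligned_sequence_set`.
#' @export
aligned_sequence_set <- function(ids, sequences) {
  stopifnot(length(ids) == length(sequences), !anyDuplicated(ids))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) stop("sequences must be aligned (equal length)")
  if (any(grepl("[^ACGTN-]", sequences))) {
    stop("sequences may contain only A, C, G, T, N, -")
  }
  structure(list(ids = as.character(ids), sequences = sequences),
            class = "aligned_sequence_set")
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of pre-aligned, equal-length sequences.
#' @return An [aligned_sequence_set()].
#' @export
read_aligned_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  chars <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "",
                  USE.NAMES = FALSE)
  aligned_sequence_set(names(dna), chars)
}

#' Write an aligned FASTA file
#'
#' @param seqs An [aligned_sequence_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "aligned_sequence_set"))
  ape::write.dna(as_dnabin(seqs), path, format = "fasta", colsep = "")
  invisible(path)
}

# character matrix / DNAbin conversion used by distance computation
as_dnabin <- function(seqs) {
  m <- do.call(rbind, strsplit(tolower(seqs$sequences), ""))
  rownames(m) <- seqs$ids
  ape::as.DNAbin(m)
}

#' Pairwise uncorrected p-distances with pairwise deletion
#'
#' For each sequence pair, alignment columns containing a gap or N in either
#' sequence are excluded and the distance is the mismatch fraction over the
#' remaining comparable columns (uncorrected p-distance, pairwise deletion).
#'
#' @param seqs An [aligned_sequence_set()] of at least 2 sequences.
#' @return A list of class `distance_matrix` with `ids` and `values`, a
#'   symmetric matrix of divergences in \[0, 1\] with zero diagonal.
#' @examples
#' s <- aligned_sequence_set(c("a", "b"), c("AC-GT", "ACAGT"))
#' pairwise_distance(s)$values  # 0: the gap column is excluded
#' @export
pairwise_distance <- function(seqs) {
  stopifnot(inherits(seqs, "aligned_sequence_set"))
  if (length(seqs$ids) < 2) stop("need at least 2 sequences")
  d <- ape::dist.dna(as_dnabin(seqs), model = "raw", pairwise.deletion = TRUE)
  m <- as.matrix(d)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 seqs$ids[bad[1]], seqs$ids[bad[2]]))
  }
  diag(m) <- 0
  structure(list(ids = seqs$ids, values = m), class = "distance_matrix")
}

#' Furthest-neighbor OTU clustering
#'
#' Complete-linkage agglomerative clustering of a distance matrix: clusters
#' are merged, in ascending order of linkage distance, for as long as the
#' maximum distance between any two members of the merged cluster is at most
#' `cutoff`. This is the "furthest neighbor" rule of classical OTU callers;
#' at the 16S convention of 97% identity use `cutoff = 0.03`, at the amoA
#' convention of 95% use `cutoff = 0.05`. Clustering is deterministic:
#' equal-distance merges follow the order of [stats::hclust()], which is
#' fixed by the input ordering of the ids.
#'
#' @param dist A [pairwise_distance()] result (or any `distance_matrix`).
#' @param cutoff Maximum within-OTU divergence, in \[0, 1\].
#' @return A named integer vector mapping each sequence id to an OTU index.
#' @export
cluster_otus <- function(dist, cutoff) {
  stopifnot(inherits(dist, "distance_matrix"), cutoff >= 0, cutoff <= 1)
  n <- length(dist$ids)
  if (n == 1) return(stats::setNames(1L, dist$ids))
  hc <- stats::hclust(stats::as.dist(dist$values), method = "complete")
  stats::cutree(hc, h = cutoff)
}

#' OTU abundance table from cluster assignments
#'
#' @param assignments Named OTU assignment vector from [cluster_otus()].
#' @return A [clone_library()] built from the per-OTU member counts.
#' @export
otu_abundances <- function(assignments) {
  clone_library(as.integer(table(assignments)))
}

#' Clone library
#'
#' A per-OTU abundance vector with its derived summary counts: library size
#' N, singleton count n1, doubleton count n2, and observed richness S_obs.
#'
#' @param otu_counts Positive integer abundances, one per OTU.
#' @return A list of class `clone_library` with `otu_counts`,
#'   `total_clones`, `singletons`, `doubletons`, `observed_richness`.
#' @examples
#' lib <- clone_library(c(20, 6, 3, 3, 1, 1, 1, 1))
#' lib$singletons  # 4
#' @export
clone_library <- function(otu_counts) {
  otu_counts <- as.integer(otu_counts)
  stopifnot(length(otu_counts) >= 1, all(otu_counts >= 1))
  structure(list(
    otu_counts = otu_counts,
    total_clones = sum(otu_counts),
    singletons = sum(otu_counts == 1L),
    doubletons = sum(otu_counts == 2L),
    observed_richness = length(otu_counts)
  ), class = "clone_library")
}

#' Round half away from zero
#'
#' Tabular presentation convention for richness and coverage integers.
#' @param x Numeric.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Bias-corrected Chao1 richness estimate
#'
#' \deqn{S_{chao1} = S_{obs} + \frac{n_1 (n_1 - 1)}{2 (n_2 + 1)}.}
#' The bias-corrected form is defined even when no doubletons are present
#' (where the classic estimator is not) and equals S_obs whenever
#' \eqn{n_1 \le 1}.
#'
#' @param library A [clone_library()].
#' @return The exact estimate (numeric); round with [round_half_up()] for
#'   tabular presentation, or use [diversity_summary()].
#' @examples
#' chao1(clone_library(c(20, 6, 3, 3, 1, 1, 1, 1)))  # 14
#' @export
chao1 <- function(library) {
  stopifnot(inherits(library, "clone_library"))
  n1 <- library$singletons
  n2 <- library$doubletons
  library$observed_richness + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' Library coverage
#'
#' Good's coverage on singleton OTUs: \eqn{C = (1 - n_1/N) \times 100},
#' where \eqn{n_1} counts OTUs represented by a single clone.
#'
#' @param library A [clone_library()].
#' @return Coverage in percent (exact value).
#' @examples
#' coverage(clone_library(c(20, 6, 3, 3, 1, 1, 1, 1)))  # 88.9
#' @export
coverage <- function(library) {
  stopifnot(inherits(library, "clone_library"))
  (1 - library$singletons / library$total_clones) * 100
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \ln p_i} with natural logarithm.
#'
#' @param library A [clone_library()].
#' @return Shannon index H.
#' @export
shannon <- function(library) {
  stopifnot(inherits(library, "clone_library"))
  p <- library$otu_counts / library$total_clones
  -sum(p * log(p))
}

#' Simpson concentration index
#'
#' \eqn{D = \sum p_i^2}; report `1 - D` for the complement (diversity) form.
#'
#' @param library A [clone_library()].
#' @return Simpson's D.
#' @export
simpson <- function(library) {
  stopifnot(inherits(library, "clone_library"))
  p <- library$otu_counts / library$total_clones
  sum(p^2)
}

#' One-row diversity summary of a clone library
#'
#' @param library A [clone_library()].
#' @return A data.frame with N, S_obs, exact and rounded Chao1, exact and
#'   rounded coverage, Shannon H, Simpson D, and 1 - D.
#' @export
diversity_summary <- function(library) {
  data.frame(
    n_clones = library$total_clones,
    s_obs = library$observed_richness,
    chao1 = chao1(library),
    chao1_rounded = round_half_up(chao1(library)),
    coverage = coverage(library),
    coverage_rounded = round_half_up(coverage(library)),
    shannon = shannon(library),
    simpson_d = simpson(library),
    simpson_1md = 1 - simpson(library)
  )
}

#' Analytic rarefaction
#'
#' Expected OTU richness in a random subsample of size k, by the
#' hypergeometric expectation
#' \deqn{E[S_k] = \sum_i \left[1 - \binom{N - N_i}{k} / \binom{N}{k}\right].}
#'
#' @param library A [clone_library()].
#' @param subsample_sizes Integer subsample sizes, each in \[1, N\].
#' @return A data.frame with columns `k` and `expected_richness`.
#' @export
rarefaction <- function(library, subsample_sizes) {
  stopifnot(inherits(library, "clone_library"),
            all(subsample_sizes >= 1))
  n_tot <- library$total_clones
  if (any(subsample_sizes > n_tot)) {
    stop("subsample size exceeds library size")
  }
  es <- vapply(subsample_sizes, function(k) {
    sum(1 - exp(lchoose(n_tot - library$otu_counts, k) - lchoose(n_tot, k)))
  }, numeric(1))
  data.frame(k = subsample_sizes, expected_richness = es)
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf("Clone library: N = %d clones, S_obs = %d OTUs (n1 = %d, n2 = %d)\n",
              x$total_clones, x$observed_richness, x$singletons, x$doubletons))
  cat(sprintf("  Chao1 = %.2f, coverage = %.0f%%\n", chao1(x), coverage(x)))
  invisible(x)
}
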