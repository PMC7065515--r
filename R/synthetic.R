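# Seeded synthetic-data generators emulating the statistical structure of
# each analysis input: porewater profiles with a linear basal gradient, clone
# libraries from fixed or Dirichlet-sampled OTU abundances, aligned sequence
# families with controlled divergence, Dirichlet-multinomial community count
# tables, and qPCR dilution series with a specified amplification efficiency.
#
# All generators draw from R's Mersenne-Twister stream seeded locally, so the
# same seed gives bit-identical output and the caller's RNG state is left
# untouched.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Synthetic porewater profile
#'
#' A linear concentration-depth profile plus optional Gaussian noise,
#' emulating the basal nitrate gradients of a pelagic sediment column. With
#' `noise_sd = 0`, [fick_flux()] over any basal window recovers
#' \eqn{\phi D_s \times} `basal_gradient` exactly.
#'
#' @param seed Integer seed.
#' @param n_points Number of depth samples (>= 2; default 10).
#' @param basal_gradient Concentration slope, uM per meter of depth
#'   (positive: concentration grows downward, feeding the basement).
#' @param surface_conc Concentration at zero depth, uM.
#' @param noise_sd Gaussian noise SD, uM (default 0).
#' @param porosity,diffusivity Passed through to the profile (porosity
#'   fraction; diffusivity m\eqn{^2}/yr).
#' @param max_depth Deepest sample, m below seafloor (default 45).
#' @return A [porewater_profile()].
#' @export
make_porewater_profile <- function(seed, n_points = 10, basal_gradient,
                                   surface_conc, noise_sd = 0,
                                   porosity = 0.7, diffusivity = 0.01,
                                   max_depth = 45) {
  stopifnot(n_points >= 2, noise_sd >= 0)
  with_local_seed(seed, {
    depths <- seq(0, max_depth, length.out = n_points)
    conc <- surface_conc + basal_gradient * depths +
      if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
    porewater_profile(depths, conc, porosity, diffusivity)
  })
}

#' Synthetic clone library
#'
#' Either passes an explicit OTU abundance vector through verbatim, or draws
#' OTU proportions from a symmetric Dirichlet and clone counts from a
#' multinomial, emulating the small clone libraries (tens of clones, a
#' handful of OTUs) typical of functional-gene surveys.
#'
#' @param seed Integer seed (unused in verbatim mode).
#' @param abundance_vector Explicit positive counts; if given with
#'   `n_clones`, their sum must equal it.
#' @param dirichlet_params Symmetric Dirichlet concentration parameter for
#'   sampled proportions.
#' @param n_otus Number of OTUs in sampled mode.
#' @param n_clones Library size in sampled mode (>= 1).
#' @return A [clone_library()].
#' @examples
#' make_clone_library(1, abundance_vector = c(20, 6, 3, 3, 1, 1, 1, 1))
#' @export
make_clone_library <- function(seed = 1, abundance_vector = NULL,
                               dirichlet_params = 1, n_otus = NULL,
                               n_clones = NULL) {
  if (!is.null(abundance_vector)) {
    if (!is.null(n_clones) && sum(abundance_vector) != n_clones) {
      stop("abundance_vector sums to ", sum(abundance_vector),
           ", not n_clones = ", n_clones)
    }
    return(clone_library(abundance_vector))
  }
  stopifnot(!is.null(n_otus), !is.null(n_clones), n_clones >= 1, n_otus >= 1)
  with_local_seed(seed, {
    p <- stats::rgamma(n_otus, shape = dirichlet_params)
    p <- p / sum(p)
    counts <- as.vector(stats::rmultinom(1, n_clones, p))
    clone_library(sort(counts[counts > 0], decreasing = TRUE))
  })
}

#' Synthetic aligned sequence family with controlled divergence
#'
#' Builds `n_clades` clade ancestors by mutating a common root at
#' `between_clade_divergence / 2` per site, then mutates each ancestor at
#' `within_clade_divergence / 2` per site for each leaf, so realized mean
#' pairwise divergences approximate the requested within/between levels
#' (close for alignments of a few hundred positions or more, where the
#' overlap of independently mutated sites is a small correction). With
#' within-divergence 0 each clade is a set of identical sequences and
#' clustering at any cutoff below the between-divergence yields exactly
#' `n_clades` OTUs.
#'
#' @param seed Integer seed.
#' @param n_clades Number of clades (>= 1).
#' @param seqs_per_clade Sequences per clade (>= 1).
#' @param length Alignment length in nucleotides.
#' @param within_clade_divergence,between_clade_divergence Target mean
#'   pairwise p-distances; require
#'   `0 <= within < between <= 0.75` (0.75 is the random-sequence limit).
#' @return An [aligned_sequence_set()] with ids `cladeXX_seqYY`.
#' @export
make_sequence_set <- function(seed, n_clades, seqs_per_clade, length,
                              within_clade_divergence,
                              between_clade_divergence) {
  if (!(within_clade_divergence >= 0 &&
        within_clade_divergence < between_clade_divergence &&
        between_clade_divergence <= 0.75)) {
    stop("need 0 <= within < between <= 0.75")
  }
  stopifnot(n_clades >= 1, seqs_per_clade >= 1, length >= 1)
  bases <- c("A", "C", "G", "T")
  mutate <- function(seq, rate) {
    hit <- stats::runif(length) < rate
    if (any(hit)) {
      seq[hit] <- vapply(seq[hit], function(b) {
        sample(setdiff(bases, b), 1)
      }, "")
    }
    seq
  }
  with_local_seed(seed, {
    root <- sample(bases, length, replace = TRUE)
    ids <- character(0); seqs <- character(0)
    for (k in seq_len(n_clades)) {
      anc <- mutate(root, between_clade_divergence / 2)
      for (j in seq_len(seqs_per_clade)) {
        leaf <- mutate(anc, within_clade_divergence / 2)
        ids <- c(ids, sprintf("clade%02d_seq%02d", k, j))
        seqs <- c(seqs, paste(leaf, collapse = ""))
      }
    }
    aligned_sequence_set(ids, seqs)
  })
}

#' Synthetic community count table
#'
#' Dirichlet-multinomial counts for a focal family's clades plus a residual
#' "other" compartment, per habitat design: each habitat has a within-family
#' clade composition and a family fraction of total reads, emulating a
#' seawater community dominated by one clade and a rock community dominated
#' by another with the family a small slice of the whole. Expected clade
#' profiles equal the design proportions; `overdispersion = 0` gives plain
#' multinomial sampling.
#'
#' @param seed Integer seed.
#' @param habitat_design Named list (habitat -> named clade proportion
#'   vector summing to 1).
#' @param sample_info data.frame with columns `sample`, `habitat`,
#'   `depth_mbsf`.
#' @param reads_per_sample Reads per sample (single value or per-sample
#'   vector; a zero gives an all-zero row, flagged downstream).
#' @param overdispersion Dirichlet-multinomial overdispersion; proportions
#'   are drawn from Dirichlet(design / overdispersion) when > 0.
#' @param otus_per_clade OTUs per clade, splitting the clade mass uniformly
#'   (default 1).
#' @param family Focal family label (default "Nitrosopumilaceae").
#' @param family_fraction Named per-habitat fraction of reads in the focal
#'   family (default: seawater 0.0115, sediment 0.10, basalt 0.005,
#'   magnitudes typical of the three habitats).
#' @return A [community_table()].
#' @export
make_community_table <- function(seed, habitat_design, sample_info,
                                 reads_per_sample, overdispersion = 0,
                                 otus_per_clade = 1,
                                 family = "Nitrosopumilaceae",
                                 family_fraction = c(seawater = 0.0115,
                                                     sediment = 0.10,
                                                     basalt = 0.005)) {
  stopifnot(all(sample_info$habitat %in% names(habitat_design)),
            all(sample_info$habitat %in% names(family_fraction)),
            overdispersion >= 0)
  for (h in names(habitat_design)) {
    if (abs(sum(habitat_design[[h]]) - 1) > 1e-9) {
      stop("clade proportions for habitat '", h, "' must sum to 1")
    }
  }
  clades <- unique(unlist(lapply(habitat_design, names)))
  otu_ids <- as.vector(t(outer(clades, seq_len(otus_per_clade),
                               function(cl, i) sprintf("%s_OTU%d", cl, i))))
  otu_clade <- rep(clades, each = otus_per_clade)
  taxonomy <- data.frame(otu = c(otu_ids, "Other_OTU1"),
                         family = c(rep(family, length(otu_ids)), "other"),
                         clade = c(otu_clade, "unclassified"))
  reads <- rep_len(reads_per_sample, nrow(sample_info))
  with_local_seed(seed, {
    counts <- t(vapply(seq_len(nrow(sample_info)), function(i) {
      h <- sample_info$habitat[i]
      props <- stats::setNames(rep(0, length(clades)), clades)
      props[names(habitat_design[[h]])] <- habitat_design[[h]]
      p_otu <- rep(props / otus_per_clade, each = otus_per_clade)
      ff <- family_fraction[[h]]
      p <- c(p_otu * ff, 1 - ff)
      if (overdispersion > 0) {
        alpha <- p / overdispersion
        g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
        p <- g / sum(g)
      }
      if (reads[i] == 0) rep(0, length(p)) else
        as.vector(stats::rmultinom(1, reads[i], p))
    }, numeric(length(otu_ids) + 1)))
    dimnames(counts) <- list(sample_info$sample, taxonomy$otu)
    community_table(counts, sample_info, taxonomy)
  })
}

#' Synthetic qPCR dilution series
#'
#' Quantification cycles from the log-linear amplification model
#' \deqn{C_q = C_{q,10^5} + \frac{\log_{10}(10^5) - \log_{10}(copies)}
#'   {\log_{10}(1 + E)} + \epsilon,}
#' over a geometric dilution series (default 10x steps from 1.5e5 down to
#' 1.5 copies/ul, the span of a linearized-fosmid standard). With
#' `noise_sd = 0`, [fit_standard_curve()] recovers the planted efficiency
#' exactly.
#'
#' @param seed Integer seed.
#' @param efficiency Amplification efficiency E in (0, 1.1].
#' @param cq_at_1e5 Cq at 1e5 copies/ul (default 24).
#' @param dilution_factor Step between levels (default 10).
#' @param n_levels Number of dilution levels (>= 3; default 6).
#' @param noise_sd Gaussian Cq noise SD (default 0).
#' @param start_copies Top of the series, copies/ul (default 1.5e5).
#' @return A [dilution_series()].
#' @export
make_qpcr_series <- function(seed, efficiency = 0.99, cq_at_1e5 = 24,
                             dilution_factor = 10, n_levels = 6,
                             noise_sd = 0, start_copies = 1.5e5) {
  stopifnot(efficiency > 0, efficiency <= 1.1, n_levels >= 3,
            dilution_factor > 1, noise_sd >= 0)
  with_local_seed(seed, {
    copies <- start_copies / dilution_factor^(seq_len(n_levels) - 1)
    cq <- cq_at_1e5 + (log10(1e5) - log10(copies)) / log10(1 + efficiency) +
      if (noise_sd > 0) stats::rnorm(n_levels, 0, noise_sd) else 0
    dilution_series(copies, cq)
  })
}
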