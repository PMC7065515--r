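# Independent oracles used across the suite. These deliberately re-derive
# results by naive means (hand loops, enumeration, simulation) and share no
# code with the package implementation.

# p-distance by direct column-wise comparison with pairwise deletion
hand_p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(ok)) stop("no comparable columns")
  sum(a[ok] != b[ok]) / sum(ok)
}

# naive agglomerative complete linkage: repeatedly merge the pair of
# clusters with the smallest maximum inter-member distance, while that
# distance is <= cutoff
naive_complete_linkage <- function(dmat, cutoff) {
  clusters <- as.list(seq_len(nrow(dmat)))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- max(dmat[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(j, i)
        }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(nrow(dmat))
  for (k in seq_along(clusters)) assign[clusters[[k]]] <- k
  assign
}

# partitions agree up to relabeling
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# discretized along-path integration of the conservative box model: the path
# is cut into segments, each receiving an equal share of the total diffusive
# input; returns the endpoint concentration in uM
segmented_endpoint <- function(model, n_segments = 100) {
  i_mol <- mean(c(model$flux_start, model$flux_end)) *
    model$effective_exchange_area / 1000
  conc <- model$start_concentration / 1000  # mol/m^3
  for (s in seq_len(n_segments)) {
    conc <- conc + (i_mol / n_segments) / model$flow_rate
  }
  conc * 1000
}

# random valid flow-path model for property tests
random_flow_path_model <- function() {
  flow_path_model(
    path_length = stats::runif(1, 100, 10000),
    flow_rate = stats::runif(1, 0.005, 0.5),
    start_concentration = stats::runif(1, 1, 50),
    end_concentration_observed = stats::runif(1, 1, 50),
    flux_start = stats::runif(1, 0, 0.05),
    flux_end = stats::runif(1, 0, 0.05),
    effective_exchange_area = stats::runif(1, 0.1, 50)
  )
}
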