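# Independent oracles used across the test suite. These deliberately take
# different computational routes than the package code they check.

# Elemental-formula monoisotopic mass: builds the molecular formula of an
# unsaturated/saturated oligogalacturonide from residue counts and sums
# atomic isotope masses (independent of the package's building-block rule).
# anhydro-GalA = C6H8O6; methyl adds CH2; acetyl adds C2H2O; saturated
# parent adds H2O.
elemental_mono_mass <- function(dp, n_methyl, n_acetyl, unsaturated = TRUE) {
  nC <- 6 * dp + n_methyl + 2 * n_acetyl
  nH <- 8 * dp + 2 * n_methyl + 2 * n_acetyl + if (unsaturated) 0 else 2
  nO <- 6 * dp + n_acetyl + if (unsaturated) 0 else 1
  nC * 12 + nH * 1.00782503 + nO * 15.99491462
}

# Brute-force agglomerative complete-linkage clustering: returns the sorted
# vector of merge heights. O(n^4), fine for n <= 5.
naive_complete_linkage_heights <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), identity)
  d <- as.matrix(stats::dist(mat))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < best_h) { best_h <- h; best <- c(a, b) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Recursive enumeration of every terminal product reachable from a chain
# under a cleavage rule (exhaustive over cleavage choices, not stochastic).
# Chains are (methyl logical vector, unsat flag); acetyls omitted (rates
# only rescale, reachability is unchanged for penalty > 0).
reachable_terminal_products <- function(methyl, unsat, rule) {
  ch <- residue_chain(methyl, unsaturated = unsat)
  cb <- cleavable_bonds(ch, rule)
  if (nrow(cb) == 0L)
    return(list(list(methyl = methyl, unsat = unsat)))
  out <- list()
  for (b in cb$bond) {
    left <- reachable_terminal_products(methyl[seq_len(b)], unsat, rule)
    right <- reachable_terminal_products(methyl[seq(b + 1L, length(methyl))],
                                         TRUE, rule)
    out <- c(out, left, right)
  }
  unique(out)
}

# All labeled oligomers of a given dp with methyl patterns exhaustive and
# up to `max_acetyl` acetyl groups placed over 2 sites per residue.
all_labeled_oligomers <- function(dp, max_acetyl = 2L) {
  methyl_pat <- expand.grid(rep(list(c(FALSE, TRUE)), dp))
  slots <- rep(seq_len(dp), each = 2L)
  acetyl_sets <- list(integer(0))
  for (k in seq_len(max_acetyl)) {
    acetyl_sets <- c(acetyl_sets,
                     utils::combn(length(slots), k, simplify = FALSE))
  }
  out <- list()
  for (r in seq_len(nrow(methyl_pat))) {
    m <- as.logical(methyl_pat[r, ])
    for (ix in acetyl_sets) {
      a <- tabulate(slots[ix], nbins = dp)
      out[[length(out) + 1L]] <- labeled_oligomer(m, a)
    }
  }
  out
}

# Tiny helper: mean initial cleavable-bond rate per residue of a chain set.
total_initial_rate <- function(chains, rule) {
  sum(vapply(chains, function(ch) sum(cleavable_bonds(ch, rule)$rate),
             numeric(1)))
}
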