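# MS2 fragment prediction for labeled oligogalacturonides, using the
# Domon-Costello nomenclature for 1,4-linked uronides.
#
# Neutral fragment bookkeeping (nominal mode; per-residue contribution
# r_k = 176 + 14*methyl_k + 42*acetyl_k, parent unsaturated M = sum r_k):
#   C_i  = sum(r_1..r_i)        (non-reducing side, keeps the Delta-4,5 end;
#                                chemically an unsaturated oligomer of i
#                                residues, hence C_i rule = parent rule)
#   B_i  = C_i - H2O
#   Z_j  = sum(r_{n-j+1}..r_n)  (reducing side; isomeric with a C ion of the
#                                complementary composition)
#   Y_j  = Z_j + H2O
#   0,2A_i = C_i - 60           (cross-ring, loses C1+C2 as C2H4O2; the
#                                standard 0,2 cleavage for 1,4-linked sugars)
# Substituent masses travel with the fragment containing the substituted
# residue.

#' Labeled oligogalacturonide
#'
#' An explicit residue-by-residue structure, ordered from the non-reducing
#' to the reducing end, with per-residue methyl and acetyl annotations.
#'
#' @param methyl Logical vector, one element per residue (O-6 methyl ester).
#' @param acetyl Integer vector of acetyl counts per residue (0, 1 or 2;
#'   O-2/O-3 positions are not distinguished by the mass model).
#' @param unsaturated Logical, Delta-4,5 unsaturated non-reducing end.
#' @return Object of class `labeled_oligomer`.
#' @examples
#' labeled_oligomer(c(TRUE, TRUE, TRUE, TRUE), c(0, 0, 0, 1))
#' @export
labeled_oligomer <- function(methyl, acetyl = integer(length(methyl)),
                             unsaturated = TRUE) {
  methyl <- as.logical(methyl)
  acetyl <- as.integer(acetyl)
  if (length(methyl) < 1L) stop("need at least one residue", call. = FALSE)
  if (length(acetyl) != length(methyl))
    stop("methyl and acetyl must have one entry per residue", call. = FALSE)
  if (any(is.na(methyl)) || any(is.na(acetyl)) ||
      any(acetyl < 0L) || any(acetyl > 2L))
    stop("acetyl counts must be 0, 1 or 2", call. = FALSE)
  structure(list(methyl = methyl, acetyl = acetyl,
                 unsaturated = isTRUE(unsaturated)),
            class = "labeled_oligomer")
}

#' Composition of a labeled oligomer
#' @param olig A [labeled_oligomer()].
#' @return The aggregate [oligo_composition()].
#' @export
oligomer_composition <- function(olig) {
  stopifnot(inherits(olig, "labeled_oligomer"))
  oligo_composition(length(olig$methyl), sum(olig$methyl), sum(olig$acetyl),
                    olig$unsaturated)
}

# Neutral composition of the residues a fragment contains. Glycosidic
# series B/C take residues 1..i (non-reducing side); Z/Y take the last j;
# cross-ring 0,2A takes residues 1..i with residue i truncated (its
# substituents are retained: O-3/O-6/O-2 bookkeeping is not resolved at
# unit resolution, so substituent loss is modeled only via explicit
# neutral-loss annotations).
#' Residues contained in a predicted fragment
#'
#' @param olig A [labeled_oligomer()].
#' @param series `"B"`, `"C"`, `"Z"`, `"Y"` or `"A02"`.
#' @param index Fragment index i (glycosidic: `1 <= i <= dp - 1`).
#' @return [oligo_composition()] of the fragment's residues (for `Z`/`Y`
#'   the non-reducing end of the fragment is the newly exposed one, so the
#'   composition is reported unsaturated for `Z` and saturated for `Y`,
#'   matching their neutral masses).
#' @export
fragment_composition <- function(olig, series, index) {
  stopifnot(inherits(olig, "labeled_oligomer"))
  n <- length(olig$methyl)
  series <- match.arg(series, c("B", "C", "Z", "Y", "A02"))
  glycosidic <- series %in% c("B", "C", "Z", "Y")
  if (glycosidic && (index < 1L || index > n - 1L))
    stop("glycosidic fragment index must lie in [1, dp - 1]", call. = FALSE)
  if (series %in% c("B", "C", "A02")) {
    keep <- seq_len(index)
    unsat <- olig$unsaturated
  } else {
    keep <- seq(n - index + 1L, n)
    unsat <- TRUE  # Z: beta-elimination-type cleavage, anhydro composition
  }
  if (series == "Y") unsat <- FALSE
  oligo_composition(length(keep), sum(olig$methyl[keep]),
                    sum(olig$acetyl[keep]), unsat)
}

.frag_neutral_mass <- function(olig, series, index, mode = "nominal") {
  comp <- fragment_composition(olig, series, index)
  base <- .mass_rule(comp$dp, comp$n_methyl, comp$n_acetyl, TRUE, mode)
  w <- .MASS$water[[mode]]
  switch(series,
         C = base + if (olig$unsaturated) 0 else w,
         B = base - w + if (olig$unsaturated) 0 else w,
         Z = base,
         Y = base + w,
         A02 = base - (if (mode == "nominal") 60 else 60.02113) +
           if (olig$unsaturated) 0 else w)
}

#' Predict MS2 fragment ions
#'
#' Negative mode emits the C and Z ladders (isomeric masses: a matched peak
#' cannot distinguish `C_i` from the `Z_j` of complementary composition)
#' plus the 0,2A cross-ring series, as deprotonated ions. When the
#' reducing-end residue is methylated, companion ions with a 32 Da methanol
#' loss are emitted for the precursor and for reducing-end-containing (Z)
#' fragments. Positive mode emits B and C ladders with the ammonium ion
#' retained and, by default, an empirical -7 Da series-wide offset that
#' reproduces the fragmentation behaviour observed for fully methoxylated
#' oligogalacturonides on the iontrap; the offset is chemically unexplained
#' and is therefore applied as an opaque, flagged correction, never folded
#' into the mass model.
#'
#' @param olig A [labeled_oligomer()] with dp >= 2 (dp = 1 returns an empty
#'   table).
#' @param polarity `"negative"` or `"positive"`.
#' @param z Charge of the emitted fragment ions (1 or 2).
#' @param include_losses Emit neutral-loss companion ions (methanol -32).
#' @param empirical_offset_da Offset added to every positive-mode fragment
#'   m/z; default -7. Set 0 to disable. Ignored in negative mode.
#' @return data.frame `series, index, polarity, z, neutral_mass, mz,
#'   neutral_loss, empirical_offset` (one row per ion; the precursor is
#'   included as series `"M"`, index dp, without the offset).
#' @export
predict_fragments <- function(olig, polarity = c("negative", "positive"),
                              z = 1L, include_losses = TRUE,
                              empirical_offset_da = -7) {
  stopifnot(inherits(olig, "labeled_oligomer"))
  polarity <- match.arg(polarity)
  z <- as.integer(z)
  n <- length(olig$methyl)
  empty <- data.frame(series = character(), index = integer(),
                      polarity = character(), z = integer(),
                      neutral_mass = numeric(), mz = numeric(),
                      neutral_loss = numeric(), empirical_offset = numeric())
  if (n < 2L) return(empty)
  offset <- if (polarity == "positive") empirical_offset_da else 0
  ad <- if (polarity == "negative") adduct_spec("deprotonated", z)
        else adduct_spec("ammonium", z)

  rows <- list()
  add <- function(series, index, loss = 0, with_offset = TRUE) {
    nm <- if (series == "M") {
      comp <- oligomer_composition(olig)
      nominal_mass(comp)
    } else .frag_neutral_mass(olig, series, index)
    nm <- nm - loss
    off <- if (with_offset) offset else 0
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, index = index, polarity = polarity, z = z,
      neutral_mass = nm, mz = adduct_mz(nm, ad) + off,
      neutral_loss = loss, empirical_offset = off)
  }

  red_methyl <- olig$methyl[n]
  if (polarity == "negative") {
    for (i in seq_len(n - 1L)) add("C", i)
    for (j in seq_len(n - 1L)) {
      add("Z", j)
      if (include_losses && red_methyl) add("Z", j, loss = 32)
    }
    for (i in seq(2L, n)) add("A02", i)
    add("M", n, with_offset = FALSE)
    if (include_losses && red_methyl) add("M", n, loss = 32,
                                          with_offset = FALSE)
  } else {
    for (i in seq_len(n - 1L)) { add("B", i); add("C", i) }
    add("M", n, with_offset = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Localize acetyl substituents from fragment evidence
#'
#' B/C fragments contain residues 1..i counted from the non-reducing end, so
#' observing whether each fragment retained or lost the acetyl group brackets
#' the acetylated residue: a fragment that retained acetyl places at least
#' one acetyl at positions <= i, a fragment that lost it excludes positions
#' <= i. The function enumerates all placements of `n_acetyl` acetyls
#' consistent with every observation and returns the union of feasible
#' residue positions; an empty set signals contradictory evidence. Without
#' observations, all positions are feasible. The result shrinks (set
#' intersection semantics) as observations accumulate.
#'
#' @param dp Degree of polymerization of the candidate.
#' @param n_acetyl Number of acetyls on the candidate (>= 1).
#' @param observations data.frame with columns `series` ("B" or "C"),
#'   `index` (1..dp-1) and `acetyl_retained` (logical: did the fragment
#'   carry at least one acetyl).
#' @return Sorted integer vector of feasible acetyl positions (1-based from
#'   the non-reducing end); `integer(0)` on contradiction.
#' @examples
#' obs <- data.frame(series = c("B", "C"), index = 3,
#'                   acetyl_retained = FALSE)
#' localize_acetyl(4, 1, obs)  # reducing-end residue: 4
#' @export
localize_acetyl <- function(dp, n_acetyl, observations = NULL) {
  dp <- as.integer(dp); n_acetyl <- as.integer(n_acetyl)
  stopifnot(dp >= 2L, n_acetyl >= 1L)
  if (!is.null(observations) && nrow(observations) > 0L) {
    if (any(observations$index < 1L | observations$index > dp - 1L))
      stop("fragment index out of range for dp", call. = FALSE)
    if (any(!observations$series %in% c("B", "C")))
      stop("only B/C fragment observations carry positional information",
           call. = FALSE)
  }
  # placements: multisets of positions, at most 2 acetyls per residue
  slots <- rep(seq_len(dp), each = 2L)
  placements <- utils::combn(length(slots), n_acetyl, simplify = FALSE)
  placements <- unique(lapply(placements, function(ix) sort(slots[ix])))
  ok <- vapply(placements, function(pos) {
    if (is.null(observations) || nrow(observations) == 0L) return(TRUE)
    all(vapply(seq_len(nrow(observations)), function(k) {
      i <- observations$index[k]
      has <- any(pos <= i)
      if (observations$acetyl_retained[k]) has else !has
    }, logical(1)))
  }, logical(1))
  sort(unique(unlist(placements[ok])))
}
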