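# Mechanistic digest simulator: homogalacturonan chains with controlled
# methylation/acetylation patterns, subsite-rule beta-elimination, and an
# exact (Gillespie) stochastic realization producing product compositions
# over time and synthetic LC-MS-like peak tables.
#
# Subsite convention: bond i joins residues i and i+1 (counted from the
# non-reducing end). The enzyme spans subsites -4..+4 across the cleaved
# bond: subsite +1 is residue i+1 (reducing-end side), +k is residue i+k,
# -1 is residue i, -k is residue i-k+1. Cleavage requires a methylated
# GalA in +1; a methylated +3 gives the full rate, otherwise cleavage
# proceeds at the reduced partial rate rho (strict mode: rho = 0, so +3
# must exist and be methylated). Acetyl groups anywhere in the occupied
# window multiply the rate by a penalty per acetyl.

#' Homogalacturonan residue chain
#'
#' @param methyl Logical vector (O-6 methyl ester per residue), ordered
#'   non-reducing to reducing end.
#' @param acetyl_o2,acetyl_o3 Logical vectors of O-2/O-3 acetylation.
#' @param unsaturated Logical, Delta-4,5 unsaturated non-reducing end
#'   (FALSE for native substrate chains, TRUE for lyase products).
#' @return Object of class `residue_chain`.
#' @export
residue_chain <- function(methyl,
                          acetyl_o2 = logical(length(methyl)),
                          acetyl_o3 = logical(length(methyl)),
                          unsaturated = FALSE) {
  methyl <- as.logical(methyl)
  n <- length(methyl)
  if (n < 1L) stop("chain needs at least one residue", call. = FALSE)
  if (length(acetyl_o2) != n || length(acetyl_o3) != n)
    stop("acetyl vectors must match chain length", call. = FALSE)
  structure(list(methyl = methyl, acetyl_o2 = as.logical(acetyl_o2),
                 acetyl_o3 = as.logical(acetyl_o3),
                 unsaturated = isTRUE(unsaturated)),
            class = "residue_chain")
}

#' Composition of a residue chain
#' @param chain A [residue_chain()].
#' @return [oligo_composition()] with acetyls counted over both positions.
#' @export
chain_composition <- function(chain) {
  stopifnot(inherits(chain, "residue_chain"))
  oligo_composition(length(chain$methyl), sum(chain$methyl),
                    sum(chain$acetyl_o2) + sum(chain$acetyl_o3),
                    chain$unsaturated)
}

#' Substrate specification for the chain generator
#'
#' @param n_chains Number of chains.
#' @param chain_length Integer chain length, or a vector of lengths sampled
#'   uniformly with replacement.
#' @param dm Degree of methoxylation, percent of residues carrying an O-6
#'   methyl ester (0-100).
#' @param dac Degree of acetylation, percent of residues carrying an acetyl
#'   group (0-100; the generator places one acetyl per acetylated residue,
#'   O-2 or O-3 with equal probability).
#' @param methyl_pattern `"random"` (i.i.d. Bernoulli) or `"blockwise"`
#'   (methyls placed in contiguous runs; blockwise distributions yield
#'   higher lyase activity at equal DM).
#' @param block_length Run length for blockwise placement.
#' @param inert_fraction Fraction of residues inert to the lyase (a coarse
#'   stand-in for RG-I insertions and other non-GalA backbone content);
#'   inert residues are never methylated and so never satisfy subsite
#'   requirements.
#' @return Object of class `substrate_spec`.
#' @export
substrate_spec <- function(n_chains, chain_length, dm, dac = 0,
                           methyl_pattern = c("random", "blockwise"),
                           block_length = 5L, inert_fraction = 0) {
  methyl_pattern <- match.arg(methyl_pattern)
  if (dm < 0 || dm > 100) stop("DM must lie in [0, 100]", call. = FALSE)
  if (dac < 0 || dac > 100) stop("DAc must lie in [0, 100]", call. = FALSE)
  if (inert_fraction < 0 || inert_fraction >= 1)
    stop("inert_fraction must lie in [0, 1)", call. = FALSE)
  if (any(chain_length < 1)) stop("chain_length must be >= 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 dm = dm, dac = dac, methyl_pattern = methyl_pattern,
                 block_length = as.integer(block_length),
                 inert_fraction = inert_fraction),
            class = "substrate_spec")
}

#' Substrate presets from pectin compositional data
#'
#' Returns the shipped table of pectin substrate parameters
#' (monosaccharide contents in umol/g dry matter, DAc, DM) for apple,
#' citrus and sugar beet pectin, plus a synthetic polygalacturonic acid row
#' (no compositional assay exists for the commercial PGA; pure anhydro-GalA
#' polymer is assumed, flagged in the `synthetic` column).
#'
#' @param substrate Optional preset name (`"apple"`, `"citrus"`,
#'   `"sugarbeet"`, `"pga"`); when given, a single row is returned.
#' @return data.frame of preset parameters.
#' @export
pectin_presets <- function(substrate = NULL) {
  path <- system.file("extdata", "pectin_substrates.csv",
                      package = "pelprofiler", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(substrate)) {
    tab <- tab[tab$substrate == substrate, , drop = FALSE]
    if (nrow(tab) == 0L) stop("unknown substrate preset: ", substrate,
                              call. = FALSE)
  }
  tab
}

#' Generate substrate chains
#'
#' Realized DM and DAc converge to the specified values as the total
#' residue count grows. Blockwise mode targets `round(dm/100 * L)` methyls
#' per chain, placed as non-overlapping runs of `block_length` at random
#' positions (the final run is truncated to hit the target count);
#' random mode methylates residues i.i.d.
#'
#' @param spec A [substrate_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return List of [residue_chain()] objects.
#' @export
generate_chains <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "substrate_spec"))
  if (!is.null(seed)) set.seed(seed)
  lens <- if (length(spec$chain_length) == 1L)
    rep(spec$chain_length, spec$n_chains)
  else sample(spec$chain_length, spec$n_chains, replace = TRUE)
  lapply(lens, function(L) {
    inert <- if (spec$inert_fraction > 0)
      stats::runif(L) < spec$inert_fraction else rep(FALSE, L)
    methyl <- if (spec$methyl_pattern == "random") {
      stats::runif(L) < spec$dm / 100
    } else {
      .blockwise_methyls(L, round(spec$dm / 100 * L), spec$block_length)
    }
    methyl[inert] <- FALSE
    ac <- stats::runif(L) < spec$dac / 100
    side <- stats::runif(L) < 0.5
    residue_chain(methyl, acetyl_o2 = ac & side, acetyl_o3 = ac & !side,
                  unsaturated = FALSE)
  })
}

# Place `target` methyls on a chain of length L as runs of `block` starting
# at random free positions; runs are truncated at the chain end and at the
# target count.
.blockwise_methyls <- function(L, target, block) {
  methyl <- rep(FALSE, L)
  placed <- 0L
  starts <- sample.int(L)
  for (s in starts) {
    if (placed >= target) break
    if (methyl[s]) next
    run <- seq(s, min(L, s + block - 1L))
    run <- run[!methyl[run]]
    run <- run[seq_len(min(length(run), target - placed))]
    methyl[run] <- TRUE
    placed <- placed + length(run)
  }
  methyl
}

#' Cleavage rule (subsite model)
#'
#' @param rho Partial-rate factor in `[0, 1]` for bonds where only subsite
#'   +1 is methylated (+3 missing or unmethylated); 0 gives the strict
#'   \{+1, +3\} rule. Default 0.25: cleavage with only +1 methylated
#'   proceeds, at clearly lower specific rate.
#' @param acetyl_penalty Multiplicative factor in `(0, 1]` applied once per
#'   acetyl group on any residue occupying subsites -4..+4. Default 0.5.
#' @param block_acetyl_plus1 If TRUE, any acetyl on the +1 residue blocks
#'   cleavage outright (off by default; whether acetylation at +1 blocks
#'   the beta-elimination chemistry is unresolved).
#' @return Object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(rho = 0.25, acetyl_penalty = 0.5,
                          block_acetyl_plus1 = FALSE) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (acetyl_penalty <= 0 || acetyl_penalty > 1)
    stop("acetyl_penalty must lie in (0, 1]", call. = FALSE)
  structure(list(rho = rho, acetyl_penalty = acetyl_penalty,
                 block_acetyl_plus1 = isTRUE(block_acetyl_plus1)),
            class = "cleavage_rule")
}

#' Strict \{+1, +3\} cleavage rule
#' @param acetyl_penalty See [cleavage_rule()].
#' @return A [cleavage_rule()] with `rho = 0`.
#' @export
strict_rule <- function(acetyl_penalty = 0.5) {
  cleavage_rule(rho = 0, acetyl_penalty = acetyl_penalty)
}

# Relative rate of every bond (vector of length L-1) for methyl vector m
# and per-residue acetyl counts ac. Hot path: no classes, no data.frame.
.bond_rates <- function(m, ac, rule) {
  L <- length(m)
  if (L < 2L) return(numeric(0))
  i <- seq_len(L - 1L)
  plus1 <- m[i + 1L]
  plus3 <- (i + 3L <= L) & c(m, FALSE, FALSE, FALSE)[i + 3L]
  base <- ifelse(plus1, ifelse(plus3, 1, rule$rho), 0)
  if (any(ac > 0L) && any(base > 0)) {
    cs <- c(0L, cumsum(ac))
    lo <- pmax(1L, i - 3L)           # subsite -4 residue
    hi <- pmin(L, i + 4L)            # subsite +4 residue
    win <- cs[hi + 1L] - cs[lo]
    base <- base * rule$acetyl_penalty^win
    if (rule$block_acetyl_plus1) base[ac[i + 1L] > 0L] <- 0
  }
  base
}

#' Cleavable bonds of a chain under a subsite rule
#'
#' @param chain A [residue_chain()].
#' @param rule A [cleavage_rule()].
#' @return data.frame `bond` (index i, bond between residues i and i+1)
#'   and `rate` (relative rate > 0); zero-rate bonds are omitted.
#' @export
cleavable_bonds <- function(chain, rule = cleavage_rule()) {
  stopifnot(inherits(chain, "residue_chain"), inherits(rule, "cleavage_rule"))
  rates <- .bond_rates(chain$methyl,
                       as.integer(chain$acetyl_o2) +
                         as.integer(chain$acetyl_o3), rule)
  keep <- which(rates > 0)
  data.frame(bond = keep, rate = rates[keep])
}

.split_chain <- function(chain, bond) {
  L <- length(chain$methyl)
  left <- seq_len(bond); right <- seq(bond + 1L, L)
  list(
    residue_chain(chain$methyl[left], chain$acetyl_o2[left],
                  chain$acetyl_o3[left], unsaturated = chain$unsaturated),
    # the reducing-end-side fragment (subsite +1 side) gains the
    # Delta-4,5-unsaturated non-reducing end
    residue_chain(chain$methyl[right], chain$acetyl_o2[right],
                  chain$acetyl_o3[right], unsaturated = TRUE))
}

# Summarize a list of bare chains (m = methyl logicals, ac = acetyl
# counts, u = unsaturated flag) into composition counts + conservation
# totals.
.bare_summary <- function(chains, time, cleavages) {
  key <- vapply(chains, function(ch)
    paste(length(ch$m), sum(ch$m), sum(ch$ac),
          as.integer(ch$u), sep = "/"), character(1))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "/", fixed = TRUE))
  comps <- data.frame(dp = as.integer(parts[, 1]),
                      n_methyl = as.integer(parts[, 2]),
                      n_acetyl = as.integer(parts[, 3]),
                      unsaturated = parts[, 4] == "1",
                      count = as.integer(tab), row.names = NULL)
  comps <- comps[order(comps$dp, comps$n_methyl, comps$n_acetyl,
                       comps$unsaturated), , drop = FALSE]
  rownames(comps) <- NULL
  list(time = time, cleavage_count = cleavages, compositions = comps,
       total_residues = sum(comps$dp * comps$count),
       total_methyl = sum(comps$n_methyl * comps$count),
       total_acetyl = sum(comps$n_acetyl * comps$count),
       n_chains = length(chains),
       unsaturated_ends = sum(comps$count[comps$unsaturated]))
}

#' Simulate a lyase digest (exact stochastic simulation)
#'
#' Continuous-time Markov (Gillespie) simulation of beta-elimination: each
#' event cleaves one bond chosen with probability proportional to its
#' relative subsite rate, splitting the chain; the reducing-end-side
#' fragment gains an unsaturated non-reducing end. Chains without cleavable
#' bonds are moved to a terminal pool and never revisited. Snapshots
#' summarize the full state (terminal pool included) at the requested
#' times.
#'
#' @param chains List of [residue_chain()] (e.g. from [generate_chains()]).
#' @param rule A [cleavage_rule()].
#' @param rate_constant Overall rate constant (events per unit relative
#'   rate per minute); scales time only.
#' @param time_points Ascending numeric vector of snapshot times (minutes).
#'   `Inf` is allowed as the last entry and yields the terminal state.
#' @param seed Optional integer seed.
#' @param max_events Safety cap on the number of cleavage events.
#' @return Object of class `pel_digest`: list with `snapshots` (one
#'   `.state_summary` per time point: time, cleavage_count, composition
#'   counts, conservation totals), `final_chains`, `cleavage_count`.
#' @export
simulate_digest <- function(chains, rule = cleavage_rule(),
                            rate_constant = 1, time_points = c(0, Inf),
                            seed = NULL, max_events = 1e6) {
  stopifnot(inherits(rule, "cleavage_rule"), rate_constant > 0)
  if (is.unsorted(time_points)) stop("time_points must be ascending",
                                     call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # Hot-loop chain representation: plain list(m, ac) with the acetyl count
  # vector; unsaturation tracked separately. Chains whose total rate is 0
  # go to a terminal pool and are never revisited.
  as_bare <- function(ch) list(m = ch$methyl,
                               ac = as.integer(ch$acetyl_o2) +
                                 as.integer(ch$acetyl_o3),
                               a2 = ch$acetyl_o2, a3 = ch$acetyl_o3,
                               u = ch$unsaturated)
  bare <- lapply(chains, as_bare)
  rates0 <- lapply(bare, function(b) .bond_rates(b$m, b$ac, rule))
  tot0 <- vapply(rates0, sum, numeric(1))
  is_act <- tot0 > 0
  active <- bare[is_act]; act_bonds <- rates0[is_act]
  act_rate <- tot0[is_act]
  terminal <- bare[!is_act]

  t_now <- 0; events <- 0L
  snapshots <- vector("list", length(time_points))
  snap_i <- 1L
  take_snaps_up_to <- function(t_event) {
    while (snap_i <= length(time_points) && time_points[snap_i] < t_event) {
      snapshots[[snap_i]] <<- .bare_summary(c(active, terminal),
                                            time_points[snap_i], events)
      snap_i <<- snap_i + 1L
    }
  }

  repeat {
    total <- sum(act_rate)
    if (total <= 0 || events >= max_events) {
      while (snap_i <= length(time_points)) {
        snapshots[[snap_i]] <- .bare_summary(c(active, terminal),
                                             time_points[snap_i], events)
        snap_i <- snap_i + 1L
      }
      break
    }
    dt <- stats::rexp(1, rate_constant * total)
    take_snaps_up_to(t_now + dt)
    if (snap_i > length(time_points)) break
    t_now <- t_now + dt
    ci <- sample.int(length(active), 1L, prob = act_rate)
    ch <- active[[ci]]
    br <- act_bonds[[ci]]
    pos <- which(br > 0)
    b <- if (length(pos) == 1L) pos else
      pos[sample.int(length(pos), 1L, prob = br[pos])]
    events <- events + 1L
    L <- length(ch$m)
    il <- seq_len(b); ir <- seq(b + 1L, L)
    left <- list(m = ch$m[il], ac = ch$ac[il], a2 = ch$a2[il],
                 a3 = ch$a3[il], u = ch$u)
    right <- list(m = ch$m[ir], ac = ch$ac[ir], a2 = ch$a2[ir],
                  a3 = ch$a3[ir], u = TRUE)  # new Delta-4,5 end
    # replace slot ci with the first non-terminal half, append the other
    filled <- FALSE
    for (h in list(left, right)) {
      hr <- .bond_rates(h$m, h$ac, rule)
      s <- sum(hr)
      if (s <= 0) terminal[[length(terminal) + 1L]] <- h
      else if (!filled) {
        active[[ci]] <- h; act_bonds[[ci]] <- hr; act_rate[ci] <- s
        filled <- TRUE
      } else {
        k <- length(active) + 1L
        active[[k]] <- h; act_bonds[[k]] <- hr; act_rate[k] <- s
      }
    }
    if (!filled) {  # both halves terminal: drop slot ci
      active[[ci]] <- NULL; act_bonds[[ci]] <- NULL
      act_rate <- act_rate[-ci]
    }
  }
  final <- lapply(c(active, terminal), function(b)
    residue_chain(b$m, b$a2, b$a3, unsaturated = b$u))
  structure(list(snapshots = snapshots[!vapply(snapshots, is.null,
                                               logical(1))],
                 final_chains = final,
                 cleavage_count = events),
            class = "pel_digest")
}

#' @export
print.pel_digest <- function(x, ...) {
  cat("pel_digest:", length(x$snapshots), "snapshots,",
      x$cleavage_count, "cleavage events,",
      length(x$final_chains), "final chains\n")
  invisible(x)
}

#' A235 absorbance trace from a digest
#'
#' Beer-Lambert conversion of accumulated 4,5-unsaturated product to
#' absorbance at 235 nm: `A235(t) = epsilon * l * C(t)` with
#' `C(t) = cleavage_count(t) * mol_per_event / volume_L`.
#'
#' @param digest A `pel_digest` (snapshots carry the cleavage counts).
#' @param extinction Molar extinction coefficient (default 5500 1/(M cm),
#'   the 4,5-unsaturated galacturonide value).
#' @param path_cm Optical path length in cm.
#' @param mol_per_event Moles of real product represented by one simulated
#'   cleavage (the simulation-to-assay scale).
#' @param volume_l Reaction volume in litres.
#' @return data.frame `time, cleavages, conc_M, a235`.
#' @export
absorbance_trace <- function(digest, extinction = 5500, path_cm = 1,
                             mol_per_event = 1e-9, volume_l = 1e-3) {
  stopifnot(inherits(digest, "pel_digest"), extinction > 0, path_cm > 0,
            volume_l > 0)
  tm <- vapply(digest$snapshots, `[[`, numeric(1), "time")
  cl <- vapply(digest$snapshots, `[[`, numeric(1), "cleavage_count")
  conc <- cl * mol_per_event / volume_l
  data.frame(time = tm, cleavages = cl, conc_M = conc,
             a235 = extinction * path_cm * conc)
}

#' Synthesize an LC-MS-like peak table from a digest snapshot
#'
#' Unsaturated products within the library DP range are mapped to their
#' compositions; each observed composition yields one positive-mode
#' ammonium-adduct peak (z = 1 below 1100 Da, z = 2 above, mirroring
#' iontrap charge behaviour) with intensity proportional to the molar
#' count times multiplicative lognormal noise of the given CV, and m/z
#' jittered uniformly within +/- `mz_jitter`. Retention time is a
#' deterministic function of composition (PGC-like: later for larger and
#' more substituted compounds). Products outside the library (saturated
#' original-end fragments, DP beyond range, methyl-free compositions) are
#' reported separately, not silently dropped.
#'
#' @param snapshot One element of a `pel_digest`'s `snapshots`.
#' @param library Compound library data.frame ([enumerate_library()]).
#' @param noise_cv Coefficient of variation of the multiplicative intensity
#'   noise (0.09 reproduces the ~9% technical CV of normalized LC-MS
#'   intensities; 0 gives intensities exactly proportional to counts).
#' @param seed Optional integer seed.
#' @param intensity_scale Intensity units per molecule count.
#' @param mz_jitter Half-width of the uniform m/z jitter (Da).
#' @return List with `peaks` (data.frame `mz, rt, intensity, polarity,
#'   charge, true_name`) and `excluded` (composition counts outside the
#'   library).
#' @export
synthesize_peak_table <- function(snapshot, library, noise_cv = 0.09,
                                  seed = NULL, intensity_scale = 1e4,
                                  mz_jitter = 0.1) {
  stopifnot(noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  comps <- snapshot$compositions
  lib_key <- paste(library$dp, library$n_methyl, library$n_acetyl)
  key <- paste(comps$dp, comps$n_methyl, comps$n_acetyl)
  in_lib <- comps$unsaturated & key %in% lib_key
  excl <- comps[!in_lib, , drop = FALSE]
  comps <- comps[in_lib, , drop = FALSE]
  if (nrow(comps) == 0L)
    return(list(peaks = data.frame(mz = numeric(), rt = numeric(),
                                   intensity = numeric(),
                                   polarity = character(),
                                   charge = integer(),
                                   true_name = character()),
                excluded = excl))
  mass <- .mass_rule(comps$dp, comps$n_methyl, comps$n_acetyl, TRUE,
                     "nominal")
  z <- ifelse(mass > 1100, 2L, 1L)
  mz <- (mass + 18 * z) / z
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(nrow(comps), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
  } else noise <- rep(1, nrow(comps))
  rt <- 2 + 2.5 * comps$dp + 0.3 * comps$n_methyl + 0.8 * comps$n_acetyl
  data_mz <- mz + stats::runif(nrow(comps), -mz_jitter, mz_jitter)
  peaks <- data.frame(
    mz = data_mz, rt = rt,
    intensity = intensity_scale * comps$count * noise,
    polarity = "positive", charge = z,
    true_name = mapply(function(d, m, a)
      format_oligo_name(oligo_composition(d, m, a)),
      comps$dp, comps$n_methyl, comps$n_acetyl),
    stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  list(peaks = peaks, excluded = excl)
}
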