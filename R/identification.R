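# Peak-to-compound matching, retention-time isomer grouping, and assembly
# of per-sample compound intensity profiles.

#' Match observed peaks against a compound library
#'
#' Each peak is compared to every (compound, adduct) expectation of matching
#' polarity; candidates within the mass tolerance are retained and the best
#' match is chosen by smallest absolute mass error, ties broken by lower
#' charge, then by higher methyl count, then by name (so the result is
#' invariant under permutation of the library rows).
#'
#' Two tie-break rules deserve comment. Nominal masses carry an exact
#' degeneracy: three methyl esters weigh the same as one acetyl group
#' (3 x 14 = 42 Da), so compositions `(dp, m, a+1)` and `(dp, m+3, a)`
#' cannot be separated by m/z at unit resolution. The higher-methyl
#' preference encodes the lyase-product prior (products of a
#' methyl-requiring enzyme acting on high-DM pectin are predominantly
#' methylated); every within-tolerance alternative is still reported in
#' the `candidates` column and `ambiguous` flags peaks whose best
#' distance is shared by more than one composition, so MS2 evidence can
#' overrule the prior downstream. Similarly, a doubly charged ion of a
#' compound with twice the mass can coincide with a singly charged ion;
#' supplying the `charge` column in the peak table removes that
#' ambiguity.
#'
#' The default tolerance of 0.5 Da suits unit-resolution iontrap data;
#' supply `tol_ppm` instead for high-resolution matching against
#' monoisotopic expectations.
#'
#' @param peaks data.frame with columns `mz`, `rt`, `intensity`, `polarity`
#'   (`"positive"`/`"negative"`) and optionally `charge` (used as a filter
#'   when present and non-NA).
#' @param mz_table Expectation table from [library_mz_table()].
#' @param tol_da Absolute tolerance in Da (default 0.5).
#' @param tol_ppm Optional ppm tolerance; overrides `tol_da` when given.
#' @return List with `matched` (peaks plus `name, adduct, z, expected_mz,
#'   mass_error, ambiguous, candidates`) and `unmatched` (the remaining
#'   peak rows).
#' @export
match_peaks <- function(peaks, mz_table, tol_da = 0.5, tol_ppm = NULL) {
  if (nrow(mz_table) == 0L) stop("empty compound library", call. = FALSE)
  if (!is.null(tol_ppm) && tol_ppm <= 0) stop("tolerance must be > 0")
  if (is.null(tol_ppm) && tol_da <= 0) stop("tolerance must be > 0")
  stopifnot(all(c("mz", "rt", "intensity", "polarity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("negative peak intensity")
  if (is.null(mz_table$n_methyl)) mz_table$n_methyl <- 0L
  mz_table <- mz_table[order(mz_table$name, mz_table$adduct, mz_table$z), ]

  hit_rows <- lapply(seq_len(nrow(peaks)), function(k) {
    p <- peaks[k, ]
    cand <- mz_table[mz_table$polarity == p$polarity, ]
    if (!is.null(p$charge) && !is.na(p$charge))
      cand <- cand[cand$z == p$charge, ]
    err <- p$mz - cand$mz
    tol <- if (is.null(tol_ppm)) tol_da else cand$mz * tol_ppm * 1e-6
    cand <- cand[abs(err) <= tol, ]
    err <- err[abs(err) <= tol]
    if (nrow(cand) == 0L) return(NULL)
    best <- order(abs(err), cand$z, -cand$n_methyl, cand$name)[1]
    tied <- unique(cand$name[abs(abs(err) - abs(err[best])) < 1e-9 &
                               cand$z == cand$z[best]])
    cbind(p, data.frame(name = cand$name[best], adduct = cand$adduct[best],
                        z = cand$z[best], expected_mz = cand$mz[best],
                        mass_error = err[best],
                        ambiguous = length(tied) > 1L,
                        candidates = paste(sort(unique(cand$name)),
                                           collapse = ";"),
                        stringsAsFactors = FALSE))
  })
  ok <- !vapply(hit_rows, is.null, logical(1))
  matched <- if (any(ok)) do.call(rbind, hit_rows[ok]) else
    cbind(peaks[0, ], data.frame(name = character(), adduct = character(),
                                 z = integer(), expected_mz = numeric(),
                                 mass_error = numeric(),
                                 ambiguous = logical(),
                                 candidates = character()))
  rownames(matched) <- NULL
  list(matched = matched, unmatched = peaks[!ok, , drop = FALSE])
}

#' Group retention-time isomers
#'
#' Peaks identified as the same composition but separated in retention time
#' by at least `rt_gap` are distinct structural isomers and receive isomer
#' suffixes in elution order (`#1` earliest, suffix omitted for the first).
#' Peaks of one composition co-eluting within the gap are merged into a
#' single identification with summed intensity (mean rt).
#'
#' @param matched The `matched` table from [match_peaks()].
#' @param rt_gap Minimum retention-time separation (minutes) for calling
#'   two peaks distinct isomers; default 0.5 min (baseline separation on
#'   the porous-graphite column motivates a gap rule).
#' @return data.frame like `matched` with columns `compound` (name with
#'   isomer suffix) and `isomer`; co-eluting rows are merged.
#' @export
group_isomers <- function(matched, rt_gap = 0.5) {
  if (nrow(matched) == 0L) {
    matched$compound <- character(0); matched$isomer <- integer(0)
    return(matched)
  }
  base <- vapply(matched$name, function(nm)
    format_oligo_name(parse_oligo_name(nm)$composition), character(1))
  out <- lapply(split(seq_len(nrow(matched)), base), function(ix) {
    rows <- matched[ix, , drop = FALSE]
    rows <- rows[order(rows$rt), , drop = FALSE]
    # single-linkage gap clustering along rt
    grp <- cumsum(c(1, diff(rows$rt) >= rt_gap))
    merged <- do.call(rbind, lapply(split(seq_len(nrow(rows)), grp),
                                    function(jx) {
      r <- rows[jx[1], , drop = FALSE]
      r$intensity <- sum(rows$intensity[jx])
      r$rt <- mean(rows$rt[jx])
      r
    }))
    comp <- parse_oligo_name(merged$name[1])$composition
    merged$isomer <- seq_len(nrow(merged))
    merged$compound <- vapply(merged$isomer, function(k)
      format_oligo_name(comp, k), character(1))
    merged
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble a per-sample compound intensity profile
#'
#' Every library compound receives an intensity (0 when not observed);
#' multiple adducts or charge states of one compound are summed, so total
#' profile intensity equals total matched peak intensity.
#'
#' @param idents Identifications from [group_isomers()] (or the `matched`
#'   table of [match_peaks()]; isomer grouping is then skipped and plain
#'   names are used).
#' @param library Compound library data.frame (needs a `name` column); the
#'   profile keys are exactly these names.
#' @param enzyme,substrate,time Sample annotation.
#' @return Object of class `sample_profile`: list with `enzyme`,
#'   `substrate`, `time`, and `intensities` (named numeric vector over the
#'   library compounds).
#' @export
build_profile <- function(idents, library, enzyme = NA_character_,
                          substrate = NA_character_, time = NA_real_) {
  key <- if ("compound" %in% names(idents)) idents$compound else idents$name
  intens <- stats::setNames(numeric(nrow(library)), library$name)
  if (length(key)) {
    # isomer labels absent from the library fold back into their base
    # composition (intensities summed), so nothing is silently lost when
    # the library does not enumerate retention-time isomers
    miss <- !key %in% names(intens)
    base <- sub(" #[0-9]+$", "", key[miss])
    key[miss][base %in% names(intens)] <- base[base %in% names(intens)]
    agg <- tapply(idents$intensity, key, sum)
    known <- intersect(names(agg), names(intens))
    intens[known] <- agg[known]
    extra <- setdiff(names(agg), names(intens))
    if (length(extra))
      warning("identifications outside the library dropped from profile: ",
              paste(extra, collapse = ", "))
  }
  structure(list(enzyme = enzyme, substrate = substrate, time = time,
                 intensities = intens),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  nz <- sum(x$intensities > 0)
  cat("sample_profile:", x$enzyme, "/", x$substrate, "/", x$time, "min;",
      nz, "of", length(x$intensities), "compounds observed\n")
  invisible(x)
}
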