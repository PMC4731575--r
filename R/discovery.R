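# Open (delta-mass) modification search: precursor delta computation,
# dual-hypothesis fragment annotation, site localization from shifted /
# unshifted ion brackets, modification-mass refinement preferring low-m/z
# fragments, known-PTM matching, and elemental composition enumeration with
# chemical plausibility filters.

#' Precursor delta mass of a spectrum against an unmodified peptide
#'
#' delta = (precursor m/z - proton) x z - theoretical unmodified neutral mass.
#' A positive delta is read as the total modification mass on the peptide.
#'
#' @param spec A [spectrum()] with known precursor charge.
#' @param peptide Peptide sequence string (or a one-row [digest()] span).
#' @return Delta mass in Da.
#' @export
precursor_delta <- function(spec, peptide) {
  if (is.data.frame(peptide)) peptide <- peptide$sequence
  z <- spec$charge
  if (is.na(z) || z < 1L) stop("precursor charge unknown or zero")
  (spec$pepmass - PROTON_MASS) * z - peptide_mass(peptide)
}

#' Annotate a spectrum against both unshifted and delta-shifted fragments
#'
#' For every theoretical fragment two hypotheses are generated: the
#' unmodified m/z and the m/z shifted by `delta`/z (the fragment carrying the
#' full modification). Matching is a single greedy pass ([match_peaks()])
#' over the union, so each observed peak supports one hypothesis at most.
#'
#' @param spec A [spectrum()].
#' @param peptide Peptide sequence (unmodified).
#' @param delta Precursor delta mass (Da).
#' @param tol_ppm,tol_da Matching tolerances (see [match_peaks()]).
#' @param charges Fragment charges.
#' @param include_internal Also annotate internal ions.
#' @return A list of class `open_annotation`: `matches` (all matched
#'   hypotheses with a `shifted` column), `ion_shifts` (data.frame `mz`,
#'   `shift`: per-ion modification masses from shifted matches),
#'   `n_matched`, `peptide`, `delta`.
#' @export
annotate_open <- function(spec, peptide, delta, tol_ppm = 10, tol_da = 0.01,
                          charges = 1L, include_internal = FALSE) {
  frags <- theoretical_fragments(modified_peptide(peptide), charges = charges,
                                 include_internal = include_internal,
                                 losses = NULL)
  if (abs(delta) > 2 * tol_da) {
    shifted <- frags
    shifted$mz <- shifted$mz + delta / shifted$charge
    both <- rbind(cbind(frags, shifted = FALSE), cbind(shifted, shifted = TRUE))
  } else {
    both <- cbind(frags, shifted = FALSE)   # delta indistinguishable from 0
  }
  # Mask aliased hypotheses: when two theoretical hypotheses lie within each
  # other's match windows a single observed peak cannot arbitrate between
  # them (e.g. a lysine-mass adduct shifting b_i onto unshifted b_(i+1) at a
  # K residue), so neither is allowed to vote.
  if (nrow(both) > 1L) {
    tolv <- pmin(tol_da, both$mz * tol_ppm * 1e-6)
    o <- order(both$mz)
    close_next <- c(diff(both$mz[o]) <= tolv[o][-nrow(both)] + tolv[o][-1],
                    FALSE)
    masked_sorted <- close_next | c(FALSE, close_next[-length(close_next)])
    masked <- logical(nrow(both))
    masked[o] <- masked_sorted
    both <- both[!masked, , drop = FALSE]
  }
  m <- match_peaks(spec, both, tol_ppm = tol_ppm, tol_da = tol_da)
  sh <- m[m$shifted, , drop = FALSE]
  ion_shifts <- data.frame(
    mz = sh$observed_mz,
    shift = delta + sh$error_da * sh$charge
  )
  structure(list(matches = m, ion_shifts = ion_shifts, n_matched = nrow(m),
                 peptide = peptide, delta = delta),
            class = "open_annotation")
}

#' Localize a modification from shifted / unshifted fragment brackets
#'
#' Finds the smallest peptide-local interval (i, j) consistent with the
#' matched ladder: every matched unshifted b-ion pushes the site rightwards,
#' every shifted b-ion caps it, and symmetrically for y-ions; shifted
#' internal ions shrink the interval further, and unshifted internal ions
#' trim it from either side. A fragment matched in both its shifted and
#' unshifted form (or an empty interval) marks the ladder as contradictory:
#' the result is flagged `ambiguous` with the maximal interval, not an error.
#'
#' @param delta Precursor delta mass (context only; recorded in the result).
#' @param ann An `open_annotation` from [annotate_open()], or a data.frame of
#'   matches with columns `series`, `idx`, `from`, `to`, `shifted`.
#' @param peptide Peptide sequence.
#' @return A list of class `localization`: `start`, `end` (peptide-local),
#'   `site_specific`, `ambiguous`, `supporting_b`, `supporting_y`,
#'   `supporting_internal` (counts of matched shifted ions per series).
#' @export
localize_shift <- function(delta, ann, peptide) {
  m <- if (inherits(ann, "open_annotation")) ann$matches else ann
  n <- nchar(peptide)
  lo <- 1L; hi <- n
  ambiguous <- FALSE
  key <- paste(m$series, m$idx, m$from, m$to, m$charge)
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    st <- unique(m$shifted[key == k])
    if (length(st) > 1L) ambiguous <- TRUE   # same ion both shifted & unshifted
  }
  b <- m[m$series == "b", , drop = FALSE]
  y <- m[m$series == "y", , drop = FALSE]
  itn <- m[m$series == "internal", , drop = FALSE]
  bu <- b$idx[!b$shifted]; bs <- b$idx[b$shifted]
  yu <- y$idx[!y$shifted]; ys <- y$idx[y$shifted]
  if (length(bu)) lo <- max(lo, max(bu) + 1L)
  if (length(ys)) lo <- max(lo, n - min(ys) + 1L)
  if (length(bs)) hi <- min(hi, min(bs))
  if (length(yu)) hi <- min(hi, n - max(yu))
  if (nrow(itn)) {
    for (r in which(itn$shifted)) {
      lo <- max(lo, itn$from[r]); hi <- min(hi, itn$to[r])
    }
    for (r in which(!itn$shifted)) {
      i <- itn$from[r]; j <- itn$to[r]
      if (i <= lo && j >= hi) { ambiguous <- TRUE; next }
      if (i <= lo && j >= lo) lo <- j + 1L
      else if (i <= hi && j >= hi) hi <- i - 1L
    }
  }
  if (lo > hi) ambiguous <- TRUE
  if (ambiguous) { lo <- 1L; hi <- n }
  structure(list(
    start = lo, end = hi, delta = delta,
    site_specific = !ambiguous && lo == hi,
    ambiguous = ambiguous,
    supporting_b = sum(b$shifted), supporting_y = sum(y$shifted),
    supporting_internal = if (nrow(itn)) sum(itn$shifted) else 0L
  ), class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  cat(sprintf("<localization> interval (%d, %d)%s%s; b/y/internal support %d/%d/%d\n",
              x$start, x$end,
              if (x$site_specific) " site-specific" else "",
              if (x$ambiguous) " AMBIGUOUS" else "",
              x$supporting_b, x$supporting_y, x$supporting_internal))
  invisible(x)
}

#' Refine a modification mass from per-ion shifts
#'
#' The modification mass is the arithmetic mean of the per-ion modification
#' masses over matched fragments with m/z at or below `mz_cutoff`; Orbitrap
#' resolution increases as m/z decreases, so low-mass fragment ions are
#' preferred. If no ion qualifies the mean over all ions is used.
#'
#' @param obs An `open_annotation`, or a data.frame with columns `mz` and
#'   `shift` (one row per matched shifted ion).
#' @param mz_cutoff m/z threshold (Da) for the low-mass preference.
#' @return A numeric mass (Da) with attribute `n_ions` (count averaged).
#' @export
estimate_mod_mass <- function(obs, mz_cutoff = 800) {
  shifts <- if (inherits(obs, "open_annotation")) obs$ion_shifts else obs
  if (is.null(shifts) || nrow(shifts) == 0L) stop("no ion shifts to average")
  sel <- shifts$mz <= mz_cutoff
  if (!any(sel)) sel <- rep(TRUE, nrow(shifts))
  structure(mean(shifts$shift[sel]), n_ions = sum(sel))
}

#' Match a delta mass against the known-PTM registry
#'
#' @param delta Observed modification mass (Da).
#' @param registry A [mod_registry()].
#' @param residue Residue context (one-letter code or a terminus flag);
#'   `NULL` disables the target filter.
#' @param tol Absolute tolerance (Da), > 0.
#' @return data.frame (`name`, `class`, `mass`, `diff`, `abs_diff`) of
#'   candidates with |registry delta - delta| <= tol whose targets include
#'   `residue`, sorted by |diff| then name. All qualifying candidates are
#'   reported; there is no silent winner-takes-all.
#' @examples
#' match_known_ptms(56.026, default_registry(), "K")  # propionyl
#' @export
match_known_ptms <- function(delta, registry, residue = NULL, tol = 0.01) {
  stopifnot(tol > 0)
  tab <- registry_table(registry)
  d <- tab$mono - delta
  keep <- abs(d) <= tol
  if (!is.null(residue)) {
    tgt <- vapply(registry$mods[tab$name], function(m) residue %in% m$targets,
                  logical(1))
    keep <- keep & tgt
  }
  out <- data.frame(name = tab$name[keep], class = tab$class[keep],
                    mass = tab$mono[keep], diff = -d[keep],
                    abs_diff = abs(d[keep]), stringsAsFactors = FALSE)
  out <- out[order(out$abs_diff, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate elemental compositions for a mass delta
#'
#' Exhaustive bounded search over CHNO (optionally CHNOPS) atom counts with
#' |monoisotopic mass - delta| <= tol, filtered for chemical plausibility:
#' ring-and-double-bond equivalents (RDBE) must be a non-negative integer
#' (half-integer, i.e. odd-electron radical compositions, are excluded
#' unless `allow_radical`), hydrogen count <= 2C + 2 + N (valence cap),
#' element ratios O/C <= `max_o_c` and N/C <= `max_n_c` (applied when C > 0),
#' and at most `n_max` nitrogen atoms (combinations with four or more N are
#' regarded as unrealistic at these masses).
#'
#' @param delta Target mass (Da), > 0.
#' @param tol Absolute tolerance (Da), > 0.
#' @param elements Elements to consider, subset of CHNOPS
#'   (default `c("C","H","N","O")`).
#' @param n_max Maximum nitrogen count (default 3).
#' @param allow_radical Keep half-integer-RDBE compositions (default FALSE).
#' @param max_o_c,max_n_c Ratio caps (defaults 1.2 and 1.3).
#' @return data.frame with one row per candidate: `formula`, `c`, `h`, `n`,
#'   `o`, `p`, `s`, `mass`, `diff`, `abs_diff`, `rdbe`, `radical`; sorted by
#'   |diff|, ties broken by fewer heteroatoms.
#' @examples
#' enumerate_compositions(109.05248, 0.01)  # C6H7NO only
#' @export
enumerate_compositions <- function(delta, tol, elements = c("C", "H", "N", "O"),
                                   n_max = 3L, allow_radical = FALSE,
                                   max_o_c = 1.2, max_n_c = 1.3) {
  if (tol <= 0) stop("tolerance must be > 0")
  stopifnot(delta > 0, all(elements %in% .ELEMENTS))
  hi <- delta + tol
  mC <- .ISO_MONO[["C"]]; mH <- .ISO_MONO[["H"]]; mN <- .ISO_MONO[["N"]]
  mO <- .ISO_MONO[["O"]]; mP <- .ISO_MONO[["P"]]; mS <- .ISO_MONO[["S"]]
  pmax_ <- if ("P" %in% elements) floor(hi / mP) else 0L
  smax_ <- if ("S" %in% elements) floor(hi / mS) else 0L
  cmax_ <- if ("C" %in% elements) floor(hi / mC) else 0L
  nmax_ <- if ("N" %in% elements) min(n_max, floor(hi / mN)) else 0L
  use_h <- "H" %in% elements
  rows <- list()
  for (p in 0:pmax_) for (s in 0:smax_) {
    base_ps <- p * mP + s * mS
    if (base_ps > hi) next
    for (cc in 0:cmax_) {
      base_c <- base_ps + cc * mC
      if (base_c > hi) next
      for (nn in 0:nmax_) {
        base_n <- base_c + nn * mN
        if (base_n > hi) next
        omax_ <- if ("O" %in% elements) floor((hi - base_n) / mO) else 0L
        for (oo in 0:omax_) {
          base <- base_n + oo * mO
          # solve for hydrogen count, try the two nearest integers
          h0 <- if (use_h) round((delta - base) / mH) else 0
          for (hh in unique(pmax(0, c(h0 - 1, h0, h0 + 1)))) {
            if (!use_h && hh > 0) next
            mass <- base + hh * mH
            if (abs(mass - delta) > tol) next
            if (hh > 2 * cc + 2 + nn) next
            if (cc > 0 && (oo > max_o_c * cc || nn > max_n_c * cc)) next
            r <- cc - hh / 2 + nn / 2 + 1
            radical <- (r %% 1) != 0
            if (r < 0) next
            if (radical && !allow_radical) next
            comp <- element_counts(c = cc, h = hh, n = nn, o = oo, p = p, s = s)
            rows[[length(rows) + 1L]] <- data.frame(
              formula = formula_string(comp), c = cc, h = hh, n = nn, o = oo,
              p = p, s = s, mass = mass, diff = mass - delta,
              abs_diff = abs(mass - delta), rdbe = r, radical = radical,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(formula = character(0), c = integer(0), h = integer(0),
                      n = integer(0), o = integer(0), p = integer(0),
                      s = integer(0), mass = numeric(0), diff = numeric(0),
                      abs_diff = numeric(0), rdbe = numeric(0),
                      radical = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$formula), , drop = FALSE]
  out <- out[order(out$abs_diff, out$n + out$o + out$p + out$s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Explain a mass delta as a combination of known modifications
#'
#' Enumerates all multisets of at most `max_mods` registry entries whose
#' summed delta lies within `tol` of the observed delta; used e.g. to explain
#' intact-mass satellite peaks ~190 Da above the main protein peak.
#'
#' @param delta Observed delta (Da).
#' @param registry A [mod_registry()].
#' @param max_mods Maximum number of modifications per combination, >= 1.
#' @param tol Absolute tolerance (Da).
#' @return data.frame (`combo` "+"-joined names, `n_mods`, `mass`, `diff`)
#'   sorted by |diff|; zero rows when nothing fits.
#' @export
suggest_mod_combinations <- function(delta, registry, max_mods = 3L,
                                     tol = 0.5) {
  stopifnot(max_mods >= 1)
  tab <- registry_table(registry)
  nm <- tab$name; ms <- tab$mono
  rows <- list()
  recurse <- function(start, chosen, total) {
    if (length(chosen)) {
      d <- total - delta
      if (abs(d) <= tol)
        rows[[length(rows) + 1L]] <<- data.frame(
          combo = paste(nm[chosen], collapse = "+"),
          n_mods = length(chosen), mass = total, diff = d,
          stringsAsFactors = FALSE)
    }
    if (length(chosen) == max_mods) return()
    for (k in start:length(nm)) {
      if (total + ms[k] > delta + tol && ms[k] > 0) next
      recurse(k, c(chosen, k), total + ms[k])
    }
  }
  recurse(1L, integer(0), 0)
  if (!length(rows))
    return(data.frame(combo = character(0), n_mods = integer(0),
                      mass = numeric(0), diff = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$diff), out$n_mods, out$combo), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a site-specific localization to protein coordinates
#'
#' @param loc A site-specific [localize_shift()] result.
#' @param span One-row data.frame with `start` (Met-inclusive) and `sequence`.
#' @param protein The [protein_record()] the span belongs to.
#' @return A list: `position` (Met-inclusive protein coordinate), `residue`,
#'   `domain` (label from the protein's domain annotations, or `NA`).
#' @export
classify_site <- function(loc, span, protein) {
  if (!isTRUE(loc$site_specific)) stop("interval not site-specific")
  pos <- span$start + loc$start - 1L
  residue <- substr(span$sequence, loc$start, loc$start)
  domain <- NA_character_
  if (!is.null(protein$domains)) {
    hit <- protein$domains$start <= pos & protein$domains$end >= pos
    if (any(hit)) domain <- protein$domains$label[which(hit)[1]]
  }
  list(position = pos, residue = residue, domain = domain)
}
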