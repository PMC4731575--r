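# Theoretical HCD fragment generation: b and y ladders, internal (double
# backbone cleavage) ions, and neutral losses for phospho-class modifications.
# a/c/z series are not generated: HCD spectra of these peptides are described
# by b, y and internal ions.

#' Construct a modified peptide
#'
#' @param sequence Peptide sequence, or a single row of a [digest()] table
#'   (data.frame with `sequence`, `start`, `end`, `protein_id`).
#' @param placements data.frame with columns `position` (peptide-local,
#'   1-based), `name`, `mass` (delta Da) and optionally `class`. At most one
#'   placement per position and class.
#' @param nterm_acetyl Logical; acetylated peptide N-terminus.
#' @return An object of class `modified_peptide`.
#' @export
modified_peptide <- function(sequence, placements = NULL,
                             nterm_acetyl = FALSE) {
  span <- NULL
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    span <- sequence
    sequence <- span$sequence
  }
  aa <- .check_sequence(sequence)
  if (is.null(placements))
    placements <- data.frame(position = integer(0), name = character(0),
                             mass = numeric(0), class = character(0),
                             stringsAsFactors = FALSE)
  if (nrow(placements)) {
    if (is.null(placements$class)) placements$class <- placements$name
    if (any(placements$position < 1L | placements$position > length(aa)))
      stop("placement outside peptide")
    if (anyDuplicated(placements[, c("position", "class")]))
      stop("more than one placement of the same class at a position")
  }
  structure(list(sequence = sequence, placements = placements,
                 nterm_acetyl = isTRUE(nterm_acetyl), span = span),
            class = "modified_peptide")
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(sprintf("<modified_peptide> %s%s, %d modification(s), M = %.5f Da\n",
              if (x$nterm_acetyl) "n(ac)-" else "", x$sequence,
              nrow(x$placements), peptide_mass_mp(x)))
  invisible(x)
}

#' Neutral monoisotopic mass of a modified peptide object
#' @param pep A [modified_peptide()].
#' @export
peptide_mass_mp <- function(pep) {
  peptide_mass(pep$sequence, placements = pep$placements,
               nterm_acetyl = pep$nterm_acetyl)
}

# Neutral-loss channels attached to fragments carrying the named classes.
.DEFAULT_FRAGMENT_LOSSES <- data.frame(
  label = c("H3PO4", "HPO3", "63.96-unassigned"),
  mass = c(97.976896, 79.966331, 63.961901),
  applies_to = c("phospho", "phospho", "phosphoglycerol"),
  stringsAsFactors = FALSE
)
# The 63.96 Da channel matches the mass of SO2 (63.9619 Da) but is annotated
# as unassigned: it could not be attributed to any part of a phosphoglycerol
# group.

#' Theoretical b/y/internal fragment ions of a modified peptide
#'
#' b_i ions carry every modification at positions <= i (plus any N-terminal
#' acetyl); the full-length b_n acylium ion is generated as well. y_k ions
#' carry the modifications within the C-terminal k residues;
#' internal ions (i, j) are the residue-sum + proton (b-type internal,
#' singly charged). For singly charged ions of an n-mer,
#' b_i + y_(n-i) = neutral mass + 2 x proton.
#'
#' @param pep A [modified_peptide()] (or plain sequence string).
#' @param charges Fragment charge states for b/y ions (default 1 and 2).
#' @param include_internal Generate internal ions (only for peptides of >= 5
#'   residues; internal spans are bounded to <= 12 residues and exclude the
#'   terminal residues).
#' @param losses data.frame of neutral-loss channels (`label`, `mass`,
#'   `applies_to` class) applied to fragments carrying a matching
#'   modification class; `NULL` disables losses.
#' @return data.frame with columns `series` ("b", "y", "internal"), `idx`
#'   (ladder index; NA for internal), `from`, `to` (residue coordinates
#'   covered), `charge`, `loss`, `loss_mass`, `mz`, `label`; ordered by
#'   series, index, charge.
#' @examples
#' theoretical_fragments(modified_peptide("AG"), charges = 1)
#' @export
theoretical_fragments <- function(pep, charges = c(1L, 2L),
                                  include_internal = TRUE,
                                  losses = .DEFAULT_FRAGMENT_LOSSES) {
  if (is.character(pep)) pep <- modified_peptide(pep)
  aa <- strsplit(pep$sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) stop("peptide too short to fragment (length < 2)")
  stopifnot(all(charges >= 1L))
  mv <- .residue_vector("mono")
  res <- unname(mv[aa])
  modm <- numeric(n)
  modc <- vector("list", n)
  pl <- pep$placements
  if (nrow(pl)) for (k in seq_len(nrow(pl))) {
    i <- pl$position[k]
    modm[i] <- modm[i] + pl$mass[k]
    modc[[i]] <- c(modc[[i]], pl$class[k])
  }
  ntm <- if (pep$nterm_acetyl) .ACETYL_MONO else 0
  cum <- cumsum(res + modm)
  rows <- list()
  add_row <- function(series, idx, from, to, z, loss, loss_mass, neutral) {
    mz <- (neutral - loss_mass + z * PROTON_MASS) / z
    lab <- paste0(series, if (!is.na(idx)) idx else sprintf("(%d-%d)", from, to),
                  if (z > 1L) paste0("^", z) else "",
                  if (nzchar(loss)) paste0("-", loss) else "")
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, idx = idx, from = from, to = to, charge = z,
      loss = loss, loss_mass = loss_mass, mz = mz, label = lab,
      stringsAsFactors = FALSE)
  }
  loss_rows <- function(classes) {
    if (is.null(losses) || nrow(losses) == 0L) return(data.frame())
    losses[losses$applies_to %in% classes, , drop = FALSE]
  }
  classes_in <- function(from, to) unlist(modc[from:to])
  for (i in seq_len(n)) {               # b ions (incl. the full-length b_n)
    neutral <- cum[i] + ntm             # b fragment neutral = residues + mods
    cls <- classes_in(1L, i)
    ls <- loss_rows(cls)
    for (z in charges) {
      add_row("b", i, 1L, i, as.integer(z), "", 0, neutral)
      if (nrow(ls)) for (r in seq_len(nrow(ls)))
        add_row("b", i, 1L, i, as.integer(z), ls$label[r], ls$mass[r], neutral)
    }
  }
  for (k in seq_len(n - 1L)) {          # y ions
    from <- n - k + 1L
    neutral <- (cum[n] - cum[from - 1L]) + .WATER_MONO
    cls <- classes_in(from, n)
    ls <- loss_rows(cls)
    for (z in charges) {
      add_row("y", k, from, n, as.integer(z), "", 0, neutral)
      if (nrow(ls)) for (r in seq_len(nrow(ls)))
        add_row("y", k, from, n, as.integer(z), ls$label[r], ls$mass[r], neutral)
    }
  }
  if (include_internal && n >= 5L) {    # internal (b-type), singly charged
    for (i in 2:(n - 1L)) {
      for (j in i:min(n - 1L, i + 11L)) {
        neutral <- cum[j] - cum[i - 1L]
        add_row("internal", NA_integer_, i, j, 1L, "", 0, neutral)
      }
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(match(out$series, c("b", "y", "internal")), out$idx, out$from,
               out$to, out$charge, out$loss)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Table of common neutral-loss masses used for interpreting observed losses.
.NEUTRAL_LOSS_TABLE <- data.frame(
  label = c("H2O", "NH3", "H3PO4", "HPO3", "SO2", "CO", "CH2O"),
  mass = c(18.010565, 17.026549, 97.976896, 79.966331, 63.961901,
           27.994915, 30.010565),
  stringsAsFactors = FALSE
)

#' Candidate assignments for an observed neutral-loss mass
#'
#' Matches an observed loss against a small table of common neutral losses
#' (H2O, NH3, H3PO4, HPO3, SO2, CO, CH2O).
#'
#' @param delta Observed neutral-loss mass (Da).
#' @param tol Absolute tolerance (Da), > 0.
#' @return data.frame (`label`, `mass`, `diff`) sorted by |difference|;
#'   possibly empty.
#' @examples
#' neutral_loss_candidates(63.96, 0.01)  # SO2 is the only mass match
#' @export
neutral_loss_candidates <- function(delta, tol = 0.01) {
  stopifnot(tol > 0)
  d <- .NEUTRAL_LOSS_TABLE$mass - delta
  keep <- abs(d) <= tol
  out <- data.frame(label = .NEUTRAL_LOSS_TABLE$label[keep],
                    mass = .NEUTRAL_LOSS_TABLE$mass[keep],
                    diff = d[keep], stringsAsFactors = FALSE)
  out[order(abs(out$diff)), , drop = FALSE]
}
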