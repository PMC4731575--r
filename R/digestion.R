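# In-silico digestion with trypsin, Arg-C, thermolysin and pepsin, plus
# sequence-coverage accounting. Coordinates throughout are 1-based,
# Met-INCLUSIVE: position 1 is the (usually absent) initiator methionine, so
# the mature chain of a Met-removed protein starts at position 2. This is the
# numbering frame in which histone sites such as K70 or T59 are reported.

#' Construct a protein record
#'
#' @param id Protein identifier.
#' @param sequence Mature protein sequence (canonical residues; initiator Met
#'   absent when `met_removed` is `TRUE`).
#' @param description Free-text description.
#' @param met_removed Logical; `TRUE` when the initiator methionine is absent
#'   from `sequence` but still counted in the numbering (offset 2).
#' @param domains Optional data.frame with columns `label`, `start`, `end`
#'   (Met-inclusive coordinates), e.g. NTD/GH1/CTD annotations.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "", met_removed = FALSE,
                           domains = NULL) {
  .check_sequence(sequence)
  offset <- if (met_removed) 2L else 1L
  n_coord <- nchar(sequence) + offset - 1L
  if (!is.null(domains)) {
    stopifnot(all(c("label", "start", "end") %in% names(domains)))
    if (any(domains$start > domains$end) || any(domains$start < 1) ||
        any(domains$end > n_coord))
      stop("domain interval outside [1, ", n_coord, "] or reversed")
  }
  structure(
    list(id = id, description = description, sequence = sequence,
         met_removed = met_removed, numbering_offset = offset,
         domains = domains),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa%s\n", x$id, nchar(x$sequence),
              if (x$met_removed) " (initiator Met removed)" else ""))
  if (!is.null(x$domains))
    cat("  domains:", paste(sprintf("%s:%d-%d", x$domains$label,
                                    x$domains$start, x$domains$end),
                            collapse = " "), "\n")
  invisible(x)
}

# mature index <-> Met-inclusive coordinate
mature_to_coord <- function(protein, i) i + protein$numbering_offset - 1L
coord_to_mature <- function(protein, p) p - protein$numbering_offset + 1L

.PROTEASES <- c("trypsin", "argc", "thermolysin", "pepsin")

# Returns mature-sequence positions i such that cleavage occurs between
# residues i and i+1.
cleavage_sites <- function(sequence, protease, keil = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  cut <- switch(protease,
    trypsin = aa[i] %in% c("K", "R") & !(keil & aa[i + 1L] == "P"),
    argc = aa[i] == "R" & !(keil & aa[i + 1L] == "P"),
    # thermolysin cleaves N-terminal to the hydrophobic residue
    thermolysin = aa[i + 1L] %in% c("L", "I", "A", "F", "V", "M"),
    pepsin = aa[i] %in% c("F", "L"),
    stop("unknown protease: ", protease)
  )
  i[cut]
}

#' Digest a protein in silico
#'
#' Cleavage rules: trypsin cuts C-terminal to K/R (not before P, Keil rule);
#' Arg-C cuts C-terminal to R (not before P); thermolysin cuts N-terminal to
#' L, I, A, F, V, M; pepsin cuts C-terminal to F/L (implemented as strict,
#' although the enzyme is only preferential there). Returns every span with
#' at most `max_missed` internal cleavage sites and a length within bounds,
#' ordered by start then end.
#'
#' @param protein A [protein_record()].
#' @param protease One of `"trypsin"`, `"argc"`, `"thermolysin"`, `"pepsin"`.
#' @param max_missed Maximum internal (missed) cleavage sites, >= 0.
#' @param min_len,max_len Peptide length bounds.
#' @param keil Apply the "not before proline" suppression for trypsin/Arg-C.
#' @return A data.frame of peptide spans with columns `protein_id`, `start`,
#'   `end` (Met-inclusive), `sequence`, `missed_cleavages`, `protease`.
#' @examples
#' p <- protein_record("toy", "AAKAARAA")
#' digest(p, "trypsin", max_missed = 0, min_len = 1, max_len = 50)
#' @export
digest <- function(protein, protease = .PROTEASES, max_missed = 2L,
                   min_len = 5L, max_len = 40L, keil = TRUE) {
  protease <- match.arg(protease)
  stopifnot(max_missed >= 0, min_len >= 1, min_len <= max_len)
  seq <- protein$sequence
  n <- nchar(seq)
  sites <- cleavage_sites(seq, protease, keil = keil)
  bounds <- c(0L, sites, n)  # fragment k spans (bounds[k]+1) .. bounds[k+1]
  nf <- length(bounds) - 1L
  out <- vector("list", 64L)
  cnt <- 0L
  for (a in seq_len(nf)) {
    for (b in a:min(nf, a + max_missed)) {
      st <- bounds[a] + 1L
      en <- bounds[b + 1L]
      len <- en - st + 1L
      if (len < min_len || len > max_len) next
      cnt <- cnt + 1L
      if (cnt > length(out)) out <- c(out, vector("list", length(out)))
      out[[cnt]] <- list(st, en, b - a)
    }
  }
  if (cnt == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed_cleavages = integer(0), protease = character(0),
                      stringsAsFactors = FALSE))
  st <- vapply(out[1:cnt], `[[`, integer(1), 1L)
  en <- vapply(out[1:cnt], `[[`, integer(1), 2L)
  mc <- vapply(out[1:cnt], function(z) as.integer(z[[3L]]), integer(1))
  ord <- order(st, en)
  data.frame(
    protein_id = protein$id,
    start = mature_to_coord(protein, st[ord]),
    end = mature_to_coord(protein, en[ord]),
    sequence = substring(seq, st[ord], en[ord]),
    missed_cleavages = mc[ord],
    protease = protease,
    stringsAsFactors = FALSE
  )
}

#' Sequence coverage of a set of peptide spans
#'
#' @param spans A data.frame of spans as returned by [digest()].
#' @param protein The [protein_record()] the spans belong to.
#' @return Fraction of mature-sequence residues covered by at least one span.
#' @export
coverage <- function(spans, protein) {
  if (nrow(spans) == 0L) return(0)
  if (any(spans$protein_id != protein$id))
    stop("span from foreign protein: ",
         unique(spans$protein_id[spans$protein_id != protein$id])[1])
  n <- nchar(protein$sequence)
  hit <- logical(n)
  st <- coord_to_mature(protein, spans$start)
  en <- coord_to_mature(protein, spans$end)
  if (any(st < 1L) || any(en > n)) stop("span outside protein")
  for (k in seq_along(st)) hit[st[k]:en[k]] <- TRUE
  mean(hit)
}

# --- FASTA I/O -------------------------------------------------------------
# Description lines carry optional key=value tokens:
#   met_removed=true   domain=GH1:61-130   (repeatable)

#' Read protein records from FASTA
#'
#' @param path FASTA file path.
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  lapply(seq_along(aas), function(i) {
    header <- names(aas)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    rest <- toks[-1]
    kv <- grepl("=", rest, fixed = TRUE)
    met_removed <- FALSE
    domains <- NULL
    for (tok in rest[kv]) {
      key <- sub("=.*$", "", tok)
      val <- sub("^[^=]*=", "", tok)
      if (key == "met_removed") {
        met_removed <- tolower(val) %in% c("true", "1", "yes")
      } else if (key == "domain") {
        m <- regmatches(val, regexec("^([^:]+):([0-9]+)-([0-9]+)$", val))[[1]]
        if (length(m) != 4) stop("bad domain token: ", tok)
        domains <- rbind(domains, data.frame(
          label = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
          stringsAsFactors = FALSE))
      }
    }
    protein_record(id, as.character(aas[[i]]),
                   description = paste(rest[!kv], collapse = " "),
                   met_removed = met_removed, domains = domains)
  })
}

#' Write protein records to FASTA
#'
#' @param proteins A list of [protein_record()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  headers <- vapply(proteins, function(p) {
    toks <- p$id
    if (p$met_removed) toks <- c(toks, "met_removed=true")
    if (!is.null(p$domains))
      toks <- c(toks, sprintf("domain=%s:%d-%d", p$domains$label,
                              p$domains$start, p$domains$end))
    if (nzchar(p$description)) toks <- c(toks, p$description)
    paste(toks, collapse = " ")
  }, character(1))
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
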